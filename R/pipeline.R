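#' Default pipeline configuration
#'
#' Full nested configuration for [run_pipeline()]. The `simulate` block maps
#' onto [sim_params()] (minus the seed, which is pipeline-wide); `samples` is
#' the number of replicate library sets drawn from the same transcriptome;
#' `te` controls the synthetic Ribo-Seq block and classification threshold.
#' The packaged defaults form a small demo that runs end-to-end in seconds.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    samples = 2L,
    outdir = "m6amseq_run",
    simulate = list(
      n_transcripts = 60L, depth_per_library = 4e4,
      fragment_length_mean = 30, fragment_length_sd = 5,
      fragment_length_min = 20, ip_enrichment = 5,
      fto_efficiency_m6am = 0.9, fto_efficiency_m6a = 0.05,
      frac_cap_m6am = 0.25, frac_internal_m6a = 0.25,
      stoichiometry = 0.8, cap_window = 0L, length_range = c(250L, 500L)
    ),
    peaks = list(window = 25L, step = 5L, min_fold = 2, min_ip_depth = 5,
                 pseudocount = 0.5, min_depletion = 0.3,
                 max_tss_distance = 100L, m7g_min_fold = 2),
    sites = list(min_score = 0.1, min_site_depth = 10, context_width = 30L,
                 combine = "product"),
    te = list(pseudocount = 0.5, log2_threshold = 1, depth = 2e5,
              log2_tr_modified = 2, sdlog = 0.25)
  )
}

check_keys <- function(given, template, path = "") {
  unknown <- setdiff(names(given), names(template))
  if (length(unknown) > 0)
    stop("config error: unknown key", if (length(unknown) > 1) "s",
         ": ", paste0(path, unknown, collapse = ", "))
  for (k in names(given))
    if (is.list(template[[k]]) && !is.null(names(template[[k]])))
      check_keys(as.list(given[[k]]), template[[k]], paste0(path, k, "."))
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys (at any nesting level) are rejected by name; missing keys are
#' filled from [default_config()].
#'
#' @param config partial configuration list (e.g. from [read_config()]).
#' @return completed configuration.
#' @export
validate_config <- function(config = list()) {
  template <- default_config()
  check_keys(config, template)
  merge_lists <- function(tpl, giv) {
    for (k in names(giv)) {
      tpl[[k]] <- if (is.list(tpl[[k]]) && !is.null(names(tpl[[k]])))
        merge_lists(tpl[[k]], as.list(giv[[k]])) else giv[[k]]
    }
    tpl
  }
  merge_lists(template, config)
}

#' Read / write a pipeline configuration (YAML)
#'
#' @param path YAML file.
#' @export
read_config <- function(path) validate_config(yaml::read_yaml(path))

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

log_msg <- function(...) message("[m6amSeq] ", ...)

#' Run the full m6Am-Seq analysis pipeline
#'
#' simulate -> tracks -> peak calling -> FTO/cap filtering -> site calling ->
#' consensus motif -> translation efficiency -> gene-set integration, with a
#' deterministic directory layout (`truth.tsv`, `transcripts.tsv`,
#' `sequences.fa`, `tracks/`, per-sample `peaks_S.bed` / `sites_S.tsv`,
#' `sites.tsv`, `motif.pfm`, `te.tsv`, `tr.tsv`, `report/`, `MANIFEST`,
#' `config_resolved.yaml`). Identical config + seed give byte-identical
#' outputs. Each stage logs record counts to stderr; on failure the MANIFEST
#' records which stages completed before the error is re-signalled.
#'
#' In the demo TE block, genes carrying a planted cap m6Am receive a positive
#' log2 translation ratio (`te$log2_tr_modified`) under the simulated
#' knockout, so the integration stage recovers them in the overlap set.
#'
#' @param config configuration list (validated via [validate_config()]).
#' @param outdir output directory; overrides `config$outdir` when given.
#' @param seed seed; overrides `config$seed` when given.
#' @return (invisibly) a list with the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         seed = NULL) {
  config <- validate_config(config)
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- as.integer(seed)
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "tracks"), showWarnings = FALSE)

  stages <- c("simulate", "tracks", "callpeaks", "callsites", "motif", "te",
              "integrate")
  done <- character(0)
  manifest <- function(status, failed = NULL) {
    lines <- c(sprintf("%-10s %s", done, "OK"),
               if (!is.null(failed)) sprintf("%-10s FAILED", failed),
               sprintf("%-10s %s", setdiff(stages, c(done, failed)),
                       "NOT_RUN"),
               paste("status", status))
    writeLines(lines, file.path(out, "MANIFEST"))
  }

  result <- tryCatch({
    write_config(config, file.path(out, "config_resolved.yaml"))

    ## simulate ----
    stage <- "simulate"
    simp <- do.call(sim_params, c(config$simulate, list(seed = config$seed)))
    world <- simulate_transcriptome(simp)
    write_transcript_models(world$transcripts, file.path(out, "transcripts.tsv"))
    write_sequences_fasta(world$sequences, file.path(out, "sequences.fa"))
    write_truth(world$truth, file.path(out, "truth.tsv"))
    n_samples <- as.integer(config$samples)
    aligns <- lapply(seq_len(n_samples), function(s) {
      ps <- do.call(sim_params, c(config$simulate,
                                  list(seed = config$seed + 100L * s)))
      a <- simulate_libraries(world$transcripts, world$truth, ps)
      write_alignments(a, file.path(out, sprintf("alignments_%d.tsv.gz", s)))
      a
    })
    log_msg("simulate: ", nrow(world$transcripts), " transcripts, ",
            nrow(world$truth), " truth sites, ", n_samples, " sample(s) x ",
            simp$depth_per_library, " reads/library")
    done <- c(done, stage)

    ## tracks ----
    stage <- "tracks"
    tracks <- lapply(aligns, compute_tracks, transcripts = world$transcripts)
    for (r in tracks[[1]]$roles)
      export_bedgraph(tracks[[1]], r,
                      file.path(out, "tracks", paste0(tolower(r), ".bedgraph")))
    log_msg("tracks: ", length(tracks[[1]]$roles), " libraries per sample")
    done <- c(done, stage)

    ## callpeaks ----
    stage <- "callpeaks"
    pk <- config$peaks
    peaks <- lapply(tracks, function(tr) {
      p <- call_enriched_windows(tr, window = pk$window, step = pk$step,
                                 min_fold = pk$min_fold,
                                 min_ip_depth = pk$min_ip_depth,
                                 pseudocount = pk$pseudocount)
      p <- filter_fto_sensitive(p, tr, min_depletion = pk$min_depletion)
      filter_cap_proximal(p, tr, world$transcripts,
                          max_tss_distance = pk$max_tss_distance,
                          m7g_min_fold = pk$m7g_min_fold,
                          pseudocount = pk$pseudocount)
    })
    for (s in seq_along(peaks))
      export_peaks_bed(peaks[[s]], file.path(out, sprintf("peaks_%d.bed", s)))
    log_msg("callpeaks: ", paste(vapply(peaks, nrow, integer(1)),
                                 collapse = "/"), " filtered peak(s) per sample")
    done <- c(done, stage)

    ## callsites ----
    stage <- "callsites"
    st <- config$sites
    sites <- lapply(seq_along(peaks), function(s)
      call_sites(peaks[[s]], tracks[[s]], world$sequences, world$transcripts,
                 min_score = st$min_score, min_site_depth = st$min_site_depth,
                 context_width = st$context_width, combine = st$combine))
    for (s in seq_along(sites))
      write_sites(sites[[s]], file.path(out, sprintf("sites_%d.tsv", s)))
    write_sites(sites[[1]], file.path(out, "sites.tsv"))
    log_msg("callsites: ", paste(vapply(sites, nrow, integer(1)),
                                 collapse = "/"), " site(s) per sample")
    done <- c(done, stage)

    ## motif ----
    stage <- "motif"
    motif <- consensus_motif(sites[[1]])
    write_pfm(motif, file.path(out, "motif.pfm"))
    write_contexts_fasta(sites[[1]], file.path(out, "contexts.fa"))
    log_msg("motif: consensus over ", motif$n_sites, " site(s)")
    done <- c(done, stage)

    ## te ----
    stage <- "te"
    tec <- config$te
    cap_genes <- world$transcripts$gene_id[
      world$transcripts$transcript_id %in%
        world$truth$transcript_id[world$truth$mod_type == "CAP_M6AM"]]
    l2 <- ifelse(world$transcripts$gene_id %in% cap_genes,
                 tec$log2_tr_modified, 0)
    cnt <- simulate_te_counts(world$transcripts$gene_id, l2,
                              depth = tec$depth, sdlog = tec$sdlog,
                              seed = config$seed + 7L)
    te_ctrl <- compute_te(cnt$fp_ctrl, cnt$rna_ctrl, tec$pseudocount, "control")
    te_cond <- compute_te(cnt$fp_cond, cnt$rna_cond, tec$pseudocount, "condition")
    tr <- translation_ratio(te_cond, te_ctrl, log2_threshold = tec$log2_threshold)
    write_te(rbind(te_ctrl, te_cond), file.path(out, "te.tsv"))
    write_te(tr, file.path(out, "tr.tsv"))
    log_msg("te: ", nrow(tr), " genes classified (",
            sum(tr$te_class == "UP"), " UP, ",
            sum(tr$te_class == "DOWN"), " DOWN)")
    done <- c(done, stage)

    ## integrate ----
    stage <- "integrate"
    shared <- shared_modified_genes(sites)
    te_up <- tr$gene_id[tr$te_class == "UP"]
    report <- overlap_with_te(shared, te_up)
    write_gene_report(report, file.path(out, "report"))
    log_msg("integrate: ", report$n_shared, " shared genes, ",
            report$n_overlap, " overlap TE-up (",
            ifelse(is.na(report$fraction_pct), "NA", report$fraction_pct),
            "%)")
    done <- c(done, stage)

    manifest("COMPLETE")
    invisible(list(config = config, truth = world$truth,
                   transcripts = world$transcripts, peaks = peaks,
                   sites = sites, motif = motif, tr = tr, report = report))
  }, error = function(e) {
    manifest("FAILED", failed = setdiff(stages, done)[1])
    stop(e)
  })
  result
}
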