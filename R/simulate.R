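#' Simulation parameters for a four-library m6Am-Seq experiment
#'
#' Bundles and validates every knob of the synthetic experiment. Defaults
#' describe a desk-scale study: 200 transcripts of 250-500 nt, a quarter
#' carrying a cap m6Am at the transcription start and a quarter an internal
#' m6A in the CDS, 0.8 stoichiometry, 5-fold antibody enrichment, and an FTO
#' treatment that erases 90% of m6Am marks but only 5% of internal m6A -- the
#' selectivity the assay relies on.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param depth_per_library fragments sampled per library.
#' @param fragment_length_mean,fragment_length_sd,fragment_length_min
#'   truncated-normal fragment length model (nt).
#' @param ip_enrichment acceptance weight (fold >= 1) for fragments carrying an
#'   antibody-reactive mark (anti-m6A arms) or the cap (m7G arm).
#' @param fto_efficiency_m6am,fto_efficiency_m6a probability that the FTO
#'   treatment erases a cap m6Am / internal m6A mark before IP.
#' @param frac_cap_m6am,frac_internal_m6a fractions of transcripts carrying
#'   each modification (drawn independently; a transcript may carry both).
#' @param stoichiometry fraction of molecules methylated at a planted site.
#' @param cap_window cap-proximal window (nt): cap sites are planted at
#'   position 0 when 0 (default), otherwise uniformly in `0:cap_window`; the
#'   molecule 5' end follows the site (alternative-TSS model).
#' @param length_range integer range of transcript lengths (nt).
#' @param seed integer seed; all randomness derives from it.
#' @return a validated `sim_params` list.
#' @export
sim_params <- function(n_transcripts = 200L,
                       depth_per_library = 2e5,
                       fragment_length_mean = 30,
                       fragment_length_sd = 5,
                       fragment_length_min = 20,
                       ip_enrichment = 5,
                       fto_efficiency_m6am = 0.9,
                       fto_efficiency_m6a = 0.05,
                       frac_cap_m6am = 0.25,
                       frac_internal_m6a = 0.25,
                       stoichiometry = 0.8,
                       cap_window = 0L,
                       length_range = c(250L, 500L),
                       seed = 1L) {
  p <- list(
    n_transcripts = as.integer(n_transcripts),
    depth_per_library = as.integer(depth_per_library),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    fragment_length_min = fragment_length_min,
    ip_enrichment = ip_enrichment,
    fto_efficiency_m6am = fto_efficiency_m6am,
    fto_efficiency_m6a = fto_efficiency_m6a,
    frac_cap_m6am = frac_cap_m6am,
    frac_internal_m6a = frac_internal_m6a,
    stoichiometry = stoichiometry,
    cap_window = as.integer(cap_window),
    length_range = as.integer(length_range),
    seed = as.integer(seed)
  )
  if (is.na(p$n_transcripts) || p$n_transcripts <= 0L)
    stop("parameter error: n_transcripts must be a positive integer")
  if (p$depth_per_library <= 0L)
    stop("parameter error: depth_per_library must be positive")
  fracs <- c(frac_cap_m6am = p$frac_cap_m6am,
             frac_internal_m6a = p$frac_internal_m6a,
             stoichiometry = p$stoichiometry,
             fto_efficiency_m6am = p$fto_efficiency_m6am,
             fto_efficiency_m6a = p$fto_efficiency_m6a)
  bad <- fracs < 0 | fracs > 1 | is.na(fracs)
  if (any(bad))
    stop("parameter error: ", paste(names(fracs)[bad], collapse = ", "),
         " must lie in [0, 1]")
  if (p$ip_enrichment < 1)
    stop("parameter error: ip_enrichment must be >= 1")
  if (p$fto_efficiency_m6am < p$fto_efficiency_m6a)
    stop("parameter error: fto_efficiency_m6am must be >= fto_efficiency_m6a ",
         "(FTO selectivity for m6Am over m6A)")
  if (p$fragment_length_min < 1 ||
      p$fragment_length_mean < p$fragment_length_min)
    stop("parameter error: invalid fragment length model")
  if (p$cap_window < 0L)
    stop("parameter error: cap_window must be >= 0")
  if (length(p$length_range) != 2L || p$length_range[1] > p$length_range[2] ||
      p$length_range[1] < 200L)
    stop("parameter error: length_range must be increasing and >= 200 nt")
  class(p) <- "sim_params"
  p
}

#' Generate a truth-annotated synthetic transcriptome
#'
#' Draws random transcript models and sequences, then plants modifications:
#' cap m6Am sites at the transcription start (position 0, or within
#' `cap_window`) always on an A and, when the site is offset from position 0,
#' with a C immediately 5' of it (the "CA" cap context); internal m6A sites on
#' adenosines in a planted DRACH-like "GGACT" context, well downstream of the
#' cap (>= 150 nt from the 5' end, inside the CDS).
#'
#' @param params a [sim_params()] object.
#' @return a list with `transcripts` (data.frame: transcript_id, gene_id,
#'   length, utr5_end, cds_end), `sequences` (named character, DNA alphabet)
#'   and `truth` (data.frame: transcript_id, position, mod_type,
#'   stoichiometry; positions 0-based).
#' @export
simulate_transcriptome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_transcripts
  len <- sample(seq(params$length_range[1], params$length_range[2]), n,
                replace = TRUE)
  utr5 <- pmin(sample(50:90, n, replace = TRUE), len %/% 3L)
  cds_end <- len - sample(30:60, n, replace = TRUE)
  cds_end <- pmax(cds_end, utr5 + 30L)

  base_alphabet <- c("A", "C", "G", "T")
  seqs <- vapply(len, function(L)
    paste(sample(base_alphabet, L, replace = TRUE), collapse = ""),
    character(1))
  tid <- sprintf("TX%04d", seq_len(n))
  gid <- sprintf("G%04d", seq_len(n))
  names(seqs) <- tid

  n_cap <- floor(params$frac_cap_m6am * n)
  n_int <- floor(params$frac_internal_m6a * n)
  idx_cap <- sort(sample.int(n, n_cap))
  idx_int <- sort(sample.int(n, n_int))

  cap_pos <- integer(0)
  if (n_cap > 0L) {
    cap_pos <- if (params$cap_window == 0L) rep(0L, n_cap) else
      sample(0:params$cap_window, n_cap, replace = TRUE)
    for (k in seq_len(n_cap)) {
      i <- idx_cap[k]; p0 <- cap_pos[k]
      substr(seqs[i], p0 + 1L, p0 + 1L) <- "A"
      if (p0 > 0L) substr(seqs[i], p0, p0) <- "C"
    }
  }

  int_pos <- integer(0)
  if (n_int > 0L) {
    lo <- pmax(150L, utr5[idx_int] + 1L)
    hi <- pmin(len[idx_int] - 35L, cds_end[idx_int])
    int_pos <- lo + floor(stats::runif(n_int) * (hi - lo + 1L))
    for (k in seq_len(n_int)) {
      i <- idx_int[k]; p0 <- int_pos[k]
      # GGACT with the methylated A at 0-based position p0
      substr(seqs[i], p0 - 1L, p0 + 3L) <- "GGACT"
    }
  }

  truth <- rbind(
    if (n_cap > 0L) data.frame(transcript_id = tid[idx_cap],
                               position = as.integer(cap_pos),
                               mod_type = "CAP_M6AM",
                               stoichiometry = params$stoichiometry,
                               stringsAsFactors = FALSE),
    if (n_int > 0L) data.frame(transcript_id = tid[idx_int],
                               position = as.integer(int_pos),
                               mod_type = "INTERNAL_M6A",
                               stoichiometry = params$stoichiometry,
                               stringsAsFactors = FALSE)
  )
  if (is.null(truth))
    truth <- data.frame(transcript_id = character(0), position = integer(0),
                        mod_type = character(0), stoichiometry = numeric(0),
                        stringsAsFactors = FALSE)
  truth <- truth[order(truth$transcript_id, truth$position), , drop = FALSE]
  rownames(truth) <- NULL

  list(
    transcripts = data.frame(transcript_id = tid, gene_id = gid,
                             length = as.integer(len),
                             utr5_end = as.integer(utr5),
                             cds_end = as.integer(cds_end),
                             stringsAsFactors = FALSE),
    sequences = seqs,
    truth = truth
  )
}

# Truncated-normal fragment lengths, vectorised inverse-CDF draw.
rtrunc_len <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower - 0.5, mean, sd)
  as.integer(pmax(lower, round(
    stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd))))
}

#' Simulate the four m6Am-Seq libraries
#'
#' Fragments each transcript's molecules (one cap-retaining fragment per
#' molecule; interior fragment starts uniform downstream of it), assigns
#' per-molecule methylation at truth sites as Bernoulli(stoichiometry), erases
#' marks in the FTO+ aliquot with type-specific efficiency before IP, and
#' applies IP selection by rejection sampling with acceptance weight
#' `ip_enrichment` for antibody-reactive fragments (anti-m6A arms: any
#' surviving m6Am/m6A mark; m7G arm: cap-retaining fragments) and 1 otherwise.
#' The input library is an unweighted draw.
#'
#' @param transcripts transcript model data.frame from
#'   [simulate_transcriptome()].
#' @param truth truth annotation data.frame (may have zero rows).
#' @param params a [sim_params()] object.
#' @return data.frame of alignment records with columns `library_role`,
#'   `transcript_id`, `start`, `end` (0-based half-open), exactly
#'   `depth_per_library` records per library.
#' @export
simulate_libraries <- function(transcripts, truth, params) {
  stopifnot(inherits(params, "sim_params"))
  if (nrow(truth) > 0) {
    missing_tx <- setdiff(truth$transcript_id, transcripts$transcript_id)
    if (length(missing_tx) > 0)
      stop("reference error: truth refers to unknown transcript(s): ",
           paste(missing_tx, collapse = ", "))
  }
  set.seed(params$seed + 1L)

  n_tx <- nrow(transcripts)
  L <- transcripts$length
  # Molecule 5' end: the cap m6Am position when present, else 0.
  tss <- integer(n_tx)
  cap_rows <- truth[truth$mod_type == "CAP_M6AM", , drop = FALSE]
  if (nrow(cap_rows) > 0) {
    m <- match(cap_rows$transcript_id, transcripts$transcript_id)
    tss[m] <- cap_rows$position
  }
  eff_len <- L - tss
  m_frag <- pmax(1L, as.integer(round(eff_len / params$fragment_length_mean)))

  truth_idx <- if (nrow(truth) > 0)
    match(truth$transcript_id, transcripts$transcript_id) else integer(0)

  E <- params$ip_enrichment
  depth <- params$depth_per_library

  draw_candidates <- function(nc) {
    ti <- sample.int(n_tx, nc, replace = TRUE, prob = m_frag)
    flen <- rtrunc_len(nc, params$fragment_length_mean,
                       params$fragment_length_sd, params$fragment_length_min)
    flen <- pmin(flen, eff_len[ti])
    n_interior <- pmax(0L, L[ti] - tss[ti] - flen)
    capped <- stats::runif(nc) < 1 / m_frag[ti] | n_interior == 0L
    start <- ifelse(capped, tss[ti],
                    tss[ti] + 1L + as.integer(floor(stats::runif(nc) * n_interior)))
    list(ti = ti, start = as.integer(start),
         end = as.integer(start + flen), capped = capped)
  }

  # Antibody reactivity of each candidate fragment in an anti-m6A arm.
  reactive_m6a <- function(cand, fto_treated) {
    r <- logical(length(cand$ti))
    for (j in seq_len(nrow(truth))) {
      txi <- truth_idx[j]
      pos <- truth$position[j]
      hit <- which(cand$ti == txi & cand$start <= pos & pos < cand$end)
      if (length(hit) == 0) next
      meth <- stats::runif(length(hit)) < truth$stoichiometry[j]
      if (fto_treated) {
        eff <- if (truth$mod_type[j] == "CAP_M6AM")
          params$fto_efficiency_m6am else params$fto_efficiency_m6a
        meth <- meth & stats::runif(length(hit)) >= eff
      }
      r[hit[meth]] <- TRUE
    }
    r
  }

  sample_library <- function(role) {
    acc_ti <- integer(0); acc_s <- integer(0); acc_e <- integer(0)
    rate <- if (role == "INPUT" || E == 1) 1 else 1 / E
    while (length(acc_ti) < depth) {
      need <- depth - length(acc_ti)
      nc <- max(1000L, ceiling(need / max(rate, 0.02) * 1.15))
      cand <- draw_candidates(nc)
      keep <- if (role == "INPUT" || E == 1) {
        rep(TRUE, nc)
      } else {
        w <- rep(1, nc)
        if (role == "M7G_IP") {
          w[cand$capped] <- E
        } else {
          w[reactive_m6a(cand, fto_treated = role == "M6A_IP_FTO_PLUS")] <- E
        }
        stats::runif(nc) < w / E
      }
      rate <- max(mean(keep), 0.02)
      acc_ti <- c(acc_ti, cand$ti[keep])
      acc_s <- c(acc_s, cand$start[keep])
      acc_e <- c(acc_e, cand$end[keep])
    }
    data.frame(library_role = role,
               transcript_id = transcripts$transcript_id[acc_ti[seq_len(depth)]],
               start = acc_s[seq_len(depth)],
               end = acc_e[seq_len(depth)],
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(LIBRARY_ROLES, sample_library))
  rownames(out) <- NULL
  out
}

#' Simulate gene-level Ribo-Seq/RNA-Seq count tables with known TE shifts
#'
#' Draws lognormal baseline expression, applies per-gene log2 translation
#' ratios to the condition footprint rates, and samples multinomial counts at
#' the requested depth for the four tables (footprints and RNA in control and
#' condition).
#'
#' When `balance_mass = TRUE` (default) and shifts exist in both directions,
#' the baseline expression of down-shifted genes is rescaled so the total
#' footprint output is conserved between conditions (the ribosome pool is
#' finite). Without such balancing, cpm normalization makes the translation
#' ratio identifiable only up to a global composition factor.
#'
#' @param gene_ids character vector of genes.
#' @param log2_tr true per-gene log2 translation ratio (condition vs control);
#'   recycled to `length(gene_ids)`.
#' @param depth total counts per table.
#' @param sdlog lognormal spread of baseline expression.
#' @param balance_mass conserve total footprint mass between conditions.
#' @param seed integer seed.
#' @return list of four count data.frames (`fp_ctrl`, `fp_cond`, `rna_ctrl`,
#'   `rna_cond`, each gene_id + count) plus the `truth` data.frame.
#' @export
simulate_te_counts <- function(gene_ids = sprintf("G%03d", 1:25),
                               log2_tr = rep(c(-2, -1, 0, 1, 2), length.out = 25),
                               depth = 1e6, sdlog = 0.25, balance_mass = TRUE,
                               seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(gene_ids)
  log2_tr <- rep_len(log2_tr, n)
  rna_rel <- stats::rlnorm(n, 0, sdlog)
  if (balance_mass && any(log2_tr > 0) && any(log2_tr < 0)) {
    up <- log2_tr > 0; dn <- log2_tr < 0
    gain <- sum(rna_rel[up] * (2^log2_tr[up] - 1))
    loss <- sum(rna_rel[dn] * (1 - 2^log2_tr[dn]))
    rna_rel[dn] <- rna_rel[dn] * gain / loss
  }
  fp_ctrl_rel <- rna_rel
  fp_cond_rel <- rna_rel * 2^log2_tr
  draw <- function(rel) {
    cnt <- as.integer(stats::rmultinom(1, size = depth, prob = rel))
    data.frame(gene_id = gene_ids, count = cnt, stringsAsFactors = FALSE)
  }
  list(fp_ctrl = draw(fp_ctrl_rel), fp_cond = draw(fp_cond_rel),
       rna_ctrl = draw(rna_rel), rna_cond = draw(rna_rel),
       truth = data.frame(gene_id = gene_ids, log2_tr = log2_tr,
                          stringsAsFactors = FALSE))
}
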