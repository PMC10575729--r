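site_genes <- function(x) {
  g <- if (is.data.frame(x)) {
    if ("gene_id" %in% names(x)) x$gene_id else x$transcript_id
  } else as.character(x)
  unique(g[!is.na(g)])
}

#' Genes modified in every sample
#'
#' Intersects the per-sample gene sets of site tables (a gene counts once
#' regardless of site multiplicity).
#'
#' @param per_sample_site_tables list of `m6am_sites` data.frames (or plain
#'   gene-id vectors), one per sample.
#' @return character vector of shared gene ids.
#' @export
shared_modified_genes <- function(per_sample_site_tables) {
  stopifnot(length(per_sample_site_tables) >= 1)
  Reduce(intersect, lapply(per_sample_site_tables, site_genes))
}

#' Overlap of shared modified genes with translationally changed genes
#'
#' @param shared character vector of genes modified in all samples.
#' @param te_changed character vector of translationally changed genes.
#' @return an `m6am_gene_report`: the two sets, their overlap, counts, and the
#'   percentage fraction |overlap|/|shared| (1 decimal place; NA sentinel when
#'   the shared set is empty).
#' @export
overlap_with_te <- function(shared, te_changed) {
  shared <- unique(as.character(shared))
  te_changed <- unique(as.character(te_changed))
  ov <- intersect(shared, te_changed)
  frac <- if (length(shared) == 0) NA_real_ else
    round(100 * length(ov) / length(shared), 1)
  structure(list(shared_genes = shared, te_changed_genes = te_changed,
                 overlap_genes = ov,
                 n_shared = length(shared), n_te_changed = length(te_changed),
                 n_overlap = length(ov), fraction_pct = frac),
            class = "m6am_gene_report")
}

#' Two-set Venn partition
#'
#' @param a,b sets (character vectors; duplicates ignored).
#' @return named integer vector `(only_a, only_b, both)`.
#' @export
venn_counts <- function(a, b) {
  a <- unique(a); b <- unique(b)
  both <- length(intersect(a, b))
  c(only_a = length(a) - both, only_b = length(b) - both, both = both)
}

#' @export
print.m6am_gene_report <- function(x, ...) {
  cat("m6am gene-set report\n")
  cat("  shared modified genes :", x$n_shared, "\n")
  cat("  TE-changed genes      :", x$n_te_changed, "\n")
  cat("  overlap               :", x$n_overlap, "\n")
  cat("  fraction of shared    :",
      if (is.na(x$fraction_pct)) "undefined (empty shared set)" else
        paste0(x$fraction_pct, "%"), "\n")
  invisible(x)
}

#' Write a gene-set report to a directory
#'
#' Emits `report.tsv` (counts and fraction), `summary.txt` (human-readable)
#' and one-ID-per-line gene lists for the shared, TE-changed and overlap sets.
#'
#' @param report an `m6am_gene_report`.
#' @param dir output directory (created if needed).
#' @export
write_gene_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(n_shared = report$n_shared,
                       n_te_changed = report$n_te_changed,
                       n_overlap = report$n_overlap,
                       fraction_pct = report$fraction_pct),
            file.path(dir, "report.tsv"))
  writeLines(c(
    "m6Am gene-set integration",
    sprintf("shared modified genes : %d", report$n_shared),
    sprintf("TE-changed genes      : %d", report$n_te_changed),
    sprintf("overlap               : %d", report$n_overlap),
    sprintf("fraction of shared    : %s",
            if (is.na(report$fraction_pct)) "undefined" else
              paste0(report$fraction_pct, "%"))),
    file.path(dir, "summary.txt"))
  writeLines(sort(report$shared_genes), file.path(dir, "shared_genes.txt"))
  writeLines(sort(report$te_changed_genes),
             file.path(dir, "te_changed_genes.txt"))
  writeLines(sort(report$overlap_genes), file.path(dir, "overlap_genes.txt"))
  invisible(dir)
}
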