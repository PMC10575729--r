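as_count_table <- function(x, what) {
  if (is.data.frame(x)) {
    stopifnot(all(c("gene_id", "count") %in% names(x)))
    stats::setNames(as.numeric(x$count), x$gene_id)
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else stop("input error: ", what,
              " must be a data.frame(gene_id, count) or a named numeric")
}

#' Translation efficiency from footprint and RNA counts
#'
#' TE = (footprint CDS cpm + pc) / (RNA cpm + pc) per gene. Genes missing
#' from either table are dropped (a message reports how many). Negative
#' counts are rejected; a zero-total library is a normalization error.
#'
#' @param footprint_counts Ribo-Seq CDS counts: data.frame(gene_id, count) or
#'   named numeric.
#' @param rna_counts matched RNA-Seq counts.
#' @param pseudocount cpm pseudocount applied to both terms.
#' @param condition label stored with the result.
#' @return data.frame: gene_id, footprint_cds_count, rna_count, te, condition.
#' @export
compute_te <- function(footprint_counts, rna_counts, pseudocount = 0.5,
                       condition = "condition") {
  fp <- as_count_table(footprint_counts, "footprint_counts")
  rna <- as_count_table(rna_counts, "rna_counts")
  if (any(fp < 0) || any(rna < 0))
    stop("input error: counts must be >= 0")
  if (sum(fp) == 0 || sum(rna) == 0)
    stop("normalization error: a count table has zero total counts")
  genes <- intersect(names(fp), names(rna))
  dropped <- length(union(names(fp), names(rna))) - length(genes)
  if (dropped > 0)
    message("compute_te: dropped ", dropped,
            " gene(s) missing from one table")
  fp <- fp[genes]; rna <- rna[genes]
  fp_cpm <- fp * 1e6 / sum(fp)
  rna_cpm <- rna * 1e6 / sum(rna)
  data.frame(gene_id = genes,
             footprint_cds_count = as.integer(round(fp)),
             rna_count = as.integer(round(rna)),
             te = (fp_cpm + pseudocount) / (rna_cpm + pseudocount),
             condition = condition,
             stringsAsFactors = FALSE)
}

#' Translation ratio and translational-change classification
#'
#' TR = TE_condition / TE_control per gene. A gene is DOWN when
#' log2(TR) <= -`log2_threshold` (the conventional reading of a "1-fold
#' decrease", i.e. halving, with an inclusive boundary), UP when
#' log2(TR) >= +`log2_threshold` (symmetric rule), else UNCHANGED. Genes with
#' TE_control = 0 are excluded (a message reports how many).
#'
#' @param te_cond,te_ctrl outputs of [compute_te()] for condition and control.
#' @param log2_threshold classification boundary on the log2 scale.
#' @return data.frame: gene_id, tr, log2_tr, te_class.
#' @export
translation_ratio <- function(te_cond, te_ctrl, log2_threshold = 1) {
  genes <- intersect(te_cond$gene_id, te_ctrl$gene_id)
  tc <- te_cond$te[match(genes, te_cond$gene_id)]
  t0 <- te_ctrl$te[match(genes, te_ctrl$gene_id)]
  zero <- t0 == 0
  if (any(zero))
    message("translation_ratio: excluded ", sum(zero),
            " gene(s) with zero control TE")
  genes <- genes[!zero]; tc <- tc[!zero]; t0 <- t0[!zero]
  tr <- tc / t0
  l2 <- log2(tr)
  cls <- ifelse(l2 <= -log2_threshold, "DOWN",
                ifelse(l2 >= log2_threshold, "UP", "UNCHANGED"))
  data.frame(gene_id = genes, tr = tr, log2_tr = l2, te_class = cls,
             stringsAsFactors = FALSE)
}

#' @rdname read_counts
#' @param te_table a TE or TR data.frame.
#' @export
write_te <- function(te_table, path) write_tsv(te_table, path)
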