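#' Per-nucleotide m6Am scoring
#'
#' Computes the two statistics behind single-base m6Am calling and their
#' combination: m1 = (FTO- start reads)/(FTO- depth), the fraction of
#' untreated IP fragments whose 5' end sits exactly at the position (the cap
#' signature), and m2 = (FTO- depth - FTO+ depth)/(FTO- depth) on
#' cpm-normalized depths, clamped to [0, 1] (demethylation sensitivity). Both
#' are defined as 0 at zero depth. The combined score is m1 x m2 by default
#' (high only where the position is both a dominant fragment start and
#' FTO-sensitive); `"min"` and `"mean"` combiners are selectable.
#'
#' @param start_fto_minus raw FTO- start-read count(s).
#' @param depth_fto_minus raw FTO- depth(s); must be >= the start counts.
#' @param depth_fto_plus_norm,depth_fto_minus_norm cpm-normalized depths.
#' @param combine combination rule: "product" (default), "min" or "mean".
#' @return data.frame with columns m1, m2, score (vectorized).
#' @export
score_position <- function(start_fto_minus, depth_fto_minus,
                           depth_fto_plus_norm, depth_fto_minus_norm,
                           combine = c("product", "min", "mean")) {
  combine <- match.arg(combine)
  n <- max(length(start_fto_minus), length(depth_fto_minus),
           length(depth_fto_plus_norm), length(depth_fto_minus_norm))
  start_fto_minus <- rep_len(start_fto_minus, n)
  depth_fto_minus <- rep_len(depth_fto_minus, n)
  depth_fto_plus_norm <- rep_len(depth_fto_plus_norm, n)
  depth_fto_minus_norm <- rep_len(depth_fto_minus_norm, n)
  if (any(start_fto_minus < 0) || any(depth_fto_minus < 0) ||
      any(depth_fto_plus_norm < 0) || any(depth_fto_minus_norm < 0))
    stop("data-consistency error: negative counts or depths")
  if (any(start_fto_minus > depth_fto_minus))
    stop("data-consistency error: start reads exceed depth")
  m1 <- ifelse(depth_fto_minus == 0, 0, start_fto_minus / depth_fto_minus)
  m2 <- ifelse(depth_fto_minus_norm == 0, 0,
               (depth_fto_minus_norm - depth_fto_plus_norm) /
                 depth_fto_minus_norm)
  m2 <- pmin(1, pmax(0, m2))
  score <- switch(combine,
                  product = m1 * m2,
                  min = pmin(m1, m2),
                  mean = (m1 + m2) / 2)
  data.frame(m1 = m1, m2 = m2, score = score)
}

empty_sites <- function() {
  s <- data.frame(transcript_id = character(0), gene_id = character(0),
                  position = integer(0), base = character(0),
                  m1 = numeric(0), m2 = numeric(0), score = numeric(0),
                  context = character(0), stringsAsFactors = FALSE)
  class(s) <- c("m6am_sites", "data.frame")
  s
}

# Site-centered context of `width` nt; the site occupies 0-based offset
# floor(width/2); transcript edges padded with N.
extract_context <- function(seq, pos, width) {
  off <- width %/% 2L
  lo <- pos - off            # 0-based inclusive
  hi <- pos + (width - off - 1L)
  L <- nchar(seq)
  left_pad <- max(0L, -lo)
  right_pad <- max(0L, hi - (L - 1L))
  core <- substr(seq, max(0L, lo) + 1L, min(L - 1L, hi) + 1L)
  paste0(strrep("N", left_pad), core, strrep("N", right_pad))
}

#' Call single-base m6Am sites within candidate peaks
#'
#' Scores every adenosine inside every peak whose raw FTO- depth reaches
#' `min_site_depth`, using [score_position()], and emits positions whose
#' combined score reaches `min_score`, with a site-centered sequence context
#' (N-padded at transcript edges). Scoring is strictly local to the peaks.
#'
#' @param peaks filtered `m6am_peaks` (both FTO arms must be in `tracks`).
#' @param tracks an `m6am_tracks` object.
#' @param sequences named character vector (or DNAStringSet) of transcript
#'   sequences covering all peak transcripts.
#' @param transcripts optional transcript models supplying gene ids.
#' @param min_score minimal combined score.
#' @param min_site_depth minimal raw FTO- depth at the position.
#' @param context_width context width in nt (default 30).
#' @param combine score combination rule, see [score_position()].
#' @return an `m6am_sites` data.frame sorted by (transcript_id, position).
#' @export
call_sites <- function(peaks, tracks, sequences, transcripts = NULL,
                       min_score = 0.1, min_site_depth = 10,
                       context_width = 30L,
                       combine = c("product", "min", "mean")) {
  combine <- match.arg(combine)
  require_roles(tracks, c("M6A_IP_FTO_MINUS", "M6A_IP_FTO_PLUS"))
  if (methods::is(sequences, "DNAStringSet")) {
    nm <- names(sequences); sequences <- as.character(sequences)
    names(sequences) <- sub("\\s.*$", "", nm)
  }
  if (nrow(peaks) == 0) return(empty_sites())
  ptx <- unique(peaks$transcript_id)
  miss <- setdiff(ptx, names(sequences))
  if (length(miss) > 0)
    stop("reference error: no sequence for transcript(s): ",
         paste(miss, collapse = ", "))
  short <- ptx[nchar(sequences[ptx]) < tracks$length[ptx]]
  if (length(short) > 0)
    stop("reference error: sequence shorter than transcript model for: ",
         paste(short, collapse = ", "))

  dm_cpm <- normalize_depth(tracks, "M6A_IP_FTO_MINUS", "cpm")
  dp_cpm <- normalize_depth(tracks, "M6A_IP_FTO_PLUS", "cpm")
  gene_of <- function(t) {
    if (is.null(transcripts)) return(NA_character_)
    g <- transcripts$gene_id[match(t, transcripts$transcript_id)]
    if (length(g) == 0) NA_character_ else g
  }

  res <- list()
  for (i in seq_len(nrow(peaks))) {
    t <- peaks$transcript_id[i]
    pos <- peaks$start[i]:(peaks$end[i] - 1L)
    base <- toupper(substring(sequences[[t]], pos + 1L, pos + 1L))
    draw <- tracks$depth[["M6A_IP_FTO_MINUS"]][[t]][pos + 1L]
    ok <- base == "A" & draw >= min_site_depth
    if (!any(ok)) next
    pos <- pos[ok]
    sc <- score_position(tracks$start_count[["M6A_IP_FTO_MINUS"]][[t]][pos + 1L],
                         tracks$depth[["M6A_IP_FTO_MINUS"]][[t]][pos + 1L],
                         dp_cpm[[t]][pos + 1L], dm_cpm[[t]][pos + 1L],
                         combine = combine)
    hit <- sc$score >= min_score
    if (!any(hit)) next
    pos <- pos[hit]
    res[[length(res) + 1L]] <- data.frame(
      transcript_id = t, gene_id = gene_of(t), position = pos, base = "A",
      m1 = sc$m1[hit], m2 = sc$m2[hit], score = sc$score[hit],
      context = vapply(pos, function(p)
        extract_context(sequences[[t]], p, as.integer(context_width)),
        character(1)),
      stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty_sites())
  out <- do.call(rbind, res)
  out <- out[!duplicated(paste(out$transcript_id, out$position)), , drop = FALSE]
  out <- out[order(out$transcript_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("m6am_sites", "data.frame")
  out
}

#' @export
print.m6am_sites <- function(x, ...) {
  cat("m6am_sites:", nrow(x), "site(s) on",
      length(unique(x$transcript_id)), "transcript(s)\n")
  if (nrow(x) > 0)
    print.data.frame(utils::head(x[, setdiff(names(x), "context")], 10))
  invisible(x)
}

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                 ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Position frequency matrix and IUPAC consensus from site contexts
#'
#' Tallies base frequencies per context column over non-N characters (U is
#' counted as T) and derives a per-column IUPAC consensus covering every base
#' with frequency >= 0.25. Columns consisting only of N (e.g. upstream of a
#' position-0 site) are reported as NA frequencies with consensus "N". An
#' empty site list yields an empty-summary sentinel (n_sites = 0).
#'
#' @param sites an `m6am_sites` data.frame with equal-width contexts.
#' @param min_freq inclusion threshold for the consensus (default 0.25).
#' @return an `m6am_motif` list: `pfm` (4 x width), `consensus` (IUPAC
#'   string), `n_sites`.
#' @export
consensus_motif <- function(sites, min_freq = 0.25) {
  bases <- c("A", "C", "G", "T")
  if (nrow(sites) == 0) {
    return(structure(list(pfm = matrix(numeric(0), nrow = 4, ncol = 0,
                                       dimnames = list(bases, NULL)),
                          consensus = "", n_sites = 0L),
                     class = "m6am_motif"))
  }
  widths <- unique(nchar(sites$context))
  if (length(widths) != 1)
    stop("input error: contexts have unequal widths")
  W <- widths
  mat <- matrix(unlist(strsplit(toupper(sites$context), "")), nrow = W)
  mat[mat == "U"] <- "T"
  pfm <- matrix(NA_real_, nrow = 4, ncol = W, dimnames = list(bases, NULL))
  consensus <- character(W)
  for (j in seq_len(W)) {
    col <- mat[j, ]
    col <- col[col %in% bases]
    if (length(col) == 0) { consensus[j] <- "N"; next }
    f <- table(factor(col, levels = bases)) / length(col)
    pfm[, j] <- as.numeric(f)
    inc <- bases[f >= min_freq]
    if (length(inc) == 0) inc <- bases[which.max(f)]
    consensus[j] <- IUPAC_CODES[[paste(inc, collapse = "")]]
  }
  structure(list(pfm = pfm, consensus = paste(consensus, collapse = ""),
                 n_sites = nrow(sites)),
            class = "m6am_motif")
}

#' @export
print.m6am_motif <- function(x, ...) {
  cat("m6am_motif over", x$n_sites, "site(s)\n")
  cat("consensus:", x$consensus, "\n")
  invisible(x)
}
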