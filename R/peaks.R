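empty_peaks <- function() {
  p <- data.frame(transcript_id = character(0), start = integer(0),
                  end = integer(0), summit = integer(0),
                  enrichment = numeric(0), fto_depletion = numeric(0),
                  cap_proximal = logical(0), stringsAsFactors = FALSE)
  class(p) <- c("m6am_peaks", "data.frame")
  p
}

# Mean of a track over [start, end) via precomputed cumsum (cs = c(0, cumsum)).
interval_mean <- function(cs, start, end) (cs[end + 1L] - cs[start + 1L]) / (end - start)

#' Call IP-enriched windows
#'
#' Slides fixed-width windows along every transcript and keeps those where the
#' cpm-normalized anti-m6A (FTO-) depth exceeds the input by at least
#' `min_fold` (symmetric pseudocount on both means) and the raw IP depth
#' averages at least `min_ip_depth`. Kept windows that overlap or abut are
#' merged; the summit (position of maximal FTO- IP normalized depth, ties to
#' the smallest coordinate) and the enrichment are recomputed on the merged
#' interval. `fto_depletion` and `cap_proximal` are left NA for the downstream
#' filters.
#'
#' @param tracks an `m6am_tracks` object containing INPUT and
#'   M6A_IP_FTO_MINUS.
#' @param window,step window width and step (nt).
#' @param min_fold minimum (IP cpm + pc)/(input cpm + pc) fold.
#' @param min_ip_depth minimum mean raw IP depth in a window.
#' @param pseudocount cpm pseudocount applied to both means.
#' @return an `m6am_peaks` data.frame sorted by (transcript_id, start).
#' @export
call_enriched_windows <- function(tracks, window = 25L, step = 5L,
                                  min_fold = 2, min_ip_depth = 5,
                                  pseudocount = 0.5) {
  stopifnot(window >= 1L, step >= 1L)
  require_roles(tracks, c("INPUT", "M6A_IP_FTO_MINUS"))
  ip_cpm <- normalize_depth(tracks, "M6A_IP_FTO_MINUS", "cpm")
  in_cpm <- normalize_depth(tracks, "INPUT", "cpm")

  res <- list()
  for (t in tracks$transcript_id) {
    L <- tracks$length[[t]]
    ipc <- c(0, cumsum(ip_cpm[[t]]))
    inc <- c(0, cumsum(in_cpm[[t]]))
    ipr <- c(0, cumsum(tracks$depth[["M6A_IP_FTO_MINUS"]][[t]]))
    w <- min(window, L)
    starts <- if (L <= window) 0L else
      unique(c(seq(0L, L - w, by = step), L - w))
    ends <- starts + w
    fold <- (interval_mean(ipc, starts, ends) + pseudocount) /
      (interval_mean(inc, starts, ends) + pseudocount)
    keep <- fold >= min_fold & interval_mean(ipr, starts, ends) >= min_ip_depth
    if (!any(keep)) next
    merged <- IRanges::reduce(IRanges::IRanges(start = starts[keep] + 1L,
                                               end = ends[keep]))
    ms <- IRanges::start(merged) - 1L
    me <- IRanges::end(merged)
    summit <- integer(length(ms)); enr <- numeric(length(ms))
    for (i in seq_along(ms)) {
      seg <- ip_cpm[[t]][(ms[i] + 1L):me[i]]
      summit[i] <- ms[i] + which.max(seg) - 1L
      enr[i] <- (interval_mean(ipc, ms[i], me[i]) + pseudocount) /
        (interval_mean(inc, ms[i], me[i]) + pseudocount)
    }
    res[[t]] <- data.frame(transcript_id = t, start = ms, end = me,
                           summit = summit, enrichment = enr,
                           fto_depletion = NA_real_, cap_proximal = NA,
                           stringsAsFactors = FALSE)
  }
  if (length(res) == 0) return(empty_peaks())
  out <- do.call(rbind, res)
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("m6am_peaks", "data.frame")
  out
}

#' Filter peaks on FTO sensitivity
#'
#' Populates `fto_depletion` = 1 - (mean FTO+ cpm depth)/(mean FTO- cpm depth)
#' over each peak, clamped to [0, 1] (0 when the FTO- mean is 0), and retains
#' peaks with depletion >= `min_depletion`.
#'
#' @param peaks an `m6am_peaks` data.frame.
#' @param tracks tracks containing both FTO arms.
#' @param min_depletion retention threshold in [0, 1].
#' @return the filtered peaks with `fto_depletion` populated.
#' @export
filter_fto_sensitive <- function(peaks, tracks, min_depletion = 0.3) {
  require_roles(tracks, c("M6A_IP_FTO_MINUS", "M6A_IP_FTO_PLUS"))
  if (nrow(peaks) == 0) return(peaks)
  dm <- normalize_depth(tracks, "M6A_IP_FTO_MINUS", "cpm")
  dp <- normalize_depth(tracks, "M6A_IP_FTO_PLUS", "cpm")
  dep <- vapply(seq_len(nrow(peaks)), function(i) {
    t <- peaks$transcript_id[i]
    idx <- (peaks$start[i] + 1L):peaks$end[i]
    mminus <- mean(dm[[t]][idx]); mplus <- mean(dp[[t]][idx])
    if (mminus == 0) return(0)
    min(1, max(0, 1 - mplus / mminus))
  }, numeric(1))
  peaks$fto_depletion <- dep
  out <- peaks[dep >= min_depletion, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter peaks to cap-proximal candidates
#'
#' A peak is cap-proximal when its summit lies within `max_tss_distance` of
#' the transcript 5' end and, if an m7G-IP track is available, the m7G-IP over
#' input enrichment within the peak reaches `m7g_min_fold`. Without an m7G
#' library the distance test alone applies (a message is logged).
#'
#' @param peaks an `m6am_peaks` data.frame carrying summits.
#' @param tracks an `m6am_tracks` object (INPUT required; M7G_IP optional).
#' @param transcripts transcript models (unused beyond validation; kept for
#'   interface symmetry).
#' @param max_tss_distance maximal summit distance from position 0 (nt).
#' @param m7g_min_fold minimal m7G-IP/input cpm fold within the peak.
#' @param pseudocount cpm pseudocount for the m7G fold.
#' @return the retained peaks with `cap_proximal` populated.
#' @export
filter_cap_proximal <- function(peaks, tracks, transcripts = NULL,
                                max_tss_distance = 100L, m7g_min_fold = 2,
                                pseudocount = 0.5) {
  if (nrow(peaks) == 0) return(peaks)
  has_m7g <- "M7G_IP" %in% tracks$roles
  if (!has_m7g)
    message("filter_cap_proximal: no M7G_IP library; using the TSS-distance ",
            "test alone")
  near <- peaks$summit <= max_tss_distance
  if (has_m7g) {
    require_roles(tracks, "INPUT")
    g_cpm <- normalize_depth(tracks, "M7G_IP", "cpm")
    in_cpm <- normalize_depth(tracks, "INPUT", "cpm")
    m7g_ok <- vapply(seq_len(nrow(peaks)), function(i) {
      t <- peaks$transcript_id[i]
      idx <- (peaks$start[i] + 1L):peaks$end[i]
      fold <- (mean(g_cpm[[t]][idx]) + pseudocount) /
        (mean(in_cpm[[t]][idx]) + pseudocount)
      fold >= m7g_min_fold
    }, logical(1))
    peaks$cap_proximal <- near & m7g_ok
  } else {
    peaks$cap_proximal <- near
  }
  out <- peaks[peaks$cap_proximal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.m6am_peaks <- function(x, ...) {
  cat("m6am_peaks:", nrow(x), "peak(s) on",
      length(unique(x$transcript_id)), "transcript(s)\n")
  if (nrow(x) > 0) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
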