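#' Run one simulated experiment and measure site recovery against truth
#'
#' Convenience wrapper for self-validation: simulates a transcriptome and the
#' four libraries under `params`, runs track building, peak calling, both
#' peak filters and site calling at the supplied thresholds, and scores the
#' calls against the planted truth.
#'
#' @param params a [sim_params()] object.
#' @param peaks named list overriding [call_enriched_windows()] /
#'   filter arguments (window, step, min_fold, min_ip_depth, pseudocount,
#'   min_depletion, max_tss_distance, m7g_min_fold).
#' @param sites named list overriding [call_sites()] arguments (min_score,
#'   min_site_depth, context_width, combine).
#' @return list with the `sites` table, filtered `peaks`, `n_peaks_raw`, the
#'   `truth` table and `metrics`: n_cap, n_cap_recovered (gene-level),
#'   n_exact (recovered transcripts whose top-scoring call is at the truth
#'   position), n_internal, n_internal_called (internal truth positions
#'   present among calls).
#' @export
run_site_recovery <- function(params, peaks = list(), sites = list()) {
  pk_cfg <- utils::modifyList(
    list(window = 25L, step = 5L, min_fold = 2, min_ip_depth = 5,
         pseudocount = 0.5, min_depletion = 0.3, max_tss_distance = 100L,
         m7g_min_fold = 2), peaks)
  st_cfg <- utils::modifyList(
    list(min_score = 0.1, min_site_depth = 10, context_width = 30L,
         combine = "product"), sites)

  w <- simulate_transcriptome(params)
  a <- simulate_libraries(w$transcripts, w$truth, params)
  tr <- compute_tracks(a, w$transcripts)
  p0 <- call_enriched_windows(tr, pk_cfg$window, pk_cfg$step, pk_cfg$min_fold,
                              pk_cfg$min_ip_depth, pk_cfg$pseudocount)
  p1 <- filter_fto_sensitive(p0, tr, pk_cfg$min_depletion)
  p2 <- filter_cap_proximal(p1, tr, w$transcripts, pk_cfg$max_tss_distance,
                            pk_cfg$m7g_min_fold, pk_cfg$pseudocount)
  s <- call_sites(p2, tr, w$sequences, w$transcripts, st_cfg$min_score,
                  st_cfg$min_site_depth, st_cfg$context_width, st_cfg$combine)

  cap <- w$truth[w$truth$mod_type == "CAP_M6AM", , drop = FALSE]
  int <- w$truth[w$truth$mod_type == "INTERNAL_M6A", , drop = FALSE]
  recovered_tx <- intersect(cap$transcript_id, s$transcript_id)
  top_call <- vapply(split(s, s$transcript_id),
                     function(d) d$position[which.max(d$score)], integer(1))
  n_exact <- sum(cap$position[match(names(top_call), cap$transcript_id)] ==
                   top_call, na.rm = TRUE)
  key <- function(d) paste(d$transcript_id, d$position)
  list(sites = s, peaks = p2, n_peaks_raw = nrow(p0), truth = w$truth,
       metrics = list(n_cap = nrow(cap),
                      n_cap_recovered = length(recovered_tx),
                      n_exact = n_exact,
                      n_internal = nrow(int),
                      n_internal_called = sum(key(int) %in% key(s))))
}
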