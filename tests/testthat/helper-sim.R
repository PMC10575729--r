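# Shared fixtures, built in code. quick_world() is a small simulated
# experiment reused across test files (computed once per test run).

quick_params <- function(seed = 101L, ...) {
  sim_params(n_transcripts = 60L, depth_per_library = 4e4, seed = seed, ...)
}

quick_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- quick_params()
      w <- simulate_transcriptome(p)
      a <- simulate_libraries(w$transcripts, w$truth, p)
      cache <<- list(params = p, world = w, alignments = a,
                     tracks = compute_tracks(a, w$transcripts))
    }
    cache
  }
})

# Hand-built tracks: one transcript, direct depth/start vectors per role.
toy_tracks <- function(depth_by_role, start_by_role = NULL, L = NULL) {
  if (is.null(L)) L <- length(depth_by_role[[1]])
  roles <- names(depth_by_role)
  depth <- lapply(depth_by_role, function(v) list(tx1 = as.integer(v)))
  sc <- if (is.null(start_by_role))
    lapply(depth_by_role, function(v) list(tx1 = integer(L)))
  else lapply(start_by_role, function(v) list(tx1 = as.integer(v)))
  sizes <- vapply(depth_by_role, function(v) sum(v), numeric(1))
  structure(list(transcript_id = "tx1",
                 length = c(tx1 = as.integer(L)),
                 roles = roles, depth = depth, start_count = sc,
                 library_sizes = stats::setNames(as.integer(pmax(sizes, 1)),
                                                 roles)),
            class = "m6am_tracks")
}

empty_sites_for_test <- function() {
  s <- data.frame(transcript_id = character(0), gene_id = character(0),
                  position = integer(0), base = character(0),
                  m1 = numeric(0), m2 = numeric(0), score = numeric(0),
                  context = character(0), stringsAsFactors = FALSE)
  class(s) <- c("m6am_sites", "data.frame")
  s
}

# Independent brute-force oracles -------------------------------------------

# Per-position membership count: depth[p] = #{records with start <= p < end}.
brute_depth <- function(starts, ends, L) {
  vapply(0:(L - 1), function(p) sum(starts <= p & p < ends), integer(1))
}

brute_start_count <- function(starts, L) {
  vapply(0:(L - 1), function(p) sum(starts == p), integer(1))
}

# Brute-force sliding-window scan over explicit numeric tracks.
brute_window_scan <- function(ip_cpm, in_cpm, ip_raw, window, step,
                              min_fold, min_ip_depth, pseudocount) {
  L <- length(ip_cpm)
  w <- min(window, L)
  starts <- if (L <= window) 0 else unique(c(seq(0, L - w, by = step), L - w))
  kept <- list()
  for (s in starts) {
    idx <- (s + 1):(s + w)
    fold <- (mean(ip_cpm[idx]) + pseudocount) / (mean(in_cpm[idx]) + pseudocount)
    if (fold >= min_fold && mean(ip_raw[idx]) >= min_ip_depth)
      kept[[length(kept) + 1]] <- c(s, s + w)
  }
  if (length(kept) == 0) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, kept)
  # merge overlapping/adjacent intervals
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    else out <- rbind(out, m[i, ])
  }
  out
}
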