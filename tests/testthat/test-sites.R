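test_that("m1/m2 scoring matches its definition on the worked cases", {
  # unmodified position: no depletion, no start signal
  s0 <- score_position(0, 100, 100, 100)
  expect_equal(unlist(s0), c(m1 = 0, m2 = 0, score = 0))
  # complete FTO depletion with a 30% start rate
  s1 <- score_position(30, 100, 0, 100)
  expect_equal(unlist(s1), c(m1 = 0.3, m2 = 1, score = 0.3))
  # zero-depth positions are defined as 0
  expect_equal(score_position(0, 0, 0, 0)$score, 0)
  # FTO+ deeper than FTO- clamps m2 at 0
  expect_equal(score_position(10, 100, 150, 100)$m2, 0)
  expect_error(score_position(101, 100, 0, 100), "data-consistency")
  expect_error(score_position(-1, 100, 0, 100), "data-consistency")
})

test_that("the combined score is monotone in m1 and m2 for every combiner", {
  grid <- expand.grid(start = c(0, 10, 30, 60, 100), dplus = c(0, 40, 80, 100))
  for (comb in c("product", "min", "mean")) {
    sc <- score_position(grid$start, 100, grid$dplus, 100, combine = comb)
    expect_true(all(sc$score >= 0 & sc$score <= 1))
    # increasing m1 at fixed m2
    for (dp in unique(grid$dplus)) {
      sub <- sc[grid$dplus == dp, ]
      expect_true(all(diff(sub$score[order(grid$start[grid$dplus == dp])]) >= 0))
    }
    # increasing m2 at fixed m1
    for (st in unique(grid$start)) {
      sub <- sc[grid$start == st, ]
      expect_true(all(diff(sub$score[order(-grid$dplus[grid$start == st])]) >= 0))
    }
  }
})

site_fixture <- function(seq = NULL) {
  # 100 nt transcript; an FTO-sensitive dominant start at position 10
  L <- 100
  dm <- rep(50, L); dm[11] <- 100
  dp <- rep(50, L); dp[11] <- 10
  sm <- integer(L); sm[11] <- 80
  tr <- toy_tracks(list(INPUT = rep(50, L), M6A_IP_FTO_MINUS = dm,
                        M6A_IP_FTO_PLUS = dp),
                   start_by_role = list(INPUT = integer(L),
                                        M6A_IP_FTO_MINUS = sm,
                                        M6A_IP_FTO_PLUS = integer(L)))
  tr$library_sizes[] <- 5000L  # common library size: cpm == raw x 200
  if (is.null(seq)) {
    seq <- strrep("C", L)
    substr(seq, 11, 11) <- "A"  # site at 0-based position 10
  }
  pk <- data.frame(transcript_id = "tx1", start = 0L, end = 40L, summit = 10L,
                   enrichment = 3, fto_depletion = 0.8, cap_proximal = TRUE)
  class(pk) <- c("m6am_peaks", "data.frame")
  list(tracks = tr, peaks = pk, sequences = c(tx1 = seq))
}

test_that("call_sites emits scored adenosines with N-padded context", {
  f <- site_fixture()
  s <- call_sites(f$peaks, f$tracks, f$sequences)
  expect_equal(nrow(s), 1L)
  expect_equal(s$position, 10L)
  expect_equal(s$base, "A")
  expect_equal(s$m1, 0.8)
  expect_equal(s$m2, 0.9)
  expect_equal(s$score, 0.72)
  # 30 nt site-centred context, site at 0-based offset 15, left N-pad of 5
  expect_equal(nchar(s$context), 30L)
  expect_equal(substr(s$context, 1, 5), "NNNNN")
  expect_equal(substr(s$context, 16, 16), "A")
})

test_that("a peak without adenosines yields no sites", {
  f <- site_fixture(seq = strrep("G", 100))
  expect_equal(nrow(call_sites(f$peaks, f$tracks, f$sequences)), 0L)
})

test_that("min_score = 0 emits every qualifying A in the peak", {
  f <- site_fixture(seq = strrep("A", 100))
  s <- call_sites(f$peaks, f$tracks, f$sequences, min_score = 0,
                  min_site_depth = 0)
  expect_equal(nrow(s), 40L)  # every position of the peak
  s10 <- call_sites(f$peaks, f$tracks, f$sequences, min_score = 0,
                    min_site_depth = 60)
  expect_equal(s10$position, 10L)  # only the deep position qualifies
})

test_that("scoring is local: tracks outside the peak do not change calls", {
  f <- site_fixture()
  s1 <- call_sites(f$peaks, f$tracks, f$sequences)
  f$tracks$depth$M6A_IP_FTO_MINUS$tx1[60:100] <- 999L
  f$tracks$depth$M6A_IP_FTO_PLUS$tx1[60:100] <- 999L
  s2 <- call_sites(f$peaks, f$tracks, f$sequences)
  expect_equal(s1, s2)
})

test_that("a sequence shorter than the transcript model is a reference error", {
  f <- site_fixture()
  f$sequences <- c(tx1 = "ACGT")
  expect_error(call_sites(f$peaks, f$tracks, f$sequences), "reference error")
  expect_error(call_sites(f$peaks, f$tracks, c(other = "ACGT")),
               "reference error")
})

test_that("identical contexts give unit PFM columns and their own consensus", {
  s <- data.frame(transcript_id = "t", gene_id = "g", position = 1:3,
                  base = "A", m1 = 1, m2 = 1, score = 1,
                  context = "CCGAT", stringsAsFactors = FALSE)
  m <- consensus_motif(s)
  expect_equal(m$consensus, "CCGAT")
  expect_true(all(apply(m$pfm, 2, max) == 1))
  expect_equal(colSums(m$pfm), rep(1, 5), tolerance = 1e-9)
})

test_that("uniform random contexts give near-uniform PFM columns", {
  set.seed(99)
  ctx <- vapply(1:10000, function(i)
    paste(sample(c("A", "C", "G", "T"), 7, replace = TRUE), collapse = ""),
    character(1))
  s <- data.frame(transcript_id = "t", gene_id = "g", position = 1,
                  base = "A", m1 = 1, m2 = 1, score = 1, context = ctx,
                  stringsAsFactors = FALSE)
  m <- consensus_motif(s)
  expect_true(all(abs(m$pfm - 0.25) < 0.02))
})

test_that("all-N columns and empty site lists degrade gracefully", {
  s <- data.frame(transcript_id = "t", gene_id = "g", position = 0,
                  base = "A", m1 = 1, m2 = 1, score = 1, context = "NNAGT",
                  stringsAsFactors = FALSE)
  m <- consensus_motif(s)
  expect_true(all(is.na(m$pfm[, 1])))
  expect_equal(substr(m$consensus, 1, 2), "NN")
  empty <- consensus_motif(empty_sites_for_test())
  expect_equal(empty$n_sites, 0L)
  expect_equal(empty$consensus, "")
})

test_that("site tables and PFMs round-trip through their text formats", {
  q <- quick_world()
  pk <- filter_cap_proximal(
    filter_fto_sensitive(call_enriched_windows(q$tracks), q$tracks),
    q$tracks)
  s <- call_sites(pk, q$tracks, q$world$sequences, q$world$transcripts)
  expect_gt(nrow(s), 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sites(s, path)
  expect_equal(read_sites(path), s, tolerance = 1e-6)

  m <- consensus_motif(s)
  pfm_path <- withr::local_tempfile(fileext = ".pfm")
  write_pfm(m, pfm_path)
  lines <- readLines(pfm_path)
  expect_match(lines[1], "consensus")
  expect_equal(length(lines), 2 + 4)

  fa <- withr::local_tempfile(fileext = ".fa")
  write_contexts_fasta(s, fa)
  expect_equal(sum(grepl("^>", readLines(fa))), nrow(s))
})
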