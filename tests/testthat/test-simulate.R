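test_that("parameter validation rejects degenerate settings", {
  expect_error(sim_params(n_transcripts = 0), "parameter error")
  expect_error(sim_params(frac_cap_m6am = 1.2), "parameter error")
  expect_error(sim_params(stoichiometry = -0.1), "parameter error")
  expect_error(sim_params(ip_enrichment = 0.5), "parameter error")
  expect_error(sim_params(fto_efficiency_m6am = 0.1, fto_efficiency_m6a = 0.5),
               "parameter error")
})

test_that("transcriptome generation plants the requested truth sites", {
  p <- sim_params(n_transcripts = 200L, frac_cap_m6am = 0.25,
                  frac_internal_m6a = 0.2, seed = 7L)
  w <- simulate_transcriptome(p)
  expect_equal(sum(w$truth$mod_type == "CAP_M6AM"), 50L)
  expect_equal(sum(w$truth$mod_type == "INTERNAL_M6A"), 40L)
  expect_equal(nchar(w$sequences), stats::setNames(w$transcripts$length,
                                                   w$transcripts$transcript_id))
  with(w$transcripts, {
    expect_true(all(0 < utr5_end & utr5_end < cds_end & cds_end < length))
  })
  # every truth site is on an A; cap sites at position 0 by default;
  # internal sites strictly downstream of the cap-proximal region
  base_at <- substring(w$sequences[w$truth$transcript_id],
                       w$truth$position + 1L, w$truth$position + 1L)
  expect_true(all(base_at == "A"))
  expect_true(all(w$truth$position[w$truth$mod_type == "CAP_M6AM"] == 0L))
  expect_true(all(w$truth$position[w$truth$mod_type == "INTERNAL_M6A"] >= 150L))
})

test_that("no modifications requested gives an empty truth set", {
  p <- sim_params(n_transcripts = 20L, frac_cap_m6am = 0,
                  frac_internal_m6a = 0, seed = 3L)
  w <- simulate_transcriptome(p)
  expect_equal(nrow(w$truth), 0L)
})

test_that("cap sites planted inside a cap window carry the CA context", {
  p <- sim_params(n_transcripts = 80L, cap_window = 3L, seed = 5L)
  w <- simulate_transcriptome(p)
  cap <- w$truth[w$truth$mod_type == "CAP_M6AM" & w$truth$position > 0L, ]
  expect_gt(nrow(cap), 0)
  up <- substring(w$sequences[cap$transcript_id], cap$position, cap$position)
  expect_true(all(up == "C"))
})

test_that("internal m6A sites sit in a planted DRACH-like context", {
  w <- quick_world()$world
  int <- w$truth[w$truth$mod_type == "INTERNAL_M6A", ]
  ctx <- substring(w$sequences[int$transcript_id], int$position - 1L,
                   int$position + 3L)
  expect_true(all(ctx == "GGACT"))
})

test_that("the generator and the library sampler are seed-reproducible", {
  p <- quick_params(seed = 42L)
  w1 <- simulate_transcriptome(p); w2 <- simulate_transcriptome(p)
  expect_identical(w1, w2)
  a1 <- simulate_libraries(w1$transcripts, w1$truth, p)
  a2 <- simulate_libraries(w2$transcripts, w2$truth, p)
  expect_identical(a1, a2)
})

test_that("library records respect transcript bounds and depth", {
  q <- quick_world()
  a <- q$alignments
  expect_setequal(unique(a$library_role),
                  c("INPUT", "M7G_IP", "M6A_IP_FTO_MINUS", "M6A_IP_FTO_PLUS"))
  expect_true(all(table(a$library_role) == q$params$depth_per_library))
  L <- q$world$transcripts$length[match(a$transcript_id,
                                        q$world$transcripts$transcript_id)]
  expect_true(all(a$start >= 0 & a$start < a$end & a$end <= L))
})

test_that("truth referring to an unknown transcript is a reference error", {
  q <- quick_world()
  bad <- rbind(q$world$truth,
               data.frame(transcript_id = "TX_NOPE", position = 0L,
                          mod_type = "CAP_M6AM", stoichiometry = 0.8))
  expect_error(simulate_libraries(q$world$transcripts, bad, q$params),
               "reference error")
})

test_that("IP enrichment raises anti-m6A depth at methylated positions", {
  folds <- vapply(1:3, function(s) {
    p <- sim_params(n_transcripts = 40L, depth_per_library = 3e4, seed = s)
    w <- simulate_transcriptome(p)
    a <- simulate_libraries(w$transcripts, w$truth, p)
    tr <- compute_tracks(a, w$transcripts)
    cap <- w$truth[w$truth$mod_type == "CAP_M6AM", ]
    ip <- normalize_depth(tr, "M6A_IP_FTO_MINUS", "cpm")
    inp <- normalize_depth(tr, "INPUT", "cpm")
    at <- function(tbl) mapply(function(t, pos) tbl[[t]][pos + 1],
                               cap$transcript_id, cap$position)
    mean(at(ip)) / mean(at(inp))
  }, numeric(1))
  expect_true(all(folds > 2))
})

test_that("an ineffective FTO treatment makes the two FTO arms exchangeable", {
  # with zero erasure in the treated arm the libraries are identically
  # distributed, so m2 at truth sites is centred on 0
  m2s <- unlist(lapply(1:20, function(s) {
    p <- sim_params(n_transcripts = 30L, depth_per_library = 2e4,
                    fto_efficiency_m6am = 0, fto_efficiency_m6a = 0,
                    seed = s)
    w <- simulate_transcriptome(p)
    a <- simulate_libraries(w$transcripts, w$truth, p)
    tr <- compute_tracks(a, w$transcripts)
    dm <- normalize_depth(tr, "M6A_IP_FTO_MINUS", "cpm")
    dp <- normalize_depth(tr, "M6A_IP_FTO_PLUS", "cpm")
    mapply(function(t, pos) {
      dminus <- dm[[t]][pos + 1]
      if (dminus == 0) return(NA_real_)
      (dminus - dp[[t]][pos + 1]) / dminus  # unclamped, sign-preserving
    }, w$truth$transcript_id, w$truth$position)
  }))
  expect_lt(abs(mean(m2s, na.rm = TRUE)), 0.05)
})

test_that("complete FTO erasure returns cap-site depth to input background", {
  # fully methylated cap sites, fully erased before IP: the FTO+ arm should
  # look like input there (ratio near 1 averaged over seeds)
  ratios <- vapply(1:20, function(s) {
    p <- sim_params(n_transcripts = 20L, depth_per_library = 1e4,
                    stoichiometry = 1, fto_efficiency_m6am = 1,
                    frac_internal_m6a = 0, seed = s)
    w <- simulate_transcriptome(p)
    a <- simulate_libraries(w$transcripts, w$truth, p)
    tr <- compute_tracks(a, w$transcripts)
    dp <- normalize_depth(tr, "M6A_IP_FTO_PLUS", "cpm")
    inp <- normalize_depth(tr, "INPUT", "cpm")
    cap <- w$truth[w$truth$mod_type == "CAP_M6AM", ]
    at <- function(tbl) mapply(function(t, pos) tbl[[t]][pos + 1],
                               cap$transcript_id, cap$position)
    mean(at(dp)) / mean(at(inp))
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.1)
  # while the untreated arm stays strongly enriched at the same positions
  p <- sim_params(n_transcripts = 20L, depth_per_library = 1e4,
                  stoichiometry = 1, fto_efficiency_m6am = 1,
                  frac_internal_m6a = 0, seed = 1)
  w <- simulate_transcriptome(p)
  a <- simulate_libraries(w$transcripts, w$truth, p)
  tr <- compute_tracks(a, w$transcripts)
  dm <- normalize_depth(tr, "M6A_IP_FTO_MINUS", "cpm")
  inp <- normalize_depth(tr, "INPUT", "cpm")
  cap <- w$truth[w$truth$mod_type == "CAP_M6AM", ]
  at <- function(tbl) mapply(function(t, pos) tbl[[t]][pos + 1],
                             cap$transcript_id, cap$position)
  expect_gt(mean(at(dm)) / mean(at(inp)), 2)
})

test_that("truth tables round-trip through TSV", {
  q <- quick_world()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_truth(q$world$truth, path)
  expect_equal(read_truth(path), q$world$truth)
  empty <- q$world$truth[0, ]
  write_truth(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only
})

test_that("TE count simulation is reproducible and mass-balanced", {
  a <- simulate_te_counts(seed = 9L)
  b <- simulate_te_counts(seed = 9L)
  expect_identical(a, b)
  expect_equal(sum(a$fp_ctrl$count), sum(a$fp_cond$count))
  # balanced design: expected footprint output conserved between conditions
  expect_equal(nrow(a$truth), 25L)
})
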