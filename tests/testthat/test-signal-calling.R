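# Null construction, outlier exclusion, presence testing and SNR.

make_spots <- function(blank_if, blank_sd) {
  data.frame(sample_id = "s", subarray = 1L,
             zip_id = paste0("b", seq_along(blank_if)),
             replicate = 1L, IF = blank_if, pixel_sd = blank_sd,
             type_flag = 5L)
}

test_that("null distribution adds twice the pixel SD per blank", {
  null <- build_null(make_spots(rep(100, 6), rep(10, 6)))
  expect_equal(null$adjusted_values, rep(120, 6))
  expect_equal(null$adjusted_mean, 120)
  expect_equal(null$raw_mean, 100)
  null2 <- build_null(make_spots(c(90, 110), c(5, 5)))
  expect_equal(null2$adjusted_values, c(100, 120))
  expect_equal(null2$adjusted_mean, 110)
  expect_error(build_null(make_spots(100, 10)), "insufficient-null")
})

test_that("outlier rule discards low replicates but keeps testability", {
  null <- build_null(make_spots(rep(100, 6), rep(0, 6)))
  params <- call_params()
  # threshold = 2.5 * 100 = 250
  ex <- exclude_outliers(c(500, 480, 30, 510), null, params)
  expect_equal(ex$retained, c(500, 480, 510))
  expect_identical(ex$n_excluded, 1L)
  # all high: nothing excluded
  ex2 <- exclude_outliers(rep(500, 4), null, params)
  expect_identical(ex2$n_excluded, 0L)
  # all below threshold: tested as-is (will fail the presence test)
  ex3 <- exclude_outliers(rep(50, 4), null, params)
  expect_equal(ex3$retained, rep(50, 4))
  expect_identical(ex3$n_excluded, 0L)
  # never drop below min_replicates: keep the largest ones
  ex4 <- exclude_outliers(c(500, 30, 20, 10), null, params)
  expect_identical(ex4$n_excluded, 2L)
  expect_true(500 %in% ex4$retained)
  expect_length(ex4$retained, 2L)
})

test_that("presence test agrees with an independent Welch computation", {
  null <- build_null(make_spots(c(95, 102, 99, 104, 97, 110),
                                c(5, 6, 4, 7, 5, 6)))
  reps <- c(5000, 5100, 4900, 5050)
  rec <- test_presence(reps, null, call_params())
  expect_true(rec$present)
  expect_lt(rec$p_value, 1e-4)
  expect_equal(rec$p_value,
               welch_one_sided_p(reps, null$adjusted_values),
               tolerance = 1e-8)
  # replicates exchangeable with the null: p around 0.5, absent
  rec2 <- test_presence(null$adjusted_values, null, call_params())
  expect_false(rec2$present)
  expect_gt(rec2$p_value, 0.2)
})

test_that("presence p-value matches a permutation-test tail probability", {
  set.seed(17)
  x <- c(180, 150, 210, 165)
  y <- c(120, 95, 130, 110, 105, 125)
  rec <- test_presence(x, build_null(make_spots(y, rep(0, 6))),
                       call_params())
  pooled <- c(x, y)
  nperm <- 20000L
  stat_obs <- mean(x) - mean(y)
  perm <- replicate(nperm, {
    idx <- sample(length(pooled), length(x))
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  p_perm <- (sum(perm >= stat_obs) + 1) / (nperm + 1)
  expect_lt(abs(rec$p_value - p_perm), 0.03)
})

test_that("too few replicates yields an absent call with a reason flag", {
  null <- build_null(make_spots(rep(100, 6), rep(0, 6)))
  rec <- test_presence(5000, null, call_params())
  expect_false(rec$present)
  expect_identical(rec$reason, "too_few_replicates")
  expect_true(is.na(rec$p_value))
})

test_that("conservative null: adjusted calls are a subset of raw-null calls", {
  set.seed(23)
  for (rep in 1:20) {
    blanks <- make_spots(runif(6, 80, 120), runif(6, 5, 30))
    null_adj <- build_null(blanks)
    null_raw <- null_adj
    null_raw$adjusted_values <- null_raw$raw_values
    null_raw$adjusted_mean <- null_raw$raw_mean
    x <- runif(4, 90, 260)
    p_adj <- test_presence(x, null_adj, call_params())$p_value
    p_raw <- test_presence(x, null_raw, call_params())$p_value
    expect_gte(p_adj, p_raw - 1e-12)
  }
})

test_that("call_spots runs per subarray and flags only signal probes", {
  panel <- small_panel()
  ids <- panel$probes$probe_id
  mixes <- list(template_mix(panel$templates[ids[1]], 50, label = "s1"),
                template_mix(panel$templates[ids[2]], 50, label = "s2"))
  spots <- simulate_experiment(panel$probes, panel$layout, mixes, seed = 4)
  calls <- call_spots(spots, panel$probes)
  expect_identical(nrow(calls), 6L)  # 3 probes x 2 samples
  got1 <- calls[calls$sample_id == "s1", ]
  expect_identical(got1$probe_id[got1$present], ids[1])
  got2 <- calls[calls$sample_id == "s2", ]
  expect_identical(got2$probe_id[got2$present], ids[2])
})

test_that("SNR summary splits specific from non-specific and is scale-free", {
  panel <- small_panel()
  ids <- panel$probes$probe_id
  mix <- template_mix(panel$templates[ids[1]], 50, label = "s1")
  spots <- simulate_experiment(panel$probes, panel$layout, mix, seed = 6)
  scope <- spots[spots$subarray == 1, ]
  res <- compute_snr(scope, panel$probes, expected_specific = ids[1])
  expect_gt(res$snr_s, 10)
  expect_lt(res$snr_ns, 3)
  # multiplying every IF by a constant leaves SNR unchanged
  scaled <- scope
  scaled$IF <- scaled$IF * 7.3
  scaled$pixel_sd <- scaled$pixel_sd * 7.3
  res2 <- compute_snr(scaled, panel$probes, expected_specific = ids[1])
  expect_equal(res2$per_probe$snr, res$per_probe$snr, tolerance = 1e-12)
  # probe at exactly the blank mean has SNR 1
  flat <- scope
  flat$IF[flat$type_flag == 3L] <- mean(flat$IF[flat$type_flag == 5L])
  res3 <- compute_snr(flat, panel$probes, expected_specific = ids[1])
  expect_equal(unname(res3$per_probe$snr), rep(1, 3), tolerance = 1e-12)
})

test_that("call tables round-trip through TSV", {
  panel <- small_panel()
  mix <- template_mix(panel$templates, 10, label = "rt")
  spots <- simulate_experiment(panel$probes, panel$layout, mix, seed = 8)
  calls <- call_spots(spots, panel$probes)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_call_table(calls, tsv)
  back <- read_call_table(tsv)
  expect_identical(back$probe_id, calls$probe_id)
  expect_identical(back$present, calls$present)
})

test_that("detection power: probes at SNR ~30 are called in >=99% of runs", {
  panel <- small_panel()
  ids <- panel$probes$probe_id
  # yield calibrated to SNR ~ 30: background 100, yield 29*100 a.u.
  amount <- 2900 / 400
  n_runs <- 200L
  hits <- 0L
  for (k in seq_len(n_runs)) {
    mix <- template_mix(panel$templates, amount, label = "pw")
    spots <- simulate_experiment(panel$probes, panel$layout, mix,
                                 seed = 5000L + k)
    calls <- call_spots(spots, panel$probes)
    hits <- hits + as.integer(all(calls$present))
  }
  expect_gte(hits / n_runs, 0.99)
})
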