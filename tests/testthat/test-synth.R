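test_that("RR generator degenerates to a constant series without noise", {
  p <- cohort_params(rr_sd_term = 0, ar1_coeff = 0)
  r <- generate_rr(p, "term", "MHR", n_beats = 50, seed = 3)
  expect_equal(r$samples[[1]], rep(431.2, 50))
})

test_that("RR generator is reproducible and validates its inputs", {
  p <- cohort_params()
  a <- generate_rr(p, "preterm", "MHR", n_beats = 200, seed = 9)
  b <- generate_rr(p, "preterm", "MHR", n_beats = 200, seed = 9)
  expect_identical(a$samples[[1]], b$samples[[1]])
  expect_error(generate_rr(p, "preterm", "MHR", n_beats = 1, seed = 1),
               "n_beats")
  expect_error(cohort_params(ar1_coeff = 1), "ar1_coeff")
  expect_error(cohort_params(rr_sd_term = -1), "deviations")
})

test_that("preterm RR moments converge to the configured values", {
  r <- generate_rr(cohort_params(), "preterm", "MHR", n_beats = 10000,
                   seed = 11)
  x <- r$samples[[1]]
  # AR(1) inflates the variance of the sample moments; allow the
  # autocorrelation-adjusted 3-SE band around the configured values
  phi <- 0.6
  se_mean <- 26.9 * sqrt((1 + phi) / (1 - phi) / 10000)
  expect_lt(abs(mean(x) - 413.2), 3 * se_mean)
  se_sd <- 26.9 / sqrt(2 * 10000) * sqrt((1 + phi^2) / (1 - phi^2)) * 2
  expect_lt(abs(sd(x) - 26.9), 3 * se_sd)
})

test_that("foetal RR mean sits in the 110-170 bpm baseline band", {
  for (lab in c("term", "preterm")) {
    r <- generate_rr(cohort_params(), lab, "FHR", n_beats = 5000, seed = 2)
    bpm <- 60000 / mean(r$samples[[1]])
    expect_gt(bpm, 110)
    expect_lt(bpm, 170)
  }
  # class effect carries the maternal standardised mean difference
  t <- generate_rr(cohort_params(), "term", "FHR", n_beats = 20000, seed = 4)
  p <- generate_rr(cohort_params(), "preterm", "FHR", n_beats = 20000,
                   seed = 5)
  expect_gt(mean(t$samples[[1]]), mean(p$samples[[1]]))
})

test_that("EHG burst counts follow the class Poisson rates", {
  p <- cohort_params()
  counts <- vapply(1:100, function(i) {
    attr(generate_ehg(p, "term", seed = 1000 + i), "n_bursts")
  }, numeric(1))
  # Monte-Carlo check against the Poisson mean (rate 4 per 10 min)
  expect_lt(abs(mean(counts) - 4), 3 * sqrt(4 / 100))
  counts_p <- vapply(1:100, function(i) {
    attr(generate_ehg(p, "preterm", seed = 2000 + i), "n_bursts")
  }, numeric(1))
  expect_lt(abs(mean(counts_p) - 6), 3 * sqrt(6 / 100))
})

test_that("EHG envelope is non-negative, reproducible, and guards duration", {
  p <- cohort_params()
  a <- generate_ehg(p, "term", seed = 5)
  b <- generate_ehg(p, "term", seed = 5)
  expect_identical(a$samples[[1]], b$samples[[1]])
  expect_true(all(a$samples[[1]] >= 0))
  expect_length(a$samples[[1]], 300) # 600 s at 0.5 Hz
  p$duration <- 300
  expect_error(generate_ehg(p, "term", seed = 1), "duration")
  expect_error(generate_ehg(cohort_params(), "late", seed = 1), "label")
})

test_that("zero effect size leaves only burst-timing differences", {
  p <- cohort_params(preset = "null", noise_sd_uv = 0)
  t <- generate_ehg(p, "term", seed = 7)
  q <- generate_ehg(p, "preterm", seed = 7)
  # identical seed, identical class parameters: identical envelope
  expect_identical(t$samples[[1]], q$samples[[1]])
})

test_that("cohorts have the requested composition and replay exactly", {
  p <- cohort_params(n_term = 27, n_preterm = 20)
  co <- generate_cohort(p)
  expect_equal(nrow(co), 47)
  expect_equal(as.vector(table(co$label)), c(27, 20))
  co2 <- generate_cohort(p)
  expect_identical(co$samples, co2$samples)
  expect_error(cohort_params(n_term = 0), "n_term")
})

test_that("cohort writer round-trips through delimited text", {
  co <- generate_cohort(cohort_params(n_term = 2, n_preterm = 2,
                                      signal_kind = "MHR", duration = 100,
                                      seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$patient_id, co$patient_id)
  expect_equal(as.character(back$label), as.character(co$label))
  expect_equal(back$samples, co$samples)
})
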