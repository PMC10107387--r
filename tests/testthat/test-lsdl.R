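test_that("amplitude bands retain the expected sample fractions", {
  x <- seq(0, 1, length.out = 1001) # |x| uniform on [0, A]
  lower1 <- lsdl_decompose(x, "lower", 1, A = 1)
  expect_equal(length(lower1), 501) # about half, boundary included
  upper1 <- lsdl_decompose(x, "upper", 1, A = 1)
  # complementary half-ranges: every sample in at least one region
  expect_gte(length(lower1) + length(upper1), length(x))
  # constant signal at A is fully excluded by the lower band
  expect_error(lsdl_decompose(rep(1, 100), "lower", 1, A = 1),
               class = "lsdl_too_few")
  # a zero signal is entirely retained by any lower rule
  expect_length(lsdl_decompose(numeric(100), "lower", 1, A = 1), 100)
  expect_error(lsdl_decompose(x, "lower", 1, A = 0), "A must be")
})

test_that("dyadic thresholds follow the region schedule", {
  expect_equal(sapply(1:4, lsdl_threshold, region = "lower"),
               c(1 / 2, 3 / 4, 7 / 8, 15 / 16))
  expect_equal(sapply(1:4, lsdl_threshold, region = "upper"),
               c(1 / 2, 1 / 4, 1 / 8, 1 / 16))
})

test_that("separability cost equals the defining normalised-distance ratio", {
  # hand evaluation: class means (0,0) vs (3,4) give ED = 5, so with mean
  # per-feature deviation sigma_m the cost must equal 5 / sigma_m
  f1 <- cbind(c(-1, 1), c(-2, 2))
  f2 <- cbind(c(2, 4), c(2, 6))
  pooled <- rbind(f1, f2)
  sigma_m <- mean(apply(pooled, 2, function(v) {
    sqrt(mean((v - mean(v))^2))
  }))
  expect_equal(lsdl_cost(f1, f2), 5 / sigma_m)
  expect_equal(lsdl_cost(f1, f2), oracle_cost_j(f1, f2))
})

test_that("cost is zero iff class means coincide and errors when degenerate", {
  withr::with_seed(4, {
    f1 <- matrix(rnorm(30), 10, 3)
  })
  f2 <- f1[sample(10), ] # same column means
  expect_equal(lsdl_cost(f1, f2), 0)
  expect_gt(lsdl_cost(f1, f1 + 0.5), 0)
  expect_error(lsdl_cost(matrix(1, 4, 2), matrix(1, 4, 2)), "sigma_m")
  expect_error(lsdl_cost(matrix(1, 4, 2), matrix(1, 4, 3)), "mismatch")
})

test_that("cost is invariant to common rescaling and feature shifts", {
  withr::with_seed(5, {
    f1 <- matrix(rnorm(40), 10, 4)
    f2 <- matrix(rnorm(40, 0.6), 10, 4)
  })
  j <- lsdl_cost(f1, f2)
  expect_equal(lsdl_cost(3.7 * f1, 3.7 * f2), j)
  shift <- matrix(rep(c(10, -2, 5, 0), each = 10), 10)
  expect_equal(lsdl_cost(f1 + shift, f2 + shift), j)
})

test_that("candidate selection maximises cost with the stated tie-breaks", {
  grid <- tidyr::expand_grid(region = c("upper", "lower"), iteration = 1:4)
  cand <- dplyr::mutate(grid, cost = 1)
  pick <- lsdl_select_best(cand)
  expect_equal(pick$region, "lower")
  expect_equal(pick$iteration, 1L)
  cand$cost <- c(1, 2, 1, 1, 1, 2, 1, 1) # tie across regions at iter 2
  pick <- lsdl_select_best(cand)
  expect_equal(pick$region, "lower")
  expect_error(lsdl_select_best(dplyr::mutate(grid, cost = NA_real_)),
               "no valid")
})

test_that("fitting selects the planted mid-amplitude band and replays", {
  p <- cohort_params(n_term = 6, n_preterm = 6, preset = "mid_band",
                     duration = 1800, seed = 42)
  w <- window_records(epoch_average(generate_cohort(p)))
  m <- lsdl_fit(w)
  expect_s3_class(m, "lsdl")
  expect_equal(m$best$region, "lower")
  expect_lte(m$best$iteration, 2)
  expect_equal(m$best$cost, max(m$candidates$cost, na.rm = TRUE))
  # permutation invariance w.r.t. record order
  suppressMessages({
    m2 <- lsdl_fit(w[sample(nrow(w)), ])
  })
  expect_equal(m2$best$cost, m$best$cost)
  expect_equal(m2$best$region, m$best$region)
  # apply() replays the decomposition used during the search
  dec <- predict(m, w)
  i <- which(m$candidates$region == m$best$region &
               m$candidates$iteration == m$best$iteration)
  refit <- lsdl_decompose(w$samples[[3]], m$best$region, m$best$iteration,
                          m$A, m$min_keep)
  expect_identical(dec$samples[[3]], refit)
})

test_that("fit requires both classes and a non-degenerate amplitude", {
  p <- cohort_params(n_term = 3, n_preterm = 3, duration = 600, seed = 2)
  w <- window_records(epoch_average(generate_cohort(p)))
  expect_error(lsdl_fit(w[w$label == "term", ]), "both classes")
})

test_that("model JSON round-trips and the wide table marks failures", {
  p <- cohort_params(n_term = 4, n_preterm = 4, preset = "mid_band",
                     duration = 1800, seed = 8)
  w <- window_records(epoch_average(generate_cohort(p)))
  m <- lsdl_fit(w)
  path <- withr::local_tempfile(fileext = ".json")
  write_lsdl(m, path)
  m2 <- read_lsdl(path)
  expect_equal(m2$best$cost, m$best$cost)
  expect_equal(m2$A, m$A)
  dec1 <- predict(m, w)
  dec2 <- predict(m2, w)
  expect_identical(dec1$samples, dec2$samples)
  tab <- lsdl_table(m)
  expect_equal(names(tab), c("Region", paste("Iteration", 1:4)))
  if (any(!m$candidates$valid)) expect_true(any(tab == "n/a"))
})
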