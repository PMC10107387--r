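test_that("metric arithmetic follows the confusion-matrix definitions", {
  lab <- rep(c("preterm", "term"), each = 10)
  sc <- c(rnorm(10, 3), rnorm(10))
  m <- compute_metrics(c(tp = 10, fn = 0, tn = 10, fp = 0),
                       scores = c(rep(1, 10), rep(0, 10)), labels = lab)
  expect_equal(unlist(m), c(acc = 100, sens = 100, spec = 100, auc = 100))
  m2 <- compute_metrics(c(tp = 9, fn = 1, tn = 8, fp = 2), sc, lab)
  expect_equal(m2$sens, 90)
  expect_equal(m2$spec, 80)
  expect_equal(m2$acc, 85)
  # constant scores carry no ranking information
  m3 <- compute_metrics(c(tp = 5, fn = 5, tn = 5, fp = 5),
                        rep(0.5, 20), lab)
  expect_equal(m3$auc, 50)
  expect_error(compute_metrics(c(tp = 1, fn = 1, tn = 0, fp = 0),
                               sc[1:2], c("preterm", "preterm")),
               "absent")
})

test_that("AUC equals the exhaustive pair-counting statistic", {
  expect_equal(compute_metrics(c(tp = 2, fn = 0, tn = 2, fp = 0),
                               c(0.9, 0.8, 0.4, 0.2),
                               c("preterm", "preterm", "term", "term"))$auc,
               100)
  withr::with_seed(31, {
    for (i in 1:25) {
      lab <- sample(c("term", "preterm"), 30, replace = TRUE,
                    prob = c(0.6, 0.4))
      if (length(unique(lab)) < 2) next
      sc <- round(rnorm(30), 1) # coarse scores force ties
      got <- compute_metrics(c(tp = 1, fn = 1, tn = 1, fp = 1), sc, lab)$auc
      expect_equal(got, oracle_auc(sc, lab))
    }
  })
})

test_that("accuracy is the prevalence-weighted blend of sens and spec", {
  withr::with_seed(13, cm <- c(tp = 17, fn = 3, tn = 25, fp = 6))
  lab <- rep(c("preterm", "term"), c(20, 31))
  m <- compute_metrics(cm, seq_along(lab), lab)
  prev <- 20 / 51
  expect_equal(m$acc, prev * m$sens + (1 - prev) * m$spec)
})

test_that("a separable cohort is classified perfectly by every model", {
  ft <- make_feature_tibble(30, 30, shift = 8, seed = 17)
  for (mod in c("DT", "LDA", "LR", "LSVM", "QSVM", "CSVM", "FGSVM", "KNN")) {
    rep <- crossval_eval(ft, mod, k_folds = 5, seed = 1)
    expect_equal(rep$acc, 100)
    expect_equal(rep$auc, 100)
  }
})

test_that("1-NN classification agrees with the reference implementation", {
  ft <- make_feature_tibble(25, 25, shift = 0.8, seed = 23)
  X <- as.matrix(ft[, paste0("f", 1:4)])
  y <- factor(ft$label, levels = c("term", "preterm"))
  tr <- 1:30
  te <- 31:50
  mu <- colMeans(X[tr, ])
  s <- apply(X[tr, ], 2, sd)
  got <- pretermlsdl:::fit_predict_model("KNN", X[tr, ], y[tr], X[te, ])
  want <- class::knn(scale(X[tr, ], mu, s), scale(X[te, ], mu, s),
                     y[tr], k = 1)
  expect_equal(as.character(got$class), as.character(want))
  # the distance-margin score ranks like the hard assignment
  expect_true(all((got$score > 0) == (got$class == "preterm")))
})

test_that("cross-validation pools folds, stratifies and replays on a seed", {
  ft <- make_feature_tibble(40, 30, shift = 1.2, seed = 3)
  r1 <- crossval_eval(ft, "LDA", k_folds = 10, seed = 5)
  r2 <- crossval_eval(ft, "LDA", k_folds = 10, seed = 5)
  expect_equal(glance(r1), glance(r2))
  expect_equal(sum(r1$confusion), 70)
  expect_equal(nrow(tidy(r1)), 10)
  # aggregate-confusion accuracy equals sample-weighted fold accuracy
  pf <- tidy(r1)
  expect_equal(r1$acc, sum(pf$acc * pf$n) / sum(pf$n))
  expect_error(crossval_eval(ft[1:15, ], "LDA", k_folds = 10, seed = 1),
               "k_folds")
})

test_that("patient-grouped folds keep a patient's windows together", {
  co <- generate_cohort(cohort_params(n_term = 12, n_preterm = 12, seed = 2))
  ft <- featurize(window_records(co))
  fold <- pretermlsdl:::make_folds(ft, 5, seed = 7, group_by_patient = TRUE)
  per_patient <- tapply(fold, ft$patient_id, function(f) length(unique(f)))
  expect_true(all(per_patient == 1))
})

test_that("the suite reports both arms in the wide comparison layout", {
  ft <- make_feature_tibble(25, 25, shift = 2, seed = 19)
  suite <- run_model_suite(ft, ft, models = c("LDA", "KNN"), k_folds = 5,
                           seed = 2)
  expect_equal(nrow(suite), 4)
  wide <- suite_table(suite)
  expect_equal(names(wide),
               c("Model", "Raw-Acc (%)", "LSDL-Acc (%)", "Raw-Sens (%)",
                 "LSDL-Sens (%)", "Raw-Spec (%)", "LSDL-Spec (%)",
                 "Raw-AUC (%)", "LSDL-AUC (%)"))
  expect_equal(nrow(wide), 2)
})
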