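#' The eight-model comparison set
#'
#' @return Character vector of model names: decision tree (DT), linear
#'   discriminant analysis (LDA), logistic regression (LR), linear /
#'   quadratic / cubic / fine-Gaussian SVM (LSVM, QSVM, CSVM, FGSVM) and
#'   1-nearest-neighbour (KNN).
#' @export
model_names <- function() {
  c("DT", "LDA", "LR", "LSVM", "QSVM", "CSVM", "FGSVM", "KNN")
}

# replace non-finite feature values by the column median of finite values
sanitize_features <- function(features) {
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                              logical(1))], "window")
  for (cn in feat_cols) {
    v <- features[[cn]]
    bad <- !is.finite(v)
    if (any(bad)) {
      fill <- stats::median(v[!bad])
      if (!is.finite(fill)) fill <- 0
      features[[cn]] <- replace(v, bad, fill)
    }
  }
  features
}

feature_matrix <- function(features) {
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                              logical(1))], "window")
  as.matrix(features[, feat_cols])
}

# fit one model on (X, y) and score the preterm class on Xt;
# returns list(class = factor, score = numeric)
fit_predict_model <- function(model, X, y, Xt, hyper = list()) {
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  Xt <- Xt[, keep, drop = FALSE]
  P <- ncol(X)
  cost <- hyper$cost %||% 1
  svm_score <- function(fit, Xt) {
    pr <- predict(fit, Xt, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    first <- strsplit(colnames(dv), "/")[[1]][1]
    sc <- if (first == "preterm") dv[, 1] else -dv[, 1]
    list(class = pr, score = as.numeric(sc))
  }
  switch(model,
    DT = {
      df <- data.frame(y = y, X)
      fit <- rpart::rpart(y ~ ., df, method = "class",
                          control = rpart::rpart.control(
                            minsplit = hyper$minsplit %||% 10,
                            cp = hyper$cp %||% 0.01))
      pp <- predict(fit, data.frame(Xt), type = "prob")[, "preterm"]
      list(class = factor(ifelse(pp > 0.5, "preterm", "term"),
                          levels = .classes), score = pp)
    },
    LDA = {
      fit <- suppressWarnings(MASS::lda(X, grouping = y))
      pr <- predict(fit, Xt)
      list(class = factor(as.character(pr$class), levels = .classes),
           score = pr$posterior[, "preterm"])
    },
    LR = {
      df <- data.frame(y01 = as.integer(y == "preterm"), X)
      fit <- suppressWarnings(stats::glm(y01 ~ ., df, family = stats::binomial()))
      pp <- suppressWarnings(
        predict(fit, data.frame(Xt), type = "response"))
      list(class = factor(ifelse(pp > 0.5, "preterm", "term"),
                          levels = .classes), score = as.numeric(pp))
    },
    LSVM = svm_score(e1071::svm(X, y, kernel = "linear", cost = cost,
                                scale = TRUE), Xt),
    QSVM = svm_score(e1071::svm(X, y, kernel = "polynomial", degree = 2,
                                coef0 = 1, gamma = hyper$gamma %||% 1 / P,
                                cost = cost, scale = TRUE), Xt),
    CSVM = svm_score(e1071::svm(X, y, kernel = "polynomial", degree = 3,
                                coef0 = 1, gamma = hyper$gamma %||% 1 / P,
                                cost = cost, scale = TRUE), Xt),
    FGSVM = svm_score(e1071::svm(X, y, kernel = "radial",
                                 gamma = hyper$gamma %||% 16 / P,
                                 cost = cost, scale = TRUE), Xt),
    KNN = {
      # 1-NN, Euclidean on train-standardised features; the continuous
      # score is the distance margin between the nearest neighbour of each
      # class (positive when the preterm neighbour is closer)
      mu <- colMeans(X)
      s <- apply(X, 2, stats::sd)
      s[s == 0] <- 1
      Z <- scale(X, mu, s)
      Zt <- scale(Xt, mu, s)
      d2 <- outer(rowSums(Zt^2), rowSums(Z^2), "+") - 2 * Zt %*% t(Z)
      d2[d2 < 0] <- 0
      d_pre <- apply(d2[, y == "preterm", drop = FALSE], 1, min)
      d_term <- apply(d2[, y == "term", drop = FALSE], 1, min)
      cls <- as.character(y)[apply(d2, 1, which.min)]
      list(class = factor(cls, levels = .classes),
           score = sqrt(d_term) - sqrt(d_pre))
    },
    stop("unknown model: ", model, call. = FALSE)
  )
}

#' Classification metrics from a confusion matrix and scores
#'
#' Accuracy, sensitivity and specificity from the pooled confusion counts
#' (preterm positive), and AUC of the continuous scores via the trapezoidal
#' ROC with midrank tie handling, all expressed in percent.
#'
#' @param confusion Named numeric vector `c(tp=, fn=, tn=, fp=)`.
#' @param scores Numeric preterm scores, one per sample.
#' @param labels True labels aligned with `scores`.
#' @return One-row tibble with `acc`, `sens`, `spec`, `auc` in percent.
#' @export
#' @examples
#' compute_metrics(c(tp = 9, fn = 1, tn = 8, fp = 2),
#'                 scores = c(rnorm(10, 1), rnorm(10)),
#'                 labels = rep(c("preterm", "term"), each = 10))
compute_metrics <- function(confusion, scores, labels) {
  cm <- confusion[c("tp", "fn", "tn", "fp")]
  if (any(is.na(cm)) || any(cm < 0) || sum(cm) == 0) {
    stop("confusion must hold non-negative tp/fn/tn/fp counts",
         call. = FALSE)
  }
  if ((cm["tp"] + cm["fn"]) == 0 || (cm["tn"] + cm["fp"]) == 0) {
    stop("a class is absent; sensitivity/specificity undefined",
         call. = FALSE)
  }
  labels <- as_class_factor(labels)
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = as.numeric(scores),
    levels = .classes, direction = "<", quiet = TRUE)))
  tibble::tibble(
    acc = 100 * (cm[["tp"]] + cm[["tn"]]) / sum(cm),
    sens = 100 * cm[["tp"]] / (cm[["tp"]] + cm[["fn"]]),
    spec = 100 * cm[["tn"]] / (cm[["tn"]] + cm[["fp"]]),
    auc = 100 * auc
  )
}

make_folds <- function(features, k_folds, seed, group_by_patient = FALSE) {
  lab <- as_class_factor(features$label)
  fold <- integer(nrow(features))
  withr::with_seed(seed, {
    if (group_by_patient) {
      for (cl in .classes) {
        pats <- unique(features$patient_id[lab == cl])
        pf <- stats::setNames(rep_len(seq_len(k_folds), length(pats)),
                              sample(pats))
        idx <- which(lab == cl)
        fold[idx] <- pf[features$patient_id[idx]]
      }
    } else {
      for (cl in .classes) {
        idx <- sample(which(lab == cl))
        fold[idx] <- rep_len(seq_len(k_folds), length(idx))
      }
    }
  })
  fold
}

#' Cross-validated evaluation of one classifier
#'
#' Stratified k-fold cross-validation at window level (or grouped by
#' patient): each training fold is optionally SMOTE-balanced, the model fit
#' on it, and the held-out fold scored. Metrics are pooled from the
#' aggregate confusion matrix and the pooled scores; per-fold metrics are
#' also kept. Preterm is the positive class throughout. Deterministic for a
#' fixed seed.
#'
#' @param features Feature tibble (from [featurize()], or any tibble with
#'   `label` plus numeric feature columns).
#' @param model One of [model_names()].
#' @param k_folds Number of folds (default 10).
#' @param seed RNG seed (folds, SMOTE).
#' @param balance Apply SMOTE inside training folds (default `TRUE`).
#' @param smote_mode `"within_folds"` (leakage-safe default) or
#'   `"before_split"` (balance the full table first, the replication
#'   protocol).
#' @param k_neighbors SMOTE neighbourhood size.
#' @param group_by_patient Use patient-grouped folds so windows of one
#'   patient never straddle train and test.
#' @param hyper Optional named list of hyperparameter overrides.
#' @return An `eval_report` object; see [tidy()] / [glance()].
#' @export
crossval_eval <- function(features, model, k_folds = 10, seed = 1,
                          balance = TRUE,
                          smote_mode = c("within_folds", "before_split"),
                          k_neighbors = 5, group_by_patient = FALSE,
                          hyper = list()) {
  smote_mode <- match.arg(smote_mode)
  stopifnot(model %in% model_names())
  features <- sanitize_features(features)
  lab <- as_class_factor(features$label)
  if (any(table(lab) < k_folds)) {
    stop("need at least k_folds samples per class", call. = FALSE)
  }
  if (balance && smote_mode == "before_split") {
    features <- smote_balance(features, k_neighbors,
                              seed = derive_seed(seed, "smote_global"))
    features$synthetic <- NULL
    lab <- as_class_factor(features$label)
  }
  fold <- make_folds(features, k_folds, derive_seed(seed, "folds"),
                     group_by_patient)
  X <- feature_matrix(features)
  scores <- numeric(nrow(features))
  preds <- factor(rep(NA_character_, nrow(features)), levels = .classes)
  per_fold <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- fold != f
    te <- !tr
    if (length(unique(lab[te])) < 2 || length(unique(lab[tr])) < 2) {
      stop("a fold lost a class; use fewer folds or more data",
           call. = FALSE)
    }
    Xtr <- X[tr, , drop = FALSE]
    ytr <- lab[tr]
    if (balance && smote_mode == "within_folds") {
      trn <- tibble::as_tibble(Xtr)
      trn$label <- ytr
      bal <- smote_balance(trn, k_neighbors,
                           seed = derive_seed(seed, paste0("smote", f)))
      ytr <- as_class_factor(bal$label)
      Xtr <- as.matrix(bal[, colnames(X)])
    }
    withr::with_seed(derive_seed(seed, paste0("fit", f)), {
      fp <- fit_predict_model(model, Xtr, ytr, X[te, , drop = FALSE], hyper)
    })
    preds[te] <- fp$class
    scores[te] <- fp$score
    cmf <- fold_confusion(lab[te], fp$class)
    per_fold[[f]] <- dplyr::bind_cols(
      tibble::tibble(fold = f, n = sum(te)),
      compute_metrics(cmf, fp$score, lab[te]))
  }
  cm <- fold_confusion(lab, preds)
  metrics <- compute_metrics(cm, scores, lab)
  structure(list(model = model, acc = metrics$acc, sens = metrics$sens,
                 spec = metrics$spec, auc = metrics$auc,
                 confusion = cm, per_fold = dplyr::bind_rows(per_fold),
                 scores = scores, labels = lab, n = nrow(features)),
            class = "eval_report")
}

fold_confusion <- function(truth, pred) {
  c(tp = sum(truth == "preterm" & pred == "preterm"),
    fn = sum(truth == "preterm" & pred == "term"),
    tn = sum(truth == "term" & pred == "term"),
    fp = sum(truth == "term" & pred == "preterm"))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("%s: Acc %.1f%%  Sens %.1f%%  Spec %.1f%%  AUC %.1f%% (n = %d)\n",
              x$model, x$acc, x$sens, x$spec, x$auc, x$n))
  invisible(x)
}

#' @describeIn crossval_eval Per-fold metrics.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_fold

#' @describeIn crossval_eval One-row pooled summary.
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(model = x$model, acc = x$acc, sens = x$sens,
                 spec = x$spec, auc = x$auc, n = x$n)
}

#' Run the eight-model suite over raw and LSDL-decomposed features
#'
#' Evaluates every requested model on both preprocessing arms with the same
#' folds and seed, producing the long comparison table (one row per model
#' and arm).
#'
#' @param features_raw Feature table of the raw windows.
#' @param features_lsdl Feature table of the LSDL-decomposed windows
#'   (aligned rows).
#' @param models Subset of [model_names()].
#' @param ... Passed to [crossval_eval()].
#' @param seed RNG seed shared across models and arms.
#' @param k_folds Folds (default 10).
#' @return Tibble with `model`, `arm` (`raw` / `lsdl`), `acc`, `sens`,
#'   `spec`, `auc`.
#' @export
run_model_suite <- function(features_raw, features_lsdl,
                            models = model_names(), k_folds = 10, seed = 1,
                            ...) {
  arms <- list(raw = features_raw, lsdl = features_lsdl)
  purrr::map(models, function(m) {
    purrr::imap(arms, function(ft, arm) {
      rep <- crossval_eval(ft, m, k_folds = k_folds, seed = seed, ...)
      dplyr::bind_cols(tibble::tibble(model = m, arm = arm), glance(rep)[-1])
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Suite results in the conventional wide comparison layout
#'
#' @param suite Output of [run_model_suite()].
#' @return Tibble with columns `Model`, `Raw-Acc (%)`, `LSDL-Acc (%)`, ...,
#'   `LSDL-AUC (%)`, one row per model.
#' @export
suite_table <- function(suite) {
  long <- tidyr::pivot_longer(suite[, c("model", "arm", "acc", "sens",
                                        "spec", "auc")],
                              cols = c("acc", "sens", "spec", "auc"),
                              names_to = "metric")
  long$col <- paste0(ifelse(long$arm == "raw", "Raw-", "LSDL-"),
                     c(acc = "Acc", sens = "Sens", spec = "Spec",
                       auc = "AUC")[long$metric], " (%)")
  wide <- tidyr::pivot_wider(long[, c("model", "col", "value")],
                             names_from = "col", values_from = "value")
  ord <- c("Model", as.vector(t(outer(
    c("Acc", "Sens", "Spec", "AUC"),
    c("Raw-", "LSDL-"), function(m, a) paste0(a, m, " (%)")))))
  names(wide)[1] <- "Model"
  wide[, ord]
}

#' Plot the raw vs LSDL suite comparison
#'
#' @param object Output of [run_model_suite()].
#' @param metric Which metric to plot.
#' @return A ggplot.
#' @export
plot_suite <- function(object, metric = c("acc", "auc", "sens", "spec")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$model,
                                       y = .data[[metric]],
                                       fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = paste0(toupper(metric), " (%)"),
                  fill = "arm") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::theme_minimal()
}
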