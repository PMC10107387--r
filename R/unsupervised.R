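kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centres <- matrix(NA_real_, k, ncol(X))
  centres[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums(sweep(X, 2, centres[1, ])^2)
  if (k > 1) {
    for (j in 2:k) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centres[j, ] <- X[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums(sweep(X, 2, centres[j, ])^2))
    }
  }
  centres
}

lloyd_once <- function(X, k, tol = 1e-6, max_iter = 300) {
  centres <- kmeanspp_init(X, k)
  wss_trace <- numeric(0)
  assign <- integer(nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(j) rowSums(sweep(X, 2, centres[j, ])^2))
    assign <- max.col(-d2, ties.method = "first")
    wss_trace <- c(wss_trace, sum(d2[cbind(seq_len(nrow(X)), assign)]))
    new_centres <- centres
    for (j in seq_len(k)) {
      rows <- assign == j
      if (any(rows)) {
        new_centres[j, ] <- colMeans(X[rows, , drop = FALSE])
      } else {
        # re-seed an emptied cluster at the point farthest from its centre
        new_centres[j, ] <- X[which.max(d2[cbind(seq_len(nrow(X)), assign)]), ]
      }
    }
    shift <- max(abs(new_centres - centres))
    centres <- new_centres
    if (shift < tol) break
  }
  d2 <- sapply(seq_len(k), function(j) rowSums(sweep(X, 2, centres[j, ])^2))
  assign <- max.col(-d2, ties.method = "first")
  wss <- sum(d2[cbind(seq_len(nrow(X)), assign)])
  list(assign = assign, centres = centres, wss = wss,
       wss_trace = c(wss_trace, wss))
}

#' Two-cluster K-Means partitioning with restarts
#'
#' Lloyd iterations from k-means++ seeding, run `restarts` times. Restart
#' selection follows either the label-aware replication rule (keep the
#' partition whose evaluated overall accuracy is maximal, matching the
#' replication convention of keeping the maximum over five repetitions;
#' requires `labels`)
#' or the label-free rule (minimum within-cluster sum of squares).
#'
#' @param X Numeric feature matrix (or feature tibble; numeric columns
#'   except `window` are used).
#' @param n_clusters Number of clusters (default 2).
#' @param restarts Number of restarts (default 5).
#' @param seed RNG seed.
#' @param labels Optional true labels for the label-aware selection rule.
#' @param select `"accuracy"` (needs `labels`) or `"wss"`.
#' @return Integer cluster assignments with attributes `centres`, `wss`,
#'   `wss_trace` and `n_restarts_used`.
#' @export
kmeans_partition <- function(X, n_clusters = 2, restarts = 5, seed = 1,
                             labels = NULL,
                             select = c("accuracy", "wss")) {
  select <- match.arg(select)
  if (is.data.frame(X)) X <- feature_matrix(X)
  X <- as.matrix(X)
  if (nrow(unique(X)) < n_clusters) {
    stop("need at least n_clusters distinct rows", call. = FALSE)
  }
  if (select == "accuracy" && is.null(labels)) {
    stop("label-aware restart selection needs `labels`", call. = FALSE)
  }
  runs <- purrr::map(seq_len(restarts), function(r) {
    withr::with_seed(derive_seed(seed, paste0("kmeans", r)),
                     lloyd_once(X, n_clusters))
  })
  crit <- purrr::map_dbl(runs, function(run) {
    if (select == "wss") -run$wss else {
      evaluate_clusters(run$assign, labels)$overall_acc
    }
  })
  best <- runs[[which.max(crit)]]
  structure(best$assign, centres = best$centres, wss = best$wss,
            wss_trace = best$wss_trace, n_restarts_used = restarts)
}

log_mvn_density <- function(X, mu, sigma) {
  p <- ncol(X)
  ch <- chol(sigma) # errors on non-PD covariance -> failed restart
  z <- forwardsolve(t(ch), t(sweep(X, 2, mu)))
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * p * log(2 * pi)
}

em_gmm_once <- function(X, k, reg, tol, max_iter) {
  n <- nrow(X)
  p <- ncol(X)
  init <- lloyd_once(X, k)
  mu <- init$centres
  sigma <- lapply(seq_len(k), function(j) {
    rows <- init$assign == j
    s <- if (sum(rows) > p) stats::cov(X[rows, , drop = FALSE]) else stats::cov(X)
    s + diag(reg, p)
  })
  w <- as.numeric(table(factor(init$assign, levels = seq_len(k))) / n)
  w[w == 0] <- 1e-6
  w <- w / sum(w)
  ll_old <- -Inf
  resp <- NULL
  for (it in seq_len(max_iter)) {
    logd <- sapply(seq_len(k), function(j) {
      log(w[j]) + log_mvn_density(X, mu[j, ], sigma[[j]])
    })
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    if (!is.finite(ll)) stop("degenerate likelihood", call. = FALSE)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    nk <- colSums(resp)
    if (any(nk < 1e-8)) stop("emptied mixture component", call. = FALSE)
    w <- nk / n
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(resp[, j] * X) / nk[j]
      Xc <- sweep(X, 2, mu[j, ])
      # regularisation added to the covariance diagonal at every M-step
      sigma[[j]] <- crossprod(Xc * sqrt(resp[, j])) / nk[j] + diag(reg, p)
    }
  }
  list(assign = max.col(resp, ties.method = "first"), resp = resp,
       mu = mu, sigma = sigma, weights = w, loglik = ll)
}

#' Two-component Gaussian-mixture partitioning
#'
#' Full-covariance EM with a regularisation value added to each covariance
#' diagonal at every M-step (default 0.1), log-likelihood tolerance 1e-6,
#' at most 500 iterations, hard assignment by maximum posterior
#' responsibility. Degenerate restarts (singular covariance, emptied
#' component) are recorded as failures; if every restart fails the fit
#' errors; such a fit is reported as "n/a" in the clustering table.
#'
#' @inheritParams kmeans_partition
#' @param n_components Mixture components (default 2).
#' @param reg Diagonal regularisation added each M-step (default 0.1).
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return Integer assignments with attributes `responsibilities`, `means`,
#'   `loglik`, `n_failed_restarts`.
#' @export
gmm_partition <- function(X, n_components = 2, reg = 0.1, restarts = 5,
                          tol = 1e-6, max_iter = 500, seed = 1,
                          labels = NULL, select = c("accuracy", "wss")) {
  select <- match.arg(select)
  if (is.data.frame(X)) X <- feature_matrix(X)
  X <- as.matrix(X)
  if (nrow(X) < ncol(X)) {
    stop("fewer rows than dimensions; reduce dimensionality first ",
         "(e.g. pca_coords())", call. = FALSE)
  }
  if (select == "accuracy" && is.null(labels)) {
    stop("label-aware restart selection needs `labels`", call. = FALSE)
  }
  runs <- purrr::map(seq_len(restarts), function(r) {
    withr::with_seed(derive_seed(seed, paste0("gmm", r)), {
      tryCatch(em_gmm_once(X, n_components, reg, tol, max_iter),
               error = function(e) NULL)
    })
  })
  failed <- purrr::map_lgl(runs, is.null)
  if (all(failed)) {
    stop("all GMM restarts failed (singular or degenerate components)",
         call. = FALSE)
  }
  runs <- runs[!failed]
  crit <- purrr::map_dbl(runs, function(run) {
    if (select == "wss") run$loglik else {
      evaluate_clusters(run$assign, labels)$overall_acc
    }
  })
  best <- runs[[which.max(crit)]]
  structure(best$assign, responsibilities = best$resp, means = best$mu,
            loglik = best$loglik, n_failed_restarts = sum(failed))
}

#' Evaluate a two-cluster partition against the class labels
#'
#' Chooses the cluster-to-class bijection that maximises overall accuracy,
#' then reports the percentage of preterm windows in the preterm-mapped
#' cluster, likewise for term, and the overall accuracy as the truncated
#' (floored) unweighted mean of the two per-class accuracies — the summary
#' reporting convention of this analysis family's clustering tables.
#'
#' @param assignments Integer cluster assignments (two clusters).
#' @param labels True class labels aligned with `assignments`.
#' @return One-row tibble: `preterm_acc`, `term_acc`, `overall_acc`
#'   (integer percent), `mapping` (list-column, cluster id for each class).
#' @export
#' @examples
#' evaluate_clusters(c(1, 1, 2, 2), c("preterm", "preterm", "term", "term"))
evaluate_clusters <- function(assignments, labels) {
  labels <- as_class_factor(labels)
  cl <- sort(unique(assignments))
  if (length(cl) == 1) {
    cl <- c(cl, cl[1] + 1L) # degenerate single-cluster partition
    message("evaluate_clusters: single-cluster assignment; one class maps ",
            "to an empty cluster")
  }
  score <- function(map) { # map = cluster ids for c(preterm, term)
    p <- 100 * mean(assignments[labels == "preterm"] == map[1])
    t <- 100 * mean(assignments[labels == "term"] == map[2])
    c(p = p, t = t)
  }
  m1 <- score(c(cl[1], cl[2]))
  m2 <- score(c(cl[2], cl[1]))
  if (mean(m1) >= mean(m2)) {
    acc <- m1
    map <- c(preterm = cl[1], term = cl[2])
  } else {
    acc <- m2
    map <- c(preterm = cl[2], term = cl[1])
  }
  tibble::tibble(
    preterm_acc = acc[["p"]], term_acc = acc[["t"]],
    overall_acc = overall_accuracy(acc[["p"]], acc[["t"]]),
    mapping = list(map)
  )
}

#' Overall clustering accuracy convention
#'
#' The truncated (floored) unweighted mean of the two per-class accuracies,
#' in integer percent: `floor((preterm_acc + term_acc) / 2)`.
#'
#' @param preterm_acc,term_acc Per-class accuracies in percent.
#' @return Integer percent.
#' @export
#' @examples
#' overall_accuracy(88, 54) # 71
overall_accuracy <- function(preterm_acc, term_acc) {
  as.integer(floor((preterm_acc + term_acc) / 2))
}

#' Run both clustering models and tabulate per-class accuracies
#'
#' @param features Feature tibble with `label`.
#' @param restarts,seed,reg,select Passed through to the partitioners.
#' @return Tibble with columns `Model`, `Preterm (%)`,
#'   `Term (%)`, `Overall accuracy (%)`; a failed GMM is reported as
#'   `"n/a"`.
#' @export
cluster_report <- function(features, restarts = 5, seed = 1, reg = 0.1,
                           select = c("accuracy", "wss")) {
  select <- match.arg(select)
  labels <- as_class_factor(features$label)
  X <- scale(feature_matrix(sanitize_features(features)))
  X <- X[, apply(X, 2, function(c) all(is.finite(c))), drop = FALSE]
  one <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(`Model` = name, `Preterm (%)` = "n/a",
                            `Term (%)` = "n/a",
                            `Overall accuracy (%)` = "n/a"))
    }
    ev <- evaluate_clusters(res, labels)
    tibble::tibble(
      `Model` = name,
      `Preterm (%)` = sprintf("%.0f", ev$preterm_acc),
      `Term (%)` = sprintf("%.0f", ev$term_acc),
      `Overall accuracy (%)` = sprintf("%d", ev$overall_acc))
  }
  dplyr::bind_rows(
    one("GMM", function() gmm_partition(X, reg = reg, restarts = restarts,
                                        seed = seed, labels = labels,
                                        select = select)),
    one("K-Means", function() kmeans_partition(X, restarts = restarts,
                                               seed = seed, labels = labels,
                                               select = select))
  )
}
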