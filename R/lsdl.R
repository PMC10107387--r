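#' Threshold fraction of a decomposition candidate
#'
#' The LSDL candidate grid is dyadic in the reference amplitude `A`: lower
#' region iteration `i` retains samples with `|x| <= A * (2^i - 1) / 2^i`
#' (A/2, 3A/4, 7A/8, 15A/16), upper region iteration `i` retains samples
#' with `|x| >= A / 2^i` (A/2, A/4, A/8, A/16). Each iteration therefore
#' widens the retained band from the quiet (lower) or the loud (upper) end.
#'
#' @param region `"lower"` or `"upper"`.
#' @param iteration Integer 1-4 (or up to `max_iterations`).
#' @return The threshold as a fraction of `A`.
#' @export
lsdl_threshold <- function(region = c("lower", "upper"), iteration) {
  region <- match.arg(region)
  stopifnot(iteration >= 1)
  if (region == "lower") (2^iteration - 1) / 2^iteration else 1 / 2^iteration
}

#' Decompose a signal by an amplitude-band rule
#'
#' Retains the samples inside the candidate's amplitude band (see
#' [lsdl_threshold()]) and concatenates them in time order (excision, not
#' zero-filling). Errors with condition class `lsdl_too_few` when fewer than
#' `min_keep` samples survive.
#'
#' @param x Numeric sample vector.
#' @param region `"lower"` or `"upper"`.
#' @param iteration Iteration index (1-4).
#' @param A Reference amplitude (> 0), normally the maximum absolute
#'   amplitude over the training windows.
#' @param min_keep Minimum surviving samples (default 16).
#' @return The retained samples.
#' @export
#' @examples
#' lsdl_decompose(seq(0, 1, 0.01), "lower", 1, A = 1)
lsdl_decompose <- function(x, region = c("lower", "upper"), iteration, A,
                           min_keep = 16) {
  region <- match.arg(region)
  if (!is.finite(A) || A <= 0) stop("reference amplitude A must be > 0",
                                    call. = FALSE)
  thr <- A * lsdl_threshold(region, iteration)
  keep <- if (region == "lower") abs(x) <= thr else abs(x) >= thr
  y <- x[keep]
  if (length(y) < min_keep) {
    stop(structure(
      class = c("lsdl_too_few", "error", "condition"),
      list(message = sprintf(
        "only %d of %d samples survive the %s/iter-%d band (min_keep = %d)",
        length(y), length(x), region, iteration, min_keep),
        call = NULL)))
  }
  y
}

#' Class-separability cost J
#'
#' The normalised Euclidean distance between the two class-mean feature
#' vectors: `J = ED(p, q) / sigma_m`, where `p` and `q` are the per-class
#' column means, `ED` their Euclidean distance, and `sigma_m` the mean over
#' features of the population SD computed on the pooled windows of both
#' classes. `J = 0` iff the class means coincide; `J` is invariant under a
#' common positive rescaling of all features.
#'
#' @param feats_class1,feats_class2 Numeric feature matrices (windows in
#'   rows, the same features in columns).
#' @return The scalar J-score.
#' @export
#' @examples
#' f1 <- matrix(rnorm(20), 10, 2)
#' lsdl_cost(f1, f1 + 1)
lsdl_cost <- function(feats_class1, feats_class2) {
  f1 <- as.matrix(feats_class1)
  f2 <- as.matrix(feats_class2)
  if (nrow(f1) == 0 || nrow(f2) == 0) stop("empty feature matrix",
                                           call. = FALSE)
  if (ncol(f1) != ncol(f2)) stop("feature count mismatch", call. = FALSE)
  p <- colMeans(f1)
  q <- colMeans(f2)
  pooled <- rbind(f1, f2)
  mu <- colMeans(pooled)
  sigma <- sqrt(colMeans(sweep(pooled, 2, mu)^2)) # population SD per feature
  sigma_m <- mean(sigma)
  if (!is.finite(sigma_m) || sigma_m == 0) {
    stop("sigma_m is zero (all features constant); J undefined",
         call. = FALSE)
  }
  sqrt(sum((p - q)^2)) / sigma_m
}

#' Select the best threshold candidate
#'
#' The argmax-J rule over the candidate table: invalid candidates (failed
#' decompositions, `NA` cost) are excluded; exact cost ties break toward the
#' lower region, then the smaller iteration.
#'
#' @param candidates Tibble with columns `region`, `iteration`, `cost` and
#'   optionally `valid`.
#' @return The winning one-row tibble.
#' @export
#' @examples
#' cand <- tidyr::expand_grid(region = c("upper", "lower"), iteration = 1:4)
#' cand$cost <- c(2.1231, 2.1326, 2.1355, 2.1368, 2.2506, 2.3212, 2.3194, 2.1926)
#' lsdl_select_best(cand)
lsdl_select_best <- function(candidates) {
  ok <- candidates[!is.na(candidates$cost), ]
  if ("valid" %in% names(ok)) ok <- ok[ok$valid, ]
  if (nrow(ok) == 0) stop("no valid decomposition candidate", call. = FALSE)
  ok <- dplyr::arrange(ok, dplyr::desc(.data$cost), .data$region,
                       .data$iteration)
  ok[1, ]
}

#' Fit the Linear Series Decomposition Learner
#'
#' For every region x iteration candidate: decompose each training window,
#' extract the feature ensemble, and score the between-class separability
#' [lsdl_cost()]. The reference amplitude `A` is the maximum absolute
#' amplitude over the training windows only (never test data). Candidates
#' for which any window leaves fewer than `min_keep` samples are recorded
#' with an invalid (`NA`) cost and excluded from the argmax.
#'
#' @param windows Window tibble from [window_records()]; both classes must
#'   be present.
#' @param config A [feature_config()].
#' @param max_iterations Iterations per region (default 4, i.e. 8
#'   candidates).
#' @param min_keep Passed to [lsdl_decompose()].
#' @return An object of class `lsdl`: `best` (winning candidate row), `A`,
#'   `candidates` (full table), `config`, and the cached per-candidate
#'   feature matrices used for permutation tests.
#' @export
lsdl_fit <- function(windows, config = feature_config(), max_iterations = 4,
                     min_keep = 16) {
  labs <- as_class_factor(windows$label)
  if (length(unique(labs[!is.na(labs)])) < 2) {
    stop("both classes must be present in the training windows",
         call. = FALSE)
  }
  A <- max(purrr::map_dbl(windows$samples, ~ max(abs(.x))))
  if (A <= 0) stop("degenerate training amplitude (A = 0)", call. = FALSE)
  grid <- tidyr::expand_grid(region = c("upper", "lower"),
                             iteration = seq_len(max_iterations))
  feats <- vector("list", nrow(grid))
  res <- purrr::pmap(grid, function(region, iteration) {
    mats <- purrr::map(windows$samples, function(x) {
      tryCatch(lsdl_decompose(x, region, iteration, A, min_keep),
               lsdl_too_few = function(e) NULL)
    })
    n_failed <- sum(purrr::map_lgl(mats, is.null))
    if (n_failed > 0) {
      return(list(cost = NA_real_, n_failed = n_failed, feats = NULL))
    }
    fm <- do.call(rbind, purrr::pmap(
      list(mats, windows$fs, windows$kind),
      function(x, fs, kind) {
        cfg <- config
        cfg$eps_threshold <- resolve_eps(config, kind)
        extract_features(x, fs, cfg)
      }))
    fin <- apply(fm, 2, function(col) all(is.finite(col)))
    cost <- tryCatch(
      lsdl_cost(fm[labs == "preterm", fin, drop = FALSE],
                fm[labs == "term", fin, drop = FALSE]),
      error = function(e) NA_real_)
    list(cost = cost, n_failed = 0L, feats = fm)
  })
  cand <- dplyr::mutate(
    grid,
    threshold = purrr::map2_dbl(.data$region, .data$iteration,
                                lsdl_threshold),
    cost = purrr::map_dbl(res, "cost"),
    n_failed = purrr::map_int(res, "n_failed"),
    valid = !is.na(.data$cost)
  )
  best <- lsdl_select_best(cand)
  structure(list(best = best, A = A, candidates = cand, config = config,
                 min_keep = min_keep,
                 feature_tables = purrr::map(res, "feats"), labels = labs),
            class = "lsdl")
}

#' Apply a fitted LSDL rule to windows
#'
#' Decomposes every window with the fitted band. Windows that leave too few
#' samples fall back to the raw window with a warning (set `strict = TRUE`
#' to error instead).
#'
#' @param object A fitted `lsdl` model.
#' @param windows Window tibble.
#' @param strict Error instead of falling back on too-few-samples windows.
#' @param ... Unused.
#' @return The window tibble with decomposed `samples`.
#' @export
predict.lsdl <- function(object, windows, strict = FALSE, ...) {
  b <- object$best
  out <- windows
  out$samples <- purrr::map(windows$samples, function(x) {
    tryCatch(
      lsdl_decompose(x, b$region, b$iteration, object$A, object$min_keep),
      lsdl_too_few = function(e) {
        if (strict) stop(e)
        warning("window fell below min_keep after decomposition; ",
                "raw window retained", call. = FALSE)
        x
      })
  })
  out
}

#' Permutation null of the best J-score
#'
#' Re-evaluates the argmax-J over the cached candidate feature matrices
#' under random label permutations, giving the null distribution of the
#' selected cost on a cohort with no class effect.
#'
#' @param object A fitted `lsdl` model.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return Numeric vector of length `n_perm` of null best-J values.
#' @export
lsdl_null_j <- function(object, n_perm = 99, seed = 1) {
  mats <- object$feature_tables
  ok <- !purrr::map_lgl(mats, is.null)
  labs <- object$labels
  withr::with_seed(seed, {
    purrr::map_dbl(seq_len(n_perm), function(i) {
      pl <- sample(labs)
      max(purrr::map_dbl(mats[ok], function(fm) {
        fin <- apply(fm, 2, function(col) all(is.finite(col)))
        tryCatch(lsdl_cost(fm[pl == "preterm", fin, drop = FALSE],
                           fm[pl == "term", fin, drop = FALSE]),
                 error = function(e) NA_real_)
      }), na.rm = TRUE)
    })
  })
}

#' @export
print.lsdl <- function(x, ...) {
  b <- x$best
  cat("LSDL model\n")
  cat(sprintf("  best: %s region, iteration %d (threshold %.4f * A), J = %.4f\n",
              b$region, b$iteration, b$threshold, b$cost))
  cat(sprintf("  reference amplitude A = %.4g\n", x$A))
  cat(sprintf("  %d candidates evaluated (%d valid)\n",
              nrow(x$candidates), sum(x$candidates$valid)))
  invisible(x)
}

#' @describeIn lsdl_fit Candidate table, one row per region x iteration.
#' @param x A fitted `lsdl` model.
#' @param ... Unused.
#' @method tidy lsdl
#' @export
tidy.lsdl <- function(x, ...) x$candidates

#' @describeIn lsdl_fit One-row summary of the fitted rule.
#' @method glance lsdl
#' @export
glance.lsdl <- function(x, ...) {
  tibble::tibble(region = x$best$region, iteration = x$best$iteration,
                 threshold = x$best$threshold, cost = x$best$cost,
                 A = x$A, n_candidates = nrow(x$candidates),
                 n_valid = sum(x$candidates$valid))
}

#' Candidate table in the wide two-region layout
#'
#' Two rows (upper/lower threshold) by iteration columns, invalid
#' candidates shown as `"n/a"`.
#'
#' @param model A fitted `lsdl` model.
#' @return A tibble.
#' @export
lsdl_table <- function(model) {
  cand <- model$candidates
  wide <- tidyr::pivot_wider(
    dplyr::transmute(
      cand,
      Region = ifelse(.data$region == "upper", "Upper threshold",
                      "Lower threshold"),
      iteration = paste("Iteration", .data$iteration),
      cell = ifelse(is.na(.data$cost), "n/a", sprintf("%.4f", .data$cost))),
    names_from = "iteration", values_from = "cell")
  wide[order(wide$Region, decreasing = TRUE), ]
}

#' Serialize / restore a fitted LSDL model as JSON
#'
#' Stores the winning rule, the reference amplitude and the candidate table
#' (not the cached feature matrices).
#'
#' @param model A fitted `lsdl` model.
#' @param path Output path.
#' @return `write_lsdl` the path invisibly; `read_lsdl` a reduced `lsdl`
#'   object usable with [predict.lsdl()].
#' @export
write_lsdl <- function(model, path) {
  obj <- list(
    best = as.list(model$best),
    A = model$A,
    min_keep = model$min_keep,
    candidates = model$candidates
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lsdl
#' @export
read_lsdl <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(best = tibble::as_tibble(obj$best), A = obj$A,
                 candidates = tibble::as_tibble(obj$candidates),
                 config = feature_config(), min_keep = obj$min_keep,
                 feature_tables = NULL, labels = NULL),
            class = "lsdl")
}

#' Plot the candidate costs of a fitted LSDL model
#'
#' @param object A fitted `lsdl` model.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot lsdl
#' @export
autoplot.lsdl <- function(object, ...) {
  cand <- object$candidates
  best <- object$best
  ggplot2::ggplot(cand, ggplot2::aes(x = factor(.data$iteration),
                                     y = .data$cost,
                                     fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(
      data = best,
      ggplot2::aes(x = factor(.data$iteration), y = .data$cost),
      shape = 8, size = 3, inherit.aes = FALSE) +
    ggplot2::labs(x = "iteration", y = "separability cost J",
                  fill = "region",
                  title = "LSDL candidate separability") +
    ggplot2::theme_minimal()
}
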