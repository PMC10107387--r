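#' SMOTE oversampling of the minority class
#'
#' Brings the minority class to parity by synthesising points on segments
#' between minority rows and their k nearest same-class neighbours
#' (Euclidean distance in feature space): each synthetic row is
#' `x_i + u * (x_nn - x_i)` with `u ~ Uniform(0, 1)`. Majority rows and all
#' original rows pass through unchanged. Deterministic for a fixed seed.
#'
#' The returned table carries a logical `synthetic` column and (as the
#' `"parents"` attribute) the parent row, neighbour row and `u` of every
#' synthetic point, so the convex-interpolation property can be audited.
#'
#' @param features Feature tibble with a `label` column; every numeric
#'   column except `window` is treated as a feature.
#' @param k_neighbors Number of candidate neighbours (default 5); the
#'   minority class must have at least `k_neighbors + 1` members.
#' @param seed RNG seed.
#' @return The balanced tibble (original rows first, then synthetic rows).
#' @export
#' @examples
#' ft <- tibble::tibble(label = rep(c("term", "preterm"), c(12, 7)),
#'                      f1 = rnorm(19), f2 = rnorm(19))
#' table(smote_balance(ft, seed = 1)$label)
smote_balance <- function(features, k_neighbors = 5, seed = 1) {
  stopifnot(k_neighbors >= 1, "label" %in% names(features))
  lab <- as_class_factor(features$label)
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                              logical(1))], "window")
  counts <- table(lab)
  out <- dplyr::mutate(features, synthetic = FALSE)
  if (counts[1] == counts[2]) return(out)
  minority <- names(counts)[which.min(counts)]
  n_syn <- abs(diff(as.integer(counts)))
  idx_min <- which(lab == minority)
  n_min <- length(idx_min)
  if (n_min < k_neighbors + 1) {
    stop("minority class too small for k_neighbors = ", k_neighbors,
         call. = FALSE)
  }
  X <- as.matrix(features[idx_min, feat_cols])
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k_neighbors)]))
  withr::with_seed(seed, {
    parent <- sample.int(n_min, n_syn, replace = TRUE)
    pick <- sample.int(k_neighbors, n_syn, replace = TRUE)
    u <- runif(n_syn)
  })
  neighbour <- nn[cbind(parent, pick)]
  syn <- X[parent, , drop = FALSE] +
    u * (X[neighbour, , drop = FALSE] - X[parent, , drop = FALSE])
  syn_tbl <- tibble::as_tibble(syn)
  syn_tbl$label <- factor(minority, levels = .classes)
  if ("patient_id" %in% names(features)) {
    syn_tbl$patient_id <- sprintf("SYN%03d", seq_len(n_syn))
  }
  if ("window" %in% names(features)) syn_tbl$window <- NA_integer_
  syn_tbl$synthetic <- TRUE
  res <- dplyr::bind_rows(out, syn_tbl[, names(out)])
  attr(res, "parents") <- tibble::tibble(
    parent = idx_min[parent], neighbour = idx_min[neighbour], u = u)
  res
}
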