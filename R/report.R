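#' Principal-component coordinates of a feature table
#'
#' Standardises every feature (zero mean, unit SD; zero-variance features
#' are dropped with a warning, since the ensemble mixes units spanning
#' orders of magnitude), then projects onto the leading principal
#' components. Components are ordered by decreasing explained variance and
#' signed so each component's largest-magnitude loading is positive.
#'
#' @param features Feature tibble (>= 3 rows, >= 2 features).
#' @param n_components Components to keep (default 2).
#' @return An object of class `pca_coords`: `coords` tibble (id/label
#'   columns plus `PC1`, `PC2`, ...) and `explained_variance` fractions.
#' @export
pca_coords <- function(features, n_components = 2) {
  X <- feature_matrix(sanitize_features(features))
  if (nrow(X) < 3 || ncol(X) < 2) {
    stop("need at least 3 rows and 2 features", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  k <- min(n_components, ncol(pc$rotation))
  for (j in seq_len(k)) {
    if (pc$rotation[which.max(abs(pc$rotation[, j])), j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  idc <- intersect(c("patient_id", "label", "window"), names(features))
  coords <- dplyr::bind_cols(features[, idc],
                             tibble::as_tibble(pc$x[, seq_len(k),
                                                    drop = FALSE]))
  structure(list(coords = coords,
                 explained_variance = pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_coords")
}

#' @export
print.pca_coords <- function(x, ...) {
  cat("PCA coordinates:", nrow(x$coords), "rows\n")
  cat("explained variance:",
      paste(sprintf("%.3f", head(x$explained_variance, 5)), collapse = " "),
      "\n")
  invisible(x)
}

#' @describeIn pca_coords Coordinates as a tibble.
#' @param x A `pca_coords` object.
#' @param ... Unused.
#' @method tidy pca_coords
#' @export
tidy.pca_coords <- function(x, ...) x$coords

#' Plot the first two principal components by class
#'
#' @param object A [pca_coords()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pca_coords
#' @export
autoplot.pca_coords <- function(object, ...) {
  ev <- object$explained_variance
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Assemble an end-to-end experiment configuration
#'
#' @param cohort A [cohort_params()] object (its `signal_kind` selects the
#'   signal analysed).
#' @param epoch_s Envelope epoch length in seconds.
#' @param n_windows Disjoint windows per record.
#' @param features A [feature_config()].
#' @param max_iterations LSDL iterations per region.
#' @param models Supervised models to run.
#' @param k_folds Cross-validation folds.
#' @param smote_mode SMOTE placement (see [crossval_eval()]).
#' @param k_neighbors SMOTE neighbourhood size.
#' @param restarts Clustering restarts.
#' @param gmm_reg GMM covariance regularisation.
#' @param cluster_arm `"lsdl"` (default) or `"raw"` feature table for
#'   clustering.
#' @param output_dir Where [run_experiment()] writes its artifacts.
#' @param master_seed Master seed; every stage derives its own seed from it
#'   via [derive_seed()].
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_params(),
                              epoch_s = 2, n_windows = 10,
                              features = feature_config(),
                              max_iterations = 4,
                              models = model_names(), k_folds = 10,
                              smote_mode = "within_folds", k_neighbors = 5,
                              restarts = 5, gmm_reg = 0.1,
                              cluster_arm = c("lsdl", "raw"),
                              output_dir = tempfile("experiment"),
                              master_seed = 1) {
  structure(list(cohort = cohort, epoch_s = epoch_s, n_windows = n_windows,
                 features = features, max_iterations = max_iterations,
                 models = models, k_folds = k_folds,
                 smote_mode = smote_mode, k_neighbors = k_neighbors,
                 restarts = restarts, gmm_reg = gmm_reg,
                 cluster_arm = match.arg(cluster_arm),
                 output_dir = output_dir, master_seed = master_seed),
            class = "experiment_config")
}

#' Run a full experiment from a configuration
#'
#' Generates the cohort, preprocesses and windows it, fits the LSDL, builds
#' both feature tables, evaluates the supervised suite and both clustering
#' models, computes PCA coordinates, and writes every artifact under
#' `config$output_dir`: record files + manifest, the fitted LSDL (JSON) and
#' its candidate table (CSV, wide two-region layout), raw and decomposed feature
#' tables, the supervised comparison table, the clustering table, PCA
#' coordinates, and a run log with the derived stage seeds. Byte-identical
#' outputs for identical configuration and master seed.
#'
#' @param config An [experiment_config()].
#' @return Manifest tibble (`artifact`, `path`), invisibly the full result
#'   list as attribute `"results"`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  ms <- config$master_seed
  stage_seeds <- c(cohort = derive_seed(ms, "cohort"),
                   suite = derive_seed(ms, "suite"),
                   clustering = derive_seed(ms, "clustering"))

  params <- config$cohort
  params$seed <- stage_seeds[["cohort"]]
  cohort <- generate_cohort(params)
  write_cohort(cohort, out("records"))

  if (params$signal_kind == "EHG") {
    cohort <- epoch_average(cohort, config$epoch_s)
  }
  cohort <- select_records(cohort, min_len = config$n_windows)
  windows <- window_records(cohort, config$n_windows)

  model <- lsdl_fit(windows, config$features, config$max_iterations)
  write_lsdl(model, out("lsdl_model.json"))
  readr::write_csv(lsdl_table(model), out("lsdl_candidates.csv"))

  features_raw <- featurize(windows, config$features)
  features_lsdl <- featurize(windows, config$features, lsdl = model)
  readr::write_csv(features_raw, out("features_raw.csv"))
  readr::write_csv(features_lsdl, out("features_lsdl.csv"))

  suite <- run_model_suite(features_raw, features_lsdl,
                           models = config$models,
                           k_folds = config$k_folds,
                           seed = stage_seeds[["suite"]],
                           smote_mode = config$smote_mode,
                           k_neighbors = config$k_neighbors)
  readr::write_csv(suite_table(suite), out("supervised_report.csv"))

  cluster_features <- if (config$cluster_arm == "lsdl") features_lsdl else {
    features_raw
  }
  clusters <- cluster_report(cluster_features, restarts = config$restarts,
                             seed = stage_seeds[["clustering"]],
                             reg = config$gmm_reg)
  readr::write_csv(clusters, out("clustering_report.csv"))

  pca <- pca_coords(cluster_features)
  readr::write_csv(tidy(pca), out("pca_coords.csv"))

  log_lines <- c(
    paste0("package_version: ", as.character(utils::packageVersion("pretermlsdl"))),
    paste0("master_seed: ", ms),
    paste0("signal_kind: ", params$signal_kind),
    paste0("stage_seed_", names(stage_seeds), ": ", stage_seeds))
  writeLines(log_lines, out("run_log.txt"))

  manifest <- tibble::tibble(
    artifact = c("records", "lsdl_model", "lsdl_candidates", "features_raw",
                 "features_lsdl", "supervised_report", "clustering_report",
                 "pca_coords", "run_log"),
    path = c(out("records"), out("lsdl_model.json"),
             out("lsdl_candidates.csv"), out("features_raw.csv"),
             out("features_lsdl.csv"), out("supervised_report.csv"),
             out("clustering_report.csv"), out("pca_coords.csv"),
             out("run_log.txt")))
  attr(manifest, "results") <- list(lsdl = model, suite = suite,
                                    clusters = clusters, pca = pca)
  manifest
}
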