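#' Derive a stage seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed. Per-stage seeds
#' are derived deterministically by hashing the stage name (a short label such
#' as `"cohort"` or `"folds"`) together with the master seed, so that adding a
#' stage never perturbs the random stream of another.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "cohort")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- 0
  for (k in utf8ToInt(paste(stage, collapse = ""))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((abs(master) %% 2147483647 * 10007 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# class labels used throughout; preterm is the positive class
.classes <- c("term", "preterm")

as_class_factor <- function(label) {
  factor(as.character(label), levels = .classes)
}

assert_label <- function(label) {
  if (!is.character(label) || length(label) != 1 || !label %in% .classes) {
    stop("`label` must be one of \"term\", \"preterm\"", call. = FALSE)
  }
  label
}
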