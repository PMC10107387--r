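#' Epoch-average a cohort to its amplitude envelope
#'
#' Replaces each record's samples by the mean of the absolute amplitude over
#' non-overlapping epochs of `epoch_s` seconds (the export convention of the
#' acquisition software: a 2-second epoch-averaging scheme producing a
#' down-sampled envelope). The trailing partial epoch is dropped and the
#' output sampling rate becomes `1/epoch_s`.
#'
#' @param cohort Cohort tibble; every record needs a finite `fs > 0`.
#' @param epoch_s Epoch length in seconds (default 2).
#' @return The cohort with down-sampled envelope records.
#' @export
epoch_average <- function(cohort, epoch_s = 2) {
  stopifnot(nrow(cohort) > 0)
  if (any(!is.finite(cohort$fs) | cohort$fs <= 0)) {
    stop("epoch averaging needs records with a positive sampling rate",
         call. = FALSE)
  }
  m <- floor(epoch_s * cohort$fs[1])
  if (any(floor(epoch_s * cohort$fs) < 1)) {
    stop("epoch_s * fs must be >= 1", call. = FALSE)
  }
  out <- cohort
  out$samples <- purrr::map2(cohort$samples, cohort$fs, function(x, fs) {
    m <- floor(epoch_s * fs)
    if (length(x) < m) stop("record shorter than one epoch", call. = FALSE)
    n_out <- floor(length(x) / m)
    colMeans(matrix(abs(x[seq_len(n_out * m)]), nrow = m))
  })
  out$fs <- 1 / epoch_s
  out
}

#' Down-select records by minimum length
#'
#' Keeps exactly the records with at least `min_len` samples, preserving
#' order, and messages the excluded patient ids (mirroring the study's
#' down-selection of exported files with enough usable signal).
#'
#' @param cohort Cohort tibble.
#' @param min_len Minimum number of samples (>= 1).
#' @return The filtered cohort; warns if nothing survives.
#' @export
select_records <- function(cohort, min_len) {
  stopifnot(min_len >= 1)
  len <- purrr::map_int(cohort$samples, length)
  dropped <- cohort$patient_id[len < min_len]
  if (length(dropped) > 0) {
    message("select_records: excluded ", paste(dropped, collapse = ", "))
  }
  out <- cohort[len >= min_len, ]
  if (nrow(out) == 0) warning("no records survive the length filter")
  out
}

#' Split each record into equal disjoint windows
#'
#' Divides every record into `n_windows` contiguous equal slices of
#' `floor(N / n_windows)` samples; the trailing remainder is discarded so
#' all windows have identical length within a record.
#'
#' @param cohort Cohort tibble.
#' @param n_windows Number of windows per record (default 10).
#' @return A window tibble: `patient_id`, `label`, `kind`, `fs`, `window`
#'   (1-based index), `samples` (list-column).
#' @export
#' @examples
#' co <- generate_cohort(cohort_params(n_term = 1, n_preterm = 1))
#' w <- window_records(co)
#' table(w$window)
window_records <- function(cohort, n_windows = 10) {
  stopifnot(n_windows >= 1)
  len <- purrr::map_int(cohort$samples, length)
  if (any(len < n_windows)) {
    stop("record(s) shorter than n_windows: ",
         paste(cohort$patient_id[len < n_windows], collapse = ", "),
         call. = FALSE)
  }
  purrr::pmap(cohort, function(patient_id, label, kind, fs, samples, ...) {
    wlen <- floor(length(samples) / n_windows)
    tibble::tibble(
      patient_id = patient_id,
      label = as_class_factor(label),
      kind = kind,
      fs = fs,
      window = seq_len(n_windows),
      samples = lapply(seq_len(n_windows), function(j) {
        samples[((j - 1) * wlen + 1):(j * wlen)]
      })
    )
  }) |>
    dplyr::bind_rows()
}
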