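#' Write a cohort to delimited text files
#'
#' One file per record: `#`-prefixed header lines (`patient_id`, `label`,
#' `kind`, `fs`) followed by one sample per line at full double precision,
#' plus a `manifest.csv` (patient_id, label, kind, path). [read_cohort()]
#' round-trips exactly.
#'
#' @param cohort Cohort tibble (from [generate_cohort()] or [read_cohort()]).
#' @param dir Output directory (created if missing).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    rec <- cohort[i, ]
    path <- file.path(dir, paste0(rec$patient_id, ".txt"))
    hdr <- c(
      paste0("# patient_id=", rec$patient_id),
      paste0("# label=", as.character(rec$label)),
      paste0("# kind=", rec$kind),
      paste0("# fs=", if (is.na(rec$fs)) "NA" else sprintf("%.17g", rec$fs))
    )
    writeLines(c(hdr, sprintf("%.17g", rec$samples[[1]])), path)
    paths[i] <- basename(path)
  }
  manifest <- tibble::tibble(
    patient_id = cohort$patient_id,
    label = as.character(cohort$label),
    kind = cohort$kind,
    path = paths
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the record files.
#' @return A cohort tibble.
#' @export
read_cohort <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  recs <- purrr::pmap(manifest, function(patient_id, label, kind, path) {
    lines <- readLines(file.path(dir, path))
    is_hdr <- startsWith(lines, "#")
    hdr <- lines[is_hdr]
    fs_chr <- sub("^# fs=", "", hdr[startsWith(hdr, "# fs=")])
    fs <- if (fs_chr == "NA") NA_real_ else as.numeric(fs_chr)
    new_record(patient_id, label, kind, fs, as.numeric(lines[!is_hdr]))
  })
  dplyr::bind_rows(recs)
}
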