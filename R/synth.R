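#' Cohort generator parameters
#'
#' Collects every knob of the synthetic two-class cohort generator. Defaults
#' encode the study conditions the pipeline targets: an EHG contraction
#' envelope sampled once per 2-second epoch (0.5 Hz) over 10 minutes of
#' active labour with at least four contractions per 10 minutes, and
#' maternal beat-to-beat RR series with class means/SDs of
#' 431.2 +/- 31.0 ms (term) and 413.2 +/- 26.9 ms (preterm). Foetal RR
#' baselines span 110-170 bpm.
#'
#' @param n_term,n_preterm Records per class (defaults 27 and 20, the EHG
#'   cohort sizes).
#' @param signal_kind One of `"EHG"`, `"MHR"`, `"FHR"`.
#' @param fs Sampling rate of the EHG envelope in Hz (default 0.5, one
#'   sample per 2-s epoch).
#' @param duration Record duration in seconds (default 600).
#' @param rr_mean_term,rr_sd_term,rr_mean_preterm,rr_sd_preterm Maternal RR
#'   class means and SDs in ms.
#' @param fhr_baseline_bpm Length-2 range of foetal heart-rate baseline in
#'   beats per minute.
#' @param burst_rate_per_10min Named pair `c(term=, preterm=)` of expected
#'   contraction bursts per 10 minutes; both must be at least 4 (the
#'   active-labour criterion).
#' @param burst_amp_gain Named pair of class multipliers on the burst peak
#'   amplitude.
#' @param burst_amp_uv Base burst peak amplitude in microvolts.
#' @param burst_width_s Gaussian burst width (SD of the temporal window) in
#'   seconds.
#' @param noise_sd_uv SD of the rectified baseline noise in microvolts.
#' @param artifact_rate_per_10min Rate of class-independent high-amplitude
#'   bursts per 10 minutes (0 disables them). These emulate movement or
#'   electrode artefacts common to both classes.
#' @param artifact_amp_uv Peak amplitude of artefact bursts in microvolts.
#' @param ar1_coeff Lag-1 autoregressive coefficient of the RR series,
#'   `|ar1_coeff| < 1`.
#' @param seed Master seed for [generate_cohort()].
#' @param preset Convenience scenario: `"amplitude"` (default; class effect
#'   in burst amplitude and rate), `"mid_band"` (class effect confined to
#'   mid-amplitude bursts, with identical high-amplitude artefact bursts in
#'   both classes), or `"null"` (no class effect anywhere; negative
#'   control).
#' @return A list of class `cohort_params`.
#' @export
#' @examples
#' p <- cohort_params(n_term = 4, n_preterm = 4)
#' p$rr_mean_term
cohort_params <- function(n_term = 27, n_preterm = 20,
                          signal_kind = c("EHG", "MHR", "FHR"),
                          fs = 0.5, duration = 600,
                          rr_mean_term = 431.2, rr_sd_term = 31.0,
                          rr_mean_preterm = 413.2, rr_sd_preterm = 26.9,
                          fhr_baseline_bpm = c(110, 170),
                          burst_rate_per_10min = c(term = 4, preterm = 6),
                          burst_amp_gain = c(term = 1, preterm = 1.4),
                          burst_amp_uv = 12, burst_width_s = 15,
                          noise_sd_uv = 1.5,
                          artifact_rate_per_10min = 0,
                          artifact_amp_uv = 30,
                          ar1_coeff = 0.6, seed = 1,
                          preset = c("amplitude", "mid_band", "null")) {
  signal_kind <- match.arg(signal_kind)
  preset <- match.arg(preset)
  p <- list(
    n_term = n_term, n_preterm = n_preterm, signal_kind = signal_kind,
    fs = fs, duration = duration,
    rr_mean_term = rr_mean_term, rr_sd_term = rr_sd_term,
    rr_mean_preterm = rr_mean_preterm, rr_sd_preterm = rr_sd_preterm,
    fhr_baseline_bpm = fhr_baseline_bpm,
    burst_rate_per_10min = burst_rate_per_10min,
    burst_amp_gain = burst_amp_gain,
    burst_amp_uv = burst_amp_uv, burst_width_s = burst_width_s,
    noise_sd_uv = noise_sd_uv,
    artifact_rate_per_10min = artifact_rate_per_10min,
    artifact_amp_uv = artifact_amp_uv,
    ar1_coeff = ar1_coeff, seed = seed, preset = preset
  )
  if (preset == "mid_band") {
    # class signal lives in mid-amplitude contraction bursts; saturation
    # artefacts at the top of the amplitude range are shared by both
    # classes and carry no class information
    if (missing(artifact_rate_per_10min)) p$artifact_rate_per_10min <- 6
    if (missing(artifact_amp_uv)) p$artifact_amp_uv <- 60
    if (missing(burst_amp_gain)) p$burst_amp_gain <- c(term = 1, preterm = 1.5)
    if (missing(burst_rate_per_10min)) {
      p$burst_rate_per_10min <- c(term = 4, preterm = 7)
    }
  }
  if (preset == "null") {
    p$burst_rate_per_10min <- c(term = 4, preterm = 4)
    p$burst_amp_gain <- c(term = 1, preterm = 1)
    p$rr_mean_preterm <- p$rr_mean_term
    p$rr_sd_preterm <- p$rr_sd_term
  }
  validate_cohort_params(p)
  structure(p, class = "cohort_params")
}

validate_cohort_params <- function(p) {
  if (p$n_term < 1 || p$n_preterm < 1) {
    stop("n_term and n_preterm must both be >= 1", call. = FALSE)
  }
  if (any(c(p$rr_sd_term, p$rr_sd_preterm) < 0)) {
    stop("RR standard deviations must be >= 0", call. = FALSE)
  }
  if (any(p$burst_rate_per_10min < 4)) {
    stop("burst rates must be >= 4 per 10 min (active-labour criterion)",
         call. = FALSE)
  }
  if (abs(p$ar1_coeff) >= 1) {
    stop("|ar1_coeff| must be < 1", call. = FALSE)
  }
  if (p$fs <= 0 || p$duration <= 0) {
    stop("fs and duration must be positive", call. = FALSE)
  }
  invisible(p)
}

new_record <- function(patient_id, label, kind, fs, samples) {
  tibble::tibble(
    patient_id = patient_id,
    label = as_class_factor(label),
    kind = kind,
    fs = fs,
    samples = list(as.numeric(samples))
  )
}

# sum of Gaussian-windowed bursts evaluated on time grid t
burst_train <- function(t, n_bursts, duration, width_s, amp_uv) {
  y <- numeric(length(t))
  if (n_bursts < 1) return(y)
  centre <- runif(n_bursts, 0, duration)
  width <- width_s * exp(rnorm(n_bursts, 0, 0.15))
  amp <- amp_uv * exp(rnorm(n_bursts, 0, 0.2))
  for (j in seq_len(n_bursts)) {
    y <- y + amp[j] * exp(-(t - centre[j])^2 / (2 * width[j]^2))
  }
  y
}

#' Generate one synthetic EHG contraction-envelope record
#'
#' Produces a non-negative uterine-contraction envelope: rectified Gaussian
#' baseline noise plus Gaussian-windowed contraction bursts whose count over
#' the record is Poisson with the class's expected rate, and whose peak
#' amplitude carries the class effect (preterm gain larger by default). When
#' `artifact_rate_per_10min > 0`, class-independent tall bursts are added at
#' the same rate in both classes. With `scale = "raw"` a 900 Hz carrier-burst
#' record is produced instead (to exercise [epoch_average()]).
#'
#' @param params A [cohort_params()] object.
#' @param label `"term"` or `"preterm"`.
#' @param seed Integer seed; fixed seed gives an identical record.
#' @param scale `"envelope"` (default) generates directly at the exported
#'   envelope scale (`params$fs`); `"raw"` generates at 900 Hz with an
#'   oscillatory carrier under the same burst envelope.
#' @param patient_id Identifier stored in the record.
#' @return A one-row record tibble (`patient_id`, `label`, `kind`, `fs`,
#'   `samples` list-column).
#' @export
#' @examples
#' r <- generate_ehg(cohort_params(), "term", seed = 1)
#' length(r$samples[[1]])
generate_ehg <- function(params, label, seed,
                         scale = c("envelope", "raw"), patient_id = "P00") {
  assert_label(label)
  scale <- match.arg(scale)
  if (params$duration < 600) {
    stop("duration must be >= 600 s (one full 10-minute active-labour block)",
         call. = FALSE)
  }
  fs <- if (scale == "raw") 900 else params$fs
  withr::with_seed(seed, {
    n <- floor(params$duration * fs)
    t <- (seq_len(n) - 1) / fs
    rate <- params$burst_rate_per_10min[[label]] * params$duration / 600
    nb <- rpois(1, rate)
    bw <- if (length(params$burst_width_s) > 1) {
      params$burst_width_s[[label]]
    } else {
      params$burst_width_s
    }
    env <- burst_train(t, nb, params$duration, bw,
                       params$burst_amp_uv * params$burst_amp_gain[[label]])
    x <- if (scale == "raw") {
      env * sin(2 * pi * 0.8 * t) + rnorm(n, 0, params$noise_sd_uv)
    } else {
      env + abs(rnorm(n, 0, params$noise_sd_uv))
    }
    if (params$artifact_rate_per_10min > 0 && scale == "envelope") {
      # saturation artefacts: during movement/electrode-contact episodes the
      # exported envelope rails at the amplifier ceiling, identically in
      # both classes, so the artefact occupies the single amplitude A
      # disjoint from the contraction-burst band below it
      na <- rpois(1, params$artifact_rate_per_10min * params$duration / 600)
      aw <- params$artifact_width_s %||% (max(params$burst_width_s) / 3)
      if (na > 0) {
        centre <- runif(na, 0, params$duration)
        for (j in seq_len(na)) {
          x[abs(t - centre[j]) <= aw] <- params$artifact_amp_uv
        }
      }
    }
  })
  rec <- new_record(patient_id, label, "EHG", fs, x)
  attr(rec, "n_bursts") <- nb
  rec
}

rr_class_moments <- function(params, label, kind) {
  if (kind == "MHR") {
    mu <- if (label == "term") params$rr_mean_term else params$rr_mean_preterm
    s <- if (label == "term") params$rr_sd_term else params$rr_sd_preterm
  } else {
    # foetal moments: baseline midpoint converted to ms, class effect carried
    # over from the maternal series at the same standardised mean difference
    mu_t <- 60000 / mean(params$fhr_baseline_bpm)
    scale <- mu_t / params$rr_mean_term
    sd_t <- params$rr_sd_term * scale
    sd_p <- params$rr_sd_preterm * scale
    d <- (params$rr_mean_term - params$rr_mean_preterm) /
      sqrt((params$rr_sd_term^2 + params$rr_sd_preterm^2) / 2)
    if (label == "term") {
      mu <- mu_t; s <- sd_t
    } else {
      mu <- mu_t - d * sqrt((sd_t^2 + sd_p^2) / 2); s <- sd_p
    }
  }
  list(mu = mu, sd = s)
}

#' Generate one synthetic beat-to-beat RR record
#'
#' RR intervals follow a stationary AR(1) process around the class mean:
#' `RR_i = mu + phi * (RR_{i-1} - mu) + eps_i`, with the innovation SD scaled
#' by `sqrt(1 - phi^2)` so the stationary SD equals the configured class SD.
#' Maternal (`MHR`) moments come straight from the class configuration;
#' foetal (`FHR`) moments are derived from the 110-170 bpm baseline with the
#' maternal standardised mean difference. All intervals are clipped positive.
#'
#' @inheritParams generate_ehg
#' @param kind `"MHR"` or `"FHR"`.
#' @param n_beats Number of intervals; default covers `params$duration` at
#'   the class mean rate.
#' @return A one-row record tibble; `fs` is `NA` (RR series are indexed by
#'   beat, not time).
#' @export
#' @examples
#' r <- generate_rr(cohort_params(), "term", "MHR", n_beats = 100, seed = 1)
#' mean(r$samples[[1]])
generate_rr <- function(params, label, kind = c("MHR", "FHR"),
                        n_beats = NULL, seed = 1, patient_id = "P00") {
  assert_label(label)
  kind <- match.arg(kind)
  mom <- rr_class_moments(params, label, kind)
  phi <- params$ar1_coeff
  if (mom$sd < 0) stop("SD must be >= 0", call. = FALSE)
  if (abs(phi) >= 1) stop("|ar1_coeff| must be < 1", call. = FALSE)
  n <- n_beats %||% max(2L, round(params$duration * 1000 / mom$mu))
  if (n < 2) stop("n_beats must be >= 2", call. = FALSE)
  withr::with_seed(seed, {
    innov_sd <- mom$sd * sqrt(1 - phi^2)
    dev1 <- rnorm(1, 0, mom$sd)
    innov <- rnorm(n - 1, 0, innov_sd)
    dev <- c(dev1, as.numeric(stats::filter(innov, phi, method = "recursive",
                                            init = dev1)))
    x <- pmax(mom$mu + dev, 1)
  })
  new_record(patient_id, label, kind, NA_real_, x)
}

#' Generate a labelled synthetic cohort
#'
#' Produces `n_term + n_preterm` records of the configured signal kind, with
#' distinct per-record seeds derived deterministically from the master seed,
#' so the same parameters always reproduce the identical cohort.
#'
#' @param params A [cohort_params()] object.
#' @param kind Signal kind; defaults to `params$signal_kind`.
#' @return A cohort tibble, one row per record.
#' @export
#' @examples
#' co <- generate_cohort(cohort_params(n_term = 3, n_preterm = 2))
#' table(co$label)
generate_cohort <- function(params, kind = params$signal_kind) {
  validate_cohort_params(params)
  ids <- c(sprintf("T%02d", seq_len(params$n_term)),
           sprintf("P%02d", seq_len(params$n_preterm)))
  labels <- rep(.classes, c(params$n_term, params$n_preterm))
  recs <- purrr::map2(ids, labels, function(id, lab) {
    s <- derive_seed(params$seed, paste0(kind, "_", id))
    if (kind == "EHG") {
      generate_ehg(params, lab, seed = s, patient_id = id)
    } else {
      generate_rr(params, lab, kind = kind, seed = s, patient_id = id)
    }
  })
  dplyr::bind_rows(recs)
}
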