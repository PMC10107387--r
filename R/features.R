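#' Feature-extraction configuration
#'
#' @param eps_threshold Amplitude threshold (signal units) used by the
#'   zero-crossing, slope-sign-change and peak-count features. `NULL`
#'   (default) resolves per signal kind in [featurize()]: 1 microvolt for
#'   EHG envelopes, 0 for RR series (where a microvolt threshold is
#'   meaningless).
#' @param sampen_m Sample-entropy template length (default 2).
#' @param sampen_r Sample-entropy tolerance factor; the tolerance is
#'   `sampen_r * sd(window)` (default 0.2).
#' @param ar_order Autoregressive model order (fixed at 4 in the ensemble).
#' @param ceps_order Number of cepstral coefficients (4).
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(eps_threshold = NULL, sampen_m = 2,
                           sampen_r = 0.2, ar_order = 4, ceps_order = 4) {
  stopifnot(is.null(eps_threshold) || eps_threshold >= 0,
            sampen_m >= 1, sampen_r > 0)
  structure(list(eps_threshold = eps_threshold, sampen_m = sampen_m,
                 sampen_r = sampen_r, ar_order = ar_order,
                 ceps_order = ceps_order),
            class = "feature_config")
}

feature_names <- function() {
  c("MAV", "WL", "ZC", "SSC", "RMS", paste0("AR", 1:4), "SampEN",
    paste0("Ceps", 1:4), "MFL", "MedFrq", "PeakFrq", "NP", "SSI", "VAR")
}

resolve_eps <- function(config, kind = NULL) {
  if (!is.null(config$eps_threshold)) return(config$eps_threshold)
  if (!is.null(kind) && kind == "EHG") 1 else 0
}

#' Sample entropy of a window
#'
#' `-ln(A/B)` where `B` counts pairs of distinct templates of length `m`
#' within Chebyshev distance `r` of each other, and `A` the same for length
#' `m + 1`; self-matches are excluded and templates are taken at the
#' `n - m` positions where both lengths exist. Tolerance is
#' `r_factor * sd(x)`. Returns `NaN` when no matches exist or the window
#' has zero variance.
#'
#' @param x Numeric window.
#' @param m Template length.
#' @param r_factor Tolerance as a multiple of the window SD.
#' @return Sample entropy (unitless), or `NaN`.
#' @export
sample_entropy <- function(x, m = 2, r_factor = 0.2) {
  n <- length(x)
  if (n < m + 2) return(NaN)
  r <- r_factor * stats::sd(x)
  if (!is.finite(r) || r <= 0) return(NaN)
  np <- n - m # template positions shared by lengths m and m + 1
  cheb_count <- function(len) {
    d <- matrix(0, np, np)
    for (k in 0:(len - 1)) {
      d <- pmax(d, abs(outer(x[(1:np) + k], x[(1:np) + k], "-")))
    }
    (sum(d <= r) - np) / 2
  }
  B <- cheb_count(m)
  A <- cheb_count(m + 1)
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

burg_coefficients <- function(x, order) {
  if (length(x) <= order || stats::sd(x) == 0) return(rep(0, order))
  fit <- tryCatch(stats::ar.burg(x, aic = FALSE, order.max = order,
                                 demean = TRUE),
                  error = function(e) NULL)
  if (is.null(fit) || length(fit$ar) != order) return(rep(0, order))
  as.numeric(fit$ar)
}

# cepstrum from AR coefficients; phi are the predictor coefficients
# (x_t = sum phi_l x_{t-l} + e) so the error-filter coefficients are -phi
ar_cepstrum <- function(phi, order) {
  a <- -phi
  cc <- numeric(order)
  cc[1] <- -a[1]
  if (order > 1) {
    for (p in 2:order) {
      l <- 1:(p - 1)
      cc[p] <- -a[p] - sum((1 - l / p) * a[l] * cc[p - l])
    }
  }
  cc
}

# raw periodogram of the demeaned, Hann-windowed signal; DC bin excluded
hann_periodogram <- function(x, fs) {
  n <- length(x)
  xc <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  p <- Mod(stats::fft(xc * w))^2
  m <- floor(n / 2)
  list(f = fs * (1:m) / n, p = p[2:(m + 1)])
}

#' Extract the 20-dimensional feature vector from one window
#'
#' Time-domain: MAV, WL, ZC, SSC, RMS, MFL, NP, SSI, VAR. Model-based:
#' order-4 Burg autoregressive coefficients (AR1-AR4) and the four cepstral
#' coefficients derived from them (Ceps1-Ceps4). Nonlinear: sample entropy
#' (SampEN). Spectral: median and peak frequency of the Hann-windowed raw
#' periodogram (MedFrq, PeakFrq), DC excluded.
#'
#' @param window Numeric sample vector.
#' @param fs Sampling rate in Hz (used by the spectral features; RR series
#'   may pass `NA`, in which case frequencies are per-beat, `fs = 1`).
#' @param config A [feature_config()]; a `NULL` `eps_threshold` is treated
#'   as 0 here (resolve per kind via [featurize()]).
#' @return A named numeric vector of length 20.
#' @export
#' @examples
#' extract_features(c(1, -2, 3, 0, 2, -1, 1, 0.5), fs = 1)
extract_features <- function(window, fs, config = feature_config()) {
  x <- as.numeric(window)
  n <- length(x)
  min_n <- max(config$ar_order + 1, config$sampen_m + 2, 8)
  if (n < min_n) stop("window too short for feature extraction", call. = FALSE)
  if (!is.finite(fs) || fs <= 0) fs <- 1
  eps <- config$eps_threshold %||% 0

  d <- diff(x)
  mav <- mean(abs(x))
  wl <- sum(abs(d))
  zc <- sum(x[-n] * x[-1] < 0 & abs(d) >= eps)
  i <- 2:(n - 1)
  ssc <- sum((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > 0 &
               pmax(abs(x[i] - x[i - 1]), abs(x[i] - x[i + 1])) >= eps)
  rms <- sqrt(mean(x^2))
  phi <- burg_coefficients(x, config$ar_order)
  sampen <- sample_entropy(x, config$sampen_m, config$sampen_r)
  ceps <- if (all(phi == 0)) numeric(config$ceps_order) else {
    ar_cepstrum(phi, config$ceps_order)
  }
  mfl <- log10(sqrt(sum(d^2)))
  spec <- hann_periodogram(x, fs)
  tot <- sum(spec$p)
  if (tot > 0) {
    medfrq <- spec$f[which(cumsum(spec$p) >= tot / 2)[1]]
    peakfrq <- spec$f[which.max(spec$p)]
  } else {
    medfrq <- 0
    peakfrq <- 0
  }
  np_ <- sum(x[i] > x[i - 1] & x[i] > x[i + 1] &
               pmin(x[i] - x[i - 1], x[i] - x[i + 1]) >= eps)
  ssi <- sum(x^2)
  v <- stats::var(x)

  out <- c(mav, wl, zc, ssc, rms, phi, sampen, ceps, mfl, medfrq, peakfrq,
           np_, ssi, v)
  names(out) <- feature_names()
  out
}

#' Build the labelled feature table for a windowed cohort
#'
#' One row per window with the 20 features plus `patient_id`, `label` and
#' `window`. If an LSDL model is supplied, every window is decomposed by the
#' fitted rule first. The amplitude threshold `eps` resolves per signal
#' kind when left `NULL` in the config (1 microvolt for EHG, 0 for RR).
#'
#' @param windows Window tibble from [window_records()].
#' @param config A [feature_config()].
#' @param lsdl Optional fitted [lsdl_fit()] model.
#' @return A feature tibble.
#' @export
featurize <- function(windows, config = feature_config(), lsdl = NULL) {
  cols <- c("patient_id", "label", "window", feature_names())
  if (nrow(windows) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      c(list(character(), factor(levels = .classes), integer()),
        rep(list(numeric()), 20)), cols))
    return(out)
  }
  if (!is.null(lsdl)) windows <- predict(lsdl, windows)
  feats <- purrr::pmap(windows, function(samples, fs, kind, ...) {
    cfg <- config
    cfg$eps_threshold <- resolve_eps(config, kind)
    extract_features(samples, fs, cfg)
  })
  n_nan <- sum(!purrr::map_lgl(feats, ~ all(is.finite(.x))))
  if (n_nan > 0) {
    message("featurize: ", n_nan, " window(s) with non-finite features ",
            "(degenerate windows; see sample_entropy)")
  }
  dplyr::bind_cols(
    windows[, c("patient_id", "label", "window")],
    tibble::as_tibble(do.call(rbind, feats))
  )
}
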