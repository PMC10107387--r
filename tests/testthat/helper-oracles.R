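# Independent naive-loop oracles. These deliberately avoid the package's
# implementation paths (explicit loops, O(N^2) DFT sums, hand-written Burg
# recursion) so they can serve as a second route for the same definitions.

oracle_burg <- function(x, p) {
  x <- x - mean(x)
  f <- x
  b <- x
  a <- 1
  for (m in 1:p) {
    ff <- f[2:length(f)]
    bb <- b[1:(length(b) - 1)]
    k <- -2 * sum(ff * bb) / (sum(ff^2) + sum(bb^2))
    a <- c(a, 0) + k * rev(c(a, 0))
    fn <- ff + k * bb
    bn <- bb + k * ff
    f <- fn
    b <- bn
  }
  -a[-1] # predictor (phi) convention
}

oracle_sampen <- function(x, m, r_factor) {
  n <- length(x)
  r <- r_factor * sd(x)
  np <- n - m
  count <- function(len) {
    cnt <- 0
    for (i in 1:(np - 1)) {
      for (j in (i + 1):np) {
        d <- 0
        for (k in 0:(len - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  B <- count(m)
  A <- count(m + 1)
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

# O(N^2) DFT periodogram with a Hann window, DC excluded
oracle_spectrum <- function(x, fs) {
  n <- length(x)
  xc <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  xw <- xc * w
  m <- floor(n / 2)
  p <- numeric(m)
  for (k in 1:m) {
    re <- 0
    im <- 0
    for (t in 1:n) {
      ang <- -2 * pi * k * (t - 1) / n
      re <- re + xw[t] * cos(ang)
      im <- im + xw[t] * sin(ang)
    }
    p[k] <- re^2 + im^2
  }
  list(f = fs * (1:m) / n, p = p)
}

oracle_features <- function(x, fs, eps = 0, m = 2, rf = 0.2) {
  n <- length(x)
  if (!is.finite(fs) || fs <= 0) fs <- 1
  mav <- sum(abs(x)) / n
  wl <- 0
  for (i in 1:(n - 1)) wl <- wl + abs(x[i + 1] - x[i])
  zc <- 0
  for (i in 1:(n - 1)) {
    if (x[i] * x[i + 1] < 0 && abs(x[i] - x[i + 1]) >= eps) zc <- zc + 1
  }
  ssc <- 0
  np_ <- 0
  for (i in 2:(n - 1)) {
    d1 <- x[i] - x[i - 1]
    d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && max(abs(d1), abs(d2)) >= eps) ssc <- ssc + 1
    if (d1 > 0 && d2 > 0 && min(d1, d2) >= eps) np_ <- np_ + 1
  }
  rms <- sqrt(sum(x^2) / n)
  phi <- oracle_burg(x, 4)
  a <- -phi
  cc <- numeric(4)
  cc[1] <- -a[1]
  for (p in 2:4) {
    s <- 0
    for (l in 1:(p - 1)) s <- s + (1 - l / p) * a[l] * cc[p - l]
    cc[p] <- -a[p] - s
  }
  sampen <- oracle_sampen(x, m, rf)
  mfl <- log10(sqrt(sum(diff(x)^2)))
  sp <- oracle_spectrum(x, fs)
  tot <- sum(sp$p)
  medfrq <- sp$f[which(cumsum(sp$p) >= tot / 2)[1]]
  peakfrq <- sp$f[which.max(sp$p)]
  ssi <- sum(x^2)
  v <- sum((x - mean(x))^2) / (n - 1)
  out <- c(mav, wl, zc, ssc, rms, phi, sampen, cc, mfl, medfrq, peakfrq,
           np_, ssi, v)
  names(out) <- c("MAV", "WL", "ZC", "SSC", "RMS", paste0("AR", 1:4),
                  "SampEN", paste0("Ceps", 1:4), "MFL", "MedFrq", "PeakFrq",
                  "NP", "SSI", "VAR")
  out
}

# direct evaluation of the separability cost definition
oracle_cost_j <- function(f1, f2) {
  nw <- ncol(f1)
  p <- numeric(nw)
  q <- numeric(nw)
  for (w in 1:nw) {
    p[w] <- mean(f1[, w])
    q[w] <- mean(f2[, w])
  }
  ed <- 0
  for (w in 1:nw) ed <- ed + (p[w] - q[w])^2
  ed <- sqrt(ed)
  pooled <- rbind(f1, f2)
  sig <- numeric(nw)
  for (w in 1:nw) {
    mu <- mean(pooled[, w])
    sig[w] <- sqrt(sum((pooled[, w] - mu)^2) / nrow(pooled))
  }
  ed / mean(sig)
}

# AUC by exhaustive pair counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "preterm"]
  neg <- scores[labels == "term"]
  cnt <- 0
  for (p in pos) {
    for (q in neg) {
      cnt <- cnt + (p > q) + 0.5 * (p == q)
    }
  }
  100 * cnt / (length(pos) * length(neg))
}

expect_rel_equal <- function(got, want, rel_tol) {
  ok <- (is.nan(got) & is.nan(want)) |
    abs(got - want) <= rel_tol * pmax(1, abs(want))
  expect_true(all(ok), label = paste(
    "relative mismatch at:",
    paste(names(want)[!ok], collapse = ", ")))
}

# small two-class Gaussian feature table for balancing / model tests
make_feature_tibble <- function(n_term, n_preterm, shift = 0, p = 4,
                                seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_term * p), n_term),
               matrix(rnorm(n_preterm * p, mean = shift), n_preterm))
  })
  ft <- tibble::as_tibble(as.data.frame(X),
                          .name_repair = ~ paste0("f", seq_along(.x)))
  ft$label <- rep(c("term", "preterm"), c(n_term, n_preterm))
  ft
}
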