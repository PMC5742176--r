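# Shared fixtures and independent oracles for the test suite.

# Binomial multiplicative cascade: a canonical multifractal measure.
# Each dyadic interval's mass splits into fractions (p, 1-p) assigned
# to its children in random order.
binomial_cascade <- function(levels, p = 0.3, seed = 1) {
  set.seed(seed)
  w <- 1
  for (i in seq_len(levels)) {
    flip <- sample(c(TRUE, FALSE), length(w), replace = TRUE)
    a <- ifelse(flip, p, 1 - p)
    w <- as.vector(rbind(w * a, w * (1 - a)))
  }
  w
}

# Least-squares slope of the log-periodogram: an estimator of -gamma
# that is independent of the MFDFA code path.  A Hann taper and a
# low-frequency fit band keep spectral leakage from biasing steep
# slopes (an untapered full-band fit cannot resolve slopes beyond -3).
periodogram_slope <- function(x, frac = 1 / 8) {
  n <- length(x)
  m <- n %/% 2
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  pg <- Mod(stats::fft((x - mean(x)) * w))[2:(m + 1)]^2 / n
  fr <- (1:m) / n
  k <- 2:floor(m * frac)
  unname(stats::coef(stats::lm(log(pg[k]) ~ log(fr[k])))[2])
}

# Precision / recall matching of detected vs true event times.
detection_f1 <- function(detected, truth, tol = 0.1) {
  if (!length(detected) || !length(truth)) return(0)
  used <- logical(length(detected))
  tp <- 0L
  for (t0 in truth) {
    d <- abs(detected - t0)
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol) {
      tp <- tp + 1L
      used[j] <- TRUE
    }
  }
  prec <- tp / length(detected)
  rec <- tp / length(truth)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# Blink times for a session: draw a BRV series and accumulate it,
# clipping to the session span with a margin for the pulse template.
session_blink_times <- function(duration, rate = 18, alpha_target = 1,
                                seed = 1) {
  iv <- as.numeric(blink_intervals(duration, rate,
                                   alpha_target = alpha_target,
                                   seed = seed))
  tt <- cumsum(iv)
  tt[tt < duration - 0.2]
}
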