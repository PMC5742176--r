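#' Default analysis scale set
#'
#' Window half-lengths l (in series samples) used by the scaling
#' analysis: \{8, 10, 12, 14, 16, 20, 22, 26, 32, 38, 46, 54, 64\},
#' an approximately geometric ladder suited to interval series of a
#' few hundred points.  Each scale l corresponds to sub-windows of
#' length 2l.
#'
#' @return integer vector of scales.
#' @export
brv_scales <- function() {
  c(8L, 10L, 12L, 14L, 16L, 20L, 22L, 26L, 32L, 38L, 46L, 54L, 64L)
}

#' DFA profile (integrated series)
#'
#' Cumulative sum of the mean-centered series, the standard first step
#' of detrended fluctuation analysis.  Integration shifts the scale
#' exponent by +1: analyzing the profile of white noise gives
#' \eqn{\alpha = 0.5}, of pink noise 1, of brown noise 1.5 — the
#' conventional colored-noise taxonomy.
#'
#' @param x numeric series, length >= 2.
#' @return numeric vector of the same length.
#' @export
dfa_profile <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L, all(is.finite(x)))
  cumsum(x - mean(x))
}

#' Gaussian sub-band detrending
#'
#' Subtracts a Gaussian-smoothed (low-pass) copy of the series, leaving
#' the fluctuations whose wavelengths are comparable to or shorter than
#' the analysis scale l.  Unlike windowed polynomial subtraction this
#' is a single linear, shift-invariant operator, so it cannot introduce
#' the segmentation discontinuities of classical DFA detrending.  The
#' kernel spread grows with the scale (default \eqn{\sigma = l/4},
#' kernel truncated at \eqn{\pm 4\sigma}), keeping the suppressed band
#' proportional to the window length.
#'
#' @param x numeric series.
#' @param l analysis scale (window half-length, samples).
#' @param sigma Gaussian kernel SD in samples; default \code{l/4}.
#' @return the fluctuation series \code{x - smooth(x)}, same length.
#' @export
subband_detrend <- function(x, l, sigma = l / 4) {
  stopifnot(is.numeric(x), l >= 4, sigma > 0)
  x - gauss_smooth(x, sigma)
}

#' Overlapping sub-window variances at one scale
#'
#' Splits the fluctuation series into \eqn{N_l = \lfloor n/l \rfloor - 1}
#' sub-windows of length 2l advancing by step l (50\% overlap) and
#' returns the population variance of each.
#'
#' @param fluct fluctuation series (output of
#'   \code{\link{subband_detrend}}).
#' @param l scale (window half-length).
#' @return numeric vector of \eqn{N_l} variances.
#' @export
window_variances <- function(fluct, l) {
  n <- length(fluct)
  l <- as.integer(l)
  Nl <- n %/% l - 1L
  if (Nl < 1L)
    stop("scale too large: no complete window of length ", 2L * l,
         " fits a series of length ", n)
  vapply(seq_len(Nl), function(k) {
    w <- fluct[((k - 1L) * l + 1L):((k + 1L) * l)]
    m <- sum(w) / length(w)
    sum((w - m)^2) / length(w)
  }, numeric(1))
}

#' Partition function of sub-window variances
#'
#' \deqn{\chi(q, l) = \sum_{k=1}^{N_l} [\sigma^2_k(l)]^{q/2}}
#' i.e. the sum of sub-window fluctuation magnitudes
#' \eqn{\sigma_k = \sqrt{\sigma^2_k}} raised to the moment order q.
#' \eqn{\chi(0, l) = N_l} exactly.  Across scales,
#' \eqn{\chi(q,l) \propto l^{\tau(q)}} defines the mass exponent
#' \eqn{\tau(q)}.
#'
#' @param variances vector of sub-window variances \eqn{\sigma^2_k}.
#' @param q moment order.
#' @return the scalar \eqn{\chi(q, l)}.
#' @export
partition_function <- function(variances, q) {
  stopifnot(length(variances) >= 1L, all(variances >= 0))
  if (q < 0 && any(variances == 0))
    stop("degenerate window: zero variance with q < 0 diverges")
  sum(variances^(q / 2))
}

#' Normalized partition weights
#'
#' \deqn{\mu_k(q, l) = [\sigma^2_k(l)]^{q/2} / \chi(q, l)}
#' the summands of \code{\link{partition_function}} normalized to 1;
#' the measure weights of the direct (Chhabra-Jensen style) spectrum
#' estimation.  At q = 0 every window gets weight \eqn{1/N_l}.
#'
#' @inheritParams partition_function
#' @return vector of weights summing to 1.
#' @export
mu_weights <- function(variances, q) {
  chi <- partition_function(variances, q)
  if (chi <= 0) stop("partition function is zero: all windows degenerate")
  variances^(q / 2) / chi
}

# Numerically stable per-(q,l) statistics computed in log space:
# log chi, A = sum mu*log(sigma^2), F = sum mu*log(mu).  Zero-variance
# windows keep their chi(0,l) contribution but are excluded from the
# weighted logs (they carry zero measure for q > 0 and are degenerate
# otherwise).
.row_stats <- function(v, q) {
  Nl <- length(v)
  wv <- v[v > 0]
  if (!length(wv))
    stop("all sub-window variances are zero (constant input?)")
  s <- (q / 2) * log(wv)
  m <- max(s)
  e <- exp(s - m)
  lchi <- if (q == 0) log(Nl) else m + log(sum(e))
  mu <- e / sum(e)
  c(lchi = lchi,
    A = sum(mu * log(wv)),
    FF = sum(mu * log(mu)),
    dropped = Nl - length(wv))
}

.ols_slope <- function(y, x) {
  xc <- x - mean(x); yc <- y - mean(y)
  b <- sum(xc * yc) / sum(xc * xc)
  ss_res <- sum((yc - b * xc)^2)
  ss_tot <- sum(yc^2)
  c(slope = b, r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Multifractal detrended fluctuation analysis of a series
#'
#' Fits the multifractal scaling model
#' \eqn{\chi(q, l) \propto l^{\tau(q)}} to a time (or event-interval)
#' series and returns the mass exponents \eqn{\tau(q)}, Holder
#' exponents \eqn{\alpha(q)}, spectrum values \eqn{f(q)} and the
#' headline scale exponent \eqn{\alpha = \alpha(q = 0)}, the location
#' of the peak of the multifractal spectrum \eqn{f(\alpha)}.
#'
#' Two detrending back-ends are provided.  \code{method = "subband"}
#' (the default) applies the linear Gaussian sub-band filter of
#' \code{\link{subband_detrend}} and measures variances in overlapping
#' sub-windows of length 2l; \code{method = "poly"} is classical MFDFA
#' with least-squares polynomial detrending (order \code{poly_order})
#' in non-overlapping windows of length 2l taken from both ends of the
#' series, retained as an independent cross-check.
#'
#' The series is first integrated to its profile
#' (\code{\link{dfa_profile}}; disable with \code{integrate = FALSE}),
#' so that white, pink and brown input map to \eqn{\alpha} = 0.5, 1,
#' 1.5.  For each retained scale l the per-window variances give
#' \eqn{\log\chi(q,l)}, the weighted log-variance sum
#' \eqn{A(q,l)=\sum_k \mu_k \ln \sigma^2_k} and the weighted entropy
#' \eqn{F(q,l)=\sum_k \mu_k \ln \mu_k}; ordinary least-squares slopes
#' against \eqn{\ln l} over the retained scales estimate \eqn{\tau(q)},
#' \eqn{\alpha(q)} and \eqn{f(q)}.  Because variances are squared
#' fluctuation magnitudes, the \eqn{A} slope is halved
#' (\code{calibration = 0.5}) to express \eqn{\alpha(q)} in fluctuation
#' units — the convention under which white noise gives
#' \eqn{\alpha(0) = 0.5}; \code{calibration = 1} reports the raw
#' log-variance slope instead.  With a common retained scale set the
#' three slope estimates satisfy the Legendre relation
#' \eqn{f(q) = q\,\alpha(q) - \tau(q)} identically (at the default
#' calibration), since \eqn{\ln\mu_k = (q/2)\ln\sigma^2_k - \ln\chi}
#' makes the three regressions linearly dependent.
#'
#' Scales for which fewer than 4 sub-windows fit are dropped; fewer
#' than 5 retained scales is an error.  Zero-variance windows are
#' excluded from the weighted sums (with a warning) since their
#' contribution diverges for q < 0.
#'
#' @param x numeric series: a BRV interval sequence (analyzed by event
#'   index) or any regularly sampled signal.
#' @param scales window half-lengths l, strictly increasing, min >= 4
#'   (default \code{\link{brv_scales}}).
#' @param q moment orders for the spectrum (default \code{seq(-3, 3,
#'   0.5)}); 0 is always included.
#' @param method \code{"subband"} (Gaussian sub-band detrending,
#'   default) or \code{"poly"} (classical polynomial MFDFA).
#' @param integrate integrate to the profile first (default
#'   \code{TRUE}).
#' @param sigma_rule function mapping scale l to the Gaussian kernel
#'   SD (default \code{l/4}; sub-band method only).
#' @param calibration factor applied to the log-variance regression
#'   slope for \eqn{\alpha(q)} (default 0.5; see Details).
#' @param poly_order polynomial detrending order (poly method only,
#'   default 1).
#' @return an object of class \code{"mfdfa"}: a list with the q grid,
#'   \code{tau}, \code{alpha}, \code{f}, \code{h} (generalized Hurst
#'   exponents \eqn{(\tau(q)+1)/q}, with \eqn{h(0) = \alpha(0)}),
#'   per-q regression \code{r_squared}, the headline \code{alpha0} and
#'   its fit diagnostics, the retained \code{scales}, and the per-scale
#'   matrices \code{log_chi}, \code{A}, \code{F} used in the fits.
#' @examples
#' w <- colored_noise(4096, gamma = 0, seed = 42)
#' fit <- mfdfa(w)
#' fit$alpha0            # about 0.5 for white noise
#' coef(fit)
#' @seealso \code{\link{alpha0}} for the scalar-exponent shortcut,
#'   \code{\link{alpha_from_gamma}} for the spectral-exponent relation.
#' @export
mfdfa <- function(x, scales = brv_scales(), q = seq(-3, 3, by = 0.5),
                  method = c("subband", "poly"), integrate = TRUE,
                  sigma_rule = function(l) l / 4, calibration = 0.5,
                  poly_order = 1) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), all(is.finite(x)))
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 5L || any(scales < 4L))
    stop("'scales' must contain >= 5 values, each >= 4")
  q <- sort(unique(c(0, as.numeric(q))))
  n <- length(x)
  if (n < 2L * scales[1L])
    stop("series too short: need at least ", 2L * scales[1L], " points")

  y <- if (integrate) dfa_profile(x) else as.numeric(x)

  keep <- scales[(n %/% scales - 1L) >= 4L]
  if (method == "subband") {
    max_kernel_ok <- vapply(keep, function(l)
      2L * max(1L, as.integer(ceiling(4 * sigma_rule(l)))) + 1L <= n,
      logical(1))
    keep <- keep[max_kernel_ok]
  }
  if (length(keep) < 5L)
    stop("insufficient scales: only ", length(keep),
         " of the requested scales are usable for a series of length ",
         n, " (need >= 5)")

  var_list <- lapply(keep, function(l) {
    if (method == "subband") {
      fl <- subband_detrend(y, l, sigma_rule(l))
      window_variances(fl, l)
    } else {
      .poly_variances(y, l, poly_order)
    }
  })

  nq <- length(q); ns <- length(keep)
  log_chi <- A <- FF <- matrix(NA_real_, nq, ns,
                               dimnames = list(q = q, l = keep))
  dropped_any <- 0L
  for (j in seq_len(ns)) {
    for (i in seq_len(nq)) {
      st <- .row_stats(var_list[[j]], q[i])
      log_chi[i, j] <- st["lchi"]; A[i, j] <- st["A"]; FF[i, j] <- st["FF"]
      dropped_any <- dropped_any + st["dropped"]
    }
  }
  if (dropped_any > 0)
    warning("zero-variance sub-windows excluded from weighted sums")

  ll <- log(keep)
  tau <- alpha <- fq <- r2 <- numeric(nq)
  for (i in seq_len(nq)) {
    ft <- .ols_slope(log_chi[i, ], ll)
    tau[i] <- ft["slope"]; r2[i] <- ft["r2"]
    alpha[i] <- calibration * .ols_slope(A[i, ], ll)["slope"]
    fq[i] <- .ols_slope(FF[i, ], ll)["slope"]
  }
  h <- ifelse(q == 0, alpha / (2 * calibration), (tau + 1) / q)
  i0 <- which(q == 0)
  a0fit <- .ols_slope(A[i0, ], ll)

  structure(list(q = q, tau = tau, alpha = alpha, f = fq, h = h,
                 r_squared = r2,
                 alpha0 = alpha[i0], alpha0_r2 = unname(a0fit["r2"]),
                 scales = keep, n = n, method = method,
                 integrate = integrate, calibration = calibration,
                 poly_order = if (method == "poly") poly_order else NULL,
                 log_chi = log_chi, A = A, F = FF,
                 call = match.call()),
            class = "mfdfa")
}

# classical MFDFA variances: non-overlapping windows of length 2l from
# both ends, least-squares polynomial detrending, residual mean square
.poly_variances <- function(y, l, order) {
  n <- length(y)
  w <- 2L * as.integer(l)
  nwin <- n %/% w
  if (nwin < 1L) stop("scale too large for series")
  tt <- seq_len(w)
  X <- outer(tt, 0:order, `^`)
  one_end <- function(idx0) {
    vapply(seq_len(nwin), function(k) {
      seg <- y[(idx0 + (k - 1L) * w + 1L):(idx0 + k * w)]
      r <- stats::.lm.fit(X, seg)$residuals
      sum(r^2) / w
    }, numeric(1))
  }
  c(one_end(0L), one_end(n - nwin * w))
}

#' Scale exponent alpha(q = 0) of a series
#'
#' Convenience wrapper around \code{\link{mfdfa}} returning only the
#' headline exponent \eqn{\alpha = \alpha(0)} — the average growth rate
#' of windowed fluctuation magnitude with window size, and the peak
#' position of the multifractal spectrum.  Values near 0.5, 1 and 1.5
#' indicate white-, pink- and brown-noise-like dynamics.
#'
#' @inheritParams mfdfa
#' @param ... further arguments passed to \code{\link{mfdfa}}.
#' @return a list of class \code{"scaling_exponent"}: \code{alpha0},
#'   \code{fit_r2} (R-squared of the log-log regression at q = 0) and
#'   \code{n_scales_used}.
#' @export
alpha0 <- function(x, scales = brv_scales(), ...) {
  fit <- mfdfa(x, scales = scales, q = 0, ...)
  structure(list(alpha0 = fit$alpha0, fit_r2 = fit$alpha0_r2,
                 n_scales_used = length(fit$scales)),
            class = "scaling_exponent")
}

#' @export
print.scaling_exponent <- function(x, ...) {
  cat(sprintf("alpha(q=0) = %.4f  (fit R^2 = %.3f, %d scales)\n",
              x$alpha0, x$fit_r2, x$n_scales_used))
  invisible(x)
}

#' @export
print.mfdfa <- function(x, ...) {
  cat("Multifractal DFA fit (", x$method,
      if (x$method == "poly") paste0(", order ", x$poly_order), ")\n",
      sep = "")
  cat(sprintf("  series length %d, %d scales [%d..%d]%s\n", x$n,
              length(x$scales), min(x$scales), max(x$scales),
              if (x$integrate) ", integrated profile" else ""))
  cat(sprintf("  alpha(0) = %.4f  (fit R^2 = %.3f)\n",
              x$alpha0, x$alpha0_r2))
  rng <- range(x$alpha)
  cat(sprintf("  alpha(q) range over q in [%g, %g]: [%.3f, %.3f]\n",
              min(x$q), max(x$q), rng[1], rng[2]))
  invisible(x)
}

#' @export
summary.mfdfa <- function(object, ...) {
  tab <- data.frame(q = object$q, tau = object$tau, alpha = object$alpha,
                    f = object$f, h = object$h,
                    r_squared = object$r_squared)
  structure(list(table = tab, alpha0 = object$alpha0,
                 alpha0_r2 = object$alpha0_r2,
                 width = max(object$alpha) - min(object$alpha),
                 method = object$method, n = object$n,
                 scales = object$scales),
            class = "summary.mfdfa")
}

#' @export
print.summary.mfdfa <- function(x, digits = 4, ...) {
  cat("Multifractal spectrum (", x$method, " detrending), n = ", x$n,
      "\n\n", sep = "")
  print(format(x$table, digits = digits), row.names = FALSE)
  cat(sprintf("\nalpha(0) = %.4f (R^2 %.3f); spectrum width max-min = %.3f\n",
              x$alpha0, x$alpha0_r2, x$width))
  invisible(x)
}

#' @export
coef.mfdfa <- function(object, which = c("alpha0", "spectrum"), ...) {
  which <- match.arg(which)
  if (which == "alpha0") c(alpha0 = object$alpha0)
  else stats::setNames(object$alpha, paste0("alpha(", object$q, ")"))
}

#' Plot an MFDFA fit
#'
#' Left panel: log-log scaling of the mean sub-window fluctuation at
#' q = 0 against scale, with the fitted line whose slope (times the
#' calibration) is \eqn{\alpha(0)}.  Right panel: the multifractal
#' spectrum \eqn{f} versus \eqn{\alpha(q)}.
#'
#' @param x an \code{"mfdfa"} object.
#' @param ... passed to \code{plot}.
#' @export
plot.mfdfa <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  i0 <- which(x$q == 0)
  ll <- log(x$scales)
  graphics::plot(ll, x$A[i0, ], xlab = "ln l",
                 ylab = expression(sum(mu[k] ~ ln ~ sigma[k]^2)),
                 main = sprintf("q = 0 scaling (alpha = %.3f)", x$alpha0),
                 ...)
  graphics::abline(stats::lm(x$A[i0, ] ~ ll), lty = 2)
  graphics::plot(x$alpha, x$f, type = "b", xlab = expression(alpha(q)),
                 ylab = "f(q)", main = "multifractal spectrum", ...)
  invisible(x)
}

#' Simulate series with the fitted scale exponent
#'
#' Draws colored-noise surrogates whose spectral exponent
#' \eqn{\gamma = 2\alpha(0) - 1} matches the fitted headline exponent;
#' useful as a monofractal null for the fitted series.
#'
#' @param object an \code{"mfdfa"} fit.
#' @param nsim number of surrogate series.
#' @param seed optional integer seed.
#' @param ... ignored.
#' @return a list of numeric series, each of the fitted length.
#' @export
simulate.mfdfa <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, lapply(seq_len(nsim), function(i)
    colored_noise(max(object$n, 64L),
                  gamma = gamma_from_alpha(max(object$alpha0, 1e-3)))[
                    seq_len(object$n)]))
}
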