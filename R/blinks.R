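#' Detect eye-blink events in frontal EEG
#'
#' Band-pass filters each frontal channel (zero-phase Butterworth,
#' default 0.5-10 Hz, the band carrying the blink deflection), sets an
#' adaptive amplitude threshold at \code{threshold_k} times the MAD of
#' the filtered trace (never below \code{min_amplitude}), picks local
#' maxima above threshold, and enforces a refractory period by greedily
#' keeping the largest peaks.  With \code{coincidence = TRUE} (default)
#' an event must be confirmed by a peak on both Fp1 and Fp2 within
#' \code{coincidence_ms}; blink deflections are strongly bilateral, so
#' coincidence suppresses unilateral artifacts.
#'
#' Because the threshold is proportional to the MAD, detection is
#' amplitude-scale equivariant: rescaling the signal (and
#' \code{min_amplitude}) by any positive constant leaves event times
#' unchanged.
#'
#' @param rec an \code{\link{eeg_recording}} of at least 10 s.
#' @param threshold_k MAD multiplier for the adaptive threshold
#'   (default 4).
#' @param refractory_ms minimum separation between events in
#'   milliseconds (default 250).
#' @param coincidence require both channels to confirm each event
#'   (default \code{TRUE}).
#' @param coincidence_ms matching window for cross-channel confirmation
#'   (default 50 ms).
#' @param band band-pass edges in Hz (default \code{c(0.5, 10)}).
#' @param min_amplitude absolute floor on the threshold in microvolts
#'   (default 10); scales with the signal under the equivariance above.
#' @return a data frame of class \code{"blink_events"} with columns
#'   \code{peak_time} (s from recording start), \code{amplitude}
#'   (filtered-trace peak, uV) and \code{channel_support}, sorted by
#'   time.
#' @export
detect_blinks <- function(rec, threshold_k = 4, refractory_ms = 250,
                          coincidence = TRUE, coincidence_ms = 50,
                          band = c(0.5, 10), min_amplitude = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  dur <- eeg_duration(rec)
  if (dur < 10)
    stop("recording too short for filter warm-up (", round(dur, 2),
         " s < 10 s)")
  stopifnot(threshold_k > 0, refractory_ms > 0, length(band) == 2L,
            band[1] > 0, band[2] > band[1], band[2] < fs / 2,
            min_amplitude >= 0)

  bf <- signal::butter(2, band * 2 / fs, type = "pass")
  refr <- refractory_ms / 1000

  peaks_one <- function(x) {
    xf <- as.numeric(signal::filtfilt(bf, x))
    thr <- max(threshold_k * stats::mad(xf), min_amplitude)
    n <- length(xf)
    if (n < 3L) return(data.frame(peak_time = numeric(0),
                                  amplitude = numeric(0)))
    i <- 2L:(n - 1L)
    cand <- i[xf[i] > xf[i - 1L] & xf[i] >= xf[i + 1L] & xf[i] > thr]
    if (!length(cand)) return(data.frame(peak_time = numeric(0),
                                         amplitude = numeric(0)))
    tt <- (cand - 1L) / fs
    amp <- xf[cand]
    # refractory: strongest peaks win
    o <- order(amp, decreasing = TRUE)
    keep_t <- numeric(0); keep_a <- numeric(0)
    for (j in o) {
      if (!length(keep_t) || all(abs(keep_t - tt[j]) >= refr)) {
        keep_t <- c(keep_t, tt[j]); keep_a <- c(keep_a, amp[j])
      }
    }
    ord <- order(keep_t)
    data.frame(peak_time = keep_t[ord], amplitude = keep_a[ord])
  }

  p1 <- peaks_one(rec$channels$Fp1)
  p2 <- peaks_one(rec$channels$Fp2)

  if (coincidence) {
    co <- coincidence_ms / 1000
    out_t <- numeric(0); out_a <- numeric(0)
    if (nrow(p1) && nrow(p2)) {
      used2 <- logical(nrow(p2))
      for (i in seq_len(nrow(p1))) {
        d <- abs(p2$peak_time - p1$peak_time[i])
        d[used2] <- Inf
        j <- which.min(d)
        if (length(j) && is.finite(d[j]) && d[j] <= co) {
          used2[j] <- TRUE
          out_t <- c(out_t, (p1$peak_time[i] + p2$peak_time[j]) / 2)
          out_a <- c(out_a, max(p1$amplitude[i], p2$amplitude[j]))
        }
      }
    }
    ev <- data.frame(peak_time = out_t, amplitude = out_a,
                     channel_support = rep("Fp1+Fp2", length(out_t)))
  } else {
    ev <- rbind(cbind(p1, channel_support = rep("Fp1", nrow(p1))),
                cbind(p2, channel_support = rep("Fp2", nrow(p2))))
    if (nrow(ev)) {
      o <- order(ev$amplitude, decreasing = TRUE)
      keep <- integer(0)
      for (j in o) {
        if (!length(keep) ||
            all(abs(ev$peak_time[keep] - ev$peak_time[j]) >= refr))
          keep <- c(keep, j)
      }
      ev <- ev[sort(keep), , drop = FALSE]
    }
  }
  ev <- ev[order(ev$peak_time), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("blink_events", "data.frame")
  ev
}

#' Stack inter-blink intervals into a BRV series
#'
#' The interval series is the first difference of the event times:
#' \code{intervals[i] = peak_time[i+1] - peak_time[i]}.  \code{n}
#' events yield \code{n - 1} intervals, and the intervals telescope
#' back to the total span exactly.
#'
#' @param events a \code{blink_events} data frame (or anything with a
#'   numeric \code{peak_time} column), at least 2 events.
#' @param session optional session label for the resulting series.
#' @return a \code{\link{brv_series}}.
#' @export
build_brv <- function(events, session = NA_character_) {
  tt <- events$peak_time
  if (is.null(tt) || length(tt) < 2L)
    stop("insufficient events: need >= 2 blinks to form intervals")
  if (is.unsorted(tt)) tt <- sort(tt)
  brv_series(diff(tt), session = session)
}

#' Blink rate in blinks per minute
#'
#' @param events a \code{blink_events} data frame.
#' @param duration_s session duration in seconds (> 0).
#' @return \code{60 * nrow(events) / duration_s}.
#' @export
blink_rate <- function(events, duration_s) {
  stopifnot(duration_s > 0)
  60 * nrow(events) / duration_s
}

#' Quality-control check on a BRV series
#'
#' Sessions with too few blinks produce interval series too short for
#' scaling analysis and are excluded (the smallest analysis scale
#' needs several sub-windows to estimate a variance).  The default
#' minimum of 30 intervals is conservative and configurable.
#'
#' @param brv a \code{\link{brv_series}}.
#' @param min_intervals minimum interval count to pass (default 30;
#'   boundary inclusive).
#' @return a list of class \code{"qc_report"}: \code{n_blinks},
#'   \code{n_intervals}, \code{passed}, \code{reason}.
#' @export
qc_filter <- function(brv, min_intervals = 30) {
  stopifnot(inherits(brv, "brv"))
  n_int <- length(brv)
  passed <- n_int >= min_intervals
  structure(list(n_blinks = n_int + 1L, n_intervals = n_int,
                 passed = passed,
                 reason = if (passed) "ok" else "short BRV series"),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC:", if (x$passed) "PASS" else "FAIL", "-", x$reason,
      sprintf("(%d blinks, %d intervals)\n", x$n_blinks, x$n_intervals))
  invisible(x)
}

#' Write detected blink events as CSV
#'
#' Columns \code{peak_time_s}, \code{amplitude_uV}.
#'
#' @param events a \code{blink_events} data frame.
#' @param path output path.
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(peak_time_s = sprintf("%.17g", events$peak_time),
                   amplitude_uV = sprintf("%.17g", events$amplitude))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, col.names = TRUE)
  invisible(path)
}
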