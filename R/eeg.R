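#' Two-channel frontal EEG recording
#'
#' Container for a frontopolar (Fp1/Fp2) EEG trace in microvolts at a
#' fixed sampling rate.  Fp1 and Fp2 sit closest to the eyes in the
#' 10-20 montage and carry the largest blink deflections, which is why
#' blink extraction works from these two channels alone.
#'
#' @param fp1,fp2 numeric traces in microvolts, equal length, finite.
#' @param fs sampling rate in Hz (> 0).
#' @param start_offset seconds between the session start and the first
#'   sample (default 0).
#' @return an object of class \code{"eeg_recording"} with elements
#'   \code{fs}, \code{channels} (a named list \code{Fp1}, \code{Fp2})
#'   and \code{start_offset}.
#' @export
eeg_recording <- function(fp1, fp2, fs, start_offset = 0) {
  if (!is.numeric(fp1) || !is.numeric(fp2))
    stop("channels must be numeric")
  if (length(fp1) != length(fp2))
    stop("Fp1 and Fp2 must have the same length")
  if (any(!is.finite(fp1)) || any(!is.finite(fp2)))
    stop("channel values must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  structure(list(fs = fs,
                 channels = list(Fp1 = as.numeric(fp1),
                                 Fp2 = as.numeric(fp2)),
                 start_offset = start_offset),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$channels$Fp1)
  cat(sprintf("EEG recording: 2 channels (Fp1, Fp2), %d samples @ %g Hz (%.1f s)\n",
              n, x$fs, n / x$fs))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an \code{\link{eeg_recording}}.
#' @export
eeg_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  length(rec$channels$Fp1) / rec$fs
}

#' Synthesize two-channel frontal EEG with embedded blink artifacts
#'
#' Builds a test signal: independent colored background noise on each
#' channel plus a smooth raised-cosine pulse at each requested blink
#' time, rendered identically on Fp1 and Fp2 (blink deflections are
#' strongly bilateral at the frontopolar sites).  The pulse
#' \eqn{a/2\,(1+\cos(2\pi (t-t_0)/w))} has compact support of width
#' \code{template_width} and peak \code{template_amplitude}, a rough
#' stand-in for the frontal blink waveform.
#'
#' @param duration seconds of signal.
#' @param blink_times numeric vector of event times in seconds, each in
#'   \code{[0, duration)}.
#' @param fs sampling rate in Hz (default 250).
#' @param template_amplitude pulse peak in microvolts (default 100).
#' @param template_width pulse full width in milliseconds (default 300).
#' @param noise_gamma spectral exponent of the background noise
#'   (default 1, pink, the typical broadband EEG spectrum).
#' @param noise_sd background noise SD in microvolts (default 15; 0
#'   gives a noiseless fixture).
#' @param seed optional integer seed.
#' @return an \code{\link{eeg_recording}} with
#'   \code{round(fs * duration)} samples per channel and the generating
#'   parameters attached as attribute \code{"spec"}.
#' @export
synth_eeg <- function(duration, blink_times, fs = 250,
                      template_amplitude = 100, template_width = 300,
                      noise_gamma = 1, noise_sd = 15, seed = NULL) {
  stopifnot(fs > 0, duration > 0, template_width > 0,
            template_amplitude >= 0, noise_sd >= 0)
  blink_times <- sort(as.numeric(blink_times))
  if (length(blink_times) && (any(blink_times < 0) ||
                              any(blink_times >= duration)))
    stop("all blink_times must lie in [0, duration)")
  n <- as.integer(round(fs * duration))
  width_s <- template_width / 1000
  if (length(blink_times) > 1L && any(diff(blink_times) < width_s))
    warning("blink templates closer than template_width overlap; ",
            "rendered additively")

  pulse_on <- function() {
    x <- numeric(n)
    tt <- seq_len(n) / fs  # sample i at time i/fs
    for (t0 in blink_times) {
      i0 <- max(1L, as.integer(floor((t0 - width_s / 2) * fs)))
      i1 <- min(n, as.integer(ceiling((t0 + width_s / 2) * fs)))
      if (i1 < i0) next
      seg <- tt[i0:i1]
      inside <- abs(seg - t0) <= width_s / 2
      x[i0:i1] <- x[i0:i1] + inside * template_amplitude / 2 *
        (1 + cos(2 * pi * (seg - t0) / width_s))
    }
    x
  }

  with_seed(seed, {
    noise <- function() {
      if (noise_sd == 0) numeric(n)
      else colored_noise(max(n, 64L), gamma = noise_gamma,
                         sd = noise_sd)[seq_len(n)]
    }
    p <- pulse_on()
    rec <- eeg_recording(p + noise(), p + noise(), fs = fs)
    attr(rec, "spec") <- list(duration = duration, fs = fs,
                              blink_times = blink_times,
                              template_amplitude = template_amplitude,
                              template_width = template_width,
                              noise_gamma = noise_gamma,
                              noise_sd = noise_sd, seed = seed)
    rec
  })
}

#' Write / read two-channel EEG as CSV
#'
#' Columns \code{time_s}, \code{Fp1_uV}, \code{Fp2_uV}, comma-separated
#' with a header line and '.' decimal mark.  Values are printed with 17
#' significant digits so that a write/read round trip is bit-exact.
#' The writer also emits a JSON sidecar \code{<path>.json} with the
#' generating spec (if any) and the sampling rate.
#'
#' @param rec an \code{\link{eeg_recording}}.
#' @param path output CSV path.
#' @return \code{path} invisibly (writer); an \code{eeg_recording}
#'   (reader).
#' @export
write_eeg_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- length(rec$channels$Fp1)
  df <- data.frame(
    time_s  = sprintf("%.17g", rec$start_offset + (seq_len(n) - 1L) / rec$fs),
    Fp1_uV  = sprintf("%.17g", rec$channels$Fp1),
    Fp2_uV  = sprintf("%.17g", rec$channels$Fp2))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     quote = FALSE, col.names = TRUE)
  jsonlite::write_json(list(fs = rec$fs, n_samples = n,
                            spec = attr(rec, "spec")),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_eeg_csv
#' @param fs sampling rate in Hz; if \code{NULL}, inferred from the
#'   \code{time_s} column (which must then be present and uniformly
#'   increasing).
#' @param channel_names names of the two channel columns
#'   (default \code{c("Fp1_uV", "Fp2_uV")}).
#' @export
read_eeg_csv <- function(path, fs = NULL,
                         channel_names = c("Fp1_uV", "Fp2_uV")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, colClasses = NA),
                 error = function(e) stop("cannot parse CSV ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0L) stop("empty EEG file: ", path)
  miss <- setdiff(channel_names, names(df))
  if (length(miss))
    stop("channel column(s) missing: ", paste(miss, collapse = ", "))
  for (cn in channel_names)
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in channel column ", cn)
  start_offset <- 0
  if ("time_s" %in% names(df)) {
    tv <- df$time_s
    if (!is.numeric(tv)) stop("non-numeric time column")
    if (any(diff(tv) <= 0)) stop("time column is not strictly increasing")
    if (is.null(fs)) fs <- 1 / stats::median(diff(tv))
    start_offset <- tv[1L]
  }
  if (is.null(fs))
    stop("'fs' must be given when the file has no time_s column")
  eeg_recording(df[[channel_names[1L]]], df[[channel_names[2L]]],
                fs = fs, start_offset = start_offset)
}
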