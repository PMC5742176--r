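#' Pipeline run configuration
#'
#' Collects every tunable of the simulate -> detect -> BRV -> alpha ->
#' statistics chain in one flat list so that a run is fully described
#' by (config, seed).  Defaults follow the study protocol where one is
#' stated (250 Hz sampling, the \code{\link{brv_scales}} scale set,
#' 5-min rest / 10-min task sessions) and the package's documented
#' choices otherwise.
#'
#' @param seed integer RNG seed.
#' @param fs EEG sampling rate, Hz.
#' @param scales analysis scale set.
#' @param threshold_k,refractory_ms,coincidence,min_amplitude blink
#'   detection parameters (see \code{\link{detect_blinks}}).
#' @param qc_min_intervals minimum BRV length to retain a session.
#' @param sigma_divisor Gaussian kernel rule: \eqn{\sigma(l) = l /}
#'   \code{sigma_divisor}.
#' @param integrate integrate series to the profile before MFDFA.
#' @param rest_duration,iq_duration session lengths in seconds.
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(seed = 1L, fs = 250, scales = brv_scales(),
                       threshold_k = 4, refractory_ms = 250,
                       coincidence = TRUE, min_amplitude = 10,
                       qc_min_intervals = 30, sigma_divisor = 4,
                       integrate = TRUE, rest_duration = 300,
                       iq_duration = 600) {
  structure(list(seed = as.integer(seed), fs = fs, scales = scales,
                 threshold_k = threshold_k, refractory_ms = refractory_ms,
                 coincidence = coincidence, min_amplitude = min_amplitude,
                 qc_min_intervals = qc_min_intervals,
                 sigma_divisor = sigma_divisor, integrate = integrate,
                 rest_duration = rest_duration, iq_duration = iq_duration),
            class = "run_config")
}

.config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

.mfdfa_from_config <- function(brv, config) {
  div <- config$sigma_divisor
  alpha0(as.numeric(brv), scales = config$scales,
         integrate = config$integrate,
         sigma_rule = function(l) l / div)
}

#' Process one subject's two sessions end to end
#'
#' Runs blink detection, QC, BRV construction and scale-exponent
#' estimation on a resting and an IQ-session recording and returns one
#' cohort row.  A session failing QC flags the subject as excluded
#' (with the reason) rather than silently dropping it.
#'
#' @param eeg_rest,eeg_iq \code{\link{eeg_recording}} objects.
#' @param config a \code{\link{run_config}}.
#' @param id subject identifier.
#' @return a list of class \code{"subject_record"}: \code{id},
#'   \code{rest_br}, \code{rest_alpha}, \code{iq_br}, \code{iq_alpha},
#'   \code{excluded}, \code{reason}, per-session QC reports.
#' @export
run_subject <- function(eeg_rest, eeg_iq, config = run_config(), id = NA) {
  one <- function(rec, label) {
    ev <- detect_blinks(rec, threshold_k = config$threshold_k,
                        refractory_ms = config$refractory_ms,
                        coincidence = config$coincidence,
                        min_amplitude = config$min_amplitude)
    dur <- eeg_duration(rec)
    br <- blink_rate(ev, dur)
    if (nrow(ev) < 2L)
      return(list(br = br, alpha = NA_real_,
                  qc = structure(list(n_blinks = nrow(ev), n_intervals = 0L,
                                      passed = FALSE,
                                      reason = "short BRV series"),
                                 class = "qc_report")))
    brv <- build_brv(ev, session = label)
    qc <- qc_filter(brv, config$qc_min_intervals)
    alpha <- NA_real_
    if (qc$passed) {
      # a series can clear the blink-count QC yet still be too short
      # for the scale ladder; that is an exclusion, not a crash
      alpha <- tryCatch(.mfdfa_from_config(brv, config)$alpha0,
                        error = function(e) {
                          qc$passed <<- FALSE
                          qc$reason <<- "too short for scaling analysis"
                          NA_real_
                        })
    }
    list(br = br, alpha = alpha, qc = qc)
  }
  rest <- one(eeg_rest, "rest")
  iq <- one(eeg_iq, "iq")
  excluded <- !rest$qc$passed || !iq$qc$passed
  structure(list(id = id, rest_br = rest$br, rest_alpha = rest$alpha,
                 iq_br = iq$br, iq_alpha = iq$alpha,
                 excluded = excluded,
                 reason = if (!rest$qc$passed) rest$qc$reason
                          else if (!iq$qc$passed) iq$qc$reason else "ok",
                 qc_rest = rest$qc, qc_iq = iq$qc),
            class = "subject_record")
}

#' Full cohort statistics report
#'
#' Recomputes every cohort-level statistic from a per-subject table:
#' overall and per-group means/SDs, the median split, the four
#' group ANOVAs (resting/IQ blink rate and scale exponent), the two
#' between-session ANOVAs, the resting-alpha vs score correlation with
#' its regression line, and Shapiro-Wilk normality checks.  When run
#' on the bundled cohort the fixture's MD5 is verified first.
#'
#' @param path cohort CSV path (default the bundled 24-subject table).
#' @param verify_checksum verify the bundled fixture's MD5 (default
#'   \code{TRUE} when \code{path} is the bundled file).
#' @return a list of class \code{"brv_report"} with elements
#'   \code{n}, \code{summary}, \code{split}, \code{anova}
#'   (list per measurement), \code{sessions} (list per measurement
#'   pair), \code{correlation}, \code{normality}, \code{flags},
#'   \code{version}, \code{config_hash}.
#' @export
cohort_report <- function(path = cohort_fixture_path(),
                          verify_checksum = identical(path,
                                                      cohort_fixture_path())) {
  if (verify_checksum) {
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, .cohort_fixture_md5))
      stop("fixture checksum mismatch: got ", md5)
  }
  tab <- load_cohort(path)
  split <- median_split(tab)
  hi <- split$high_idx; lo <- split$low_idx
  cols <- c("rest_br", "rest_alpha", "iq_br", "iq_alpha")
  anovas <- lapply(stats::setNames(cols, cols), function(cn)
    one_way_anova(tab[[cn]][hi], tab[[cn]][lo]))
  sessions <- list(
    br = compare_sessions(tab, c("rest_br", "iq_br")),
    alpha = compare_sessions(tab, c("rest_alpha", "iq_alpha")))
  corr <- pearson_cor(tab$rest_alpha, tab$iq_score)
  normality <- lapply(stats::setNames(cols, cols), function(cn)
    shapiro_wilk(tab[[cn]]))
  flags <- character(0)
  if (nrow(tab) != 24L)
    flags <- c(flags, sprintf("cohort has n = %d, not 24", nrow(tab)))
  structure(list(n = nrow(tab),
                 summary = session_summary(tab, split),
                 split = split, anova = anovas, sessions = sessions,
                 correlation = corr, normality = normality,
                 flags = flags,
                 version = as.character(utils::packageVersion("blinkrv")),
                 table_md5 = unname(tools::md5sum(path))),
            class = "brv_report")
}

#' @export
print.brv_report <- function(x, ...) {
  cat("BRV cohort report (n =", x$n, ")\n\n")
  print(round(x$summary, 3))
  cat("\n")
  print(x$split)
  for (cn in names(x$anova)) {
    cat(sprintf("  %-10s group ANOVA: F(%d,%d) = %.3f, p = %.3f\n", cn,
                x$anova[[cn]]$df[1], x$anova[[cn]]$df[2],
                x$anova[[cn]]$F, x$anova[[cn]]$p))
  }
  for (cn in names(x$sessions)) {
    cat(sprintf("  %-10s rest-vs-task ANOVA: F(%d,%d) = %.3f, p = %.4f\n",
                cn, x$sessions[[cn]]$df[1], x$sessions[[cn]]$df[2],
                x$sessions[[cn]]$F, x$sessions[[cn]]$p))
  }
  cat("  resting alpha vs score: ")
  print(x$correlation)
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Simulate a cohort and run the full analysis
#'
#' Generates a synthetic cohort with group-specific resting scale
#' exponents (the high-score group receiving \code{alpha_high}, the
#' rest \code{alpha_low}), estimates each subject's exponents from the
#' generated interval series, and runs the cohort statistics — a
#' recovery/power harness for the median-split design.  Interval
#' series are generated directly by default; \code{from_eeg = TRUE}
#' additionally renders each session as synthetic EEG and re-detects
#' the blinks (slower, exercises the whole chain).
#'
#' @param n_subjects cohort size (>= 4; smaller cohorts draw a
#'   degrees-of-freedom warning).
#' @param effect list with \code{alpha_high}, \code{alpha_low}
#'   (resting-session targets; defaults 0.94 / 0.72),
#'   \code{alpha_iq} (both groups' task target, default 0.62),
#'   \code{rest_rate}, \code{iq_rate} (blinks/min, defaults 18, 19).
#' @param seed integer seed.
#' @param config a \code{\link{run_config}}.
#' @param from_eeg run the EEG synthesis + detection path.
#' @return list with \code{cohort} (the generated table),
#'   \code{report} (its \code{\link{cohort_report}}-style statistics)
#'   and \code{truth} (the generating targets).
#' @export
simulate_cohort <- function(n_subjects = 24,
                            effect = list(alpha_high = 0.94,
                                          alpha_low = 0.72,
                                          alpha_iq = 0.62,
                                          rest_rate = 18, iq_rate = 19),
                            seed = 1L, config = run_config(seed = seed),
                            from_eeg = FALSE) {
  stopifnot(n_subjects >= 4)
  if (n_subjects < 8)
    warning("very small cohort: ANOVA degrees of freedom (1, ",
            n_subjects - 2L, ")")
  effect <- utils::modifyList(list(alpha_high = 0.94, alpha_low = 0.72,
                                   alpha_iq = 0.62, rest_rate = 18,
                                   iq_rate = 19), effect)
  n_hi <- max(1L, round(n_subjects * 9 / 24))
  is_hi <- seq_len(n_subjects) <= n_hi
  # scores: high group strictly above the median of the whole cohort
  scores <- ifelse(is_hi, 6L, 3L)

  one_session <- function(subj, rate, target, dur, label) {
    sd_subj <- (subj * 7919L + as.integer(seed) * 104729L) %% 2147483647L
    if (from_eeg) {
      brv0 <- blink_intervals(dur, rate, alpha_target = target,
                              seed = sd_subj, session = label)
      times <- cumsum(as.numeric(brv0))
      times <- times[times < dur - 0.2]
      rec <- synth_eeg(dur, blink_times = times, fs = config$fs,
                       seed = sd_subj + 1L)
      ev <- detect_blinks(rec, threshold_k = config$threshold_k,
                          refractory_ms = config$refractory_ms,
                          coincidence = config$coincidence,
                          min_amplitude = config$min_amplitude)
      brv <- build_brv(ev, session = label)
      br <- blink_rate(ev, dur)
    } else {
      brv <- blink_intervals(dur, rate, alpha_target = target,
                             seed = sd_subj, session = label)
      br <- 60 * (length(brv) + 1L) / dur
    }
    qc <- qc_filter(brv, config$qc_min_intervals)
    list(br = br,
         alpha = if (qc$passed) .mfdfa_from_config(brv, config)$alpha0
                 else NA_real_,
         passed = qc$passed)
  }

  rows <- lapply(seq_len(n_subjects), function(i) {
    rest <- one_session(i, effect$rest_rate,
                        if (is_hi[i]) effect$alpha_high else effect$alpha_low,
                        config$rest_duration, "rest")
    iq <- one_session(i + n_subjects, effect$iq_rate, effect$alpha_iq,
                      config$iq_duration, "iq")
    data.frame(id = i, rest_br = rest$br, rest_alpha = rest$alpha,
               iq_br = iq$br, iq_alpha = iq$alpha, iq_score = scores[i],
               excluded = !(rest$passed && iq$passed))
  })
  tab <- do.call(rbind, rows)
  excluded <- tab$id[tab$excluded]
  tab <- tab[!tab$excluded,
             c("id", "rest_br", "rest_alpha", "iq_br", "iq_alpha",
               "iq_score")]
  class(tab) <- c("cohort", "data.frame")

  split <- median_split(tab)
  report <- list(
    n = nrow(tab), n_excluded = length(excluded),
    split = split,
    anova_rest_alpha = one_way_anova(tab$rest_alpha[split$high_idx],
                                     tab$rest_alpha[split$low_idx]),
    correlation = pearson_cor(tab$rest_alpha, tab$iq_score))
  list(cohort = tab, report = report,
       truth = c(effect, list(n_high = n_hi, seed = seed)))
}
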