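#' Load a per-subject cohort table
#'
#' Reads a CSV with one row per subject and the six columns
#' \code{id}, \code{rest_br}, \code{rest_alpha}, \code{iq_br},
#' \code{iq_alpha}, \code{iq_score}: blink rate (blinks/min) and BRV
#' scale exponent for the resting and IQ-test sessions, plus the IQ
#' test score (0-13, one point per problem).  The package bundles a
#' reference cohort of 24 subjects as
#' \code{system.file("extdata", "blink_cohort.csv", package = "blinkrv")}.
#'
#' @param path CSV path; default the bundled 24-subject cohort.
#' @return a data frame of class \code{"cohort"}.
#' @export
load_cohort <- function(path = cohort_fixture_path()) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("id", "rest_br", "rest_alpha", "iq_br", "iq_alpha", "iq_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty cohort table")
  for (cn in need)
    if (!is.numeric(df[[cn]]))
      stop("non-numeric values in column ", cn)
  if (anyDuplicated(df$id))
    stop("duplicate subject id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (any(df$rest_br < 0) || any(df$iq_br < 0))
    stop("blink rates must be >= 0")
  if (any(df$iq_score < 0 | df$iq_score > 13))
    stop("iq_score must lie in [0, 13]")
  df <- df[, need]
  class(df) <- c("cohort", "data.frame")
  df
}

#' @rdname load_cohort
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "blink_cohort.csv", package = "blinkrv",
              mustWork = TRUE)
}

# MD5 of the bundled cohort CSV, pinned at packaging time so pipeline
# reports can verify fixture integrity.
.cohort_fixture_md5 <- "d7b99fec731df2d8c05c3fd4ffeff33c"

#' Split a cohort at the median score
#'
#' Partitions subjects into a high group (score strictly above the
#' sample median) and a low group (at or below).  For an even cohort
#' the median is the mean of the two central order statistics.
#'
#' @param cohort a \code{\link{load_cohort}} table.
#' @param score_col column to split on (default \code{"iq_score"}).
#' @return a list of class \code{"group_split"}: \code{threshold},
#'   \code{high} and \code{low} (id vectors), \code{high_idx},
#'   \code{low_idx} (row indices).
#' @export
median_split <- function(cohort, score_col = "iq_score") {
  stopifnot(nrow(cohort) > 0, score_col %in% names(cohort))
  s <- cohort[[score_col]]
  thr <- stats::median(s)
  hi <- s > thr
  structure(list(threshold = thr,
                 high = cohort$id[hi], low = cohort$id[!hi],
                 high_idx = which(hi), low_idx = which(!hi)),
            class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("median split at %g: %d high / %d low\n",
              x$threshold, length(x$high), length(x$low)))
  invisible(x)
}

#' One-way ANOVA for two groups
#'
#' Classic fixed-effects one-way analysis of variance,
#' \eqn{F = MS_{between}/MS_{within}} with df \eqn{(1, n_a+n_b-2)} and
#' an upper-tail p-value; equivalent to the squared pooled-variance
#' two-sample t statistic.  Delegates to
#' \code{\link[stats]{oneway.test}} with \code{var.equal = TRUE}.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return a list of class \code{"anova_result"}: \code{F}, \code{df}
#'   (between, within), \code{p}, group \code{means}.
#' @export
one_way_anova <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L,
            length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(structure(list(F = 0, df = c(1L, length(a) + length(b) - 2L),
                            p = 1, means = c(mean(a), mean(b))),
                       class = "anova_result"))
    stop("infinite F: zero within-group variance with unequal means")
  }
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  ow <- stats::oneway.test(v ~ g, data.frame(v = c(a, b), g = g),
                           var.equal = TRUE)
  structure(list(F = unname(ow$statistic),
                 df = unname(c(ow$parameter[1L], ow$parameter[2L])),
                 p = unname(ow$p.value),
                 means = c(mean(a), mean(b))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}

#' Pearson correlation with regression line
#'
#' Product-moment correlation with the two-sided p-value from the t
#' transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}} (via
#' \code{\link[stats]{cor.test}}) and the least-squares line of y on x.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with
#'   nonzero variance.
#' @return a list of class \code{"correlation_result"}: \code{r},
#'   \code{p}, \code{r_squared}, \code{slope}, \code{intercept},
#'   \code{n}, \code{df}.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance input")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  structure(list(r = unname(ct$estimate), p = ct$p.value,
                 r_squared = unname(ct$estimate)^2,
                 slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 n = length(x), df = length(x) - 2L),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r(%d) = %.3f, p = %.4g, R^2 = %.3f  (y = %.3f + %.3f x)\n",
              x$df, x$r, x$p, x$r_squared, x$intercept, x$slope))
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' Standard W statistic and p-value, delegated to
#' \code{\link[stats]{shapiro.test}}; provided so pipeline reports can
#' record the normality check alongside the ANOVAs.
#'
#' @param x numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with \code{W} and \code{p}.
#' @export
shapiro_wilk <- function(x) {
  if (!is.numeric(x) || length(x) < 3L || length(x) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(x) == 0) stop("degenerate (constant) input")
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Per-column summaries, overall and by median-split group
#'
#' Sample mean and SD (n-1 denominator) of each measurement column,
#' for the whole cohort and for the high/low score groups.
#'
#' @param cohort a \code{\link{load_cohort}} table.
#' @param split optional precomputed \code{\link{median_split}}.
#' @return a data frame with rows \code{overall}, \code{high},
#'   \code{low} and columns \code{<col>_mean}, \code{<col>_sd}; SDs of
#'   single-row groups are \code{NA}.
#' @export
session_summary <- function(cohort, split = median_split(cohort)) {
  cols <- c("rest_br", "rest_alpha", "iq_br", "iq_alpha")
  rows <- list(overall = seq_len(nrow(cohort)),
               high = split$high_idx, low = split$low_idx)
  out <- do.call(rbind, lapply(rows, function(idx) {
    stats_ <- lapply(cols, function(cn) {
      v <- cohort[[cn]][idx]
      c(mean = mean(v), sd = if (length(v) >= 2L) stats::sd(v) else NA_real_)
    })
    as.data.frame(as.list(stats::setNames(
      unlist(stats_), paste(rep(cols, each = 2), c("mean", "sd"), sep = "_"))))
  }))
  rownames(out) <- names(rows)
  out
}

#' Compare the two sessions of one measurement
#'
#' One-way ANOVA treating the resting-session and IQ-session values of
#' all n subjects as two independent groups (df 1, 2n-2), e.g. to ask
#' whether the cohort's scale exponents differ between rest and task.
#'
#' @param cohort a \code{\link{load_cohort}} table.
#' @param column_pair two column names, rest first (default the alpha
#'   pair).
#' @return an \code{\link{one_way_anova}} result.
#' @export
compare_sessions <- function(cohort,
                             column_pair = c("rest_alpha", "iq_alpha")) {
  stopifnot(length(column_pair) == 2L,
            all(column_pair %in% names(cohort)))
  one_way_anova(cohort[[column_pair[1L]]], cohort[[column_pair[2L]]])
}
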