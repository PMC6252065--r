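#' Circular lagged cross-correlation of two diel profiles
#'
#' For each lag h, the Pearson correlation of the predator profile shifted
#' circularly by h hours against the prey profile, using all 24 hourly bins at
#' every lag (wrap-around shifting, so the degrees of freedom are constant,
#' n - 2 = 22). A positive lag h correlates x at hour a + h with y at hour a.
#'
#' @param profile_x,profile_y numeric vectors of 24 hourly values (counts);
#'   neither may be constant.
#' @param lags integer lags in hours (default -12..11).
#' @return named numeric vector of correlations r(h).
#' @export
circular_ccf <- function(profile_x, profile_y, lags = -12:11) {
  stopifnot(length(profile_x) == 24, length(profile_y) == 24)
  if (stats::sd(profile_x) == 0 || stats::sd(profile_y) == 0)
    stop("constant profile: cross-correlation undefined")
  r <- vapply(lags, function(h) {
    stats::cor(profile_x[((0:23 + h) %% 24) + 1], profile_y)
  }, numeric(1))
  names(r) <- lags
  r
}

#' t statistic for a correlation coefficient
#'
#' \eqn{t = r \sqrt{(n - 2) / (1 - r^2)}}, the usual test statistic for a
#' Pearson correlation over n paired observations (n = 24 hourly bins here,
#' giving 22 degrees of freedom).
#'
#' @param r correlation coefficient(s), \eqn{|r| \le 1}.
#' @param n number of paired observations (> 2).
#' @return t value(s); \eqn{|r| = 1} yields \code{Inf} with a warning.
#' @export
t_statistic <- function(r, n = 24) {
  stopifnot(n > 2, all(abs(r) <= 1))
  if (any(abs(r) == 1)) warning("|r| = 1: t statistic is infinite")
  r * sqrt((n - 2) / (1 - r^2))
}

#' Critical t value
#'
#' Upper quantile of the Student t distribution: the threshold that \eqn{|t|}
#' must exceed for significance at level p (one-tailed by default; 1.72 at
#' p = 0.05 with 22 degrees of freedom).
#'
#' @param p significance level in (0, 1).
#' @param df degrees of freedom (>= 1).
#' @param tails 1 (default) or 2.
#' @return the critical t value.
#' @export
critical_t <- function(p = 0.05, df = 22, tails = 1) {
  if (!(p > 0 && p < 1)) stop("p must be in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  stats::qt(1 - p / tails, df)
}

#' Summarise a lagged cross-correlation
#'
#' Computes the per-lag t values, the maximal runs of consecutive significant
#' lags (|t| above the critical value), and the peak lag: the significant lag
#' with the largest |r| (ties broken towards the smallest |lag|, then the
#' negative lag).
#'
#' @param r named numeric vector of per-lag correlations from
#'   \code{\link{circular_ccf}}.
#' @param n number of bins (default 24).
#' @param t_crit critical t value (default \code{critical_t(0.05, n - 2, 1)}).
#' @return a \code{ccf_result}: list with \code{lags}, \code{r}, \code{t},
#'   \code{t_crit}, \code{significant}, \code{ranges} (data.frame from/to),
#'   \code{peak_lag} (NA when no lag is significant), \code{peak_r},
#'   \code{peak_t}.
#' @export
summarise_ccf <- function(r, n = 24, t_crit = critical_t(0.05, n - 2, 1)) {
  lags <- as.integer(names(r))
  t <- t_statistic(r, n)
  sig <- abs(t) > t_crit
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  ranges <- data.frame(from = lags[starts[keep]], to = lags[ends[keep]])
  if (any(sig)) {
    cand <- which(sig)
    # max |r|, ties -> smallest |lag|, then negative lag first
    o <- cand[order(-abs(r[cand]), abs(lags[cand]), lags[cand])]
    pk <- o[1]
    peak_lag <- lags[pk]; peak_r <- unname(r[pk]); peak_t <- unname(t[pk])
  } else {
    peak_lag <- NA_integer_; peak_r <- NA_real_; peak_t <- NA_real_
  }
  structure(list(lags = lags, r = unname(r), t = unname(t), t_crit = t_crit,
                 significant = unname(sig), ranges = ranges,
                 peak_lag = peak_lag, peak_r = peak_r, peak_t = peak_t),
            class = "ccf_result")
}

#' @export
print.ccf_result <- function(x, ...) {
  cat("<ccf_result> ", sum(x$significant), " significant lag(s); t_crit = ",
      round(x$t_crit, 3), "\n", sep = "")
  if (nrow(x$ranges)) {
    cat("  ranges:", paste(sprintf("[%d, %d]", x$ranges$from, x$ranges$to),
                           collapse = " "), "\n")
    cat(sprintf("  peak lag %d h: r = %.3f, t = %.2f\n",
                x$peak_lag, x$peak_r, abs(x$peak_t)))
  } else {
    cat("  no significant lags\n")
  }
  invisible(x)
}

#' Significance stars for a t value
#'
#' @param t t value(s).
#' @param df degrees of freedom.
#' @return character: \code{"***"} p <= 0.0001, \code{"**"} p <= 0.001,
#'   \code{"*"} p <= 0.05, \code{""} otherwise (one-tailed).
#' @export
significance_stars <- function(t, df = 22) {
  p <- stats::pt(abs(t), df, lower.tail = FALSE)
  ifelse(p <= 1e-4, "***", ifelse(p <= 1e-3, "**", ifelse(p <= 0.05, "*", "")))
}
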