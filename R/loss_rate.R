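## Per-division chromosome loss-rate estimation.
##
## Both estimators invert the retention model f_n = f_0 (1 - r)^n:
##   * clone assay: the median per-clone GFP-negative fraction after n
##     divisions gives f_n = 1 - median; clones that are 100% negative are
##     excluded (chromosome presumed lost at day 0, before any division the
##     model counts);
##   * bulk time course: log-linear regression of ln(f) on division number.
## Confidence intervals are percentile bootstrap (over clones, or over
## regression residuals).

#' Number of divisions in a culture period
#'
#' @param days Culture length in days (>= 0).
#' @param divisions_per_day Divisions per day (DT40: 3).
#' @return Integer division count `round(days * divisions_per_day)`.
#' @examples
#' num_divisions(7, 3)   # 21
#' @export
num_divisions <- function(days, divisions_per_day = 3) {
  if (any(days < 0)) stop("days must be >= 0")
  as.integer(round(days * divisions_per_day))
}

#' Invert the retention model
#'
#' Solves `f_n = f_0 (1 - r)^n` for the per-division loss rate
#' `r = 1 - (f_n / f_0)^(1/n)`.
#'
#' @param f0 Initial retaining fraction in (0, 1\].
#' @param f_n Retaining fraction after `n` divisions (`0 <= f_n <= f0`).
#' @param n Number of divisions (>= 1).
#' @return Loss rate per division; if `f_n = 0` (complete loss) returns 1
#'   with attribute `complete_loss = TRUE` and a warning.
#' @examples
#' invert_retention(1, 1 - 0.0296, 21) * 100  # ~0.14 %/division
#' @export
invert_retention <- function(f0, f_n, n) {
  stopifnot(f0 > 0, f0 <= 1, n >= 1)
  if (f_n > f0) stop("f_n must not exceed f0")
  if (f_n < 0) stop("f_n must be >= 0")
  if (f_n == 0) {
    warning("complete loss (f_n = 0): loss rate saturates at 1")
    return(structure(1, complete_loss = TRUE))
  }
  1 - (f_n / f0)^(1 / n)
}

new_loss_rate_estimate <- function(r, n_divisions, f0, method, ci, level,
                                   n_units) {
  stopifnot(r >= 0, r <= 1)
  structure(list(r_per_division = r, n_divisions = n_divisions, f0 = f0,
                 method = method, ci_lower = ci[1], ci_upper = ci[2],
                 ci_level = level, n_units = n_units),
            class = "loss_rate_estimate")
}

#' @export
print.loss_rate_estimate <- function(x, ...) {
  cat(sprintf("Per-division loss rate (%s): %.4f%%/division\n",
              x$method, 100 * x$r_per_division))
  cat(sprintf("  %d divisions, f0 = %g, %d %s\n", x$n_divisions, x$f0,
              x$n_units, if (x$method == "clone_median") "clones" else "timepoints"))
  cat(sprintf("  %g%% bootstrap CI: [%.4f%%, %.4f%%]\n", 100 * x$ci_level,
              100 * x$ci_lower, 100 * x$ci_upper))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric bootstrap of an arbitrary statistic over the rows (or
#' elements) of `data`, deterministic under a fixed seed.
#'
#' @param statistic Function of a resampled `data` returning a scalar.
#' @param data Vector or data frame to resample with replacement.
#' @param n_resamples Number of bootstrap resamples (>= 100).
#' @param level Interval coverage level (default 0.95).
#' @param seed Optional RNG seed.
#' @return Numeric `c(lower, upper)` percentile interval.
#' @export
bootstrap_ci <- function(statistic, data, n_resamples = 2000, level = 0.95,
                         seed = NULL) {
  stopifnot(n_resamples >= 100, level > 0, level < 1)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 2) {
    warning("degenerate data: bootstrap interval collapses to the point estimate")
    est <- statistic(data)
    return(c(est, est))
  }
  with_seed(seed, {
    stats_boot <- vapply(seq_len(n_resamples), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      res <- if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
      statistic(res)
    }, numeric(1))
    alpha <- (1 - level) / 2
    unname(stats::quantile(stats_boot, c(alpha, 1 - alpha), type = 7))
  })
}

#' Estimate the loss rate from a limiting-dilution clone assay
#'
#' Takes the median per-clone GFP-negative fraction `m` (after excluding
#' clones at 100% negative, presumed to have lost the chromosome at day 0)
#' and inverts the retention model with `f0 = 1`:
#' `r = 1 - (1 - m)^(1/n)`. The median is used rather than the mean because
#' losses in the first few divisions produce a heavy right tail of clone
#' fractions.
#'
#' @param assay A `clone_assay` data frame (column `gfp_negative_fraction`;
#'   attribute or argument `duration_days`).
#' @param divisions_per_day Divisions per day (default from the assay
#'   attribute, else 3).
#' @param duration_days Assay length in days (default from the assay
#'   attribute).
#' @param exclude_complete_loss Drop clones with 100% negative cells
#'   (default TRUE, matching the assay's published analysis rule).
#' @param n_resamples,level,seed Bootstrap settings (percentile CI over
#'   clones).
#' @return A `loss_rate_estimate` (method `"clone_median"`).
#' @export
estimate_from_clone_assay <- function(assay,
                                      divisions_per_day = NULL,
                                      duration_days = NULL,
                                      exclude_complete_loss = TRUE,
                                      n_resamples = 2000, level = 0.95,
                                      seed = NULL) {
  divisions_per_day <- divisions_per_day %||% attr(assay, "divisions_per_day") %||% 3
  duration_days <- duration_days %||% attr(assay, "duration_days")
  if (is.null(duration_days)) stop("duration_days not given and not an assay attribute")
  fr <- assay$gfp_negative_fraction
  stopifnot(all(fr >= 0 & fr <= 1))
  if (exclude_complete_loss) fr <- fr[fr < 1]
  if (length(fr) == 0) stop("no clones left after excluding complete-loss clones")
  n <- num_divisions(duration_days, divisions_per_day)
  if (n < 1) stop("assay must span at least one division")
  est_r <- function(fractions) {
    m <- stats::median(fractions)
    if (m >= 1) 1 else 1 - (1 - m)^(1 / n)
  }
  r <- est_r(fr)
  ci <- bootstrap_ci(est_r, fr, n_resamples = n_resamples, level = level,
                     seed = seed)
  ci <- c(min(ci[1], r), max(ci[2], r))  # percentile CI must contain the point
  new_loss_rate_estimate(r, n, 1, "clone_median", ci, level, length(fr))
}

#' Fit the loss rate to a bulk retention time course
#'
#' Least-squares fit of `ln(f) = ln(f0) + n ln(1 - r)` where `f` is the
#' retained (GFP-positive) fraction and `n = divisions_per_day * day`. With
#' `f0_mode = "fixed"` the intercept is pinned to the day-0 measurement
#' (or 1 if day 0 is absent); with `"free"` it is fitted.
#'
#' @param samples Data frame with columns `day` and `retained_fraction`
#'   (values in (0, 1\]); a `flow_timecourse` is accepted directly, using
#'   `1 - fraction_gfp_negative` as the retained fraction.
#' @param divisions_per_day Divisions per day (default 3).
#' @param f0_mode `"fixed"` (default) or `"free"`.
#' @param n_resamples,level,seed Residual-bootstrap settings.
#' @return A `loss_rate_estimate` (method `"timecourse"`).
#' @export
fit_timecourse <- function(samples, divisions_per_day = 3,
                           f0_mode = c("fixed", "free"),
                           n_resamples = 2000, level = 0.95, seed = NULL) {
  f0_mode <- match.arg(f0_mode)
  if (inherits(samples, "flow_timecourse") &&
      !("retained_fraction" %in% names(samples))) {
    samples <- data.frame(day = samples$day,
                          retained_fraction = 1 - samples$fraction_gfp_negative)
  }
  stopifnot(all(c("day", "retained_fraction") %in% names(samples)))
  keep <- samples$retained_fraction > 0
  samples <- samples[keep, , drop = FALSE]
  if (nrow(samples) < 2) stop("need at least 2 timepoints with nonzero retention")
  if (any(samples$retained_fraction > 1)) stop("retained fractions must be <= 1")
  n <- samples$day * divisions_per_day
  y <- log(samples$retained_fraction)
  fit_r <- function(n, y) {
    if (f0_mode == "fixed") {
      i0 <- which(n == 0)
      logf0 <- if (length(i0)) mean(y[i0]) else 0
      use <- n > 0
      slope <- sum(n[use] * (y[use] - logf0)) / sum(n[use]^2)
      c(r = 1 - exp(slope), logf0 = logf0)
    } else {
      cf <- stats::coef(stats::lm(y ~ n))
      c(r = 1 - exp(unname(cf[2])), logf0 = unname(cf[1]))
    }
  }
  est <- fit_r(n, y)
  r <- max(0, min(1, est["r"]))
  ## residual bootstrap: refit on fitted values + resampled residuals
  fitted <- est["logf0"] + n * log(1 - est["r"])
  resid <- y - fitted
  ci <- if (length(resid) >= 3) {
    with_seed(seed, {
      rs <- vapply(seq_len(n_resamples), function(i) {
        yb <- fitted + sample(resid, length(resid), replace = TRUE)
        unname(fit_r(n, yb)["r"])
      }, numeric(1))
      alpha <- (1 - level) / 2
      unname(stats::quantile(rs, c(alpha, 1 - alpha), type = 7))
    })
  } else c(r, r)
  ci <- c(max(0, min(ci[1], r)), min(1, max(ci[2], r)))
  new_loss_rate_estimate(unname(r), max(n), exp(unname(est["logf0"])),
                         "timecourse", ci, level, nrow(samples))
}
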