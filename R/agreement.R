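# Agreement statistics: repeated-measures correlation (rmcorr), Bland-Altman
# limits of agreement, and simple-regression R^2, built from first
# principles.

#' Repeated-measures correlation
#'
#' The common within-subject association between two variables measured
#' repeatedly on the same subjects, estimated by analysis of covariance with
#' subject as a categorical factor and a shared slope. With the sequential
#' sum-of-squares decomposition this reduces to the Pearson correlation of
#' the subject-mean-centered pairs,
#' \deqn{r = \frac{\sum x_c y_c}{\sqrt{\sum x_c^2 \sum y_c^2}}, \qquad
#'   df = N_{obs} - N_{subjects} - 1,}
#' with a two-sided p-value from the t distribution on `df` degrees of
#' freedom. Incomplete pairs are dropped listwise; subjects left with fewer
#' than two pairs are excluded with a warning.
#'
#' @param subject Subject identifiers (coerced to factor).
#' @param x,y Paired measurements.
#' @return Object of class `rmcorr_result`: `r`, `df`, `p`, `n_subjects`,
#'   `n_obs`.
#' @examples
#' d <- simulate_rm_panel(20, 3, r_within = 0.6, seed = 1)
#' rmcorr(d$subject, d$x, d$y)
#' @export
rmcorr <- function(subject, x, y) {
  stopifnot(length(subject) == length(x), length(x) == length(y))
  ok <- stats::complete.cases(x, y, subject)
  subject <- factor(subject[ok]); x <- x[ok]; y <- y[ok]
  counts <- table(subject)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warnf("excluding %d subject(s) with < 2 complete pairs", length(small))
    keep <- !(subject %in% small)
    subject <- droplevels(subject[keep]); x <- x[keep]; y <- y[keep]
  }
  k <- nlevels(subject)
  n <- length(x)
  if (k < 2L) stopf("rmcorr needs >= 2 subjects with >= 2 complete pairs")
  df <- n - k - 1L
  if (df < 1L) stopf("non-positive degrees of freedom (n = %d, subjects = %d)",
                     n, k)
  xc <- x - stats::ave(x, subject)
  yc <- y - stats::ave(y, subject)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (denom <= 0) stopf("no within-subject variance in x or y")
  r <- sum(xc * yc) / denom
  r <- max(min(r, 1), -1)
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(r) * sqrt(df / (1 - r^2)), df)
  structure(list(r = r, df = df, p = p, n_subjects = k, n_obs = n),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("Repeated-measures correlation: r = %.3f, df = %d, p = %.3g (%d subjects, %d obs)\n",
              x$r, x$df, x$p, x$n_subjects, x$n_obs))
  invisible(x)
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the paired differences `a - b`; the limits of
#' agreement are `bias +/- loa_mult * sd` of the differences (sample SD,
#' n-1 denominator). The default multiplier is 2; 1.96 is available via
#' `loa_mult`.
#'
#' @param a,b Paired measurement vectors (same units).
#' @param loa_mult Limits-of-agreement multiplier (default 2).
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`.
#' @examples
#' bland_altman(c(10, 12, 9), c(9.5, 12.5, 9))
#' @export
bland_altman <- function(a, b, loa_mult = 2) {
  stopifnot(length(a) == length(b))
  ok <- stats::complete.cases(a, b)
  d <- a[ok] - b[ok]
  if (length(d) < 2L) stopf("Bland-Altman needs >= 2 complete pairs")
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - loa_mult * sd_diff,
                 loa_high = bias + loa_mult * sd_diff,
                 loa_mult = loa_mult, n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, LoA [%.4g, %.4g] (mean +/- %g SD, n = %d)\n",
              x$bias, x$loa_low, x$loa_high, x$loa_mult, x$n))
  invisible(x)
}

#' Simple linear regression with R-squared
#'
#' Ordinary least squares of `y` on `x`; `r2` is the squared Pearson
#' correlation and `p` the two-sided t-test on the slope.
#'
#' @param x,y Numeric vectors, `n >= 3`, `var(x) > 0`.
#' @return List `slope`, `intercept`, `r2`, `p`, `n`.
#' @export
linreg_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stopf("need >= 3 complete pairs")
  if (var(x) <= 0) stopf("x has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2L, 4L] else NA_real_
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r2 = r2, p = p, n = length(x))
}

#' Agreement report: EIT-derived vs esophageal-derived quantities
#'
#' For each measured/predicted pair present in the cohort (by default DP_L,
#' EL and PI), computes the simple regression ([linreg_r2()]), Bland-Altman
#' agreement ([bland_altman()]) and the intra-patient repeated-measures
#' correlation ([rmcorr()]). Rows with `usable == FALSE` (the per-measurement
#' quality flag) are excluded from all statistics.
#'
#' @param cohort data.frame with a `patient_id` column and paired columns
#'   named in `pairs`.
#' @param pairs Named list mapping a quantity label to
#'   `c(measured_column, predicted_column)`.
#' @param loa_mult Limits-of-agreement multiplier passed to [bland_altman()].
#' @return Object of class `agreement_report`: per-quantity list with
#'   `regression`, `bland_altman`, `rmcorr`, plus `n_rows_used`.
#' @export
agreement_report <- function(cohort,
                             pairs = list(dpl = c("dpl", "dpl_eit"),
                                          el = c("el", "el_eit"),
                                          pi = c("pi", "pi_eit")),
                             loa_mult = 2) {
  d <- as.data.frame(cohort)
  if ("usable" %in% names(d)) d <- d[d$usable %in% TRUE, , drop = FALSE]
  out <- list()
  for (nm in names(pairs)) {
    cols <- pairs[[nm]]
    if (!all(cols %in% names(d))) next
    meas <- d[[cols[1L]]]
    pred <- d[[cols[2L]]]
    out[[nm]] <- list(
      measured = cols[1L], predicted = cols[2L],
      regression = linreg_r2(pred, meas),
      bland_altman = bland_altman(pred, meas, loa_mult = loa_mult),
      rmcorr = tryCatch(rmcorr(d$patient_id, pred, meas),
                        error = function(e) NULL)
    )
  }
  if (length(out) == 0L) stopf("no measured/predicted column pair found")
  structure(c(out, list(n_rows_used = nrow(d))), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  for (nm in setdiff(names(x), "n_rows_used")) {
    q <- x[[nm]]
    cat(sprintf("%s (%s vs %s): R^2 = %.3f; bias = %.4g, LoA [%.3g, %.3g]",
                nm, q$predicted, q$measured, q$regression$r2,
                q$bland_altman$bias, q$bland_altman$loa_low,
                q$bland_altman$loa_high))
    if (!is.null(q$rmcorr)) cat(sprintf("; rmcorr r = %.3f", q$rmcorr$r))
    cat("\n")
  }
  cat(sprintf("rows used: %d\n", x$n_rows_used))
  invisible(x)
}

#' Plot an agreement report
#'
#' One scatter-with-identity panel and one Bland-Altman panel per quantity
#' (base graphics).
#'
#' @param x An `agreement_report`.
#' @param cohort The cohort the report was computed from.
#' @param ... Unused.
#' @return Invisibly, `x`.
#' @export
plot.agreement_report <- function(x, cohort, ...) {
  d <- as.data.frame(cohort)
  if ("usable" %in% names(d)) d <- d[d$usable %in% TRUE, , drop = FALSE]
  qs <- setdiff(names(x), "n_rows_used")
  old <- graphics::par(mfrow = c(length(qs), 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (nm in qs) {
    q <- x[[nm]]
    meas <- d[[q$measured]]; pred <- d[[q$predicted]]
    plot(pred, meas, xlab = q$predicted, ylab = q$measured,
         main = sprintf("%s: R^2 = %.2f", nm, q$regression$r2))
    graphics::abline(0, 1, lty = 2)
    avg <- (pred + meas) / 2; diff <- pred - meas
    plot(avg, diff, xlab = "mean", ylab = "difference",
         main = sprintf("bias %.2g", q$bland_altman$bias))
    graphics::abline(h = c(q$bland_altman$bias, q$bland_altman$loa_low,
                           q$bland_altman$loa_high), lty = c(1, 2, 2))
  }
  invisible(x)
}
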