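# Non-invasive estimation of transpulmonary driving pressure (DP_L) from
# airway mechanics + EIT regional ventilation, and the derived lung
# elastance (EL_EIT) and inspiratory transpulmonary pressure (PI_EIT).

# Published coefficients of the five-regressor model, stored to full printed
# precision and never rounded internally.
.published_coefs <- c(k = 16.64, alpha = 0.074683, beta = 0.230941,
                      gamma = -0.21449, delta = -0.15974, eps = -0.32996)

new_dpl_model <- function(coefs, r2 = NA_real_, fitted_on = "published",
                          fit = NULL, panel = NULL) {
  structure(list(k = coefs[["k"]], alpha = coefs[["alpha"]],
                 beta = coefs[["beta"]], gamma = coefs[["gamma"]],
                 delta = coefs[["delta"]], eps = coefs[["eps"]],
                 r2 = r2, fitted_on = fitted_on, fit = fit, panel = panel),
            class = "dpl_model")
}

#' The published DP_L prediction model
#'
#' Five-regressor linear model estimating transpulmonary driving pressure
#' from ideal body weight, respiratory-system elastance and the tidal
#' ventilation percentages of the three most ventral EIT regions (ROI4 is
#' intentionally absent):
#' \deqn{\widehat{DP}_L = k + \alpha\, IBW + \beta\, Ers + \gamma\, roi1\%
#'   + \delta\, roi2\% + \epsilon\, roi3\%}
#' with k = 16.64, alpha = 0.074683, beta = 0.230941, gamma = -0.21449,
#' delta = -0.15974, epsilon = -0.32996 (ROI percentages on the 0-100
#' scale).
#'
#' @return A `dpl_model` with `fitted_on = "published"`.
#' @examples
#' predict_dpl(published_dpl_model(), 65, 27, 19, 37, 31)
#' @export
published_dpl_model <- function() {
  new_dpl_model(.published_coefs, r2 = 0.84, fitted_on = "published")
}

#' Predict transpulmonary driving pressure
#'
#' Evaluates a [published_dpl_model()] / [fit_dpl_model()] linear model.
#' Vectorized over the covariates. Inputs outside the physiologic ranges
#' (Ers in \[5, 80\] cmH2O/L, ROI% in \[0, 100\]) and negative predictions
#' (non-physiologic extrapolation) produce warnings, not errors.
#'
#' @param model A `dpl_model`.
#' @param ibw_kg Ideal body weight (kg).
#' @param ers Respiratory-system elastance (cmH2O/L).
#' @param roi1_pct,roi2_pct,roi3_pct Tidal ventilation percentages of ROI1-3
#'   (0-100 scale).
#' @param warn Emit range warnings (default `TRUE`).
#' @return Predicted DP_L (cmH2O).
#' @export
predict_dpl <- function(model, ibw_kg, ers, roi1_pct, roi2_pct, roi3_pct,
                        warn = TRUE) {
  stopifnot(inherits(model, "dpl_model"))
  args <- list(ibw_kg = ibw_kg, ers = ers, roi1_pct = roi1_pct,
               roi2_pct = roi2_pct, roi3_pct = roi3_pct)
  for (nm in names(args)) {
    if (is.null(args[[nm]]) || length(args[[nm]]) == 0L || anyNA(args[[nm]]))
      stopf("missing covariate: %s", nm)
  }
  if (warn) {
    if (any(ers < 5 | ers > 80))
      warnf("Ers outside the physiologic range [5, 80] cmH2O/L")
    rois <- c(roi1_pct, roi2_pct, roi3_pct)
    if (any(rois < 0 | rois > 100))
      warnf("ROI%% outside [0, 100]")
  }
  out <- model$k + model$alpha * ibw_kg + model$beta * ers +
    model$gamma * roi1_pct + model$delta * roi2_pct + model$eps * roi3_pct
  if (warn && any(out < 0))
    warnf("negative predicted DP_L (non-physiologic extrapolation)")
  out
}

#' Refit the DP_L prediction model on a cohort panel
#'
#' Pooled ordinary least squares with intercept on the stacked patient-by-
#' condition rows (the panel index is retained as model metadata); this is
#' the estimator whose in-sample mean residual is zero by construction,
#' matching a near-zero Bland-Altman bias of predictions against the fitting
#' data. `method = "within"` instead applies the fixed-effects within
#' estimator (all variables demeaned by patient) as a sensitivity analysis.
#'
#' @param cohort A `cohort_table` (or data.frame) with columns `dpl`,
#'   `ibw_kg`, `ers`, `roi1_pct`, `roi2_pct`, `roi3_pct`, `patient_id`; rows
#'   with `usable == FALSE` are excluded.
#' @param method `"pooled"` (default) or `"within"`.
#' @return A `dpl_model` with `fitted_on = "refit"` (or `"refit_within"`),
#'   `r2`, and the underlying `lm` fit in `$fit`.
#' @examples
#' co <- make_cohort(cohort_spec(n_patients = 10, dpl_noise_sd = 0, seed = 3))
#' fit_dpl_model(co)$beta
#' @export
fit_dpl_model <- function(cohort, method = c("pooled", "within")) {
  method <- match.arg(method)
  need <- c("dpl", "ibw_kg", "ers", "roi1_pct", "roi2_pct", "roi3_pct",
            "patient_id")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stopf("cohort is missing columns: %s",
                          paste(miss, collapse = ", "))
  d <- as.data.frame(cohort)
  if ("usable" %in% names(d)) d <- d[d$usable %in% TRUE, , drop = FALSE]
  d <- d[stats::complete.cases(d[, need]), , drop = FALSE]
  if (nrow(d) < 10L) stopf("need >= 10 complete rows, got %d", nrow(d))
  if (length(unique(d$patient_id)) < 2L) stopf("need >= 2 patients")

  vars <- c("ibw_kg", "ers", "roi1_pct", "roi2_pct", "roi3_pct")
  if (method == "within") {
    for (v in c("dpl", vars))
      d[[v]] <- d[[v]] - stats::ave(d[[v]], d$patient_id)
    # patient-invariant regressors (typically IBW) vanish under demeaning
    vars <- vars[vapply(vars, function(v) var(d[[v]]) > 1e-12, logical(1))]
  }
  fit <- lm(stats::reformulate(vars, response = "dpl"), data = d)
  if (fit$rank < length(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stopf("rank-deficient design; collinear columns: %s",
          paste(bad, collapse = ", "))
  }
  cf <- setNames(rep(NA_real_, 6L),
                 c("(Intercept)", "ibw_kg", "ers", "roi1_pct", "roi2_pct",
                   "roi3_pct"))
  cf[names(coef(fit))] <- coef(fit)
  r2 <- if (var(d$dpl) < 1e-12) 0 else summary(fit)$r.squared
  if (!is.finite(r2)) r2 <- 0
  new_dpl_model(
    c(k = unname(cf["(Intercept)"]), alpha = unname(cf["ibw_kg"]),
      beta = unname(cf["ers"]), gamma = unname(cf["roi1_pct"]),
      delta = unname(cf["roi2_pct"]), eps = unname(cf["roi3_pct"])),
    r2 = r2,
    fitted_on = if (method == "within") "refit_within" else "refit",
    fit = fit, panel = d$patient_id)
}

#' @export
print.dpl_model <- function(x, ...) {
  cat("DP_L prediction model (", x$fitted_on, ")\n", sep = "")
  cat(sprintf("  DP_L = %.4f + %.6f*IBW + %.6f*Ers + %.5f*roi1%% + %.5f*roi2%% + %.5f*roi3%%\n",
              x$k, x$alpha, x$beta, x$gamma, x$delta, x$eps))
  if (is.finite(x$r2)) cat(sprintf("  R^2 = %.3f\n", x$r2))
  invisible(x)
}

#' EIT-derived lung elastance
#'
#' `EL_EIT = DP_L,EIT / TV` with TV in litres (cmH2O/L) — the dimensionally
#' consistent form of the elastance definition `EL = DP_L / TV`.
#'
#' @param dpl_eit Predicted transpulmonary driving pressure (cmH2O).
#' @param tv_ml Tidal volume (ml), positive.
#' @return Lung elastance (cmH2O/L).
#' @export
derive_el_eit <- function(dpl_eit, tv_ml) {
  if (any(tv_ml <= 0)) stopf("tv_ml must be positive")
  dpl_eit / (tv_ml / 1000)
}

#' EIT-derived elastance-based inspiratory transpulmonary pressure
#'
#' `PI_EIT = Pplat - Pplat * (Ers - EL_EIT)/Ers = Pplat * EL_EIT / Ers`:
#' the plateau pressure scaled by the lung's share of the respiratory-system
#' elastance.
#'
#' @param pplat Plateau pressure (cmH2O).
#' @param ers Respiratory-system elastance (cmH2O/L), positive.
#' @param el_eit EIT-derived lung elastance (cmH2O/L).
#' @return Inspiratory transpulmonary pressure (cmH2O). Warns if
#'   `el_eit > ers` (PI would exceed Pplat).
#' @export
derive_pi_eit <- function(pplat, ers, el_eit) {
  if (any(ers <= 0)) stopf("ers must be positive")
  if (any(el_eit > ers))
    warnf("el_eit exceeds ers: PI_EIT exceeds Pplat")
  pplat * (el_eit / ers)
}
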