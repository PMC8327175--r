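# Shared fixtures: a reference patient whose mechanics give round numbers
# (EL 18, Ecw 9 -> Ers 27 cmH2O/L; TV 400 ml at 6 ml/kg) and a short,
# noiseless VCV scenario with a long expiratory time so the residual volume
# is negligible.

ref_patient <- function(...) {
  patient_params(el_true = 18, ecw_true = 9, rrs = 8, ibw_kg = 400 / 6,
                 roi_base = c(0.19, 0.37, 0.31, 0.13),
                 roi_peep_slope = c(0, 0, 0, 0), ...)
}

ref_scenario <- function(...) {
  args <- list(peep_set = 10, resp_rate = 12, n_breaths = 12)
  over <- list(...)
  args[names(over)] <- over
  do.call(vcv_scenario, args)
}

ref_bundle <- function(params = ref_patient(), scenario = ref_scenario()) {
  simulate_vcv(params, scenario)
}

# Deterministic repeated-measures fixture whose rmcorr result was frozen
# from an independent ANCOVA implementation.
rm_fixture <- function() {
  withr::with_seed(11, {
    subj <- rep(1:6, each = 4)
    x <- rnorm(24, mean = rep(rnorm(6, 10, 3), each = 4), sd = 1)
    y <- 2 - 0.7 * x + rep(rnorm(6, 0, 2), each = 4) + rnorm(24, 0, 0.5)
    data.frame(subj = subj, x = x, y = y)
  })
}
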