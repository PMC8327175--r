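test_that("breath segmentation round-trips the simulator", {
  b <- ref_bundle(scenario = ref_scenario(n_breaths = 14))
  br <- segment_breaths(b)
  # the first cycle has no preceding sub-threshold sample, so n - 1 starts
  expect_equal(nrow(br), 13)
  expect_true(all(abs(br$tv_ml - 400) / 400 < 0.01))
  expect_true(all(diff(br$start) > 0))
})

test_that("all-zero flow yields an empty breath list with a warning", {
  d <- data.frame(t = seq(0, 10, by = 0.01), paw = 5, flow = 0, peso = 5)
  expect_warning(br <- segment_breaths(d), "no breath")
  expect_equal(nrow(br), 0)
})

test_that("inter-breath flow noise below threshold creates no spurious breaths", {
  b <- ref_bundle()
  n0 <- nrow(segment_breaths(b, min_insp_flow = 100))
  noisy <- b
  quiet <- abs(noisy$signals$flow) < 1
  noisy$signals$flow[quiet] <- noisy$signals$flow[quiet] +
    withr::with_seed(3, runif(sum(quiet), -49, 49))
  expect_equal(nrow(segment_breaths(noisy, min_insp_flow = 100)), n0)
})

test_that("occlusion pauses are located and read correctly", {
  b <- ref_bundle()   # 0.5 s pauses
  br <- segment_breaths(b)
  sig <- b$signals
  for (i in seq_len(nrow(br))) {
    pw <- detect_pauses(b, br[i, ], flow_eps = 10, min_dur_s = 0.2)
    expect_true(pw$usable)
    expect_gte(diff(pw$insp) / 100, 0.3)    # >= 0.3 s at fs = 100 Hz
    expect_gte(diff(pw$exp) / 100, 0.3)
  }
  # noiseless plateau readout: median(paw over insp window final half)
  # equals PEEP + Ers * (TV + residual volume); the DP identity is exact
  ba <- analyze_breaths(b)
  expect_true(all(abs((ba$pplat - ba$peep_tot) - 27 * 0.4) < 0.01))
})

test_that("a breath without an inspiratory pause is flagged unusable", {
  b <- ref_bundle(scenario = ref_scenario(pause_insp_s = 0))
  ba <- analyze_breaths(b)
  expect_true(all(!ba$usable))
  expect_error(summarize_mechanics(ba), "no usable breath")
})

test_that("mechanics formulas and identities hold on landmark averages", {
  # landmark medians of a typical ARDS panel: Pplat 23, PEEPtot 13, TV 375
  breaths <- data.frame(
    breath = 1:3, start = 1, end = 2, tv_ml = 375, ppeak = 31,
    pplat = 23, peep_tot = 13, peso_insp = 14.3, peso_exp = 11.3,
    usable = TRUE, ordered_ok = TRUE)
  s <- summarize_mechanics(breaths)
  expect_equal(s$dp, 10)
  expect_equal(s$ers, 10 / 0.375)            # 26.7 cmH2O/L
  expect_equal(s$dpl, 7)
  expect_equal(s$el, 7 / 0.375)              # 18.7 cmH2O/L
  expect_equal(s$ers, s$el + s$ecw, tolerance = 1e-9)
  expect_equal(s$pi, s$pplat * s$el / s$ers, tolerance = 1e-9)
  expect_equal(s$pi, s$pplat - s$pplat * (s$ecw / s$ers), tolerance = 1e-9)

  # averaging order: identical breaths make both orders agree exactly
  s2 <- summarize_mechanics(breaths, per_breath = TRUE)
  expect_equal(s2$dpl, s$dpl, tolerance = 1e-12)
})

test_that("summary averages use at most the last 10 usable breaths", {
  b <- ref_bundle(scenario = ref_scenario(n_breaths = 15))
  s <- summarize_mechanics(analyze_breaths(b))
  expect_equal(s$n_breaths_used, 10)
})

test_that("end-expiratory transpulmonary pressure may be negative", {
  breaths <- data.frame(
    breath = 1, start = 1, end = 2, tv_ml = 375, ppeak = 30,
    pplat = 23, peep_tot = 10, peso_insp = 14, peso_exp = 11,
    usable = TRUE, ordered_ok = TRUE)
  s <- summarize_mechanics(breaths)
  expect_lt(s$pl_exp, 0)   # no clamping
})

test_that("measured DP_L increases strictly with true lung elastance", {
  dpl_at <- function(el) {
    p <- patient_params(el_true = el, ecw_true = 9, rrs = 8, ibw_kg = 400 / 6)
    summarize_mechanics(analyze_breaths(simulate_vcv(p, ref_scenario())))$dpl
  }
  vals <- vapply(c(12, 18, 24, 30), dpl_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("pause-window medians and breath averaging suppress the cardiac artifact", {
  sc <- ref_scenario(cardiac_amp = 1, noise_sd_paw = 0.05,
                     noise_sd_peso = 0.05, resp_rate = 19, seed = 5)
  s <- summarize_mechanics(analyze_breaths(ref_bundle(scenario = sc)))
  expect_lt(abs(s$dpl - 18 * 0.4), 0.5)   # 1 cmH2O artifact largely removed
  expect_lt(abs(s$dp - 27 * 0.4), 0.25)
})

test_that("occlusion test reads the Peso/Paw swing ratio", {
  occ <- simulate_occlusion(paw_swing = 5, ratio = 1)
  r <- occlusion_test(occ$paw, occ$peso)
  expect_equal(r$ratio, 1, tolerance = 1e-9)
  expect_true(r$valid)

  occ2 <- simulate_occlusion(paw_swing = 5, ratio = 0.6)
  r2 <- occlusion_test(occ2$paw, occ2$peso)
  expect_equal(r2$ratio, 0.6, tolerance = 1e-9)
  expect_false(r2$valid)

  # offset invariance: Peso = Paw + constant
  expect_equal(occlusion_test(occ$paw, occ$paw + 7)$ratio, 1)
  expect_error(occlusion_test(rep(5, 10), rep(8, 10)), "no oscillation")
})
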