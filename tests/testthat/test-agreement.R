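test_that("rmcorr is exact on common-slope within-subject lines", {
  subj <- rep(1:4, each = 3)
  x <- rep(c(1, 2, 3), 4)
  y <- 2 * x + rep(c(0, 5, 10, 20), each = 3)   # shared slope, own intercepts
  r <- rmcorr(subj, x, y)
  expect_equal(r$r, 1)
  expect_equal(r$df, 12 - 4 - 1)
  expect_equal(r$p, 0)
  yneg <- -2 * x + rep(c(0, 5, 10, 20), each = 3)
  expect_equal(rmcorr(subj, x, yneg)$r, -1)
})

test_that("rmcorr matches an independent ANCOVA oracle on a frozen fixture", {
  d <- rm_fixture()
  r <- rmcorr(d$subj, d$x, d$y)
  # frozen from an independent repeated-measures correlation implementation
  expect_equal(r$r, -0.6573503025740636, tolerance = 1e-9)
  expect_equal(r$df, 17)
  expect_equal(r$p, 0.002225390638442283, tolerance = 1e-9)

  # and against the sequential sum-of-squares ANCOVA decomposition
  fit <- lm(y ~ factor(subj) + x, data = d)
  a <- anova(fit)
  r_anova <- sign(coef(fit)[["x"]]) *
    sqrt(a["x", "Sum Sq"] / (a["x", "Sum Sq"] + a["Residuals", "Sum Sq"]))
  expect_equal(r$r, r_anova, tolerance = 1e-12)
})

test_that("rmcorr is affine-invariant with sign following the slope", {
  d <- simulate_rm_panel(30, 3, r_within = 0.4, seed = 17)
  r0 <- rmcorr(d$subject, d$x, d$y)
  expect_equal(rmcorr(d$subject, 3 + 2 * d$x, d$y)$r, r0$r, tolerance = 1e-12)
  expect_equal(rmcorr(d$subject, -d$x, d$y)$r, -r0$r, tolerance = 1e-12)
})

test_that("rmcorr recovers a generating within-subject correlation of -0.68", {
  d <- simulate_rm_panel(200, 3, r_within = -0.68, seed = 7)
  r <- rmcorr(d$subject, d$x, d$y)
  expect_equal(r$r, -0.68, tolerance = 0.05)
  expect_equal(r$df, 600 - 200 - 1)
  expect_lt(r$p, 0.001)
})

test_that("rmcorr drops short subjects and enforces minimum structure", {
  subj <- c(1, 1, 1, 2, 2, 2, 3)
  x <- c(1, 2, 3, 1, 2, 3, 1)
  y <- c(1, 2, 3, 2, 3, 4, 9)
  expect_warning(r <- rmcorr(subj, x, y), "excluding 1 subject")
  expect_equal(r$n_subjects, 2)
  expect_error(suppressWarnings(rmcorr(c(1, 1, 2), c(1, 2, 1), c(1, 2, 1))),
               ">= 2 subjects")
})

test_that("rmcorr null type-I error is calibrated near 0.05", {
  alpha_hits <- vapply(1:500, function(s) {
    d <- local({
      withr::with_seed(10000 + s, {
        data.frame(subject = rep(1:20, each = 3),
                   x = rnorm(60), y = rnorm(60))
      })
    })
    rmcorr(d$subject, d$x, d$y)$p < 0.05
  }, logical(1))
  expect_gte(mean(alpha_hits), 0.03)
  expect_lte(mean(alpha_hits), 0.07)
})

test_that("Bland-Altman bias and limits follow mean +/- 2 SD", {
  a <- c(10, 12, 9); expect_equal(bland_altman(a, a)$bias, 0)
  expect_equal(bland_altman(a, a)$loa_high, 0)

  d <- rep(c(-1.2, 1.2), 30)
  ba <- bland_altman(d, rep(0, 60))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_high, 2 * 1.2 * sqrt(60 / 59), tolerance = 1e-12)
  expect_equal(ba$loa_low, -ba$loa_high)

  # translation shifts the bias only; swapping arguments negates it
  b <- withr::with_seed(2, rnorm(40)); a2 <- b + withr::with_seed(3, rnorm(40))
  ba1 <- bland_altman(a2, b); ba2 <- bland_altman(a2 + 3, b)
  expect_equal(ba2$bias, ba1$bias + 3)
  expect_equal(ba2$sd_diff, ba1$sd_diff)
  ba3 <- bland_altman(b, a2)
  expect_equal(ba3$bias, -ba1$bias)
  expect_equal(ba3$sd_diff, ba1$sd_diff)

  expect_error(bland_altman(1, 1), ">= 2")
  expect_equal(bland_altman(a2, b, loa_mult = 1.96)$loa_high,
               ba1$bias + 1.96 * ba1$sd_diff)
})

test_that("simple regression R^2 behaves as the squared Pearson correlation", {
  x <- 1:20
  r <- suppressWarnings(linreg_r2(x, 2 * x + 1))
  expect_equal(r$r2, 1)
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 1)

  withr::with_seed(4, {
    xn <- rnorm(1000); yn <- rnorm(1000)
    rn <- linreg_r2(xn, yn)
    expect_lt(rn$r2, 0.01)
    expect_equal(linreg_r2(yn, xn)$r2, rn$r2, tolerance = 1e-12)
  })
  expect_error(linreg_r2(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("agreement report is exact when predictions equal measurements", {
  co <- make_cohort(cohort_spec(n_patients = 10, seed = 19))
  co$dpl_eit <- co$dpl
  rep_ <- suppressWarnings(   # identical pairs trip lm's perfect-fit warning
    agreement_report(co, pairs = list(dpl = c("dpl", "dpl_eit"))))
  expect_equal(rep_$dpl$regression$r2, 1)
  expect_equal(rep_$dpl$bland_altman$bias, 0)
  expect_equal(rep_$dpl$bland_altman$loa_high, 0)
  expect_equal(rep_$dpl$rmcorr$r, 1)
})

test_that("agreement report honors the per-measurement quality flag", {
  co <- make_cohort(cohort_spec(n_patients = 20, seed = 20))
  co$dpl_eit <- co$dpl + withr::with_seed(1, rnorm(60, 0, 0.5))
  co$usable[1] <- FALSE   # one measurement excluded after quality check
  rep_ <- agreement_report(co, pairs = list(dpl = c("dpl", "dpl_eit")))
  expect_equal(rep_$n_rows_used, 59)
  expect_equal(rep_$dpl$bland_altman$n, 59)
  expect_true(is.finite(rep_$dpl$regression$r2))
  expect_true(is.finite(rep_$dpl$rmcorr$r))
})
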