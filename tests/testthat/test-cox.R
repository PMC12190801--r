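sim_one_cov <- function(n, beta, seed, shape = 1.2, scale = 10,
                        censor = c(0.5, 8)) {
  simulate_cohort(cohort_spec(
    n = n, beta_death = beta, beta_mi = c(),
    baseline_death = list(shape = shape, scale = scale), baseline_mi = NULL,
    censor_range = censor
  ), seed = seed)
}

test_that("a null covariate gives HR near 1 with CI spanning 1", {
  co <- sim_one_cov(3000, c(), seed = 8)
  co$noise <- rnorm(nrow(co))
  fit <- fit_cox(co, "noise", event_of_interest = "death")
  td <- tidy(fit, exponentiate = TRUE)
  expect_lt(abs(td$estimate - 1), 0.1)
  expect_true(td$conf.low < 1 && td$conf.high > 1)
})

test_that("per-SD hazard ratios are invariant to affine covariate rescaling", {
  co <- sim_one_cov(2000, c(vat_density_hu = log(1.5)), seed = 12)
  f1 <- fit_cox(co, "vat_density_hu", event_of_interest = "death")
  co2 <- co
  co2$vat_density_hu <- 10 * co2$vat_density_hu + 250
  f2 <- fit_cox(co2, "vat_density_hu", event_of_interest = "death")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-10)
})

test_that("log-transformed covariates are standardized after the transform", {
  co <- sim_one_cov(2000, c(mfr = log(0.7)), seed = 13)
  fit <- fit_cox(co, "mfr", event_of_interest = "death", log_covariates = "mfr")
  sc <- fit$scaling
  expect_true(sc$log_transformed)
  expect_equal(sc$center, mean(log(co$mfr)))
  expect_equal(sc$scale, sd(log(co$mfr)))
  # the per-SD estimate recovers the true log-hazard on the log scale
  expect_lt(abs(tidy(fit)$estimate - log(0.7)), 3 * tidy(fit)$std.error)
  expect_error(
    fit_cox(dplyr::mutate(co, mfr = mfr - 5), "mfr",
            event_of_interest = "death", log_covariates = "mfr"),
    "positive"
  )
})

test_that("categorical CAC enters with zero as the reference", {
  co <- simulate_cohort(cohort_spec(n = 3000), seed = 14)
  fit <- fit_cox(co, c("age", "cac_category"))
  terms <- tidy(fit)$term
  expect_false(any(grepl("cac_category0$", terms)))
  expect_true(any(grepl("cac_category1-99", terms, fixed = TRUE)))
})

test_that("models with fewer than 10 events are refused", {
  co <- sim_one_cov(30, c(), seed = 15, censor = c(0.001, 0.01))
  expect_error(fit_cox(co, "age", event_of_interest = "death"), "at least 10")
})

test_that("LR chi-square increments behave like nested likelihood ratios", {
  co <- sim_one_cov(2000, c(vat_density_hu = log(1.6)), seed = 16)
  co$noise <- rnorm(nrow(co))
  base <- fit_cox(co, "age", event_of_interest = "death")
  ext <- fit_cox(co, c("age", "vat_density_hu"), event_of_interest = "death")
  full <- fit_cox(co, c("age", "vat_density_hu", "noise"),
                  event_of_interest = "death")

  inc <- lr_chi2_increment(base, ext)
  expect_gte(inc$chisq, 0)
  expect_identical(inc$df, 1L)
  expect_true(inc$significant)  # a true effect at alpha = .001

  # additivity over a nested chain A < B < C
  ab <- lr_chi2_increment(base, ext)$chisq
  bc <- lr_chi2_increment(ext, full)$chisq
  ac <- lr_chi2_increment(base, full)$chisq
  expect_equal(ab + bc, ac, tolerance = 1e-8)

  # a duplicated (collinear) covariate adds ~zero chi-square
  co$dup <- co$vat_density_hu
  ext2 <- suppressWarnings(
    fit_cox(co, c("age", "vat_density_hu", "dup"), event_of_interest = "death")
  )
  expect_lt(lr_chi2_increment(ext, ext2)$chisq, 1e-6)

  # different models on different subjects are refused
  other <- fit_cox(co[1:1500, ], c("age", "vat_density_hu"),
                   event_of_interest = "death")
  expect_error(lr_chi2_increment(base, other), "different subjects or events")
  expect_error(lr_chi2_increment(ext, base), "not nested|not a subset")
})

test_that("true per-SD log-hazards are recovered without bias", {
  # 30 replicates at n = 2000 with true log-HR = ln 2 (the full 200-replicate
  # calibration is exercised by the acceptance suite)
  ests <- ses <- numeric(30)
  for (r in 1:30) {
    co <- sim_one_cov(2000, c(vat_density_hu = log(2)), seed = 1000 + r)
    td <- tidy(fit_cox(co, "vat_density_hu", event_of_interest = "death"))
    ests[r] <- td$estimate; ses[r] <- td$std.error
  }
  expect_lt(abs(mean(ests) - log(2)) / log(2), 0.05)
  cover <- mean(abs(ests - log(2)) <= 1.96 * ses)
  expect_gte(cover, 0.8)
})

test_that("schoenfeld diagnostics flag a strong time-varying effect", {
  set.seed(77)
  n <- 2000
  x <- rnorm(n)
  # piecewise hazard: effect +1 before t = 1, -1 after -> gross PH violation
  t1 <- rexp(n, exp(x))
  t2 <- 1 + rexp(n, exp(-x))
  tt <- ifelse(t1 < 1, t1, t2)
  d <- tibble::tibble(time = tt, event = factor("death",
                      levels = c("censored", "death", "mi")), x = x)
  fit <- fit_cox(d, "x", event_of_interest = "death")
  zp <- schoenfeld_check(fit)
  expect_lt(zp$p.value[zp$term == "x"], 0.001)

  # a time-constant effect is usually not flagged
  co <- sim_one_cov(2000, c(vat_density_hu = log(1.5)), seed = 18)
  fitc <- fit_cox(co, "vat_density_hu", event_of_interest = "death")
  zpc <- schoenfeld_check(fitc)
  expect_true(all(c("vat_density_hu", "GLOBAL") %in% zpc$term))

  # a model with no covariates emits no tests
  null_fit <- fit_cox(co, character(0), event_of_interest = "death")
  expect_identical(nrow(schoenfeld_check(null_fit)), 0L)
})

test_that("tidy and glance expose broom-style summaries", {
  co <- sim_one_cov(1000, c(vat_density_hu = log(1.5)), seed = 19)
  fit <- fit_cox(co, c("age", "vat_density_hu"), event_of_interest = "death")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$lr_chisq, 2 * (gl$loglik - gl$null_loglik))
  expect_identical(gl$nevent, fit$nevent)
  expect_s3_class(autoplot(fit), "ggplot")
})
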