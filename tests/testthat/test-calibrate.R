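test_that("published corrections evaluate exactly and increase with area", {
  expect_equal(apply_vat_correction(0, 0), 7.224)
  expect_equal(apply_vat_correction(100, 1), 126.007)
  expect_equal(apply_vat_correction(50, 0), 62.824)
  expect_equal(apply_sat_correction(0, 0), 0.67)
  expect_equal(apply_sat_correction(100, 1), 107.707)
  expect_equal(apply_sat_correction(200, 0), 208.07)

  a <- seq(0, 300, by = 10)
  expect_true(all(diff(apply_vat_correction(a, 0)) > 0))
  expect_true(all(diff(apply_sat_correction(a, 1)) > 0))
  expect_error(apply_vat_correction(-1, 0), "non-negative")
  expect_error(apply_sat_correction(10, 2), "indicator")
})

test_that("inverse-frequency weights are reciprocal subgroup counts", {
  rec <- data.frame(
    sex = c(rep("female", 10), rep("male", 30)),
    age_category = "adult")
  w <- inverse_frequency_weights(rec)
  expect_equal(w[1], 1 / 10)
  expect_equal(w[11], 1 / 30)
  # weighted count per cell sums to 1
  expect_equal(sum(w[rec$sex == "female"]), 1)
  expect_equal(sum(w[rec$sex == "male"]), 1)

  one <- data.frame(sex = rep("male", 7), age_category = rep("child", 7))
  expect_equal(inverse_frequency_weights(one), rep(1 / 7, 7))
})

test_that("WLS recovers generating coefficients exactly in the noiseless limit", {
  sp <- cohort_sim_spec(n = 60, coefficients = c(7.224, 1.112, 7.583),
                        residual_sd = 0, seed = 30L)
  co <- generate_cohort(sp, "vat")
  fit <- fit_wls(co, "vat_manual_cm2", c("vat_otsu_cm2", "obesity"))
  expect_equal(unname(fit$terms), c(7.224, 1.112, 7.583), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  sp2 <- cohort_sim_spec(n = 60, coefficients = c(0.67, 1.037, 3.337),
                         residual_sd = 0, predictor_range_cm2 = c(20, 400),
                         seed = 31L)
  co2 <- generate_cohort(sp2, "sat")
  fit2 <- fit_wls(co2, "sat_manual_cm2", c("sat_otsu_cm2", "age_category"))
  expect_equal(unname(fit2$terms), c(0.67, 1.037, 3.337), tolerance = 1e-6)
})

test_that("equal weights reduce WLS to ordinary least squares", {
  sp <- cohort_sim_spec(n = 80, residual_sd = 6, seed = 32L)
  co <- generate_cohort(sp, "vat")
  wls <- fit_wls(co, "vat_manual_cm2", c("vat_otsu_cm2", "obesity"),
                 weights = rep(2, 80))
  ols <- lm(vat_manual_cm2 ~ vat_otsu_cm2 + obesity, data = co)
  expect_equal(unname(wls$terms), unname(coef(ols)), tolerance = 1e-10)
})

test_that("rank deficiency errors name the collinear terms", {
  sp <- cohort_sim_spec(n = 40, residual_sd = 1, seed = 33L)
  co <- generate_cohort(sp, "vat")
  co$dup <- co$vat_otsu_cm2
  expect_error(fit_wls(co, "vat_manual_cm2", c("vat_otsu_cm2", "dup")),
               "rank deficient")
})

test_that("model selection drops inactive terms and is deterministic", {
  sp <- cohort_sim_spec(n = 2000, coefficients = c(7.224, 1.112, 7.583),
                        residual_sd = 2, seed = 34L)
  co <- generate_cohort(sp, "vat")
  sel1 <- select_model(co, "vat_manual_cm2")
  sel2 <- select_model(co, "vat_manual_cm2")
  expect_identical(sel1$terms, sel2$terms)
  # only obesity is active in the generating model
  expect_true("obesity" %in% sel1$terms)
  expect_false(any(c("sex", "age_category") %in% sel1$terms))

  single <- select_model(co, "vat_manual_cm2", candidates = "obesity")
  expect_identical(single$terms, "obesity")
})

test_that("selection excludes inactive demographics in most simulated cohorts", {
  # generating model: intercept + slope + obesity only; sex/age and all
  # interactions are noise terms the selection should reject
  n_clean <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    sp <- cohort_sim_spec(n = 2000, coefficients = c(7.224, 1.112, 7.583),
                          residual_sd = 2, seed = 5000L + r)
    co <- generate_cohort(sp, "vat")
    sel <- select_model(co, "vat_manual_cm2")
    extra <- setdiff(sel$terms, "obesity")
    if (length(extra) == 0) n_clean <- n_clean + 1L
  }
  expect_gte(n_clean / reps, 0.95)
})

test_that("VIF matches its closed form", {
  set.seed(35)
  n <- 400
  x1 <- rnorm(n)
  z <- rnorm(n)
  # construct x2 with exact sample correlation 0.8
  x1c <- scale(x1)[, 1]
  zperp <- scale(residuals(lm(z ~ x1c)))[, 1]
  x2 <- 0.8 * x1c + sqrt(1 - 0.64) * zperp
  rec <- data.frame(a = x1c, b = x2, c = rnorm(n))
  v <- vif(rec, c("a", "b"))
  expect_equal(unname(v), rep(1 / (1 - 0.64), 2), tolerance = 1e-9)

  # orthogonal pair
  rec2 <- data.frame(a = x1c, b = zperp)
  expect_equal(unname(vif(rec2, c("a", "b"))), c(1, 1), tolerance = 1e-9)

  # duplicated term: infinite VIF, not an error
  rec3 <- data.frame(a = x1c, b = x1c)
  expect_true(all(is.infinite(vif(rec3, c("a", "b")))))
})

test_that("interaction centering follows its contract", {
  sp <- cohort_sim_spec(n = 500, residual_sd = 3, seed = 36L)
  co <- generate_cohort(sp, "vat")
  terms <- c("obesity", "vat_otsu_cm2", "obesity:vat_otsu_cm2")

  # the centered product column is literally (dummy - mean) * area
  Xc <- slicefat:::build_design(co, terms, center = TRUE)
  expect_equal(Xc[, "obesity:vat_otsu_cm2"],
               (co$obesity - mean(co$obesity)) * co$vat_otsu_cm2)
  # main-effect columns themselves are left uncentered
  expect_equal(Xc[, "obesity"], as.numeric(co$obesity))

  # when the partner main effect (the area) is among the other columns,
  # the centered product spans the same space as the raw one, so the
  # dummy's VIF is invariant: centering is a reparameterization there
  raw <- vif(co, terms, center_interactions = FALSE)
  cen <- vif(co, terms, center_interactions = TRUE)
  expect_equal(cen[["obesity"]], raw[["obesity"]], tolerance = 1e-9)
})

test_that("Bland-Altman limits follow the mean ± 1.96 SD definition", {
  x <- c(1, 2, 3, 4, 5)
  same <- bland_altman(x, x)
  expect_equal(unlist(same[c("mean_diff", "loa_lower", "loa_upper")]),
               c(mean_diff = 0, loa_lower = 0, loa_upper = 0))

  off <- bland_altman(x + 3, x)
  expect_equal(unlist(off[c("mean_diff", "loa_lower", "loa_upper")]),
               c(mean_diff = 3, loa_lower = 3, loa_upper = 3))

  set.seed(37)
  d <- rnorm(500, 2, 4)
  ba <- bland_altman(d, rep(0, 500))
  expect_equal(ba$loa_upper - ba$mean_diff, 1.96 * sd(d))
  expect_equal(ba$mean_diff - ba$loa_lower, 1.96 * sd(d))
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("BCa bootstrap is deterministic and degenerates gracefully", {
  x <- rnorm(40)
  a <- bootstrap_bca(x, mean, n_resamples = 500, seed = 9L)
  b <- bootstrap_bca(x, mean, n_resamples = 500, seed = 9L)
  expect_identical(a, b)

  expect_warning(cz <- bootstrap_bca(rep(3, 20), mean, n_resamples = 100,
                                     seed = 1L),
                 "degenerate")
  expect_equal(cz$lower, cz$upper)
  expect_equal(cz$lower, 3)
})

test_that("cross-validation reaches zero error in the noiseless limit", {
  sp <- cohort_sim_spec(n = 40, residual_sd = 0, seed = 38L)
  co <- generate_cohort(sp, "vat")
  cv <- cross_validate(co, "vat_manual_cm2", c("vat_otsu_cm2", "obesity"),
                       scheme = "loocv")
  expect_lt(cv$rmse_cm2, 1e-6)
  expect_gte(cv$rmse_cm2, cv$mae_cm2 - 1e-12)
})

test_that("repeated k-fold summaries are reproducible given the seed", {
  sp <- cohort_sim_spec(n = 68, residual_sd = 11.5, seed = 39L)
  co <- generate_cohort(sp, "vat")
  cv1 <- cross_validate(co, "vat_manual_cm2", c("vat_otsu_cm2", "obesity"),
                        scheme = "kfold", repeats = 10, seed = 4L)
  cv2 <- cross_validate(co, "vat_manual_cm2", c("vat_otsu_cm2", "obesity"),
                        scheme = "kfold", repeats = 10, seed = 4L)
  expect_identical(cv1, cv2)
})

test_that("LOOCV R² tracks the in-sample R² at the cohort's noise level", {
  # cohorts at the study's size and residual scale: the LOOCV estimate
  # should be nearly unbiased for the in-sample fit
  diffs <- vapply(1:60, function(r) {
    sp <- cohort_sim_spec(n = 68, residual_sd = 11.5, seed = 6000L + r)
    co <- generate_cohort(sp, "vat")
    fit <- fit_wls(co, "vat_manual_cm2", c("vat_otsu_cm2", "obesity"),
                   weighting = "none")
    cv <- cross_validate(co, "vat_manual_cm2", c("vat_otsu_cm2", "obesity"),
                         scheme = "loocv", weighting = "none")
    cv$r_squared - fit$r_squared
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.02)
})

test_that("shipped model files reproduce the printed corrections", {
  for (f in c("vat_eq1.json", "sat_eq2.json")) {
    model <- read_calibration_model(
      system.file("extdata", f, package = "slicefat"))
    rec <- data.frame(vat_otsu_cm2 = c(0, 100), sat_otsu_cm2 = c(0, 100),
                      obesity = c(0, 1),
                      age_category = c("child", "adult"))
    got <- predict_from_terms(model, rec)
    want <- if (f == "vat_eq1.json") {
      apply_vat_correction(c(0, 100), c(0, 1))
    } else {
      apply_sat_correction(c(0, 100), c(0, 1))
    }
    expect_equal(got, want)
  }
})

test_that("calibration models serialize and round-trip through JSON", {
  sp <- cohort_sim_spec(n = 50, residual_sd = 3, seed = 41L)
  co <- generate_cohort(sp, "vat")
  fit <- fit_wls(co, "vat_manual_cm2", c("vat_otsu_cm2", "obesity"))
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration_model(fit, f)
  back <- read_calibration_model(f)
  expect_equal(back$terms, fit$terms)
  expect_equal(predict_from_terms(back, co), predict(fit, co))
})
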