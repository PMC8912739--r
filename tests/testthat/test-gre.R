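test_that("GRE point estimate is the coefficient ratio", {
  expect_equal(gre_point(log(1.74), log(1.74) / 42.3), 42.3)
  expect_equal(gre_point(0, 0.013), 0)
  # exact inverse identity
  set.seed(41)
  for (i in 1:20) {
    bE <- rnorm(1); bG <- rnorm(1, 0.013, 0.005)
    if (bG == 0) next
    expect_equal(gre_point(bE, bG) * bG, bE, tolerance = 1e-12)
  }
  expect_error(gre_point(0.5, 0), "undefined|zero")
})

test_that("delta interval is symmetric with the closed-form width", {
  # exactly known denominator: width collapses to 2 z sqrt(var_E)/|beta_G|
  bG <- 0.013
  ci <- gre_ci_delta(0.55, bG, var_E = 0.04, var_G = 0, cov_EG = 0)
  z <- qnorm(0.975)
  expect_equal(ci$ci_high - ci$ci_low, 2 * z * sqrt(0.04) / abs(bG),
               tolerance = 1e-12)

  # null numerator: symmetric about 0 with SE = sqrt(var_E)/|beta_G|
  ci0 <- gre_ci_delta(0, bG, var_E = 0.04, var_G = 1e-6, cov_EG = 0)
  expect_equal(ci0$gre, 0)
  expect_equal(ci0$se, sqrt(0.04) / bG, tolerance = 1e-6)
  expect_equal(ci0$ci_low, -ci0$ci_high, tolerance = 1e-9)

  # symmetry about the point estimate on arbitrary inputs
  set.seed(42)
  for (i in 1:50) {
    bE <- rnorm(1, 0.4, 0.3); bG2 <- rnorm(1, 0.013, 0.003)
    vE <- runif(1, 1e-4, 0.1); vG <- runif(1, 1e-8, 1e-5)
    cEG <- runif(1, -1, 1) * sqrt(vE * vG)
    ci <- gre_ci_delta(bE, bG2, vE, vG, cEG)
    expect_lt(abs((ci$gre - ci$ci_low) - (ci$ci_high - ci$gre)), 1e-9)
  }
  expect_error(gre_ci_delta(1, 0.01, var_E = -1, var_G = 1), "positive")
})

test_that("delta and Fieller intervals match a parametric bootstrap", {
  # strong denominator (|beta_G|/SE > 5): all three methods agree; the
  # first-order delta width needs t of about 7 or more, the exact-quadratic
  # Fieller set tracks the bootstrap at any t
  set.seed(43)
  for (t in c(8, 12)) {
    bE <- 0.55; vE <- 0.02
    bG <- 0.013; vG <- (bG / t)^2
    cEG <- 0.3 * sqrt(vE * vG)
    delta <- gre_ci_delta(bE, bG, vE, vG, cEG)
    fieller <- gre_ci_fieller(bE, bG, vE, vG, cEG)
    boot <- gre_ci_boot(bE, bG, vE, vG, cEG, draws = 10000)
    expect_true(fieller$bounded)
    w_b <- boot$ci_high - boot$ci_low
    expect_lt(abs((delta$ci_high - delta$ci_low) - w_b) / w_b, 0.05)
    expect_lt(abs((fieller$ci_high - fieller$ci_low) - w_b) / w_b, 0.05)
  }
  f6 <- gre_ci_fieller(0.55, 0.013, 0.02, (0.013 / 6)^2, 0)
  b6 <- gre_ci_boot(0.55, 0.013, 0.02, (0.013 / 6)^2, 0, draws = 10000)
  expect_lt(abs((f6$ci_high - f6$ci_low) - (b6$ci_high - b6$ci_low)) /
            (b6$ci_high - b6$ci_low), 0.05)
})

test_that("Fieller set degrades gracefully for a weak denominator", {
  # very strong denominator: Fieller collapses onto delta
  d <- gre_ci_delta(0.5, 0.013, 1e-3, (0.013 / 50)^2, 0)
  f <- gre_ci_fieller(0.5, 0.013, 1e-3, (0.013 / 50)^2, 0)
  expect_equal(f$ci_low, d$ci_low, tolerance = 5e-3)
  expect_equal(f$ci_high, d$ci_high, tolerance = 5e-3)

  # denominator not significant at the level: unbounded set flagged
  f2 <- gre_ci_fieller(0.5, 0.013, 1e-3, var_G = 0.013^2, cov_EG = 0)
  expect_false(f2$bounded)
})

test_that("model-derived GREs are invariant to the PRS percentile coding", {
  co <- shared_data()$cohort
  co$prs_per10 <- co$prs_percentile / 10
  f1 <- gre_fit(cc_status ~ exposure + prs_percentile + age + sex, co)
  f2 <- gre_fit(cc_status ~ exposure + prs_per10 + age + sex, co,
                prs = "prs_per10", prs_scale = "per10")
  for (col in c("gre", "ci_low", "ci_high", "beta_G"))
    expect_equal(f1$gre[[col]], f2$gre[[col]], tolerance = 1e-8)
  # arbitrary rescaling of the percentile axis leaves the GRE unchanged
  co$prs_x <- co$prs_percentile * 3.7
  f3 <- gre_from_model(
    fit_logistic(cc_status ~ exposure + prs_x + age + sex, co),
    prs = "prs_x")
  expect_equal(f3$gre / 3.7, f1$gre$gre, tolerance = 1e-8)
})

test_that("gre_fit demands a continuous PRS term and reports contrasts", {
  co <- shared_data()$cohort
  expect_error(
    gre_from_model(
      fit_logistic(cc_status ~ exposure + prs_category + age + sex, co),
      prs = "prs_percentile"),
    "continuous")
  m <- gre_fit(cc_status ~ exposure + prs_percentile + age + sex, co)
  expect_s3_class(m, "gre_fit")
  expect_equal(m$gre$contrast, exposure_levels()[-1])
  expect_equal(sign(m$gre$gre), sign(m$gre$beta_E) * sign(m$gre$beta_G))
  expect_true(all(m$gre$ci_low <= m$gre$gre & m$gre$gre <= m$gre$ci_high))
  # methods behave
  expect_equal(coef(m), coef(m$fit))
  expect_equal(dim(confint(m, "gre")), c(3, 2))
  expect_length(residuals(m), m$fit$n_used)
  expect_equal(nrow(simulate(m, nsim = 2, seed = 1)), m$fit$n_used)
  expect_output(print(summary(m)), "Coefficients")
})

test_that("GRE recovery: estimates centre on the simulated truth", {
  cfg <- sim_config(n_cases = 4000, n_controls = 4000, n_loci = 60, seed = 44)
  dat <- simulate_cohort(cfg)
  co <- add_prs(dat$cohort, dat$dosages, dat$panel)
  m <- gre_fit(reformulate(c("exposure", "prs_percentile", "age", "sex",
                             default_covariates()$name),
                           response = "cc_status"), co)
  truth <- cfg$beta_exposure[3] / cfg$beta_prs  # about 42 percentiles
  row <- m$gre[m$gre$contrast == "gt1_day", ]
  expect_true(row$ci_low <= truth && truth <= row$ci_high)
})
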