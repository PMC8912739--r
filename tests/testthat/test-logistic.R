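test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  d <- data.frame(y = rep(c(1, 1, 0, 0), c(30, 10, 10, 30)),
                  x = rep(c(1, 0, 1, 0), c(30, 10, 10, 30)))
  fit <- fit_logistic(y ~ x, d)
  # cross-product oracle: 30*30 / (10*10) = 9
  expect_equal(unname(exp(coef(fit)["x"])), 9, tolerance = 1e-6)
  ot <- or_table(fit)
  expect_true(ot$ci_low <= ot$or && ot$or <= ot$ci_high)
  expect_equal(fit$n_used, 80)
  expect_equal(fit$n_dropped, 0)
})

test_that("covariance is symmetric PSD and Wald CIs bracket the OR", {
  co <- shared_data()$cohort
  fit <- fit_logistic(cc_status ~ exposure + prs_percentile + age + sex, co)
  V <- vcov(fit)
  expect_lt(max(abs(V - t(V))), 1e-10)
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  ot <- or_table(fit)
  expect_true(all(ot$ci_low <= ot$or & ot$or <= ot$ci_high))
  expect_equal(unname(AIC(fit)),
               2 * length(coef(fit)) - 2 * as.numeric(logLik(fit)))
})

test_that("degenerate designs raise named diagnostics", {
  set.seed(31)
  x <- rnorm(60)
  sep <- data.frame(y = as.integer(x > 0), x = x)
  expect_error(suppressWarnings(fit_logistic(y ~ x, sep)),
               "separation|converge")
  d <- data.frame(y = rbinom(100, 1, 0.5), a = rnorm(100))
  d$b <- d$a
  expect_error(suppressWarnings(fit_logistic(y ~ a + b, d)), "aliased.*b")
  expect_error(fit_logistic(y ~ a, data.frame(y = rep(2, 30), a = rnorm(30))),
               "binary")
  expect_error(fit_logistic(y ~ a, data.frame(y = rep(c(0, 1), length.out = 11),
                                              a = rnorm(11))),
               "too few")
})

test_that("complete-case bookkeeping adds up", {
  co <- shared_data()$cohort
  co$age[1:37] <- NA
  fit <- fit_logistic(cc_status ~ exposure + age + sex, co)
  expect_equal(fit$n_used + fit$n_dropped, nrow(co))
  expect_equal(fit$n_dropped, 37)
})

test_that("stepwise AIC keeps forced terms and finds strong candidates", {
  set.seed(32)
  n <- 5000
  d <- data.frame(age = rnorm(n, 70, 8), sex = rbinom(n, 1, 0.5),
                  strong = rbinom(n, 1, 0.3), noise1 = rbinom(n, 1, 0.4),
                  noise2 = rnorm(n))
  d$y <- draw_logistic(cbind(d$strong), 1.0, intercept = -1)
  sel <- stepwise_aic(d, "y", forced = c("age", "sex"),
                      candidates = c("strong", "noise1", "noise2"))
  expect_true("strong" %in% sel$selected)
  expect_true(all(c("age", "sex") %in%
                  attr(terms(sel$model$formula), "term.labels")))

  # zero candidates: the forced-only model comes back
  sel0 <- stepwise_aic(d, "y", forced = c("age", "sex"),
                       candidates = character(0))
  expect_length(sel0$selected, 0)
  expect_error(stepwise_aic(d, "y", forced = "age", candidates = "age"),
               "disjoint")
})

test_that("Wald and LRT interaction tests agree asymptotically", {
  set.seed(33)
  n <- 20000
  e <- factor(sample(exposure_levels(), n, replace = TRUE,
                     prob = c(0.12, 0.61, 0.24, 0.03)),
              levels = exposure_levels())
  g <- runif(n, 0, 100)
  X <- cbind(model.matrix(~e)[, -1], g)
  d <- data.frame(y = draw_logistic(X, c(0.2, 0.35, 0.55, 0.013),
                                    intercept = -1.5),
                  e = e, g = g)
  lrt <- interaction_test(y ~ e + g, d, pair = c("e", "g"), method = "lrt")
  wald <- interaction_test(y ~ e + g, d, pair = c("e", "g"), method = "wald")
  expect_equal(lrt$df, 3)
  expect_equal(wald$df, 3)
  expect_lt(abs(wald$p_value - lrt$p_value) / lrt$p_value, 0.10)

  # 4-level exposure x 5-level PRS category: 12 product coefficients
  co <- shared_data()$cohort
  lrt12 <- interaction_test(cc_status ~ exposure + prs_category + age + sex,
                            co, pair = c("exposure", "prs_category"))
  expect_equal(lrt12$df, 12)
  expect_gt(lrt12$p_value, 0)
  expect_lte(lrt12$p_value, 1)

  # empty cross cell is reported by name
  co2 <- co[!(co$exposure == "gt1_day" & co$prs_category == "very_low"), ]
  expect_error(
    interaction_test(cc_status ~ exposure + prs_category, co2,
                     pair = c("exposure", "prs_category")),
    "gt1_day:very_low")
})

test_that("joint-effect grid is anchored at the uniform reference cell", {
  co <- shared_data()$cohort
  grid <- joint_effects(co, covariates = c("age", "sex"))
  expect_equal(nrow(grid), 20)
  ref <- grid[grid$prs_category == "medium" & grid$exposure == "le1_wk", ]
  expect_equal(ref$or, 1)
  expect_true(is.na(ref$ci_low))
  expect_true(all(grid$n_cases + grid$n_controls > 0))
  # removing one cell triggers a named error
  co3 <- co[!(co$exposure == "gt1_day" & co$prs_category == "very_low"), ]
  expect_error(joint_effects(co3, covariates = c("age", "sex")),
               "very_low:gt1_day")
})

test_that("without interaction the joint cell OR factorises", {
  set.seed(34)
  n <- 30000
  g <- factor(sample(c("medium", "very_high"), n, TRUE),
              levels = c("medium", "very_high"))
  e <- factor(sample(c("le1_wk", "gt1_day"), n, TRUE),
              levels = c("le1_wk", "gt1_day"))
  bg <- 0.8; be <- 0.55
  y <- draw_logistic(cbind(g == "very_high", e == "gt1_day"), c(bg, be),
                     intercept = -1.2)
  d <- data.frame(cc_status = y, prs_category = g, exposure = e)
  grid <- joint_effects(d, ref = c(prs = "medium", exposure = "le1_wk"))
  cell <- grid[grid$prs_category == "very_high" & grid$exposure == "gt1_day", ]
  se_cell <- (log(cell$ci_high) - log(cell$ci_low)) / (2 * qnorm(0.975))
  expect_lt(abs(log(cell$or) - (bg + be)), 3 * se_cell)
})

test_that("descriptive table matches the closed-form Pearson statistic", {
  d <- data.frame(
    cc_status = rep(c(1, 0), each = 100),
    trait = c(rep(c("yes", "no"), c(50, 50)), rep(c("yes", "no"), c(25, 75))),
    onelevel = "same", age = rnorm(200, 70, 5))
  tab <- descriptive_table(d, vars = c("trait", "onelevel", "age"),
                           matching_factors = "age")
  # hand-computed Pearson chi-square for (50,50)/(25,75): 200*(50*75-50*25)^2
  # / (100*100*75*125) = 13.333..., p = pchisq upper tail
  chi_oracle <- 200 * (50 * 75 - 50 * 25)^2 / (100 * 100 * 75 * 125)
  p_oracle <- pchisq(chi_oracle, 1, lower.tail = FALSE)
  p_got <- tab$p_value[tab$characteristic == "trait" & !is.na(tab$p_value)]
  expect_equal(p_got, p_oracle, tolerance = 1e-12)
  expect_match(tab$note[tab$characteristic == "onelevel"][1], "skipped")
  expect_match(tab$note[tab$characteristic == "age"][1], "matching")

  # a strongly shifted 4-level intake distribution is flagged at p < 1e-4
  intake <- matrix(c(387, 2925, 1358, 222, 469, 2444, 979, 124), ncol = 2)
  expect_lt(suppressWarnings(chisq.test(intake, correct = FALSE)$p.value),
            1e-4)
  d2 <- data.frame(
    cc_status = rep(c(1, 0), c(4892, 4016)),
    intake = c(rep(exposure_levels(), c(387, 2925, 1358, 222)),
               rep(exposure_levels(), c(469, 2444, 979, 124))))
  tab2 <- descriptive_table(d2, vars = "intake")
  expect_lt(tab2$p_value[1], 1e-4)
})

test_that("exposure OR confidence intervals attain nominal coverage", {
  set.seed(35)
  n <- 2000; reps <- 200; b <- 0.4
  hits <- 0
  for (r in seq_len(reps)) {
    x <- rbinom(n, 1, 0.3)
    d <- data.frame(y = draw_logistic(cbind(x), b, intercept = -0.8), x = x)
    ot <- or_table(fit_logistic(y ~ x, d))
    hits <- hits + (ot$ci_low <= exp(b) && exp(b) <= ot$ci_high)
  }
  expect_gte(hits / reps, 0.91)
  expect_lte(hits / reps, 0.99)
})
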