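#' Genetic risk equivalent point estimate
#'
#' The GRE translates an exposure effect into PRS-percentile units: it is the
#' ratio `beta_E / beta_G` of the exposure log odds ratio to the log odds
#' ratio per single PRS percentile, both taken from the same logistic model.
#' A GRE of 20 means the exposure contrast carries the same risk as having a
#' PRS 20 percentiles higher.
#'
#' @param beta_E Exposure log odds ratio(s) (vectorised).
#' @param beta_G Log odds ratio per single PRS percentile (nonzero scalar).
#' @return GRE value(s) in PRS percentiles.
#' @examples
#' gre_point(log(1.74), log(1.74) / 42.3)  # 42.3
#' @export
gre_point <- function(beta_E, beta_G) {
  stopifnot(length(beta_G) == 1, is.finite(beta_G))
  if (beta_G == 0)
    stop("beta_G is zero: the GRE is undefined for a non-informative PRS")
  beta_E / beta_G
}

#' Delta-method confidence interval for a GRE
#'
#' First-order Taylor (delta-method) interval for the coefficient ratio
#' `beta_E / beta_G`:
#' `SE^2 = var_E/beta_G^2 + beta_E^2 var_G/beta_G^4 - 2 beta_E cov_EG/beta_G^3`,
#' with normal critical values. The interval is symmetric about the point
#' estimate by construction.
#'
#' @param beta_E,beta_G Coefficients (see [gre_point()]).
#' @param var_E,var_G Their variances (positive).
#' @param cov_EG Their covariance (default 0).
#' @param level Confidence level (default 0.95).
#' @return List with `gre`, `se`, `ci_low`, `ci_high`.
#' @export
gre_ci_delta <- function(beta_E, beta_G, var_E, var_G, cov_EG = 0,
                         level = 0.95) {
  if (var_E <= 0 || var_G < 0) stop("variances must be positive")
  g <- gre_point(beta_E, beta_G)
  se2 <- var_E / beta_G^2 + beta_E^2 * var_G / beta_G^4 -
    2 * beta_E * cov_EG / beta_G^3
  if (se2 < 0)
    stop("negative delta-method variance (", format(se2),
         "); covariance inputs are inconsistent")
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(se2)
  list(gre = g, se = se, ci_low = g - z * se, ci_high = g + z * se)
}

#' Fieller confidence set for a GRE
#'
#' Exact-quadratic (Fieller) confidence set for the coefficient ratio. When
#' the denominator coefficient is significantly nonzero at the chosen level
#' the set is a finite interval close to the delta interval; otherwise it is
#' the complement of an interval or the whole real line, returned with
#' `bounded = FALSE`.
#'
#' @inheritParams gre_ci_delta
#' @return List with `gre`, `ci_low`, `ci_high`, `bounded` and `type`
#'   (`"interval"`, `"complement"` or `"all_reals"`; limits are `NA` for the
#'   unbounded whole-line case, and for a complement set they delimit the
#'   excluded interval).
#' @export
gre_ci_fieller <- function(beta_E, beta_G, var_E, var_G, cov_EG = 0,
                           level = 0.95) {
  if (var_E <= 0 || var_G <= 0) stop("variances must be positive")
  g <- gre_point(beta_E, beta_G)
  z2 <- qnorm(1 - (1 - level) / 2)^2
  a <- beta_G^2 - z2 * var_G
  b <- -2 * (beta_E * beta_G - z2 * cov_EG)
  cc <- beta_E^2 - z2 * var_E
  disc <- b^2 - 4 * a * cc
  if (a > 0) {
    roots <- sort((-b + c(-1, 1) * sqrt(max(disc, 0))) / (2 * a))
    list(gre = g, ci_low = roots[1], ci_high = roots[2],
         bounded = TRUE, type = "interval")
  } else if (disc > 0) {
    roots <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
    list(gre = g, ci_low = roots[1], ci_high = roots[2],
         bounded = FALSE, type = "complement")
  } else {
    list(gre = g, ci_low = NA_real_, ci_high = NA_real_,
         bounded = FALSE, type = "all_reals")
  }
}

#' Parametric-bootstrap confidence interval for a GRE
#'
#' Draws `(beta_E, beta_G)` pairs from their asymptotic bivariate normal
#' distribution and takes percentile limits of the simulated ratios. Used as
#' an independent cross-check of the delta and Fieller intervals; percentile
#' limits can be erratic when the denominator distribution crosses zero.
#'
#' @inheritParams gre_ci_delta
#' @param draws Number of bootstrap draws.
#' @return List with `gre`, `ci_low`, `ci_high`, `draws`.
#' @export
gre_ci_boot <- function(beta_E, beta_G, var_E, var_G, cov_EG = 0,
                        level = 0.95, draws = 10000) {
  if (var_E <= 0 || var_G <= 0) stop("variances must be positive")
  g <- gre_point(beta_E, beta_G)
  rho2 <- cov_EG^2 / (var_E * var_G)
  if (rho2 > 1) stop("covariance implies |correlation| > 1")
  e <- rnorm(draws, 0, sqrt(var_E))
  ## conditional normal draw for the denominator given the numerator
  gmean <- beta_G + cov_EG / var_E * e
  gsd <- sqrt(var_G * (1 - rho2))
  gg <- rnorm(draws, gmean, gsd)
  r <- (beta_E + e) / gg
  qs <- quantile(r, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
  list(gre = g, ci_low = qs[1], ci_high = qs[2], draws = draws)
}

#' GREs for every exposure contrast of a fitted logistic model
#'
#' Extracts the exposure-contrast coefficients and the continuous PRS
#' coefficient (with their covariances) from a fitted model and returns one
#' GRE per non-reference exposure level. Results are always expressed per
#' single PRS percentile regardless of the model's PRS coding.
#'
#' @param fit A fitted logistic model (from [fit_logistic()] or [gre_fit()]'s
#'   internal fit) whose terms include the exposure factor and a continuous
#'   PRS term.
#' @param exposure Name of the exposure factor in the model.
#' @param prs Name of the continuous PRS term (its coefficient name in the
#'   model).
#' @param prs_scale `"percentile"` if the PRS column is in single percentiles,
#'   `"per10"` if it is percentile/10 (log-OR per 10 percentiles).
#' @param method CI method: `"delta"` (default), `"fieller"` or
#'   `"bootstrap"`.
#' @param level Confidence level.
#' @param boot_draws Draws for `method = "bootstrap"`.
#' @return Data.frame of class `gre_table`: one row per contrast with
#'   `contrast`, `or`, `or_low`, `or_high`, `beta_E`, `beta_G`, `cov_EG`,
#'   `gre`, `ci_low`, `ci_high`, `bounded`, `method`.
#' @export
gre_from_model <- function(fit, exposure = "exposure",
                           prs = "prs_percentile",
                           prs_scale = c("percentile", "per10"),
                           method = c("delta", "fieller", "bootstrap"),
                           level = 0.95, boot_draws = 10000) {
  prs_scale <- match.arg(prs_scale)
  method <- match.arg(method)
  b <- coef(fit); V <- vcov(fit)
  if (!prs %in% names(b))
    stop("continuous PRS term '", prs, "' not found among model ",
         "coefficients; the GRE requires a continuous PRS coding")
  contrasts <- grep(paste0("^", exposure), names(b), value = TRUE)
  contrasts <- setdiff(contrasts, prs)
  if (!length(contrasts))
    stop("no exposure contrasts matching '", exposure, "' in the model")
  s <- if (prs_scale == "per10") 10 else 1
  beta_G <- unname(b[prs]) / s
  var_G <- V[prs, prs] / s^2
  rows <- lapply(contrasts, function(tm) {
    beta_E <- unname(b[tm]); var_E <- V[tm, tm]
    cov_EG <- V[tm, prs] / s
    ci <- switch(method,
      delta = gre_ci_delta(beta_E, beta_G, var_E, var_G, cov_EG, level),
      fieller = gre_ci_fieller(beta_E, beta_G, var_E, var_G, cov_EG, level),
      bootstrap = gre_ci_boot(beta_E, beta_G, var_E, var_G, cov_EG, level,
                              draws = boot_draws))
    z <- qnorm(1 - (1 - level) / 2)
    data.frame(
      contrast = sub(paste0("^", exposure), "", tm),
      or = exp(beta_E),
      or_low = exp(beta_E - z * sqrt(var_E)),
      or_high = exp(beta_E + z * sqrt(var_E)),
      beta_E = beta_E, beta_G = beta_G, cov_EG = cov_EG,
      gre = ci$gre, ci_low = ci$ci_low, ci_high = ci$ci_high,
      bounded = if (is.null(ci$bounded)) TRUE else ci$bounded,
      method = method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gre_table", class(out))
  out
}

#' @export
print.gre_table <- function(x, digits = 3, ...) {
  y <- data.frame(
    contrast = x$contrast,
    `OR (95% CI)` = sprintf("%.2f (%.2f, %.2f)", x$or, x$or_low, x$or_high),
    `GRE (95% CI)` = ifelse(
      x$bounded,
      sprintf("%.1f (%.1f, %.1f)", x$gre, x$ci_low, x$ci_high),
      sprintf("%.1f (unbounded %s set)", x$gre, x$method)),
    check.names = FALSE, stringsAsFactors = FALSE)
  print(y, right = FALSE, row.names = FALSE)
  invisible(x)
}

#' Fit the GRE model: adjusted logistic regression with per-contrast GREs
#'
#' The package's central fitting function. Fits a logistic model of
#' case-control status on a categorical exposure, a continuous PRS term and
#' any adjustment covariates, and derives the genetic risk equivalent (the
#' PRS-percentile difference matching each exposure contrast's effect) with
#' confidence intervals from the joint coefficient covariance.
#'
#' @param formula Logistic model formula; must contain `exposure` and `prs`
#'   as main effects.
#' @param data Cohort data.frame (one row per subject).
#' @param exposure Name of the exposure factor (its first level is the
#'   reference; the reference GRE is reported as absent, not 0).
#' @param prs Name of the continuous PRS column used in the formula.
#' @param prs_scale `"percentile"` (default) or `"per10"` -- the units the
#'   `prs` column is coded in. Reported GREs are always per single
#'   percentile, so refitting with either coding yields identical results.
#' @param ci_method `"delta"` (default), `"fieller"` or `"bootstrap"`.
#' @param level Confidence level for ORs and GREs.
#' @param boot_draws Bootstrap draws when `ci_method = "bootstrap"`.
#' @return Object of class `gre_fit` with components `fit` (the underlying
#'   [fit_logistic()] model), `gre` (a `gre_table`), `or` (exposure OR
#'   table), plus the call and settings. Standard methods are provided:
#'   `print`, `summary`, `coef`, `vcov`, `confint`, `logLik`, `predict`,
#'   `residuals`, `simulate` and `plot`.
#' @examples
#' dat <- simulate_cohort(sim_config(n_cases = 400, n_controls = 400,
#'                                   n_loci = 30, seed = 11))
#' cohort <- add_prs(dat$cohort, dat$dosages, dat$panel)
#' m <- gre_fit(cc_status ~ exposure + prs_percentile + age + sex,
#'              data = cohort)
#' m
#' @export
gre_fit <- function(formula, data, exposure = "exposure",
                    prs = "prs_percentile",
                    prs_scale = c("percentile", "per10"),
                    ci_method = c("delta", "fieller", "bootstrap"),
                    level = 0.95, boot_draws = 10000) {
  prs_scale <- match.arg(prs_scale)
  ci_method <- match.arg(ci_method)
  labs <- attr(terms(formula), "term.labels")
  if (!exposure %in% labs || !prs %in% labs)
    stop("formula must include '", exposure, "' and '", prs,
         "' as main effects")
  fit <- fit_logistic(formula, data)
  gt <- gre_from_model(fit, exposure = exposure, prs = prs,
                       prs_scale = prs_scale, method = ci_method,
                       level = level, boot_draws = boot_draws)
  structure(list(fit = fit, gre = gt,
                 or = or_table(fit, level = level),
                 exposure = exposure, prs = prs, prs_scale = prs_scale,
                 ci_method = ci_method, level = level,
                 call = match.call()),
            class = "gre_fit")
}

#' @export
print.gre_fit <- function(x, ...) {
  cat("Genetic-risk-equivalent model\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("n =", x$fit$n_used, "complete cases (", x$fit$n_dropped,
      "dropped )\n\n")
  cat("Exposure contrasts vs reference ('",
      levels(x$fit$model[[x$exposure]])[1], "'):\n", sep = "")
  print(x$gre)
  invisible(x)
}

#' @export
summary.gre_fit <- function(object, ...) {
  structure(list(gre_fit = object,
                 coefficients = summary(object$fit)$coefficients,
                 aic = AIC(object$fit),
                 loglik = as.numeric(logLik(object$fit))),
            class = "summary.gre_fit")
}

#' @export
print.summary.gre_fit <- function(x, ...) {
  print(x$gre_fit)
  cat("\nCoefficients:\n")
  stats::printCoefmat(x$coefficients, signif.stars = FALSE)
  cat("\nlog-likelihood:", format(x$loglik), "  AIC:", format(x$aic), "\n")
  invisible(x)
}

#' @export
coef.gre_fit <- function(object, ...) coef(object$fit)

#' @export
vcov.gre_fit <- function(object, ...) vcov(object$fit)

#' @export
logLik.gre_fit <- function(object, ...) logLik(object$fit)

#' Confidence intervals from a GRE model
#'
#' @param object A [gre_fit()] object.
#' @param parm `"gre"` (default) for per-contrast GRE intervals, or `"coef"`
#'   for Wald intervals on the logistic coefficients.
#' @param level Confidence level.
#' @param ... Unused.
#' @export
confint.gre_fit <- function(object, parm = c("gre", "coef"),
                            level = 0.95, ...) {
  parm <- match.arg(parm)
  if (parm == "gre") {
    gt <- gre_from_model(object$fit, exposure = object$exposure,
                         prs = object$prs, prs_scale = object$prs_scale,
                         method = object$ci_method, level = level)
    out <- as.matrix(gt[, c("ci_low", "ci_high")])
    rownames(out) <- gt$contrast
    return(out)
  }
  b <- coef(object$fit); se <- sqrt(diag(vcov(object$fit)))
  z <- qnorm(1 - (1 - level) / 2)
  cbind(lower = b - z * se, upper = b + z * se)
}

#' @export
predict.gre_fit <- function(object, ...) predict(object$fit, ...)

#' @export
residuals.gre_fit <- function(object, ...) residuals(object$fit, ...)

#' @export
simulate.gre_fit <- function(object, nsim = 1, seed = NULL, ...)
  simulate(object$fit, nsim = nsim, seed = seed, ...)

#' Forest-style plot of the fitted GREs
#'
#' @param x A [gre_fit()] object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gre_fit <- function(x, ...) {
  gt <- x$gre
  k <- nrow(gt)
  xlim <- range(c(0, gt$ci_low, gt$ci_high), na.rm = TRUE)
  plot(NA, xlim = xlim, ylim = c(0.5, k + 0.5), yaxt = "n",
       xlab = "GRE (PRS percentiles)", ylab = "",
       main = "Genetic risk equivalents by exposure contrast", ...)
  axis(2, at = k:1, labels = gt$contrast, las = 1)
  segments(gt$ci_low, k:1, gt$ci_high, k:1)
  points(gt$gre, k:1, pch = 16)
  abline(v = 0, lty = 3)
  invisible(x)
}
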