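#' Fit an adjusted logistic model on complete cases
#'
#' A maximum-likelihood logistic fit (IRLS, observed-information covariance)
#' with the data-hygiene contract the rest of the package relies on: rows
#' missing any involved variable are dropped and counted, non-convergence and
#' (quasi-)separation raise explicit errors rather than returning unstable
#' estimates, and rank deficiency is reported with the names of the aliased
#' terms.
#'
#' @param formula Model formula; the response must be binary (0/1, logical or
#'   a two-level factor).
#' @param data Data.frame.
#' @param epsilon,maxit IRLS convergence tolerance and iteration cap.
#' @return A `glm` object of class `c("cc_logit", "glm", "lm")` with extra
#'   fields `n_used` and `n_dropped` (complete-case bookkeeping always
#'   satisfies `n_used + n_dropped == nrow(data)`).
#' @examples
#' d <- data.frame(y = rep(c(1, 1, 0, 0), c(30, 10, 10, 30)),
#'                 x = rep(c(1, 0, 1, 0), c(30, 10, 10, 30)))
#' exp(coef(fit_logistic(y ~ x, d))["x"])  # classical 2x2 OR = 9
#' @export
fit_logistic <- function(formula, data, epsilon = 1e-10, maxit = 100) {
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("variables not found in data: ", paste(missing_vars, collapse = ", "))
  cc <- complete.cases(data[vars])
  used <- data[cc, vars, drop = FALSE]
  y <- used[[all.vars(formula)[1]]]
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2) stop("outcome must be binary")
  } else if (!all(y %in% c(0, 1))) {
    stop("outcome must be binary (0/1)")
  }
  fit <- glm(formula, data = used, family = binomial(),
             control = list(epsilon = epsilon, maxit = maxit))
  if (nrow(used) < length(coef(fit)) + 10)
    stop("too few complete-case rows (", nrow(used), ") for ",
         length(coef(fit)), " parameters")
  if (!fit$converged)
    stop("logistic fit did not converge in ", maxit, " iterations")
  if (anyNA(coef(fit)))
    stop("rank-deficient design; aliased terms: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  ## quasi-separation: boundary fitted probabilities with exploding slopes
  eta <- abs(fit$linear.predictors)
  if (max(eta) > 15 && any(abs(coef(fit)[-1]) > 10))
    stop("(quasi-)separation detected: fitted probabilities at 0/1 with ",
         "diverging coefficients; inspect sparse covariate cells")
  fit$n_used <- nrow(used)
  fit$n_dropped <- nrow(data) - nrow(used)
  class(fit) <- c("cc_logit", class(fit))
  fit
}

#' Odds ratios with Wald confidence intervals from a fitted model
#'
#' @param fit A fitted logistic model ([fit_logistic()] or `glm`).
#' @param terms Optional character vector of coefficient names to keep
#'   (default: all but the intercept).
#' @param level Confidence level.
#' @return Data.frame with `term`, `beta`, `se`, `or`, `ci_low`, `ci_high`,
#'   `p_value`; always `ci_low <= or <= ci_high`.
#' @export
or_table <- function(fit, terms = NULL, level = 0.95) {
  b <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  keep <- if (is.null(terms)) setdiff(names(b), "(Intercept)") else terms
  bad <- setdiff(keep, names(b))
  if (length(bad)) stop("terms not in model: ", paste(bad, collapse = ", "))
  z <- qnorm(1 - (1 - level) / 2)
  data.frame(
    term = keep,
    beta = unname(b[keep]), se = unname(se[keep]),
    or = exp(unname(b[keep])),
    ci_low = exp(unname(b[keep] - z * se[keep])),
    ci_high = exp(unname(b[keep] + z * se[keep])),
    p_value = 2 * pnorm(-abs(unname(b[keep] / se[keep]))),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Forward-backward covariate selection by AIC
#'
#' Greedy bidirectional search over candidate covariates around a forced core
#' model: at each step every single-term addition and deletion is scored and
#' the move with the largest AIC drop is taken, stopping when no move lowers
#' the AIC. Forced terms (typically the matching factors) can never be
#' removed. Deterministic given the data. Candidate models that fail to
#' converge are skipped with a warning.
#'
#' @param data Data.frame.
#' @param outcome Name of the binary outcome column.
#' @param forced Character vector of term labels always kept in the model.
#' @param candidates Character vector of candidate term labels (disjoint from
#'   `forced`).
#' @return List of class `stepwise_aic`: `model` (the selected
#'   [fit_logistic()] fit on the common complete-case set), `selected`
#'   (candidate terms retained), `forced`, `aic`.
#' @export
stepwise_aic <- function(data, outcome, forced, candidates) {
  overlap <- intersect(forced, candidates)
  if (length(overlap))
    stop("candidates must be disjoint from forced terms: ",
         paste(overlap, collapse = ", "))
  vars <- unique(c(outcome, all.vars(reformulate(c(forced, candidates)))))
  cc <- complete.cases(data[vars])
  used <- data[cc, , drop = FALSE]
  lower <- reformulate(forced, response = outcome)
  upper <- reformulate(c(forced, candidates), response = outcome)
  base <- glm(lower, data = used, family = binomial())
  sel <- withCallingHandlers(
    MASS::stepAIC(base, scope = list(lower = lower, upper = upper),
                  direction = "both", trace = 0),
    warning = function(w) {
      warning("candidate model issue during stepwise search: ",
              conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  kept <- attr(terms(sel), "term.labels")
  if (!all(forced %in% kept))
    stop("internal error: a forced term was removed during selection")
  model <- fit_logistic(reformulate(kept, response = outcome), used)
  structure(list(model = model, selected = setdiff(kept, forced),
                 forced = forced, aic = AIC(model)),
            class = "stepwise_aic")
}

#' @export
print.stepwise_aic <- function(x, ...) {
  cat("AIC stepwise selection (forced:",
      paste(x$forced, collapse = " + "), ")\n")
  cat("selected candidates:",
      if (length(x$selected)) paste(x$selected, collapse = " + ")
      else "<none>", "\n")
  cat("AIC:", format(x$aic), "\n")
  invisible(x)
}

#' Multiplicative interaction test between an exposure and a modifier
#'
#' Adds the full block of cross-product terms between the two variables to a
#' main-effects logistic model and jointly tests the block: likelihood-ratio
#' test by default (chi-square with df = number of product coefficients, e.g.
#' 3 for a 4-level exposure by a continuous modifier, 12 for a 4-level by
#' 5-level pair), or a Wald test on the same block.
#'
#' @param formula Main-effects model formula containing both variables.
#' @param data Data.frame.
#' @param pair Character vector of length 2 naming the interacting variables.
#' @param method `"lrt"` (default) or `"wald"`.
#' @return List with `p_value`, `statistic`, `df`, `method`.
#' @export
interaction_test <- function(formula, data, pair,
                             method = c("lrt", "wald")) {
  method <- match.arg(method)
  stopifnot(length(pair) == 2)
  labs <- attr(terms(formula), "term.labels")
  if (!all(pair %in% labs))
    stop("both pair variables must appear as main effects in the formula")
  v1 <- data[[pair[1]]]; v2 <- data[[pair[2]]]
  if (is.factor(v1) && is.factor(v2)) {
    tab <- table(v1, v2)
    if (any(tab == 0)) {
      empty <- which(tab == 0, arr.ind = TRUE)
      stop("empty cross cells between ", pair[1], " and ", pair[2], ": ",
           paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]],
                 sep = ":", collapse = ", "))
    }
  }
  vars <- unique(c(all.vars(formula), pair))
  used <- data[complete.cases(data[vars]), , drop = FALSE]
  f1 <- update(formula,
               as.formula(paste(". ~ . +", pair[1], ":", pair[2])))
  fit0 <- fit_logistic(formula, used)
  fit1 <- fit_logistic(f1, used)
  df <- length(coef(fit1)) - length(coef(fit0))
  if (df < 1) stop("interaction block is empty")
  if (method == "lrt") {
    stat <- as.numeric(2 * (logLik(fit1) - logLik(fit0)))
  } else {
    inter_idx <- setdiff(names(coef(fit1)), names(coef(fit0)))
    b <- coef(fit1)[inter_idx]
    V <- vcov(fit1)[inter_idx, inter_idx, drop = FALSE]
    stat <- drop(t(b) %*% solve(V, b))
  }
  list(p_value = pchisq(stat, df, lower.tail = FALSE),
       statistic = unname(stat), df = df, method = method)
}

#' Joint-effect odds-ratio grid for exposure by PRS category
#'
#' Estimates one OR per (PRS category, exposure level) cell against a single
#' uniform reference cell (by default the medium-PRS, lowest-intake group),
#' from one adjusted logistic model with a 20-level cell factor.
#'
#' @param data Cohort table containing the two factors and any adjustment
#'   variables.
#' @param covariates Character vector of adjustment term labels (may be
#'   empty).
#' @param exposure,prs_cat Column names of the exposure and PRS-category
#'   factors.
#' @param outcome Binary outcome column name.
#' @param ref Named character vector: the reference cell.
#' @param level Confidence level.
#' @return Data.frame with one row per cell: `prs_category`, `exposure`,
#'   `n_cases`, `n_controls`, `or`, `ci_low`, `ci_high`; the reference cell
#'   has `or = 1` and `NA` limits.
#' @export
joint_effects <- function(data, covariates = character(),
                          exposure = "exposure", prs_cat = "prs_category",
                          outcome = "cc_status",
                          ref = c(prs = "medium", exposure = "le1_wk"),
                          level = 0.95) {
  vars <- unique(c(outcome, exposure, prs_cat,
                   if (length(covariates)) all.vars(reformulate(covariates))))
  used <- data[complete.cases(data[vars]), , drop = FALSE]
  g <- droplevels(used[[prs_cat]]); e <- droplevels(used[[exposure]])
  tab <- table(g, e)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    stop("empty joint cells: ",
         paste(rownames(tab)[empty[, 1]], colnames(tab)[empty[, 2]],
               sep = ":", collapse = ", "))
  }
  cell <- interaction(g, e, sep = ":", lex.order = FALSE)
  cell <- relevel(cell, ref = paste(ref[["prs"]], ref[["exposure"]], sep = ":"))
  used$.cell <- cell
  f <- reformulate(c(".cell", covariates), response = outcome)
  fit <- fit_logistic(f, used)
  ors <- or_table(fit, level = level)
  ors <- ors[startsWith(ors$term, ".cell"), ]
  ors$cell <- sub("^\\.cell", "", ors$term)

  grid <- expand.grid(prs_category = levels(g), exposure = levels(e),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$cell <- paste(grid$prs_category, grid$exposure, sep = ":")
  case_tab <- table(g[used[[outcome]] == 1], e[used[[outcome]] == 1])
  ctrl_tab <- table(g[used[[outcome]] == 0], e[used[[outcome]] == 0])
  grid$n_cases <- mapply(function(a, b) case_tab[a, b],
                         grid$prs_category, grid$exposure)
  grid$n_controls <- mapply(function(a, b) ctrl_tab[a, b],
                            grid$prs_category, grid$exposure)
  m <- match(grid$cell, ors$cell)
  grid$or <- ifelse(is.na(m), 1, ors$or[m])
  grid$ci_low <- ors$ci_low[m]
  grid$ci_high <- ors$ci_high[m]
  grid$cell <- NULL
  grid
}

#' Case-control descriptive table with chi-square tests
#'
#' Counts and percentages per level for each characteristic, by case-control
#' status, with a Pearson chi-square p-value on the complete-case
#' contingency table. Continuous characteristics are summarised as median
#' (Q1, Q3) without a test; frequency-matching factors are flagged as not
#' tested; single-level characteristics are skipped with a note. Missing
#' values are excluded from tests and reported.
#'
#' @param data Cohort table.
#' @param vars Character vector of characteristic column names.
#' @param outcome Binary outcome column name.
#' @param matching_factors Characteristics not tested because controls were
#'   matched on them.
#' @return Data.frame of class `descriptive_table`: one row per
#'   characteristic level with case/control counts and percentages, plus
#'   per-characteristic `p_value` and `note`.
#' @export
descriptive_table <- function(data, vars, outcome = "cc_status",
                              matching_factors = c("age", "sex")) {
  y <- data[[outcome]]
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    n_missing <- sum(is.na(x))
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 10) {
      qs <- function(sel) stats::quantile(x[sel], c(0.25, 0.5, 0.75),
                                          na.rm = TRUE)
      qc <- qs(y == 1); qq <- qs(y == 0)
      rows[[v]] <- data.frame(
        characteristic = v, level = "median (Q1, Q3)",
        cases = sprintf("%.0f (%.0f, %.0f)", qc[2], qc[1], qc[3]),
        controls = sprintf("%.0f (%.0f, %.0f)", qq[2], qq[1], qq[3]),
        p_value = NA_real_,
        note = if (v %in% matching_factors) "matching factor; not tested"
               else "continuous; not tested",
        n_missing = n_missing, stringsAsFactors = FALSE)
      next
    }
    x <- factor(x)
    tab <- table(x, y)
    lev_rows <- data.frame(
      characteristic = v, level = rownames(tab),
      cases = sprintf("%d (%.1f)", tab[, "1"],
                      100 * tab[, "1"] / sum(tab[, "1"])),
      controls = sprintf("%d (%.1f)", tab[, "0"],
                         100 * tab[, "0"] / sum(tab[, "0"])),
      p_value = NA_real_, note = "", n_missing = n_missing,
      stringsAsFactors = FALSE)
    if (v %in% matching_factors) {
      lev_rows$note[1] <- "matching factor; not tested"
    } else if (nrow(tab) < 2) {
      lev_rows$note[1] <- "single level; test skipped"
    } else {
      lev_rows$p_value[1] <-
        suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    }
    rows[[v]] <- lev_rows
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("descriptive_table", class(out))
  out
}

#' @export
print.descriptive_table <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$p_value <- ifelse(is.na(y$p_value), "",
                      ifelse(y$p_value < 1e-4, "<0.0001",
                             sprintf("%.4f", y$p_value)))
  print(y, right = FALSE)
  invisible(x)
}
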