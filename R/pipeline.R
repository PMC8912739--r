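## Stage wrapper: any failure aborts with the stage name in front.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(stage, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full desk-scale study reproduction
#'
#' Orchestrates the complete analysis on a cohort + dosage matrix + panel:
#' exclusion of missing-exposure rows, PRS build and percentile
#' stratification, AIC covariate selection, the main association table
#' (age-sex and fully adjusted models with a multiplicative interaction
#' test), per-PRS-category ORs with a per-category trend, the 5 x 4
#' joint-effect grid against the medium-PRS/lowest-intake reference, site-
#' and stage-specific ORs and GREs, and subgroup GREs with interaction
#' tests.
#'
#' @param cohort Participant table (`id`, `cc_status`, `age`, `sex`,
#'   `exposure`, covariates, `site`, `stage`).
#' @param dosages Dosage matrix (subject ids as rownames).
#' @param panel Risk-loci panel.
#' @param candidates Candidate covariates for stepwise selection (default:
#'   every [default_covariates()] name present in the cohort).
#' @param prs_reference Percentile reference group (`"controls"` or
#'   `"all"`).
#' @param ci_method GRE confidence-interval method.
#' @param level Confidence level.
#' @param subgroups Stratifiers for the subgroup GRE analyses; any of
#'   `"age"`, `"sex"`, `"family_history"`, `"colonoscopy"` present in the
#'   cohort.
#' @param age_cut Age cutpoint for the age subgroup (default 55).
#' @param seed Seed recorded in the provenance block (analyses themselves
#'   are deterministic given the data).
#' @return Object of class `study_report` with elements `table1` through
#'   `table5`, `figure2`, `selected_covariates` and `provenance`.
#' @seealso [gre_fit()], [subgroup_gre()]
#' @export
run_study <- function(cohort, dosages, panel,
                      candidates = intersect(default_covariates()$name,
                                             names(cohort)),
                      prs_reference = c("controls", "all"),
                      ci_method = c("delta", "fieller", "bootstrap"),
                      level = 0.95,
                      subgroups = intersect(
                        c("age", "sex", "family_history", "colonoscopy"),
                        names(cohort)),
                      age_cut = 55, seed = NA_integer_) {
  prs_reference <- match.arg(prs_reference)
  ci_method <- match.arg(ci_method)
  n_total <- nrow(cohort)

  miss <- is.na(cohort$exposure)
  cohort <- cohort[!miss, , drop = FALSE]
  n_excluded <- sum(miss)

  cohort <- run_stage("prs_build",
                      add_prs(cohort, dosages, panel,
                              reference = prs_reference))

  table1 <- run_stage("descriptives",
    descriptive_table(cohort, vars = c("age", "sex", "exposure", candidates)))

  selection <- run_stage("covariate_selection",
    stepwise_aic(cohort, outcome = "cc_status",
                 forced = c("age", "sex", "exposure", "prs_percentile"),
                 candidates = candidates))
  adj <- selection$selected

  ## main association table: age-sex model and fully adjusted model
  table2 <- run_stage("main_associations", {
    basic <- fit_logistic(cc_status ~ exposure + age + sex, cohort)
    full <- gre_fit(
      reformulate(c("exposure", "prs_percentile", "age", "sex", adj),
                  response = "cc_status"),
      cohort, ci_method = ci_method, level = level)
    inter <- interaction_test(
      reformulate(c("exposure", "prs_percentile", "age", "sex", adj),
                  response = "cc_status"),
      cohort, pair = c("exposure", "prs_percentile"))
    basic_or <- or_table(basic, level = level)
    basic_or <- basic_or[startsWith(basic_or$term, "exposure"), ]
    full_or <- full$or[startsWith(full$or$term, "exposure"), ]
    list(age_sex_or = basic_or, adjusted_or = full_or,
         gre = full$gre, p_interaction = inter$p_value,
         model = paste("n =", full$fit$n_used))
  })

  table3 <- run_stage("prs_stratified", {
    strata <- levels(cohort$prs_category)
    per_stratum <- lapply(strata, function(s) {
      d <- cohort[cohort$prs_category == s, , drop = FALSE]
      f <- reformulate(c("exposure", "age", "sex", adj),
                       response = "cc_status")
      ors <- or_table(fit_logistic(f, d), level = level)
      ors <- ors[startsWith(ors$term, "exposure"), ]
      d$exposure_trend <- as.integer(d$exposure) - 1L
      tr <- or_table(fit_logistic(
        reformulate(c("exposure_trend", "age", "sex", adj),
                    response = "cc_status"), d),
        terms = "exposure_trend", level = level)
      list(prs_category = s, or = ors, trend = tr)
    })
    names(per_stratum) <- strata
    inter <- interaction_test(
      reformulate(c("exposure", "prs_category", "age", "sex", adj),
                  response = "cc_status"),
      cohort, pair = c("exposure", "prs_category"))
    list(strata = per_stratum, p_interaction = inter$p_value,
         interaction_df = inter$df)
  })

  table4 <- run_stage("joint_effects",
    joint_effects(cohort, covariates = c("age", "sex", adj), level = level))

  table5 <- run_stage("site_stage_gre", {
    subsets <- list(
      all = rep(TRUE, nrow(cohort)),
      colon = cohort$cc_status == 0 |
        cohort$site %in% c("proximal", "distal", "unspecified"),
      proximal = cohort$cc_status == 0 | cohort$site %in% "proximal",
      distal = cohort$cc_status == 0 | cohort$site %in% "distal",
      rectum = cohort$cc_status == 0 | cohort$site %in% "rectum",
      stage_I_III = cohort$cc_status == 0 | cohort$stage %in% "I-III",
      stage_IV = cohort$cc_status == 0 | cohort$stage %in% "IV")
    f <- reformulate(c("exposure", "prs_percentile", "age", "sex", adj),
                     response = "cc_status")
    lapply(subsets, function(keep) {
      d <- cohort[keep, , drop = FALSE]
      m <- gre_fit(f, d, ci_method = ci_method, level = level)
      list(n_cases = sum(d$cc_status == 1),
           n_controls = sum(d$cc_status == 0),
           gre = m$gre, model = paste("n =", m$fit$n_used))
    })
  })

  figure2 <- run_stage("subgroup_gre", {
    out <- lapply(subgroups, function(sg)
      subgroup_gre(cohort, stratifier = sg,
                   covariates = c("age", "sex", setdiff(adj, sg)),
                   age_cut = age_cut, ci_method = ci_method, level = level))
    names(out) <- subgroups
    out
  })

  structure(list(
    table1 = table1, table2 = table2, table3 = table3,
    table4 = table4, table5 = table5, figure2 = figure2,
    selected_covariates = adj,
    provenance = list(seed = seed, n_input = n_total,
                      n_excluded_missing_exposure = n_excluded,
                      n_analysed = nrow(cohort),
                      prs_reference = prs_reference,
                      ci_method = ci_method, level = level)
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  p <- x$provenance
  cat("Case-control study report:", p$n_analysed, "analysed (",
      p$n_excluded_missing_exposure, "excluded for missing exposure )\n")
  cat("Selected covariates:",
      if (length(x$selected_covariates))
        paste(x$selected_covariates, collapse = " + ") else "<none>", "\n\n")
  cat("Adjusted exposure effects and genetic risk equivalents:\n")
  print(x$table2$gre)
  cat("\np (exposure x PRS interaction, continuous):",
      format.pval(x$table2$p_interaction, digits = 2), "\n")
  cat("p (exposure x PRS interaction, 5-level):",
      format.pval(x$table3$p_interaction, digits = 2), "\n")
  invisible(x)
}

#' Subgroup-specific GREs with a pooled interaction test
#'
#' Splits the cohort by a binary stratifier (age dichotomised at `age_cut`,
#' sex, or any binary covariate), fits the adjusted GRE model within each
#' stratum (the stratifier itself removed from the covariates), and tests
#' effect modification through the block of stratifier-by-exposure product
#' terms in the pooled model. Strata in which a model cannot be estimated
#' (e.g. an empty exposure level) are flagged and their GREs omitted with a
#' note rather than failing the analysis.
#'
#' @param cohort Cohort table with PRS columns attached (see [add_prs()]).
#' @param stratifier Column name (or `"age"` for the age dichotomy).
#' @param covariates Adjustment terms for the stratum models (the stratifier
#'   is removed automatically).
#' @param prs Continuous PRS column.
#' @param prs_scale PRS coding passed to [gre_fit()]; GREs are reported per
#'   single percentile either way.
#' @param age_cut Age cutpoint when `stratifier = "age"`.
#' @param ci_method,level CI settings.
#' @return List of class `subgroup_gre`: `stratifier`, `strata` (per-stratum
#'   GRE table or a `note`), `p_interaction`, `df`.
#' @export
subgroup_gre <- function(cohort, stratifier,
                         covariates = c("age", "sex"),
                         prs = "prs_percentile",
                         prs_scale = "percentile",
                         age_cut = 55,
                         ci_method = "delta", level = 0.95) {
  if (stratifier == "age") {
    strat <- factor(ifelse(cohort$age <= age_cut,
                           paste0("le", age_cut), paste0("gt", age_cut)),
                    levels = c(paste0("le", age_cut), paste0("gt", age_cut)))
  } else {
    if (!stratifier %in% names(cohort))
      stop("stratifier not in cohort: ", stratifier)
    strat <- factor(cohort[[stratifier]])
  }
  covariates <- setdiff(covariates, stratifier)
  cohort$.stratum <- strat
  levs <- levels(droplevels(strat))
  if (length(levs) < 2) {
    warning("stratifier '", stratifier,
            "' has a single level; returning the pooled model only")
    pooled <- gre_fit(
      reformulate(c("exposure", prs, covariates), response = "cc_status"),
      cohort, prs = prs, prs_scale = prs_scale,
      ci_method = ci_method, level = level)
    return(structure(list(stratifier = stratifier,
                          strata = list(pooled = pooled$gre),
                          p_interaction = NA_real_, df = NA_integer_),
                     class = "subgroup_gre"))
  }
  f <- reformulate(c("exposure", prs, covariates), response = "cc_status")
  strata <- lapply(levs, function(lv) {
    d <- cohort[!is.na(strat) & strat == lv, , drop = FALSE]
    if (any(table(d$exposure, d$cc_status) == 0))
      return(list(note = paste0("stratum '", lv,
                                "': empty exposure level; GRE omitted")))
    tryCatch({
      m <- gre_fit(f, d, prs = prs, prs_scale = prs_scale,
                   ci_method = ci_method, level = level)
      list(gre = m$gre, n = m$fit$n_used)
    }, error = function(e)
      list(note = paste0("stratum '", lv, "': ", conditionMessage(e))))
  })
  names(strata) <- levs
  pooled_f <- reformulate(c("exposure", ".stratum", prs, covariates),
                          response = "cc_status")
  inter <- tryCatch(
    interaction_test(pooled_f, cohort, pair = c("exposure", ".stratum")),
    error = function(e) list(p_value = NA_real_, df = NA_integer_))
  structure(list(stratifier = stratifier, strata = strata,
                 p_interaction = inter$p_value, df = inter$df),
            class = "subgroup_gre")
}

#' @export
print.subgroup_gre <- function(x, ...) {
  cat("Subgroup GREs by", x$stratifier, "\n")
  for (lv in names(x$strata)) {
    cat("--", lv, "--\n")
    s <- x$strata[[lv]]
    if (!is.null(s$note)) cat(s$note, "\n") else print(s$gre)
  }
  cat("p (interaction):", format.pval(x$p_interaction, digits = 2), "\n")
  invisible(x)
}
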