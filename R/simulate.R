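#' Default covariate battery for the cohort generator
#'
#' Binary lifestyle/medical covariates with control-population prevalences
#' typical of an elderly European colorectal-cancer case-control study, and
#' plausible default log odds ratios. Used by [sim_config()] when no covariate
#' table is supplied; override single entries through its `covariate_effects`
#' and `covariate_prevalences` arguments.
#'
#' @return A data.frame with columns `name`, `prevalence`, `log_or`.
#' @export
default_covariates <- function() {
  data.frame(
    name = c("education_low", "smoking_current", "bmi_obese", "diabetes",
             "family_history", "colonoscopy"),
    prevalence = c(0.552, 0.109, 0.157, 0.135, 0.109, 0.603),
    log_or = log(c(1.3, 1.4, 1.4, 1.3, 1.6, 0.4)),
    stringsAsFactors = FALSE
  )
}

#' Exposure category labels
#'
#' Four ordered intake-frequency categories for the combined red/processed
#' meat variable; the lowest category is the analysis reference.
#' @return Character vector of the four level labels.
#' @export
exposure_levels <- function() c("le1_wk", "multi_wk", "daily", "gt1_day")

#' Simulation configuration for the synthetic case-control generator
#'
#' Bundles and validates every parameter of the generative model: a logistic
#' disease model on a 4-level intake exposure, a PRS percentile, age, sex and
#' binary covariates, sampled retrospectively (all cases, then controls,
#' optionally frequency-matched on age decade and sex) from a simulated
#' source population.
#'
#' Defaults encode the study conditions the package is validated under:
#' 140 risk loci, exposure log odds ratios `log(c(1.19, 1.41, 1.73))` for the
#' upper three intake categories versus the lowest, and a PRS effect of
#' `log(1.74)/42.3` (about 0.0131) per percentile.
#'
#' @param n_cases,n_controls Positive target sample sizes.
#' @param n_loci Number of independent risk loci (default 140).
#' @param risk_allele_freqs Optional vector of per-locus risk-allele
#'   frequencies in (0,1); length `n_loci`. If `NULL`, drawn uniformly from
#'   (0.1, 0.9) under `seed`.
#' @param beta_prs True log odds ratio per single PRS percentile.
#' @param beta_exposure Length-3 vector of true log odds ratios for exposure
#'   categories 2-4 versus category 1.
#' @param exposure_control_prevalences Probabilities of the four intake
#'   categories in the source population (must sum to 1).
#' @param beta_age Log odds ratio per year of age (centred at 70 years).
#' @param beta_sex Log odds ratio for male versus female sex.
#' @param male_prevalence Probability of male sex in the source population.
#' @param covariates Data.frame as returned by [default_covariates()].
#' @param covariate_effects,covariate_prevalences Optional named numeric
#'   vectors overriding single `log_or` / `prevalence` entries of
#'   `covariates`.
#' @param matching Frequency-match controls to cases on age decade and sex?
#' @param target_prevalence Overall disease probability in the source
#'   population; the model intercept is calibrated to it.
#' @param pool_factor Source-population size as a multiple of the minimum
#'   needed in expectation; raise it if case sampling proves infeasible.
#' @param dosage_jitter_sd Standard deviation of clamped Gaussian noise added
#'   to integer allele counts, mimicking imputed dosages (default 0).
#' @param missing_exposure_rate Fraction of sampled subjects whose exposure is
#'   set to missing (default 0).
#' @param confounding Optional `list(covariate =, gamma =)`: shifts the
#'   cumulative-logit of the exposure distribution by `gamma` for carriers of
#'   the named binary covariate, inducing exposure-covariate confounding.
#' @param seed Integer seed; the same configuration always yields the same
#'   dataset.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_cases = 2500, n_controls = 2500,
                       n_loci = 140, risk_allele_freqs = NULL,
                       beta_prs = log(1.74) / 42.3,
                       beta_exposure = log(c(1.19, 1.41, 1.73)),
                       exposure_control_prevalences = c(0.117, 0.608, 0.244, 0.031),
                       beta_age = 0.04, beta_sex = log(1.2),
                       male_prevalence = 0.614,
                       covariates = default_covariates(),
                       covariate_effects = NULL,
                       covariate_prevalences = NULL,
                       matching = TRUE,
                       target_prevalence = 0.05,
                       pool_factor = 1.4,
                       dosage_jitter_sd = 0,
                       missing_exposure_rate = 0,
                       confounding = NULL,
                       seed = 1L) {
  stopifnot(length(n_cases) == 1, length(n_controls) == 1)
  if (n_cases < 1 || n_controls < 1)
    stop("n_cases and n_controls must be positive")
  if (n_loci < 1) stop("n_loci must be positive")
  if (!is.null(risk_allele_freqs)) {
    if (length(risk_allele_freqs) != n_loci)
      stop("risk_allele_freqs must have length n_loci")
    if (any(risk_allele_freqs <= 0 | risk_allele_freqs >= 1))
      stop("risk_allele_freqs must lie strictly in (0, 1)")
  }
  if (length(beta_exposure) != 3)
    stop("beta_exposure must give 3 log-ORs (categories 2-4 vs 1)")
  if (length(exposure_control_prevalences) != 4 ||
      any(exposure_control_prevalences <= 0))
    stop("exposure_control_prevalences must be 4 positive probabilities")
  if (abs(sum(exposure_control_prevalences) - 1) > 1e-9)
    stop("exposure_control_prevalences must sum to 1")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie in (0, 1)")
  if (missing_exposure_rate < 0 || missing_exposure_rate >= 1)
    stop("missing_exposure_rate must lie in [0, 1)")
  stopifnot(is.data.frame(covariates),
            all(c("name", "prevalence", "log_or") %in% names(covariates)))
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), covariates$name)
    if (length(bad)) stop("unknown covariate(s) in covariate_effects: ",
                          paste(bad, collapse = ", "))
    covariates$log_or[match(names(covariate_effects), covariates$name)] <-
      unname(covariate_effects)
  }
  if (!is.null(covariate_prevalences)) {
    bad <- setdiff(names(covariate_prevalences), covariates$name)
    if (length(bad)) stop("unknown covariate(s) in covariate_prevalences: ",
                          paste(bad, collapse = ", "))
    covariates$prevalence[match(names(covariate_prevalences), covariates$name)] <-
      unname(covariate_prevalences)
  }
  if (any(covariates$prevalence <= 0 | covariates$prevalence >= 1))
    stop("covariate prevalences must lie strictly in (0, 1)")
  if (!is.null(confounding)) {
    stopifnot(is.list(confounding),
              all(c("covariate", "gamma") %in% names(confounding)))
    if (!confounding$covariate %in% covariates$name)
      stop("confounding covariate not in covariate table: ",
           confounding$covariate)
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_loci = as.integer(n_loci), risk_allele_freqs = risk_allele_freqs,
    beta_prs = beta_prs, beta_exposure = beta_exposure,
    exposure_control_prevalences = exposure_control_prevalences,
    beta_age = beta_age, beta_sex = beta_sex,
    male_prevalence = male_prevalence,
    covariates = covariates, matching = isTRUE(matching),
    target_prevalence = target_prevalence, pool_factor = pool_factor,
    dosage_jitter_sd = dosage_jitter_sd,
    missing_exposure_rate = missing_exposure_rate,
    confounding = confounding, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a genotype-dosage matrix
#'
#' Draws Hardy-Weinberg allele counts Binomial(2, f) per locus, optionally
#' perturbed by clamped Gaussian noise to mimic imputed dosages. Column means
#' converge to `2 * freqs` and every entry lies in `[0, 2]`.
#'
#' @param n_subjects Number of rows.
#' @param freqs Vector of risk-allele frequencies, each strictly in (0, 1).
#' @param seed Optional integer seed (left untouched if `NULL`).
#' @param jitter_sd Standard deviation of the additive noise; 0 gives integer
#'   allele counts.
#' @return Numeric matrix `n_subjects` x `length(freqs)`.
#' @examples
#' d <- simulate_dosages(100, rep(0.5, 5), seed = 1)
#' range(d)
#' @export
simulate_dosages <- function(n_subjects, freqs, seed = NULL, jitter_sd = 0) {
  if (any(!is.finite(freqs)) || any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must lie strictly in (0, 1)")
  if (n_subjects < 1) stop("n_subjects must be positive")
  if (!is.null(seed)) set.seed(seed)
  m <- length(freqs)
  d <- matrix(rbinom(n_subjects * m, size = 2L,
                     prob = rep(freqs, each = n_subjects)),
              nrow = n_subjects, ncol = m)
  if (jitter_sd > 0) {
    d <- d + matrix(rnorm(n_subjects * m, sd = jitter_sd), n_subjects, m)
    d <- pmin(pmax(d, 0), 2)
  }
  d
}

## Exposure categories from cumulative-logit cutpoints, optionally shifted by
## gamma for carriers of the confounding covariate.
draw_exposure <- function(n, prev, z = NULL, gamma = 0) {
  kappa <- qlogis(cumsum(prev)[1:3])
  if (is.null(z) || gamma == 0) {
    idx <- sample.int(4L, n, replace = TRUE, prob = prev)
  } else {
    u <- runif(n)
    shift <- gamma * z
    idx <- 1L +
      (u > plogis(kappa[1] - shift)) +
      (u > plogis(kappa[2] - shift)) +
      (u > plogis(kappa[3] - shift))
  }
  factor(exposure_levels()[idx], levels = exposure_levels())
}

## Truncated-normal age draw on [lo, hi] by inverse-CDF.
draw_age <- function(n, mean = 69.5, sd = 9, lo = 30, hi = 95) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Simulate a complete synthetic case-control dataset
#'
#' Generates a source population under the configured logistic disease model
#' (intercept calibrated so the overall disease probability equals
#' `target_prevalence`), then samples all required cases and random or
#' frequency-matched controls -- mirroring a population-based case-control
#' design. Case tumours receive a site (proximal colon / distal colon /
#' rectum / unspecified) and a stage (I-III / IV / unknown) label drawn at
#' prevalences typical of incident colorectal cancer, independent of all risk
#' factors.
#'
#' The disease model acts on the PRS percentile computed within the source
#' population; downstream analyses recompute percentiles from the sampled
#' data (controls by default), which approximates that scale well at low
#' disease prevalence.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_cohort`: a list with elements
#'   `cohort` (data.frame: `id`, `cc_status` 0/1, `age`, `sex`, `exposure`,
#'   binary covariates, `site`, `stage`), `dosages` (subjects x loci matrix,
#'   rownames = subject ids), `panel` (data.frame `locus_id`, `risk_allele`,
#'   `frequency`) and `truth` (the config plus the calibrated intercept and
#'   realised allele frequencies).
#' @examples
#' dat <- simulate_cohort(sim_config(n_cases = 150, n_controls = 150,
#'                                   n_loci = 20, seed = 7))
#' table(dat$cohort$cc_status)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$target_prevalence
  n_pool <- ceiling(config$pool_factor *
                    max(config$n_cases / p, config$n_controls / (1 - p)))

  freqs <- config$risk_allele_freqs
  if (is.null(freqs)) freqs <- runif(config$n_loci, 0.1, 0.9)
  panel <- data.frame(
    locus_id = sprintf("rs%06d", seq_len(config$n_loci)),
    risk_allele = sample(c("A", "C", "G", "T"), config$n_loci, replace = TRUE),
    frequency = freqs,
    stringsAsFactors = FALSE
  )

  age <- draw_age(n_pool)
  sex <- factor(ifelse(runif(n_pool) < config$male_prevalence,
                       "male", "female"), levels = c("female", "male"))
  covs <- config$covariates
  covmat <- sapply(covs$prevalence,
                   function(pr) as.integer(runif(n_pool) < pr))
  colnames(covmat) <- covs$name

  conf_z <- NULL; conf_gamma <- 0
  if (!is.null(config$confounding)) {
    conf_z <- covmat[, config$confounding$covariate]
    conf_gamma <- config$confounding$gamma
  }
  exposure <- draw_exposure(n_pool, config$exposure_control_prevalences,
                            z = conf_z, gamma = conf_gamma)

  dos <- simulate_dosages(n_pool, freqs,
                          jitter_sd = config$dosage_jitter_sd)
  colnames(dos) <- panel$locus_id
  score <- rowSums(dos)
  percentile <- 100 * rank(score, ties.method = "average") / n_pool

  lp <- config$beta_prs * percentile +
    c(0, config$beta_exposure)[as.integer(exposure)] +
    config$beta_age * (age - 70) +
    config$beta_sex * (sex == "male") +
    drop(covmat %*% covs$log_or)
  alpha <- uniroot(function(a) mean(plogis(a + lp)) - p,
                   interval = c(-30, 30), tol = 1e-10)$root
  disease <- rbinom(n_pool, 1L, plogis(alpha + lp))

  n_dis <- sum(disease); n_nondis <- n_pool - n_dis
  if (n_dis < config$n_cases)
    stop("infeasible case target: source population of ", n_pool,
         " produced only ", n_dis, " cases for a target of ",
         config$n_cases, "; increase pool_factor or target_prevalence")
  if (n_nondis < config$n_controls)
    stop("infeasible control target: only ", n_nondis,
         " non-diseased subjects for a target of ", config$n_controls)

  case_idx <- sample(which(disease == 1L), config$n_cases)
  ctrl_pool <- which(disease == 0L)
  if (config$matching) {
    stratum <- interaction(cut(age, c(30, seq(40, 90, 10), 95),
                               include.lowest = TRUE), sex, drop = FALSE)
    case_tab <- table(stratum[case_idx])
    want <- case_tab * config$n_controls / config$n_cases
    n_strat <- floor(want)
    rem <- config$n_controls - sum(n_strat)
    if (rem > 0) {
      extra <- order(want - n_strat, decreasing = TRUE)[seq_len(rem)]
      n_strat[extra] <- n_strat[extra] + 1L
    }
    ctrl_idx <- integer(0)
    for (s in names(case_tab)[n_strat > 0]) {
      avail <- ctrl_pool[stratum[ctrl_pool] == s]
      need <- n_strat[[s]]
      if (length(avail) < need)
        stop("infeasible frequency matching: stratum ", s, " has ",
             length(avail), " controls but needs ", need,
             "; increase pool_factor")
      ctrl_idx <- c(ctrl_idx, sample(avail, need))
    }
  } else {
    ctrl_idx <- sample(ctrl_pool, config$n_controls)
  }

  keep <- c(case_idx, ctrl_idx)
  n <- length(keep)
  cohort <- data.frame(
    id = sprintf("S%06d", seq_len(n)),
    cc_status = rep(c(1L, 0L), c(config$n_cases, config$n_controls)),
    age = age[keep],
    sex = sex[keep],
    exposure = exposure[keep],
    stringsAsFactors = FALSE
  )
  cohort <- cbind(cohort, as.data.frame(covmat[keep, , drop = FALSE]))

  cohort$site <- NA_character_
  cohort$stage <- NA_character_
  is_case <- cohort$cc_status == 1L
  cohort$site[is_case] <- sample(
    c("proximal", "distal", "rectum", "unspecified"),
    sum(is_case), replace = TRUE, prob = c(0.324, 0.258, 0.375, 0.043))
  cohort$stage[is_case] <- sample(
    c("I-III", "IV", "unknown"),
    sum(is_case), replace = TRUE, prob = c(0.813, 0.136, 0.051))

  if (config$missing_exposure_rate > 0) {
    miss <- runif(n) < config$missing_exposure_rate
    cohort$exposure[miss] <- NA
  }

  dosages <- dos[keep, , drop = FALSE]
  rownames(dosages) <- cohort$id

  truth <- config
  truth$intercept <- alpha
  truth$risk_allele_freqs <- freqs
  structure(list(cohort = cohort, dosages = dosages, panel = panel,
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic case-control dataset:",
      sum(x$cohort$cc_status == 1), "cases,",
      sum(x$cohort$cc_status == 0), "controls,",
      ncol(x$dosages), "loci\n")
  cat("Exposure distribution (controls):\n")
  print(table(x$cohort$exposure[x$cohort$cc_status == 0], useNA = "ifany"))
  invisible(x)
}

#' Combine two intake-frequency items into the 4-level exposure
#'
#' For users holding separate red-meat and processed-meat frequency items on
#' the common 6-level scale (never, <1/week, 1/week, multiple/week, 1/day,
#' multiple/day). The default combiner takes the elementwise maximum of the
#' two item levels and maps it onto the four analysis categories; this is a
#' documented package assumption, not an externally specified rule, and the
#' mapping is configurable.
#'
#' @param red,processed Integer vectors (1-6) or factors on the 6-level scale.
#' @param mapping Integer vector of length 6 assigning each combined item
#'   level to an exposure category 1-4.
#' @return Factor with levels [exposure_levels()].
#' @export
combine_intake_items <- function(red, processed,
                                 mapping = c(1L, 1L, 1L, 2L, 3L, 4L)) {
  to_int <- function(v) if (is.factor(v)) as.integer(v) else as.integer(v)
  r <- to_int(red); p <- to_int(processed)
  if (length(r) != length(p)) stop("items must have equal length")
  if (any(stats::na.omit(c(r, p)) < 1 | stats::na.omit(c(r, p)) > 6))
    stop("item levels must lie in 1..6")
  stopifnot(length(mapping) == 6, all(mapping %in% 1:4))
  combined <- pmax(r, p)
  factor(exposure_levels()[mapping[combined]], levels = exposure_levels())
}

#' Write a synthetic dataset as plain-text files
#'
#' Writes `cohort.tsv` (tab-delimited, header row), `dosages.tsv` (subject ids
#' in column 1), `panel.tsv` and `config.yml` into `dir`. Output is
#' byte-identical across runs from the same configuration.
#'
#' @param x A `synthetic_cohort` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(d, f) write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(x$cohort, "cohort.tsv")
  tsv(data.frame(id = rownames(x$dosages), x$dosages,
                 check.names = FALSE, stringsAsFactors = FALSE),
      "dosages.tsv")
  tsv(x$panel, "panel.tsv")
  cfg <- x$truth
  cfg$covariates <- as.list(setNames(cfg$covariates$log_or,
                                     cfg$covariates$name))
  yaml::write_yaml(lapply(unclass(cfg), function(v)
    if (is.factor(v)) as.character(v) else v),
    file.path(dir, "config.yml"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `cohort.tsv`, `dosages.tsv`, `panel.tsv`.
#' @return A list with `cohort`, `dosages` (matrix) and `panel`, factor levels
#'   restored for `sex` and `exposure`.
#' @export
read_dataset <- function(dir) {
  cohort <- read.table(file.path(dir, "cohort.tsv"), sep = "\t",
                       header = TRUE, stringsAsFactors = FALSE)
  cohort$sex <- factor(cohort$sex, levels = c("female", "male"))
  cohort$exposure <- factor(cohort$exposure, levels = exposure_levels())
  dtab <- read.table(file.path(dir, "dosages.tsv"), sep = "\t",
                     header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
  dosages <- as.matrix(dtab[, -1, drop = FALSE])
  rownames(dosages) <- dtab[[1]]
  panel <- read.table(file.path(dir, "panel.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  list(cohort = cohort, dosages = dosages, panel = panel)
}
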