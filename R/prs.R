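#' Compute the polygenic risk score from a dosage matrix
#'
#' The score is the (optionally weighted) sum of risk-allele dosages across
#' the panel loci: `score_i = sum_j w_j * dosage_ij`. With the default unit
#' weights this is the plain allele count, bounded by `[0, 2 * n_loci]`.
#' Dosage columns are matched to the panel by `locus_id`; order in the matrix
#' is irrelevant.
#'
#' @param dosages Numeric matrix, subjects x loci, entries in `[0, 2]`,
#'   with column names giving locus ids.
#' @param panel Data.frame with columns `locus_id` and, optionally, `weight`
#'   (defaults to 1 per locus).
#' @return Named numeric vector of scores (names = rownames of `dosages`).
#' @examples
#' d <- matrix(c(0, 1, 2, 2), 2, 2, dimnames = list(NULL, c("rs1", "rs2")))
#' compute_prs(d, data.frame(locus_id = c("rs1", "rs2")))
#' @export
compute_prs <- function(dosages, panel) {
  stopifnot(is.matrix(dosages), is.data.frame(panel),
            "locus_id" %in% names(panel))
  if (anyDuplicated(panel$locus_id))
    stop("panel locus ids are not unique")
  if (is.null(colnames(dosages)))
    stop("dosage matrix must carry locus ids as column names")
  missing_in_mat <- setdiff(panel$locus_id, colnames(dosages))
  extra_in_mat <- setdiff(colnames(dosages), panel$locus_id)
  if (length(missing_in_mat) || length(extra_in_mat))
    stop("locus mismatch between dosage matrix and panel; ",
         "missing from matrix: [",
         paste(head(missing_in_mat, 5), collapse = ", "),
         "]; absent from panel: [",
         paste(head(extra_in_mat, 5), collapse = ", "), "]")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]; observed range ",
         rng[1], " to ", rng[2])
  w <- if ("weight" %in% names(panel)) panel$weight else rep(1, nrow(panel))
  if (any(w < 0)) stop("panel weights must be nonnegative")
  drop(dosages[, panel$locus_id, drop = FALSE] %*% w)
}

#' PRS percentiles and five-level risk categories
#'
#' Converts raw scores to percentiles of a reference distribution using mean
#' ranks for ties: the percentile of score `s` is `100 * (mean rank of s
#' within the reference) / (reference size)`. Categories follow the standard
#' five-level stratification: very low (<=10th percentile), low (11th-25th),
#' medium (26th-75th), high (76th-90th), very high (>90th).
#'
#' @param scores Numeric vector of PRS values to be placed.
#' @param reference Reference score vector defining the percentile scale, or
#'   `"self"` (default) to use `scores` itself. In a case-control analysis the
#'   natural reference is the control scores, which approximate the source
#'   population.
#' @return Data.frame with columns `score`, `percentile` (in (0, 100]) and
#'   `category` (factor: very_low, low, medium, high, very_high).
#' @examples
#' prs_percentiles(1:100)$percentile  # percentile of k is k
#' @export
prs_percentiles <- function(scores, reference = "self") {
  if (identical(reference, "self")) reference <- scores
  if (!length(reference)) stop("reference score vector is empty")
  if (any(!is.finite(reference)) || any(!is.finite(scores)))
    stop("scores and reference must be finite")
  nref <- length(reference)
  ## mean rank of each score within the reference: count below + (ties+1)/2
  srt <- sort(reference)
  below <- findInterval(scores, srt, left.open = TRUE)
  upto <- findInterval(scores, srt)
  ## scores beyond the reference maximum cap at the 100th percentile
  pct <- pmin(100 * (below + (upto - below + 1) / 2) / nref, 100)
  data.frame(score = scores, percentile = pct,
             category = prs_category(pct))
}

#' Map PRS percentiles to the five risk categories
#'
#' Boundaries sit exactly at percentiles 10, 25, 75 and 90, the lower tail
#' closed: `(0,10]` very low, `(10,25]` low, `(25,75]` medium, `(75,90]`
#' high, `(90,100]` very high.
#'
#' @param percentile Numeric vector in (0, 100].
#' @return Factor with levels `very_low`, `low`, `medium`, `high`,
#'   `very_high`.
#' @export
prs_category <- function(percentile) {
  if (any(percentile <= 0 | percentile > 100, na.rm = TRUE))
    stop("percentiles must lie in (0, 100]")
  cut(percentile, breaks = c(0, 10, 25, 75, 90, 100),
      labels = c("very_low", "low", "medium", "high", "very_high"),
      include.lowest = FALSE, right = TRUE)
}

#' Attach PRS score, percentile and category to a cohort table
#'
#' Computes the allele-count PRS for every cohort row from the dosage matrix
#' (matched by subject id), assigns percentiles against the chosen reference
#' group, and appends `prs_score`, `prs_percentile` and `prs_category`
#' columns.
#'
#' @param cohort Data.frame with columns `id` and `cc_status` (1 = case).
#' @param dosages Dosage matrix with subject ids as rownames.
#' @param panel Risk-loci panel (see [compute_prs()]).
#' @param reference `"controls"` (default) to define percentiles on the
#'   control score distribution, or `"all"` for the pooled sample.
#' @return The cohort with the three PRS columns appended.
#' @export
add_prs <- function(cohort, dosages, panel,
                    reference = c("controls", "all")) {
  reference <- match.arg(reference)
  stopifnot(all(c("id", "cc_status") %in% names(cohort)))
  if (is.null(rownames(dosages)) || !all(cohort$id %in% rownames(dosages)))
    stop("dosage matrix must contain a row for every cohort id")
  score <- compute_prs(dosages[cohort$id, , drop = FALSE], panel)
  ref <- if (reference == "controls") score[cohort$cc_status == 0] else score
  pp <- prs_percentiles(score, reference = ref)
  cohort$prs_score <- pp$score
  cohort$prs_percentile <- pp$percentile
  cohort$prs_category <- pp$category
  cohort
}
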