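#' Published OR and GRE estimates used for internal-consistency checks
#'
#' Adjusted odds ratios and genetic risk equivalents, by outcome subset and
#' intake contrast, as published by a large German population-based
#' case-control study of red/processed meat intake, polygenic risk and
#' colorectal cancer (about 5100 cases and 4100 controls; PRS over 140 risk
#' loci). Each outcome block compares the upper three intake categories to
#' intake at most once per week.
#'
#' Because the GRE is the ratio of the exposure and per-percentile PRS
#' coefficients from one model, the rows of each block are mutually
#' consistent: the top contrast's OR and GRE imply the PRS coefficient
#' `log(or)/gre`, from which every other contrast's GRE can be recomputed
#' from its OR alone (see [implied_prs_coef()]). The package's consistency
#' checks exploit exactly this structure.
#'
#' @return Data.frame with columns `outcome` (all, colon, proximal, distal,
#'   rectum, stage_I_III, stage_IV), `contrast` (see [exposure_levels()]),
#'   `or`, `or_low`, `or_high`, `gre`, `gre_low`, `gre_high`.
#' @export
published_gre_estimates <- function() {
  path <- system.file("extdata", "published_gre_estimates.tsv",
                      package = "genriskeq", mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' PRS-percentile coefficient implied by a published OR/GRE pair
#'
#' Inverts the GRE definition: given a contrast's odds ratio and its GRE,
#' the per-percentile PRS log odds ratio of the underlying model is
#' `log(or) / gre`.
#'
#' @param or Published odds ratio for the contrast.
#' @param gre Published GRE (PRS percentiles) for the same contrast.
#' @return Log odds ratio per single PRS percentile.
#' @examples
#' implied_prs_coef(1.74, 42.3)  # about 0.0131
#' @export
implied_prs_coef <- function(or, gre) {
  stopifnot(or > 0, gre != 0)
  log(or) / gre
}
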