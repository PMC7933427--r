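#' Shipped analysis defaults
#'
#' The parameter values the quantification scheme is built around, in
#' one place: background positivity is calibrated as the 90th percentile
#' of negative-control dots per cell (strictly exceeded), high expression
#' means strictly more than 20 dots per cell, enrichment filtering uses
#' FDR <= 0.05 and fold ratio >= 2 (both inclusive), genes count as
#' expressed above 10 normalised counts and as detectable by in situ
#' hybridisation above 100, and the study design is 3 animals with 2
#' hemisections each per probe combination.
#'
#' @return named list of defaults.
#' @export
dorsalcode_defaults <- function() {
  list(
    background_percentile = 90,
    positivity_strict = TRUE,
    high_expression_threshold = 20,
    high_expression_strict = TRUE,
    fdr_max = 0.05,
    min_fold = 2,
    expressed_threshold = unname(expressed_thresholds["expressed"]),
    in_situ_threshold = unname(expressed_thresholds["in_situ_detectable"]),
    n_animals = 3,
    hemisections_per_animal = 2
  )
}
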