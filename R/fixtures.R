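#' Reference contingency tables from a published attention-training trial
#'
#' Treatment-by-outcome 2x2 count tables transcribed from the baseline
#' tables of a published randomized trial of early attention training after
#' acquired brain injury (systematic attention-process training, APT, versus
#' activity-based attention training, ABAT; outcome CHANGE / NO CHANGE from
#' individual-chart change detection). They serve as desk-scale reference
#' inputs: the association suite reproduces the trial's printed chi-square,
#' Fisher, Cramer's V and odds-ratio values from these counts.
#'
#' Orientation: rows = treatment (APT first), columns = outcome (CHANGE
#' first).
#'
#' @return Named list of 2x2 integer matrices with dimnames:
#' \describe{
#'   \item{`treatment_outcome`}{full cohort, N = 59.}
#'   \item{`stroke_treatment_outcome`}{stroke patients only, N = 46.}
#'   \item{`highcr_treatment_outcome`}{high cognitive-reserve patients only,
#'     N = 42.}
#' }
#' @examples
#' chi_square_test(attention_trial_tables()$treatment_outcome)
#' @export
attention_trial_tables <- function() {
  dn <- list(arm = c("APT", "ABAT"), outcome = c("CHANGE", "NO_CHANGE"))
  list(
    treatment_outcome = matrix(c(27L, 5L, 15L, 12L), nrow = 2,
                               byrow = TRUE, dimnames = dn),
    stroke_treatment_outcome = matrix(c(22L, 4L, 9L, 11L), nrow = 2,
                                      byrow = TRUE, dimnames = dn),
    highcr_treatment_outcome = matrix(c(19L, 2L, 13L, 8L), nrow = 2,
                                      byrow = TRUE, dimnames = dn)
  )
}
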