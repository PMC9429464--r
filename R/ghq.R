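#' GHQ-12 item labels
#'
#' Short labels for the twelve General Health Questionnaire items, in the
#' conventional order.  Items 1-6 are positively phrased, items 7-12
#' negatively phrased; after the usual 1-4 Likert coding a higher category
#' indicates more psychiatric morbidity for every item, so no reverse
#' scoring is applied anywhere in the package.
#'
#' @return Character vector of length 12.
#' @export
ghq_items <- function() {
  c("concentrate", "useful", "decisions", "enjoy", "face_problems",
    "happy", "sleep", "strain", "overcome", "depressed",
    "confidence", "worthless")
}

# Published adult-survey category counts for the 12 items (4 Likert
# categories).
# Used only as *defaults*: the synthetic-data generator turns these margins
# into standard-normal thresholds so that simulated response frequencies
# resemble a real adult household survey.
.ghq_reference_counts <- function() {
  m <- matrix(c(
      52, 1748,  181, 18,
     191, 1596,  164, 42,
     133, 1747,  108, 12,
      95, 1598,  247, 55,
      84, 1753,  109, 19,
     189, 1612,  137, 31,
     673, 1025,  255, 47,
     541, 1096,  315, 44,
     760, 1059,  140, 34,
     811,  891,  228, 40,
     886,  873,  174, 34,
    1349,  502,   91, 29), nrow = 12, byrow = TRUE)
  rownames(m) <- ghq_items()
  colnames(m) <- paste0("cat", 1:4)
  m
}

#' Default factor loadings for a GHQ-12-style latent morbidity factor
#'
#' Unstandardised loadings (first fixed to 1 for identification) typical of
#' a unidimensional adult-survey fit; used as the generator's ground truth
#' unless overridden.
#'
#' @return Named numeric vector of length 12.
#' @export
ghq_loadings <- function() {
  stats::setNames(
    c(1, 1.415, 0.954, 1.837, 0.964, 2.059,
      3.366, 3.575, 3.482, 4.516, 4.225, 3.634),
    ghq_items())
}

#' Default item thresholds on the standard-normal scale
#'
#' Three increasing cut-points per item, derived from reference adult-survey
#' category margins via the inverse normal CDF.
#'
#' @return List of 12 numeric vectors, each strictly increasing, length 3.
#' @export
ghq_thresholds <- function() {
  counts <- .ghq_reference_counts()
  out <- lapply(seq_len(nrow(counts)), function(p) {
    cp <- cumsum(counts[p, ]) / sum(counts[p, ])
    stats::qnorm(cp[-length(cp)])
  })
  names(out) <- rownames(counts)
  out
}

# Individual-level predictor columns, in dataset order.
.ind_predictors <- function() {
  c("x_co", "age", "male", "working", "history", "householder",
    "closeness", "bmi")
}

# Household-level predictor columns.
.hh_predictors <- function() c("deprivation", "hh_closeness")

#' Default structural coefficients
#'
#' Individual-level (`beta`) and household-level (`gamma`) regression
#' coefficients of the latent morbidity factor, typical of an adult
#' household survey; generator ground truth unless overridden.
#'
#' @return List with numeric vectors `beta` (length 8, named as the
#'   individual-level predictor columns) and `gamma` (length 2).
#' @export
ghq_structural <- function() {
  list(
    beta = stats::setNames(
      c(0.020, -0.001, -0.026, -0.019, 0.076, 0.028, -0.056, 0.002),
      .ind_predictors()),
    gamma = stats::setNames(c(0.004, -0.013), .hh_predictors())
  )
}

#' Hypothesised signs of the structural coefficients
#'
#' Directions for one-sided tests of the predictor effects: morbidity is
#' expected to rise with a co-resident's or one's own mental-health
#' history, householder status, obesity and deprivation, and to fall with
#' age, male gender, working status and closeness to other people.
#'
#' @return Named numeric vector of +1/-1 over all ten predictors.
#' @export
ghq_hypotheses <- function() {
  stats::setNames(
    c(+1, -1, -1, -1, +1, +1, -1, +1, +1, -1),
    c(.ind_predictors(), .hh_predictors()))
}
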