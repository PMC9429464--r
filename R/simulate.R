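#' Simulation configuration for clustered ordinal questionnaire data
#'
#' Assembles and validates the ground-truth parameters of the generating
#' model: households of two or more adults share a household-level latent
#' morbidity factor (a random intercept for the individual factor), each
#' member's latent factor drives twelve ordinal items through an ordinal
#' probit measurement model, and both levels carry observed predictors.
#'
#' The generating equations are
#' \deqn{\eta_j^{HH} = \gamma' Z_j + u_j, \quad u_j \sim N(0, \psi_{HH})}
#' \deqn{\eta_{ij} = \beta' X_{ij} + \eta_j^{HH} + e_{ij}, \quad
#'       e_{ij} \sim N(0, \psi_{Ind})}
#' \deqn{Y^*_{pij} = \lambda_p \eta_{ij} + \epsilon_{pij}, \quad
#'       \epsilon \sim N(0, \Theta)}
#' with \eqn{Y_{pij} = c} iff \eqn{Y^*_{pij}} falls between cut-points
#' \eqn{\tau_{p,c-1}} and \eqn{\tau_{p,c}}.
#'
#' @param n_households Number of households to generate.
#' @param household_sizes Integer vector of possible household sizes (all
#'   at least 2).
#' @param size_probs Probabilities for `household_sizes`.
#' @param loadings Numeric vector of 12 factor loadings; the first must be
#'   1 (scale anchor).
#' @param thresholds List of 12 strictly increasing cut-point vectors
#'   (3 cuts for 4 categories) on the standard-normal scale.
#' @param psi_ind,psi_hh Latent residual variances (individual / household),
#'   both non-negative.
#' @param beta Named individual-level coefficients over
#'   `x_co, age, male, working, history, householder, closeness, bmi`.
#' @param gamma Named household-level coefficients over
#'   `deprivation, hh_closeness`.
#' @param theta Indicator residual structure: `NULL` (default) for
#'   delta-style scaling in which each residual variance is chosen so that
#'   the latent response has unit variance at the generating parameters
#'   (thresholds are then standard-normal cut-points); a length-12 vector
#'   of variances; or a 12x12 positive semi-definite covariance matrix.
#' @param missing_rate MCAR missingness proportion in `[0, 1)` applied by
#'   [simulate_households()] after generation (0 = none).
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @return An object of class `sim_config`.
#' @seealso [simulate_households()]
#' @export
sim_config <- function(n_households = 888,
                       household_sizes = 2:4,
                       size_probs = c(0.7, 0.2, 0.1),
                       loadings = ghq_loadings(),
                       thresholds = ghq_thresholds(),
                       psi_ind = 0.013,
                       psi_hh = 0.003,
                       beta = ghq_structural()$beta,
                       gamma = ghq_structural()$gamma,
                       theta = NULL,
                       missing_rate = 0,
                       seed = 1L) {
  if (!is.numeric(n_households) || n_households < 1)
    stop("n_households must be a positive count")
  if (any(household_sizes < 2))
    stop("household_sizes: all household sizes must be >= 2")
  if (length(size_probs) != length(household_sizes) || any(size_probs < 0))
    stop("size_probs must be non-negative and match household_sizes")
  if (length(loadings) != 12L)
    stop("loadings must have length 12")
  if (abs(loadings[1] - 1) > 1e-12)
    stop("loadings: first loading must be fixed to 1")
  if (!is.list(thresholds) || length(thresholds) != 12L)
    stop("thresholds must be a list of 12 cut-point vectors")
  for (p in seq_along(thresholds)) {
    tau <- thresholds[[p]]
    if (any(diff(tau) <= 0))
      stop(sprintf("thresholds: cut-points for item %d are not strictly increasing", p))
  }
  if (psi_ind < 0) stop("psi_ind must be >= 0")
  if (psi_hh < 0) stop("psi_hh must be >= 0")
  beta <- .check_named(beta, .ind_predictors(), "beta")
  gamma <- .check_named(gamma, .hh_predictors(), "gamma")
  if (!is.null(theta)) {
    if (is.matrix(theta)) {
      if (!isSymmetric(unname(theta)) || nrow(theta) != 12L)
        stop("theta matrix must be symmetric 12x12")
      ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) stop("theta must be positive semi-definite")
    } else if (length(theta) == 12L) {
      if (any(theta < 0)) stop("theta variances must be >= 0")
    } else stop("theta must be NULL, a length-12 vector, or a 12x12 matrix")
  }
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(list(
    n_households = as.integer(n_households),
    household_sizes = as.integer(household_sizes),
    size_probs = size_probs / sum(size_probs),
    loadings = unname(loadings),
    thresholds = unname(thresholds),
    psi_ind = psi_ind, psi_hh = psi_hh,
    beta = beta, gamma = gamma, theta = theta,
    missing_rate = missing_rate,
    seed = as.integer(seed)), class = "sim_config")
}

.check_named <- function(x, nms, what) {
  if (length(x) != length(nms))
    stop(sprintf("%s must have length %d", what, length(nms)))
  if (!is.null(names(x)) && !all(names(x) == nms)) {
    if (!setequal(names(x), nms))
      stop(sprintf("%s names must be %s", what, paste(nms, collapse = ", ")))
    x <- x[nms]
  }
  stats::setNames(as.numeric(x), nms)
}

# Truncated-normal draws on [lo, Inf) via inverse CDF.
.rtnorm_lower <- function(n, mean, sd, lo) {
  u <- stats::runif(n, stats::pnorm((lo - mean) / sd), 1)
  mean + sd * stats::qnorm(u)
}

#' Generate a synthetic clustered household survey
#'
#' Draws households, predictors, two-level latent morbidity scores and
#' ordinal item responses from the generating model described in
#' [sim_config()].  Predictor distributions default to margins typical of
#' an English adult household survey: age ~ N(55.8, 18.4^2) truncated at
#' 16, 49.7% male, 46.4% working, a 24.1% lifetime prevalence of common
#' mental disorder, householder status, 1-5 closeness to other people, BMI
#' ~ N(26.7, 5.3^2), household deprivation quintiles, and household
#' closeness constructed as the household mean of members' closeness plus
#' noise.  The co-resident flag `x_co` is *derived* from other members'
#' history (never sampled), preserving its logical dependence.
#'
#' @param config A [sim_config()] object.
#' @return A `household_data` data frame (one row per individual) with
#'   columns `household`, `person`, `y1`..`y12`, the eight individual and
#'   two household predictors, plus attributes `truth` (generating
#'   parameters and the realised latent scores `eta_ind`, `eta_hh`,
#'   residuals `u`, `e`) and `config`.
#' @export
simulate_households <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_households
  sizes <- sample(config$household_sizes, J, replace = TRUE,
                  prob = config$size_probs)
  N <- sum(sizes)
  hh <- rep(seq_len(J), sizes)

  deprivation <- sample(1:5, J, replace = TRUE,
                        prob = c(549, 500, 458, 352, 284) / 2143)
  age <- .rtnorm_lower(N, 55.76, 18.38, 16)
  male <- stats::rbinom(N, 1, 0.497)
  working <- stats::rbinom(N, 1, 0.464)
  history <- stats::rbinom(N, 1, 0.241)
  first <- !duplicated(hh)
  householder <- ifelse(first, 1L, stats::rbinom(N, 1, 0.7))
  closeness <- sample(1:5, N, replace = TRUE,
                      prob = c(22, 102, 616, 886, 370) / 1996)
  bmi <- stats::rnorm(N, 26.72, 5.3)
  hh_close_mean <- tapply(closeness, hh, mean)
  hh_closeness <- pmin(pmax(hh_close_mean + stats::rnorm(J, 0, 0.3), 1), 5)

  dat <- data.frame(
    household = hh,
    person = stats::ave(hh, hh, FUN = seq_along),
    age = age, male = male, working = working, history = history,
    householder = householder, closeness = closeness, bmi = bmi,
    deprivation = deprivation[hh], hh_closeness = hh_closeness[hh])
  dat$x_co <- .coresident_flag(dat$household, dat$history)
  dat <- dat[, c("household", "person", "x_co", "age", "male", "working",
                 "history", "householder", "closeness", "bmi",
                 "deprivation", "hh_closeness")]

  Z <- cbind(deprivation, as.numeric(hh_closeness))
  X <- as.matrix(dat[, .ind_predictors()])
  u <- stats::rnorm(J, 0, sqrt(config$psi_hh))
  eta_hh <- drop(Z %*% config$gamma) + u
  e <- stats::rnorm(N, 0, sqrt(config$psi_ind))
  eta_ind <- drop(X %*% config$beta) + eta_hh[hh] + e

  lam <- config$loadings
  theta <- config$theta
  if (is.null(theta)) {
    v_eta <- stats::var(eta_ind)
    theta <- 1 - lam^2 * v_eta
    if (any(theta <= 0))
      stop("delta-scaled residual variances are non-positive (latent ",
           "variance too large for the loadings); supply theta explicitly")
  }
  if (is.matrix(theta)) {
    eps <- matrix(stats::rnorm(N * 12), N, 12) %*%
      chol(theta + diag(1e-12, 12))
  } else {
    eps <- matrix(stats::rnorm(N * 12), N, 12) %*% diag(sqrt(theta))
  }
  ystar <- outer(eta_ind, lam) + eps
  for (p in 1:12) {
    cuts <- c(-Inf, config$thresholds[[p]], Inf)
    dat[[paste0("y", p)]] <- as.integer(cut(ystar[, p], cuts, labels = FALSE))
  }
  dat <- dat[, c("household", "person", paste0("y", 1:12),
                 .ind_predictors(), .hh_predictors())]
  class(dat) <- c("household_data", "data.frame")
  attr(dat, "truth") <- list(
    loadings = lam, thresholds = config$thresholds, theta = theta,
    psi_ind = config$psi_ind, psi_hh = config$psi_hh,
    beta = config$beta, gamma = config$gamma,
    eta_ind = eta_ind, eta_hh = eta_hh, u = u, e = e)
  attr(dat, "config") <- config
  if (config$missing_rate > 0)
    dat <- apply_missingness(dat, config$missing_rate,
                             seed = config$seed + 1L)
  dat
}

.coresident_flag <- function(household, history) {
  sizes <- table(household)
  if (any(sizes < 2))
    stop("co-resident flag undefined: household(s) with a single member: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  n_hist <- tapply(history, household, sum)[as.character(household)]
  as.integer((n_hist - history) > 0)
}

#' Derive the co-resident mental-health-history flag
#'
#' Sets `x_co = 1` for an individual iff at least one *other* member of the
#' same household has a personal history of common mental disorder
#' (`history = 1`); the individual's own history is excluded.  Idempotent.
#'
#' @param data A `household_data` data frame with `household` and `history`.
#' @return The data with `x_co` recomputed.
#' @export
derive_coresident_flag <- function(data) {
  stopifnot(all(c("household", "history") %in% names(data)))
  if (anyNA(data$history))
    stop("history must be observed for all members")
  data$x_co <- .coresident_flag(data$household, data$history)
  data
}

#' Apply MCAR missingness to a household dataset
#'
#' Independently sets each item response and each of the `closeness`,
#' `bmi` and `hh_closeness` cells to `NA` with the given probability,
#' emulating item non-response ahead of listwise deletion.  Reproducible
#' for a fixed seed.
#'
#' @param data A `household_data` data frame.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The data with missing cells.
#' @export
apply_missingness <- function(data, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(data)
  set.seed(seed)
  cols <- intersect(c(paste0("y", 1:12), "closeness", "bmi", "hh_closeness"),
                    names(data))
  for (cl in cols) {
    hit <- stats::runif(nrow(data)) < rate
    data[[cl]][hit] <- NA
  }
  data
}

#' @export
print.household_data <- function(x, ...) {
  cat(sprintf("Household survey data: %d individuals in %d households\n",
              nrow(x), length(unique(x$household))))
  if (!is.null(attr(x, "truth")))
    cat("  (synthetic; ground-truth latent scores stored in attr 'truth')\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}
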