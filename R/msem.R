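#' Measurement model for the latent morbidity factor
#'
#' Bundles the fixed measurement part used by [msem()]: loadings,
#' per-item thresholds and indicator residual variances.  By the scale
#' convention of the package the first loading is 1 and thresholds are on
#' the standard-normal (delta) scale; the constructor checks shapes and
#' monotone thresholds but deliberately does not force `loadings[1] == 1`,
#' so degenerate measurement parts can be built for testing.
#'
#' @param loadings Numeric vector of loadings.
#' @param thresholds List of increasing cut-point vectors, one per item.
#' @param theta Indicator residual variances (positive), one per item.
#' @return Object of class `measurement_model`.
#' @export
measurement_model <- function(loadings, thresholds, theta) {
  K <- length(loadings)
  stopifnot(length(thresholds) == K, length(theta) == K)
  for (p in seq_len(K))
    if (any(diff(thresholds[[p]]) <= 0))
      stop(sprintf("thresholds for item %d not strictly increasing", p))
  if (any(theta <= 0)) stop("theta must be positive")
  structure(list(loadings = unname(as.numeric(loadings)),
                 thresholds = lapply(thresholds, as.numeric),
                 theta = unname(as.numeric(theta))),
            class = "measurement_model")
}

#' Build a measurement model from a DWLS CFA fit
#'
#' Takes loadings from the CFA, thresholds from the polychoric stage, and
#' derives residual variances under the delta convention
#' (\eqn{\theta_p = 1 - \lambda_p^2 \hat\psi}); variances are floored at
#' 0.02 with a warning if a Heywood-like loading drives them negative.
#'
#' @param fit A [cfa_dwls()] fit.
#' @param polymat The [polychoric()] object the fit used.
#' @return A [measurement_model()].
#' @export
measurement_from_cfa <- function(fit, polymat) {
  stopifnot(inherits(fit, "cfa_dwls"), inherits(polymat, "polychoric"))
  theta <- 1 - fit$loadings^2 * fit$psi
  if (any(theta <= 0)) {
    warning("non-positive delta-scale residual variance floored at 0.02")
    theta <- pmax(theta, 0.02)
  }
  measurement_model(fit$loadings, polymat$thresholds, theta)
}

# Gauss-Hermite rule rescaled for N(0,1) expectations: E f(Z) ~ sum w f(x)
.gh_rule <- function(n) {
  gq <- statmod::gauss.quad(n, "hermite")
  list(x = sqrt(2) * gq$nodes, w = gq$weights / sqrt(pi))
}

# Prepare listwise-complete, household-sorted arrays for the C++ kernel.
# The individual design matrix always carries a leading intercept column:
# with thresholds fixed at their stage-1 estimates, a free structural
# intercept absorbs the latent mean (free thresholds and a latent
# intercept are not separately identified, so exactly one is estimated).
.msem_data <- function(data, items, predictors, hh_predictors) {
  cols <- c(items, predictors, hh_predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[, cols, drop = FALSE])
  d <- data[keep, , drop = FALSE]
  size <- table(d$household)
  d <- d[d$household %in% names(size)[size >= 2], , drop = FALSE]
  if (nrow(d) == 0) stop("no complete households of size >= 2 remain")
  d <- d[order(d$household), , drop = FALSE]
  hh_ids <- unique(d$household)
  hh <- match(d$household, hh_ids)
  len <- as.integer(table(hh))
  start <- c(0L, cumsum(len)[-length(len)])
  Y <- as.matrix(d[, items, drop = FALSE])
  storage.mode(Y) <- "integer"
  X <- cbind("(Intercept)" = 1, as.matrix(d[, predictors, drop = FALSE]))
  Zfull <- as.matrix(d[, hh_predictors, drop = FALSE])
  Z <- Zfull[start + 1L, , drop = FALSE]
  list(Y = Y, X = X, Z = Z, Zfull = Zfull, hh = hh, hh_ids = hh_ids,
       start = start, len = len, n = nrow(d), J = length(hh_ids),
       dropped = sum(!keep) + (sum(keep) - nrow(d)))
}

#' Fit the two-level latent-factor structural model
#'
#' Full-information maximum likelihood for the random-intercept latent
#' factor model: a household-level latent morbidity factor (regressed on
#' household predictors) acts as the intercept of each member's
#' individual factor (regressed on individual predictors), which drives
#' the ordinal items through a fixed ordinal-probit measurement model.
#' The marginal likelihood integrates the household residual
#' \eqn{u_j \sim N(0,\psi_{HH})} and each member's residual
#' \eqn{e_{ij} \sim N(0,\psi_{Ind})} by nested Gauss-Hermite quadrature;
#' variances are optimised on the log scale so they stay non-negative,
#' with estimates below 1e-7 reported as boundary solutions.
#'
#' By default the measurement part (loadings, thresholds, residual
#' variances) is fixed — typically at [measurement_from_cfa()] estimates —
#' and only the structural parameters are estimated (`joint = TRUE` frees
#' the loadings too, keeping the first at 1).  Loadings are invariant
#' across the two levels: one loading vector serves both.
#'
#' @param data A `household_data` data frame (or compatible); incomplete
#'   rows are removed listwise and households reduced below 2 members are
#'   dropped.
#' @param measurement A [measurement_model()].
#' @param predictors,hh_predictors Individual- and household-level
#'   predictor columns (character; may be `character(0)`).
#' @param items Item columns, default `y1`..`y12`.
#' @param null If `TRUE`, fit the structural null model (all regression
#'   coefficients constrained to zero; only the variance components are
#'   estimated).
#' @param nodes Quadrature nodes per dimension (>= 3; default 15).
#' @param joint Also estimate loadings 2..K by ML.
#' @param start Optional starting values on the working scale
#'   (beta, gamma, log psi_ind, log psi_hh, then free loadings if joint).
#' @param se Compute standard errors from the numerical Hessian.
#' @return An object of class `msem`.
#' @export
msem <- function(data, measurement,
                 predictors = .ind_predictors(),
                 hh_predictors = .hh_predictors(),
                 items = paste0("y", 1:12),
                 null = FALSE, nodes = 15, joint = FALSE,
                 start = NULL, se = TRUE) {
  stopifnot(inherits(measurement, "measurement_model"))
  if (nodes < 3) stop("need at least 3 quadrature nodes")
  if (null) { predictors <- character(0); hh_predictors <- character(0) }
  dd <- .msem_data(data, items, predictors, hh_predictors)
  px <- ncol(dd$X); pz <- ncol(dd$Z)
  xnames <- colnames(dd$X)
  gh <- .gh_rule(nodes)
  K <- length(measurement$loadings)

  # optimise on standardized predictors (unit working scale), then map back
  Xs <- dd$X; Zs <- dd$Z
  mu_x <- sd_x <- numeric(0)
  if (px > 1) {
    mu_x <- colMeans(dd$X[, -1, drop = FALSE])
    sd_x <- pmax(apply(dd$X[, -1, drop = FALSE], 2, stats::sd), 1e-12)
    Xs[, -1] <- sweep(sweep(dd$X[, -1, drop = FALSE], 2, mu_x), 2, sd_x, "/")
  }
  mu_z <- sd_z <- numeric(0)
  if (pz > 0) {
    mu_z <- colMeans(dd$Z)
    sd_z <- pmax(apply(dd$Z, 2, stats::sd), 1e-12)
    Zs <- sweep(sweep(dd$Z, 2, mu_z), 2, sd_z, "/")
  }

  kernel <- function(par, want_grad) {
    beta <- par[seq_len(px)]
    gamma <- par[px + seq_len(pz)]
    lpi <- par[px + pz + 1]; lph <- par[px + pz + 2]
    lam <- measurement$loadings
    if (joint) lam <- c(lam[1], par[px + pz + 2 + seq_len(K - 1)])
    msem_loglik_cpp(dd$Y, Xs, Zs, dd$start, dd$len,
                    lam, measurement$thresholds, measurement$theta,
                    beta, gamma, exp(lpi), exp(lph),
                    gh$x, gh$w, want_grad, joint)
  }
  cache <- new.env()
  fngr <- function(par) {
    key <- paste(format(par, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      out <- kernel(par, TRUE)
      g <- out$grad
      if (joint) g <- g[-(px + pz + 3)]  # drop fixed first loading
      cache$key <- key; cache$f <- out$loglik; cache$g <- g
    }
    list(f = cache$f, g = cache$g)
  }
  nll <- function(par) -fngr(par)$f
  ngr <- function(par) -fngr(par)$g

  npar <- px + pz + 2 + if (joint) K - 1 else 0
  if (is.null(start)) {
    start <- c(rep(0, px + pz), log(0.05), log(0.02),
               if (joint) measurement$loadings[-1])
    if (!null && (px + pz) > 0) {
      # variance components from a quick null fit make good starts
      nf <- msem(data, measurement, null = TRUE, nodes = max(7, nodes %/% 2),
                 items = items, se = FALSE)
      start[1] <- nf$coefficients[["(Intercept)"]]
      start[px + pz + 1] <- log(max(nf$psi[["ind"]], 1e-6))
      start[px + pz + 2] <- log(max(nf$psi[["hh"]], 1e-6))
    }
  }
  lower <- c(rep(-Inf, px + pz), -18, -18, if (joint) rep(-Inf, K - 1))
  opt <- stats::optim(start, nll, ngr, method = "L-BFGS-B",
                      lower = lower,
                      control = list(maxit = 500, factr = 1e7))
  par <- opt$par
  # back-transform to the natural predictor scale
  Tm <- diag(npar)
  if (px > 1) {
    Tm[cbind(1 + seq_len(px - 1), 1 + seq_len(px - 1))] <- 1 / sd_x
    Tm[1, 1 + seq_len(px - 1)] <- -mu_x / sd_x
  }
  if (pz > 0) {
    Tm[cbind(px + seq_len(pz), px + seq_len(pz))] <- 1 / sd_z
    Tm[1, px + seq_len(pz)] <- -mu_z / sd_z
  }
  par_nat <- drop(Tm %*% par)
  par_nat[px + pz + 1:2] <- par[px + pz + 1:2]   # log psi: untouched
  beta <- stats::setNames(par_nat[seq_len(px)], xnames)
  gamma <- stats::setNames(par_nat[px + seq_len(pz)], hh_predictors)
  psi <- c(ind = exp(par[px + pz + 1]), hh = exp(par[px + pz + 2]))
  boundary <- psi < 1e-7
  lam_hat <- measurement$loadings
  if (joint) lam_hat <- c(lam_hat[1], par[px + pz + 2 + seq_len(K - 1)])

  vc <- NULL; separ <- rep(NA_real_, npar)
  if (se) {
    H <- tryCatch(stats::optimHess(par, nll, ngr), error = function(e) NULL)
    vc_work <- if (!is.null(H))
      tryCatch(solve(H), error = function(e) NULL) else NULL
    if (!is.null(vc_work)) {
      # map to the natural predictor scale, then the delta method for the
      # variance components
      Dg <- rep(1, npar)
      Dg[px + pz + 1] <- psi[["ind"]]
      Dg[px + pz + 2] <- psi[["hh"]]
      vc <- (Tm %*% vc_work %*% t(Tm)) * tcrossprod(Dg)
      nms <- c(xnames, hh_predictors, "psi_ind", "psi_hh",
               if (joint) paste0("lambda", 2:K))
      dimnames(vc) <- list(nms, nms)
      separ <- sqrt(pmax(diag(vc), 0))
    } else warning("Hessian not invertible; standard errors unavailable")
  }
  ll <- fngr(par)$f
  obj <- structure(list(
    coefficients = c(beta, gamma),
    psi = psi, loadings = lam_hat,
    se = stats::setNames(separ,
      c(xnames, hh_predictors, "psi_ind", "psi_hh",
        if (joint) paste0("lambda", 2:K))),
    vcov = vc, loglik = ll, npar = npar,
    n = dd$n, n_households = dd$J, dropped = dd$dropped,
    aic = -2 * ll + 2 * npar, bic = -2 * ll + npar * log(dd$n),
    nodes = nodes, null = null, joint = joint,
    boundary = boundary, converged = opt$convergence == 0,
    optim = opt[c("counts", "convergence", "message")],
    measurement = measurement,
    predictors = predictors, hh_predictors = hh_predictors,
    items = items, data = dd, call = match.call()),
    class = "msem")
  if (!obj$converged) warning("optimizer did not report convergence: ",
                              opt$message)
  obj
}

#' Fit the structural null model
#'
#' Convenience wrapper for [msem()] with all structural coefficients
#' constrained to zero; returns the baseline variance components
#' \eqn{\psi^{(Ind)}_{Null}, \psi^{(HH)}_{Null}} used for latent ICC and
#' explained-variance computations.
#'
#' @inheritParams msem
#' @param ... Passed to [msem()].
#' @return An `msem` object with `null = TRUE`.
#' @export
msem_null <- function(data, measurement, ...) {
  msem(data, measurement, null = TRUE, ...)
}

#' Marginal log-likelihood of a single household
#'
#' Exposes the quadrature kernel for one household: the log of the joint
#' probability of its members' item responses, integrating the household
#' residual (outer) and each member's residual (inner).
#'
#' @param y Integer matrix (members x items) of ordinal responses.
#' @param measurement A [measurement_model()].
#' @param x Optional numeric matrix (members x p) of individual
#'   predictors, with coefficient vector `beta`.
#' @param z Optional numeric vector of household predictors, with `gamma`.
#' @param beta,gamma Structural coefficients (default none).
#' @param psi_ind,psi_hh Latent residual variances.
#' @param nodes Quadrature nodes per dimension.
#' @return Scalar log-probability.
#' @export
household_loglik <- function(y, measurement, x = NULL, z = NULL,
                             beta = numeric(0), gamma = numeric(0),
                             psi_ind = 0, psi_hh = 0, nodes = 15) {
  y <- as.matrix(y); storage.mode(y) <- "integer"
  ni <- nrow(y)
  if (is.null(x)) x <- matrix(0, ni, 0)
  z <- matrix(if (is.null(z)) numeric(0) else z, nrow = 1)
  gh <- .gh_rule(nodes)
  msem_loglik_cpp(y, as.matrix(x), z, 0L, ni,
                  measurement$loadings, measurement$thresholds,
                  measurement$theta, beta, gamma, psi_ind, psi_hh,
                  gh$x, gh$w, FALSE, FALSE)$loglik
}

#' Intraclass correlation of the latent factor
#'
#' Share of latent-morbidity variance attributable to between-household
#' differences: \eqn{\psi^{(HH)} / (\psi^{(HH)} + \psi^{(Ind)})}.
#'
#' @param psi_hh,psi_ind Non-negative variance components (not both zero).
#' @return Proportion in `[0, 1]`.
#' @export
latent_icc <- function(psi_hh, psi_ind) {
  if (psi_hh < 0 || psi_ind < 0) stop("variance components must be >= 0")
  if (psi_hh + psi_ind == 0) stop("ICC undefined: both components zero")
  psi_hh / (psi_hh + psi_ind)
}

#' Proportion of latent variance explained by the predictors
#'
#' \eqn{(\psi_{Null} - \psi_{Full}) / \psi_{Null}} at either level; a
#' negative value (full-model residual exceeding the null's) is returned
#' with a warning rather than suppressed.
#'
#' @param psi_null Null-model variance component (> 0).
#' @param psi_full Full-model variance component.
#' @return Proportion (possibly negative).
#' @export
explained_variance <- function(psi_null, psi_full) {
  if (psi_null <= 0) stop("psi_null must be > 0")
  out <- (psi_null - psi_full) / psi_null
  if (out < 0) warning("negative explained variance: full-model residual ",
                       "variance exceeds the null model's")
  out
}

#' Directional hypothesis tests of the structural parameters
#'
#' For each parameter with a hypothesised sign, reports the Wald z
#' statistic, the one-sided p-value in the hypothesised direction, the
#' two-sided p-value, and a significance tier
#' (`a`: p < 0.01, `b`: p < 0.05, `c`: p < 0.1, `ns` otherwise).
#' `psi_hh` may be included among the directions (sign +1) to test for
#' between-household variance.
#'
#' @param fit An [msem()] fit with standard errors.
#' @param directions Named vector of +1/-1; default [ghq_hypotheses()].
#' @return Data frame: estimate, se, z, p_one_sided, p_two_sided, tier.
#' @export
hypothesis_tests <- function(fit, directions = ghq_hypotheses()) {
  stopifnot(inherits(fit, "msem"))
  est <- c(fit$coefficients, psi_hh = unname(fit$psi[["hh"]]))
  se <- fit$se[c(names(fit$coefficients), "psi_hh")]
  names(se) <- names(est)
  use <- intersect(names(directions), names(est))
  if (!length(use)) stop("no hypothesised parameters found in the fit")
  dir <- directions[use]
  z <- est[use] / se[use]
  bad <- !is.finite(z)
  if (any(bad)) warning("zero or missing SE for: ",
                        paste(use[bad], collapse = ", "))
  p1 <- ifelse(dir > 0, stats::pnorm(z, lower.tail = FALSE), stats::pnorm(z))
  p2 <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  tier <- cut(p1, c(-Inf, 0.01, 0.05, 0.1, Inf),
              labels = c("a", "b", "c", "ns"))
  data.frame(parameter = use, estimate = unname(est[use]),
             se = unname(se[use]), direction = unname(dir),
             z = unname(z), p_one_sided = unname(p1),
             p_two_sided = unname(p2),
             tier = as.character(tier), row.names = NULL)
}

#' Standardized coefficients and loadings
#'
#' Coefficients are scaled by SD(predictor)/SD(latent factor), with the
#' latent SD taken from the model-implied total variance (variance of the
#' fitted linear predictor over individuals plus both residual
#' components); household predictors use their individual-level
#' expansion.  Standardized loadings are
#' \eqn{\lambda_p\,SD(\eta)/SD(Y^*_p)} with
#' \eqn{Var(Y^*_p) = \lambda_p^2 Var(\eta) + \theta_p}.
#'
#' @param fit An [msem()] fit.
#' @return List with `beta`, `gamma`, `loadings`, and `sd_eta`.
#' @export
standardized_coefs <- function(fit) {
  stopifnot(inherits(fit, "msem"))
  dd <- fit$data
  px <- ncol(dd$X); pz <- ncol(dd$Z)
  lin <- drop(dd$X %*% fit$coefficients[seq_len(px)])
  if (pz) lin <- lin + drop(dd$Zfull %*% fit$coefficients[px + seq_len(pz)])
  v_eta <- stats::var(lin) + fit$psi[["ind"]] + fit$psi[["hh"]]
  sd_eta <- sqrt(v_eta)
  sx <- if (px > 1) apply(dd$X[, -1, drop = FALSE], 2, stats::sd) else
    numeric(0)
  sz <- if (pz) apply(dd$Zfull, 2, stats::sd) else numeric(0)
  if (any(c(sx, sz) == 0)) warning("zero-variance predictor")
  lam <- fit$loadings
  list(beta = fit$coefficients[1 + seq_len(px - 1)] * sx / sd_eta,
       gamma = fit$coefficients[px + seq_len(pz)] * sz / sd_eta,
       loadings = lam * sd_eta / sqrt(lam^2 * v_eta + fit$measurement$theta),
       sd_eta = sd_eta)
}

#' @export
print.msem <- function(x, digits = 4, ...) {
  cat(sprintf("Two-level latent-factor model (%s; FIML, %d-node quadrature)\n",
              if (x$null) "structural null" else "full structural", x$nodes))
  cat(sprintf("  %d individuals in %d households; logLik %.2f, AIC %.1f, BIC %.1f\n",
              x$n, x$n_households, x$loglik, x$aic, x$bic))
  if (length(x$coefficients)) {
    cat("Coefficients:\n")
    print(round(x$coefficients, digits))
  }
  cat(sprintf("Variance components: psi_ind = %.4f, psi_hh = %.4f%s\n",
              x$psi[["ind"]], x$psi[["hh"]],
              if (any(x$boundary)) "  [boundary]" else ""))
  invisible(x)
}

#' @export
summary.msem <- function(object, ...) {
  est <- c(object$coefficients, object$psi)
  names(est) <- c(names(object$coefficients), "psi_ind", "psi_hh")
  se <- object$se[names(est)]
  z <- est / se
  tab <- data.frame(estimate = est, se = se,
                    ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se,
                    z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  std <- if (!object$null) standardized_coefs(object) else NULL
  if (!is.null(std)) {
    sv <- c(std$beta, std$gamma)
    tab$standardized <- sv[match(rownames(tab), names(sv))]
  }
  out <- list(table = tab, fit = object)
  class(out) <- "summary.msem"
  out
}

#' @export
print.summary.msem <- function(x, digits = 4, ...) {
  print(x$fit)
  cat("\n")
  print(round(x$table, digits))
  invisible(x)
}

#' @export
coef.msem <- function(object, ...) object$coefficients

#' @export
vcov.msem <- function(object, ...) object$vcov

#' @export
logLik.msem <- function(object, ...) {
  structure(object$loglik, df = object$npar, nobs = object$n,
            class = "logLik")
}

#' @export
confint.msem <- function(object, parm, level = 0.95, ...) {
  est <- c(object$coefficients, object$psi)
  names(est) <- c(names(object$coefficients), "psi_ind", "psi_hh")
  se <- object$se[names(est)]
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - q * se, est + q * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2)),
                        "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Parametric simulation from a fitted two-level model
#'
#' Draws new item responses conditional on the observed predictors and
#' household structure of the fitting data (a parametric bootstrap):
#' household and individual residuals are drawn at the fitted variance
#' components, latent responses at the fitted measurement part.
#'
#' @param object An [msem()] fit.
#' @param nsim Number of datasets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `nsim` data frames shaped like the fitting data.
#' @export
simulate.msem <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dd <- object$data
  meas <- object$measurement
  px <- ncol(dd$X); pz <- ncol(dd$Z)
  m <- drop(dd$X %*% object$coefficients[seq_len(px)])
  if (pz) m <- m + drop(dd$Zfull %*%
                          object$coefficients[px + seq_len(pz)])
  K <- length(meas$loadings)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    u <- stats::rnorm(dd$J, 0, sqrt(object$psi[["hh"]]))
    e <- stats::rnorm(dd$n, 0, sqrt(object$psi[["ind"]]))
    eta <- m + u[dd$hh] + e
    ystar <- outer(eta, meas$loadings) +
      matrix(stats::rnorm(dd$n * K), dd$n, K) %*% diag(sqrt(meas$theta))
    df <- data.frame(household = dd$hh_ids[dd$hh],
                     person = stats::ave(dd$hh, dd$hh, FUN = seq_along))
    for (p in seq_len(K)) {
      cuts <- c(-Inf, meas$thresholds[[p]], Inf)
      df[[object$items[p]]] <- as.integer(cut(ystar[, p], cuts,
                                              labels = FALSE))
    }
    if (px > 1) df <- cbind(df, as.data.frame(dd$X[, -1, drop = FALSE]))
    if (pz) df <- cbind(df, as.data.frame(dd$Zfull))
    class(df) <- c("household_data", "data.frame")
    out[[s]] <- df
  }
  if (nsim == 1) out[[1]] else out
}

#' Empirical Bayes latent morbidity scores
#'
#' Posterior means of the individual latent factor
#' \eqn{E[\eta_{ij} | Y_j]} (and of the household factor) at the fitted
#' parameters, computed on the same quadrature grid as the likelihood.
#'
#' @param object An [msem()] fit.
#' @param ... Unused.
#' @return Data frame with `household`, `person`, `eta_ind` and `eta_hh`.
#' @export
predict.msem <- function(object, ...) {
  dd <- object$data
  meas <- object$measurement
  gh <- .gh_rule(object$nodes)
  Q <- length(gh$x)
  s_hh <- sqrt(object$psi[["hh"]]); s_in <- sqrt(object$psi[["ind"]])
  px <- ncol(dd$X); pz <- ncol(dd$Z)
  m <- drop(dd$X %*% object$coefficients[seq_len(px)])
  if (pz) m <- m + drop(dd$Zfull %*% object$coefficients[px + seq_len(pz)])
  K <- length(meas$loadings)
  lam <- meas$loadings; sdp <- sqrt(meas$theta)
  logg_eta <- function(eta) {     # N-vector eta -> N-vector log g_i(eta)
    out <- rep(0, length(eta))
    for (p in seq_len(K)) {
      cuts <- c(-Inf, meas$thresholds[[p]], Inf)
      cc <- dd$Y[, p]
      hi <- (cuts[cc + 1] - lam[p] * eta) / sdp[p]
      lo <- (cuts[cc] - lam[p] * eta) / sdp[p]
      out <- out + log(pmax(stats::pnorm(hi) - stats::pnorm(lo), 1e-300))
    }
    out
  }
  A <- matrix(0, dd$n, Q)     # inner integral per (individual, outer node)
  Ce <- matrix(0, dd$n, Q)    # inner integral weighted by e
  for (a in seq_len(Q)) for (b in seq_len(Q)) {
    g <- exp(logg_eta(m + s_hh * gh$x[a] + s_in * gh$x[b]))
    A[, a] <- A[, a] + gh$w[b] * g
    Ce[, a] <- Ce[, a] + gh$w[b] * s_in * gh$x[b] * g
  }
  logA <- log(pmax(A, 1e-300))
  S <- rowsum(logA, dd$hh)                       # J x Q
  Smax <- apply(S, 1, max)
  Qw <- sweep(exp(S - Smax), 2, gh$w, `*`)
  den <- rowSums(Qw)
  post <- Qw / den                               # J x Q posterior over u
  Eu <- drop(post %*% (s_hh * gh$x))
  Ee <- rowSums(post[dd$hh, , drop = FALSE] * Ce / A)
  zg <- if (pz) drop(dd$Z %*% object$coefficients[px + seq_len(pz)]) else
    rep(0, dd$J)
  data.frame(household = dd$hh_ids[dd$hh],
             person = stats::ave(dd$hh, dd$hh, FUN = seq_along),
             eta_ind = m + Eu[dd$hh] + Ee,
             eta_hh = (zg + Eu)[dd$hh])
}

#' Coefficient plot for a fitted two-level model
#'
#' Dot-and-interval display of the standardized structural coefficients
#' with 95% intervals.
#'
#' @param x An [msem()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.msem <- function(x, ...) {
  if (x$null) stop("nothing to plot for a null model")
  std <- standardized_coefs(x)
  est <- c(std$beta, std$gamma)
  scale <- est / x$coefficients
  se <- x$se[names(x$coefficients)] * abs(scale)
  ord <- order(est)
  graphics::plot(est[ord], seq_along(est), xlab = "standardized coefficient",
                 ylab = "", yaxt = "n", pch = 19,
                 xlim = range(c(est - 1.96 * se, est + 1.96 * se)), ...)
  graphics::segments(est[ord] - 1.96 * se[ord], seq_along(est),
                     est[ord] + 1.96 * se[ord], seq_along(est))
  graphics::abline(v = 0, lty = 2)
  graphics::axis(2, at = seq_along(est), labels = names(est)[ord], las = 1,
                 cex.axis = 0.8)
  invisible(x)
}
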