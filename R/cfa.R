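# Lower-triangle pair index (p > q), fixed ordering shared by all
# correlation-vector computations in this file.
.pair_index <- function(K) {
  ij <- which(lower.tri(diag(K)), arr.ind = TRUE)
  colnames(ij) <- c("p", "q")
  ij
}

#' Model-implied correlation matrix of a one-factor ordinal model
#'
#' Under the delta parameterisation the latent responses have unit
#' variance, so the implied correlation between items p and q is
#' \eqn{\lambda_p \lambda_q \psi + \theta_{pq}} with a fixed unit
#' diagonal.  A non-positive-semi-definite implied matrix is flagged with
#' a warning rather than silently accepted.
#'
#' @param loadings Numeric vector of factor loadings.
#' @param psi Factor variance.
#' @param error_cov Optional symmetric matrix of error covariances
#'   (diagonal ignored), or `NULL`.
#' @return Implied correlation matrix with unit diagonal.
#' @export
implied_correlations <- function(loadings, psi, error_cov = NULL) {
  K <- length(loadings)
  S <- tcrossprod(loadings) * psi
  if (!is.null(error_cov)) S <- S + (error_cov - diag(diag(error_cov)))
  diag(S) <- 1
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    warning("implied correlation matrix is not positive semi-definite")
  S
}

# Pack/unpack: par = c(lambda[-1], psi, theta over freed pairs)
.cfa_sigma <- function(par, K, free_idx, ij) {
  lam <- c(1, par[seq_len(K - 1)])
  psi <- par[K]
  sig <- lam[ij[, 1]] * lam[ij[, 2]] * psi
  if (length(free_idx))
    sig[free_idx] <- sig[free_idx] + par[K + seq_along(free_idx)]
  list(sig = sig, lam = lam, psi = psi)
}

# Jacobian d sigma / d par, rows = pairs, cols = free parameters.
.cfa_delta <- function(par, K, free_idx, ij) {
  lam <- c(1, par[seq_len(K - 1)])
  psi <- par[K]
  M <- nrow(ij)
  D <- matrix(0, M, length(par))
  for (j in 2:K) {
    hit <- ij[, 1] == j | ij[, 2] == j
    other <- ifelse(ij[hit, 1] == j, ij[hit, 2], ij[hit, 1])
    D[hit, j - 1] <- lam[other] * psi
  }
  D[, K] <- lam[ij[, 1]] * lam[ij[, 2]]
  if (length(free_idx))
    D[cbind(free_idx, K + seq_along(free_idx))] <- 1
  D
}

#' Fit a one-factor measurement model by diagonally weighted least squares
#'
#' Minimises \eqn{F = (s - \sigma(\theta))' W^{-1} (s - \sigma(\theta))}
#' over the free loadings (the first is fixed to 1 to anchor the latent
#' scale), the factor variance, and any freed error covariances, where `s`
#' is the polychoric correlation vector and `W` the diagonal of its
#' asymptotic variances.  The test statistic is \eqn{\chi^2 = (n-1)\hat F}
#' (plain, uncorrected DWLS); standard errors use
#' \eqn{(\Delta' W^{-1} \Delta)^{-1}/(n-1)}.
#'
#' @param polymat A [polychoric()] object.
#' @param free_cov Optional 2-column matrix/data frame of item pairs
#'   (names or indices) whose error covariances are freely estimated.
#' @param start Optional starting parameter vector.
#' @return Object of class `cfa_dwls` with elements `loadings`, `psi`,
#'   `error_cov` (data frame), `se` (full parameter SE vector), `F`,
#'   `chisq`, `df`, `n`, `indices` (a [fit_indices()] object),
#'   `std_loadings`, `residuals` (pair residual vector), plus internals
#'   used by [modification_indices()].
#' @export
cfa_dwls <- function(polymat, free_cov = NULL, start = NULL) {
  stopifnot(inherits(polymat, "polychoric"))
  K <- ncol(polymat$rho)
  items <- colnames(polymat$rho)
  ij <- .pair_index(K)
  s <- polymat$rho[lower.tri(polymat$rho)]
  w <- polymat$avar[lower.tri(polymat$avar)]
  if (any(!is.finite(w) | w <= 0))
    stop("non-finite or non-positive asymptotic variances in weights ",
         "(boundary polychoric estimates?)")
  free_idx <- integer(0)
  if (!is.null(free_cov)) {
    fc <- as.matrix(free_cov)
    if (is.character(fc)) fc <- matrix(match(fc, items), ncol = 2)
    free_idx <- apply(fc, 1, function(r) {
      p <- max(r); q <- min(r)
      which(ij[, 1] == p & ij[, 2] == q)
    })
    if (anyNA(free_idx) || anyDuplicated(free_idx))
      stop("free_cov contains unknown or duplicated pairs")
  }
  n_free <- (K - 1) + 1 + length(free_idx)
  M <- nrow(ij)
  if (n_free > M)
    stop("model not identified: more free parameters than sample statistics")
  df <- M - n_free

  if (is.null(start)) {
    ed <- eigen(polymat$rho, symmetric = TRUE)
    a <- ed$vectors[, 1] * sqrt(max(ed$values[1], 0.1))
    if (a[1] < 0) a <- -a
    a[1] <- max(a[1], 0.05)
    start <- c((a / a[1])[-1], a[1]^2, rep(0, length(free_idx)))
  }
  obj <- function(par) {
    r <- s - .cfa_sigma(par, K, free_idx, ij)$sig
    sum(r^2 / w)
  }
  grad <- function(par) {
    r <- s - .cfa_sigma(par, K, free_idx, ij)$sig
    D <- .cfa_delta(par, K, free_idx, ij)
    drop(-2 * crossprod(D, r / w))
  }
  opt <- stats::optim(start, obj, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  # Gauss-Newton polish: quadratic convergence near the optimum and exact
  # solution of just-identified (saturated) specifications
  par <- opt$par
  f_cur <- obj(par)
  for (it in seq_len(100)) {
    r <- s - .cfa_sigma(par, K, free_idx, ij)$sig
    D <- .cfa_delta(par, K, free_idx, ij)
    step <- tryCatch(solve(crossprod(D, D / w) + diag(1e-10, length(par)),
                           crossprod(D, r / w)),
                     error = function(e) NULL)
    if (is.null(step)) break
    lam_step <- 1
    repeat {
      cand <- par + lam_step * drop(step)
      f_new <- obj(cand)
      if (f_new <= f_cur || lam_step < 1e-6) break
      lam_step <- lam_step / 2
    }
    if (f_new > f_cur - 1e-15) break
    par <- cand; f_cur <- f_new
  }
  opt$convergence <- 0L
  mod <- .cfa_sigma(par, K, free_idx, ij)
  resid <- s - mod$sig
  Fhat <- sum(resid^2 / w)
  n <- polymat$n
  chisq <- max((n - 1) * Fhat, 0)
  D <- .cfa_delta(par, K, free_idx, ij)
  info <- crossprod(D, D / w)            # Delta' W^-1 Delta
  acov <- tryCatch(solve(info) / (n - 1), error = function(e) NULL)
  se <- if (is.null(acov)) rep(NA_real_, length(par)) else
    sqrt(pmax(diag(acov), 0))
  lam <- mod$lam
  std <- lam * sqrt(max(mod$psi, 0))
  if (any(abs(std) > 1))
    warning("Heywood case: standardized loading exceeds 1 in absolute value")
  Fb <- sum(s^2 / w)
  chisq_b <- (n - 1) * Fb
  idx <- fit_indices(chisq, df, chisq_b, M, n)
  ec <- if (length(free_idx))
    data.frame(item1 = items[ij[free_idx, 2]], item2 = items[ij[free_idx, 1]],
               estimate = par[K + seq_along(free_idx)],
               se = se[K + seq_along(free_idx)])
  else data.frame(item1 = character(), item2 = character(),
                  estimate = numeric(), se = numeric())
  structure(list(
    loadings = stats::setNames(lam, items),
    loadings_se = stats::setNames(c(NA, se[seq_len(K - 1)]), items),
    psi = mod$psi, psi_se = se[K],
    error_cov = ec, std_loadings = stats::setNames(std, items),
    F = Fhat, chisq = chisq, df = df, n = n,
    baseline_chisq = chisq_b, baseline_df = M,
    indices = idx, residuals = resid, weights = w, s = s,
    par = par, se = se, free_idx = free_idx, ij = ij, items = items,
    converged = opt$convergence == 0,
    iterations = opt$counts), class = "cfa_dwls")
}

#' Incremental and absolute fit indices from chi-square statistics
#'
#' Closed forms used throughout the package:
#' \deqn{CFI = 1 - \max(\chi^2-df,0)/\max(\chi^2_b-df_b,\ \chi^2-df,\ 0)}
#' \deqn{TLI = ((\chi^2_b/df_b)-(\chi^2/df)) / ((\chi^2_b/df_b)-1)}
#' \deqn{RMSEA = \sqrt{\max(\chi^2-df,0)/(df\,(n-1))}}
#' \deqn{GFI = 1 - \chi^2/\chi^2_b}
#' (GFI here is the weighted residual-sum-of-squares variant: the
#' baseline discrepancy is the weighted total sum of squares of the
#' sample correlations).  TLI and RMSEA are undefined (`NA`) at `df = 0`.
#'
#' @param chisq,df Model test statistic and degrees of freedom.
#' @param chisq_b,df_b Baseline (independence) model counterparts.
#' @param n Sample size.
#' @return Object of class `fit_indices` (a named list).
#' @export
fit_indices <- function(chisq, df, chisq_b, df_b, n) {
  num <- max(chisq - df, 0)
  den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli <- if (df > 0 && df_b > 0 && chisq_b / df_b != 1)
    ((chisq_b / df_b) - (chisq / df)) / ((chisq_b / df_b) - 1)
  else NA_real_
  rmsea <- if (df > 0) sqrt(max(chisq - df, 0) / (df * (n - 1))) else NA_real_
  gfi <- if (chisq_b > 0) 1 - chisq / chisq_b else NA_real_
  structure(list(cfi = cfi, tli = tli, rmsea = rmsea, gfi = gfi,
                 chisq = chisq, df = df,
                 baseline_chisq = chisq_b, baseline_df = df_b, n = n),
            class = "fit_indices")
}

#' @export
print.fit_indices <- function(x, digits = 3, ...) {
  cat(sprintf("chisq = %.3f on %d df (baseline %.3f on %d df, n = %d)\n",
              x$chisq, x$df, x$baseline_chisq, x$baseline_df, x$n))
  cat(sprintf("CFI = %s  TLI = %s  RMSEA = %s  GFI = %s\n",
              format(round(x$cfi, digits)), format(round(x$tli, digits)),
              format(round(x$rmsea, digits)), format(round(x$gfi, digits))))
  invisible(x)
}

#' Modification indices for fixed-to-zero error covariances
#'
#' Univariate score (Lagrange-multiplier) statistics: the estimated drop
#' in the model chi-square if one currently-fixed error covariance were
#' freed, together with the expected value of the freed parameter (EPC).
#' Parameters already free are excluded.
#'
#' @param fit A [cfa_dwls()] fit.
#' @return Data frame with `item1`, `item2`, `mi`, `epc`, sorted by
#'   decreasing `mi`; class `mod_indices`.
#' @export
modification_indices <- function(fit) {
  stopifnot(inherits(fit, "cfa_dwls"))
  K <- length(fit$loadings)
  ij <- fit$ij
  candidates <- setdiff(seq_len(nrow(ij)), fit$free_idx)
  D <- .cfa_delta(fit$par, K, fit$free_idx, ij)
  w <- fit$weights
  info_ff <- crossprod(D, D / w)
  res <- lapply(candidates, function(k) {
    g <- -2 * fit$residuals[k] / w[k]
    d_j <- numeric(nrow(ij)); d_j[k] <- 1
    H_jj <- 2 / w[k]
    H_jf <- 2 * crossprod(D, d_j / w)      # cross second derivatives
    Heff <- drop(H_jj - t(H_jf) %*% solve(info_ff * 2, H_jf))
    if (!is.finite(Heff) || Heff <= 0) return(NULL)
    mi <- (fit$n - 1) * g^2 / (2 * Heff)
    data.frame(item1 = fit$items[ij[k, 2]], item2 = fit$items[ij[k, 1]],
               mi = mi, epc = -g / Heff)
  })
  drop_null <- !vapply(res, is.null, logical(1))
  if (any(!drop_null))
    warning("singular information; ", sum(!drop_null), " parameter(s) skipped")
  out <- do.call(rbind, res[drop_null])
  out <- out[order(-out$mi), ]
  rownames(out) <- NULL
  class(out) <- c("mod_indices", "data.frame")
  out
}

#' Stepwise freeing of error covariances by modification index
#'
#' Starting from the specified model, repeatedly frees the error
#' covariance with the largest modification index while the largest index
#' exceeds `threshold` (default 3.84, the 5% chi-square-1 critical value)
#' and degrees of freedom remain; reaching `df = 0` stops with a
#' saturation notice.  Each step's statistic, freed pair and fit indices
#' are logged in the audit trail.
#'
#' @param polymat A [polychoric()] object.
#' @param free_cov Starting set of freed pairs (default none).
#' @param threshold Stop once the largest MI is at or below this
#'   (`Inf` returns the starting model untouched).
#' @param max_steps Safety cap on the number of freed covariances.
#' @return List with `fit` (final [cfa_dwls()]), `free_cov` (matrix of
#'   freed pairs), and `trail` (data frame: step, pair, mi, chisq, df,
#'   cfi, rmsea).
#' @export
stepwise_free_covariances <- function(polymat, free_cov = NULL,
                                      threshold = 3.84, max_steps = 66) {
  fc <- if (is.null(free_cov)) NULL else as.matrix(free_cov)
  fit <- cfa_dwls(polymat, fc)
  trail <- data.frame(step = 0L, item1 = NA, item2 = NA, mi = NA,
                      chisq = fit$chisq, df = fit$df,
                      cfi = fit$indices$cfi, rmsea = fit$indices$rmsea)
  step <- 0L
  while (is.finite(threshold) && step < max_steps && fit$df > 0) {
    mi <- modification_indices(fit)
    if (nrow(mi) == 0 || mi$mi[1] <= threshold) break
    step <- step + 1L
    new_pair <- c(mi$item1[1], mi$item2[1])
    fc <- rbind(fc, new_pair, deparse.level = 0)
    fit <- cfa_dwls(polymat, fc)
    trail <- rbind(trail, data.frame(
      step = step, item1 = new_pair[1], item2 = new_pair[2], mi = mi$mi[1],
      chisq = fit$chisq, df = fit$df,
      cfi = fit$indices$cfi, rmsea = fit$indices$rmsea))
    if (fit$df == 0) {
      message("model saturated (df = 0); stepwise search stopped")
      break
    }
  }
  list(fit = fit, free_cov = fc, trail = trail)
}

#' @export
print.cfa_dwls <- function(x, digits = 3, ...) {
  cat("One-factor ordinal CFA (DWLS)\n")
  cat(sprintf("  n = %d, chisq = %.3f on %d df; %d freed error covariance(s)\n",
              x$n, x$chisq, x$df, nrow(x$error_cov)))
  cat(sprintf("  CFI = %.3f  TLI = %.3f  RMSEA = %.3f  GFI = %.3f\n",
              x$indices$cfi, x$indices$tli, x$indices$rmsea, x$indices$gfi))
  invisible(x)
}

#' @export
summary.cfa_dwls <- function(object, ...) {
  lam <- object$loadings; se <- object$loadings_se
  tab <- data.frame(
    loading = lam, se = se,
    ci_lower = lam - 1.96 * se, ci_upper = lam + 1.96 * se,
    standardized = object$std_loadings)
  out <- list(loadings = tab, psi = object$psi, psi_se = object$psi_se,
              error_cov = object$error_cov, indices = object$indices)
  class(out) <- "summary.cfa_dwls"
  out
}

#' @export
print.summary.cfa_dwls <- function(x, digits = 3, ...) {
  cat("Factor loadings (first fixed to 1):\n")
  print(round(x$loadings, digits))
  cat(sprintf("\nFactor variance psi = %.4f (se %.4f)\n", x$psi, x$psi_se))
  if (nrow(x$error_cov))
    { cat("\nFreed error covariances:\n"); print(round2df(x$error_cov, digits)) }
  cat("\n"); print(x$indices)
  invisible(x)
}

# round numeric columns of a data frame for display
round2df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

#' @export
coef.cfa_dwls <- function(object, ...) object$loadings
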