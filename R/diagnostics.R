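#' Indicator-level intraclass correlation
#'
#' Fits a two-level random-intercept ordinal probit null model for one
#' item by maximum likelihood with Gauss-Hermite quadrature: the item's
#' latent response is \eqn{Y^*_{ij} = b_j + \epsilon_{ij}} with
#' \eqn{b_j \sim N(0, \sigma^2_b)}, a unit probit residual and free
#' thresholds.  The ICC is reported on the latent-response scale,
#' \eqn{\sigma^2_b / (\sigma^2_b + 1)}, and therefore lies in `[0, 1)`.
#'
#' @param data A `household_data` data frame.
#' @param item Item column name (e.g. `"y8"`).
#' @param nodes Quadrature nodes (default 15).
#' @return The ICC (scalar), with attributes `sigma2_b` and `thresholds`.
#' @export
indicator_icc <- function(data, item, nodes = 15) {
  ok <- !is.na(data[[item]])
  y <- data[[item]][ok]
  hh <- match(data$household[ok], unique(data$household[ok]))
  counts <- tabulate(y, max(y))
  if (sum(counts > 0) < 2) stop(sprintf("degenerate item '%s'", item))
  if (!any(table(hh) >= 2))
    stop("no household with >= 2 observed members; ICC unidentified")
  C <- length(counts)
  gh <- .gh_rule(nodes)
  unpack_tau <- function(par)
    if (C > 2) cumsum(c(par[1], exp(par[2:(C - 1)]))) else par[1]
  nll <- function(par) {
    tau <- unpack_tau(par)
    sb <- sqrt(exp(par[C]))
    cuts <- c(-Inf, tau, Inf)
    logp <- matrix(0, length(y), length(gh$x))
    for (a in seq_along(gh$x)) {
      b <- sb * gh$x[a]
      logp[, a] <- log(pmax(stats::pnorm(cuts[y + 1] - b) -
                              stats::pnorm(cuts[y] - b), 1e-300))
    }
    S <- rowsum(logp, hh)
    Smax <- apply(S, 1, max)
    -sum(Smax + log(drop(exp(S - Smax) %*% gh$w)))
  }
  tau0 <- stats::qnorm(cumsum(counts)[-C] / sum(counts))
  start <- c(tau0[1], if (C > 2) log(pmax(diff(tau0), 0.05)), log(0.1))
  opt <- stats::optim(start, nll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  s2b <- exp(opt$par[C])
  structure(s2b / (s2b + 1), sigma2_b = s2b, thresholds = unpack_tau(opt$par))
}

#' Pearson correlation matrix of the predictors
#'
#' Correlations on the plain numeric codings (binary as 0/1, ordinal as
#' integer scores, continuous as-is), the convention used for mixed
#' predictor sets in survey collinearity screening.
#'
#' @param data A `household_data` data frame.
#' @param predictors Columns to correlate; default all ten predictors.
#' @return Symmetric correlation matrix with unit diagonal; constant
#'   columns yield `NA` entries with a warning.
#' @export
predictor_correlations <- function(data,
                                   predictors = c(.ind_predictors(),
                                                  .hh_predictors())) {
  X <- as.matrix(as.data.frame(data)[, predictors, drop = FALSE])
  if (nrow(stats::na.omit(X)) < 2) stop("fewer than 2 complete rows")
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0))
    warning("constant column(s): ", paste(predictors[sds == 0], collapse = ", "))
  suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
}

#' Collinearity diagnostics (tolerance and VIF)
#'
#' For each predictor, the auxiliary R-squared from regressing it on all
#' the others; tolerance is \eqn{1 - R^2}, VIF its exact reciprocal.
#' Flags raised at VIF > 5 or tolerance < 0.20.  Exact collinearity gives
#' tolerance 0 and an infinite VIF, flagged.
#'
#' @param data A `household_data` data frame (complete cases used).
#' @param predictors Columns to assess.
#' @return Object of class `collinearity_report`: data frame with
#'   `r_squared`, `tolerance`, `vif`, `concern`; the predictor
#'   correlation matrix is attached as attribute `correlations`.
#' @export
collinearity <- function(data,
                         predictors = c(.ind_predictors(),
                                        .hh_predictors())) {
  X <- as.data.frame(data)[, predictors, drop = FALSE]
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) <= length(predictors))
    stop("too few complete rows for auxiliary regressions")
  qrX <- qr(cbind(1, as.matrix(X)))
  full_rank <- qrX$rank == length(predictors) + 1
  out <- do.call(rbind, lapply(predictors, function(k) {
    others <- setdiff(predictors, k)
    r2 <- if (length(others)) {
      fit <- stats::lm(stats::reformulate(others, response = k), data = X)
      # suppressed: summary.lm warns on the perfect fits this flags anyway
      suppressWarnings(summary(fit)$r.squared)
    } else 0
    tol <- 1 - r2
    vif <- if (tol < 1e-12) Inf else 1 / tol
    data.frame(predictor = k, r_squared = r2, tolerance = tol, vif = vif,
               concern = vif > 5 | tol < 0.20)
  }))
  rownames(out) <- NULL
  if (!full_rank)
    warning("design matrix rank deficient: exact collinearity present")
  attr(out, "correlations") <- predictor_correlations(X, predictors)
  class(out) <- c("collinearity_report", "data.frame")
  out
}

#' @export
print.collinearity_report <- function(x, digits = 3, ...) {
  cat("Collinearity diagnostics (concern: VIF > 5 or tolerance < 0.20)\n")
  y <- as.data.frame(x)
  y[c("r_squared", "tolerance", "vif")] <-
    lapply(y[c("r_squared", "tolerance", "vif")], round, digits)
  print(y)
  cm <- attr(x, "correlations")
  cat(sprintf("largest absolute predictor correlation: %.3f\n",
              max(abs(cm[lower.tri(cm)]), na.rm = TRUE)))
  invisible(x)
}
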