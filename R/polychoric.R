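#' Estimate item thresholds from category counts
#'
#' First stage of limited-information ordinal modelling: the cut-point
#' separating categories c and c+1 on the latent-response (standard
#' normal) scale is the normal quantile of the cumulative proportion
#' through category c.  Empty categories are collapsed into the adjacent
#' non-empty category with a warning, so the returned cut-points are
#' always strictly increasing and finite.
#'
#' @param counts Non-negative integer vector of category counts (ordered).
#' @param item Optional item name used in messages.
#' @return Strictly increasing numeric vector of thresholds, of length
#'   one less than the number of non-empty categories.
#' @export
estimate_thresholds <- function(counts, item = "item") {
  if (any(counts < 0)) stop("negative category count")
  nz <- counts[counts > 0]
  if (length(nz) < 2)
    stop(sprintf("degenerate item '%s': fewer than 2 non-empty categories", item))
  if (length(nz) < length(counts))
    warning(sprintf("item '%s': %d empty categor%s collapsed",
                    item, length(counts) - length(nz),
                    if (length(counts) - length(nz) == 1) "y" else "ies"))
  cp <- cumsum(nz) / sum(nz)
  stats::qnorm(cp[-length(cp)])
}

# Bivariate standard normal CDF, infinite bounds allowed.
.pbvn <- function(h, k, rho) {
  if (!is.finite(h) && h > 0) return(if (is.finite(k)) stats::pnorm(k) else
    if (k > 0) 1 else 0)
  if (!is.finite(k) && k > 0) return(stats::pnorm(h))
  if (!is.finite(h) || !is.finite(k)) return(0)  # either bound is -Inf
  mvtnorm::pmvnorm(upper = c(h, k),
                   corr = matrix(c(1, rho, rho, 1), 2),
                   algorithm = mvtnorm::TVPACK())[1]
}

# Cell probabilities of a two-way ordinal table under bivariate normality
# with row cuts a, column cuts b (finite, increasing) and correlation rho.
.bvn_cell_probs <- function(a, b, rho) {
  ca <- c(-Inf, a, Inf); cb <- c(-Inf, b, Inf)
  R <- length(ca); C <- length(cb)
  H <- matrix(0, R, C)
  for (i in seq_len(R)) for (j in seq_len(C))
    H[i, j] <- .pbvn(ca[i], cb[j], rho)
  P <- H[-1, -1, drop = FALSE] - H[-R, -1, drop = FALSE] -
    H[-1, -C, drop = FALSE] + H[-R, -C, drop = FALSE]
  pmax(P, 0)
}

#' Polychoric correlation of a two-way contingency table
#'
#' Two-step maximum likelihood: thresholds are fixed at the inverse-normal
#' quantiles of the table margins (or supplied), then the latent
#' correlation maximises the bivariate-normal multinomial likelihood.
#' The estimate is clipped to \eqn{\pm 0.995} to keep downstream weight
#' matrices finite; hitting the clip is flagged.  The asymptotic variance
#' comes from the observed information (negative second derivative of the
#' profile log-likelihood at the optimum).
#'
#' @param tab Matrix of cell counts (rows = item 1 categories, columns =
#'   item 2 categories).
#' @param thresholds Optional list of two cut-point vectors; default
#'   estimated from the margins.
#' @param items Character vector of two names for messages.
#' @return List with `rho`, `var` (sampling variance of the estimate),
#'   `avar` (unit-level asymptotic variance, `n * var`), `n`,
#'   `thresholds`, and logical `boundary`.
#' @export
polychoric_pair <- function(tab, thresholds = NULL,
                            items = c("item1", "item2")) {
  tab <- as.matrix(tab)
  keep_r <- rowSums(tab) > 0; keep_c <- colSums(tab) > 0
  tab <- tab[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop(sprintf("degenerate margins for pair (%s, %s)", items[1], items[2]))
  n <- sum(tab)
  if (is.null(thresholds)) {
    a <- estimate_thresholds(rowSums(tab), items[1])
    b <- estimate_thresholds(colSums(tab), items[2])
  } else {
    a <- thresholds[[1]]; b <- thresholds[[2]]
  }
  ll <- function(rho) sum(tab * log(pmax(.bvn_cell_probs(a, b, rho), 1e-300)))
  clip <- 0.995
  opt <- stats::optimise(ll, c(-clip, clip), maximum = TRUE, tol = 1e-7)
  rho <- opt$maximum
  boundary <- FALSE
  # optimise never returns the exact endpoints; snap when pressed against them
  if (rho > clip - 1e-4 && ll(clip) >= opt$objective - 1e-8) {
    rho <- clip; boundary <- TRUE
  } else if (rho < -clip + 1e-4 && ll(-clip) >= opt$objective - 1e-8) {
    rho <- -clip; boundary <- TRUE
  }
  if (!is.finite(ll(rho)))
    stop(sprintf("polychoric likelihood non-finite for pair (%s, %s)",
                 items[1], items[2]))
  if (boundary) {
    v <- NA_real_
  } else {
    h <- 1e-3
    d2 <- (ll(rho + h) - 2 * ll(rho) + ll(rho - h)) / h^2
    if (!is.finite(d2) || d2 >= 0)
      stop(sprintf("information for pair (%s, %s) not positive; estimate at %.3f",
                   items[1], items[2], rho))
    v <- -1 / d2
  }
  list(rho = rho, var = v, avar = n * v, n = n,
       thresholds = list(a, b), boundary = boundary)
}

#' Polychoric correlation matrix of ordinal items
#'
#' Assembles all pairwise polychoric correlations, their asymptotic
#' variances (the DWLS weights) and per-item thresholds.  Each pair uses
#' the rows complete for that pair; under the pipeline's listwise-deletion
#' policy the data arriving here are already fully complete, making the
#' pairwise and listwise analyses identical.
#'
#' @param data Data frame or matrix of ordinal items (integer codes), or a
#'   `household_data` frame from which `items` columns are taken.
#' @param items Column names to use; default `y1`..`y12` when present,
#'   otherwise all columns.
#' @return Object of class `polychoric`: list with `rho` (symmetric
#'   correlation matrix, unit diagonal), `avar` (matrix of unit-level
#'   asymptotic variances, `NA` diagonal), `n_pair` (matrix of pair sample
#'   sizes), `thresholds` (per-item list), `boundary` (logical matrix),
#'   and `n` (minimum pair n, used for test statistics).
#' @export
polychoric <- function(data, items = NULL) {
  if (is.null(items)) {
    items <- if (all(paste0("y", 1:12) %in% colnames(data)))
      paste0("y", 1:12) else colnames(data)
  }
  Y <- as.matrix(as.data.frame(data)[, items, drop = FALSE])
  K <- ncol(Y)
  if (K < 2) stop("need at least 2 items")
  rho <- diag(1, K); avar <- matrix(NA_real_, K, K)
  npair <- matrix(NA_real_, K, K); bnd <- matrix(FALSE, K, K)
  thresholds <- vector("list", K)
  for (p in seq_len(K)) {
    yp <- Y[, p][!is.na(Y[, p])]
    thresholds[[p]] <- estimate_thresholds(tabulate(yp, max(yp)), items[p])
  }
  for (p in seq_len(K - 1)) for (q in (p + 1):K) {
    ok <- stats::complete.cases(Y[, c(p, q)])
    tab <- table(factor(Y[ok, p]), factor(Y[ok, q]))
    est <- tryCatch(
      polychoric_pair(tab, items = items[c(p, q)]),
      error = function(e) stop(sprintf("pair (%s, %s): %s",
                                       items[p], items[q], conditionMessage(e)),
                               call. = FALSE))
    rho[p, q] <- rho[q, p] <- est$rho
    avar[p, q] <- avar[q, p] <- est$avar
    npair[p, q] <- npair[q, p] <- est$n
    bnd[p, q] <- bnd[q, p] <- est$boundary
  }
  dimnames(rho) <- dimnames(avar) <- dimnames(npair) <-
    dimnames(bnd) <- list(items, items)
  names(thresholds) <- items
  structure(list(rho = rho, avar = avar, n_pair = npair,
                 thresholds = thresholds, boundary = bnd,
                 n = min(npair, na.rm = TRUE)),
            class = "polychoric")
}

#' @export
print.polychoric <- function(x, digits = 3, ...) {
  K <- ncol(x$rho)
  cat(sprintf("Polychoric correlations: %d items, n = %d%s\n", K, x$n,
              if (any(x$boundary)) " [boundary estimates present]" else ""))
  print(round(x$rho, digits))
  invisible(x)
}
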