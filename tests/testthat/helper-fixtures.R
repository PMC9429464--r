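# Shared fixtures and independent oracles for the test suite.

# Tiny measurement models ---------------------------------------------------

# K-item measurement part with simple defaults; loadings[1] need not be 1 so
# degenerate cases (all-zero loadings) can be exercised.
toy_measurement <- function(loadings = c(1, 0.8),
                            thresholds = NULL,
                            theta = NULL) {
  K <- length(loadings)
  if (is.null(thresholds))
    thresholds <- rep(list(c(-0.5, 0.5, 1.5)), K)
  if (is.null(theta)) theta <- rep(1, K)
  measurement_model(loadings, thresholds, theta)
}

# Hand-rolled toy household frame (no simulation) for flag/filter tests.
toy_households <- function(history, ages = NULL) {
  hh <- rep(seq_along(history), lengths(history))
  d <- data.frame(household = hh,
                  person = unlist(lapply(history, seq_along)),
                  history = unlist(history))
  if (!is.null(ages)) d$age <- unlist(ages)
  class(d) <- c("household_data", "data.frame")
  d
}

# Independent oracles --------------------------------------------------------

# Grid-search ML for the polychoric correlation: maximises the same
# bivariate-normal multinomial likelihood over a two-stage rho grid,
# computing cell probabilities directly from mvtnorm.
oracle_polychoric_grid <- function(tab) {
  tab <- as.matrix(tab)
  a <- qnorm(cumsum(rowSums(tab))[-nrow(tab)] / sum(tab))
  b <- qnorm(cumsum(colSums(tab))[-ncol(tab)] / sum(tab))
  cellp <- function(rho) {
    ca <- c(-Inf, a, Inf); cb <- c(-Inf, b, Inf)
    H <- outer(seq_along(ca), seq_along(cb), Vectorize(function(i, j) {
      if (ca[i] == -Inf || cb[j] == -Inf) return(0)
      if (ca[i] == Inf && cb[j] == Inf) return(1)
      if (ca[i] == Inf) return(pnorm(cb[j]))
      if (cb[j] == Inf) return(pnorm(ca[i]))
      mvtnorm::pmvnorm(upper = c(ca[i], cb[j]),
                       corr = matrix(c(1, rho, rho, 1), 2),
                       algorithm = mvtnorm::TVPACK())[1]
    }))
    P <- H[-1, -1] - H[-nrow(H), -1] - H[-1, -ncol(H)] + H[-nrow(H), -ncol(H)]
    pmax(P, 1e-300)
  }
  ll <- function(rho) sum(tab * log(cellp(rho)))
  coarse <- seq(-0.99, 0.99, by = 0.01)
  l1 <- vapply(coarse, ll, 0)
  r1 <- coarse[which.max(l1)]
  fine <- seq(max(-0.994, r1 - 0.02), min(0.994, r1 + 0.02), by = 5e-4)
  fine[which.max(vapply(fine, ll, 0))]
}

# Random non-degenerate two-way ordinal table from a latent bivariate normal.
random_ordinal_table <- function(n = 500, rho = NULL, nr = 3, nc = 3) {
  if (is.null(rho)) rho <- runif(1, -0.8, 0.8)
  x <- matrix(rnorm(2 * n), n, 2) %*% chol(matrix(c(1, rho, rho, 1), 2))
  ca <- sort(runif(nr - 1, -1.2, 1.2))
  cb <- sort(runif(nc - 1, -1.2, 1.2))
  tab <- table(cut(x[, 1], c(-Inf, ca, Inf)), cut(x[, 2], c(-Inf, cb, Inf)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(random_ordinal_table(n, rho, nr, nc))
  tab
}

# Monte-Carlo oracle for the household marginal likelihood: draws the
# household residual and each member's residual, averaging the product of
# ordinal-probit category probabilities (Rao-Blackwellised over the
# indicator residuals, so the integrand is smooth).
oracle_household_mc <- function(y, meas, m = NULL, psi_ind, psi_hh,
                                ndraw = 1e6, seed = 42) {
  set.seed(seed)
  ni <- nrow(y); K <- ncol(y)
  if (is.null(m)) m <- rep(0, ni)
  u <- rnorm(ndraw, 0, sqrt(psi_hh))
  g <- rep(1, ndraw)
  for (i in seq_len(ni)) {
    e <- rnorm(ndraw, 0, sqrt(psi_ind))
    eta <- m[i] + u + e
    gi <- rep(1, ndraw)
    for (p in seq_len(K)) {
      cuts <- c(-Inf, meas$thresholds[[p]], Inf)
      z_hi <- (cuts[y[i, p] + 1] - meas$loadings[p] * eta) /
        sqrt(meas$theta[p])
      z_lo <- (cuts[y[i, p]] - meas$loadings[p] * eta) / sqrt(meas$theta[p])
      gi <- gi * (pnorm(z_hi) - pnorm(z_lo))
    }
    g <- g * gi
  }
  log(mean(g))
}

# One-factor ordinal sample at given *standardized* loadings (unit latent
# variance), optionally with one correlated error pair.
simulate_onefactor <- function(n, std_loadings, thresholds,
                               error_pair = NULL, error_r = 0) {
  K <- length(std_loadings)
  eta <- rnorm(n)
  th <- 1 - std_loadings^2
  Theta <- diag(th)
  if (!is.null(error_pair)) {
    i <- error_pair[1]; j <- error_pair[2]
    Theta[i, j] <- Theta[j, i] <- error_r * sqrt(th[i] * th[j])
  }
  eps <- matrix(rnorm(n * K), n, K) %*% chol(Theta)
  ystar <- outer(eta, std_loadings) + eps
  d <- as.data.frame(lapply(seq_len(K), function(p)
    as.integer(cut(ystar[, p], c(-Inf, thresholds[[p]], Inf),
                   labels = FALSE))))
  names(d) <- paste0("y", seq_len(K))
  d
}

# ANOVA-style empirical ICC of scores nested in clusters (oracle for the
# generator's stored latent scores).
empirical_icc <- function(score, cluster) {
  mb <- tapply(score, cluster, mean)
  vb <- var(mb[match(cluster, names(mb))])  # between, individual-expanded
  vw <- mean(tapply(score, cluster, var))
  vb_adj <- vb - vw / mean(table(cluster))  # remove within leakage
  max(vb_adj, 0) / (max(vb_adj, 0) + vw)
}
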