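# Build a synthetic polychoric object lying exactly on the model manifold,
# so the DWLS fixed point can be checked without sampling noise.
exact_polymat <- function(loadings, psi, error_cov = NULL, n = 2000,
                          avar = 1) {
  K <- length(loadings)
  rho <- suppressWarnings(implied_correlations(loadings, psi, error_cov))
  items <- paste0("y", seq_len(K))
  dimnames(rho) <- list(items, items)
  av <- matrix(avar, K, K); diag(av) <- NA
  np <- matrix(n, K, K); diag(np) <- NA
  structure(list(rho = rho, avar = av, n_pair = np,
                 thresholds = rep(list(c(-1, 0, 1)), K),
                 boundary = matrix(FALSE, K, K), n = n),
            class = "polychoric")
}

test_that("implied correlations follow the product rule", {
  S <- implied_correlations(c(0.6, 0.5), 1)
  expect_equal(S[1, 2], 0.30)
  expect_equal(diag(S), c(1, 1))
  # zero loadings: off-diagonals equal the error covariances alone
  ec <- matrix(0, 3, 3); ec[1, 2] <- ec[2, 1] <- 0.4
  S0 <- implied_correlations(rep(0, 3), 1, ec)
  expect_equal(S0[1, 2], 0.4)
  expect_equal(S0[1, 3], 0)
  # a non-PSD implied matrix is flagged
  ec2 <- matrix(0.99, 3, 3) * (1 - diag(3)); ec2[1, 2] <- ec2[2, 1] <- -0.99
  expect_warning(implied_correlations(rep(0, 3), 1, ec2), "positive semi")
})

test_that("DWLS reaches the discrepancy-zero fixed point on exact input", {
  lam <- c(1, 1.4, 0.9, 1.8, 1.0, 2.1)
  pm <- exact_polymat(lam, 0.05)
  fit <- cfa_dwls(pm)
  expect_lt(fit$F, 1e-10)
  expect_equal(fit$chisq, 0, tolerance = 1e-6)
  expect_equal(unname(fit$loadings), lam, tolerance = 1e-4)
  expect_equal(fit$psi, 0.05, tolerance = 1e-5)
  expect_equal(fit$df, 15 - 6)
  expect_equal(fit$indices$cfi, 1)
})

test_that("two starting points reach the same optimum", {
  set.seed(6)
  d <- simulate_onefactor(1500, c(0.3, 0.5, 0.6, 0.45, 0.55),
                          rep(list(c(-1, 0.2, 1.3)), 5))
  pm <- polychoric(d, paste0("y", 1:5))
  f1 <- cfa_dwls(pm)
  f2 <- cfa_dwls(pm, start = c(rep(1.5, 4), 0.3))
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-4)
  expect_equal(f1$psi, f2$psi, tolerance = 1e-5)
})

test_that("a saturated specification drives the discrepancy to zero", {
  set.seed(7)
  d <- simulate_onefactor(800, c(0.4, 0.5, 0.6, 0.5),
                          rep(list(c(-1, 0.2, 1.3)), 4))
  pm <- polychoric(d, paste0("y", 1:4))
  # 6 statistics; 3 loadings + psi + 2 free covariances = 6 parameters
  # (pairs chosen so the remaining equations stay generically solvable)
  fit <- cfa_dwls(pm, free_cov = rbind(c("y1", "y2"), c("y1", "y3")))
  expect_equal(fit$df, 0)
  expect_lt(fit$F, 1e-8)
  expect_equal(fit$chisq, 0, tolerance = 1e-4)
  expect_true(is.na(fit$indices$rmsea))
  # over-parameterised specification is rejected
  expect_error(cfa_dwls(pm, free_cov = rbind(c("y1", "y2"), c("y3", "y4"),
                                             c("y1", "y3"))),
               "identified")
})

test_that("standardized loadings are recovered at survey-like truth", {
  std <- c(0.134, 0.189, 0.128, 0.246, 0.129, 0.276,
           0.450, 0.478, 0.466, 0.604, 0.565, 0.486)
  set.seed(8)
  d <- simulate_onefactor(20000, std, ghq_thresholds())
  pm <- polychoric(d)
  fit <- cfa_dwls(pm)
  # Monte-Carlo tolerance at n = 20,000: all standardized loadings close
  expect_equal(unname(fit$std_loadings), std, tolerance = 0.035)
  expect_gt(fit$indices$cfi, 0.95)
})

test_that("fit indices reproduce their closed forms exactly", {
  fi <- fit_indices(50, 40, 500, 66, 1000)
  expect_equal(fi$cfi, 1 - 10 / 434, tolerance = 1e-12)
  expect_equal(fi$tli, (500 / 66 - 50 / 40) / (500 / 66 - 1),
               tolerance = 1e-12)
  expect_equal(fi$rmsea, sqrt(10 / (40 * 999)), tolerance = 1e-12)
  expect_equal(round(c(fi$cfi, fi$tli, fi$rmsea), 3),
               c(0.977, 0.962, 0.016))
  # truncation at perfect fit
  fi2 <- fit_indices(30, 40, 500, 66, 1000)
  expect_equal(fi2$cfi, 1)
  expect_equal(fi2$rmsea, 0)
  # fit equal to its own baseline
  fi3 <- fit_indices(500, 66, 500, 66, 1000)
  expect_equal(fi3$cfi, 0)
  # df = 0 leaves TLI/RMSEA undefined
  fi4 <- fit_indices(0, 0, 500, 66, 1000)
  expect_true(is.na(fi4$tli) && is.na(fi4$rmsea))
})

test_that("modification indices point at the omitted error covariance", {
  set.seed(9)
  d <- simulate_onefactor(3000, c(0.4, 0.5, 0.6, 0.5, 0.45, 0.55),
                          rep(list(c(-1, 0.2, 1.3)), 6),
                          error_pair = c(2, 5), error_r = 0.4)
  pm <- polychoric(d, paste0("y", 1:6))
  fit <- cfa_dwls(pm)
  mi <- modification_indices(fit)
  expect_setequal(sort(c(mi$item1[1], mi$item2[1])), c("y2", "y5"))
  expect_true(all(mi$mi >= 0))
  # freed parameters are excluded from the table
  fit2 <- cfa_dwls(pm, free_cov = rbind(c("y2", "y5")))
  mi2 <- modification_indices(fit2)
  expect_false(any(mi2$item1 == "y2" & mi2$item2 == "y5" |
                     mi2$item1 == "y5" & mi2$item2 == "y2"))
  # score statistic approximates the actual chi-square drop on refit
  drop_chisq <- fit$chisq - fit2$chisq
  expect_gt(mi$mi[1], 10)
  expect_equal(mi$mi[1], drop_chisq, tolerance = 0.15 * drop_chisq)
})

test_that("freeing a parameter never increases the discrepancy", {
  set.seed(10)
  d <- simulate_onefactor(1200, c(0.4, 0.5, 0.6, 0.5, 0.45),
                          rep(list(c(-1, 0.2, 1.3)), 5))
  pm <- polychoric(d, paste0("y", 1:5))
  f0 <- cfa_dwls(pm)
  pairs <- rbind(c("y1", "y2"), c("y2", "y4"), c("y3", "y5"))
  for (k in seq_len(nrow(pairs))) {
    fk <- cfa_dwls(pm, free_cov = pairs[k, , drop = FALSE])
    expect_lte(fk$F, f0$F + 1e-10)
  }
})

test_that("stepwise freeing recovers true covariances in MI order", {
  set.seed(11)
  n <- 4000
  std <- c(0.4, 0.5, 0.6, 0.5, 0.45, 0.55)
  th <- rep(list(c(-1, 0.2, 1.3)), 6)
  # two strong true error covariances
  K <- 6; eta <- rnorm(n); res_v <- 1 - std^2
  Theta <- diag(res_v)
  Theta[1, 4] <- Theta[4, 1] <- 0.45 * sqrt(res_v[1] * res_v[4])
  Theta[2, 6] <- Theta[6, 2] <- 0.35 * sqrt(res_v[2] * res_v[6])
  ystar <- outer(eta, std) + matrix(rnorm(n * K), n, K) %*% chol(Theta)
  d <- as.data.frame(lapply(1:K, function(p)
    as.integer(cut(ystar[, p], c(-Inf, th[[p]], Inf), labels = FALSE))))
  names(d) <- paste0("y", 1:K)
  pm <- polychoric(d, names(d))
  sw <- stepwise_free_covariances(pm)
  freed <- apply(sw$free_cov, 1, function(r) paste(sort(r), collapse = "-"))
  expect_true(all(c("y1-y4", "y2-y6") %in% freed[1:2]))
  # the stronger covariance is freed first
  expect_equal(freed[1], "y1-y4")
  # an infinite threshold returns the starting model untouched
  sw0 <- stepwise_free_covariances(pm, threshold = Inf)
  expect_null(sw0$free_cov)
  expect_equal(sw0$fit$df, sw0$fit$baseline_df - 6)
})

test_that("Heywood configurations raise a warning", {
  pm <- exact_polymat(c(1, 1.1, 0.9), 0.9)
  expect_warning(cfa_dwls(pm), "Heywood")
})
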