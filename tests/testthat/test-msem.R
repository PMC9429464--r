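test_that("household likelihood reduces to marginal probabilities without a
           latent contribution", {
  # zero loadings and zero variances: items are independent with category
  # probabilities given by the thresholds alone
  th <- list(c(-0.5, 0.5, 1.5), c(-1, 0, 1))
  meas <- measurement_model(c(0, 0), th, c(1, 1))
  y <- rbind(c(1, 2), c(3, 4))
  ll <- household_loglik(y, meas, psi_ind = 0, psi_hh = 0)
  manual <- 0
  for (i in 1:2) for (p in 1:2) {
    cuts <- c(-Inf, th[[p]], Inf)
    manual <- manual + log(pnorm(cuts[y[i, p] + 1]) - pnorm(cuts[y[i, p]]))
  }
  expect_equal(ll, manual, tolerance = 1e-10)
})

test_that("zero household variance factorises the household likelihood", {
  meas <- toy_measurement(c(1, 0.8), theta = c(0.6, 0.7))
  y <- rbind(c(2, 3), c(1, 2))
  joint <- household_loglik(y, meas, psi_ind = 0.4, psi_hh = 0, nodes = 25)
  solo <- household_loglik(y[1, , drop = FALSE], meas, psi_ind = 0.4,
                           psi_hh = 0, nodes = 25) +
    household_loglik(y[2, , drop = FALSE], meas, psi_ind = 0.4,
                     psi_hh = 0, nodes = 25)
  expect_equal(joint, solo, tolerance = 1e-8)
})

test_that("quadrature agrees with Monte-Carlo integration", {
  meas <- measurement_model(c(1, 1.3), list(c(-0.4, 0.6, 1.4),
                                            c(-0.9, 0.1, 1.1)),
                            c(0.7, 0.55))
  y <- rbind(c(2, 3), c(1, 1))
  ll <- household_loglik(y, meas, psi_ind = 0.3, psi_hh = 0.2, nodes = 21)
  mc <- oracle_household_mc(y, meas, psi_ind = 0.3, psi_hh = 0.2,
                            ndraw = 2e5, seed = 31)
  expect_equal(ll, mc, tolerance = 3e-3)
})

test_that("analytic gradient matches numerical differentiation", {
  skip_if_not_installed("numDeriv")
  set.seed(12)
  d <- simulate_households(sim_config(n_households = 40, seed = 12))
  tr <- attr(d, "truth")
  meas <- measurement_model(tr$loadings, tr$thresholds, tr$theta)
  dd <- mlsem:::.msem_data(d, paste0("y", 1:12), mlsem:::.ind_predictors(),
                           mlsem:::.hh_predictors())
  gh <- mlsem:::.gh_rule(9)
  # standardized X as used internally is irrelevant here: check the kernel
  f <- function(par) {
    mlsem:::msem_loglik_cpp(dd$Y, dd$X, dd$Z, dd$start, dd$len,
                            tr$loadings, tr$thresholds, tr$theta,
                            par[1:9], par[10:11],
                            exp(par[12]), exp(par[13]),
                            gh$x, gh$w, FALSE, FALSE)$loglik
  }
  par0 <- c(-0.1, 0.01, -0.002, -0.01, 0.02, 0.05, 0.01, -0.03, 0.001,
            0.005, -0.01, log(0.02), log(0.006))
  g_ana <- mlsem:::msem_loglik_cpp(dd$Y, dd$X, dd$Z, dd$start, dd$len,
                                   tr$loadings, tr$thresholds, tr$theta,
                                   par0[1:9], par0[10:11],
                                   exp(par0[12]), exp(par0[13]),
                                   gh$x, gh$w, TRUE, FALSE)$grad
  g_num <- numDeriv::grad(f, par0)
  expect_equal(g_ana, g_num, tolerance = 1e-5)
})

test_that("log-likelihood is invariant to household and member order", {
  d <- simulate_households(sim_config(n_households = 30, seed = 13))
  tr <- attr(d, "truth")
  meas <- measurement_model(tr$loadings, tr$thresholds, tr$theta)
  ll_of <- function(dat) {
    dd <- mlsem:::.msem_data(dat, paste0("y", 1:12),
                             mlsem:::.ind_predictors(),
                             mlsem:::.hh_predictors())
    gh <- mlsem:::.gh_rule(9)
    mlsem:::msem_loglik_cpp(dd$Y, dd$X, dd$Z, dd$start, dd$len,
                            tr$loadings, tr$thresholds, tr$theta,
                            rep(0, 9), c(0, 0), 0.013, 0.003,
                            gh$x, gh$w, FALSE, FALSE)$loglik
  }
  set.seed(99)
  expect_equal(ll_of(d), ll_of(d[sample(nrow(d)), ]), tolerance = 1e-9)
})

test_that("null and full fits are properly nested and stable in nodes", {
  d <- simulate_households(sim_config(n_households = 120, seed = 15))
  tr <- attr(d, "truth")
  meas <- measurement_model(tr$loadings, tr$thresholds, tr$theta)
  f0 <- msem_null(d, meas, nodes = 7, se = FALSE)
  f1 <- msem(d, meas, nodes = 7, se = FALSE)
  expect_lte(f0$loglik, f1$loglik + 1e-6)
  expect_true(all(f1$psi >= 0))
  # doubling the quadrature rule leaves the optimum essentially unchanged
  f1b <- msem(d, meas, nodes = 15, se = FALSE)
  expect_equal(coef(f1), coef(f1b), tolerance = 1e-3)
  expect_lt(abs(f1$loglik - f1b$loglik), 0.01)
})

test_that("latent ICC and explained variance follow their closed forms", {
  expect_equal(latent_icc(0.008, 0.026), 0.008 / 0.034, tolerance = 1e-12)
  expect_equal(latent_icc(0, 0.4), 0)
  expect_equal(latent_icc(0.3, 0.3), 0.5)
  expect_error(latent_icc(0, 0), "undefined")
  expect_error(latent_icc(-0.1, 0.2), ">= 0")
  expect_equal(explained_variance(0.026, 0.013), 0.5)
  expect_equal(explained_variance(0.008, 0.003), 0.625)
  expect_equal(explained_variance(0.4, 0.4), 0)
  expect_error(explained_variance(0, 0.1), "> 0")
  expect_warning(ev <- explained_variance(0.01, 0.02), "negative")
  expect_equal(ev, -1)
})

test_that("directional tests translate z into one-sided tiers", {
  fake <- structure(list(
    coefficients = c("(Intercept)" = 0.1, history = 0, age = -0.02,
                     male = 0.03),
    psi = c(ind = 0.01, hh = 0.004),
    se = c("(Intercept)" = 0.05, history = 0.01, age = 0.0086,
           male = 0.005, psi_ind = 0.002, psi_hh = 0.001)),
    class = "msem")
  ht <- hypothesis_tests(fake, c(history = +1, age = -1, male = -1,
                                 psi_hh = +1))
  row <- function(p) ht[ht$parameter == p, ]
  # zero estimate: one-sided p exactly one half
  expect_equal(row("history")$p_one_sided, 0.5)
  # z = 2.326 in the hypothesised direction: p ~ 0.01, boundary tier
  expect_equal(row("age")$z, -2.3256, tolerance = 1e-3)
  expect_equal(row("age")$p_one_sided, 0.01, tolerance = 5e-3)
  expect_equal(row("age")$tier, "b")
  # direction violated with large |z|: p near 1, not significant
  expect_gt(row("male")$p_one_sided, 0.99)
  expect_equal(row("male")$tier, "ns")
  expect_equal(row("psi_hh")$tier, "a")
})

test_that("standardized coefficients are invariant to predictor rescaling", {
  d <- simulate_households(sim_config(n_households = 150, seed = 16))
  tr <- attr(d, "truth")
  meas <- measurement_model(tr$loadings, tr$thresholds, tr$theta)
  f1 <- msem(d, meas, nodes = 5)
  d2 <- d; d2$age <- d2$age * 2
  f2 <- msem(d2, meas, nodes = 5)
  expect_equal(coef(f2)[["age"]], coef(f1)[["age"]] / 2, tolerance = 0.02)
  s1 <- standardized_coefs(f1); s2 <- standardized_coefs(f2)
  expect_equal(s1$beta[["age"]], s2$beta[["age"]], tolerance = 1e-3)
  # standardized loadings live on the correlation scale
  expect_true(all(abs(s1$loadings) < 1))
})

test_that("empirical Bayes scores track the generating latent scores", {
  d <- simulate_households(sim_config(n_households = 250, seed = 17))
  tr <- attr(d, "truth")
  meas <- measurement_model(tr$loadings, tr$thresholds, tr$theta)
  f <- msem(d, meas, nodes = 7, se = FALSE)
  eb <- predict(f)
  expect_equal(nrow(eb), f$n)
  expect_gt(cor(eb$eta_ind, tr$eta_ind), 0.6)
})

test_that("parametric simulation from a fit round-trips its own scale", {
  d <- simulate_households(sim_config(n_households = 150, seed = 18))
  tr <- attr(d, "truth")
  meas <- measurement_model(tr$loadings, tr$thresholds, tr$theta)
  f <- msem_null(d, meas, nodes = 5, se = FALSE)
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), f$n)
  expect_true(all(as.matrix(sims[[1]][, paste0("y", 1:12)]) %in% 1:4))
  # refitting on its own simulation recovers similar variance components
  f2 <- msem_null(sims[[1]], meas, nodes = 5, se = FALSE)
  expect_equal(f2$psi[["ind"]], f$psi[["ind"]], tolerance = 0.5)
})

test_that("information criteria follow the likelihood and count", {
  d <- simulate_households(sim_config(n_households = 80, seed = 19))
  tr <- attr(d, "truth")
  meas <- measurement_model(tr$loadings, tr$thresholds, tr$theta)
  f <- msem_null(d, meas, nodes = 5, se = FALSE)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$npar)
  expect_equal(f$bic, -2 * f$loglik + f$npar * log(f$n))
  expect_equal(AIC(f), f$aic)
  expect_equal(BIC(f), f$bic)
})

test_that("joint estimation frees the loadings and improves the fit", {
  d <- simulate_households(sim_config(n_households = 120, seed = 20))
  tr <- attr(d, "truth")
  # start from a deliberately distorted measurement part
  distorted <- measurement_model(tr$loadings * c(1, rep(1.4, 11)),
                                 tr$thresholds, tr$theta)
  f_fixed <- msem_null(d, distorted, nodes = 5, se = FALSE)
  f_joint <- msem_null(d, distorted, nodes = 5, joint = TRUE, se = FALSE)
  expect_gte(f_joint$loglik, f_fixed$loglik)
  expect_equal(f_joint$loadings[1], 1)   # anchor stays fixed
  # freed loadings move back toward the generating values
  err_fixed <- mean(abs(distorted$loadings[-1] - tr$loadings[-1]))
  err_joint <- mean(abs(f_joint$loadings[-1] - tr$loadings[-1]))
  expect_lt(err_joint, err_fixed)
})
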