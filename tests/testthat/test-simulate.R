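test_that("configuration validation rejects bad inputs by name", {
  expect_error(sim_config(psi_ind = -1), "psi_ind")
  expect_error(sim_config(psi_hh = -0.1), "psi_hh")
  expect_error(sim_config(thresholds = c(ghq_thresholds()[-12],
                                         list(c(1, 1, 2)))),
               "item 12")
  expect_error(sim_config(household_sizes = 1:3), "household_sizes")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(loadings = c(2, ghq_loadings()[-1])),
               "first loading")
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- sim_config(n_households = 60, seed = 9)
  d1 <- simulate_households(cfg)
  d2 <- simulate_households(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_households(sim_config(n_households = 60, seed = 10))
  expect_false(identical(d1$y1, d3$y1))
})

test_that("generated data satisfy the structural invariants", {
  d <- simulate_households(sim_config(n_households = 120, seed = 4))
  expect_true(all(table(d$household) >= 2))
  for (p in paste0("y", 1:12)) expect_true(all(d[[p]] %in% 1:4))
  # household-level columns constant within household
  for (zc in c("deprivation", "hh_closeness"))
    expect_true(all(tapply(d[[zc]], d$household,
                           function(v) length(unique(v))) == 1))
  # stored latent scores satisfy the generating equations exactly
  tr <- attr(d, "truth")
  hh <- match(d$household, unique(d$household))
  X <- as.matrix(d[, names(tr$beta)])
  eta_rebuilt <- drop(X %*% tr$beta) + tr$eta_hh[hh] + tr$e
  expect_equal(eta_rebuilt, tr$eta_ind, tolerance = 1e-12)
  Z1 <- tapply(d$deprivation, hh, function(v) v[1])
  Z2 <- tapply(d$hh_closeness, hh, function(v) v[1])
  eta_hh_rebuilt <- drop(cbind(Z1, Z2) %*% tr$gamma) + tr$u
  expect_equal(unname(eta_hh_rebuilt), tr$eta_hh, tolerance = 1e-12)
})

test_that("no between-household variation when psi_hh, gamma, beta are zero", {
  cfg <- sim_config(n_households = 2000, psi_hh = 0, psi_ind = 1,
                    beta = rep(0, 8), gamma = c(0, 0), theta = rep(1, 12),
                    seed = 21)
  d <- simulate_households(cfg)
  tr <- attr(d, "truth")
  expect_true(all(tr$eta_hh == 0))
  icc <- empirical_icc(tr$eta_ind, d$household)
  expect_lt(icc, 0.02)
})

test_that("variance ratio of stored household scores matches psi_hh share", {
  cfg <- sim_config(n_households = 2000, psi_hh = 0.25, psi_ind = 0.75,
                    beta = rep(0, 8), gamma = c(0, 0), theta = rep(1, 12),
                    seed = 22)
  d <- simulate_households(cfg)
  tr <- attr(d, "truth")
  ratio <- var(tr$eta_hh) / (var(tr$eta_hh) + var(tr$e))
  expect_equal(ratio, 0.25, tolerance = 0.03)
  icc <- empirical_icc(tr$eta_ind, d$household)
  expect_equal(icc, 0.25, tolerance = 0.04)
})

test_that("marginal category frequencies match the probit-implied margins", {
  # thresholds put item 8 at margins (0.271, 0.549, 0.158, 0.022); with a
  # null structural part and unit-variance delta scaling the simulated
  # frequencies must agree within 3 multinomial standard errors
  probs <- c(0.271, 0.549, 0.158, 0.022)
  th <- ghq_thresholds()
  th[[8]] <- qnorm(cumsum(probs)[-4])
  cfg <- sim_config(n_households = 20900, thresholds = th,
                    psi_ind = 0.03, psi_hh = 0.01,
                    beta = rep(0, 8), gamma = c(0, 0), seed = 23)
  d <- simulate_households(cfg)
  n <- nrow(d)
  expect_gte(n, 49000)
  obs <- tabulate(d$y8, 4) / n
  mc_se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(obs - probs) <= 3 * mc_se))
})

test_that("co-resident flag excludes self and is idempotent", {
  d <- toy_households(list(c(1, 0), c(0, 0, 0), c(1, 1)))
  d$x_co <- NULL
  d1 <- derive_coresident_flag(d)
  expect_identical(d1$x_co, c(0L, 1L, 0L, 0L, 0L, 1L, 1L))
  expect_identical(derive_coresident_flag(d1)$x_co, d1$x_co)
  expect_error(derive_coresident_flag(toy_households(list(c(1, 0), 1))),
               "single")
})

test_that("missingness is MCAR at the requested rate and reproducible", {
  d <- simulate_households(sim_config(n_households = 280, seed = 14))
  expect_identical(apply_missingness(d, 0), d)
  m1 <- apply_missingness(d, 0.1, seed = 3)
  m2 <- apply_missingness(d, 0.1, seed = 3)
  expect_identical(m1, m2)
  cells <- c(paste0("y", 1:12), "closeness", "bmi", "hh_closeness")
  n_cells <- length(cells) * nrow(d)
  n_miss <- sum(is.na(m1[, cells]))
  # binomial 99% interval around rate * n_cells
  expect_true(abs(n_miss - 0.1 * n_cells) <=
                2.576 * sqrt(n_cells * 0.1 * 0.9))
  expect_error(apply_missingness(d, 1), "rate")
})
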