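test_that("trait expansion builds intercept, scaled continuous and dummies", {
  toy <- toy_fixture()
  Tq <- expand_traits(toy$traits)
  expect_identical(rownames(Tq), c("intercept", "length_mm", "ctmax_c",
                                   "trophic_groupmid", "trophic_grouptop"))
  expect_equal(unname(Tq["intercept", ]), rep(1, 8))
  expect_equal(mean(Tq["length_mm", ]), 0, tolerance = 1e-12)
  expect_equal(sd(Tq["length_mm", ]), 1, tolerance = 1e-12)
  expect_equal(unname(Tq["trophic_grouptop", ]),
               as.numeric(toy$traits$categorical$trophic_group == "top"))
  # log-standardisation: equal log-ratios give equal spacing
  tt <- trait_table(cbind(length_mm = c(a = 1, b = 10, c = 100)))
  Tl <- expand_traits(tt)
  expect_equal(diff(Tl["length_mm", ])[[1]], diff(Tl["length_mm", ])[[2]],
               tolerance = 1e-12)
})

test_that("Tjur R2 follows its definition", {
  expect_equal(tjur_r2(c(1, 0, 1, 0), c(0.8, 0.2, 0.6, 0.4)), 0.4,
               tolerance = 1e-12)
  y <- c(1, 1, 0, 0, 1)
  expect_equal(tjur_r2(y, y), 1)
  expect_equal(tjur_r2(y, rep(0.3, 5)), 0)
  expect_error(tjur_r2(rep(1, 4), runif(4)), "constant")
  set.seed(2)
  y2 <- rbinom(30, 1, 0.5); y2[1:2] <- c(0, 1)
  p2 <- runif(30)
  expect_equal(tjur_r2(y2, p2), oracle_tjur(y2, p2), tolerance = 1e-12)
})

test_that("sign-support filtering counts posterior tail mass", {
  beta <- array(0, c(2, 2, 20))
  beta[1, 1, ] <- abs(rnorm(20)) + 0.1          # positive in all samples
  beta[2, 1, ] <- c(rep(1, 17), rep(-1, 3))     # positive in 17/20
  beta[1, 2, ] <- rnorm(20)
  post <- make_posterior_stub(beta)
  sf <- support_filter(post, "beta", 0.90)
  expect_equal(unname(sf$support[1, 1]), 1)
  expect_true(sf$mask[1, 1])
  expect_equal(unname(sf$support[2, 1]), 0.85)
  expect_false(sf$mask[2, 1])
  expect_error(support_filter(post, "beta", 0.4), "threshold")
  expect_error(support_filter(post, "beta", 1), "threshold")
  # both documented default thresholds are admissible
  expect_s3_class(support_filter(post, "beta", 0.95), "sign_support")
})

test_that("residual associations recover closed-form loading structure", {
  S <- 3; N <- 10
  lam <- array(rep(c(1, 1, -1), N), c(1, S, N),
               dimnames = list(NULL, c("f1", "f2", "z1"), NULL))
  beta <- array(0, c(1, S, N), dimnames = list("intercept",
                                               c("f1", "f2", "z1"), NULL))
  post <- make_posterior_stub(beta, lambda_site = lam,
                              guild = c(f1 = "fish", f2 = "fish",
                                        z1 = "zooplankton"))
  ra <- residual_associations(post, 0.95)
  expect_equal(ra$mean_correlation["f1", "f2"], 1)
  expect_equal(ra$mean_correlation["f1", "z1"], -1)
  expect_equal(ra$mean_correlation["f2", "z1"], -1)
  expect_true(all(ra$mask[upper.tri(ra$mask)]))
  expect_s3_class(ra$guild_summary, "data.frame")

  # zero loadings: nothing can be retained
  lam0 <- array(0, c(1, S, N))
  post0 <- make_posterior_stub(beta, lambda_site = lam0)
  ra0 <- residual_associations(post0, 0.95)
  expect_false(any(ra0$mask))
  expect_true(all(ra0$support[upper.tri(ra0$support)] <= 0.5))

  # no factors at all: identity with a warning
  post_nf <- make_posterior_stub(beta)
  expect_warning(ra_nf <- residual_associations(post_nf), "no latent factors")
  expect_false(any(ra_nf$mask))
})

test_that("PSRF separates mixed from unmixed chains", {
  set.seed(14)
  draws <- rnorm(1000)
  same <- array(c(draws, draws), c(1, 1, 2000))
  post_same <- make_posterior_stub(same, gamma = array(c(draws, draws),
                                                       c(1, 1, 2000)),
                                   chain = rep(1:2, each = 1000))
  cv_same <- check_convergence(post_same)
  expect_lt(abs(cv_same$psrf_beta[1, 1] - 1), 0.05)

  apart <- array(c(rnorm(1000, 0), rnorm(1000, 5)), c(1, 1, 2000))
  post_apart <- make_posterior_stub(apart, gamma = apart,
                                    chain = rep(1:2, each = 1000))
  cv_apart <- check_convergence(post_apart)
  expect_gt(cv_apart$psrf_beta[1, 1], 1.5)
  expect_gt(cv_apart$summary["max_psrf"], 1.5)
})

test_that("variance partitioning follows the variance algebra", {
  J <- 40; N <- 6
  set.seed(3)
  x1 <- rnorm(J); x2 <- rnorm(J)
  x2 <- residuals(lm(x2 ~ x1))                     # orthogonalise
  x1 <- (x1 - mean(x1)) / sd(x1); x2 <- (x2 - mean(x2)) / sd(x2)
  X <- cbind(intercept = 1, a = x1, b = x2)
  rownames(X) <- sprintf("s%02d", 1:J)
  beta <- array(rep(c(0, 1, 2), 2 * N), c(3, 2, N),
                dimnames = list(colnames(X), c("sp1", "sp2"), NULL))
  y <- matrix(rbinom(J * 2, 1, 0.5), J, 2,
              dimnames = list(rownames(X), c("sp1", "sp2")))
  post <- make_posterior_stub(beta, X = X, y = y)
  vp <- variance_partitioning(post, tjur = c(sp1 = 0.5, sp2 = 0.25))
  expect_equal(unname(vp$raw["a", ]), rep(0.2, 2), tolerance = 1e-10)
  expect_equal(unname(vp$raw["b", ]), rep(0.8, 2), tolerance = 1e-10)
  expect_equal(colSums(vp$raw), c(sp1 = 1, sp2 = 1), tolerance = 1e-12)
  expect_equal(colSums(vp$adjusted), c(sp1 = 0.5, sp2 = 0.25),
               tolerance = 1e-12)

  # single covariate, no random effects: full share to that covariate
  post1 <- make_posterior_stub(beta[c(1, 2), , , drop = FALSE],
                               X = X[, c(1, 2)], y = y)
  vp1 <- variance_partitioning(post1, tjur = c(sp1 = 0.3, sp2 = 0.3))
  expect_equal(unname(vp1$raw["a", ]), rep(1, 2), tolerance = 1e-12)
  expect_error(variance_partitioning(post, groups = list(g = character())),
               "empty")
})

test_that("intercept-only fit recovers the probit of prevalence", {
  occ <- cbind(spA = rep(c(1, 0), 20), spB = rep(c(0, 1, 1, 0), 10))
  rownames(occ) <- sprintf("s%02d", 1:40)
  comm <- community_table(occ, c(spA = "fish", spB = "zooplankton"))
  fit <- fit_jsdm(comm, make_intercept_env(40),
                  make_intercept_traits(colnames(occ)),
                  spec = jsdm_spec(0, 0),
                  mcmc = mcmc_config(thin = 1, samples = 800, n_chains = 2,
                                     transient = 200, seed = 2))
  bmean <- apply(fit$draws$beta, c(1, 2), mean)
  expect_lt(max(abs(bmean)), 0.15)      # probit^{-1}(0.5) = 0
})

test_that("identical seed and configuration give bit-identical samples", {
  toy <- toy_fixture()
  sim <- generate_metacommunity(sim_config(n_sites = 40, n_fish = 4,
                                           n_zoo = 4, seed = 6))
  pe <- sim_preprocess(sim$env)
  mc <- mcmc_config(thin = 1, samples = 30, n_chains = 2, transient = 20,
                    seed = 77)
  f1 <- fit_jsdm(sim$community, pe, sim$traits,
                 spec = jsdm_spec(1, 1, alpha_grid_n = 11), mcmc = mc)
  f2 <- fit_jsdm(sim$community, pe, sim$traits,
                 spec = jsdm_spec(1, 1, alpha_grid_n = 11), mcmc = mc)
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$alpha, f2$draws$alpha)
  expect_identical(f1$fitted, f2$fitted)
})

test_that("posterior means match a brute-force grid posterior", {
  # intercept-only, fixed Gamma = 0 and V = 1: species posteriors are
  # independent 1-D probit posteriors that a quadrature grid can evaluate
  set.seed(42)
  J <- 20
  occ <- cbind(spA = c(rep(1, 12), rep(0, 8)),
               spB = c(rep(1, 5), rep(0, 15)))[sample(J), ]
  rownames(occ) <- sprintf("s%02d", 1:J)
  comm <- community_table(occ, c(spA = "fish", spB = "zooplankton"))
  fit <- fit_jsdm(comm, make_intercept_env(J),
                  make_intercept_traits(colnames(occ)),
                  spec = jsdm_spec(0, 0),
                  mcmc = mcmc_config(thin = 2, samples = 2000, n_chains = 2,
                                     transient = 500, seed = 9),
                  fixed = list(gamma = matrix(0, 1, 1),
                               V = matrix(1, 1, 1)))
  bmean <- apply(fit$draws$beta, c(1, 2), mean)
  grid_mean <- function(y) {
    b <- seq(-4, 4, length.out = 4001)
    ll <- vapply(b, function(bb)
      sum(y * pnorm(bb, log.p = TRUE) + (1 - y) * pnorm(-bb, log.p = TRUE)),
      numeric(1))
    w <- exp(ll + dnorm(b, log = TRUE) - max(ll))
    sum(b * w) / sum(w)
  }
  expect_equal(bmean[1, "spA"], grid_mean(occ[, "spA"]), tolerance = 0.04)
  expect_equal(bmean[1, "spB"], grid_mean(occ[, "spB"]), tolerance = 0.04)
})

test_that("prior-only sampling reproduces the trait-implied prior mean", {
  occ <- cbind(spA = rep(c(1, 0), 10), spB = rep(c(0, 1), 10))
  rownames(occ) <- sprintf("s%02d", 1:20)
  comm <- community_table(occ, c(spA = "fish", spB = "zooplankton"))
  fit <- fit_jsdm(comm, make_intercept_env(20),
                  make_intercept_traits(colnames(occ)),
                  spec = jsdm_spec(0, 0),
                  mcmc = mcmc_config(thin = 1, samples = 1500, n_chains = 2,
                                     transient = 100, seed = 4),
                  fixed = list(gamma = matrix(0.7, 1, 1),
                               V = matrix(0.25, 1, 1)),
                  prior_only = TRUE)
  expect_equal(mean(fit$draws$beta), 0.7, tolerance = 0.05)
})

test_that("degenerate species and misaligned tables are rejected", {
  occ <- cbind(spA = rep(1, 12), spB = rep(c(0, 1), 6))
  rownames(occ) <- sprintf("s%02d", 1:12)
  comm <- community_table(occ, c(spA = "fish", spB = "zooplankton"))
  expect_error(fit_jsdm(comm, make_intercept_env(12),
                        make_intercept_traits(colnames(occ)),
                        spec = jsdm_spec(0, 0)),
               "constant occurrence")
})
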