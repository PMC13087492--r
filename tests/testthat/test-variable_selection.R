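make_rf_data <- function(J = 80, n_noise = 3, n_species = 4, seed = 1) {
  set.seed(seed)
  x1 <- rnorm(J)
  noise <- matrix(rnorm(J * n_noise), J,
                  dimnames = list(NULL, paste0("noise", seq_len(n_noise))))
  cv <- cbind(x1 = x1, noise)
  rownames(cv) <- sprintf("s%02d", seq_len(J))
  coords <- cbind(lon = rnorm(J), lat = rnorm(J))
  occ <- matrix(rep(as.integer(x1 > 0), n_species), J,
                dimnames = list(rownames(cv), paste0("sp", seq_len(n_species))))
  cls <- setNames(rep("climate", ncol(cv)), colnames(cv))
  list(community = community_table(occ, setNames(rep("fish", n_species),
                                                 colnames(occ))),
       env = env_table(cv, cls, coords))
}

test_that("a deterministic driver ranks first and noise importance is null", {
  set.seed(99)
  diffs <- replicate(5, {
    d <- make_rf_data(seed = sample.int(1e6, 1))
    imp <- fit_species_forests(d$community, d$env, n_trees = 200, seed = 1,
                               include_coords = FALSE)
    c(first = imp$ranking[1] == "x1",
      gap = imp$global_importance["x1"] -
        max(imp$global_importance[paste0("noise", 1:3)]))
  })
  expect_true(all(as.logical(diffs["first", ])))
  expect_true(all(as.numeric(diffs["gap.x1", ]) > 0.1))
})

test_that("pure-noise covariates have importance indistinguishable from zero", {
  set.seed(31)
  per_seed <- sapply(1:10, function(s) {
    J <- 60
    cv <- matrix(rnorm(J * 4), J, dimnames = list(sprintf("s%02d", 1:J),
                                                  paste0("v", 1:4)))
    occ <- matrix(rbinom(J * 3, 1, 0.5), J,
                  dimnames = list(rownames(cv), paste0("sp", 1:3)))
    occ[1:2, ] <- rbind(1, 0)          # keep responses non-constant
    comm <- community_table(occ, setNames(rep("fish", 3), colnames(occ)))
    env <- env_table(cv, setNames(rep("climate", 4), colnames(cv)),
                     cbind(lon = rnorm(J), lat = rnorm(J)))
    fit_species_forests(comm, env, n_trees = 300, seed = s,
                        include_coords = FALSE)$global_importance
  })
  mc_mean <- rowMeans(per_seed)
  mc_se <- apply(per_seed, 1, sd) / sqrt(ncol(per_seed))
  # per-covariate band widened for the four-way comparison; the grand mean
  # carries the sharper unbiasedness check
  expect_true(all(abs(mc_mean) <= 3 * mc_se + 1e-3))
  grand <- mean(per_seed)
  grand_se <- sd(colMeans(per_seed)) / sqrt(ncol(per_seed))
  expect_lte(abs(grand), 2 * grand_se + 1e-3)
})

test_that("global importance is invariant to species order and recomposable", {
  d <- make_rf_data(seed = 7)
  # make species responses heterogeneous
  occ <- d$community$occurrence
  set.seed(8)
  occ[, 2] <- rbinom(nrow(occ), 1, 0.5)
  occ[, 3] <- as.integer(d$env$covariates[, "noise1"] > 0)
  comm <- community_table(occ, d$community$guild)
  imp <- fit_species_forests(comm, d$env, n_trees = 150, seed = 3,
                             include_coords = FALSE)
  perm <- c(3, 1, 4, 2)
  comm_p <- community_table(occ[, perm], d$community$guild[perm])
  imp_p <- fit_species_forests(comm_p, d$env, n_trees = 150, seed = 3,
                               include_coords = FALSE)
  expect_equal(imp_p$global_importance, imp$global_importance,
               tolerance = 1e-12)
  # aggregate equals the error-weighted recombination of the parts
  w <- pmax(0, 1 - imp$oob_error)
  expect_equal(imp$global_importance,
               colSums(imp$importance * w) / sum(w), tolerance = 1e-12)
})

test_that("identical species give equal weights and the unweighted mean", {
  d <- make_rf_data(seed = 11)   # all species share the same response
  imp <- fit_species_forests(d$community, d$env, n_trees = 100, seed = 2,
                             include_coords = FALSE)
  expect_true(sd(imp$weights) < 1e-12)
  expect_equal(imp$global_importance, colMeans(imp$importance),
               tolerance = 1e-12)
})

test_that("constant-occurrence species are skipped with a warning", {
  d <- make_rf_data(seed = 13)
  occ <- d$community$occurrence
  occ[, 4] <- 1
  comm <- community_table(occ, d$community$guild)
  expect_warning(imp <- fit_species_forests(comm, d$env, n_trees = 50,
                                            seed = 1,
                                            include_coords = FALSE),
                 "sp4")
  expect_false("sp4" %in% rownames(imp$importance))
})

test_that("top-k selection preserves order and applies exclusions", {
  fake <- structure(list(global_importance =
                           setNames(12:1, c("temp_max", "lat", "temp_min",
                                            "lon", "watershed", "lake_area",
                                            "popdens", "precip", "seasonality",
                                            "elevation", "extra1", "extra2")),
                         ranking = c("temp_max", "lat", "temp_min", "lon",
                                     "watershed", "lake_area", "popdens",
                                     "precip", "seasonality", "elevation",
                                     "extra1", "extra2")),
                    class = "importance_table")
  # coordinates inside the top 10 leave eight fixed terms once excluded
  sel <- select_top_k(fake, k = 10, exclude = c("lat", "lon"))
  expect_length(sel, 8)
  expect_identical(sel[1], "temp_max")
  expect_false(any(c("lat", "lon") %in% sel))

  expect_identical(select_top_k(fake, k = 2), c("temp_max", "lat"))
  expect_warning(all_of_them <- select_top_k(fake, k = 50), "retaining all")
  expect_length(all_of_them, 12)

  toy3 <- structure(list(ranking = c("c", "b", "a"),
                         global_importance = setNames(3:1, c("c", "b", "a"))),
                    class = "importance_table")
  expect_identical(select_top_k(toy3, k = 2), c("c", "b"))
})
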