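test_that("shipped fixture loads, aligns and round-trips exactly", {
  base <- system.file("extdata", package = "multitroph")
  cls <- c(temp_max = "climate", precip_total = "climate",
           lake_area = "morphometry")
  ds <- load_dataset(file.path(base, "toy_community.csv"),
                     file.path(base, "toy_env.csv"),
                     file.path(base, "toy_traits.csv"),
                     covariate_class = cls)
  expect_equal(dim(ds$community$occurrence), c(6L, 8L))
  expect_setequal(unique(ds$community$guild), c("fish", "zooplankton"))
  expect_identical(rownames(ds$community$occurrence),
                   rownames(ds$env$covariates))
  expect_identical(colnames(ds$community$occurrence),
                   ds$traits$species_ids)

  tmp <- tempfile()
  write_dataset(ds$community, ds$env, ds$traits, tmp)
  ds2 <- load_dataset(paste0(tmp, "_community.csv"),
                      paste0(tmp, "_env.csv"),
                      paste0(tmp, "_traits.csv"), covariate_class = cls)
  expect_identical(ds2$community$occurrence, ds$community$occurrence)
  expect_identical(ds2$env$covariates, ds$env$covariates)
  expect_equal(ds2$traits$continuous, ds$traits$continuous)
  expect_equal(ds2$traits$categorical, ds$traits$categorical)
})

test_that("validation rejects malformed tables with informative errors", {
  toy <- toy_fixture()
  occ <- toy$community$occurrence
  bad <- occ
  bad[2, 3] <- 2
  expect_error(community_table(bad, toy$community$guild), "0/1")
  expect_error(community_table(bad, toy$community$guild), "s2")

  # binarize flag admits abundances explicitly
  ct <- community_table(bad, toy$community$guild, binarize = TRUE)
  expect_identical(sort(unique(as.vector(ct$occurrence))), c(0L, 1L))

  dup <- occ
  rownames(dup)[2] <- "s1"
  expect_error(community_table(dup, toy$community$guild), "duplicated site")

  expect_error(community_table(occ, toy$community$guild[-1]),
               "without a guild")

  # env missing a site that the community has
  base <- system.file("extdata", package = "multitroph")
  env_df <- utils::read.csv(file.path(base, "toy_env.csv"))
  tmp_env <- tempfile(fileext = ".csv")
  utils::write.csv(env_df[-4, ], tmp_env, row.names = FALSE)
  cls <- c(temp_max = "climate", precip_total = "climate",
           lake_area = "morphometry")
  expect_error(
    load_dataset(file.path(base, "toy_community.csv"), tmp_env,
                 file.path(base, "toy_traits.csv"), covariate_class = cls),
    "s4")
})

test_that("rare-species filter drops singletons, is idempotent, errors when empty", {
  toy <- toy_fixture()
  occ <- toy$community$occurrence
  occ[, "f5"] <- c(1, 0, 0, 0, 0, 0)     # make f5 a singleton
  ct <- community_table(occ, toy$community$guild)

  filtered <- filter_rare_species(ct, min_sites = 2)
  expect_identical(attr(filtered, "removed"), "f5")
  expect_identical(colnames(filtered$occurrence), setdiff(colnames(occ), "f5"))

  # no-op when every species clears the threshold, and idempotent
  again <- filter_rare_species(filtered, min_sites = 2)
  expect_identical(again$occurrence, filtered$occurrence)
  untouched <- filter_rare_species(toy$community, min_sites = 2)
  expect_identical(untouched$occurrence, toy$community$occurrence)

  expect_error(filter_rare_species(ct, min_sites = 10), "all species")
})

test_that("preprocessing transforms, screens collinear pairs, imputes and standardises", {
  set.seed(71)
  n <- 20
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, 0, 0.05)       # |r| > 0.9 with x1
  x3 <- rnorm(n)                     # low correlation with both
  stopifnot(abs(cor(x1, x2)) > 0.9, abs(cor(x1, x3)) < 0.5,
            abs(cor(x2, x3)) < 0.5)
  cv <- cbind(a = x1, b = x2, c = x3)
  rownames(cv) <- sprintf("s%02d", 1:n)
  coords <- cbind(lon = rnorm(n), lat = rnorm(n))
  env <- env_table(cv, c(a = "climate", b = "climate", c = "morphometry"),
                   coords)
  pe <- preprocess_env(env, pipeline_config())
  # later-listed member of the offending pair dropped, exactly one drop
  expect_identical(pe$preprocessing$dropped, "b")
  expect_identical(colnames(pe$covariates), c("a", "c"))
  expect_equal(unname(colMeans(pe$covariates)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(pe$covariates, 2, sd)), c(1, 1),
               tolerance = 1e-12)

  # imputation: mean fills with observed column mean, median is default
  cv_na <- cv
  cv_na[3, "c"] <- NA
  env_na <- env_table(cv_na, env$covariate_class, coords)
  pe_mean <- preprocess_env(env_na, pipeline_config(impute = "mean"))
  raw_mean <- mean(cv_na[-3, "c"])
  expect_equal(unname(pe_mean$preprocessing$center["c"] +
                        pe_mean$covariates[3, "c"] *
                        pe_mean$preprocessing$scale["c"]),
               raw_mean, tolerance = 1e-12)
  pe_med <- preprocess_env(env_na, pipeline_config())
  expect_identical(pe_med$preprocessing$imputed, "c")

  # log transform of a non-positive cell names the offender
  cv_neg <- cv
  cv_neg[, "a"] <- abs(cv_neg[, "a"]) + 1
  cv_neg[5, "a"] <- -1
  env_neg <- env_table(cv_neg, env$covariate_class, coords)
  expect_error(preprocess_env(env_neg,
                              pipeline_config(transform = c(a = "log"))),
               "s05")

  # zero-variance covariate dropped with a warning
  cv_const <- cbind(cv, d = rep(4, n))
  env_const <- env_table(cv_const, c(env$covariate_class, d = "climate"),
                         coords)
  expect_warning(pe_c <- preprocess_env(env_const, pipeline_config()),
                 "zero-variance")
  expect_false("d" %in% colnames(pe_c$covariates))
})

test_that("baseline standardisation is reused verbatim on scenario tables", {
  toy <- toy_fixture()
  pe <- preprocess_env(toy$env,
                       pipeline_config(transform = c(lake_area = "log")))
  # zero-change replacement reproduces the baseline design exactly
  same <- build_scenario_env(pe, pe$preprocessing$raw[, c("temp_max",
                                                          "precip_total")],
                             scenario = "SSP1-2.6")
  expect_equal(same$covariates, pe$covariates, tolerance = 1e-14)
  expect_identical(same$scenario, "SSP1-2.6")
  # shift on the raw scale maps to delta / sd on the standardised scale
  shifted <- pe$preprocessing$raw[, "temp_max", drop = FALSE] + 2
  env2 <- build_scenario_env(pe, shifted)
  expect_equal(env2$covariates[, "temp_max"] - pe$covariates[, "temp_max"],
               rep(2 / pe$preprocessing$scale[["temp_max"]], 6),
               ignore_attr = TRUE, tolerance = 1e-12)
  # morphometry replacement refused
  expect_error(build_scenario_env(pe, pe$preprocessing$raw[, "lake_area",
                                                           drop = FALSE]),
               "climate")
})

test_that("pipeline configuration validates and reads from YAML", {
  expect_error(pipeline_config(cor_threshold = 1.2))
  expect_error(pipeline_config(support_beta = 0.4))
  cfg_path <- tempfile(fileext = ".yaml")
  writeLines(c("transform:", "  lake_area: log", "cor_threshold: 0.85",
               "impute: mean", "seed: 42", "mcmc:", "  thin: 2",
               "  samples: 10", "  n_chains: 2", "  transient: 5"),
             cfg_path)
  cfg <- read_pipeline_config(cfg_path)
  expect_identical(cfg$transform, c(lake_area = "log"))
  expect_equal(cfg$cor_threshold, 0.85)
  expect_identical(cfg$impute, "mean")
  expect_identical(cfg$seed, 42L)
  expect_identical(cfg$mcmc$thin, 2L)
})
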