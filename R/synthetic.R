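# Synthetic metacommunities with known ground truth.
#
# The generator follows the same generative model the sampler fits:
# liabilities z = X beta + eta_site Lambda_site + eta_spatial Lambda_spatial
# + standard normal noise, occurrences y = 1[z > 0], with species-level
# coefficients drawn around trait-implied means, beta_j ~ N(Gamma' t_j, V).

# Built-in covariate recipe: name, class, latitudinal trend and noise on the
# raw scale, and the variance-stabilising transform the pipeline applies.
.sim_covariate_recipe <- function() {
  list(
    temp_max = list(class = "climate", base = 29, lat_slope = -1.1,
                    noise_sd = 1.3, transform = "identity"),
    temp_min = list(class = "climate", base = -8, lat_slope = -0.5,
                    noise_sd = 2.0, transform = "identity"),
    precip_total = list(class = "climate", base = 900, lat_slope = 14,
                        noise_sd = 80, transform = "identity"),
    lake_area = list(class = "morphometry", base = NA, lat_slope = 0,
                     noise_sd = NA, transform = "log")
  )
}

.default_sim_gamma <- function(trait_rows, covariate_cols) {
  g <- matrix(0, length(trait_rows), length(covariate_cols),
              dimnames = list(trait_rows, covariate_cols))
  set_if <- function(r, c, v) if (r %in% trait_rows && c %in% covariate_cols)
    g[r, c] <<- v
  # shared positive responses: warmth and lake size favour occurrence
  set_if("intercept", "temp_max", 0.6)
  set_if("intercept", "lake_area", 0.7)
  # larger-bodied species respond more negatively to maximum temperature
  set_if("length_mm", "temp_max", -0.8)
  # heat-tolerant species respond more positively to maximum temperature
  set_if("ctmax_c", "temp_max", 0.6)
  # top trophic group disfavoured by high precipitation
  set_if("trophic_grouptop", "precip_total", -0.6)
  g
}

#' Simulation configuration
#'
#' @param n_sites Number of lakes placed along the latitudinal gradient.
#' @param n_fish,n_zoo Species per guild.
#' @param covariates Which of the built-in covariates to generate; any subset
#'   of `temp_max`, `temp_min`, `precip_total` (climate) and `lake_area`
#'   (morphometry).
#' @param gamma Optional trait-by-covariate effect matrix (rows = expanded
#'   trait design incl. intercept, columns = intercept + covariates). `NULL`
#'   uses the planted defaults; `0` disables all trait effects.
#' @param v_diag Diagonal of the residual niche covariance V (species-level
#'   spread of beta around the trait-implied mean).
#' @param n_cross_pairs Number of planted fish-zooplankton residual
#'   association pairs (one site-level latent factor).
#' @param cross_loading Absolute loading of planted pair members.
#' @param n_spatial_factors Number of spatially structured latent factors.
#' @param alpha_true Spatial decay scale (degrees) of spatial factors.
#' @param spatial_loading_sd Loading spread of spatial factors.
#' @param lat_range,lon_range Geographic extent (decimal degrees).
#' @param max_attempts Redraws allowed per species before giving up when a
#'   draw yields a degenerate (near-constant) occurrence column.
#' @param seed Integer seed (mandatory; every random component derives from
#'   it).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 150, n_fish = 15, n_zoo = 15,
                       covariates = c("temp_max", "temp_min",
                                      "precip_total", "lake_area"),
                       gamma = NULL, v_diag = 0.25,
                       n_cross_pairs = 3, cross_loading = 1.2,
                       n_spatial_factors = 0, alpha_true = 5,
                       spatial_loading_sd = 0.5,
                       lat_range = c(45, 62), lon_range = c(-79, -64),
                       max_attempts = 60, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed")
  recipe <- .sim_covariate_recipe()
  unknown <- setdiff(covariates, names(recipe))
  if (length(unknown))
    stop("unknown covariates: ", paste(unknown, collapse = ", "))
  stopifnot(n_sites > 0, n_fish > 0, n_zoo > 0, n_cross_pairs >= 0,
            n_spatial_factors >= 0, max_attempts >= 1)
  if (n_cross_pairs > min(n_fish, n_zoo))
    stop("more planted pairs than species in a guild")
  structure(list(n_sites = as.integer(n_sites), n_fish = as.integer(n_fish),
                 n_zoo = as.integer(n_zoo), covariates = covariates,
                 gamma = gamma, v_diag = v_diag,
                 n_cross_pairs = as.integer(n_cross_pairs),
                 cross_loading = cross_loading,
                 n_spatial_factors = as.integer(n_spatial_factors),
                 alpha_true = alpha_true,
                 spatial_loading_sd = spatial_loading_sd,
                 lat_range = lat_range, lon_range = lon_range,
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic two-guild metacommunity
#'
#' Places sites along a latitudinal climate gradient, draws traits, builds
#' trait-implied species coefficients, adds latent-factor structure
#' (including planted fish-zooplankton association pairs), and thresholds
#' probit liabilities into presence-absence data. All ground truth is
#' returned for parameter-recovery checks.
#'
#' @param config A [sim_config()].
#' @return A list with `community` (a `community_table`), `env` (a raw
#'   `env_table`), `traits` (a `trait_table`) and `truth` (true parameters:
#'   `gamma`, `beta`, `V`, `lambda_site`, `lambda_spatial`, `alpha`,
#'   `planted_pairs`, the standardised design `X` actually used, the
#'   `transform` map, and the expanded `trait_design`).
#' @export
generate_metacommunity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  J <- config$n_sites
  S <- config$n_fish + config$n_zoo
  recipe <- .sim_covariate_recipe()[config$covariates]

  site_ids <- sprintf("site_%03d", seq_len(J))
  lat <- sort(stats::runif(J, config$lat_range[1], config$lat_range[2]))
  lon <- stats::runif(J, config$lon_range[1], config$lon_range[2])
  coords <- cbind(lon = lon, lat = lat)
  rownames(coords) <- site_ids

  raw <- matrix(NA_real_, J, length(recipe),
                dimnames = list(site_ids, names(recipe)))
  for (v in names(recipe)) {
    r <- recipe[[v]]
    raw[, v] <- if (v == "lake_area") {
      stats::rlnorm(J, meanlog = 2, sdlog = 1)
    } else {
      r$base + r$lat_slope * (lat - config$lat_range[1]) +
        stats::rnorm(J, 0, r$noise_sd)
    }
  }
  cov_class <- vapply(recipe, `[[`, character(1), "class")
  transform_map <- vapply(recipe, `[[`, character(1), "transform")

  # standardized design actually entering the liabilities
  xt <- raw
  for (v in names(recipe)) if (transform_map[[v]] == "log") xt[, v] <- log(xt[, v])
  xs <- scale(xt)
  attr(xs, "scaled:center") <- attr(xs, "scaled:scale") <- NULL
  X <- cbind(intercept = 1, xs)

  species_ids <- c(sprintf("fish_%02d", seq_len(config$n_fish)),
                   sprintf("zoo_%02d", seq_len(config$n_zoo)))
  guild <- stats::setNames(rep(c("fish", "zooplankton"),
                               c(config$n_fish, config$n_zoo)), species_ids)
  length_mm <- c(stats::rlnorm(config$n_fish, log(150), 0.6),
                 stats::rlnorm(config$n_zoo, log(0.8), 0.4))
  ctmax_c <- stats::rnorm(S, 30, 3)
  trophic <- sample(c("low", "mid", "top"), S, replace = TRUE,
                    prob = c(0.4, 0.4, 0.2))
  continuous <- cbind(length_mm = length_mm, ctmax_c = ctmax_c)
  rownames(continuous) <- species_ids
  categorical <- data.frame(trophic_group = factor(trophic,
                                                   c("low", "mid", "top")),
                            row.names = species_ids)
  traits <- trait_table(continuous, categorical)
  Tq <- expand_traits(traits)          # Q x S expanded design

  K <- ncol(X)
  Q <- nrow(Tq)
  gamma <- config$gamma
  if (is.null(gamma)) {
    gamma <- .default_sim_gamma(rownames(Tq), colnames(X))
  } else if (identical(gamma, 0)) {
    gamma <- matrix(0, Q, K, dimnames = list(rownames(Tq), colnames(X)))
  } else {
    gamma <- as.matrix(gamma)
    stopifnot(nrow(gamma) == Q, ncol(gamma) == K)
    dimnames(gamma) <- list(rownames(Tq), colnames(X))
  }
  V <- diag(rep(config$v_diag, length.out = K), K)
  dimnames(V) <- list(colnames(X), colnames(X))

  # planted cross-guild association factor (site-level)
  H1 <- as.integer(config$n_cross_pairs > 0)
  lambda_site <- matrix(0, H1, S, dimnames = list(NULL, species_ids))
  planted <- NULL
  if (H1 == 1) {
    fish_idx <- sample(seq_len(config$n_fish), config$n_cross_pairs)
    zoo_idx <- config$n_fish + sample(seq_len(config$n_zoo),
                                      config$n_cross_pairs)
    signs <- rep_len(c(1, -1), config$n_cross_pairs)
    lambda_site[1, fish_idx] <- config$cross_loading
    lambda_site[1, zoo_idx] <- signs * config$cross_loading
    planted <- data.frame(fish = species_ids[fish_idx],
                          zoo = species_ids[zoo_idx], sign = signs)
  }
  eta_site <- matrix(stats::rnorm(J * H1), J, H1)

  H2 <- config$n_spatial_factors
  lambda_spatial <- matrix(0, H2, S, dimnames = list(NULL, species_ids))
  eta_spatial <- matrix(0, J, H2)
  if (H2 > 0) {
    lambda_spatial[] <- stats::rnorm(H2 * S, 0, config$spatial_loading_sd)
    d <- as.matrix(stats::dist(coords))
    Sg <- exp(-d / config$alpha_true)
    L <- chol(Sg + diag(1e-8, J))
    for (h in seq_len(H2)) eta_spatial[, h] <- drop(crossprod(L, stats::rnorm(J)))
  }

  random_part <- eta_site %*% lambda_site + eta_spatial %*% lambda_spatial
  Lv <- chol(V)
  M <- crossprod(gamma, Tq)            # K x S trait-implied means
  beta <- matrix(NA_real_, K, S, dimnames = list(colnames(X), species_ids))
  occ <- matrix(NA_integer_, J, S, dimnames = list(site_ids, species_ids))
  for (j in seq_len(S)) {
    ok <- FALSE
    for (att in seq_len(config$max_attempts)) {
      bj <- M[, j] + drop(crossprod(Lv, stats::rnorm(K)))
      zj <- drop(X %*% bj) + random_part[, j] + stats::rnorm(J)
      yj <- as.integer(zj > 0)
      if (sum(yj) >= 2 && sum(yj) <= J - 2) {
        beta[, j] <- bj
        occ[, j] <- yj
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("species ", species_ids[j],
                  " remained degenerate after ", config$max_attempts,
                  " redraws; adjust the configuration")
  }

  community <- community_table(occ, guild)
  env <- env_table(raw, cov_class, coords, scenario = "baseline")
  truth <- list(gamma = gamma, beta = beta, V = V,
                lambda_site = lambda_site, lambda_spatial = lambda_spatial,
                alpha = if (H2 > 0) config$alpha_true else numeric(),
                planted_pairs = planted, X = X,
                transform = transform_map, trait_design = Tq,
                seed = config$seed)
  list(community = community, env = env, traits = traits, truth = truth)
}

#' Shift climate covariates of a raw environment table
#'
#' Produces a scenario variant by adding per-covariate deltas (scalar or
#' per-site vectors) to climate-class covariates on the raw scale.
#'
#' @param env A raw `env_table` (baseline).
#' @param deltas Named list/vector of shifts; names must be climate-class
#'   covariates; each element a scalar or a per-site vector.
#' @param scenario Label for the shifted table (default `"custom"`).
#' @return The shifted raw `env_table`.
#' @export
generate_scenario_shift <- function(env, deltas, scenario = "custom") {
  stopifnot(inherits(env, "env_table"))
  deltas <- as.list(deltas)
  for (v in names(deltas)) {
    if (!v %in% colnames(env$covariates))
      stop("unknown covariate in deltas: ", v)
    if (env$covariate_class[[v]] != "climate")
      stop("scenario shifts may only target climate covariates; '", v,
           "' is ", env$covariate_class[[v]])
  }
  x <- env$covariates
  for (v in names(deltas)) {
    d <- deltas[[v]]
    if (!length(d) %in% c(1L, nrow(x)))
      stop("delta for ", v, " must be scalar or one value per site")
    x[, v] <- x[, v] + d
  }
  env_table(x, env$covariate_class, env$coords, scenario = scenario)
}

#' Tiny fixed example dataset
#'
#' A deterministic 6-site, 8-species (5 fish + 3 zooplankton), 3-covariate
#' dataset used throughout the documentation and tests. Its per-site
#' richness is c(5, 5, 6, 3, 4, 3).
#'
#' @return A list with `community`, `env`, `traits` (raw tables).
#' @export
toy_fixture <- function() {
  sites <- paste0("s", 1:6)
  species <- c(paste0("f", 1:5), paste0("z", 1:3))
  occ <- matrix(c(
    # f1 f2 f3 f4 f5 z1 z2 z3
    1, 1, 0, 0, 1, 1, 0, 1,   # s1
    1, 1, 1, 0, 0, 1, 1, 0,   # s2
    1, 0, 1, 1, 0, 1, 1, 1,   # s3
    1, 0, 0, 1, 0, 0, 1, 0,   # s4
    0, 0, 1, 1, 0, 1, 0, 1,   # s5
    0, 0, 0, 1, 1, 1, 0, 0    # s6
  ), nrow = 6, byrow = TRUE, dimnames = list(sites, species))
  guild <- stats::setNames(rep(c("fish", "zooplankton"), c(5, 3)), species)
  covariates <- cbind(temp_max = c(26, 24, 21, 19, 16, 14),
                      precip_total = c(950, 980, 1010, 990, 1060, 1100),
                      lake_area = c(12, 5, 48, 7, 150, 22))
  rownames(covariates) <- sites
  coords <- cbind(lon = c(-72, -71, -70.5, -69.8, -69, -68),
                  lat = c(46, 48, 50, 52.5, 55, 58))
  rownames(coords) <- sites
  cov_class <- c(temp_max = "climate", precip_total = "climate",
                 lake_area = "morphometry")
  continuous <- cbind(length_mm = c(300, 150, 80, 450, 120, 0.4, 1.2, 0.6),
                      ctmax_c = c(32, 30, 28, 26, 24, 35, 33, 34))
  rownames(continuous) <- species
  categorical <- data.frame(
    trophic_group = factor(c("top", "mid", "low", "top", "mid",
                             "low", "mid", "low"), c("low", "mid", "top")),
    row.names = species)
  list(community = community_table(occ, guild),
       env = env_table(covariates, cov_class, coords),
       traits = trait_table(continuous, categorical))
}
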