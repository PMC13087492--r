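# Table containers, CSV I/O and preprocessing for the pipeline.

#' Site-by-species occurrence table
#'
#' Container for a binary (presence-absence) site-by-species matrix with a
#' guild label per species. This is the response matrix of the joint model.
#'
#' @param occurrence Numeric matrix, sites in rows, species in columns, with
#'   entries in \{0, 1\}. Row and column names are the site and species
#'   identifiers and must be unique.
#' @param guild Named character vector mapping every species identifier to a
#'   guild label (typically `"fish"` or `"zooplankton"`).
#' @param binarize If `TRUE`, positive abundances are converted to 1 before
#'   validation. Abundance inputs must opt in explicitly; otherwise any entry
#'   outside \{0, 1\} is an error.
#'
#' @return An object of class `community_table` with elements `occurrence`
#'   (integer matrix) and `guild`.
#' @examples
#' occ <- matrix(c(1, 0, 1, 1, 0, 1), nrow = 2,
#'               dimnames = list(c("s1", "s2"), c("spA", "spB", "spC")))
#' ct <- community_table(occ, c(spA = "fish", spB = "fish", spC = "zooplankton"))
#' richness(ct)
#' @export
community_table <- function(occurrence, guild, binarize = FALSE) {
  occurrence <- as.matrix(occurrence)
  if (is.null(rownames(occurrence)) || is.null(colnames(occurrence)))
    stop("occurrence matrix needs site row names and species column names")
  if (anyDuplicated(rownames(occurrence)))
    stop("duplicated site identifiers: ",
         paste(unique(rownames(occurrence)[duplicated(rownames(occurrence))]),
               collapse = ", "))
  if (anyDuplicated(colnames(occurrence)))
    stop("duplicated species identifiers: ",
         paste(unique(colnames(occurrence)[duplicated(colnames(occurrence))]),
               collapse = ", "))
  if (binarize) occurrence[] <- as.numeric(occurrence > 0)
  bad <- which(!(occurrence %in% c(0, 1)))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(occurrence))
    stop(sprintf(
      "occurrence values must be 0/1; first offending cell [%s, %s] = %s",
      rownames(occurrence)[idx[1]], colnames(occurrence)[idx[2]],
      occurrence[bad[1]]))
  }
  guild <- unlist(guild)
  missing_guild <- setdiff(colnames(occurrence), names(guild))
  if (length(missing_guild))
    stop("species without a guild label: ", paste(missing_guild, collapse = ", "))
  storage.mode(occurrence) <- "integer"
  structure(list(occurrence = occurrence,
                 guild = guild[colnames(occurrence)]),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat("community_table:", nrow(x$occurrence), "sites x",
      ncol(x$occurrence), "species\n")
  tab <- table(x$guild)
  cat("guilds:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Site-by-covariate environment table
#'
#' Holds the (possibly preprocessed) environmental design matrix, a class
#' label per covariate (`climate`, `morphometry` or `anthropogenic`), site
#' coordinates in decimal degrees, and a scenario tag.
#'
#' @param covariates Numeric matrix, sites in rows (named), covariates in
#'   columns (named).
#' @param covariate_class Named character vector assigning each covariate to
#'   one of `climate`, `morphometry`, `anthropogenic`.
#' @param coords Two-column matrix `(lon, lat)` in decimal degrees, one row
#'   per site (same order as `covariates`).
#' @param scenario Scenario label; one of `baseline`, `SSP1-2.6`,
#'   `SSP3-7.0`, `SSP5-8.5` or `custom`.
#' @param preprocessing Optional list of fitted preprocessing parameters (see
#'   [preprocess_env()]); carried along so scenario tables reuse them.
#'
#' @return An object of class `env_table`.
#' @export
env_table <- function(covariates, covariate_class, coords,
                      scenario = "baseline", preprocessing = NULL) {
  covariates <- as.matrix(covariates)
  if (is.null(rownames(covariates)) ||
      (ncol(covariates) > 0 && is.null(colnames(covariates))))
    stop("covariate matrix needs site row names and covariate column names")
  if (anyDuplicated(rownames(covariates)))
    stop("duplicated site identifiers in env table")
  covariate_class <- unlist(covariate_class)
  unknown <- setdiff(colnames(covariates), names(covariate_class))
  if (length(unknown))
    stop("covariates without a class label: ", paste(unknown, collapse = ", "))
  bad_class <- setdiff(unique(covariate_class),
                       c("climate", "morphometry", "anthropogenic"))
  if (length(bad_class))
    stop("unknown covariate classes: ", paste(bad_class, collapse = ", "))
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(covariates) || ncol(coords) != 2)
    stop("coords must be a (lon, lat) matrix with one row per site")
  if (!all(is.finite(coords))) stop("coords must be finite")
  colnames(coords) <- c("lon", "lat")
  rownames(coords) <- rownames(covariates)
  scenarios <- c("baseline", "SSP1-2.6", "SSP3-7.0", "SSP5-8.5", "custom")
  if (!scenario %in% scenarios)
    stop("scenario must be one of: ", paste(scenarios, collapse = ", "))
  structure(list(covariates = covariates,
                 covariate_class = covariate_class[colnames(covariates)],
                 coords = coords,
                 scenario = scenario,
                 preprocessing = preprocessing),
            class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat("env_table:", nrow(x$covariates), "sites x", ncol(x$covariates),
      "covariates | scenario:", x$scenario,
      if (!is.null(x$preprocessing)) "| preprocessed" else "| raw", "\n")
  invisible(x)
}

#' Species-by-trait table
#'
#' @param continuous Numeric matrix of continuous traits (species in rows,
#'   named; e.g. body length in mm, CTmax in degrees C). May be `NULL`.
#' @param categorical Data frame of categorical traits (factors or character
#'   columns), same row names. May be `NULL`.
#'
#' @return An object of class `trait_table`.
#' @export
trait_table <- function(continuous = NULL, categorical = NULL) {
  if (is.null(continuous) && is.null(categorical))
    stop("at least one of continuous/categorical traits is required")
  species <- NULL
  if (!is.null(continuous)) {
    continuous <- as.matrix(continuous)
    if (is.null(rownames(continuous))) stop("continuous traits need species row names")
    species <- rownames(continuous)
  }
  if (!is.null(categorical)) {
    categorical <- as.data.frame(categorical, stringsAsFactors = TRUE)
    categorical[] <- lapply(categorical, as.factor)
    if (is.null(rownames(categorical)) ||
        identical(rownames(categorical), as.character(seq_len(nrow(categorical)))))
      if (is.null(species)) stop("categorical traits need species row names")
    if (is.null(species)) species <- rownames(categorical)
    if (!is.null(continuous) && !identical(rownames(categorical), species))
      stop("continuous and categorical trait tables disagree on species")
  }
  structure(list(species_ids = species, continuous = continuous,
                 categorical = categorical),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("trait_table:", length(x$species_ids), "species |",
      if (is.null(x$continuous)) 0 else ncol(x$continuous), "continuous,",
      if (is.null(x$categorical)) 0 else ncol(x$categorical), "categorical traits\n")
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the tunable knobs of the pipeline in one validated list. Defaults
#' follow the analysis conventions documented in the package vignette.
#'
#' @param transform Named character vector mapping covariate names to
#'   `"log"`, `"sqrt"` or `"identity"`. Unlisted covariates are left as-is.
#' @param cor_threshold Absolute Pearson correlation above which the
#'   later-listed member of a covariate pair is dropped.
#' @param impute Imputation method for missing covariate cells: `"median"`
#'   (default) or `"mean"`.
#' @param min_sites Minimum number of occupied sites for a species to be
#'   retained (rare-species filter); the default 2 removes species observed
#'   in a single lake.
#' @param rf_trees Number of trees per species classification forest.
#' @param rf_top_k Number of top-ranked covariates retained for the joint
#'   model.
#' @param mcmc [mcmc_config()] list of sampler settings.
#' @param support_beta,support_gamma,support_omega Posterior sign-support
#'   thresholds for beta/gamma heatmaps and residual associations.
#' @param network_alpha Two-sided p-value threshold for network edges.
#' @param seed Integer RNG seed recorded in all outputs.
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(transform = character(),
                            cor_threshold = 0.9,
                            impute = c("median", "mean"),
                            min_sites = 2,
                            rf_trees = 500,
                            rf_top_k = 10,
                            mcmc = mcmc_config(),
                            support_beta = 0.90,
                            support_gamma = 0.90,
                            support_omega = 0.95,
                            network_alpha = 0.01,
                            seed = 1L) {
  impute <- match.arg(impute)
  stopifnot(cor_threshold > 0, cor_threshold < 1,
            support_beta > 0.5, support_beta < 1,
            support_gamma > 0.5, support_gamma < 1,
            support_omega > 0.5, support_omega < 1,
            network_alpha > 0, network_alpha < 1,
            min_sites >= 1)
  structure(list(transform = transform, cor_threshold = cor_threshold,
                 impute = impute, min_sites = min_sites,
                 rf_trees = rf_trees, rf_top_k = rf_top_k, mcmc = mcmc,
                 support_beta = support_beta, support_gamma = support_gamma,
                 support_omega = support_omega,
                 network_alpha = network_alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; `mcmc` is a
#' nested mapping passed to [mcmc_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$transform)) raw$transform <- unlist(raw$transform)
  if (!is.null(raw$mcmc)) raw$mcmc <- do.call(mcmc_config, raw$mcmc)
  do.call(pipeline_config, raw)
}

#' Load and align the community, environment and trait tables
#'
#' Reads the three delimited tables, validates them, and aligns rows/columns:
#' sites ordered as in the community file, species as in the trait file
#' restricted to the community's species. All CSV files use the first column
#' as identifier.
#'
#' @param community_path CSV with `site_id` first, then one 0/1 column per
#'   species.
#' @param env_path CSV with columns `site_id`, `lon`, `lat`, then covariates.
#' @param trait_path CSV with columns `species_id`, `guild`, then trait
#'   columns; character columns become categorical traits, numeric columns
#'   continuous traits.
#' @param covariate_class Named character vector classifying every env
#'   covariate as `climate`, `morphometry` or `anthropogenic`.
#' @param scenario Scenario tag for the environment table.
#' @param binarize Passed to [community_table()].
#'
#' @return A list with elements `community`, `env`, `traits`.
#' @export
load_dataset <- function(community_path, env_path, trait_path,
                         covariate_class, scenario = "baseline",
                         binarize = FALSE) {
  for (p in c(community_path, env_path, trait_path))
    if (!file.exists(p)) stop("file not found: ", p)
  comm_df <- utils::read.csv(community_path, check.names = FALSE)
  env_df <- utils::read.csv(env_path, check.names = FALSE)
  trait_df <- utils::read.csv(trait_path, check.names = FALSE)

  occ <- as.matrix(comm_df[, -1, drop = FALSE])
  rownames(occ) <- as.character(comm_df[[1]])

  if (!all(c("lon", "lat") %in% names(env_df)))
    stop("env table must contain lon and lat columns")
  env_sites <- as.character(env_df[[1]])
  missing_env <- setdiff(rownames(occ), env_sites)
  if (length(missing_env))
    stop("sites present in community but missing from env table: ",
         paste(missing_env, collapse = ", "))
  env_df <- env_df[match(rownames(occ), env_sites), , drop = FALSE]
  cov_cols <- setdiff(names(env_df), c(names(env_df)[1], "lon", "lat"))
  covariates <- as.matrix(env_df[, cov_cols, drop = FALSE])
  rownames(covariates) <- rownames(occ)
  coords <- as.matrix(env_df[, c("lon", "lat")])

  if (!"guild" %in% names(trait_df))
    stop("trait table must contain a guild column")
  trait_species <- as.character(trait_df[[1]])
  missing_traits <- setdiff(colnames(occ), trait_species)
  if (length(missing_traits))
    stop("species present in community but missing from trait table: ",
         paste(missing_traits, collapse = ", "))
  trait_df <- trait_df[match(colnames(occ), trait_species), , drop = FALSE]
  guild <- stats::setNames(as.character(trait_df$guild), colnames(occ))

  trait_cols <- setdiff(names(trait_df), c(names(trait_df)[1], "guild"))
  is_num <- vapply(trait_df[trait_cols], is.numeric, logical(1))
  continuous <- if (any(is_num)) {
    m <- as.matrix(trait_df[, trait_cols[is_num], drop = FALSE])
    rownames(m) <- colnames(occ)
    m
  }
  categorical <- if (any(!is_num)) {
    d <- trait_df[, trait_cols[!is_num], drop = FALSE]
    rownames(d) <- colnames(occ)
    d
  }

  list(community = community_table(occ, guild, binarize = binarize),
       env = env_table(covariates, covariate_class, coords, scenario),
       traits = trait_table(continuous, categorical))
}

#' Write a dataset back to CSV
#'
#' Inverse of [load_dataset()]: writes `<prefix>_community.csv`,
#' `<prefix>_env.csv` and `<prefix>_traits.csv`.
#'
#' @param community A `community_table`.
#' @param env An `env_table` (raw covariates recommended for round-trips).
#' @param traits A `trait_table`.
#' @param prefix Path prefix for the three files.
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(community, env, traits, prefix) {
  paths <- paste0(prefix, c("_community.csv", "_env.csv", "_traits.csv"))
  occ <- community$occurrence
  utils::write.csv(data.frame(site_id = rownames(occ), occ,
                              check.names = FALSE),
                   paths[1], row.names = FALSE)
  utils::write.csv(data.frame(site_id = rownames(env$covariates),
                              lon = env$coords[, "lon"],
                              lat = env$coords[, "lat"],
                              env$covariates, check.names = FALSE),
                   paths[2], row.names = FALSE)
  td <- data.frame(species_id = traits$species_ids,
                   guild = unname(community$guild[traits$species_ids]),
                   check.names = FALSE)
  if (!is.null(traits$continuous)) td <- cbind(td, traits$continuous)
  if (!is.null(traits$categorical)) {
    cc <- traits$categorical
    cc[] <- lapply(cc, as.character)
    td <- cbind(td, cc)
  }
  utils::write.csv(td, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Remove rare species
#'
#' Drops species occupying fewer than `min_sites` sites. The default removes
#' species observed in only one lake, the criterion used before joint
#' modelling so that every modelled species carries information about
#' co-occurrence.
#'
#' @param community A `community_table`.
#' @param min_sites Minimum occupied-site count for retention.
#' @return A filtered `community_table`; the identifiers of removed species
#'   are attached as attribute `"removed"`.
#' @export
filter_rare_species <- function(community, min_sites = 2) {
  stopifnot(inherits(community, "community_table"))
  counts <- colSums(community$occurrence)
  keep <- counts >= min_sites
  if (!any(keep)) stop("rare-species filter removed all species")
  out <- community_table(community$occurrence[, keep, drop = FALSE],
                         community$guild[keep])
  attr(out, "removed") <- names(counts)[!keep]
  out
}

#' Subset a community table to one guild
#'
#' @param community A `community_table`.
#' @param guild Guild label to retain.
#' @return A `community_table` with only that guild's species.
#' @export
subset_guild <- function(community, guild) {
  stopifnot(inherits(community, "community_table"))
  if (!guild %in% community$guild)
    stop("unknown guild label: ", guild)
  keep <- community$guild == guild
  community_table(community$occurrence[, keep, drop = FALSE],
                  community$guild[keep])
}

#' Preprocess an environment table
#'
#' Applies, in order: per-covariate variance-stabilising transforms (log or
#' square root), a pairwise collinearity screen (of any covariate pair with
#' |Pearson r| above the threshold, computed on pairwise-complete
#' observations, the later-listed member is dropped), single-pass
#' column-median (or mean) imputation of missing cells, and standardisation
#' to mean 0 / sd 1. All fitted parameters (transform map, dropped columns,
#' centers, scales) are stored in `$preprocessing` so that scenario tables
#' can be pushed through the identical pipeline without refitting.
#'
#' @param env A raw `env_table`.
#' @param config A `pipeline_config` (fields `transform`, `cor_threshold`,
#'   `impute` are used).
#' @return A preprocessed `env_table` with no missing values.
#' @export
preprocess_env <- function(env, config = pipeline_config()) {
  stopifnot(inherits(env, "env_table"))
  x <- env$covariates
  tf <- config$transform
  tf_map <- stats::setNames(rep("identity", ncol(x)), colnames(x))
  tf_map[intersect(names(tf), colnames(x))] <-
    tf[intersect(names(tf), colnames(x))]
  for (v in colnames(x)) {
    if (tf_map[[v]] == "log") {
      bad <- which(x[, v] <= 0)
      if (length(bad))
        stop(sprintf("log transform of non-positive value: covariate %s, site %s",
                     v, rownames(x)[bad[1]]))
      x[, v] <- log(x[, v])
    } else if (tf_map[[v]] == "sqrt") {
      if (any(x[, v] < 0, na.rm = TRUE))
        stop("sqrt transform of negative value in covariate ", v)
      x[, v] <- sqrt(x[, v])
    }
  }

  # collinearity screen: later-listed member of each offending pair dropped
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  dropped <- character()
  for (i in seq_len(ncol(x))) {
    vi <- colnames(x)[i]
    if (vi %in% dropped) next
    for (j in seq_len(ncol(x))) {
      if (j <= i) next
      vj <- colnames(x)[j]
      if (vj %in% dropped) next
      if (is.finite(r[i, j]) && abs(r[i, j]) > config$cor_threshold)
        dropped <- c(dropped, vj)
    }
  }
  x <- x[, setdiff(colnames(x), dropped), drop = FALSE]

  # single-pass imputation
  centre_fun <- if (config$impute == "median") {
    function(v) stats::median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  imputed <- character()
  for (v in colnames(x)) {
    miss <- is.na(x[, v])
    if (any(miss)) {
      if (all(miss)) stop("covariate ", v, " is entirely missing")
      x[miss, v] <- centre_fun(x[!miss, v])
      imputed <- c(imputed, v)
    }
  }

  # drop zero-variance columns, then standardise
  sds <- apply(x, 2, stats::sd)
  zero_var <- colnames(x)[sds == 0 | !is.finite(sds)]
  if (length(zero_var)) {
    warning("dropping zero-variance covariates: ",
            paste(zero_var, collapse = ", "))
    dropped <- c(dropped, zero_var)
    x <- x[, setdiff(colnames(x), zero_var), drop = FALSE]
  }
  centers <- colMeans(x)
  scales <- apply(x, 2, stats::sd)
  x <- scale(x, center = centers, scale = scales)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL

  env_table(x, env$covariate_class[colnames(x)], env$coords, env$scenario,
            preprocessing = list(transform = tf_map,
                                 dropped = dropped,
                                 imputed = imputed,
                                 impute_method = config$impute,
                                 center = centers, scale = scales,
                                 raw = env$covariates,
                                 covariate_class = env$covariate_class))
}

# Apply a baseline's fitted preprocessing to a raw scenario table (internal).
apply_preprocessing <- function(raw_covariates, preprocessing) {
  x <- as.matrix(raw_covariates)
  keep <- names(preprocessing$center)
  for (v in keep) {
    tfv <- preprocessing$transform[[v]]
    if (is.null(tfv)) tfv <- "identity"
    if (tfv == "log") {
      if (any(x[, v] <= 0, na.rm = TRUE))
        stop("log transform of non-positive value in covariate ", v)
      x[, v] <- log(x[, v])
    } else if (tfv == "sqrt") x[, v] <- sqrt(x[, v])
  }
  x <- x[, keep, drop = FALSE]
  for (v in keep) {
    miss <- is.na(x[, v])
    if (any(miss)) x[miss, v] <- preprocessing$center[[v]]
  }
  sweep(sweep(x, 2, preprocessing$center), 2, preprocessing$scale, "/")
}
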