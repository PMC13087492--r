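# Posterior-predictive occurrence probabilities under shifted climates.

#' Build a preprocessed scenario environment table
#'
#' Replaces climate-class covariate columns of the baseline with scenario
#' values (on the raw scale) and pushes the result through the baseline's
#' fitted preprocessing (same transforms, same centers and scales — never
#' refitted), so the scenario design is expressed in baseline standard
#' deviations.
#'
#' @param baseline A preprocessed `env_table` (output of
#'   [preprocess_env()]).
#' @param scenario_climate Matrix or data frame of replacement raw values,
#'   sites in rows (same order as baseline), climate covariates in columns.
#' @param scenario Scenario label (`SSP1-2.6`, `SSP3-7.0`, `SSP5-8.5` or
#'   `custom`).
#' @return A preprocessed `env_table` tagged with the scenario label.
#' @export
build_scenario_env <- function(baseline, scenario_climate,
                               scenario = "custom") {
  stopifnot(inherits(baseline, "env_table"))
  pp <- baseline$preprocessing
  if (is.null(pp))
    stop("baseline must be a preprocessed env_table (see preprocess_env)")
  scenario_climate <- as.matrix(scenario_climate)
  raw <- pp$raw
  if (nrow(scenario_climate) != nrow(raw))
    stop("scenario table must have one row per baseline site")
  class_map <- if (!is.null(pp$covariate_class)) pp$covariate_class else
    baseline$covariate_class
  for (v in colnames(scenario_climate)) {
    if (!v %in% colnames(raw))
      stop("unknown covariate in scenario table: ", v)
    cls <- class_map[[v]]
    if (is.na(cls) || cls != "climate")
      stop("only climate covariates may be replaced; '", v, "' is ", cls)
    raw[, v] <- scenario_climate[, v]
  }
  std <- apply_preprocessing(raw, pp)
  env_table(std, baseline$covariate_class[colnames(std)], baseline$coords,
            scenario = scenario, preprocessing = pp)
}

#' Posterior-predictive occurrence probabilities
#'
#' For every retained posterior sample, computes per-site, per-species
#' occurrence probabilities under the probit link and averages the
#' probabilities (not the liabilities) over samples.
#'
#' Two prediction modes are available. `conditional_on_training_factors`
#' (default) reuses each sample's estimated site-level and spatial factor
#' values — appropriate when predicting at the training sites, as scenario
#' projection does. `marginal` integrates the latent factors over their
#' prior analytically: p = Phi(x'beta / sqrt(1 + sum_h lambda_hj^2)).
#'
#' @param posterior A `jsdm_posterior`.
#' @param env A preprocessed `env_table` whose covariates match the fitted
#'   covariate set.
#' @param mode `"conditional_on_training_factors"` or `"marginal"`.
#' @return A list of class `probability_matrix` with `prob` (sites x
#'   species, entries in \[0, 1\]) and `scenario`.
#' @export
predict_occurrence <- function(posterior, env,
                               mode = c("conditional_on_training_factors",
                                        "marginal")) {
  stopifnot(inherits(posterior, "jsdm_posterior"),
            inherits(env, "env_table"))
  mode <- match.arg(mode)
  missing_cov <- setdiff(posterior$covariate_names, colnames(env$covariates))
  if (length(missing_cov))
    stop("env table lacks fitted covariates: ",
         paste(missing_cov, collapse = ", "))
  X <- cbind(intercept = 1,
             env$covariates[, posterior$covariate_names, drop = FALSE])
  J <- nrow(X)
  S <- ncol(posterior$y)
  N <- dim(posterior$draws$beta)[3]
  H1 <- posterior$spec$n_factors_site
  H2 <- posterior$spec$n_factors_spatial
  conditional <- mode == "conditional_on_training_factors"
  if (conditional && (H1 > 0 || H2 > 0)) {
    unseen <- setdiff(rownames(X), rownames(posterior$y))
    if (length(unseen))
      stop("conditional prediction requires training sites; unseen: ",
           paste(unseen, collapse = ", "))
    if (!identical(rownames(X), rownames(posterior$y)))
      stop("conditional prediction requires the training site order")
  }
  acc <- matrix(0, J, S)
  for (n in seq_len(N)) {
    beta <- matrix(posterior$draws$beta[, , n], ncol = S)
    m <- X %*% beta
    if (conditional) {
      if (H1 > 0)
        m <- m + matrix(posterior$draws$eta_site[, , n], J, H1) %*%
          matrix(posterior$draws$lambda_site[, , n], H1, S)
      if (H2 > 0)
        m <- m + matrix(posterior$draws$eta_spatial[, , n], J, H2) %*%
          matrix(posterior$draws$lambda_spatial[, , n], H2, S)
      acc <- acc + stats::pnorm(m)
    } else {
      v <- rep(0, S)
      if (H1 > 0)
        v <- v + colSums(matrix(posterior$draws$lambda_site[, , n], H1, S)^2)
      if (H2 > 0)
        v <- v + colSums(matrix(posterior$draws$lambda_spatial[, , n], H2, S)^2)
      acc <- acc + stats::pnorm(sweep(m, 2, sqrt(1 + v), "/"))
    }
  }
  prob <- acc / N
  dimnames(prob) <- list(rownames(X), colnames(posterior$y))
  structure(list(prob = prob, scenario = env$scenario,
                 guild = posterior$guild, mode = mode),
            class = "probability_matrix")
}

#' @export
print.probability_matrix <- function(x, ...) {
  cat("probability_matrix:", nrow(x$prob), "sites x", ncol(x$prob),
      "species | scenario:", x$scenario, "| mode:", x$mode, "\n")
  invisible(x)
}

#' Write a probability matrix to CSV
#'
#' @param prob A `probability_matrix`.
#' @param path Output CSV path (site_id first column).
#' @return Invisibly, the path.
#' @export
write_probability_matrix <- function(prob, path) {
  utils::write.csv(data.frame(site_id = rownames(prob$prob), prob$prob,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
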