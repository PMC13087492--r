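# Random-forest screening of environmental covariates.

#' Per-species classification forests with error-weighted importance
#'
#' Fits one classification forest per species (binary occurrence response)
#' on the environmental covariates (plus, optionally, the site
#' coordinates, which compete as candidate predictors but are excluded
#' again before the joint model because they enter it as random levels).
#' Out-of-bag permutation importance is aggregated across species with
#' misclassification-error weights:
#' global_v = sum_s w_s I_sv / sum_s w_s, w_s = max(0, 1 - oob_error_s).
#'
#' @param community A `community_table` (rare species already removed).
#' @param env A preprocessed `env_table`.
#' @param n_trees Trees per forest.
#' @param seed Integer seed (per-species forests use `seed + species
#'   index`).
#' @param include_coords Offer `lon`/`lat` as candidate predictors.
#' @param weight Species weight: `"accuracy"` (1 - OOB error, default) or
#'   `"error"` (OOB error).
#' @return A list of class `importance_table` with `importance` (species x
#'   covariate), `oob_error`, `weights`, `global_importance` and `ranking`.
#'   Species with constant occurrence are skipped with a warning.
#' @export
fit_species_forests <- function(community, env, n_trees = 500, seed = 1L,
                                include_coords = TRUE,
                                weight = c("accuracy", "error")) {
  stopifnot(inherits(community, "community_table"),
            inherits(env, "env_table"))
  weight <- match.arg(weight)
  design <- env$covariates
  if (include_coords) design <- cbind(design, env$coords)
  Y <- community$occurrence
  prev <- colSums(Y)
  skip <- prev == 0 | prev == nrow(Y)
  if (any(skip))
    warning("species with constant occurrence skipped: ",
            paste(colnames(Y)[skip], collapse = ", "))
  species <- colnames(Y)[!skip]
  imp <- matrix(NA_real_, length(species), ncol(design),
                dimnames = list(species, colnames(design)))
  oob <- stats::setNames(numeric(length(species)), species)
  df <- as.data.frame(design)
  for (s in seq_along(species)) {
    y <- factor(Y[, species[s]], levels = c(0, 1))
    # one shared seed so the aggregate is invariant to species order
    fit <- ranger::ranger(x = df, y = y, num.trees = n_trees,
                          importance = "permutation",
                          seed = seed, num.threads = 1)
    imp[s, ] <- fit$variable.importance[colnames(design)]
    oob[s] <- fit$prediction.error
  }
  w <- if (weight == "accuracy") pmax(0, 1 - oob) else oob
  if (sum(w) == 0) w <- rep(1, length(w))
  global <- colSums(imp * w) / sum(w)
  structure(list(importance = imp, oob_error = oob, weights = w,
                 global_importance = global,
                 ranking = names(sort(global, decreasing = TRUE))),
            class = "importance_table")
}

#' @export
print.importance_table <- function(x, ...) {
  cat("importance_table:", nrow(x$importance), "species x",
      ncol(x$importance), "covariates; top:",
      paste(utils::head(x$ranking, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Retain the top-k covariates for the joint model
#'
#' Takes the k covariates with the highest global importance, then removes
#' any covariates on the exclusion list (typically `lon`/`lat`, which enter
#' the joint model as random levels rather than fixed terms), preserving
#' the importance order.
#'
#' @param importance An `importance_table`.
#' @param k Number of top covariates before exclusion (default 10).
#' @param exclude Covariate names to drop after the top-k cut.
#' @return Character vector of selected covariate names.
#' @export
select_top_k <- function(importance, k = 10, exclude = character()) {
  stopifnot(inherits(importance, "importance_table"), k >= 1)
  ranking <- importance$ranking
  if (k > length(ranking)) {
    warning("k exceeds the number of covariates; retaining all")
    k <- length(ranking)
  }
  setdiff(ranking[seq_len(k)], exclude)
}
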