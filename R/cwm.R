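# Probability-weighted community trait summaries and climate trends.

#' Community-weighted mean traits from occurrence probabilities
#'
#' Weights each species' trait value by its relative occurrence probability
#' at a site. Continuous traits give CWM_i = sum_j p_ij t_j / sum_j p_ij;
#' categorical traits give the probability-weighted proportion of each
#' level. Computed per guild, matching how trait panels are reported per
#' trophic group.
#'
#' @param prob A `probability_matrix`.
#' @param traits A `trait_table` covering the guild's species.
#' @param guild Guild label to restrict to.
#' @return A data frame of class `cwm_table`: `site_id`, one `cwm_<trait>`
#'   column per continuous trait, one `prop_<trait>_<level>` column per
#'   categorical level, plus `guild` and `scenario` attributes. Sites whose
#'   probabilities sum to zero yield `NA` with a warning.
#' @export
cwm <- function(prob, traits, guild) {
  stopifnot(inherits(prob, "probability_matrix"),
            inherits(traits, "trait_table"))
  if (is.null(prob$guild)) stop("probability matrix lacks guild labels")
  sp <- names(prob$guild)[prob$guild == guild]
  if (!length(sp)) stop("unknown guild label: ", guild)
  missing_tr <- setdiff(sp, traits$species_ids)
  if (length(missing_tr))
    stop("species without trait rows: ", paste(missing_tr, collapse = ", "))
  P <- prob$prob[, sp, drop = FALSE]
  wsum <- rowSums(P)
  if (any(wsum == 0))
    warning("sites with zero total occurrence probability: ",
            paste(rownames(P)[wsum == 0], collapse = ", "))
  wsum[wsum == 0] <- NA_real_

  out <- data.frame(site_id = rownames(P))
  if (!is.null(traits$continuous)) {
    for (v in colnames(traits$continuous)) {
      t_j <- traits$continuous[sp, v]
      out[[paste0("cwm_", v)]] <- drop(P %*% t_j) / wsum
    }
  }
  if (!is.null(traits$categorical)) {
    for (v in colnames(traits$categorical)) {
      f <- droplevels(traits$categorical[sp, v])
      for (l in levels(f)) {
        out[[paste0("prop_", v, "_", l)]] <-
          rowSums(P[, sp[f == l], drop = FALSE]) / wsum
      }
    }
  }
  attr(out, "guild") <- guild
  attr(out, "scenario") <- prob$scenario
  class(out) <- c("cwm_table", "data.frame")
  out
}

#' Trend of a community trait summary along a climate covariate
#'
#' Ordinary least squares of a CWM column on a raw-scale covariate. The
#' fitted slope sign and magnitude are the comparable quantities across
#' scenarios; smoothing is a visualization concern only.
#'
#' @param cwm_table A `cwm_table` (or any data frame with `site_id`).
#' @param env An `env_table` holding the covariate on its original scale
#'   (use the raw baseline table or `$preprocessing$raw`).
#' @param covariate Covariate name.
#' @param response Column of `cwm_table` to regress (e.g.
#'   `"cwm_length_mm"`).
#' @return A list of class `trend_fit` with `covariate`, `response`,
#'   `slope`, `intercept`, `r2`, `fit_form` and `scenario`.
#' @export
trait_climate_trend <- function(cwm_table, env, covariate, response) {
  stopifnot(inherits(env, "env_table"))
  if (!covariate %in% colnames(env$covariates))
    stop("unknown covariate: ", covariate)
  if (!response %in% names(cwm_table))
    stop("unknown response column: ", response)
  x <- env$covariates[cwm_table$site_id, covariate]
  y <- cwm_table[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0) stop("constant covariate: trend undefined")
  fit <- stats::lm(y ~ x)
  structure(list(covariate = covariate, response = response,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared, fit_form = "linear",
                 n = length(x),
                 scenario = attr(cwm_table, "scenario")),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit: %s ~ %s | slope %.4g, R2 %.3f (n = %d)%s\n",
              x$response, x$covariate, x$slope, x$r2, x$n,
              if (!is.null(x$scenario)) paste0(" | ", x$scenario) else ""))
  invisible(x)
}

#' Expected richness, weighted mean trait and size-class split per site
#'
#' Expected richness is the sum of occurrence probabilities; the weighted
#' mean trait uses the same relative-probability weights as [cwm()]; the
#' size-class split reports expected richness of species below and at/above
#' a trait cutoff (the conventional 0.5 mm split for zooplankton body
#' length).
#'
#' @param prob A `probability_matrix`.
#' @param traits A `trait_table`.
#' @param guild Guild label to restrict to.
#' @param trait Continuous trait used for the weighted mean and split.
#' @param cutoff Size-class cutoff on the trait scale (default 0.5).
#' @return A data frame: `site_id`, `expected_richness`, `mean_trait`,
#'   `richness_small`, `richness_large`.
#' @export
richness_length_summary <- function(prob, traits, guild,
                                    trait = "length_mm", cutoff = 0.5) {
  stopifnot(inherits(prob, "probability_matrix"),
            inherits(traits, "trait_table"))
  sp <- names(prob$guild)[prob$guild == guild]
  if (!length(sp)) stop("unknown guild label: ", guild)
  if (is.null(traits$continuous) || !trait %in% colnames(traits$continuous))
    stop("unknown continuous trait: ", trait)
  P <- prob$prob[, sp, drop = FALSE]
  t_j <- traits$continuous[sp, trait]
  wsum <- rowSums(P)
  small <- t_j < cutoff
  data.frame(site_id = rownames(P),
             expected_richness = wsum,
             mean_trait = ifelse(wsum > 0, drop(P %*% t_j) / wsum, NA_real_),
             richness_small = rowSums(P[, small, drop = FALSE]),
             richness_large = rowSums(P[, !small, drop = FALSE]))
}
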