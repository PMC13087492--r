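# Richness, local contributions to beta diversity, and richness-LCBD fits.

#' Per-site species richness
#'
#' @param community A `community_table`.
#' @param guild Optional guild label; if given, only that guild's species
#'   are counted.
#' @return Named integer vector of per-site richness.
#' @export
richness <- function(community, guild = NULL) {
  stopifnot(inherits(community, "community_table"))
  occ <- community$occurrence
  if (!is.null(guild)) {
    if (!guild %in% community$guild) stop("unknown guild label: ", guild)
    occ <- occ[, community$guild == guild, drop = FALSE]
  }
  rowSums(occ)
}

# Gower-centred decomposition of a dissimilarity matrix into per-site sums
# of squares: LCBD_i = SS_i / SS_total (Legendre & De Caceres framework).
lcbd_from_dissimilarity <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  rm_ <- rowMeans(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(a)
  ss_i <- diag(g)
  ss_total <- sum(ss_i)
  list(ss_i = ss_i, ss_total = ss_total)
}

jaccard_dissimilarity <- function(occ) {
  # vegdist warns about empty rows; their cells are overwritten below
  d <- as.matrix(suppressWarnings(
    vegan::vegdist(occ, method = "jaccard", binary = TRUE)))
  # sites with no species: Jaccard is 0/0 there; define empty-vs-empty as 0
  # and empty-vs-occupied as 1 (fully distinct composition)
  empty <- rowSums(occ > 0) == 0
  if (any(empty)) {
    d[empty, ] <- 1
    d[, empty] <- 1
    d[empty, empty] <- 0
  }
  diag(d) <- 0
  stats::as.dist(d)
}

#' Local contributions to beta diversity
#'
#' Computes each site's share of total compositional variance (LCBD) from a
#' pairwise Jaccard dissimilarity matrix via the Gower-centred
#' squared-dissimilarity decomposition, with permutation p-values obtained by
#' independently shuffling each species column, and Holm step-down
#' significance at family level `alpha`.
#'
#' @param community A `community_table` (typically one guild, see
#'   [subset_guild()]).
#' @param index Dissimilarity index; only `"jaccard"` is implemented.
#' @param n_perm Number of column-permutation replicates.
#' @param alpha Family-wise error level for the Holm procedure.
#' @param seed Optional integer seed making the permutations reproducible.
#' @return A list of class `lcbd_result` with per-site `lcbd`, `p_value`,
#'   Holm-adjusted `significant`, plus `index_name` and `n_permutations`.
#' @export
lcbd <- function(community, index = "jaccard", n_perm = 999, alpha = 0.05,
                 seed = NULL) {
  stopifnot(inherits(community, "community_table"))
  index <- match.arg(index, "jaccard")
  occ <- community$occurrence
  if (nrow(occ) < 2) stop("need at least two sites")
  if (ncol(occ) < 1) stop("need at least one species")
  if (nrow(unique(occ)) < 2)
    stop("no beta diversity: all sites have identical composition")

  dec <- lcbd_from_dissimilarity(jaccard_dissimilarity(occ))
  if (dec$ss_total <= 0)
    stop("no beta diversity: total sum of squares is zero")
  lcbd_obs <- dec$ss_i / dec$ss_total

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n <- nrow(occ)
  exceed <- rep(0L, n)
  for (b in seq_len(n_perm)) {
    perm <- apply(occ, 2, sample)
    rownames(perm) <- rownames(occ)
    dec_b <- lcbd_from_dissimilarity(jaccard_dissimilarity(perm))
    if (dec_b$ss_total > 0) {
      lcbd_b <- dec_b$ss_i / dec_b$ss_total
    } else {
      lcbd_b <- rep(1 / n, n)
    }
    exceed <- exceed + (lcbd_b >= lcbd_obs)
  }
  p <- (exceed + 1) / (n_perm + 1)
  p_holm <- stats::p.adjust(p, method = "holm")

  structure(list(lcbd = stats::setNames(lcbd_obs, rownames(occ)),
                 p_value = stats::setNames(p, rownames(occ)),
                 significant = stats::setNames(p_holm <= alpha, rownames(occ)),
                 index_name = index, n_permutations = n_perm,
                 alpha = alpha),
            class = "lcbd_result")
}

#' @export
print.lcbd_result <- function(x, ...) {
  cat("lcbd_result:", length(x$lcbd), "sites |", x$index_name, "index |",
      x$n_permutations, "permutations |", sum(x$significant),
      "significant (Holm, alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Linear vs. quadratic richness-LCBD regression
#'
#' Fits `y ~ x` and `y ~ x + x^2` by ordinary least squares and selects a
#' form. Because the quadratic nests the linear model, raw R-squared always
#' favours the quadratic; the default criterion is therefore adjusted
#' R-squared (ties favour the linear form). Raw R-squared selection is kept
#' as an optional mode.
#'
#' @param x,y Equal-length finite numeric vectors (at least 4 values).
#' @param criterion `"adjusted_r2"` (default) or `"r2"`.
#' @return A list of class `regression_fit` with the selected `model_form`,
#'   its `coefficients`, `r2`, `adjusted_r2`, `n`, and both candidate fits
#'   under `$candidates`.
#' @export
fit_richness_lcbd <- function(x, y, criterion = c("adjusted_r2", "r2")) {
  criterion <- match.arg(criterion)
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("x and y must be finite")
  if (stats::sd(x) == 0) stop("constant x: regression undefined")

  lin <- stats::lm(y ~ x)
  quad <- stats::lm(y ~ x + I(x^2))
  y_const <- stats::sd(y) == 0
  summ <- function(fit) {
    s <- summary(fit)
    r2 <- s$r.squared
    ar2 <- s$adj.r.squared
    # constant y: zero total sum of squares, define R2 as 0 (summary.lm
    # returns numerical noise there)
    if (y_const || !is.finite(r2)) r2 <- 0
    if (y_const || !is.finite(ar2)) ar2 <- 0
    list(coefficients = stats::coef(fit), r2 = max(0, r2),
         adjusted_r2 = ar2)
  }
  cands <- list(linear = summ(lin), quadratic = summ(quad))
  score <- if (criterion == "adjusted_r2") {
    c(cands$linear$adjusted_r2, cands$quadratic$adjusted_r2)
  } else {
    c(cands$linear$r2, cands$quadratic$r2)
  }
  form <- if (score[2] > score[1] + 1e-12) "quadratic" else "linear"
  sel <- cands[[form]]
  structure(list(model_form = form, coefficients = sel$coefficients,
                 r2 = sel$r2, adjusted_r2 = sel$adjusted_r2,
                 n = length(x), criterion = criterion, candidates = cands),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("regression_fit: %s | R2 = %.3f (adj %.3f) | n = %d\n",
              x$model_form, x$r2, x$adjusted_r2, x$n))
  invisible(x)
}

#' Combined diversity summary for both guilds
#'
#' Convenience wrapper producing the per-site table exported by the
#' pipeline: richness, LCBD, permutation p and Holm significance for each
#' guild separately (the two guilds are treated as separate test families).
#'
#' @param community A `community_table` containing both guilds.
#' @param n_perm,alpha,seed Passed to [lcbd()].
#' @return A data frame with one row per site.
#' @export
diversity_summary <- function(community, n_perm = 999, alpha = 0.05,
                              seed = NULL) {
  guilds <- unique(community$guild)
  out <- data.frame(site_id = rownames(community$occurrence))
  for (g in guilds) {
    sub <- subset_guild(community, g)
    res <- lcbd(sub, n_perm = n_perm, alpha = alpha, seed = seed)
    out[[paste0("richness_", g)]] <- unname(richness(community, g))
    out[[paste0("lcbd_", g)]] <- unname(res$lcbd)
    out[[paste0("p_", g)]] <- unname(res$p_value)
    out[[paste0("sig_", g)]] <- unname(res$significant)
  }
  out
}
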