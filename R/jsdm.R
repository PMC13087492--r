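# Trait-structured latent-factor joint species distribution model.
#
# Occurrence model (probit link): y_ij = 1[z_ij > 0],
#   z_ij = x_i' beta_j + sum_h eta_site[i,h] lambda_site[h,j]
#                      + sum_h eta_sp[i,h]  lambda_sp[h,j] + eps,  eps ~ N(0,1)
#   beta_j ~ N(Gamma' t_j, V)          (trait-implied niche hierarchy)
#   vec(Gamma) ~ N(0, gamma_var I);  V ~ Inverse-Wishart(K + 1, I)
#   loadings lambda_h ~ N(0, 1/tau_h), tau_h multiplicative-gamma shrinkage
#   eta_site ~ N(0, I);  eta_sp[, h] ~ N(0, exp(-d / alpha_h)),
#   alpha_h sampled over a fixed grid by its discrete conditional posterior.
# Fitted by Gibbs sampling with truncated-normal data augmentation.

#' Expand a trait table into the model's trait design matrix
#'
#' Continuous traits are log-transformed and standardised; categorical
#' traits become treatment-coded indicators (first level as reference); an
#' intercept row is prepended. Columns are species.
#'
#' @param traits A `trait_table`.
#' @param log_continuous Log-transform continuous traits before
#'   standardising (requires positive values).
#' @return A Q x S numeric matrix with named rows (first row `intercept`).
#' @export
expand_traits <- function(traits, log_continuous = TRUE) {
  stopifnot(inherits(traits, "trait_table"))
  S <- length(traits$species_ids)
  rows <- list(intercept = rep(1, S))
  if (!is.null(traits$continuous)) {
    for (v in colnames(traits$continuous)) {
      x <- traits$continuous[, v]
      if (anyNA(x)) stop("missing values in continuous trait ", v,
                         "; impute first")
      if (log_continuous) {
        if (any(x <= 0)) stop("log transform of non-positive trait ", v)
        x <- log(x)
      }
      s <- stats::sd(x)
      rows[[v]] <- if (s > 0) (x - mean(x)) / s else x * 0
    }
  }
  if (!is.null(traits$categorical)) {
    for (v in colnames(traits$categorical)) {
      f <- traits$categorical[[v]]
      if (anyNA(f)) stop("missing values in categorical trait ", v)
      # declared levels, not observed ones: keeps the design stable when a
      # level happens to be absent from a particular species subset
      lev <- levels(f)
      for (l in lev[-1]) rows[[paste0(v, l)]] <- as.numeric(f == l)
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- traits$species_ids
  out
}

#' Model structure specification
#'
#' @param n_factors_site Number of unstructured (site-level) latent factors.
#' @param n_factors_spatial Number of spatially structured latent factors.
#' @param alpha_grid_n Number of candidate spatial scales; the grid is
#'   equally spaced from 0 to the maximum pairwise site distance (degrees).
#' @param link Only `"probit"` is implemented.
#' @return A list of class `jsdm_spec`.
#' @export
jsdm_spec <- function(n_factors_site = 2, n_factors_spatial = 4,
                      alpha_grid_n = 101, link = "probit") {
  link <- match.arg(link, "probit")
  stopifnot(n_factors_site >= 0, n_factors_spatial >= 0, alpha_grid_n >= 2)
  structure(list(n_factors_site = as.integer(n_factors_site),
                 n_factors_spatial = as.integer(n_factors_spatial),
                 alpha_grid_n = as.integer(alpha_grid_n), link = link),
            class = "jsdm_spec")
}

#' MCMC settings
#'
#' Defaults follow the long-run analysis configuration (two chains of 1000
#' retained samples, thinning 5, transient 2500 = 500 x thin); reduced
#' settings for desk-scale simulation work are available via
#' [mcmc_config_reduced()].
#'
#' @param thin Thinning interval.
#' @param samples Retained samples per chain.
#' @param n_chains Number of chains.
#' @param transient Burn-in iterations discarded per chain.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(thin = 5, samples = 1000, n_chains = 2,
                        transient = 2500, seed = 1L) {
  stopifnot(thin >= 1, samples >= 1, n_chains >= 1, transient >= 0)
  structure(list(thin = as.integer(thin), samples = as.integer(samples),
                 n_chains = as.integer(n_chains),
                 transient = as.integer(transient), seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Reduced MCMC settings for simulation studies
#'
#' Two chains x 500 retained samples, thinning 8, transient 2000 — sized so
#' a full fit on the default synthetic metacommunity completes in minutes
#' while keeping split-chain PSRF close to 1 (see the vignette for the
#' convergence rationale behind the thinning choice).
#'
#' @param seed Integer seed.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config_reduced <- function(seed = 1L) {
  mcmc_config(thin = 8, samples = 500, n_chains = 2, transient = 2000,
              seed = seed)
}

#' Prior hyperparameters
#'
#' @param gamma_var Prior variance of each trait-effect element.
#' @param v_df_add Inverse-Wishart degrees of freedom are `K + v_df_add`.
#' @param shrink_a1,shrink_a2 Gamma shape parameters of the multiplicative
#'   shrinkage process on factor loadings (first factor, subsequent
#'   increments).
#' @return A list of class `jsdm_priors`.
#' @export
jsdm_priors <- function(gamma_var = 10, v_df_add = 1,
                        shrink_a1 = 5, shrink_a2 = 5) {
  structure(list(gamma_var = gamma_var, v_df_add = v_df_add,
                 shrink_a1 = shrink_a1, shrink_a2 = shrink_a2),
            class = "jsdm_priors")
}

# vectorised truncated-normal draws for probit augmentation:
# z ~ N(m, 1) truncated to (0, Inf) where y = 1 and (-Inf, 0] where y = 0
.rtnorm_probit <- function(m, y) {
  m <- pmin(pmax(m, -8), 8)          # guard against vanishing tail mass
  a <- stats::pnorm(-m)              # P(z - m <= -m) = P(z <= 0)
  u <- stats::runif(length(m))
  q <- ifelse(y == 1, a + u * (1 - a), u * a)
  q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
  m + stats::qnorm(q)
}

# sample columns of B ~ N(P^{-1} b, P^{-1}) given upper Cholesky U of P
.sample_prec_cols <- function(U, b) {
  mean_ <- backsolve(U, forwardsolve(t(U), b))
  mean_ + backsolve(U, matrix(stats::rnorm(length(b)), nrow(b), ncol(b)))
}

#' Fit the joint species distribution model
#'
#' Gibbs sampler for the trait-structured latent-factor probit occurrence
#' model (see the package vignette for the full model statement and update
#' equations). Retained samples are chains concatenated after discarding the
#' transient and thinning.
#'
#' @param community A `community_table` with no all-absent or all-present
#'   species (apply [filter_rare_species()] first).
#' @param env A preprocessed `env_table` (standardised covariates).
#' @param traits A `trait_table` covering all modelled species.
#' @param spec A [jsdm_spec()].
#' @param mcmc An [mcmc_config()].
#' @param priors A [jsdm_priors()].
#' @param fixed Optional list with elements `gamma` (Q x K) and/or `V`
#'   (K x K) to hold those parameters fixed instead of sampling them
#'   (used by the sampler-correctness diagnostics).
#' @param prior_only If `TRUE` the occurrence likelihood is disabled and the
#'   hierarchy is sampled from its prior (diagnostic mode).
#' @return An object of class `jsdm_posterior`: arrays `beta` (K x S x N),
#'   `gamma` (Q x K x N), `V` (K x K x N), `lambda_site`, `lambda_spatial`,
#'   `eta_site`, `eta_spatial`, `alpha` (H2 x N), `chain` (length N),
#'   `fitted` (J x S mean fitted occurrence probability), and metadata.
#' @export
fit_jsdm <- function(community, env, traits,
                     spec = jsdm_spec(), mcmc = mcmc_config(),
                     priors = jsdm_priors(), fixed = list(),
                     prior_only = FALSE) {
  stopifnot(inherits(community, "community_table"),
            inherits(env, "env_table"),
            inherits(traits, "trait_table"))
  Y <- community$occurrence
  if (!identical(rownames(Y), rownames(env$covariates)))
    stop("community and env tables are not aligned on sites")
  if (!setequal(colnames(Y), traits$species_ids))
    stop("trait table does not cover the modelled species")
  prev <- colSums(Y)
  degen <- prev == 0 | prev == nrow(Y)
  if (any(degen) && !prior_only)
    stop("species with constant occurrence cannot be modelled: ",
         paste(colnames(Y)[degen], collapse = ", "))

  X <- cbind(intercept = 1, env$covariates)
  J <- nrow(Y); S <- ncol(Y); K <- ncol(X)
  Tq <- expand_traits(traits)[, colnames(Y), drop = FALSE]
  Q <- nrow(Tq)
  H1 <- spec$n_factors_site; H2 <- spec$n_factors_spatial

  # spatial machinery: inverse correlation and log-determinant per grid alpha
  alpha_grid <- 0
  sp_inv <- sp_logdet <- NULL
  if (H2 > 0) {
    d <- as.matrix(stats::dist(env$coords))
    alpha_grid <- seq(0, max(d), length.out = spec$alpha_grid_n)
    sp_inv <- vector("list", length(alpha_grid))
    sp_logdet <- numeric(length(alpha_grid))
    sp_inv[[1]] <- diag(J)
    for (g in 2:length(alpha_grid)) {
      Sg <- exp(-d / alpha_grid[g]) + diag(1e-8, J)
      cS <- chol(Sg)
      sp_inv[[g]] <- chol2inv(cS)
      sp_logdet[g] <- 2 * sum(log(diag(cS)))
    }
  }

  XtX <- crossprod(X)
  TTt <- tcrossprod(Tq)
  v_df <- K + priors$v_df_add
  n_keep <- mcmc$samples
  N <- n_keep * mcmc$n_chains

  draws <- list(
    beta = array(NA_real_, c(K, S, N), list(colnames(X), colnames(Y), NULL)),
    gamma = array(NA_real_, c(Q, K, N), list(rownames(Tq), colnames(X), NULL)),
    V = array(NA_real_, c(K, K, N), list(colnames(X), colnames(X), NULL)),
    lambda_site = array(NA_real_, c(H1, S, N), list(NULL, colnames(Y), NULL)),
    lambda_spatial = array(NA_real_, c(H2, S, N), list(NULL, colnames(Y), NULL)),
    eta_site = array(NA_real_, c(J, H1, N), list(rownames(Y), NULL, NULL)),
    eta_spatial = array(NA_real_, c(J, H2, N), list(rownames(Y), NULL, NULL)),
    alpha = array(NA_real_, c(H2, N)))
  chain_id <- integer(N)
  fitted_acc <- matrix(0, J, S, dimnames = dimnames(Y))

  gamma_fixed <- !is.null(fixed$gamma)
  v_fixed <- !is.null(fixed$V)

  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch)
    Gm <- if (gamma_fixed) as.matrix(fixed$gamma) else matrix(0, Q, K)
    V <- if (v_fixed) as.matrix(fixed$V) else diag(K)
    Vinv <- chol2inv(chol(V))
    M <- crossprod(Gm, Tq)                       # K x S prior means
    beta <- M + matrix(stats::rnorm(K * S, 0, 0.1), K, S)
    L1 <- matrix(stats::rnorm(H1 * S, 0, 0.1), H1, S)
    L2 <- matrix(stats::rnorm(H2 * S, 0, 0.1), H2, S)
    E1 <- matrix(stats::rnorm(J * H1), J, H1)
    E2 <- matrix(stats::rnorm(J * H2), J, H2)
    delta1 <- rep(1, H1); delta2 <- rep(1, H2)
    alpha_idx <- rep(1L, H2)
    z <- matrix(0, J, S)

    n_iter <- mcmc$transient + n_keep * mcmc$thin
    kept <- 0L
    for (it in seq_len(n_iter)) {
      RE <- E1 %*% L1 + E2 %*% L2
      m_lin <- X %*% beta + RE

      if (!prior_only) {
        z[] <- .rtnorm_probit(m_lin, Y)
        # --- beta | z (shared posterior precision across species)
        P <- XtX + Vinv
        U <- chol(P)
        beta <- .sample_prec_cols(U, crossprod(X, z - RE) + Vinv %*% M)
      } else {
        beta <- M + crossprod(chol(V), matrix(stats::rnorm(K * S), K, S))
      }

      # --- Gamma | beta, V (matrix-normal regression, vectorised)
      if (!gamma_fixed) {
        Pg <- kronecker(TTt, Vinv) + diag(1 / priors$gamma_var, K * Q)
        bg <- as.vector(Vinv %*% tcrossprod(beta, Tq))   # vec(K x Q)
        Ug <- chol(Pg)
        G <- matrix(drop(.sample_prec_cols(Ug, matrix(bg))), K, Q)
        Gm <- t(G)
      }
      M <- crossprod(Gm, Tq)

      # --- V | beta, Gamma (inverse-Wishart)
      if (!v_fixed) {
        R <- beta - M
        scale_post <- diag(K) + tcrossprod(R)
        W <- stats::rWishart(1, v_df + S, chol2inv(chol(scale_post)))[, , 1]
        V <- chol2inv(chol(W))
        Vinv <- W
      }

      if (!prior_only) {
        resid <- z - X %*% beta
      }

      # --- site-level factors and loadings
      if (H1 > 0) {
        if (!prior_only) {
          R1 <- resid - E2 %*% L2
          P1 <- tcrossprod(L1) + diag(H1)
          P1inv <- chol2inv(chol(P1))
          mean_E1 <- R1 %*% crossprod(L1, P1inv)
          E1 <- mean_E1 + matrix(stats::rnorm(J * H1), J, H1) %*% chol(P1inv)
          tau1 <- cumprod(delta1)
          Pl <- crossprod(E1) + diag(tau1, H1)
          L1 <- .sample_prec_cols(chol(Pl), crossprod(E1, R1))
        } else {
          E1 <- matrix(stats::rnorm(J * H1), J, H1)
          tau1 <- cumprod(delta1)
          L1 <- matrix(stats::rnorm(H1 * S, 0, rep(1 / sqrt(tau1), S)), H1, S)
        }
        delta1 <- .update_shrinkage(L1, delta1, priors)
      }

      # --- spatially structured factors, loadings and scales
      if (H2 > 0) {
        if (!prior_only) {
          R2 <- resid - E1 %*% L1
          for (h in seq_len(H2)) {
            rh <- R2 - E2[, -h, drop = FALSE] %*% L2[-h, , drop = FALSE]
            lh <- L2[h, ]
            Ph <- sp_inv[[alpha_idx[h]]]
            Pfull <- Ph + diag(sum(lh^2), J)
            Uh <- chol(Pfull)
            E2[, h] <- drop(.sample_prec_cols(Uh, rh %*% lh))
            # discrete conditional posterior of the spatial scale
            eh <- E2[, h]
            logp <- vapply(seq_along(alpha_grid), function(g)
              -0.5 * (sp_logdet[g] + drop(crossprod(eh, sp_inv[[g]] %*% eh))),
              numeric(1))
            logp <- logp - max(logp)
            alpha_idx[h] <- sample.int(length(alpha_grid), 1,
                                       prob = exp(logp))
          }
          tau2 <- cumprod(delta2)
          Pl2 <- crossprod(E2) + diag(tau2, H2)
          L2 <- .sample_prec_cols(chol(Pl2), crossprod(E2, R2))
        } else {
          for (h in seq_len(H2)) {
            alpha_idx[h] <- sample.int(length(alpha_grid), 1)
            Sg_inv <- sp_inv[[alpha_idx[h]]]
            E2[, h] <- drop(backsolve(chol(Sg_inv),
                                      stats::rnorm(J)))
          }
          tau2 <- cumprod(delta2)
          L2 <- matrix(stats::rnorm(H2 * S, 0, rep(1 / sqrt(tau2), S)), H2, S)
        }
        delta2 <- .update_shrinkage(L2, delta2, priors)
      }

      if (!all(is.finite(beta)))
        stop("non-finite state in Gibbs sampler at iteration ", it,
             " (chain ", ch, "); dump: max |beta| = ", max(abs(beta)))

      if (it > mcmc$transient && (it - mcmc$transient) %% mcmc$thin == 0) {
        kept <- kept + 1L
        idx <- (ch - 1L) * n_keep + kept
        draws$beta[, , idx] <- beta
        draws$gamma[, , idx] <- Gm
        draws$V[, , idx] <- V
        if (H1 > 0) {
          draws$lambda_site[, , idx] <- L1
          draws$eta_site[, , idx] <- E1
        }
        if (H2 > 0) {
          draws$lambda_spatial[, , idx] <- L2
          draws$eta_spatial[, , idx] <- E2
          draws$alpha[, idx] <- alpha_grid[alpha_idx]
        }
        chain_id[idx] <- ch
        fitted_acc <- fitted_acc +
          stats::pnorm(X %*% beta + E1 %*% L1 + E2 %*% L2)
      }
    }
  }

  structure(list(
    draws = draws, chain = chain_id,
    fitted = fitted_acc / N,
    y = Y, X = X, trait_design = Tq, coords = env$coords,
    guild = community$guild,
    covariate_names = colnames(env$covariates),
    alpha_grid = alpha_grid,
    spec = spec, mcmc = mcmc, priors = priors,
    prior_only = prior_only),
    class = "jsdm_posterior")
}

# multiplicative-gamma shrinkage update (Bhattacharya-Dunson style)
.update_shrinkage <- function(L, delta, priors) {
  H <- nrow(L); S <- ncol(L)
  if (H == 0) return(delta)
  ssq <- rowSums(L^2)
  for (l in seq_len(H)) {
    tau_wo <- cumprod(delta) / delta[l]        # tau_h without delta_l, h >= l
    shape <- (if (l == 1) priors$shrink_a1 else priors$shrink_a2) +
      S * (H - l + 1) / 2
    rate <- 1 + 0.5 * sum(tau_wo[l:H] * ssq[l:H])
    delta[l] <- stats::rgamma(1, shape, rate)
  }
  delta
}

#' @export
print.jsdm_posterior <- function(x, ...) {
  d <- dim(x$draws$beta)
  cat("jsdm_posterior:", d[2], "species x", nrow(x$y), "sites |",
      d[1], "covariates (incl. intercept) |",
      dim(x$draws$gamma)[1], "trait rows |",
      x$spec$n_factors_site, "site +", x$spec$n_factors_spatial,
      "spatial factors |", d[3], "retained samples (",
      x$mcmc$n_chains, "chains )\n")
  invisible(x)
}

#' Tjur's coefficient of discrimination
#'
#' Mean fitted probability at observed presences minus mean at observed
#' absences.
#'
#' @param y Binary vector of observations.
#' @param p Fitted occurrence probabilities (same length).
#' @return A single number in \[-1, 1\].
#' @export
tjur_r2 <- function(y, p) {
  stopifnot(length(y) == length(p))
  if (all(y == y[1])) stop("Tjur R2 undefined for constant y")
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Per-species Tjur R2 of a fitted model
#'
#' @param posterior A `jsdm_posterior`.
#' @return Named numeric vector over species, using the posterior-mean
#'   fitted probabilities at the training sites.
#' @export
tjur_r2_species <- function(posterior) {
  stopifnot(inherits(posterior, "jsdm_posterior"))
  vapply(seq_len(ncol(posterior$y)), function(j)
    tjur_r2(posterior$y[, j], posterior$fitted[, j]), numeric(1)) |>
    stats::setNames(colnames(posterior$y))
}

#' Posterior sign support of beta or gamma elements
#'
#' For each element, support is the larger of the posterior probabilities of
#' a positive or a negative value; elements whose support exceeds the
#' threshold are retained in the masked mean matrix (the heatmap export).
#'
#' @param posterior A `jsdm_posterior`.
#' @param parameter `"beta"` or `"gamma"`.
#' @param threshold Support threshold in (0.5, 1); 0.90 for beta/gamma
#'   heatmaps, 0.95 for residual associations.
#' @return A list of class `sign_support` with `posterior_mean`, `support`,
#'   `mask` (logical) and `masked_mean` (mean where supported, else 0).
#' @export
support_filter <- function(posterior, parameter = c("beta", "gamma"),
                           threshold = 0.90) {
  stopifnot(inherits(posterior, "jsdm_posterior"))
  parameter <- match.arg(parameter)
  if (threshold <= 0.5 || threshold >= 1)
    stop("threshold must lie in (0.5, 1)")
  arr <- posterior$draws[[parameter]]
  mean_ <- apply(arr, c(1, 2), mean)
  pos <- apply(arr > 0, c(1, 2), mean)
  neg <- apply(arr < 0, c(1, 2), mean)
  support <- pmax(pos, neg)
  mask <- support > threshold
  structure(list(posterior_mean = mean_, support = support, mask = mask,
                 masked_mean = mean_ * mask, threshold = threshold,
                 parameter = parameter),
            class = "sign_support")
}

#' @export
print.sign_support <- function(x, ...) {
  cat(sprintf("sign_support (%s): %d/%d elements retained at > %.2f\n",
              x$parameter, sum(x$mask), length(x$mask), x$threshold))
  invisible(x)
}

#' Residual species-to-species associations
#'
#' Converts the latent-factor loadings of each retained sample into the
#' residual covariance Omega = Lambda' Lambda (summed over the site-level
#' and spatial factor groups), rescales it to a correlation matrix, and
#' applies the sign-support filter. A by-guild-pair summary (fish-fish,
#' fish-zooplankton, zooplankton-zooplankton percentages of retained
#' positive/negative pairs) is included.
#'
#' @param posterior A `jsdm_posterior` with at least one latent factor.
#' @param threshold Sign-support threshold (default 0.95).
#' @return A list of class `residual_associations` with `mean_correlation`,
#'   `support`, `mask`, and `guild_summary`.
#' @export
residual_associations <- function(posterior, threshold = 0.95) {
  stopifnot(inherits(posterior, "jsdm_posterior"))
  if (threshold <= 0.5 || threshold >= 1)
    stop("threshold must lie in (0.5, 1)")
  H <- posterior$spec$n_factors_site + posterior$spec$n_factors_spatial
  S <- dim(posterior$draws$beta)[2]
  species <- dimnames(posterior$draws$beta)[[2]]
  if (is.null(species)) species <- paste0("sp", seq_len(S))
  N <- dim(posterior$draws$beta)[3]
  if (H == 0) {
    warning("model has no latent factors; residual associations are identity")
    eye <- diag(S); dimnames(eye) <- list(species, species)
    return(structure(list(mean_correlation = eye,
                          support = matrix(0, S, S,
                                           dimnames = list(species, species)),
                          mask = matrix(FALSE, S, S,
                                        dimnames = list(species, species)),
                          guild_summary = NULL, threshold = threshold),
                     class = "residual_associations"))
  }
  acc_mean <- acc_pos <- acc_neg <- matrix(0, S, S)
  H1 <- posterior$spec$n_factors_site
  H2 <- posterior$spec$n_factors_spatial
  for (n in seq_len(N)) {
    L <- rbind(
      if (H1 > 0) matrix(posterior$draws$lambda_site[, , n], H1, S),
      if (H2 > 0) matrix(posterior$draws$lambda_spatial[, , n], H2, S))
    Om <- crossprod(L)
    dg <- sqrt(diag(Om))
    dg[dg == 0] <- 1                   # species with null loadings: corr 0
    R <- Om / tcrossprod(dg)
    diag(R) <- 1
    acc_mean <- acc_mean + R
    acc_pos <- acc_pos + (R > 0)
    acc_neg <- acc_neg + (R < 0)
  }
  mean_cor <- acc_mean / N
  support <- pmax(acc_pos, acc_neg) / N
  mask <- support > threshold
  diag(mask) <- FALSE
  dimnames(mean_cor) <- dimnames(support) <- dimnames(mask) <-
    list(species, species)

  guild <- posterior$guild[species]
  pairs <- which(upper.tri(mask), arr.ind = TRUE)
  pair_guild <- apply(pairs, 1, function(ij)
    paste(sort(c(guild[ij[1]], guild[ij[2]])), collapse = "-"))
  retained <- mask[upper.tri(mask)]
  sign_pos <- mean_cor[upper.tri(mean_cor)] > 0
  guild_summary <- do.call(rbind, lapply(unique(pair_guild), function(g) {
    sel <- pair_guild == g
    data.frame(pair = g, n_pairs = sum(sel),
               pct_positive = 100 * sum(retained[sel] & sign_pos[sel]) / sum(sel),
               pct_negative = 100 * sum(retained[sel] & !sign_pos[sel]) / sum(sel))
  }))
  structure(list(mean_correlation = mean_cor, support = support, mask = mask,
                 guild_summary = guild_summary, threshold = threshold),
            class = "residual_associations")
}

#' @export
print.residual_associations <- function(x, ...) {
  cat(sprintf("residual_associations: %d species, %d pairs retained at > %.2f\n",
              nrow(x$mask), sum(x$mask[upper.tri(x$mask)]), x$threshold))
  if (!is.null(x$guild_summary)) print(x$guild_summary, row.names = FALSE)
  invisible(x)
}

#' Split-chain convergence diagnostics
#'
#' Computes the split-chain potential scale reduction factor (PSRF) and a
#' simple effective-sample-size estimate for every beta and gamma element.
#'
#' @param posterior A `jsdm_posterior` fitted with at least two chains.
#' @return A list of class `jsdm_convergence` with matrices `psrf_beta`,
#'   `psrf_gamma`, `ess_beta`, `ess_gamma` and a `summary` vector (max and
#'   median PSRF over both parameter blocks).
#' @export
check_convergence <- function(posterior) {
  stopifnot(inherits(posterior, "jsdm_posterior"))
  if (posterior$mcmc$n_chains < 2)
    warning("PSRF requires at least two chains; values computed from split halves only")
  psrf_of <- function(arr) {
    dims <- dim(arr)[1:2]
    out <- matrix(NA_real_, dims[1], dims[2], dimnames = dimnames(arr)[1:2])
    ess <- out
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      per_chain <- lapply(unique(posterior$chain), function(ch)
        arr[i, j, posterior$chain == ch])
      out[i, j] <- .split_psrf(per_chain)
      ess[i, j] <- sum(vapply(per_chain, .ess_one, numeric(1)))
    }
    list(psrf = out, ess = ess)
  }
  b <- psrf_of(posterior$draws$beta)
  g <- psrf_of(posterior$draws$gamma)
  all_psrf <- c(b$psrf, g$psrf)
  structure(list(psrf_beta = b$psrf, psrf_gamma = g$psrf,
                 ess_beta = b$ess, ess_gamma = g$ess,
                 summary = c(max_psrf = max(all_psrf, na.rm = TRUE),
                             median_psrf = stats::median(all_psrf, na.rm = TRUE))),
            class = "jsdm_convergence")
}

#' @export
print.jsdm_convergence <- function(x, ...) {
  cat(sprintf("jsdm_convergence: max PSRF = %.3f, median PSRF = %.3f\n",
              x$summary["max_psrf"], x$summary["median_psrf"]))
  invisible(x)
}

# split-chain PSRF over a list of per-chain draw vectors
.split_psrf <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    n2 <- floor(length(v) / 2)
    list(v[seq_len(n2)], v[(n2 + 1):(2 * n2)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B_over_n <- stats::var(means)
  if (!is.finite(W) || W <= 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

# initial-positive-sequence effective sample size of one chain
.ess_one <- function(v) {
  n <- length(v)
  if (stats::var(v) == 0) return(n)
  ac <- stats::acf(v, lag.max = min(n - 1, 100), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

#' Variance partitioning of species occurrence
#'
#' For each posterior sample and species, attributes the liability variance
#' over sites to each fixed-covariate group (covariances between groups
#' split evenly between the two groups involved) and to the site-level and
#' spatial random-effect groups (sum of squared loadings). The intercept is
#' constant over sites and therefore carries no share. Negative
#' covariance-adjusted group shares are floored at zero before
#' normalisation. Fractions are averaged over samples and additionally
#' reported on the absolute scale by multiplying with each species' Tjur R2.
#'
#' @param posterior A `jsdm_posterior`.
#' @param groups Optional named list mapping group names to covariate names
#'   (defaults to one group per non-intercept covariate).
#' @param tjur Optional per-species Tjur R2 vector; defaults to
#'   [tjur_r2_species()] of the fit.
#' @return A list of class `variance_partition` with matrices `raw`
#'   (groups x species fractions summing to 1) and `adjusted` (summing to
#'   Tjur R2), plus `tjur`.
#' @export
variance_partitioning <- function(posterior, groups = NULL, tjur = NULL) {
  stopifnot(inherits(posterior, "jsdm_posterior"))
  X <- posterior$X
  covs <- setdiff(colnames(X), "intercept")
  if (is.null(groups)) groups <- stats::setNames(as.list(covs), covs)
  if (any(!lengths(groups))) stop("empty covariate group")
  unknown <- setdiff(unlist(groups), colnames(X))
  if (length(unknown))
    stop("unknown covariates in groups: ", paste(unknown, collapse = ", "))
  H1 <- posterior$spec$n_factors_site
  H2 <- posterior$spec$n_factors_spatial
  gnames <- c(names(groups),
              if (H1 > 0) "random_site", if (H2 > 0) "random_spatial")
  S <- ncol(posterior$y)
  N <- dim(posterior$draws$beta)[3]
  acc <- matrix(0, length(gnames), S, dimnames = list(gnames, colnames(posterior$y)))
  J <- nrow(X)
  for (n in seq_len(N)) {
    beta <- posterior$draws$beta[, , n]
    U <- lapply(groups, function(cols)
      X[, cols, drop = FALSE] %*% beta[cols, , drop = FALSE])
    Utot <- Reduce(`+`, U)
    cmean <- colMeans(Utot)
    shares <- vapply(U, function(u)
      colSums(sweep(u, 2, colMeans(u)) * sweep(Utot, 2, cmean)) / (J - 1),
      numeric(S))
    shares <- t(pmax(shares, 0))                       # groups x species
    rand <- NULL
    if (H1 > 0)
      rand <- rbind(rand, random_site = colSums(
        matrix(posterior$draws$lambda_site[, , n], H1, S)^2))
    if (H2 > 0)
      rand <- rbind(rand, random_spatial = colSums(
        matrix(posterior$draws$lambda_spatial[, , n], H2, S)^2))
    frac <- rbind(shares, rand)
    tot <- colSums(frac)
    tot[tot == 0] <- 1
    acc <- acc + sweep(frac, 2, tot, "/")
  }
  raw <- acc / N
  if (is.null(tjur)) tjur <- tjur_r2_species(posterior)
  adjusted <- sweep(raw, 2, tjur[colnames(raw)], "*")
  structure(list(raw = raw, adjusted = adjusted, tjur = tjur,
                 groups = groups),
            class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("variance_partition: mean raw fractions across species\n")
  print(round(rowMeans(x$raw), 3))
  invisible(x)
}
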