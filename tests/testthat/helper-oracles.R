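# Brute-force reference implementations and small object builders used as
# independent oracles. These deliberately avoid the code paths of the
# package functions they check.

# set-based Jaccard dissimilarity between two binary vectors
oracle_jaccard_pair <- function(a, b) {
  A <- which(a > 0); B <- which(b > 0)
  un <- length(union(A, B))
  if (un == 0) return(0)
  1 - length(intersect(A, B)) / un
}

oracle_jaccard_matrix <- function(occ) {
  n <- nrow(occ)
  d <- matrix(0, n, n, dimnames = list(rownames(occ), rownames(occ)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- oracle_jaccard_pair(occ[i, ], occ[j, ])
  d
}

# per-site LCBD directly from pairwise squared dissimilarities:
# SS_i = (1/n) sum_j d_ij^2 - (1/(2 n^2)) sum_jk d_jk^2
oracle_lcbd <- function(occ) {
  d <- oracle_jaccard_matrix(occ)
  n <- nrow(d)
  ss_i <- rowSums(d^2) / n - sum(d^2) / (2 * n^2)
  ss_i / sum(ss_i)
}

oracle_tjur <- function(y, p) {
  sum(p[y == 1]) / sum(y == 1) - sum(p[y == 0]) / sum(y == 0)
}

# step-down Holm adjustment written out longhand
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (k in seq_len(n)) {
    running <- max(running, (n - k + 1) * p[o[k]])
    adj[o[k]] <- min(1, running)
  }
  adj
}

# Spearman rho via explicit ranks + Pearson product-moment formula, and the
# two-sided p from the t-approximation
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  rho <- num / den
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tt), n - 2))
}

# all-pairs shortest paths by Floyd-Warshall on an unweighted edge list
oracle_mean_path <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (r in seq_len(nrow(edges))) {
    d[edges[r, 1], edges[r, 2]] <- 1
    d[edges[r, 2], edges[r, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  vals <- d[upper.tri(d) | lower.tri(d)]
  mean(vals[is.finite(vals)])
}

# Newman modularity of a given partition, from the definition
oracle_modularity <- function(nodes, edges, membership) {
  m <- nrow(edges)
  deg <- stats::setNames(rep(0, length(nodes)), nodes)
  for (r in seq_len(m)) {
    deg[edges[r, 1]] <- deg[edges[r, 1]] + 1
    deg[edges[r, 2]] <- deg[edges[r, 2]] + 1
  }
  q <- 0
  for (cmty in unique(membership)) {
    inside <- names(membership)[membership == cmty]
    e_c <- sum(apply(edges, 1, function(e) all(e %in% inside)))
    d_c <- sum(deg[inside])
    q <- q + e_c / m - (d_c / (2 * m))^2
  }
  q
}

# builders ------------------------------------------------------------------

# a cooccurrence_network from a bare edge list (rho = 1, p = 0 placeholders)
make_network <- function(edges, species, scenario = "baseline") {
  ed <- data.frame(species_a = as.character(edges[, 1]),
                   species_b = as.character(edges[, 2]),
                   rho = if (ncol(edges) > 2) as.numeric(edges[, 3]) else
                     rep(1, nrow(edges)),
                   p = rep(0, nrow(edges)), stringsAsFactors = FALSE)
  ed$sign <- ifelse(ed$rho >= 0, 1L, -1L)
  structure(list(edges = ed, species = species, guild = NULL,
                 scenario = scenario, alpha = 0.01),
            class = "cooccurrence_network")
}

# a minimal jsdm_posterior stub carrying arbitrary draw arrays
make_posterior_stub <- function(beta, gamma = NULL, lambda_site = NULL,
                                lambda_spatial = NULL, eta_site = NULL,
                                eta_spatial = NULL, chain = NULL,
                                X = NULL, y = NULL, guild = NULL,
                                fitted = NULL) {
  N <- dim(beta)[3]
  S <- dim(beta)[2]
  if (is.null(gamma)) gamma <- array(0, c(1, dim(beta)[1], N))
  H1 <- if (is.null(lambda_site)) 0L else dim(lambda_site)[1]
  H2 <- if (is.null(lambda_spatial)) 0L else dim(lambda_spatial)[1]
  if (is.null(chain)) chain <- rep(1:2, each = ceiling(N / 2))[seq_len(N)]
  species <- dimnames(beta)[[2]]
  if (is.null(species)) {
    species <- paste0("sp", seq_len(S))
    dimnames(beta)[[2]] <- species
  }
  if (is.null(guild))
    guild <- stats::setNames(rep(c("fish", "zooplankton"), length.out = S),
                             species)
  if (is.null(y)) {
    J <- if (!is.null(X)) nrow(X) else 2L
    y <- matrix(rep_len(c(0L, 1L), J * S), J, S)
    colnames(y) <- species
    if (!is.null(X)) rownames(y) <- rownames(X)
  }
  structure(list(
    draws = list(beta = beta, gamma = gamma,
                 V = array(diag(dim(beta)[1]), c(dim(beta)[1], dim(beta)[1], N)),
                 lambda_site = if (H1 > 0) lambda_site else
                   array(0, c(0, S, N)),
                 lambda_spatial = if (H2 > 0) lambda_spatial else
                   array(0, c(0, S, N)),
                 eta_site = eta_site, eta_spatial = eta_spatial,
                 alpha = array(0, c(H2, N))),
    chain = chain, fitted = fitted, y = y, X = X,
    guild = guild,
    covariate_names = if (!is.null(X)) setdiff(colnames(X), "intercept"),
    spec = jsdm_spec(n_factors_site = H1, n_factors_spatial = H2),
    mcmc = mcmc_config(samples = max(1, ceiling(N / length(unique(chain)))),
                       n_chains = length(unique(chain))),
    prior_only = FALSE),
    class = "jsdm_posterior")
}

# intercept-only environment (zero covariates) for tiny sampler checks
make_intercept_env <- function(J) {
  cov <- matrix(numeric(0), J, 0)
  rownames(cov) <- sprintf("s%02d", seq_len(J))
  coords <- cbind(lon = seq(-75, -70, length.out = J),
                  lat = seq(45, 50, length.out = J))
  rownames(coords) <- rownames(cov)
  env_table(cov, character(), coords)
}

# single-level categorical trait table => trait design is the intercept only
make_intercept_traits <- function(species) {
  trait_table(categorical = data.frame(
    grp = factor(rep("a", length(species))), row.names = species))
}

# default preprocessing used with generator output
sim_preprocess <- function(env) {
  preprocess_env(env, pipeline_config(transform = c(lake_area = "log")))
}
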