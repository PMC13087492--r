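# Significance-filtered Spearman co-occurrence networks and their metrics.

# Spearman rho (average ranks for ties) and two-sided p via the
# t-approximation with n - 2 degrees of freedom.
.spearman_pairs <- function(prob) {
  n <- nrow(prob)
  # constant columns are detected and reported by the caller; silence the
  # duplicate zero-sd warning from cor()
  rho <- suppressWarnings(stats::cor(prob, method = "spearman"))
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p)
}

#' Build a co-occurrence network from occurrence probabilities
#'
#' For every unordered species pair, computes Spearman's rank correlation
#' across sites and a two-sided p-value (t-approximation, n - 2 df), and
#' retains edges with p below `alpha`. Correlation signs are kept as edge
#' attributes; no multiple-testing correction is applied to edge p-values.
#'
#' @param prob A `probability_matrix` (or plain sites x species matrix).
#' @param alpha Edge p-value threshold (default 0.01).
#' @param guild Optional named guild vector (taken from `prob` when it is a
#'   `probability_matrix`).
#' @return A list of class `cooccurrence_network` with `edges` (data frame:
#'   `species_a`, `species_b`, `rho`, `p`, `sign`), `species`, `guild`,
#'   `scenario` and `alpha`.
#' @export
correlation_network <- function(prob, alpha = 0.01, guild = NULL) {
  scenario <- "unknown"
  if (inherits(prob, "probability_matrix")) {
    scenario <- prob$scenario
    if (is.null(guild)) guild <- prob$guild
    prob <- prob$prob
  }
  prob <- as.matrix(prob)
  if (nrow(prob) < 10) stop("need at least 10 sites")
  if (ncol(prob) < 2) stop("need at least 2 species")
  sds <- apply(prob, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant probability columns skipped: ",
            paste(colnames(prob)[sds == 0], collapse = ", "))
  }
  sp <- .spearman_pairs(prob)
  idx <- which(upper.tri(sp$rho), arr.ind = TRUE)
  keep <- is.finite(sp$p[idx]) & sp$p[idx] < alpha &
    sds[idx[, 1]] > 0 & sds[idx[, 2]] > 0
  idx <- idx[keep, , drop = FALSE]
  edges <- data.frame(
    species_a = colnames(prob)[idx[, 1]],
    species_b = colnames(prob)[idx[, 2]],
    rho = sp$rho[idx],
    p = sp$p[idx],
    sign = ifelse(sp$rho[idx] >= 0, 1L, -1L))
  structure(list(edges = edges, species = colnames(prob), guild = guild,
                 scenario = scenario, alpha = alpha),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("cooccurrence_network:", length(x$species), "species,",
      nrow(x$edges), "edges (p <", x$alpha, ") | scenario:", x$scenario, "\n")
  invisible(x)
}

# unweighted igraph on edge-incident nodes only (internal)
.network_graph <- function(net) {
  nodes <- sort(unique(c(net$edges$species_a, net$edges$species_b)))
  igraph::graph_from_data_frame(net$edges[, c("species_a", "species_b")],
                                directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' Topological metrics of a co-occurrence network
#'
#' Nodes are the species incident to at least one retained edge. Edges are
#' unweighted and sign-agnostic for all metrics. Connectance is the edge
#' density over those nodes; mean path length averages unweighted
#' shortest-path lengths over reachable ordered pairs; communities are
#' found by Girvan-Newman edge betweenness cut at the maximum-modularity
#' partition, on which Q is evaluated.
#'
#' @param net A `cooccurrence_network`.
#' @return A list of class `network_metrics`: `n_nodes`, `n_edges`,
#'   `connectance`, `mean_path_length`, `n_communities`, `modularity`, plus
#'   the community `membership`. Path length and modularity are `NA` for an
#'   empty edge set.
#' @export
network_metrics <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (nrow(net$edges) == 0) {
    return(structure(list(n_nodes = 0L, n_edges = 0L, connectance = NA_real_,
                          mean_path_length = NA_real_,
                          n_communities = NA_integer_,
                          modularity = NA_real_, membership = NULL,
                          scenario = net$scenario),
                     class = "network_metrics"))
  }
  g <- .network_graph(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  connectance <- m / (n * (n - 1) / 2)
  mpl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  comm <- igraph::cluster_edge_betweenness(g, weights = NULL)
  membership <- igraph::membership(comm)
  Q <- igraph::modularity(g, membership)
  structure(list(n_nodes = n, n_edges = m, connectance = connectance,
                 mean_path_length = mpl,
                 n_communities = length(unique(membership)),
                 modularity = Q, membership = membership,
                 scenario = net$scenario),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(paste0("network_metrics [%s]: %d nodes, %d edges, ",
                     "connectance %.3f, mean path %.3f, %s communities, ",
                     "Q = %.3f\n"),
              x$scenario, x$n_nodes, x$n_edges, x$connectance,
              x$mean_path_length, x$n_communities, x$modularity))
  invisible(x)
}

#' Edge changes between two networks
#'
#' Set differences between the edge sets of a reference (typically the
#' baseline) and another network over the same species universe. Edges are
#' unordered pairs; retained pairs whose correlation sign flipped are
#' flagged.
#'
#' @param reference,other `cooccurrence_network` objects over the same
#'   species.
#' @return A list of class `edge_change` with counts `gained`, `lost`,
#'   `retained`, `sign_flipped`, and pair data frames `gained_pairs`,
#'   `lost_pairs`, `retained_pairs`.
#' @export
compare_networks <- function(reference, other) {
  stopifnot(inherits(reference, "cooccurrence_network"),
            inherits(other, "cooccurrence_network"))
  if (!setequal(reference$species, other$species))
    stop("networks are defined over different species universes")
  key <- function(e) paste(pmin(e$species_a, e$species_b),
                           pmax(e$species_a, e$species_b), sep = "|")
  kr <- key(reference$edges)
  ko <- key(other$edges)
  gained <- setdiff(ko, kr)
  lost <- setdiff(kr, ko)
  retained <- intersect(kr, ko)
  sign_ref <- stats::setNames(reference$edges$sign, kr)
  sign_oth <- stats::setNames(other$edges$sign, ko)
  flipped <- retained[sign_ref[retained] != sign_oth[retained]]
  unkey <- function(k) {
    if (!length(k)) return(data.frame(species_a = character(),
                                      species_b = character()))
    parts <- do.call(rbind, strsplit(k, "|", fixed = TRUE))
    data.frame(species_a = parts[, 1], species_b = parts[, 2])
  }
  structure(list(gained = length(gained), lost = length(lost),
                 retained = length(retained), sign_flipped = length(flipped),
                 gained_pairs = unkey(gained), lost_pairs = unkey(lost),
                 retained_pairs = unkey(retained)),
            class = "edge_change")
}

#' @export
print.edge_change <- function(x, ...) {
  cat(sprintf("edge_change: %d gained, %d lost, %d retained (%d sign flips)\n",
              x$gained, x$lost, x$retained, x$sign_flipped))
  invisible(x)
}

#' Export a network's edge list to CSV
#'
#' @param net A `cooccurrence_network`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.csv(net$edges, path, row.names = FALSE)
  invisible(path)
}
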