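#' Global network-property summary
#'
#' Computes the standard global descriptors of an undirected network:
#' density \code{2E / (n (n-1))}, average node degree \code{2E / n},
#' diameter and characteristic path length L (shortest paths over connected
#' pairs only; a disconnected network's giant component dominates both),
#' average clustering coefficient C (nodes of degree < 2 contribute 0), the
#' Erdos-Renyi expectations \code{L_rand = ln(n) / ln(<k>)} and
#' \code{C_rand = <k> / n} used to diagnose the small-world property, and
#' the hub list (nodes with degree >= \code{hub_min_degree}, sorted by
#' degree descending).
#'
#' @param net a \code{\link{gene_network}}.
#' @param hub_min_degree minimum degree for the hub list.
#' @param paths compute path-based metrics (diameter, L); can be switched
#'   off for very large networks where only the arithmetic descriptors are
#'   needed.
#' @return object of class \code{network_summary} (a list).
#' @export
summarize_network <- function(net, hub_min_degree = 50, paths = TRUE) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$nodes)
  if (n < 2L) stop("need at least 2 nodes")
  ne <- nrow(net$edges)
  deg <- node_degree(net)
  avg_deg <- 2 * ne / n
  out <- list(
    n_nodes = n, n_edges = ne,
    density = 2 * ne / (n * (n - 1)),
    avg_degree = avg_deg,
    diameter = NA_real_, path_length = NA_real_, clustering = NA_real_,
    l_rand = if (avg_deg > 1) log(n) / log(avg_deg) else NA_real_,
    c_rand = avg_deg / n,
    hubs = sort(deg[deg >= hub_min_degree], decreasing = TRUE),
    hub_min_degree = hub_min_degree)
  if (ne > 0L) {
    g <- as_igraph(net)
    if (paths) {
      out$diameter <- igraph::diameter(g, weights = NA, unconnected = TRUE)
      out$path_length <- igraph::mean_distance(g, weights = NA,
                                               unconnected = TRUE)
    }
    cc <- igraph::transitivity(g, type = "local", isolates = "zero")
    cc[deg[igraph::V(g)$name] < 2] <- 0
    out$clustering <- mean(cc)
  }
  structure(out, class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else format(signif(v, 4))
  cat("Network summary\n")
  cat(sprintf("  nodes: %d   edges: %d\n", x$n_nodes, x$n_edges))
  cat(sprintf("  density: %s   average degree: %s\n",
              fmt(x$density), fmt(x$avg_degree)))
  cat(sprintf("  diameter: %s   characteristic path length L: %s\n",
              fmt(x$diameter), fmt(x$path_length)))
  cat(sprintf("  clustering C: %s   (random graph: L = %s, C = %s)\n",
              fmt(x$clustering), fmt(x$l_rand), fmt(x$c_rand)))
  cat(sprintf("  hubs (degree >= %d): %d\n", x$hub_min_degree,
              length(x$hubs)))
  invisible(x)
}

#' Shortest-path betweenness centrality
#'
#' Frequency with which each node lies on shortest paths between pairs of
#' other nodes (unweighted paths).  Unnormalized by default: the centre of a
#' k-leaf star scores \code{choose(k, 2)}.
#'
#' @param net a \code{gene_network}.
#' @param normalized divide by the number of node pairs excluding the node,
#'   \code{(n-1)(n-2)/2}.
#' @return named numeric vector over all nodes.
#' @export
node_betweenness <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  if (nrow(net$edges) == 0L)
    return(stats::setNames(numeric(length(net$nodes)), net$nodes))
  g <- as_igraph(net)
  b <- igraph::betweenness(g, weights = NA, directed = FALSE,
                           normalized = normalized)
  b[net$nodes]
}

#' Least-squares power-law fit of a degree distribution
#'
#' Fits a straight line to (log k, log P(k)) over observed degrees
#' \code{k >= k_min} with P(k) > 0, where P(k) is the fraction of nodes with
#' degree k — a scale-free network gives a line of slope -gamma.  The
#' cumulative variant (fraction of nodes with degree >= k, slope
#' \code{-(gamma - 1)}) is fitted as well; it is less noisy on empirical
#' graphs and reported as \code{gamma_cum}.
#'
#' @param x a \code{gene_network}, a numeric vector of node degrees, or a
#'   data.frame with columns \code{k} and \code{p} (a precomputed degree
#'   histogram).
#' @param k_min smallest degree entering the fit.
#' @return list with \code{gamma} (slope magnitude of the density fit),
#'   \code{logA} (intercept), \code{gamma_cum}, \code{r_squared},
#'   \code{n_points} and logical \code{flat} (|slope| < 0.5, flagging a
#'   distribution with no power-law decay).
#' @export
powerlaw_fit <- function(x, k_min = 1) {
  if (inherits(x, "gene_network")) x <- node_degree(x)
  if (is.data.frame(x)) {
    if (!all(c("k", "p") %in% names(x))) stop("histogram needs columns k, p")
    k <- x$k; pk <- x$p
    cum <- rev(cumsum(rev(pk)))
  } else {
    n <- length(x)
    tab <- table(x)
    k <- as.numeric(names(tab)); pk <- as.numeric(tab) / n
    cum <- rev(cumsum(rev(pk)))
  }
  sel <- k >= k_min & pk > 0
  k <- k[sel]; pk <- pk[sel]; cum <- cum[sel]
  if (length(k) < 3L)
    stop("power-law fit needs at least 3 distinct degrees >= k_min (got ",
         length(k), ")")
  fit <- stats::lm(log(pk) ~ log(k))
  slope <- unname(stats::coef(fit)[2L])
  fit_cum <- stats::lm(log(cum) ~ log(k))
  ss_tot <- sum((log(pk) - mean(log(pk)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(gamma = -slope,
       logA = unname(stats::coef(fit)[1L]),
       gamma_cum = -unname(stats::coef(fit_cum)[2L]) + 1,
       r_squared = r2,
       n_points = length(k),
       flat = abs(slope) < 0.5)
}

# number of connected components of the subgraph induced by node indices
# `sel` (integer), given the network's edge endpoint indices; union-find
components_induced <- function(sel, from_idx, to_idx) {
  t <- length(sel)
  pos <- integer(max(c(sel, from_idx, to_idx, 1L)))
  pos[sel] <- seq_len(t)
  keep <- pos[from_idx] > 0L & pos[to_idx] > 0L
  a <- pos[from_idx[keep]]; b <- pos[to_idx[keep]]
  parent <- seq_len(t)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  comp <- t
  for (e in seq_along(a)) {
    ra <- find(a[e]); rb <- find(b[e])
    if (ra != rb) { parent[ra] <- rb; comp <- comp - 1L }
  }
  comp
}

#' Permutation test of functional modularity
#'
#' A gene set forming a functional module should induce a subgraph with few
#' connected components.  The observed component count of the subgraph
#' induced by \code{genes} is compared against a null distribution obtained
#' by drawing random node sets of the same size (distributionally identical
#' to relabelling the network's genes) \code{shuffles} times.  The empirical
#' p-value uses the add-one correction
#' \code{p = (1 + #\{null <= observed\}) / (1 + shuffles)} and is therefore
#' never exactly zero.
#'
#' @param net a \code{gene_network}.
#' @param genes character vector of gene ids (>= 2), all present in the
#'   network.
#' @param shuffles number of random draws (>= 1).
#' @param seed optional integer seed.
#' @return object of class \code{modularity_result}: list with
#'   \code{n_genes}, \code{observed} component count, \code{null} sample and
#'   \code{p_value}.
#' @export
modularity_test <- function(net, genes, shuffles = 102400, seed = NULL) {
  stopifnot(inherits(net, "gene_network"))
  genes <- unique(as.character(genes))
  missing <- setdiff(genes, net$nodes)
  if (length(missing))
    stop("gene(s) absent from the network: ", paste(missing, collapse = ", "))
  if (length(genes) < 2L) stop("need at least 2 genes")
  if (shuffles < 1L) stop("shuffles must be >= 1 (p undefined otherwise)")
  if (!is.null(seed)) set.seed(seed)
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  fi <- idx[net$edges$from]; ti <- idx[net$edges$to]
  t <- length(genes)
  observed <- components_induced(unname(idx[genes]), fi, ti)
  null <- integer(shuffles)
  n <- length(net$nodes)
  for (s in seq_len(shuffles))
    null[s] <- components_induced(sample.int(n, t), fi, ti)
  structure(list(n_genes = t, observed = observed, null = null,
                 p_value = (1 + sum(null <= observed)) / (1 + shuffles),
                 shuffles = as.integer(shuffles)),
            class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat(sprintf(
    "Functional modularity test: %d genes, %d component(s) observed\n",
    x$n_genes, x$observed))
  cat(sprintf("  null mean %.2f components over %d shuffles; p = %.4g\n",
              mean(x$null), x$shuffles, x$p_value))
  invisible(x)
}
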