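#' Construct an undirected weighted gene network
#'
#' Canonical container for an inferred co-expression network: an edge list
#' with MI weights, stored with \code{from < to} lexicographically.  Self
#' loops, duplicate edges and non-positive weights are rejected.
#'
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{weight}; zero-row frames are allowed.
#' @param nodes character vector of all node ids (defaults to the edge
#'   endpoints); must contain every endpoint.  Keeping the full gene list
#'   here lets density account for unconnected genes.
#' @param params named list of provenance parameters (bins, order, epsilon,
#'   n_perm, seed, ...) embedded in any file written from the object.
#' @return object of class \code{gene_network}.
#' @export
gene_network <- function(edges, nodes = NULL, params = list()) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = as.character(edges$from),
                        to = as.character(edges$to),
                        weight = as.numeric(edges$weight),
                        stringsAsFactors = FALSE)
    if (any(edges$from == edges$to))
      stop("self-loops are not allowed: ",
           paste(utils::head(edges$from[edges$from == edges$to]), collapse = ", "))
    if (any(edges$weight <= 0))
      stop("edge weights must be positive")
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate edges: ",
           paste(utils::head(unique(gsub("\r", "--", key[duplicated(key)]))),
                 collapse = ", "))
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  ep <- union(edges$from, edges$to)
  if (is.null(nodes)) nodes <- sort(ep)
  else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) stop("duplicate node ids")
    if (!all(ep %in% nodes)) stop("edge endpoints missing from 'nodes'")
  }
  structure(list(edges = edges, nodes = nodes, params = params),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("Gene network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges))
    cat(sprintf("  MI weights in [%.4g, %.4g] nats\n",
                min(x$edges$weight), max(x$edges$weight)))
  if (length(x$params)) {
    p <- x$params
    cat("  params:", paste(names(p), unlist(lapply(p, format)), sep = "=",
                           collapse = ", "), "\n")
  }
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Node degrees of a gene network
#'
#' @param net a \code{gene_network}.
#' @return named integer vector over all nodes (isolated nodes have 0).
#' @export
node_degree <- function(net) {
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(net$edges$from); t2 <- table(net$edges$to)
    d[names(t1)] <- d[names(t1)] + as.integer(t1)
    d[names(t2)] <- d[names(t2)] + as.integer(t2)
  }
  d
}

#' Plot the degree distribution of a network on log-log axes
#'
#' Draws P(k), the fraction of nodes with degree k, against k on log-log
#' axes with the least-squares power-law fit overlaid — the standard visual
#' check for scale-free structure.
#'
#' @param x a \code{gene_network}.
#' @param k_min smallest degree included in the fit line.
#' @param ... passed to \code{plot}.
#' @return invisibly, the \code{\link{powerlaw_fit}} result.
#' @export
plot.gene_network <- function(x, k_min = 1, ...) {
  deg <- node_degree(x)
  tab <- table(deg[deg >= k_min])
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / length(deg)
  plot(k, pk, log = "xy", xlab = "degree k", ylab = "P(k)",
       main = "Degree distribution", ...)
  fit <- try(powerlaw_fit(x, k_min = k_min), silent = TRUE)
  if (!inherits(fit, "try-error")) {
    kk <- range(k)
    graphics::lines(kk, exp(fit$logA) * kk^(-fit$gamma), lty = 2)
  }
  invisible(if (inherits(fit, "try-error")) NULL else fit)
}
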