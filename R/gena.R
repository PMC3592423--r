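#' Convert a weighted network into a first-order Markov chain
#'
#' Assigns each edge (i, j) the transition probability
#' \code{w_ij = MI(i, j) / sum_k MI(i, k)}, i.e. MI-proportional row
#' normalization, so a random walker leaves a gene along its strongest
#' interactions most often.  Isolated nodes have an empty row; the walk
#' handles them by redirecting their mass to the restart preference
#' (see \code{\link{rank_genes}}).
#'
#' @param net a \code{\link{gene_network}} with at least one node.
#' @return object of class \code{transition_model}: list with \code{nodes},
#'   row-stochastic dense matrix \code{W} and logical \code{dangling}.
#' @export
transition_matrix <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  n <- length(net$nodes)
  if (n == 0L) stop("empty network")
  if (nrow(net$edges) && any(net$edges$weight < 0))
    stop("negative edge weight")
  idx <- stats::setNames(seq_len(n), net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    fi <- idx[net$edges$from]; ti <- idx[net$edges$to]
    W[cbind(fi, ti)] <- net$edges$weight
    W[cbind(ti, fi)] <- net$edges$weight
  }
  rs <- rowSums(W)
  dangling <- rs == 0
  W[!dangling, ] <- W[!dangling, , drop = FALSE] / rs[!dangling]
  structure(list(nodes = net$nodes, W = W, dangling = dangling),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("Markov transition model: %d nodes (%d dangling)\n",
              length(x$nodes), sum(x$dangling)))
  invisible(x)
}

#' Rank genes for relevance to a seed set by a restarting random walk
#'
#' Iterates \code{R <- r P + (1 - r) W' R} from the preference vector P
#' (1/t on each of the t seeds, 0 elsewhere) until the L1 change drops
#' below \code{tol}.  \code{r} is the probability of returning to a seed at
#' each step; the fixed point is the stationary distribution of the
#' restarting walk and scores every gene by its relevance to the seeds
#' through both network topology and MI edge strength.  Mass at dangling
#' (edge-less) nodes is redirected to the preference vector so the chain is
#' well-defined on any network (set \code{dangling = "error"} to insist on
#' a connected input instead).  R sums to 1 at every iteration.
#'
#' @param model a \code{\link{transition_matrix}} result.
#' @param seeds character vector of seed gene ids present in the model.
#' @param restart return probability r in (0, 1].
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param dangling \code{"redirect"} (default) or \code{"error"}.
#' @return named numeric vector R over all nodes, summing to 1; attribute
#'   \code{"iterations"} records the iteration count.
#' @export
rank_genes <- function(model, seeds, restart = 0.3, tol = 1e-10,
                       max_iter = 1000, dangling = c("redirect", "error")) {
  stopifnot(inherits(model, "transition_model"))
  dangling <- match.arg(dangling)
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, model$nodes)
  if (length(missing))
    stop("seed gene(s) absent from the network: ",
         paste(missing, collapse = ", "))
  if (restart <= 0 || restart > 1) stop("restart must be in (0, 1]")
  if (dangling == "error" && any(model$dangling))
    stop("network has ", sum(model$dangling), " edge-less node(s)")
  n <- length(model$nodes)
  P <- stats::setNames(numeric(n), model$nodes)
  P[seeds] <- 1 / length(seeds)
  if (restart == 1)
    return(structure(P, iterations = 0L))
  Wt <- t(model$W)
  R <- P
  for (it in seq_len(max_iter)) {
    Rnew <- restart * P +
      (1 - restart) * (drop(Wt %*% R) + sum(R[model$dangling]) * P)
    delta <- sum(abs(Rnew - R))
    R <- Rnew
    if (delta < tol)
      return(structure(R, iterations = it))
  }
  stop("random-walk ranking did not converge in ", max_iter,
       " iterations (L1 residual ", format(delta), ")")
}

#' Grow the minimal rank-ordered connected subnetwork around seed genes
#'
#' Sorts non-seed genes by their random-walk rank (descending; ties broken
#' lexicographically by gene id) and appends them one at a time to the seed
#' set until the subgraph induced by seeds plus appended genes forms a
#' single connected component; the first connected state stops the growth.
#' Connectivity is tracked incrementally with a union-find (appending is
#' monotone).  Only genes with positive rank are candidates; if they are
#' exhausted without connecting the seeds, an error is raised.
#'
#' @param net a \code{\link{gene_network}}.
#' @param seeds character vector of seed gene ids.
#' @param restart return probability r for the ranking walk.
#' @param ranks optional precomputed rank vector from
#'   \code{\link{rank_genes}} (computed from \code{net} when NULL).
#' @return object of class \code{subnetwork_result}: list with
#'   \code{seeds}, \code{added} (data.frame of gene and rank, in addition
#'   order), \code{edges} of the induced subgraph, \code{nodes}, the rank
#'   vector and the iteration count of the ranking.
#' @export
extract_subnetwork <- function(net, seeds, restart = 0.3, ranks = NULL) {
  stopifnot(inherits(net, "gene_network"))
  seeds <- unique(as.character(seeds))
  missing <- setdiff(seeds, net$nodes)
  if (length(missing))
    stop("seed gene(s) absent from the network: ",
         paste(missing, collapse = ", "))
  iterations <- NA_integer_
  if (is.null(ranks)) {
    ranks <- rank_genes(transition_matrix(net), seeds, restart = restart)
    iterations <- attr(ranks, "iterations")
  }
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  # adjacency lists for incremental induction
  adj <- vector("list", length(net$nodes))
  fi <- idx[net$edges$from]; ti <- idx[net$edges$to]
  for (e in seq_along(fi)) {
    adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
    adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
  }
  parent <- seq_along(net$nodes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  present <- logical(length(net$nodes))
  comp <- 0L
  add_node <- function(v) {
    present[v] <<- TRUE
    comp <<- comp + 1L
    for (u in adj[[v]]) if (present[u]) {
      ru <- find(u); rv <- find(v)
      if (ru != rv) { parent[ru] <<- rv; comp <<- comp - 1L }
    }
  }
  for (s in seeds) add_node(idx[[s]])
  cand <- setdiff(net$nodes, seeds)
  cand <- cand[ranks[cand] > 0]
  cand <- cand[order(-ranks[cand], cand)]
  added <- character()
  ci <- 0L
  while (comp > 1L) {
    ci <- ci + 1L
    if (ci > length(cand))
      stop("seed genes cannot be connected through positively-ranked genes",
           " (candidates exhausted with ", comp, " components left)")
    add_node(idx[[cand[ci]]])
    added <- c(added, cand[ci])
  }
  nodes <- c(seeds, added)
  sel <- net$edges$from %in% nodes & net$edges$to %in% nodes
  structure(list(seeds = seeds,
                 added = data.frame(gene = added,
                                    rank = unname(ranks[added]),
                                    stringsAsFactors = FALSE),
                 nodes = nodes,
                 edges = net$edges[sel, , drop = FALSE],
                 ranks = ranks,
                 iterations = iterations),
            class = "subnetwork_result")
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat(sprintf(
    "Extracted subnetwork: %d seed genes + %d added genes, %d edges\n",
    length(x$seeds), nrow(x$added), nrow(x$edges)))
  if (nrow(x$added))
    cat("  top added:",
        paste(utils::head(x$added$gene, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Read a seed-gene list from a plain-text file
#'
#' One gene id per line; blank lines and lines starting with \code{#} are
#' ignored.
#'
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_seeds <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no seed genes in ", path)
  unique(lines)
}
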