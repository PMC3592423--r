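#' Prune candidate indirect interactions with the data processing inequality
#'
#' For a Markov chain X1 -> X2 -> X3, MI(X1, X3) can exceed neither
#' MI(X1, X2) nor MI(X2, X3); the weakest edge of a triangle is therefore a
#' candidate indirect interaction.  An edge (i, k) is removed whenever some
#' common neighbour j of i and k satisfies
#' \code{MI(i,k) <= (1 - tolerance) * min(MI(i,j), MI(j,k))}.  All removal
#' decisions are evaluated against the input network (mark-and-sweep), so
#' the result does not depend on edge order.  Note the inequality is
#' non-strict: with tolerance 0, an equal-weight triangle loses all three
#' edges.  A small positive tolerance softens exact ties.
#'
#' @param net a \code{\link{gene_network}}.
#' @param tolerance in [0, 1): fraction by which MI(i,k) must fall short of
#'   the weaker of the two path edges before removal.
#' @return a \code{gene_network} with the flagged edges removed; surviving
#'   weights are unchanged.
#' @export
apply_dpi <- function(net, tolerance = 0) {
  stopifnot(inherits(net, "gene_network"))
  if (tolerance < 0 || tolerance >= 1) stop("tolerance must be in [0, 1)")
  e <- net$edges
  if (nrow(e) < 3L) return(net)
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  n <- length(net$nodes)
  D <- matrix(0, n, n)
  fi <- idx[e$from]; ti <- idx[e$to]
  D[cbind(fi, ti)] <- e$weight
  D[cbind(ti, fi)] <- e$weight
  drop <- logical(nrow(e))
  for (r in seq_len(nrow(e))) {
    i <- fi[r]; k <- ti[r]
    js <- which(D[i, ] > 0 & D[k, ] > 0)
    if (length(js))
      drop[r] <- any(e$weight[r] <= (1 - tolerance) * pmin(D[i, js], D[k, js]))
  }
  gene_network(e[!drop, , drop = FALSE], nodes = net$nodes,
               params = net$params)
}
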