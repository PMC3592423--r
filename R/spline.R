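#' Rank-transform expression profiles
#'
#' Replaces each value by its position in the ascending sort of its profile,
#' so every profile becomes a permutation of \code{1..m}.  Ties are broken
#' by original index (stable), making the transform deterministic.  Mutual
#' information is invariant under monotone (homeomorphic) transformations,
#' so rank transformation preserves it while making one pooled permutation
#' null valid for every gene pair.
#'
#' @param x numeric vector, or a matrix whose rows are profiles.
#' @return integer vector (or matrix) of ranks.
#' @export
rank_transform <- function(x) {
  if (is.matrix(x)) {
    r <- t(apply(x, 1L, rank, ties.method = "first"))
    storage.mode(r) <- "integer"
    dimnames(r) <- dimnames(x)
    return(r)
  }
  if (length(x) < 2L) stop("profile needs at least 2 observations")
  as.integer(rank(x, ties.method = "first"))
}

# Cox-de Boor evaluation of all `bins` B-spline basis functions of `order`
# at points z in [0, bins - order + 1], on the uniform knot vector with
# endpoint knots repeated `order` times.  Returns length(z) x bins matrix.
bspline_eval <- function(z, bins, order) {
  dmax <- bins - order + 1
  knots <- c(rep(0, order), seq_len(max(dmax - 1, 0)), rep(dmax, order))
  nk <- length(knots)  # bins + order
  B <- matrix(0, length(z), nk - 1L)
  # order-1 (piecewise constant); right-closed at the final interval
  for (i in seq_len(nk - 1L)) {
    if (knots[i] < knots[i + 1L])
      B[, i] <- as.numeric(z >= knots[i] & (z < knots[i + 1L] |
                                              (z == dmax & knots[i + 1L] == dmax)))
  }
  if (order > 1L) {
    for (k in 2:order) {
      Bn <- matrix(0, length(z), nk - k)
      for (i in seq_len(nk - k)) {
        d1 <- knots[i + k - 1L] - knots[i]
        d2 <- knots[i + k] - knots[i + 1L]
        t1 <- if (d1 > 0) (z - knots[i]) / d1 * B[, i] else 0
        t2 <- if (d2 > 0) (knots[i + k] - z) / d2 * B[, i + 1L] else 0
        Bn[, i] <- t1 + t2
      }
      B <- Bn
    }
  }
  B[, seq_len(bins), drop = FALSE]
}

#' Precompute the shared B-spline bin-weight table for rank data
#'
#' After rank transformation every profile is a permutation of \code{1..m},
#' so the B-spline weights of each possible rank value can be tabulated once
#' and shared by every gene: row \code{r} holds the \code{bins} basis-function
#' values at rank \code{r} mapped linearly onto the spline domain
#' \code{[0, bins - order + 1]}.  Rows sum to one (partition of unity) and
#' have at most \code{order} consecutive non-zero entries, which is what
#' makes the mutual-information estimate a smoothed ("fuzzy") histogram.
#'
#' @param m number of observations (chips).
#' @param bins number of bins M.
#' @param order B-spline order k (1 = hard binning, 3 = quadratic splines).
#' @return object of class \code{spline_basis}: list with \code{weights}
#'   (m x bins matrix), \code{m}, \code{bins}, \code{order}.
#' @export
spline_basis <- function(m, bins = 10, order = 3) {
  if (order < 1L) stop("order must be >= 1")
  if (bins < order) stop("bins (", bins, ") must be >= order (", order, ")")
  if (m < bins) stop("m (", m, ") must be >= bins (", bins, ")")
  z <- (seq_len(m) - 1) / (m - 1) * (bins - order + 1)
  W <- bspline_eval(z, bins, order)
  structure(list(weights = W, m = as.integer(m), bins = as.integer(bins),
                 order = as.integer(order)),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("B-spline basis: order %d, %d bins, %d observations\n",
              x$order, x$bins, x$m))
  invisible(x)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' B-spline mutual information of two rank profiles
#'
#' Estimates MI = H(X) + H(Y) - H(X,Y) in nats (or bits) from two
#' rank-transformed profiles, with marginal bin probabilities
#' \code{p_a = mean_j w(x_j, a)} and joint probabilities
#' \code{p_ab = mean_j w(x_j, a) w(y_j, b)} taken from the shared basis
#' weight table.  The estimate is symmetric, non-negative (clamped at 0
#' against rounding) and identical for any strictly increasing transform of
#' the underlying raw profiles.
#'
#' @param ranks_x,ranks_y integer rank vectors of length \code{basis$m}
#'   (permutations of \code{1..m}).
#' @param basis a \code{\link{spline_basis}} for the same m.
#' @param unit \code{"nats"} (natural log, default) or \code{"bits"}.
#' @return a single non-negative number.
#' @export
mutual_information <- function(ranks_x, ranks_y, basis, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  m <- basis$m
  if (length(ranks_x) != m || length(ranks_y) != m)
    stop("rank vectors must have length ", m, " to match the basis")
  Wx <- basis$weights[ranks_x, , drop = FALSE]
  Wy <- basis$weights[ranks_y, , drop = FALSE]
  hx <- entropy_nats(colMeans(Wx))
  hy <- entropy_nats(colMeans(Wy))
  hxy <- entropy_nats(crossprod(Wx, Wy) / m)
  mi <- max(hx + hy - hxy, 0)
  if (unit == "bits") mi / log(2) else mi
}

# marginal entropy shared by all rank profiles of length basis$m (every
# profile is a permutation, so column means of the weight table are the
# marginals of every gene)
marginal_entropy <- function(basis) entropy_nats(colMeans(basis$weights))

# joint entropy of two weight matrices (rows = observations)
joint_entropy <- function(Wx, Wy) entropy_nats(crossprod(Wx, Wy) / nrow(Wx))
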