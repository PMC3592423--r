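#' Block partition schedule for the all-pairs MI computation
#'
#' Partitions the symmetric n x n MI matrix into p x p blocks and assigns
#' block pairs to p logical workers over \code{floor(p/2) + 1} stages: at
#' stage i worker j handles block (j, (j + i) mod p), the circular-shift
#' pattern under which each worker's column profiles at stage i are the ones
#' its right neighbour used at stage i - 1.  When p is even, the final
#' stage assigns each block to two workers, flagged \code{half} so each
#' computes half of it; such flagged pairs jointly count as one block.
#' Every unordered block pair \{a, b\} is covered exactly once.
#'
#' @param p number of logical workers (>= 1).
#' @return data.frame with columns \code{stage}, \code{rank} (worker),
#'   \code{block_row}, \code{block_col}, \code{half} (logical).
#' @export
block_schedule <- function(p) {
  p <- as.integer(p)
  if (p < 1L) stop("p must be >= 1")
  out <- list()
  last <- p %/% 2L
  for (i in 0:last) {
    half <- (p %% 2L == 0L) && i == last && i > 0L
    for (j in 0:(p - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        stage = i, rank = j, block_row = j, block_col = (j + i) %% p,
        half = half)
    }
  }
  do.call(rbind, out)
}

# indices (within 1..n) belonging to block b of p blocks; blocks as equal as
# possible, remainder spread over the first blocks
block_members <- function(n, p, b) {
  base <- n %/% p; extra <- n %% p
  start <- b * base + min(b, extra) + 1L
  len <- base + (b < extra)
  if (len == 0L) integer(0) else seq.int(start, length.out = len)
}

#' Infer a gene network by all-pairs B-spline mutual information
#'
#' The core inference engine: rank-transforms every gene profile, computes
#' B-spline MI for all gene pairs using one shared basis weight table,
#' builds the pooled permutation null, and keeps an undirected edge wherever
#' the observed MI beats at least a fraction \code{1 - epsilon} of the
#' permutation sample.  Work is organised in the logical block schedule of
#' \code{\link{block_schedule}}; results are independent of the number of
#' workers.  Optionally applies data-processing-inequality pruning
#' (\code{\link{apply_dpi}}) to the thresholded network.
#'
#' @param x an \code{\link{expression_matrix}} (preprocessed) or a plain
#'   numeric matrix with gene rownames.
#' @param bins,spline_order B-spline estimator parameters (defaults 10 bins,
#'   order 3).
#' @param epsilon significance level for the permutation test.
#' @param n_perm number of pooled permutations.
#' @param seed integer seed for the permutation stream (recorded in the
#'   result's params).
#' @param workers logical worker count for the block schedule.
#' @param dpi_tolerance if non-NULL, run DPI pruning at this tolerance.
#' @return a \code{\link{gene_network}} whose nodes are all genes of
#'   \code{x}; attribute \code{"null"} carries the \code{mi_null} used.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(15 * 40), 15, 40,
#'             dimnames = list(paste0("g", 1:15), paste0("c", 1:40)))
#' m[2, ] <- m[1, ] + rnorm(40, sd = 0.1)   # one planted interaction
#' net <- infer_network(m, bins = 5, epsilon = 0.01, n_perm = 500, seed = 7)
#' net
#' @export
infer_network <- function(x, bins = 10, spline_order = 3, epsilon = 1e-4,
                          n_perm = 1e5, seed = NULL, workers = 1,
                          dpi_tolerance = NULL) {
  if (inherits(x, "expr_matrix")) x <- x$values
  if (!is.matrix(x) || !is.numeric(x)) stop("x must be a numeric matrix")
  if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
  n <- nrow(x); m <- ncol(x)
  if (n < 2L) stop("need at least 2 genes")
  ranks <- rank_transform(x)
  basis <- spline_basis(m, bins = bins, order = spline_order)
  null <- build_null(m, n_perm = n_perm, basis = basis, epsilon = epsilon,
                     seed = seed)
  # per-gene weight matrices share the basis table; marginal entropy is
  # common to all genes because every rank profile is a permutation of 1..m
  h_marg <- marginal_entropy(basis)
  W <- lapply(seq_len(n), function(i) basis$weights[ranks[i, ], , drop = FALSE])
  p <- max(1L, as.integer(workers))
  sched <- block_schedule(p)
  from <- character(); to <- character(); wt <- numeric()
  genes <- rownames(x)
  mi_pair <- function(i, j) max(2 * h_marg - joint_entropy(W[[i]], W[[j]]), 0)
  seen_block <- new.env(parent = emptyenv())  # dedupe half-flagged pairs
  for (s in seq_len(nrow(sched))) {
    a <- sched$block_row[s]; b <- sched$block_col[s]
    bk <- paste(min(a, b), max(a, b))
    if (!is.null(get0(bk, envir = seen_block))) next
    assign(bk, TRUE, envir = seen_block)
    ra <- block_members(n, p, a); rb <- block_members(n, p, b)
    for (i in ra) for (j in rb) {
      if (a == b && i >= j) next   # diagonal block: upper triangle only
      lo <- min(i, j); hi <- max(i, j)
      mi <- mi_pair(lo, hi)
      if (is_significant(null, mi)) {
        from <- c(from, genes[lo]); to <- c(to, genes[hi]); wt <- c(wt, mi)
      }
    }
  }
  net <- gene_network(data.frame(from = from, to = to, weight = wt),
                      nodes = genes,
                      params = list(bins = bins, order = spline_order,
                                    epsilon = epsilon, n_perm = n_perm,
                                    seed = if (is.null(seed)) NA else seed,
                                    threshold = null$threshold))
  if (!is.null(dpi_tolerance)) {
    net <- apply_dpi(net, tolerance = dpi_tolerance)
    net$params$dpi_tolerance <- dpi_tolerance
  }
  attr(net, "null") <- null
  net
}

#' @export
summary.gene_network <- function(object, hub_min_degree = 50, ...) {
  summarize_network(object, hub_min_degree = hub_min_degree, ...)
}
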