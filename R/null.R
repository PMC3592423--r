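#' Build the pooled permutation null for edge significance
#'
#' Because every rank-transformed profile is a permutation of \code{1..m},
#' the MI of the identity rank vector against a uniformly random permutation
#' has the same distribution as the permutation-null MI of any gene pair;
#' one pooled sample of \code{n_perm} such values therefore serves as the
#' null for all pairs.  An observed MI is called significant when it exceeds
#' at least a fraction \code{1 - epsilon} of the null sample, i.e. when it is
#' strictly greater than the \code{ceiling((1 - epsilon) * n_perm)}-th order
#' statistic, which is stored as the threshold.
#'
#' @param m number of observations.
#' @param n_perm number of random permutations P.
#' @param basis a \code{\link{spline_basis}} with matching m.
#' @param epsilon significance level in (0, 1); requires
#'   \code{n_perm * epsilon >= 1} so the quantile is resolvable.
#' @param seed integer seed for the permutation stream.
#' @return object of class \code{mi_null}: list with sorted \code{samples},
#'   \code{threshold}, \code{epsilon}, \code{n_perm}, \code{seed}.
#' @export
build_null <- function(m, n_perm, basis, epsilon, seed = NULL) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (n_perm * epsilon < 1)
    stop("n_perm * epsilon = ", n_perm * epsilon, " < 1: ", n_perm,
         " permutations cannot resolve a quantile at epsilon = ", epsilon,
         "; increase n_perm or epsilon")
  if (basis$m != m) stop("basis was built for m = ", basis$m, ", not ", m)
  if (!is.null(seed)) set.seed(seed)
  W_id <- basis$weights
  h_marg <- marginal_entropy(basis)
  samples <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(m)
    samples[p] <- max(2 * h_marg - joint_entropy(W_id, W_id[perm, , drop = FALSE]), 0)
  }
  samples <- sort(samples)
  threshold <- samples[ceiling((1 - epsilon) * n_perm)]
  structure(list(samples = samples, threshold = threshold,
                 epsilon = epsilon, n_perm = as.integer(n_perm),
                 seed = seed),
            class = "mi_null")
}

#' @export
print.mi_null <- function(x, ...) {
  cat(sprintf(
    "Pooled MI permutation null: %d permutations, epsilon = %g, threshold = %.6g nats\n",
    x$n_perm, x$epsilon, x$threshold))
  invisible(x)
}

#' Is an observed MI significant against the pooled null?
#'
#' @param null an \code{mi_null}.
#' @param mi numeric vector of observed MI values.
#' @return logical vector: TRUE where MI beats at least a fraction
#'   \code{1 - epsilon} of the null sample.
#' @export
is_significant <- function(null, mi) mi > null$threshold
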