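#' Sample a scale-free ground-truth regulatory topology
#'
#' Draws a weakly connected directed network by preferential attachment:
#' each new gene attaches to existing genes with probability proportional
#' to degree, and the edge is oriented old -> new (regulator -> target), so
#' the result is acyclic with node order a topological order.  Preferential
#' attachment reproduces the heavy-tailed degree distributions of curated
#' regulatory networks that benchmark generators sample from.
#'
#' @param n number of genes (>= 10).
#' @param avg_degree target mean total degree; the generator attaches
#'   \code{max(1, round(avg_degree / 2))} regulators per new gene, giving
#'   about \code{n * avg_degree / 2} edges.
#' @param seed optional integer seed (the edge list is reproducible).
#' @return object of class \code{truth_network}: data.frame with columns
#'   \code{regulator}, \code{target}; attribute \code{"genes"} holds all
#'   gene ids.
#' @export
sample_topology <- function(n, avg_degree = 2, seed = NULL) {
  if (n < 10L) stop("n must be >= 10")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::sample_pa(n, m = max(1L, round(avg_degree / 2)),
                         directed = TRUE)
  el <- igraph::as_edgelist(g, names = FALSE)  # new -> old
  genes <- sprintf("G%04d", seq_len(n))
  out <- data.frame(regulator = genes[el[, 2L]],  # older gene regulates
                    target = genes[el[, 1L]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$regulator, out$target), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, genes = genes, class = c("truth_network", "data.frame"))
}

#' Simulate expression data from a ground-truth network
#'
#' Root genes (no regulators) draw standard-normal values per sample; every
#' regulated gene is \code{f(sum of +/-1-weighted regulator values)} plus
#' Gaussian noise, with \code{f} the identity (\code{linear}), the logistic
#' function (\code{sigmoidal}) or a logistic with 10-fold slope
#' (\code{steep}, nearly a step function) — three interaction families of
#' increasing difficulty for rank-based inference.  Activation/repression
#' signs are drawn once per edge.  Genes are evaluated in topological
#' order; a cyclic truth network is either iterated to a fixed update count
#' (default) or rejected in strict mode.
#'
#' @param truth a \code{\link{sample_topology}} result (or any data.frame
#'   with \code{regulator}/\code{target} columns and a \code{"genes"}
#'   attribute).
#' @param type interaction family: \code{"linear"}, \code{"sigmoidal"} or
#'   \code{"steep"}.
#' @param m number of samples (>= 10).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed optional integer seed; the matrix is bit-reproducible.
#' @param cyclic \code{"iterate"} (run \code{n_sweeps} update sweeps) or
#'   \code{"error"}.
#' @param n_sweeps update sweeps used for cyclic networks.
#' @return an \code{\link{expression_matrix}} (single experiment
#'   \code{"synthetic"}).
#' @export
simulate_expression <- function(truth, type = c("linear", "sigmoidal", "steep"),
                                m = 200, noise_sd = 0.1, seed = NULL,
                                cyclic = c("iterate", "error"), n_sweeps = 50) {
  type <- match.arg(type)
  cyclic <- match.arg(cyclic)
  if (m < 10L) stop("m must be >= 10")
  genes <- attr(truth, "genes")
  if (is.null(genes)) genes <- sort(unique(c(truth$regulator, truth$target)))
  n <- length(genes)
  if (!is.null(seed)) set.seed(seed)
  f <- switch(type,
              linear = identity,
              sigmoidal = function(s) 1 / (1 + exp(-s)),
              steep = function(s) 1 / (1 + exp(-10 * s)))
  idx <- stats::setNames(seq_len(n), genes)
  regs <- split(idx[truth$regulator], truth$target)
  sign_of <- lapply(regs, function(r) sample(c(-1, 1), length(r), replace = TRUE))
  # Kahn topological order; detects cycles
  indeg <- stats::setNames(integer(n), genes)
  tg <- table(truth$target); indeg[names(tg)] <- as.integer(tg)
  out_of <- split(idx[truth$target], truth$regulator)
  queue <- which(indeg == 0L); order_ <- integer(0)
  indeg_w <- indeg
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_ <- c(order_, v)
    for (u in out_of[[genes[v]]]) {
      indeg_w[u] <- indeg_w[u] - 1L
      if (indeg_w[u] == 0L) queue <- c(queue, u)
    }
  }
  acyclic <- length(order_) == n
  if (!acyclic && cyclic == "error") stop("truth network is cyclic")
  X <- matrix(0, n, m,
              dimnames = list(genes, sprintf("S%04d", seq_len(m))))
  eval_gene <- function(i, noise) {
    g <- genes[i]
    r <- regs[[g]]
    if (is.null(r)) stats::rnorm(m)
    else f(colSums(X[r, , drop = FALSE] * sign_of[[g]])) + noise[i, ]
  }
  noise <- matrix(stats::rnorm(n * m, sd = noise_sd), n, m)
  if (acyclic) {
    for (i in order_) X[i, ] <- eval_gene(i, noise)
  } else {
    X[] <- stats::rnorm(n * m)
    for (s in seq_len(n_sweeps)) for (i in seq_len(n)) X[i, ] <- eval_gene(i, noise)
  }
  expression_matrix(X, "synthetic")
}

canonical_pairs <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Score a predicted network against a ground truth
#'
#' Precision (fraction of predicted edges that are true), recall (fraction
#' of true edges predicted) and their harmonic mean, the F-score.  Edge
#' direction in the truth is ignored (MI networks are undirected).  When
#' the prediction carries weights, AUROC and AUPR are also computed over
#' all possible node pairs, with non-predicted pairs scored 0 (ties handled
#' by threshold sweep; ROC area equals the tie-corrected Mann-Whitney
#' statistic, PR area by trapezoid between sweep points anchored at the
#' first retrieved block).
#'
#' @param predicted a \code{\link{gene_network}}.
#' @param truth a \code{truth_network} (or data.frame with
#'   \code{regulator}/\code{target}).
#' @param curves also compute AUROC / AUPR (needs \code{predicted} weights).
#' @return object of class \code{benchmark_score}: list with
#'   \code{precision}, \code{recall}, \code{fscore}, \code{tp},
#'   \code{n_predicted}, \code{n_true}, and \code{auroc}/\code{aupr} when
#'   requested.
#' @export
score_prediction <- function(predicted, truth, curves = TRUE) {
  stopifnot(inherits(predicted, "gene_network"))
  if (nrow(truth) == 0L) stop("empty truth network")
  tkey <- unique(canonical_pairs(as.character(truth$regulator),
                                 as.character(truth$target)))
  pkey <- canonical_pairs(predicted$edges$from, predicted$edges$to)
  tp <- sum(pkey %in% tkey)
  np <- length(pkey); nt <- length(tkey)
  precision <- if (np > 0) tp / np else 0
  recall <- tp / nt
  fscore <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  out <- list(precision = precision, recall = recall, fscore = fscore,
              tp = tp, n_predicted = np, n_true = nt)
  if (curves) {
    genes <- attr(truth, "genes")
    if (is.null(genes))
      genes <- sort(unique(c(predicted$nodes, truth$regulator, truth$target)))
    pairs <- utils::combn(sort(genes), 2L)
    allkey <- paste(pairs[1L, ], pairs[2L, ], sep = "\r")
    score <- stats::setNames(numeric(length(allkey)), allkey)
    score[pkey] <- predicted$edges$weight
    labels <- allkey %in% tkey
    cur <- ranked_curves(score, labels)
    out$auroc <- cur$auroc
    out$aupr <- cur$aupr
  }
  structure(out, class = "benchmark_score")
}

#' @export
print.benchmark_score <- function(x, ...) {
  cat(sprintf(
    "Prediction score: precision %.3f, recall %.3f, F %.3f (%d/%d predicted, %d true)\n",
    x$precision, x$recall, x$fscore, x$tp, x$n_predicted, x$n_true))
  if (!is.null(x$auroc))
    cat(sprintf("  AUROC %.3f, AUPR %.3f\n", x$auroc, x$aupr))
  invisible(x)
}

# AUROC (tie-corrected Mann-Whitney) and AUPR (threshold sweep over
# distinct score values, trapezoid) for a scored candidate set
ranked_curves <- function(score, labels) {
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    return(list(auroc = NA_real_, aupr = NA_real_))
  r <- rank(score)  # average ranks under ties
  auroc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  # sweep thresholds from the highest distinct score down
  o <- order(score, decreasing = TRUE)
  s <- score[o]; l <- labels[o]
  cum_tp <- cumsum(l)
  last_of_block <- which(!duplicated(s, fromLast = TRUE))  # block ends
  tp <- cum_tp[last_of_block]
  nsel <- last_of_block
  prec <- tp / nsel
  rec <- tp / npos
  rec0 <- c(0, rec); prec0 <- c(prec[1L], prec)
  aupr <- sum(diff(rec0) * (prec0[-1L] + prec0[-length(prec0)]) / 2)
  list(auroc = unname(auroc), aupr = unname(aupr))
}

# expected F-score of a random predictor choosing n_pred of n_pairs edges
random_fscore <- function(n_pairs, n_true, n_pred) {
  if (n_pred == 0L) return(0)
  p <- n_true / n_pairs          # expected precision
  r <- n_pred / n_pairs          # expected recall (E[tp]/n_true)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

#' Run the full inference pipeline on synthetic benchmark instances
#'
#' For each repetition: sample a ground-truth topology, simulate expression
#' data under the chosen interaction family, infer a network
#' (\code{\link{infer_network}}), prune with DPI and score against the
#' truth.  The expected F-score of a size-matched random predictor is
#' reported alongside for calibration.
#'
#' @param n genes per instance.
#' @param m samples per instance.
#' @param type interaction family (see \code{\link{simulate_expression}}).
#' @param reps repetitions (>= 1).
#' @param noise_sd simulation noise.
#' @param avg_degree truth-topology mean degree.
#' @param bins,spline_order,epsilon,n_perm,dpi_tolerance pipeline
#'   parameters passed to \code{\link{infer_network}} /
#'   \code{\link{apply_dpi}}.
#' @param seed integer seed; repetition k uses \code{seed + k}.
#' @return data.frame with one row per repetition (edges, precision,
#'   recall, fscore, f_random, auroc, aupr); attributes \code{"mean_f"} and
#'   \code{"sd_f"}.
#' @export
run_benchmark <- function(n = 100, m = 200, type = "linear", reps = 10,
                          noise_sd = 0.1, avg_degree = 2,
                          bins = 10, spline_order = 3, epsilon = 1e-4,
                          n_perm = 1e5, dpi_tolerance = 0, seed = 1) {
  if (reps < 1L) stop("reps must be >= 1")
  rows <- vector("list", reps)
  for (k in seq_len(reps)) {
    s <- seed + k
    truth <- sample_topology(n, avg_degree = avg_degree, seed = s)
    x <- simulate_expression(truth, type = type, m = m, noise_sd = noise_sd,
                             seed = s + 1000L)
    net <- infer_network(x, bins = bins, spline_order = spline_order,
                         epsilon = epsilon, n_perm = n_perm, seed = s + 2000L,
                         dpi_tolerance = dpi_tolerance)
    sc <- score_prediction(net, truth)
    rows[[k]] <- data.frame(
      rep = k, edges = nrow(net$edges),
      precision = sc$precision, recall = sc$recall, fscore = sc$fscore,
      f_random = random_fscore(n * (n - 1) / 2, sc$n_true, sc$n_predicted),
      auroc = sc$auroc, aupr = sc$aupr)
  }
  out <- do.call(rbind, rows)
  attr(out, "mean_f") <- mean(out$fscore)
  attr(out, "sd_f") <- stats::sd(out$fscore)
  out
}

#' Read a DREAM-style gold-standard edge list
#'
#' Three whitespace-separated columns: gene, gene, 0/1 indicator; rows with
#' indicator 1 are true edges.
#'
#' @param path file path.
#' @return \code{truth_network}-style data.frame with columns
#'   \code{regulator} and \code{target}.
#' @export
read_gold_standard <- function(path) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("gold standard needs 3 columns (gene, gene, 0/1)")
  d <- d[d[[3L]] == 1, 1:2]
  names(d) <- c("regulator", "target")
  rownames(d) <- NULL
  structure(d, class = c("truth_network", "data.frame"))
}

#' Challenge-style score over a set of predicted networks
#'
#' Scores each predicted (weighted) network against its gold standard by
#' AUROC and AUPR, estimates empirical p-values for both areas against a
#' null of random edge rankings, and aggregates as
#' \code{-log10} of the geometric-mean p-value per metric; the overall
#' score is the mean of the AUROC and AUPR scores.  With an empirical null
#' of size N the smallest attainable p-value is \code{1 / (N + 1)}, which
#' caps the score; large N approximates challenge-style tabulated nulls.
#'
#' @param predictions list of \code{gene_network} objects.
#' @param golds list of truth networks (same length/order).
#' @param n_null random rankings per network for the empirical null.
#' @param seed optional integer seed.
#' @return list with per-network \code{auroc}, \code{aupr},
#'   \code{p_auroc}, \code{p_aupr}, and aggregate \code{auroc_score},
#'   \code{aupr_score}, \code{score}.
#' @export
dream_score <- function(predictions, golds, n_null = 1000, seed = NULL) {
  if (length(predictions) != length(golds))
    stop("predictions and golds must have equal length")
  if (!is.null(seed)) set.seed(seed)
  k <- length(predictions)
  auroc <- aupr <- p_auroc <- p_aupr <- numeric(k)
  for (i in seq_len(k)) {
    sc <- score_prediction(predictions[[i]], golds[[i]], curves = TRUE)
    auroc[i] <- sc$auroc; aupr[i] <- sc$aupr
    genes <- attr(golds[[i]], "genes")
    if (is.null(genes))
      genes <- sort(unique(c(predictions[[i]]$nodes,
                             golds[[i]]$regulator, golds[[i]]$target)))
    pairs <- utils::combn(sort(genes), 2L)
    allkey <- paste(pairs[1L, ], pairs[2L, ], sep = "\r")
    labels <- allkey %in%
      unique(canonical_pairs(as.character(golds[[i]]$regulator),
                             as.character(golds[[i]]$target)))
    nc <- length(allkey)
    null_auroc <- null_aupr <- numeric(n_null)
    for (b in seq_len(n_null)) {
      cur <- ranked_curves(stats::runif(nc), labels)
      null_auroc[b] <- cur$auroc; null_aupr[b] <- cur$aupr
    }
    p_auroc[i] <- (1 + sum(null_auroc >= auroc[i])) / (1 + n_null)
    p_aupr[i] <- (1 + sum(null_aupr >= aupr[i])) / (1 + n_null)
  }
  auroc_score <- -log10(exp(mean(log(p_auroc))))
  aupr_score <- -log10(exp(mean(log(p_aupr))))
  list(auroc = auroc, aupr = aupr, p_auroc = p_auroc, p_aupr = p_aupr,
       auroc_score = auroc_score, aupr_score = aupr_score,
       score = (auroc_score + aupr_score) / 2)
}
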