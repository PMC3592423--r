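#' Quality-control screening of chips
#'
#' Applies the standard array-level screens to a precomputed per-chip metrics
#' table: the scale factor must lie within \code{fold}-fold of the mean scale
#' factor of the chip's experiment, the BioB spike-in must be called present,
#' and the RMA probe-level model summaries (relative log expression, RLE, and
#' normalized unscaled standard errors, NUSE) must be tightly centred — RLE
#' around 0 and NUSE around 1, each within \code{center_tol} — with IQR at
#' most \code{iqr_max}.
#'
#' @param metrics data.frame with columns \code{chip}, \code{experiment},
#'   \code{scale_factor}, \code{biob_present} (logical),
#'   \code{rle_center}, \code{rle_iqr}, \code{nuse_center}, \code{nuse_iqr}.
#' @param fold scale factors outside \code{[mean/fold, fold*mean]} of the
#'   within-experiment mean fail.
#' @param center_tol maximum distance of the RLE center from 0 and of the
#'   NUSE center from 1.
#' @param iqr_max maximum RLE and NUSE interquartile range.
#' @return character vector of chip ids that pass every screen.
#' @export
qc_filter <- function(metrics, fold = 3, center_tol = 0.075, iqr_max = 0.75) {
  need <- c("chip", "experiment", "scale_factor", "biob_present",
            "rle_center", "rle_iqr", "nuse_center", "nuse_iqr")
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols))
    stop("metrics table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(metrics$chip))
    stop("duplicate chip ids in metrics table")
  if (nrow(metrics) == 0L) stop("empty metrics table")
  if (any(metrics$scale_factor <= 0))
    stop("non-positive scale factor for chip(s): ",
         paste(metrics$chip[metrics$scale_factor <= 0], collapse = ", "))
  if (any(metrics$rle_iqr < 0) || any(metrics$nuse_iqr < 0))
    stop("negative IQR in metrics table")
  mean_sf <- stats::ave(metrics$scale_factor, metrics$experiment)
  keep <- metrics$scale_factor >= mean_sf / fold &
    metrics$scale_factor <= mean_sf * fold &
    metrics$biob_present &
    metrics$rle_iqr <= iqr_max &
    metrics$nuse_iqr <= iqr_max &
    abs(metrics$rle_center - 0) <= center_tol &
    abs(metrics$nuse_center - 1) <= center_tol
  as.character(metrics$chip[keep])
}

#' Log-transform and centre expression within experiments
#'
#' Converts raw intensities to log2 scale and subtracts, for every gene, its
#' mean log2 expression over the chips of the experiment each chip belongs
#' to, so that per-experiment per-gene means are exactly zero.  This renders
#' expression comparable across experiments processed in different
#' laboratories.
#'
#' @param raw an \code{\link{expression_matrix}} of strictly positive raw
#'   values.
#' @return an \code{expr_matrix} of centred log2 expression.
#' @export
log_center <- function(raw) {
  stopifnot(inherits(raw, "expr_matrix"))
  v <- raw$values
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive raw value for gene '%s' in chip '%s'",
                 rownames(v)[bad[1L]], colnames(v)[bad[2L]]))
  }
  lv <- log2(v)
  for (ex in unique(raw$experiment)) {
    j <- which(raw$experiment == ex)
    lv[, j] <- lv[, j, drop = FALSE] - rowMeans(lv[, j, drop = FALSE])
  }
  expression_matrix(lv, raw$experiment)
}

#' Quantile normalization across chips
#'
#' Forces every chip (column) to share the same empirical distribution: the
#' mean of the column-wise order statistics.  Ties receive the average of
#' their target values.  By default normalization runs jointly over all
#' chips; set \code{by_experiment = TRUE} to normalize within each
#' experiment separately.
#'
#' @param x an \code{expr_matrix} with no missing values.
#' @param by_experiment normalize within experiments rather than jointly.
#' @return an \code{expr_matrix}.
#' @export
quantile_normalize <- function(x, by_experiment = FALSE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (anyNA(x$values)) stop("missing values not allowed")
  v <- x$values
  if (by_experiment) {
    for (ex in unique(x$experiment)) {
      j <- which(x$experiment == ex)
      v[, j] <- limma::normalizeQuantiles(v[, j, drop = FALSE], ties = TRUE)
    }
  } else {
    v <- limma::normalizeQuantiles(v, ties = TRUE)
  }
  dimnames(v) <- dimnames(x$values)
  expression_matrix(v, x$experiment)
}

#' Remove genes with low dynamic range
#'
#' Drops genes whose expression-profile interquartile range (75th minus 25th
#' percentile, linear interpolation between order statistics — R quantile
#' type 7) falls below \code{threshold}.  Profiles with little dynamic range
#' carry no usable signal for mutual-information estimation.
#'
#' @param x an \code{expr_matrix} with at least 4 chips.
#' @param threshold minimum IQR for a gene to be kept.
#' @return list with elements \code{matrix} (filtered \code{expr_matrix})
#'   and \code{removed} (character vector of dropped gene ids).
#' @export
iqr_filter <- function(x, threshold = 0.65) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(x$values) < 4L) stop("need at least 4 chips to estimate IQR")
  iqr <- apply(x$values, 1L, function(p)
    unname(diff(stats::quantile(p, c(0.25, 0.75), type = 7))))
  keep <- iqr >= threshold
  if (!any(keep))
    stop("IQR filter removed every gene (threshold ", threshold, ")")
  list(matrix = x[keep, ], removed = rownames(x$values)[!keep])
}

#' Cluster probe-sets sharing target genes and pick representatives
#'
#' Probe-sets with no matching gene (\code{no_match}) or mapping to more than
#' \code{max_targets} genes are discarded; the remainder are clustered by the
#' transitive closure of the shares-a-gene relation, and each cluster is
#' represented by the member probe-set mapping to the fewest genes (ties
#' broken by lexicographically smallest probe-set id).
#'
#' @param map named list: probe-set id -> character vector of gene ids
#'   (empty vector = no_match).
#' @param max_targets probe-sets mapping to more genes than this are dropped.
#' @return list with \code{representatives} (character vector),
#'   \code{assignment} (named character vector probe -> representative for
#'   every surviving probe-set) and \code{discarded} (dropped probe ids).
#' @export
cluster_probesets <- function(map, max_targets = 3) {
  if (length(map) == 0L) stop("empty probe map")
  if (is.null(names(map)) || anyDuplicated(names(map)))
    stop("probe map must have unique probe-set names")
  sizes <- lengths(map)
  ok <- sizes > 0L & sizes <= max_targets
  discarded <- names(map)[!ok]
  map <- map[ok]
  if (length(map) == 0L)
    return(list(representatives = character(), assignment = character(),
                discarded = discarded))
  probes <- names(map)
  # union-find over probes, merging via shared genes
  parent <- seq_along(probes)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  gene_owner <- new.env(parent = emptyenv())
  for (i in seq_along(probes)) {
    for (g in map[[i]]) {
      j <- get0(g, envir = gene_owner)
      if (is.null(j)) assign(g, i, envir = gene_owner)
      else { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
    }
  }
  root <- vapply(seq_along(probes), find, integer(1L))
  assignment <- character(length(probes))
  reps <- character()
  for (r in unique(root)) {
    members <- probes[root == r]
    msizes <- sizes[members]
    best <- sort(members[msizes == min(msizes)])[1L]
    reps <- c(reps, best)
    assignment[root == r] <- best
  }
  names(assignment) <- probes
  list(representatives = sort(reps), assignment = assignment,
       discarded = discarded)
}

#' Full preprocessing pipeline
#'
#' Runs the preprocessing stages in order on a raw expression matrix:
#' optional QC chip screening, per-experiment log centering, joint quantile
#' normalization, IQR gene filtering and optional probe-set collapsing to
#' representatives.  Counts removed at each stage are reported via
#' \code{message()} when \code{verbose}.
#'
#' @param raw an \code{expr_matrix} of raw positive intensities, rows =
#'   probe-sets or genes.
#' @param qc optional QC metrics data.frame (see \code{\link{qc_filter}}).
#' @param probe_map optional named list probe-set -> gene ids (see
#'   \code{\link{cluster_probesets}}); rows absent from the map are kept
#'   as-is.
#' @param iqr_threshold minimum profile IQR (applied after normalization).
#' @param quantile_by_experiment passed to \code{\link{quantile_normalize}}.
#' @param verbose log stage counts.
#' @return normalized, filtered \code{expr_matrix}; attribute \code{"log"}
#'   holds the per-stage counts.
#' @export
preprocess <- function(raw, qc = NULL, probe_map = NULL, iqr_threshold = 0.65,
                       quantile_by_experiment = FALSE, verbose = TRUE) {
  stopifnot(inherits(raw, "expr_matrix"))
  log <- list(chips_in = ncol(raw$values), genes_in = nrow(raw$values))
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(qc)) {
    keep <- intersect(colnames(raw$values), qc_filter(qc))
    say("QC: kept %d / %d chips", length(keep), ncol(raw$values))
    if (length(keep) < 2L) stop("fewer than 2 chips survive QC")
    raw <- raw[, keep]
  }
  log$chips_kept <- ncol(raw$values)
  x <- log_center(raw)
  x <- quantile_normalize(x, by_experiment = quantile_by_experiment)
  f <- iqr_filter(x, iqr_threshold)
  say("IQR filter: removed %d / %d genes", length(f$removed), nrow(x$values))
  x <- f$matrix
  log$genes_after_iqr <- nrow(x$values)
  if (!is.null(probe_map)) {
    cl <- cluster_probesets(probe_map)
    keep <- intersect(rownames(x$values),
                      union(cl$representatives,
                            setdiff(rownames(x$values), names(probe_map))))
    say("probe clustering: kept %d / %d rows", length(keep), nrow(x$values))
    if (length(keep) < 2L) stop("fewer than 2 genes survive probe clustering")
    x <- x[keep, ]
  }
  log$genes_kept <- nrow(x$values)
  attr(x, "log") <- log
  x
}

#' Synthetic QC metrics table at published-study scale
#'
#' Builds a deterministic, synthetic per-chip QC metrics table emulating a
#' large multi-repository microarray acquisition: chips are spread over the
#' given number of experiments per database, all passing chips carry
#' centred metrics, and the requested number of chips per database is made
#' to fail the screens (cycling over the BioB, RLE/NUSE spread and
#' centering criteria).  The defaults mirror a four-repository acquisition
#' of 3546 arrays in 197 experiments with 409 QC removals.  This is a
#' synthetic stand-in for exercising chip accounting, not real QC data.
#'
#' @param databases data.frame with columns \code{database},
#'   \code{experiments}, \code{chips}, \code{removed}.
#' @return a QC metrics data.frame accepted by \code{\link{qc_filter}},
#'   with an extra \code{database} column.
#' @export
synthetic_qc_table <- function(databases = data.frame(
    database = c("ArrayExpress", "AtGenExpress", "GEO", "NASC"),
    experiments = c(42L, 44L, 60L, 51L),
    chips = c(816L, 1334L, 859L, 537L),
    removed = c(44L, 289L, 59L, 17L))) {
  rows <- lapply(seq_len(nrow(databases)), function(d) {
    db <- databases$database[d]
    nc <- databases$chips[d]
    nx <- databases$experiments[d]
    nr <- databases$removed[d]
    if (nr > nc) stop("cannot remove more chips than exist for ", db)
    out <- data.frame(
      chip = sprintf("%s_chip%04d", db, seq_len(nc)),
      experiment = sprintf("%s_e%03d", db, rep_len(seq_len(nx), nc)),
      database = db,
      scale_factor = 1, biob_present = TRUE,
      rle_center = 0, rle_iqr = 0.2,
      nuse_center = 1, nuse_iqr = 0.2)
    # cycle the failing chips over screens that do not shift group means
    fail_mode <- rep_len(1:5, nr)
    out$biob_present[which(fail_mode == 1)] <- FALSE
    out$rle_iqr[which(fail_mode == 2)] <- 1.2
    out$nuse_iqr[which(fail_mode == 3)] <- 0.9
    out$rle_center[which(fail_mode == 4)] <- 0.2
    out$nuse_center[which(fail_mode == 5)] <- 1.2
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
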