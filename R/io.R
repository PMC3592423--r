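#' Read an expression matrix from tab-separated text
#'
#' Format: first row chip ids, second row experiment labels (both rows with
#' an empty leading field), then one row per gene: gene id followed by m
#' numeric values.  Ragged rows, duplicate ids and non-numeric cells are
#' rejected with the offending line number.
#'
#' @param path file path.
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("expression file needs header rows and >= 1 gene")
  split_tab <- function(l) strsplit(l, "\t", fixed = TRUE)[[1L]]
  chips <- split_tab(lines[1L])[-1L]
  exps <- split_tab(lines[2L])[-1L]
  if (length(exps) != length(chips))
    stop("line 2: expected ", length(chips), " experiment labels, got ",
         length(exps))
  m <- length(chips)
  body <- lapply(seq_along(lines)[-(1:2)], function(i) {
    f <- split_tab(lines[i])
    if (length(f) != m + 1L)
      stop("line ", i, ": expected ", m + 1L, " fields, got ", length(f))
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v))
      stop("line ", i, ": non-numeric cell for gene '", f[1L], "'")
    list(id = f[1L], v = v)
  })
  ids <- vapply(body, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- do.call(rbind, lapply(body, `[[`, "v"))
  dimnames(vals) <- list(ids, chips)
  expression_matrix(vals, exps)
}

#' Write an expression matrix as tab-separated text
#'
#' Values are serialized with 17 significant digits so a write/read round
#' trip reproduces the doubles bit-for-bit.
#'
#' @param x an \code{expr_matrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("", colnames(x$values)), collapse = "\t"), con)
  writeLines(paste(c("", unname(x$experiment)), collapse = "\t"), con)
  for (i in seq_len(nrow(x$values)))
    writeLines(paste(c(rownames(x$values)[i],
                       formatC(x$values[i, ], format = "g", digits = 17)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read a QC metrics table
#'
#' Tab-separated with a header naming the columns used by
#' \code{\link{qc_filter}}; \code{biob_present} parses TRUE/FALSE or 1/0.
#'
#' @param path file path.
#' @return data.frame of per-chip metrics.
#' @export
read_qc_metrics <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("biob_present" %in% names(d))
    d$biob_present <- as.logical(d$biob_present)
  d
}

#' Read a probe-set to gene map
#'
#' Two-column TSV: probe-set id, comma-separated gene ids; an empty second
#' field marks a no-match probe-set.
#'
#' @param path file path.
#' @return named list: probe-set id -> character vector of gene ids.
#' @export
read_probe_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 1L || !nzchar(f[1L])) stop("line ", i, ": missing probe id")
    genes <- if (length(f) < 2L || !nzchar(f[2L])) character() else
      trimws(strsplit(f[2L], ",", fixed = TRUE)[[1L]])
    if (f[1L] %in% names(out)) stop("duplicate probe-set id: ", f[1L])
    out[[f[1L]]] <- genes
  }
  out
}

#' Read a network edge list
#'
#' Tab-separated \code{gene_a gene_b weight} (or SIF:
#' \code{gene_a weight gene_b}); leading \code{#} comment lines of the form
#' \code{# key=value} are parsed back into the network's params.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"sif"}.
#' @return a \code{\link{gene_network}}.
#' @export
read_network <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  params <- list()
  for (h in sub("^#\\s*", "", hdr)) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) {
      v <- suppressWarnings(as.numeric(kv[2L]))
      params[[trimws(kv[1L])]] <- if (is.na(v)) trimws(kv[2L]) else v
    }
  }
  if (!length(lines))
    return(gene_network(NULL, params = params))
  f <- strsplit(lines, "\t", fixed = TRUE)
  len <- lengths(f)
  if (any(len != 3L))
    stop("line(s) with ", paste(unique(len[len != 3L]), collapse = "/"),
         " fields; expected 3")
  m <- do.call(rbind, f)
  if (format == "sif") m <- m[, c(1L, 3L, 2L), drop = FALSE]
  w <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(w)) stop("non-numeric edge weight at line ",
                     which(is.na(w))[1L])
  gene_network(data.frame(from = m[, 1L], to = m[, 2L], weight = w,
                          stringsAsFactors = FALSE),
               params = params)
}

#' Write a network edge list
#'
#' Canonical ordering (\code{gene_a < gene_b}, rows sorted); the network's
#' provenance params are embedded as \code{# key=value} comment lines.
#' Weights are serialized with 6 significant digits by default; set
#' \code{full_precision} for an exact binary round trip.
#'
#' @param net a \code{gene_network}.
#' @param path output path.
#' @param format \code{"tsv"} (gene_a gene_b weight) or \code{"sif"}
#'   (gene_a weight gene_b, for Cytoscape import).
#' @param full_precision serialize weights with 17 significant digits.
#' @return invisibly, \code{path}.
#' @export
write_network <- function(net, path, format = c("tsv", "sif"),
                          full_precision = FALSE) {
  stopifnot(inherits(net, "gene_network"))
  format <- match.arg(format)
  con <- file(path, "w"); on.exit(close(con))
  for (k in names(net$params))
    writeLines(sprintf("# %s=%s", k, format(net$params[[k]])), con)
  w <- formatC(net$edges$weight, format = "g",
               digits = if (full_precision) 17 else 6)
  lines <- if (format == "sif")
    paste(net$edges$from, w, net$edges$to, sep = "\t")
  else
    paste(net$edges$from, net$edges$to, w, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
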