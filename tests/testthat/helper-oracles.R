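# Independent reference implementations used as oracles in the tests.
# These deliberately share no code with the package internals.

# exact discrete MI (nats) of hard-binned data: assign each value to
# equal-width bins over [min, max] and compute MI of the contingency table
oracle_hard_mi <- function(x, y, bins) {
  cut_idx <- function(v) {
    z <- (v - min(v)) / (max(v) - min(v))
    pmin(floor(z * bins) + 1L, bins)
  }
  bx <- cut_idx(x); by <- cut_idx(y)
  tab <- table(factor(bx, levels = 1:bins), factor(by, levels = 1:bins))
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  h <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  h(px) + h(py) - h(p)
}

# all-pairs shortest path lengths by BFS over an adjacency list
oracle_bfs_dists <- function(nodes, from, to) {
  n <- length(nodes)
  adj <- vector("list", n)
  fi <- match(from, nodes); ti <- match(to, nodes)
  for (e in seq_along(fi)) {
    adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
    adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.infinite(D[s, nxt])]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# betweenness by explicit enumeration of all shortest paths (tiny graphs)
oracle_betweenness <- function(nodes, from, to) {
  n <- length(nodes)
  adj <- vector("list", n)
  fi <- match(from, nodes); ti <- match(to, nodes)
  for (e in seq_along(fi)) {
    adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
    adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
  }
  paths_between <- function(s, t, dmax) {
    # enumerate all paths of length == dist(s,t) via DFS bounded by dmax
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) { out[[length(out) + 1L]] <<- path; return() }
      if (length(path) > dmax) return()
      for (u in adj[[v]]) if (!(u %in% path)) walk(c(path, u))
    }
    walk(s)
    out
  }
  D <- oracle_bfs_dists(nodes, from, to)
  b <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    ps <- paths_between(s, t, D[s, t] + 1)
    ps <- ps[lengths(ps) == D[s, t] + 1]
    for (p in ps) {
      inner <- p[-c(1, length(p))]
      b[inner] <- b[inner] + 1 / length(ps)
    }
  }
  stats::setNames(b, nodes)
}

# brute-force DPI: enumerate all ordered triples on the input network
oracle_dpi <- function(edges, tolerance = 0) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  W[cbind(edges$from, edges$to)] <- edges$weight
  W[cbind(edges$to, edges$from)] <- edges$weight
  drop <- logical(nrow(edges))
  for (r in seq_len(nrow(edges))) {
    i <- edges$from[r]; k <- edges$to[r]
    for (j in nodes) {
      if (j == i || j == k) next
      if (W[i, j] > 0 && W[j, k] > 0 &&
          edges$weight[r] <= (1 - tolerance) * min(W[i, j], W[j, k])) {
        drop[r] <- TRUE; break
      }
    }
  }
  edges[!drop, , drop = FALSE]
}

# random connected-ish weighted undirected network for property sweeps
random_network <- function(n, p_edge = 0.25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(nodes, 2))
  sel <- runif(nrow(pairs)) < p_edge
  gene_network(data.frame(from = pairs[sel, 1], to = pairs[sel, 2],
                          weight = round(runif(sum(sel), 0.1, 1), 3)),
               nodes = nodes)
}

# confusion-matrix scoring oracle for small node sets
oracle_score <- function(pred_edges, true_edges, nodes) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  allp <- t(combn(sort(nodes), 2))
  allk <- key(allp[, 1], allp[, 2])
  pk <- unique(key(pred_edges$from, pred_edges$to))
  tk <- unique(key(true_edges[[1]], true_edges[[2]]))
  tp <- sum(allk %in% pk & allk %in% tk)
  fp <- sum(allk %in% pk & !(allk %in% tk))
  fn <- sum(!(allk %in% pk) & allk %in% tk)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, fscore = f)
}

make_expr <- function(values, experiment, genes = NULL, chips = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(chips)) chips <- paste0("c", seq_len(ncol(values)))
  dimnames(values) <- list(genes, chips)
  expression_matrix(values, experiment)
}
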