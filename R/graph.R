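#' Build the directed comorbidity graph of elevated chronological risks
#'
#' Creates a directed igraph with an edge `i -> j` for every defined matrix
#' entry with `RR(i, j) > rr_threshold` (default 1). Infinite relative risks
#' do create edges; their weight is capped at the maximum finite entry of the
#' whole matrix (preserving topology while keeping weighted computations
#' finite). Isolated nodes are retained in the node set.
#'
#' @param rrm an `"rr_matrix"` object.
#' @param labels optional named character vector of code descriptions.
#' @param rr_threshold minimum relative risk for an edge (default 1,
#'   exclusive).
#' @return a directed `igraph` object; vertices carry `name` (code) and
#'   `label`, edges carry `rr`.
#' @export
build_graph <- function(rrm, labels = NULL, rr_threshold = 1) {
  stopifnot(inherits(rrm, "rr_matrix"))
  rr <- rrm$rr
  finite <- rr[is.finite(rr)]
  cap <- if (length(finite)) max(finite) else rr_threshold + 1
  w <- rr
  w[is.infinite(w)] <- cap
  sel <- which(!is.na(rr) & rr > rr_threshold, arr.ind = TRUE)
  edges <- data.frame(from = rrm$codes[sel[, 1]], to = rrm$codes[sel[, 2]],
                      rr = w[sel], stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  lab <- rrm$codes
  if (!is.null(labels)) {
    m <- unname(labels[rrm$codes])
    lab <- ifelse(is.na(m), rrm$codes, m)
  }
  igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = rrm$codes, label = lab,
                          stringsAsFactors = FALSE))
}

.adjacency <- function(g, use_weights = TRUE) {
  attr <- if (use_weights && "rr" %in% igraph::edge_attr_names(g)) "rr" else NULL
  as.matrix(igraph::as_adjacency_matrix(g, attr = attr, sparse = TRUE))
}

#' Edge density of a directed graph
#'
#' Fraction of the `n (n - 1)` possible directed pairs that carry an edge
#' (self-loops are impossible in the comorbidity graph).
#'
#' @param g a directed igraph.
#' @return fraction in `[0, 1]`.
#' @export
edge_density <- function(g) {
  n <- igraph::gorder(g)
  if (n < 2) stop("edge density undefined for fewer than 2 nodes")
  igraph::gsize(g) / (n * (n - 1))
}

#' Reciprocity of a directed graph
#'
#' Fraction of edges whose reverse edge also exists (both directions with
#' elevated relative risk).
#'
#' @param g a directed igraph with at least one edge.
#' @return fraction in `[0, 1]`.
#' @export
reciprocity <- function(g) {
  if (igraph::gsize(g) < 1) stop("reciprocity undefined for an edgeless graph")
  el <- igraph::as_edgelist(g)
  mean(paste(el[, 2], el[, 1], sep = "\r") %in%
         paste(el[, 1], el[, 2], sep = "\r"))
}

#' Directed diameter by breadth-first search
#'
#' The longest unweighted shortest directed path over all reachable ordered
#' node pairs (unreachable pairs are ignored), found by running a BFS from
#' every node. Also returns one path realizing the diameter.
#'
#' @param g a directed igraph with at least one edge.
#' @return list with `diameter` (integer), `path` (vector of node names from
#'   source to sink), `from`, `to`.
#' @export
graph_diameter <- function(g) {
  if (igraph::gsize(g) < 1) stop("diameter undefined for an edgeless graph")
  n <- igraph::gorder(g)
  nms <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g, mode = "out"), as.integer)
  best <- -1L; best_from <- NA_integer_; best_parent <- NULL
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.na(dist[w])) {
            dist[w] <- dist[v] + 1L
            parent[w] <- v
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    far <- max(dist, na.rm = TRUE)
    if (far > best) {
      best <- far; best_from <- s; best_parent <- parent
      best_to <- which(dist == far)[1]
    }
  }
  path <- best_to
  while (!is.na(best_parent[path[1]])) path <- c(best_parent[path[1]], path)
  list(diameter = as.integer(best), path = nms[path],
       from = nms[best_from], to = nms[best_to])
}

#' Graph-level summary statistics
#'
#' @param g a directed igraph.
#' @return list with `n_nodes`, `n_edges`, `n_isolated`, `edge_density`,
#'   `reciprocity`, `diameter` (the latter three `NA` where undefined).
#' @export
graph_stats <- function(g) {
  n <- igraph::gorder(g); m <- igraph::gsize(g)
  deg <- igraph::degree(g, mode = "all")
  list(
    n_nodes = n, n_edges = m, n_isolated = sum(deg == 0),
    edge_density = if (n >= 2) edge_density(g) else NA_real_,
    reciprocity = if (m >= 1) reciprocity(g) else NA_real_,
    diameter = if (m >= 1) graph_diameter(g)$diameter else NA_integer_
  )
}

#' Kleinberg hub and authority scores
#'
#' HITS by alternating power iteration: `authority <- t(A) %*% hub`,
#' `hub <- A %*% authority`, normalising each step, where `A` is the
#' (relative-risk-weighted or binary) adjacency matrix. Converged vectors are
#' scaled so that the maximum hub score and the maximum authority score are
#' both exactly 1. Initialisation is the deterministic uniform vector.
#'
#' @param g a directed igraph with at least one edge.
#' @param use_weights use edge `rr` weights (default) or binary adjacency.
#' @param tol convergence tolerance on the max absolute change.
#' @param max_iter maximum iterations. The default is generous because a
#'   graph with several weakly coupled components has near-tied leading
#'   eigenvalues, which slows power iteration considerably; each iteration
#'   is only two sparse matrix-vector products.
#' @return list with named numeric vectors `hub` and `authority` (each with
#'   maximum 1) and `iterations`.
#' @export
hits_centrality <- function(g, use_weights = TRUE, tol = 1e-12,
                            max_iter = 50000L) {
  if (igraph::gsize(g) < 1) stop("HITS undefined for an edgeless graph")
  A <- .adjacency(g, use_weights)
  n <- nrow(A)
  h <- rep(1 / sqrt(n), n)
  a <- rep(1 / sqrt(n), n)
  l2 <- function(x) { s <- sqrt(sum(x^2)); if (s > 0) x / s else x }
  for (it in seq_len(max_iter)) {
    a_new <- l2(as.vector(crossprod(A, h)))
    h_new <- l2(as.vector(A %*% a_new))
    delta <- max(abs(a_new - a), abs(h_new - h))
    a <- a_new; h <- h_new
    if (delta < tol) {
      return(list(hub = setNames(h / max(h), rownames(A)),
                  authority = setNames(a / max(a), rownames(A)),
                  iterations = it))
    }
  }
  stop(sprintf("HITS did not converge in %d iterations (tolerance reached: %.3e)",
               max_iter, delta))
}

#' PageRank scores
#'
#' Power iteration on the damped transition operator
#' `p <- (1 - d) / n + d * t(M) %*% p`, where `M` is the row-stochastic
#' transition matrix with out-edge probabilities proportional to edge weights
#' and dangling nodes redistributing uniformly over all nodes. Scores sum to
#' one.
#'
#' @param g an igraph with at least one node.
#' @param damping damping factor `d` in `[0, 1)` (default 0.85).
#' @param use_weights use edge `rr` weights for transition probabilities.
#' @param tol L1 convergence tolerance.
#' @param max_iter maximum iterations.
#' @return named numeric vector summing to 1.
#' @export
pagerank_centrality <- function(g, damping = 0.85, use_weights = TRUE,
                                tol = 1e-12, max_iter = 1000L) {
  if (damping < 0 || damping >= 1) stop("damping must lie in [0, 1)")
  n <- igraph::gorder(g)
  if (n < 1) stop("PageRank undefined for an empty graph")
  A <- .adjacency(g, use_weights)
  rs <- rowSums(A)
  M <- A / ifelse(rs > 0, rs, 1)
  M[rs == 0, ] <- 1 / n          # dangling nodes teleport uniformly
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    p_new <- (1 - damping) / n + damping * as.vector(crossprod(M, p))
    if (sum(abs(p_new - p)) < tol) {
      p_new <- p_new / sum(p_new)
      return(setNames(p_new, rownames(A)))
    }
    p <- p_new
  }
  stop(sprintf("PageRank did not converge in %d iterations", max_iter))
}

#' Ranked node centrality table
#'
#' Hub, authority and PageRank per node, sorted by the chosen column.
#'
#' @param g a directed igraph with at least one edge.
#' @param use_weights passed to [hits_centrality()] and
#'   [pagerank_centrality()].
#' @param damping passed to [pagerank_centrality()].
#' @param sort_by one of `"hub"`, `"authority"`, `"pagerank"`.
#' @return data frame `(code3, label, hub, authority, pagerank)`.
#' @export
centrality_table <- function(g, use_weights = TRUE, damping = 0.85,
                             sort_by = c("hub", "authority", "pagerank")) {
  sort_by <- match.arg(sort_by)
  hits <- hits_centrality(g, use_weights = use_weights)
  pr <- pagerank_centrality(g, damping = damping, use_weights = use_weights)
  lab <- igraph::V(g)$label
  if (is.null(lab)) lab <- igraph::V(g)$name
  out <- data.frame(code3 = igraph::V(g)$name, label = lab,
                    hub = unname(hits$hub[igraph::V(g)$name]),
                    authority = unname(hits$authority[igraph::V(g)$name]),
                    pagerank = unname(pr[igraph::V(g)$name]),
                    stringsAsFactors = FALSE)
  out[order(-out[[sort_by]], out$code3), , drop = FALSE]
}

#' Export a comorbidity graph as GEXF
#'
#' Minimal GEXF 1.2 writer: node attributes (`label` plus any numeric or
#' character vertex attributes such as `hub`, `authority`, `pagerank`,
#' `community`) and the edge `rr` weight.
#'
#' @param g a directed igraph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(g, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", as.character(x), fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  vattrs <- setdiff(igraph::vertex_attr_names(g), c("name", "label"))
  nms <- igraph::V(g)$name
  lab <- igraph::V(g)$label
  if (is.null(lab)) lab <- nms
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="directed">',
    '    <attributes class="node">',
    sprintf('      <attribute id="%d" title="%s" type="%s"/>',
            seq_along(vattrs) - 1L, esc(vattrs),
            vapply(vattrs, function(a)
              if (is.numeric(igraph::vertex_attr(g, a))) "double" else "string",
              character(1))),
    '    </attributes>',
    '    <nodes>')
  for (i in seq_along(nms)) {
    av <- vapply(seq_along(vattrs), function(k) {
      sprintf('<attvalue for="%d" value="%s"/>', k - 1L,
              esc(igraph::vertex_attr(g, vattrs[k], index = i)))
    }, character(1))
    lines <- c(lines,
               sprintf('      <node id="%s" label="%s">%s</node>',
                       esc(nms[i]), esc(lab[i]),
                       if (length(av)) paste0("<attvalues>", paste(av, collapse = ""),
                                              "</attvalues>") else ""))
  }
  lines <- c(lines, '    </nodes>', '    <edges>')
  if (igraph::gsize(g) > 0) {
    el <- igraph::as_edgelist(g)
    w <- igraph::E(g)$rr
    if (is.null(w)) w <- rep(1, nrow(el))
    lines <- c(lines,
               sprintf('      <edge id="%d" source="%s" target="%s" weight="%s"/>',
                       seq_len(nrow(el)) - 1L, esc(el[, 1]), esc(el[, 2]),
                       format(w, digits = 10)))
  }
  lines <- c(lines, '    </edges>', '  </graph>', '</gexf>')
  writeLines(lines, path)
  invisible(path)
}
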