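#' Highest-relative-risk subsequent diagnoses of a focal code
#'
#' The `k` out-neighbours of `code` with the highest edge relative risk,
#' ties broken by code order. Fewer than `k` are returned when the
#' out-degree is smaller.
#'
#' @param g a directed comorbidity igraph (edges carry `rr`).
#' @param code focal three-digit code.
#' @param k maximum number of neighbours (default 10).
#' @return object of class `"ego_view"`: list with `focal`, `direction`
#'   and `table` (data frame `code3`, `rr`, sorted by `rr` descending).
#' @export
top_successors <- function(g, code, k = 10L) {
  .ego_view(g, code, k, mode = "out")
}

#' Highest-relative-risk preceding diagnoses of a focal code
#'
#' Mirror image of [top_successors()] on incoming edges: the `k`
#' in-neighbours whose edge into `code` carries the highest relative risk.
#'
#' @inheritParams top_successors
#' @return an `"ego_view"` (direction `"predecessors"`).
#' @export
top_predecessors <- function(g, code, k = 10L) {
  .ego_view(g, code, k, mode = "in")
}

.check_code <- function(g, code, what = "code") {
  nms <- igraph::V(g)$name
  if (!code %in% nms) {
    near <- nms[startsWith(nms, substr(code, 1, 2))]
    if (!length(near)) near <- head(sort(nms), 5)
    stop(sprintf("unknown %s '%s'; nearest matches: %s",
                 what, code, paste(head(sort(near), 5), collapse = ", ")))
  }
}

.ego_view <- function(g, code, k, mode) {
  .check_code(g, code)
  es <- igraph::incident(g, code, mode = mode)
  other <- if (mode == "out") igraph::head_of(g, es) else igraph::tail_of(g, es)
  tab <- data.frame(code3 = igraph::V(g)$name[as.integer(other)],
                    rr = igraph::edge_attr(g, "rr", es),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$rr, tab$code3), , drop = FALSE]
  tab <- head(tab, k)
  rownames(tab) <- NULL
  structure(list(focal = code,
                 direction = if (mode == "out") "successors" else "predecessors",
                 table = tab),
            class = "ego_view")
}

#' @export
print.ego_view <- function(x, ...) {
  cat(sprintf("Top %s of %s by chronological RR\n", x$direction, x$focal))
  print(x$table)
  invisible(x)
}

#' Greedy maximum-relative-risk trajectory path
#'
#' Starting at `source`, repeatedly follows the highest-relative-risk
#' out-edge to a not-yet-visited node (ties broken by code order), stopping
#' at `target` (if supplied and reached), at a node with no unvisited
#' out-neighbour, or once the path holds `max_len` nodes.
#'
#' @param g a directed comorbidity igraph.
#' @param source starting code.
#' @param target optional destination code.
#' @param max_len maximum number of nodes on the path (default 10).
#' @return object of class `"trajectory_path"`: list with `codes` (ordered
#'   node names), `rr` (per-step relative risks, length
#'   `length(codes) - 1`), and `reached` (`NA` when no target was given).
#' @export
greedy_max_rr_path <- function(g, source, target = NULL, max_len = 10L) {
  .check_code(g, source, "source")
  if (!is.null(target)) .check_code(g, target, "target")
  path <- source
  rrs <- numeric()
  current <- source
  while (length(path) < max_len &&
         (is.null(target) || current != target)) {
    es <- igraph::incident(g, current, mode = "out")
    if (!length(es)) break
    nb <- igraph::V(g)$name[as.integer(igraph::head_of(g, es))]
    w <- igraph::edge_attr(g, "rr", es)
    ok <- !nb %in% path
    if (!any(ok)) break
    nb <- nb[ok]; w <- w[ok]
    pick <- order(-w, nb)[1]
    path <- c(path, nb[pick])
    rrs <- c(rrs, w[pick])
    current <- nb[pick]
  }
  structure(list(codes = path, rr = rrs,
                 reached = if (is.null(target)) NA else current == target),
            class = "trajectory_path")
}

#' @export
print.trajectory_path <- function(x, ...) {
  cat("Greedy max-RR path:", paste(x$codes, collapse = " -> "), "\n")
  if (length(x$rr))
    cat("  step RRs:", paste(sprintf("%.2f", x$rr), collapse = ", "), "\n")
  if (!is.na(x$reached)) cat("  target reached:", x$reached, "\n")
  invisible(x)
}

#' Render an ego view or trajectory as a DOT subgraph
#'
#' @param x an `"ego_view"` or `"trajectory_path"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dot_view <- function(x, path) {
  lines <- "digraph comorbidity {"
  if (inherits(x, "ego_view")) {
    for (i in seq_len(nrow(x$table))) {
      e <- if (x$direction == "successors")
        sprintf('  "%s" -> "%s" [label="%.2f"];', x$focal, x$table$code3[i],
                x$table$rr[i])
      else
        sprintf('  "%s" -> "%s" [label="%.2f"];', x$table$code3[i], x$focal,
                x$table$rr[i])
      lines <- c(lines, e)
    }
  } else if (inherits(x, "trajectory_path")) {
    if (length(x$codes) > 1)
      lines <- c(lines, sprintf('  "%s" -> "%s" [label="%.2f"];',
                                x$codes[-length(x$codes)], x$codes[-1], x$rr))
  } else stop("x must be an ego_view or trajectory_path")
  writeLines(c(lines, "}"), path)
  invisible(path)
}
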