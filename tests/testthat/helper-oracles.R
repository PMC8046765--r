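# Independent brute-force oracles and random fixture generators.
# These re-derive every quantity from first principles (loops, dense linear
# algebra, exhaustive enumeration) and never call the code paths they check.

# ---- random fixtures -------------------------------------------------------

random_micro_cohort <- function(seed) {
  set.seed(seed)
  np <- sample(2:12, 1)
  nc <- sample(2:4, 1)
  patients <- paste0("p", seq_len(np))
  codes <- paste0("c", seq_len(nc))
  rows <- list()
  for (p in patients) {
    k <- sample(0:6, 1)
    if (k > 0)
      rows[[p]] <- data.frame(
        patient_id = p,
        code3 = sample(codes, k, replace = TRUE),
        event_date = as.Date("2000-01-01") + sample(0:400, k, replace = TRUE),
        stringsAsFactors = FALSE)
  }
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), code3 = character(),
               event_date = as.Date(character()))
  rownames(events) <- NULL
  list(events = events, patients = patients, codes = codes)
}

random_rr_graph <- function(n, p_edge = 0.3, allow_edgeless = FALSE) {
  repeat {
    A <- matrix(runif(n * n) < p_edge, n, n)
    diag(A) <- FALSE
    if (any(A) || allow_edgeless) break
  }
  el <- which(A, arr.ind = TRUE)
  edges <- if (nrow(el)) data.frame(from = paste0("c", el[, 1]),
                                    to = paste0("c", el[, 2]),
                                    rr = round(1 + runif(nrow(el)) * 4, 3))
  else data.frame(from = character(), to = character(), rr = numeric())
  igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = paste0("c", seq_len(n))))
}

# ---- relative-risk oracle --------------------------------------------------

# Loops over patients and re-derives the six categories from raw event rows.
brute_pair_counts <- function(events, code_i, code_j, patients) {
  cnt <- c(n_i_then_j = 0, n_i_never_j = 0, n_j_then_i = 0,
           n_j_never_i = 0, n_neither = 0, n_coincident = 0)
  for (p in patients) {
    ev <- events[events$patient_id == p, , drop = FALSE]
    si <- ev$event_date[ev$code3 == code_i]
    sj <- ev$event_date[ev$code3 == code_j]
    di <- if (length(si)) min(si) else NA
    dj <- if (length(sj)) min(sj) else NA
    key <- if (is.na(di) && is.na(dj)) "n_neither"
    else if (!is.na(di) && is.na(dj)) "n_i_never_j"
    else if (is.na(di) && !is.na(dj)) "n_j_never_i"
    else if (di < dj) "n_i_then_j"
    else if (dj < di) "n_j_then_i"
    else "n_coincident"
    cnt[key] <- cnt[key] + 1
  }
  cnt
}

brute_rr_value <- function(cnt) {
  f1_den <- cnt[["n_i_then_j"]] + cnt[["n_i_never_j"]]
  if (f1_den == 0) return(NA_real_)
  f1 <- cnt[["n_i_then_j"]] / f1_den
  f2_num <- cnt[["n_j_never_i"]] + cnt[["n_j_then_i"]]
  f2_den <- f2_num + cnt[["n_neither"]]
  if (f2_num == 0) return(if (f1 > 0) Inf else NA_real_)
  f1 / (f2_num / f2_den)
}

brute_rr_matrix <- function(events, codes, patients) {
  n <- length(codes)
  rr <- matrix(NA_real_, n, n, dimnames = list(codes, codes))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    rr[i, j] <- brute_rr_value(brute_pair_counts(events, codes[i], codes[j],
                                                 patients))
  }
  rr
}

# ---- graph-statistic oracles ----------------------------------------------

brute_density <- function(g) {
  el <- igraph::as_edgelist(g)
  n <- igraph::gorder(g)
  nrow(el) / (n * (n - 1))
}

brute_reciprocity <- function(g) {
  el <- igraph::as_edgelist(g)
  hit <- 0
  for (k in seq_len(nrow(el)))
    if (any(el[, 1] == el[k, 2] & el[, 2] == el[k, 1])) hit <- hit + 1
  hit / nrow(el)
}

# Floyd-Warshall on the unweighted directed graph.
brute_diameter <- function(g) {
  n <- igraph::gorder(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(g, names = FALSE)
  D[el] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  max(D[is.finite(D)])
}

# Dense eigendecomposition oracle for HITS (scaled so max = 1).
brute_hits <- function(g, use_weights = TRUE) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (use_weights) "rr" else NULL, sparse = TRUE))
  a <- abs(eigen(t(A) %*% A, symmetric = TRUE)$vectors[, 1])
  h <- abs(eigen(A %*% t(A), symmetric = TRUE)$vectors[, 1])
  list(hub = setNames(h / max(h), rownames(A)),
       authority = setNames(a / max(a), rownames(A)))
}

# Direct linear solve of the PageRank equations.
brute_pagerank <- function(g, damping = 0.85, use_weights = TRUE) {
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (use_weights) "rr" else NULL, sparse = TRUE))
  n <- nrow(A)
  rs <- rowSums(A)
  M <- A / ifelse(rs > 0, rs, 1)
  M[rs == 0, ] <- 1 / n
  p <- solve(diag(n) - damping * t(M), rep((1 - damping) / n, n))
  setNames(p / sum(p), rownames(A))
}

# ---- partition enumeration -------------------------------------------------

all_set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_set_partitions(n - 1))
    for (m in seq_len(max(p) + 1L))
      out[[length(out) + 1L]] <- c(p, m)
  out
}

# Minimum two-level codelength over all partitions of the node set, using the
# package's codelength evaluation (the enumeration validates the search).
exhaustive_min_codelength <- function(g, tau = 0.15) {
  fl <- comorbidnet:::.flow_setup(g, tau, use_weights = TRUE)
  min(vapply(all_set_partitions(igraph::gorder(g)),
             function(p) comorbidnet:::.partition_codelength(fl, p),
             numeric(1)))
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Two directed 4-cliques joined by one edge each way.
two_clique_graph <- function(w_in = 3, w_cross = 1.5) {
  nodes <- paste0("c", 1:8)
  blk <- list(1:4, 5:8)
  edges <- NULL
  for (b in blk) for (i in b) for (j in b) if (i != j)
    edges <- rbind(edges, data.frame(from = nodes[i], to = nodes[j],
                                     rr = w_in * (1 + runif(1) / 10)))
  edges <- rbind(edges,
                 data.frame(from = "c1", to = "c5", rr = w_cross),
                 data.frame(from = "c5", to = "c1", rr = w_cross))
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

# Small simulated cohort run through the preprocessing front end.
sim_to_rr <- function(cfg, min_followup = 5) {
  res <- simulate_cohort(cfg)
  coll <- collapse_events(res$events)
  fu <- filter_followup(coll$events, min_followup)
  fo <- first_occurrences(fu$events)
  diag_codes <- network_exclusions(sort(unique(fo$code3)))
  codes <- prevalence_filter(fo[fo$code3 %in% diag_codes, , drop = FALSE],
                             length(fu$patients))
  list(rrm = rr_matrix(fo, codes, fu$patients), truth = res$truth,
       fo = fo, patients = fu$patients, codes = codes)
}
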