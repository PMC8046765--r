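#' Two-level map equation codelength of a partition
#'
#' The expected per-step description length, in bits, of a random walk on the
#' graph encoded with a two-level codebook (one index codebook across
#' modules, one codebook per module):
#' \deqn{L(M) = q_\curvearrowleft H(Q) + \sum_m p_m^\circlearrowright H(P_m)}
#' Node visit rates are the PageRank stationary distribution with damping
#' `1 - tau` (uniform teleportation, dangling nodes uniform). Module exit
#' rates use recorded teleportation:
#' `q_m = sum over a in m of p_a * (tau * (n - n_m)/n + (1 - tau) * P(a -> outside m))`,
#' with transition probabilities proportional to edge weights when
#' `use_weights` is set. Logarithms are base 2 and `0 log 0 = 0`.
#'
#' @param g a directed igraph.
#' @param membership integer community labels, one per node, either named by
#'   node name or in vertex order.
#' @param tau teleportation probability in `[0, 1)` (default 0.15).
#' @param use_weights use edge `rr` weights for transitions.
#' @return codelength in bits (nonnegative scalar).
#' @export
map_equation <- function(g, membership, tau = 0.15, use_weights = TRUE) {
  fl <- .flow_setup(g, tau, use_weights)
  memb <- .check_membership(g, membership)
  .partition_codelength(fl, memb)
}

.check_membership <- function(g, membership) {
  nms <- igraph::V(g)$name
  if (!is.null(names(membership))) {
    if (!all(nms %in% names(membership)))
      stop("membership does not label every node")
    membership <- membership[nms]
  }
  if (length(membership) != length(nms) || anyNA(membership))
    stop("membership must label every node exactly once")
  as.integer(factor(membership))
}

# Precompute flow quantities shared by all codelength evaluations:
# visit rates p, row-stochastic transition matrix Tm (dangling rows uniform).
.flow_setup <- function(g, tau, use_weights) {
  n <- igraph::gorder(g)
  if (n < 1) stop("empty graph")
  if (tau < 0 || tau >= 1) stop("tau must lie in [0, 1)")
  A <- .adjacency(g, use_weights)
  rs <- rowSums(A)
  Tm <- A / ifelse(rs > 0, rs, 1)
  Tm[rs == 0, ] <- 1 / n
  p <- pagerank_centrality(g, damping = 1 - tau, use_weights = use_weights)
  list(n = n, p = unname(p), Tm = Tm, tau = tau,
       sum_plogp_nodes = sum(.xlogx(unname(p))), names = igraph::V(g)$name)
}

.xlogx <- function(x) ifelse(x > 0, x * log2(x), 0)

# Exit rate of one module given its member indices.
.module_exit <- function(fl, idx) {
  n_m <- length(idx)
  if (n_m == 0L) return(0)
  inside <- rowSums(fl$Tm[idx, idx, drop = FALSE])
  sum(fl$p[idx] * (fl$tau * (fl$n - n_m) / fl$n + (1 - fl$tau) * (1 - inside)))
}

# Codelength from per-module aggregates (q = exit rates, pm = visit-rate
# sums, both over nonempty modules).
.codelength_from_terms <- function(fl, q, pm) {
  q_tot <- sum(q)
  .xlogx(q_tot) - 2 * sum(.xlogx(q)) - fl$sum_plogp_nodes +
    sum(.xlogx(q + pm))
}

.partition_codelength <- function(fl, memb) {
  mods <- split(seq_len(fl$n), memb)
  q <- vapply(mods, function(idx) .module_exit(fl, idx), numeric(1))
  pm <- vapply(mods, function(idx) sum(fl$p[idx]), numeric(1))
  .codelength_from_terms(fl, q, pm)
}

#' Map-equation community detection with multi-restart search
#'
#' Minimises the two-level [map_equation()] codelength over partitions.
#' Each of the `n_runs` seeded restarts starts from singleton modules and
#' repeatedly sweeps the nodes in random order, moving each node to the
#' neighbouring (or a fresh) module that most decreases the codelength, until
#' a full sweep makes no move; module-merge passes follow. The candidate set
#' also always contains the all-in-one partition, so the returned codelength
#' never exceeds that of the singleton or the one-module partition. Ties are
#' broken towards fewer modules, then lexicographically smaller canonical
#' labels.
#'
#' @param g a directed igraph with at least one node.
#' @param n_runs number of restarts (default 100).
#' @param seed integer seed; restarts are seeded deterministically from it.
#' @param tau teleportation probability (default 0.15).
#' @param use_weights use edge `rr` weights.
#' @return object of class `"rr_partition"`: list with `membership`
#'   (named integer vector with dense labels), `codelength` (bits),
#'   `n_modules`, and the search settings.
#' @export
detect_communities <- function(g, n_runs = 100L, seed = 1L, tau = 0.15,
                               use_weights = TRUE) {
  if (n_runs < 1) stop("n_runs must be at least 1")
  fl <- .flow_setup(g, tau, use_weights)
  n <- fl$n

  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  run_seeds <- as.integer(floor(runif(n_runs) * 2147483646)) + 1L

  # candidate-move neighbourhood: modules of out- and in-neighbours
  nbr <- lapply(seq_len(n), function(v) {
    unique(c(as.integer(igraph::neighbors(g, v, mode = "out")),
             as.integer(igraph::neighbors(g, v, mode = "in"))))
  })

  best <- NULL
  consider <- function(memb, L) {
    cand <- list(membership = .canonical_labels(memb), codelength = L)
    if (is.null(best)) { best <<- cand; return(invisible()) }
    dL <- L - best$codelength
    if (dL < -1e-12) best <<- cand
    else if (abs(dL) <= 1e-12) {
      k_new <- max(cand$membership); k_old <- max(best$membership)
      if (k_new < k_old ||
          (k_new == k_old && .lex_less(cand$membership, best$membership)))
        best <<- cand
    }
    invisible()
  }

  # always-available candidates
  consider(rep(1L, n), .partition_codelength(fl, rep(1L, n)))
  consider(seq_len(n), .partition_codelength(fl, seq_len(n)))

  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    res <- .one_run(fl, nbr)
    consider(res$memb, res$L)
  }

  structure(list(
    membership = setNames(best$membership, fl$names),
    codelength = best$codelength,
    n_modules = max(best$membership),
    n_runs = n_runs, tau = tau, use_weights = use_weights, seed = seed
  ), class = "rr_partition")
}

#' @export
print.rr_partition <- function(x, ...) {
  cat(sprintf("Map-equation partition: %d modules, codelength %.4f bits (%d runs)\n",
              x$n_modules, x$codelength, x$n_runs))
  print(table(module = x$membership))
  invisible(x)
}

.canonical_labels <- function(memb) {
  as.integer(factor(memb, levels = unique(memb)))
}

.lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

# One local-moving + merge restart. Maintains per-module aggregates so a
# candidate move only recomputes the exit rates of the two affected modules.
.one_run <- function(fl, nbr) {
  n <- fl$n
  memb <- seq_len(n)
  members <- as.list(seq_len(n))
  q <- vapply(members, function(idx) .module_exit(fl, idx), numeric(1))
  pm <- fl$p
  L <- .codelength_from_terms(fl, q, pm)

  recompute <- function() {
    active <- lengths(members) > 0
    .codelength_from_terms(fl, q[active], pm[active])
  }

  repeat {
    moved <- FALSE
    for (v in sample.int(n)) {
      cur <- memb[v]
      cand_mods <- setdiff(unique(memb[nbr[[v]]]), cur)
      if (length(members[[cur]]) > 1L) {
        free <- which(lengths(members) == 0L)
        cand_mods <- c(cand_mods,
                       if (length(free)) free[1] else length(members) + 1L)
      }
      if (!length(cand_mods)) next
      src_new <- setdiff(members[[cur]], v)
      q_src <- .module_exit(fl, src_new)
      pm_src <- pm[cur] - fl$p[v]
      best_L <- L; best_m <- cur
      for (m in cand_mods) {
        dst_new <- c(if (m <= length(members)) members[[m]] else integer(), v)
        q_dst <- .module_exit(fl, dst_new)
        pm_dst <- (if (m <= length(members)) pm[m] else 0) + fl$p[v]
        q2 <- q; pm2 <- pm
        if (m > length(q2)) { q2 <- c(q2, 0); pm2 <- c(pm2, 0) }
        q2[cur] <- q_src; pm2[cur] <- pm_src
        q2[m] <- q_dst; pm2[m] <- pm_dst
        keep <- pm2 > 0 | seq_along(pm2) %in% c(cur, m)
        keep[cur] <- length(src_new) > 0
        keep[m] <- TRUE
        L_try <- .codelength_from_terms(fl, q2[keep], pm2[keep])
        if (L_try < best_L - 1e-12) { best_L <- L_try; best_m <- m }
      }
      if (best_m != cur) {
        if (best_m > length(members)) {
          members[[best_m]] <- integer()
          q <- c(q, 0); pm <- c(pm, 0)
        }
        members[[cur]] <- src_new
        members[[best_m]] <- c(members[[best_m]], v)
        memb[v] <- best_m
        q[cur] <- q_src
        pm[cur] <- if (length(src_new)) pm[cur] - fl$p[v] else 0
        q[best_m] <- .module_exit(fl, members[[best_m]])
        pm[best_m] <- pm[best_m] + fl$p[v]
        L <- recompute()
        moved <- TRUE
      }
    }
    if (!moved) break
  }

  # merge passes
  repeat {
    active <- which(lengths(members) > 0)
    if (length(active) < 2) break
    best_L <- L; best_pair <- NULL; best_q <- NA_real_
    for (ai in seq_along(active)[-length(active)]) {
      for (bi in (ai + 1):length(active)) {
        a <- active[ai]; b <- active[bi]
        un <- c(members[[a]], members[[b]])
        q_ab <- .module_exit(fl, un)
        sel <- setdiff(active, c(a, b))
        L_try <- .codelength_from_terms(
          fl, c(q[sel], q_ab), c(pm[sel], pm[a] + pm[b]))
        if (L_try < best_L - 1e-12) {
          best_L <- L_try; best_pair <- c(a, b); best_q <- q_ab
        }
      }
    }
    if (is.null(best_pair)) break
    a <- best_pair[1]; b <- best_pair[2]
    members[[a]] <- c(members[[a]], members[[b]])
    members[[b]] <- integer()
    memb[memb == b] <- a
    q[a] <- best_q; q[b] <- 0
    pm[a] <- pm[a] + pm[b]; pm[b] <- 0
    L <- best_L
  }

  list(memb = memb, L = L)
}
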