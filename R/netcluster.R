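# Thresholded sequence-similarity network over merged candidates,
# community resolution by (weighted) modularity optimization, and
# seed-anchored community selection.  The Louvain implementation is the
# package's own: deterministic under a seed, with the returned Q always
# equal to an independent recomputation of the modularity formula.

#' Build a similarity network over candidate sequences
#'
#' Nodes are candidate ids; an undirected edge joins two candidates when
#' the percent identity of their optimal local alignment is strictly
#' above `threshold_pct` (the edge weight is that percent identity).
#' Isolated nodes are retained.
#'
#' @param candidates a [seq_set()].
#' @param scheme a [scoring_scheme()].
#' @param threshold_pct strict lower bound on percent identity.
#' @param weighted keep percent identity as the edge weight (otherwise
#'   all retained edges weigh 1).
#' @return object of class `sim_graph`: `nodes`, `edges` (data frame
#'   `u`, `v`, `w`), `threshold`, `m` (total edge weight).
#' @export
build_similarity_graph <- function(candidates, scheme = scoring_scheme(),
                                   threshold_pct = 20, weighted = TRUE) {
  stopifnot(inherits(candidates, "seq_set"), nrow(candidates) >= 1L)
  n <- nrow(candidates)
  edges <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      al <- local_align(candidates[i, , drop = FALSE],
                        candidates[j, , drop = FALSE], scheme)
      if (al$pct_identity > threshold_pct) {
        edges[[length(edges) + 1L]] <- data.frame(
          u = candidates$id[i], v = candidates$id[j],
          w = if (weighted) al$pct_identity else 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(u = character(), v = character(), w = numeric(),
               stringsAsFactors = FALSE)
  sim_graph(candidates$id, edges, threshold = threshold_pct)
}

#' Construct a similarity graph from an edge list
#'
#' @param nodes character vector of node ids.
#' @param edges data frame `u`, `v`, `w` (undirected, no self-loops).
#' @param threshold threshold recorded for provenance.
#' @return a `sim_graph`.
#' @export
sim_graph <- function(nodes, edges, threshold = NA_real_) {
  nodes <- as.character(nodes)
  stopifnot(!anyDuplicated(nodes))
  if (nrow(edges)) {
    stopifnot(all(edges$u %in% nodes), all(edges$v %in% nodes))
    if (any(edges$u == edges$v)) stop("self-loops are not allowed")
    if (any(edges$w <= 0)) stop("edge weights must be positive")
    key <- paste(pmin(edges$u, edges$v), pmax(edges$u, edges$v))
    if (anyDuplicated(key)) stop("duplicate edges")
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold,
                 m = sum(edges$w)),
            class = "sim_graph")
}

#' @export
print.sim_graph <- function(x, ...) {
  cat("sim_graph: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (total weight ", format(x$m), ")\n", sep = "")
  invisible(x)
}

# weighted degree (strength) per node
graph_strength <- function(graph) {
  k <- stats::setNames(rep(0, length(graph$nodes)), graph$nodes)
  if (nrow(graph$edges)) {
    for (i in seq_len(nrow(graph$edges))) {
      e <- graph$edges[i, ]
      k[e$u] <- k[e$u] + e$w
      k[e$v] <- k[e$v] + e$w
    }
  }
  k
}

#' Weighted modularity of a partition
#'
#' `Q = sum_c [ Sigma_in,c / (2m) - (Sigma_tot,c / (2m))^2 ]` where
#' `Sigma_in,c` is twice the intra-community edge weight and
#' `Sigma_tot,c` the weighted degree sum of community `c`.  An edgeless
#' graph has `Q = 0` by convention.
#'
#' @param graph a `sim_graph`.
#' @param membership named vector (all nodes) of community labels.
#' @param resolution resolution parameter multiplying the null term.
#' @return numeric scalar in `[-0.5, 1]`.
#' @export
modularity_q <- function(graph, membership, resolution = 1) {
  miss <- setdiff(graph$nodes, names(membership))
  if (length(miss))
    stop("partition does not cover node(s): ", paste(miss, collapse = ", "))
  m <- graph$m
  if (m == 0) return(0)
  comm <- as.character(membership[graph$nodes])
  sig_in <- tapply(rep(0, length(graph$nodes)), comm, sum)
  if (nrow(graph$edges)) {
    same <- membership[graph$edges$u] == membership[graph$edges$v]
    intra <- tapply(graph$edges$w[same],
                    as.character(membership[graph$edges$u[same]]), sum)
    sig_in[names(intra)] <- 2 * intra
  }
  k <- graph_strength(graph)
  sig_tot <- tapply(k, comm, sum)
  sum(sig_in[names(sig_tot)] / (2 * m) -
        resolution * (sig_tot / (2 * m))^2)
}

#' Louvain community detection
#'
#' Standard two-phase modularity optimization: greedy local moves in a
#' seeded-shuffled node order until no move improves Q, then community
#' aggregation, repeated until the Q gain drops below `1e-12`.
#' Deterministic under a fixed seed.  The reported `q` equals
#' [modularity_q()] of the returned membership exactly.
#'
#' @param graph a `sim_graph`.
#' @param rng_seed integer seed for the node-order shuffle.
#' @param resolution resolution parameter (1 = plain modularity).
#' @return object of class `graph_partition`: `membership` (named
#'   integer vector over the original nodes), `q`, and `q_history` (Q
#'   after each local-move/aggregation pass; non-decreasing).
#' @export
louvain <- function(graph, rng_seed = 1L, resolution = 1) {
  stopifnot(inherits(graph, "sim_graph"), length(graph$nodes) >= 1L)
  nodes <- graph$nodes
  if (!nrow(graph$edges) || graph$m == 0) {
    memb <- stats::setNames(seq_along(nodes), nodes)
    return(structure(list(membership = memb, q = 0),
                     class = "graph_partition"))
  }
  withr::with_seed(as.integer(rng_seed), {
    # current (possibly aggregated) graph state
    cur_n <- length(nodes)
    cur_edges <- data.frame(u = match(graph$edges$u, nodes),
                            v = match(graph$edges$v, nodes),
                            w = graph$edges$w)
    node_map <- seq_len(cur_n)  # original node -> current super-node
    m2 <- 2 * graph$m
    q_prev <- -Inf
    q_history <- numeric(0)
    repeat {
      res <- louvain_one_level(cur_n, cur_edges, m2, resolution)
      # map original nodes through this level's assignment
      node_map <- res$comm[node_map]
      q_now <- modularity_q(graph,
                            stats::setNames(node_map, nodes), resolution)
      q_history <- c(q_history, q_now)
      if (q_now - q_prev < 1e-12) break
      q_prev <- q_now
      # aggregate: community labels become the next level's super-nodes
      agg <- aggregate_communities(res$comm, cur_edges)
      node_map <- match(node_map, agg$labs)
      cur_n <- agg$n
      cur_edges <- agg$edges
      if (cur_n == 1L) break
    }
    memb <- stats::setNames(match(node_map, sort(unique(node_map))), nodes)
    structure(list(membership = memb,
                   q = modularity_q(graph, memb, resolution),
                   q_history = q_history),
              class = "graph_partition")
  })
}

# one local-move phase on an integer-labelled multigraph with self-loops
# (self-loop weight counts fully towards Sigma_in)
louvain_one_level <- function(n, edges, m2, resolution) {
  # adjacency lists
  adj <- vector("list", n)
  self_w <- rep(0, n)
  k <- rep(0, n)
  for (i in seq_len(nrow(edges))) {
    u <- edges$u[i]; v <- edges$v[i]; w <- edges$w[i]
    if (u == v) {
      self_w[u] <- self_w[u] + w
      k[u] <- k[u] + 2 * w
    } else {
      adj[[u]] <- rbind(adj[[u]], c(v, w))
      adj[[v]] <- rbind(adj[[v]], c(u, w))
      k[u] <- k[u] + w; k[v] <- k[v] + w
    }
  }
  comm <- seq_len(n)
  sig_tot <- k
  improved <- TRUE
  order_nodes <- sample.int(n)
  while (improved) {
    improved <- FALSE
    for (u in order_nodes) {
      cu <- comm[u]
      # weights from u to each neighbouring community
      w_to <- numeric(0)
      if (!is.null(adj[[u]])) {
        nb_comm <- comm[adj[[u]][, 1]]
        w_to <- tapply(adj[[u]][, 2], nb_comm, sum)
      }
      w_cu <- if (as.character(cu) %in% names(w_to))
        w_to[[as.character(cu)]] else 0
      sig_tot[cu] <- sig_tot[cu] - k[u]
      best_c <- cu; best_gain <- 0
      cand <- unique(c(names(w_to)))
      m <- m2 / 2
      for (cc in cand) {
        c_int <- as.integer(cc)
        if (c_int == cu) next
        # delta-Q of moving u from cu (already excluded from sig_tot) to c
        gain <- (w_to[[cc]] - w_cu) / m -
          resolution * k[u] * (sig_tot[c_int] - sig_tot[cu]) / (2 * m * m)
        if (gain > best_gain + 1e-15) { best_gain <- gain; best_c <- c_int }
      }
      sig_tot[best_c] <- sig_tot[best_c] + k[u]
      if (best_c != cu) { comm[u] <- best_c; improved <- TRUE }
    }
  }
  list(comm = comm)
}

aggregate_communities <- function(comm, edges) {
  labs <- sort(unique(comm))
  relabel <- match(comm, labs)   # old node -> new super-node
  eu <- relabel[edges$u]; ev <- relabel[edges$v]
  a <- pmin(eu, ev); b <- pmax(eu, ev)
  key <- paste(a, b)
  agg_w <- tapply(edges$w, key, sum)
  parts <- do.call(rbind, strsplit(names(agg_w), " ", fixed = TRUE))
  new_edges <- data.frame(u = as.integer(parts[, 1]),
                          v = as.integer(parts[, 2]),
                          w = as.numeric(agg_w))
  list(n = length(labs), edges = new_edges, labs = labs)
}

#' Select the communities containing seed sequences
#'
#' Returns the union of all communities holding at least one seed;
#' seeds absent from the graph are reported and ignored, and it is an
#' error for no seed to be present at all.
#'
#' @param graph the `sim_graph` that was clustered.
#' @param partition a [louvain()] result (or any named membership).
#' @param seed_ids character vector of seed node ids.
#' @return character vector of selected node ids (including the seeds).
#' @export
select_seed_communities <- function(graph, partition, seed_ids) {
  memb <- if (inherits(partition, "graph_partition"))
    partition$membership else partition
  present <- intersect(seed_ids, names(memb))
  absent <- setdiff(seed_ids, names(memb))
  if (length(absent))
    message("seed(s) not in graph, ignored: ", paste(absent, collapse = ", "))
  if (!length(present))
    stop("no seed sequence present in the graph: empty family")
  target <- unique(memb[present])
  names(memb)[memb %in% target]
}

#' Write / read a graph as an edge-list TSV
#' @param graph a `sim_graph`.
#' @param path output file.
#' @export
write_graph_tsv <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
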