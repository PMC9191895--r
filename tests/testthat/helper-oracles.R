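# Independent oracles and shared fixtures for the test suite.  Oracles are
# deliberately written with different algorithms/data structures than the
# package code they check.

# plain-R affine-gap Smith-Waterman score (three dense matrices, no
# traceback) -- the reference DP for the compiled aligner
ref_sw_score <- function(a, b, S, gap_open, gap_ext) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open, X[i, j + 1] + gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open, Y[i + 1, j] + gap_ext)
      diagbest <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- max(0, diagbest + S[av[i], bv[j]])
      if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  best
}

random_protein <- function(n, pool = setdiff(pepfam::AA_ALPHABET, "X")) {
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

# all set partitions of n elements as membership vectors (restricted
# growth strings)
set_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxc) {
    if (length(assign) == n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (c in seq_len(maxc + 1L)) rec(c(assign, c), max(maxc, c))
  }
  rec(integer(0), 0L)
  out
}

# fast weighted modularity for brute-force search:
# Q = intra/m - sum_c (tot_c / 2m)^2
fast_q <- function(strength, eu, ev, w, memb) {
  m <- sum(w)
  intra <- sum(w[memb[eu] == memb[ev]])
  tot <- tapply(strength, memb, sum)
  intra / m - sum((tot / (2 * m))^2)
}

brute_force_best_q <- function(graph) {
  n <- length(graph$nodes)
  eu <- match(graph$edges$u, graph$nodes)
  ev <- match(graph$edges$v, graph$nodes)
  w <- graph$edges$w
  strength <- rep(0, n)
  for (i in seq_along(w)) {
    strength[eu[i]] <- strength[eu[i]] + w[i]
    strength[ev[i]] <- strength[ev[i]] + w[i]
  }
  best <- -Inf
  for (p in set_partitions(n)) {
    q <- fast_q(strength, eu, ev, w, p)
    if (q > best) best <- q
  }
  best
}

# regex oracle for the cysteine-spacing motif (lookahead for overlaps)
cys_regex_oracle <- function(s, min_gap = 9, max_gap = 11) {
  grepl(sprintf("C(?=[^C]{%d,%d}C)", min_gap, max_gap), s, perl = TRUE)
}

# graph helpers
two_triangles_graph <- function() {
  sim_graph(letters[1:6],
            data.frame(u = c("a", "b", "c", "d", "e", "f"),
                       v = c("b", "c", "a", "e", "f", "d"),
                       w = 1, stringsAsFactors = FALSE))
}

k_cliques_graph <- function(k, size = 4) {
  nodes <- paste0("n", seq_len(k * size))
  ed <- list()
  for (c in seq_len(k)) {
    idx <- ((c - 1) * size + 1):(c * size)
    for (i in idx) for (j in idx) if (i < j)
      ed[[length(ed) + 1L]] <- data.frame(u = nodes[i], v = nodes[j], w = 1,
                                          stringsAsFactors = FALSE)
  }
  sim_graph(nodes, do.call(rbind, ed))
}

# expensive shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

get_default_bench <- function() {
  if (is.null(.fixture_cache$bench))
    .fixture_cache$bench <- generate_benchmark(family_spec())
  .fixture_cache$bench
}

get_default_run <- function() {
  if (is.null(.fixture_cache$run)) {
    b <- get_default_bench()
    .fixture_cache$run <- suppressMessages(
      run_peptide_discovery(b$proteome, b$genomes, b$annotations, b$seeds,
                            b$expression))
  }
  .fixture_cache$run
}

get_small_bench <- function() {
  if (is.null(.fixture_cache$small))
    .fixture_cache$small <- generate_benchmark(
      family_spec(n_species = 3, members_per_species = 3,
                  decoys_per_species = 10, rng_seed = 11))
  .fixture_cache$small
}

get_rk_bench <- function() {
  if (is.null(.fixture_cache$rk))
    .fixture_cache$rk <- generate_rk_family(n_species = 4,
                                            members_per_species = 2,
                                            n_lrr = 12, n_decoys = 100,
                                            rng_seed = 1)
  .fixture_cache$rk
}
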