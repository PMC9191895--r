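# Distance estimation, neighbor-joining tree construction, rooting,
# age-cutoff clade extraction, bootstrap support and occupancy-trimmed
# sequence-logo matrices.  NJ on Poisson-corrected distances stands in
# for approximate-ML tree building; its exactness on additive matrices is
# the module's primary oracle.

#' Pairwise distances from a multiple alignment
#'
#' p-distance = mismatches over shared ungapped columns (pairwise
#' deletion; `X` is excluded like a gap).  The Poisson correction
#' `d = -ln(1 - p)` is capped at `cap` for saturated pairs.
#'
#' @param aln an [msa()].
#' @param model `"p"` or `"poisson"`.
#' @param cap maximum corrected distance.
#' @return object of class `dist_matrix`: symmetric matrix with zero
#'   diagonal, plus `model` and `cap` attributes.
#' @export
msa_distance <- function(aln, model = c("poisson", "p"), cap = 10) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "msa"), length(aln$id) >= 2L)
  mat <- msa_matrix(aln)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  ok <- mat != "-" & mat != "X"
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    shared <- ok[i, ] & ok[j, ]
    ns <- sum(shared)
    if (ns == 0L)
      stop("no shared ungapped columns between ", aln$id[i], " and ",
           aln$id[j])
    p <- sum(mat[i, shared] != mat[j, shared]) / ns
    d <- if (model == "p") p else {
      if (p >= 1 - exp(-cap)) cap else -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "model") <- model
  attr(D, "cap") <- cap
  class(D) <- c("dist_matrix", class(D))
  D
}

fmt_bl <- function(x) sprintf("%.17g", max(x, 0))

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration on the Q criterion
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`; ties are broken
#' by the lexicographically smallest pair of cluster representatives
#' (smallest leaf label in each cluster).  Negative branch lengths are
#' clamped to zero with the subtraction shifted to the sister branch.
#' On an additive (tree-metric) matrix the generating topology and all
#' path lengths are recovered exactly.
#'
#' @param D symmetric distance matrix with row/col names (>= 3 taxa).
#' @return an unrooted \pkg{ape} `phylo` object.
#' @export
nj_tree <- function(D) {
  D <- unclass(D)
  stopifnot(is.matrix(D), nrow(D) == ncol(D), nrow(D) >= 3L)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12)))
    stop("distance matrix must be symmetric")
  ids <- rownames(D)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(D)))
  frag <- ids          # newick fragment per active cluster
  rep_label <- ids     # lexicographic representative per cluster
  act <- seq_len(nrow(D))
  Dm <- D
  while (length(act) > 3L) {
    n <- length(act)
    r <- rowSums(Dm[act, act])
    # Q matrix over active clusters
    best <- NULL
    for (a in seq_len(n - 1L)) for (b in seq((a + 1L), n)) {
      i <- act[a]; j <- act[b]
      q <- (n - 2) * Dm[i, j] - r[a] - r[b]
      pair <- sort(c(rep_label[i], rep_label[j]))
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 &&
           (pair[1] < best$pair[1] ||
            (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
        best <- list(q = q, a = a, b = b, i = i, j = j, pair = pair)
      }
    }
    i <- best$i; j <- best$j
    dij <- Dm[i, j]
    bi <- dij / 2 + (r[best$a] - r[best$b]) / (2 * (n - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- dij; bi <- 0 }
    if (bj < 0) { bi <- dij; bj <- 0 }
    new_frag <- paste0("(", frag[i], ":", fmt_bl(bi), ",",
                       frag[j], ":", fmt_bl(bj), ")")
    # distances from the new cluster u to every other active cluster
    others <- setdiff(act, c(i, j))
    du <- (Dm[i, others] + Dm[j, others] - dij) / 2
    Dm[i, others] <- du; Dm[others, i] <- du
    frag[i] <- new_frag
    rep_label[i] <- min(rep_label[i], rep_label[j])
    act <- setdiff(act, j)
  }
  # final three clusters: three-point formulas
  i <- act[1]; j <- act[2]; k <- act[3]
  bi <- (Dm[i, j] + Dm[i, k] - Dm[j, k]) / 2
  bj <- (Dm[i, j] + Dm[j, k] - Dm[i, k]) / 2
  bk <- (Dm[i, k] + Dm[j, k] - Dm[i, j]) / 2
  nwk <- paste0("(", frag[i], ":", fmt_bl(bi), ",",
                frag[j], ":", fmt_bl(bj), ",",
                frag[k], ":", fmt_bl(bk), ");")
  ape::read.tree(text = nwk)
}

#' Root a tree on an outgroup leaf or at the midpoint
#'
#' Outgroup rooting inserts the root at the midpoint of the outgroup's
#' pendant edge, so all pairwise leaf path lengths are preserved.
#'
#' @param tree a `phylo` object.
#' @param outgroup leaf label, or `NULL` for midpoint rooting.
#' @return a rooted `phylo`.
#' @export
root_tree <- function(tree, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(outgroup)) return(phytools::midpoint.root(tree))
  tip <- which(tree$tip.label == outgroup)
  if (!length(tip)) stop("outgroup leaf '", outgroup, "' not in tree")
  pend <- which(tree$edge[, 2] == tip)
  half <- tree$edge.length[pend] / 2
  rooted <- phytools::reroot(tree, tip, position = half)
  rooted
}

node_ages <- function(tree) {
  # age of a node = maximum branch-length path to any descendant leaf
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  age <- rep(0, n_all)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    cand <- age[child] + ord$edge.length[e]
    if (cand > age[parent]) age[parent] <- cand
  }
  age
}

#' Cut a rooted tree into clades by an age cutoff
#'
#' A node's age is its maximum branch-length path to any descendant
#' leaf.  Clades are the maximal nodes of age `<= cutoff` (the node
#' qualifies, its parent does not), so every leaf belongs to exactly one
#' clade: the result is a partition of the leaf set, and raising the
#' cutoff only merges clades.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param cutoff age cutoff in branch-length units.
#' @return object of class `clade_set`: data frame `clade`, `node`,
#'   `age`, `n_members`, plus a `members` list-attribute.
#' @export
clades_by_age <- function(tree, cutoff) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("clade extraction requires a rooted tree")
  n_tip <- length(tree$tip.label)
  age <- node_ages(tree)
  root <- n_tip + 1L
  parent_of <- rep(NA_integer_, n_tip + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  qualifies <- age <= cutoff
  is_clade <- qualifies &
    (is.na(parent_of) | !qualifies[ifelse(is.na(parent_of), root, parent_of)])
  nodes <- which(is_clade)
  members <- lapply(nodes, function(nd) {
    if (nd <= n_tip) tree$tip.label[nd]
    else ape::extract.clade(tree, nd)$tip.label
  })
  out <- data.frame(clade = seq_along(nodes), node = nodes,
                    age = age[nodes],
                    n_members = lengths(members))
  attr(out, "members") <- members
  attr(out, "cutoff") <- cutoff
  class(out) <- c("clade_set", "data.frame")
  out
}

#' Bootstrap support for the internal bipartitions of an NJ tree
#'
#' Alignment columns are resampled with replacement, an NJ tree is built
#' per replicate, and support is the fraction of replicates containing
#' each internal bipartition of the reference tree (no realignment).
#'
#' @param aln an [msa()] with at least 4 rows.
#' @param n_replicates number of bootstrap replicates (>= 1).
#' @param rng_seed integer seed.
#' @param model distance model passed to [msa_distance()].
#' @return list: `tree` (reference NJ tree), `support` (numeric vector,
#'   one value per internal node of the reference tree, in `[0, 1]`).
#' @export
bootstrap_support <- function(aln, n_replicates = 100L, rng_seed = 1L,
                              model = "poisson") {
  stopifnot(inherits(aln, "msa"), n_replicates >= 1L)
  if (length(aln$id) < 4L)
    stop("bootstrap support needs >= 4 sequences (no internal edges)")
  mat <- msa_matrix(aln)
  ref <- nj_tree(msa_distance(aln, model = model))
  boots <- withr::with_seed(as.integer(rng_seed), {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
      rep_aln <- msa(aln$id, apply(mat[, cols, drop = FALSE], 1L, paste,
                                   collapse = ""))
      tryCatch(nj_tree(msa_distance(rep_aln, model = model)),
               error = function(e) NULL)
    })
  })
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(ref, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  list(tree = ref, support = counts / length(boots))
}

# drop alignment columns below the occupancy threshold (strict <)
trim_msa_occupancy <- function(aln, occupancy_min = 0.05) {
  mat <- msa_matrix(aln)
  occ <- colMeans(mat != "-")
  keep <- occ >= occupancy_min
  if (!any(keep)) stop("all columns fall below the occupancy threshold")
  msa(aln$id, apply(mat[, keep, drop = FALSE], 1L, paste, collapse = ""))
}

#' Sequence-logo matrix with occupancy trimming
#'
#' Columns seen in fewer than `occupancy_min` of the sequences (strict
#' `<`; a column at exactly the threshold is retained) are removed;
#' per-column residue frequencies are computed over non-gap residues and
#' the information content is `IC = log2(20) - H` bits.
#'
#' @param aln an [msa()].
#' @param occupancy_min occupancy threshold (default 5%).
#' @return object of class `logo_matrix`: `freq` (columns x 20), `ic`
#'   (bits, in `[0, log2 20]`), `columns` (original column indices).
#' @export
sequence_logo <- function(aln, occupancy_min = 0.05) {
  stopifnot(inherits(aln, "msa"))
  mat <- msa_matrix(aln)
  occ <- colMeans(mat != "-")
  keep <- which(occ >= occupancy_min)
  if (!length(keep)) stop("all columns trimmed: nothing to draw")
  std <- setdiff(AA_ALPHABET, "X")
  freq <- matrix(0, length(keep), 20L, dimnames = list(NULL, std))
  ic <- numeric(length(keep))
  for (k in seq_along(keep)) {
    col <- mat[, keep[k]]
    col <- col[col %in% std]
    f <- as.numeric(table(factor(col, levels = std))) / length(col)
    freq[k, ] <- f
    h <- -sum(f[f > 0] * log2(f[f > 0]))
    ic[k] <- log2(20) - h
  }
  structure(list(freq = freq, ic = ic, columns = keep,
                 occupancy_min = occupancy_min),
            class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat("logo_matrix: ", length(x$ic), " columns, mean IC ",
      sprintf("%.2f", mean(x$ic)), " bits\n", sep = "")
  invisible(x)
}

#' Write a logo matrix as TSV (column, 20 frequencies, IC)
#' @param logo a [sequence_logo()] result.
#' @param path output file.
#' @export
write_logo_tsv <- function(logo, path) {
  tab <- data.frame(column = logo$columns, logo$freq, IC = logo$ic)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
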