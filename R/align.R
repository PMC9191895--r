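# Pairwise local alignment and progressive multiple alignment.  The local
# aligner is an affine-gap Smith-Waterman (three-state DP, compiled);
# percent identity over aligned columns is the quantity thresholded when
# the similarity network is built.

# integer encoding of sequences against a fixed alphabet
encode_seq <- function(s, alphabet = AA_ALPHABET) {
  v <- match(strsplit(s, "", fixed = TRUE)[[1]], alphabet)
  if (anyNA(v)) stop("sequence contains characters outside the alphabet")
  v
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B <- e$BLOSUM62
  M <- matrix(0, 21L, 21L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  std <- setdiff(AA_ALPHABET, "X")
  M[std, std] <- B[std, std]
  # X is treated as background: contributes nothing either way
  M["X", ] <- 0; M[, "X"] <- 0
  M
}

#' Scoring scheme for protein alignment
#'
#' Defaults follow common practice for short-protein search: BLOSUM62
#' substitution scores with affine gap costs of -11 to open (first gapped
#' residue) and -1 per extension.  `X` scores 0 against everything.
#'
#' @param matrix symmetric substitution matrix over [AA_ALPHABET].
#' @param gap_open,gap_extend negative gap costs, `gap_open <= gap_extend < 0`.
#' @return an object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = blosum62_matrix(),
                           gap_open = -11, gap_extend = -1) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (!(gap_open <= gap_extend && gap_extend < 0))
    stop("need gap_open <= gap_extend < 0")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend),
            class = "scoring_scheme")
}

#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman with deterministic traceback (ties resolved
#' diagonal, then up, then left).  A best score of zero yields an empty
#' alignment.
#'
#' @param a,b sequences: character strings, or single-row [seq_set()]s.
#' @param scheme a [scoring_scheme()].
#' @return list of class `local_alignment` with fields `query`/`subject`
#'   ids, 1-based inclusive `q_range`/`s_range`, gapped `q_aln`/`s_aln`
#'   strings, raw `score` and `pct_identity` (identical columns over all
#'   alignment columns, in percent).
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  ga <- as_single_seq(a); gb <- as_single_seq(b)
  empty <- function() {
    structure(list(query = ga$id, subject = gb$id,
                   q_range = c(NA_integer_, NA_integer_),
                   s_range = c(NA_integer_, NA_integer_),
                   q_aln = "", s_aln = "", score = 0,
                   pct_identity = 0), class = "local_alignment")
  }
  if (!nzchar(ga$residues) || !nzchar(gb$residues)) return(empty())
  av <- encode_seq(ga$residues); bv <- encode_seq(gb$residues)
  r <- sw_align_cpp(av, bv, scheme$matrix, scheme$gap_open, scheme$gap_extend)
  if (r$score <= 0) return(empty())
  ach <- strsplit(ga$residues, "", fixed = TRUE)[[1]]
  bch <- strsplit(gb$residues, "", fixed = TRUE)[[1]]
  qa <- ifelse(r$a_path > 0, ach[pmax(r$a_path, 1L)], "-")
  sa <- ifelse(r$b_path > 0, bch[pmax(r$b_path, 1L)], "-")
  ident <- sum(qa == sa & qa != "-")
  structure(list(query = ga$id, subject = gb$id,
                 q_range = c(r$a_start, r$a_end),
                 s_range = c(r$b_start, r$b_end),
                 q_aln = paste(qa, collapse = ""),
                 s_aln = paste(sa, collapse = ""),
                 score = r$score,
                 pct_identity = 100 * ident / length(qa)),
            class = "local_alignment")
}

as_single_seq <- function(x) {
  if (inherits(x, "seq_set")) {
    stopifnot(nrow(x) == 1L)
    list(id = x$id, residues = x$residues)
  } else {
    list(id = "seq", residues = toupper(as.character(x)))
  }
}

#' Search a database with a set of seed sequences
#'
#' Every database sequence is locally aligned against every seed; pairs
#' reaching both the identity and the raw-score cutoff are reported.
#' This is the recruitment step of round one of the iterative search.
#'
#' @param db,seeds [seq_set()]s (protein).
#' @param scheme a [scoring_scheme()].
#' @param min_pct minimum percent identity of the local alignment.
#' @param min_score minimum raw alignment score.
#' @param max_hits optional cap on reported hits per seed (best first).
#' @return data frame: `query` (db id), `subject` (seed id), `score`,
#'   `pct_identity`, `q_start`, `q_end`, `s_start`, `s_end`.
#' @export
all_vs_seed_search <- function(db, seeds, scheme = scoring_scheme(),
                               min_pct = 20, min_score = 0,
                               max_hits = Inf) {
  stopifnot(inherits(db, "seq_set"), inherits(seeds, "seq_set"),
            nrow(db) > 0L, nrow(seeds) > 0L)
  out <- vector("list", nrow(db) * nrow(seeds))
  k <- 0L
  for (j in seq_len(nrow(seeds))) {
    rows <- list()
    for (i in seq_len(nrow(db))) {
      al <- local_align(db[i, , drop = FALSE], seeds[j, , drop = FALSE], scheme)
      if (al$score >= min_score && al$pct_identity >= min_pct &&
          al$score > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = db$id[i], subject = seeds$id[j],
          score = al$score, pct_identity = al$pct_identity,
          q_start = al$q_range[1], q_end = al$q_range[2],
          s_start = al$s_range[1], s_end = al$s_range[2],
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) {
      tab <- do.call(rbind, rows)
      tab <- tab[order(-tab$score, tab$query), , drop = FALSE]
      if (is.finite(max_hits) && nrow(tab) > max_hits)
        tab <- tab[seq_len(max_hits), , drop = FALSE]
      k <- k + 1L
      out[[k]] <- tab
    }
  }
  if (k == 0L)
    return(data.frame(query = character(), subject = character(),
                      score = numeric(), pct_identity = numeric(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  rownames(res) <- NULL
  res
}

# column frequency profile of an msa block (rows x 21), gaps contribute
# nothing so heavily gapped columns carry little weight in merging
msa_freq_profile <- function(aln_strings) {
  mat <- do.call(rbind, strsplit(aln_strings, "", fixed = TRUE))
  L <- ncol(mat)
  F <- matrix(0, L, 21L)
  n <- nrow(mat)
  for (a in seq_along(AA_ALPHABET)) {
    F[, a] <- colSums(mat == AA_ALPHABET[a]) / n
  }
  F
}

#' Progressive multiple sequence alignment
#'
#' Guide tree: UPGMA (average linkage) on pairwise p-distances derived
#' from local alignments.  Profiles are then merged leaf-to-root with
#' affine-gap profile-profile alignment (expected substitution score
#' between column frequency vectors).
#'
#' @param records a [seq_set()] of protein sequences.
#' @param scheme a [scoring_scheme()].
#' @return an [msa()] whose rows degap to the input sequences; column
#'   count is at least the longest input.
#' @export
progressive_msa <- function(records, scheme = scoring_scheme()) {
  stopifnot(inherits(records, "seq_set"), nrow(records) >= 1L)
  n <- nrow(records)
  if (n == 1L) return(msa(records$id, records$residues))
  # pairwise p-distances from local alignments
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    al <- local_align(records[i, , drop = FALSE], records[j, , drop = FALSE],
                      scheme)
    # distance: 1 - identity fraction relative to the shorter sequence, so
    # weak/no local alignment means large distance
    len <- min(nchar(records$residues[i]), nchar(records$residues[j]))
    ident <- al$pct_identity / 100 * nchar(al$q_aln)
    D[i, j] <- D[j, i] <- 1 - min(1, ident / len)
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # merge following hclust topology
  blocks <- lapply(seq_len(n), function(i)
    list(rows = i, aln = records$residues[i]))
  merged <- vector("list", nrow(hc$merge))
  get_block <- function(ref) if (ref < 0) blocks[[-ref]] else merged[[ref]]
  for (k in seq_len(nrow(hc$merge))) {
    b1 <- get_block(hc$merge[k, 1]); b2 <- get_block(hc$merge[k, 2])
    merged[[k]] <- merge_blocks(b1, b2, scheme)
  }
  final <- merged[[nrow(hc$merge)]]
  ord <- order(final$rows)
  msa(records$id[final$rows[ord]], final$aln[ord])
}

merge_blocks <- function(b1, b2, scheme) {
  F1 <- msa_freq_profile(b1$aln); F2 <- msa_freq_profile(b2$aln)
  S <- F1 %*% scheme$matrix %*% t(F2)
  r <- nw_profile_cpp(S, scheme$gap_open, scheme$gap_extend)
  splice <- function(aln, path) {
    ch <- strsplit(aln, "", fixed = TRUE)
    vapply(ch, function(v) {
      paste(ifelse(path > 0, v[pmax(path, 1L)], "-"), collapse = "")
    }, character(1))
  }
  list(rows = c(b1$rows, b2$rows),
       aln = c(splice(b1$aln, r$a_path), splice(b2$aln, r$b_path)))
}

#' Sum-of-pairs score of an alignment
#'
#' Used as an internal-consistency measure for the progressive aligner;
#' gap columns score the gap-open/extend cost against residues and zero
#' against gaps.
#'
#' @param m an [msa()].
#' @param scheme a [scoring_scheme()].
#' @return numeric scalar.
#' @export
msa_sp_score <- function(m, scheme = scoring_scheme()) {
  mat <- msa_matrix(m)
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    a <- mat[i, ]; b <- mat[j, ]
    both <- a != "-" & b != "-"
    tot <- tot + sum(scheme$matrix[cbind(a[both], b[both])])
    # affine gap runs relative to the pair
    gaprun <- function(g, other) {
      r <- rle(g & other != "-")
      sum(vapply(which(r$values), function(k) {
        scheme$gap_open + (r$lengths[k] - 1) * scheme$gap_extend
      }, numeric(1)))
    }
    tot <- tot + gaprun(a == "-", b) + gaprun(b == "-", a)
  }
  tot
}
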