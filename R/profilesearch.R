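# Position-profile construction, calibrated iterative search over
# proteomes, and six-frame genomic rescue of unannotated family members.
# The profile is a log-odds PSSM aligned to targets with affine gaps
# (profile-column deletions and target insertions); statistical
# significance comes from an extreme-value (Gumbel) fit to scores against
# residue-shuffled targets, so E = N * P(S >= s) is owned by this module
# and nothing else.

EULER_GAMMA <- 0.5772156649015329

#' Build a position profile (log-odds PSSM) from an alignment
#'
#' Per-column residue probabilities use background-weighted pseudocounts,
#' `p = (count + alpha * b) / (n + alpha)` with `n` the number of ungapped
#' residues in the column.  Columns whose occupancy (non-gap fraction)
#' falls below `min_occupancy` are dropped (match-column rule).  Log-odds
#' are base 2; `X` scores 0 everywhere.
#'
#' @param aln an [msa()].
#' @param alpha pseudocount weight (> 0).
#' @param background named background frequencies over the 20 standard
#'   residues (default uniform).
#' @param min_occupancy match-column occupancy threshold.
#' @param gap_open,gap_extend affine gap costs used when the profile is
#'   aligned to targets (bit scale).
#' @return object of class `pssm` with fields `probs` (L x 20),
#'   `logodds` (L x 21, `X` column zero), `consensus`, `alpha`,
#'   `background`, `columns` (indices of retained alignment columns) and
#'   `calib` (`NULL` until [calibrate_evalue()]).
#' @export
build_profile <- function(aln, alpha = 1, background = NULL,
                          min_occupancy = 0.5,
                          gap_open = -4, gap_extend = -1) {
  stopifnot(inherits(aln, "msa"), alpha > 0)
  std <- setdiff(AA_ALPHABET, "X")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), std)
  }
  background <- background[std]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-8)
    stop("background must be a distribution over the 20 standard residues")
  mat <- msa_matrix(aln)
  nrow_aln <- nrow(mat)
  occ <- colMeans(mat != "-")
  keep <- which(occ >= min_occupancy)
  if (!length(keep)) stop("alignment has no column above the occupancy threshold")
  L <- length(keep)
  probs <- matrix(0, L, 20L, dimnames = list(NULL, std))
  for (k in seq_len(L)) {
    col <- mat[, keep[k]]
    col <- col[col %in% std]
    n_i <- length(col)
    cnt <- table(factor(col, levels = std))
    probs[k, ] <- (as.numeric(cnt) + alpha * background) / (n_i + alpha)
  }
  logodds <- matrix(0, L, 21L, dimnames = list(NULL, AA_ALPHABET))
  logodds[, std] <- log2(sweep(probs, 2, background, "/"))
  consensus <- std[apply(probs, 1, which.max)]
  structure(list(probs = probs, logodds = logodds,
                 consensus = paste(consensus, collapse = ""),
                 alpha = alpha, background = background,
                 columns = keep, n_seq = nrow_aln,
                 gap_open = gap_open, gap_extend = gap_extend,
                 calib = NULL),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("pssm: ", nrow(x$logodds), " match columns (from ", x$n_seq,
      " sequences)\n", "consensus: ", x$consensus, "\n", sep = "")
  if (!is.null(x$calib))
    cat(sprintf("calibrated: mu = %.3f, lambda = %.4f, N = %d\n",
                x$calib$mu, x$calib$lambda, x$calib$n_db))
  invisible(x)
}

# raw best local profile-vs-sequence alignment score
profile_score <- function(profile, residues) {
  t <- encode_seq(residues)
  sw_profile_cpp(profile$logodds, t, profile$gap_open, profile$gap_extend)
}

shuffle_residues <- function(s) {
  paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Calibrate an extreme-value E-value model for a profile
#'
#' Scores the profile against residue-shuffled database sequences and
#' fits a Gumbel distribution by the method of moments
#' (`lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda` with the
#' Euler-Mascheroni constant).  E-values are then
#' `E = N * P(S >= s)` with the fitted tail and `N` the size of the
#' searched database.
#'
#' @param profile a [build_profile()] result.
#' @param db a [seq_set()] representative of the search database.
#' @param n_shuffles number of shuffled null targets (>= 100).
#' @param rng_seed integer seed (fixed seed, identical model).
#' @return object of class `evalue_model`: `mu`, `lambda`, `n_db`.
#' @export
calibrate_evalue <- function(profile, db, n_shuffles = 200L, rng_seed = 1L) {
  stopifnot(inherits(profile, "pssm"), inherits(db, "seq_set"),
            nrow(db) > 0L)
  if (n_shuffles < 100L) stop("n_shuffles must be >= 100")
  scores <- withr::with_seed(as.integer(rng_seed), {
    vapply(seq_len(n_shuffles), function(k) {
      s <- db$residues[((k - 1L) %% nrow(db)) + 1L]
      profile_score(profile, shuffle_residues(s))$score
    }, numeric(1))
  })
  sdev <- stats::sd(scores)
  if (!is.finite(sdev) || sdev == 0)
    stop("degenerate null score distribution (zero variance)")
  lambda <- pi / (sdev * sqrt(6))
  mu <- mean(scores) - EULER_GAMMA / lambda
  structure(list(mu = mu, lambda = lambda, n_db = nrow(db)),
            class = "evalue_model")
}

#' Tail probability and E-value under a calibrated model
#'
#' `evalue_pval` is `P(S >= s)` under the fitted Gumbel null;
#' `evalue` multiplies it by the database size.  Doubling `n_db`
#' doubles every E-value exactly.
#'
#' @param model an [calibrate_evalue()] result.
#' @param score numeric score(s).
#' @param n_db database size (defaults to the calibration size).
#' @return numeric vector.
#' @export
evalue_pval <- function(model, score) {
  -expm1(-exp(-model$lambda * (score - model$mu)))
}

#' @rdname evalue_pval
#' @export
evalue <- function(model, score, n_db = model$n_db) {
  n_db * evalue_pval(model, score)
}

#' Search a protein database with a profile
#'
#' Best local profile alignment per target, converted to E-values with
#' `N` = number of targets searched.  Hits at `E <= evalue_max` are
#' returned sorted by E-value (then score, then id).
#'
#' @param profile a [build_profile()] result.
#' @param db a [seq_set()] of protein targets.
#' @param model an [calibrate_evalue()] result; when `NULL` and
#'   `calibrate = TRUE` the model is fitted on the fly against `db`.
#' @param evalue_max reporting threshold.
#' @param calibrate allow on-the-fly calibration.
#' @param n_shuffles,rng_seed calibration parameters.
#' @return data frame: `target`, `species`, `t_start`, `t_end`,
#'   `p_start`, `p_end`, `score`, `evalue`, `provenance`.
#' @export
profile_search <- function(profile, db, model = NULL, evalue_max = 10,
                           calibrate = TRUE, n_shuffles = 200L,
                           rng_seed = 1L) {
  stopifnot(inherits(profile, "pssm"), inherits(db, "seq_set"))
  if (nrow(db) == 0L)
    return(data.frame(target = character(), species = character(),
                      t_start = integer(), t_end = integer(),
                      p_start = integer(), p_end = integer(),
                      score = numeric(), evalue = numeric(),
                      provenance = character(), stringsAsFactors = FALSE))
  if (is.null(model)) {
    if (!calibrate)
      stop("no E-value model supplied and on-the-fly calibration disabled")
    model <- calibrate_evalue(profile, db, n_shuffles = n_shuffles,
                              rng_seed = rng_seed)
  }
  res <- lapply(seq_len(nrow(db)), function(i) {
    r <- profile_score(profile, db$residues[i])
    data.frame(target = db$id[i], species = db$species[i],
               t_start = r$t_start, t_end = r$t_end,
               p_start = r$p_start, p_end = r$p_end,
               score = r$score, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$evalue <- evalue(model, tab$score, n_db = nrow(db))
  tab$provenance <- "protein-search"
  tab <- tab[tab$evalue <= evalue_max, , drop = FALSE]
  tab <- tab[order(tab$evalue, -tab$score, tab$target), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Iterative profile search
#'
#' Round one recruits candidates by pairwise local alignment against the
#' seeds ([all_vs_seed_search()]); each later round realigns the
#' included set, rebuilds and recalibrates the profile, re-searches the
#' database and includes new hits at `E <= inclusion_evalue`.  The
#' included set grows monotonically; iteration stops at a fixpoint (no
#' new inclusions) or after `rounds` rounds.
#'
#' @param seeds,db [seq_set()]s.
#' @param scheme a [scoring_scheme()] for round-one recruitment.
#' @param rounds maximum number of rounds (>= 1).
#' @param inclusion_evalue profile-round inclusion threshold.
#' @param min_pct,min_score round-one pairwise cutoffs.
#' @param alpha,n_shuffles,rng_seed profile and calibration parameters.
#' @return list: `included` (db subset, a [seq_set()]), `profile`
#'   (final, `NULL` when only one round ran), `hits` (hit table with an
#'   `iteration` column), `rounds_run`, `converged`.
#' @export
iterative_search <- function(seeds, db, scheme = scoring_scheme(),
                             rounds = 5L, inclusion_evalue = 1e-5,
                             min_pct = 20, min_score = 50, alpha = 1,
                             n_shuffles = 200L, rng_seed = 1L) {
  stopifnot(rounds >= 1L)
  first <- all_vs_seed_search(db, seeds, scheme, min_pct = min_pct,
                              min_score = min_score)
  included <- unique(first$query)
  hits <- if (nrow(first)) {
    data.frame(target = first$query, species =
                 db$species[match(first$query, db$id)],
               t_start = first$q_start, t_end = first$q_end,
               score = first$score, evalue = NA_real_,
               iteration = 1L, provenance = "protein-search",
               stringsAsFactors = FALSE)
  } else {
    data.frame(target = character(), species = character(),
               t_start = integer(), t_end = integer(), score = numeric(),
               evalue = numeric(), iteration = integer(),
               provenance = character(), stringsAsFactors = FALSE)
  }
  profile <- NULL
  converged <- FALSE
  r <- 1L
  while (r < rounds) {
    r <- r + 1L
    set_records <- rbind(seeds,
                         db[db$id %in% included & !db$id %in% seeds$id, ,
                            drop = FALSE])
    class(set_records) <- c("seq_set", "data.frame")
    aln <- progressive_msa(set_records, scheme)
    profile <- build_profile(aln, alpha = alpha)
    model <- calibrate_evalue(profile, db, n_shuffles = n_shuffles,
                              rng_seed = as.integer(rng_seed) + r)
    tab <- profile_search(profile, db, model,
                          evalue_max = inclusion_evalue)
    new <- setdiff(tab$target, included)
    if (nrow(tab)) {
      add <- tab[tab$target %in% new, , drop = FALSE]
      if (nrow(add)) {
        add$iteration <- r
        add <- add[, c("target", "species", "t_start", "t_end", "score",
                       "evalue", "iteration", "provenance")]
        hits <- rbind(hits, add)
      }
    }
    if (!length(new)) { converged <- TRUE; break }
    included <- c(included, new)
  }
  inc <- db[db$id %in% included, , drop = FALSE]
  class(inc) <- c("seq_set", "data.frame")
  list(included = inc, profile = profile, hits = hits,
       rounds_run = r, converged = converged || r >= rounds)
}

# ---- six-frame genomic rescue -------------------------------------------

# enumerate ATG->stop open reading frames of a single genome record in all
# six frames; aa lengths exclude the stop, genomic intervals include it
find_orfs <- function(genome_seq, min_len, max_len) {
  L <- nchar(genome_seq)
  out <- list()
  for (strand in c("+", "-")) {
    s0 <- if (strand == "+") genome_seq else revcomp_dna(genome_seq)
    for (f in 0:2) {
      sub_len <- L - f
      sub_len <- sub_len - (sub_len %% 3L)
      if (sub_len < 3L) next
      sub <- substr(s0, f + 1L, f + sub_len)
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "solve"))
      stops <- c(0L, which(strsplit(aa, "", fixed = TRUE)[[1]] == "*"))
      ch <- strsplit(aa, "", fixed = TRUE)[[1]]
      for (k in seq_len(length(stops) - 1L)) {
        seg_start <- stops[k] + 1L
        seg_stop <- stops[k + 1L]          # position of '*'
        if (seg_stop - seg_start < min_len) next
        m_pos <- seg_start - 1L + which(ch[seg_start:(seg_stop - 1L)] == "M")
        for (p in m_pos) {
          aalen <- seg_stop - p
          if (aalen < min_len || aalen > max_len) next
          pep <- substr(aa, p, seg_stop - 1L)
          if (strand == "+") {
            nt_start <- f + 3L * (p - 1L) + 1L
            nt_end <- f + 3L * seg_stop
          } else {
            nt_start <- L - (f + 3L * seg_stop) + 1L
            nt_end <- L - f - 3L * (p - 1L)
          }
          out[[length(out) + 1L]] <- data.frame(
            start = nt_start, end = nt_end, strand = strand,
            frame = f + 1L, protein = pep, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Rescue unannotated family members from genomic DNA
#'
#' Translates every genome in all six frames, extracts ATG-to-stop open
#' reading frames within the peptide length bounds, discards any ORF
#' whose genomic interval overlaps an annotated feature by one or more
#' base pairs (on either strand), and scores the survivors against the
#' family profile.  Survivors at `E <= evalue_max` are emitted as
#' de-novo protein records carrying their genomic coordinates.
#'
#' @param genomes DNA [seq_set()], one record per chromosome/scaffold
#'   (the record's `species` field is propagated).
#' @param annotations interval table ([read_intervals()] dialect);
#'   `NULL` or empty is treated as no annotation, with a warning.
#' @param profile family [build_profile()] result.
#' @param min_len,max_len ORF length bounds in residues (stop excluded).
#' @param evalue_max inclusion threshold.
#' @param n_shuffles,rng_seed calibration parameters.
#' @return list: `hits` (hit table, provenance `dna-search`, with
#'   genomic `seq_id`, `start`, `end`, `strand`, `frame`), `records`
#'   (de-novo [seq_set()], deduplicated by species and sequence).
#' @export
dna_rescue <- function(genomes, annotations, profile, min_len = 25L,
                       max_len = 300L, evalue_max = 1e-5,
                       n_shuffles = 200L, rng_seed = 1L) {
  stopifnot(inherits(genomes, "seq_set"), all(genomes$moltype == "dna"),
            inherits(profile, "pssm"))
  if (is.null(annotations) || nrow(annotations) == 0L) {
    warning("no annotation table supplied: treating all genomic ORFs as ",
            "unannotated")
    annotations <- data.frame(seq_id = character(), start = integer(),
                              end = integer(), strand = character(),
                              feature = character(), stringsAsFactors = FALSE)
  }
  orfs <- list()
  for (i in seq_len(nrow(genomes))) {
    o <- find_orfs(genomes$residues[i], min_len, max_len)
    if (nrow(o)) {
      o$seq_id <- genomes$id[i]
      o$species <- genomes$species[i]
      orfs[[length(orfs) + 1L]] <- o
    }
  }
  empty_hits <- data.frame(target = character(), species = character(),
                           seq_id = character(), start = integer(),
                           end = integer(), strand = character(),
                           frame = integer(), score = numeric(),
                           evalue = numeric(), provenance = character(),
                           stringsAsFactors = FALSE)
  empty_rec <- seq_set("x", "M")[0, ]
  if (!length(orfs)) return(list(hits = empty_hits, records = empty_rec))
  orfs <- do.call(rbind, orfs)

  # annotation masking: >= 1 bp overlap on either strand discards the ORF
  if (nrow(annotations)) {
    q <- IRanges::IRanges(orfs$start, orfs$end)
    keep <- rep(TRUE, nrow(orfs))
    for (sid in unique(orfs$seq_id)) {
      ann <- annotations[annotations$seq_id == sid, , drop = FALSE]
      rows <- which(orfs$seq_id == sid)
      if (!nrow(ann)) next
      s <- IRanges::IRanges(ann$start, ann$end)
      ov <- IRanges::overlapsAny(q[rows], s)
      keep[rows[ov]] <- FALSE
    }
    orfs <- orfs[keep, , drop = FALSE]
  }
  if (!nrow(orfs)) return(list(hits = empty_hits, records = empty_rec))

  # content-deterministic order: the calibration (and therefore every
  # E-value) depends only on the ORF sequences, not on which strand of the
  # input they were enumerated from -- this makes the rescue exactly
  # invariant under reverse-complementing a genome
  orfs <- orfs[order(orfs$species, orfs$protein, orfs$start), , drop = FALSE]
  orfs$id <- paste0(orfs$seq_id, "_", orfs$start, "_", orfs$end, "_",
                    ifelse(orfs$strand == "+", "p", "m"))
  db <- seq_set(orfs$id, orfs$protein, species = orfs$species,
                source = "denovo")
  model <- calibrate_evalue(profile, db,
                            n_shuffles = max(100L, n_shuffles),
                            rng_seed = rng_seed)
  tab <- profile_search(profile, db, model, evalue_max = evalue_max)
  if (!nrow(tab)) return(list(hits = empty_hits, records = empty_rec))
  sel <- orfs[match(tab$target, orfs$id), , drop = FALSE]
  hits <- data.frame(target = tab$target, species = sel$species,
                     seq_id = sel$seq_id, start = sel$start,
                     end = sel$end, strand = sel$strand,
                     frame = sel$frame, score = tab$score,
                     evalue = tab$evalue, provenance = "dna-search",
                     stringsAsFactors = FALSE)
  recs <- seq_set(sel$id, sel$protein, species = sel$species,
                  source = "denovo")
  dup <- duplicated(paste(recs$species, recs$residues, sep = "\r"))
  recs <- recs[!dup, , drop = FALSE]
  class(recs) <- c("seq_set", "data.frame")
  hits <- hits[!dup, , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, records = recs)
}

#' Merge protein-search and DNA-search candidates into the relaxed set
#'
#' Union keyed by (species, sequence); when the same sequence was found
#' by both routes the annotated (protein-search) record is kept.
#'
#' @param protein_records,dna_records [seq_set()]s (either may be empty).
#' @return a [candidate_set()] at stage `"relaxed"`.
#' @export
merge_candidates <- function(protein_records, dna_records) {
  all_rec <- rbind(protein_records, dna_records)
  class(all_rec) <- c("seq_set", "data.frame")
  if (nrow(all_rec)) {
    pref <- match(all_rec$source, c("annotated", "seed", "denovo", "decoy"))
    ord <- order(pref)
    all_rec <- all_rec[ord, , drop = FALSE]
    key <- paste(all_rec$species, all_rec$residues, sep = "\r")
    all_rec <- all_rec[!duplicated(key), , drop = FALSE]
    class(all_rec) <- c("seq_set", "data.frame")
  }
  candidate_set(all_rec, "relaxed")
}

#' Serialize a profile as a tab-delimited matrix
#'
#' Header comment lines record the pseudocount, background and (when
#' present) the E-value calibration, so a profile file is a complete,
#' reusable search model.
#'
#' @param profile a [build_profile()] result.
#' @param path output file.
#' @param model optional [calibrate_evalue()] result to embed.
#' @export
write_profile <- function(profile, path, model = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# alpha=", profile$alpha), con)
  writeLines(paste0("# background=",
                    paste(sprintf("%.6g", profile$background),
                          collapse = ",")), con)
  writeLines(paste0("# consensus=", profile$consensus), con)
  if (!is.null(model))
    writeLines(sprintf("# calibration mu=%.10g lambda=%.10g N=%d",
                       model$mu, model$lambda, model$n_db), con)
  tab <- as.data.frame(profile$logodds)
  utils::write.table(cbind(column = seq_len(nrow(tab)), tab), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
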