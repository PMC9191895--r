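# Length filters, the relaxed->confident cysteine-spacing refinement, and
# rule-based domain segmentation of receptor kinases (signal peptide,
# transmembrane, ectodomain, LRR repeats, kinase motifs).  The SP/TM/
# kinase/LRR callers are transparent hydropathy- and motif-rule stand-ins
# for SignalP/TMHMM/PFAM-style predictors: their thresholds are package
# constants, and no fidelity to the original predictors is claimed.

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector over [AA_ALPHABET]; `X` scores 0.
#' @export
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

SMALL_RESIDUES <- c("A", "G", "S", "C", "T", "V")

kd_values <- function(residues) {
  unname(KD_SCALE[strsplit(residues, "", fixed = TRUE)[[1]]])
}

sliding_mean <- function(x, w) {
  if (length(x) < w) return(numeric(0))
  cs <- cumsum(c(0, x))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' Candidate set: a staged family hypothesis
#'
#' @param members a [seq_set()].
#' @param stage `"relaxed"` or `"confident"`.
#' @param excluded ids removed by explicit (logged) manual exclusion.
#' @return object of class `candidate_set`.
#' @export
candidate_set <- function(members, stage = c("relaxed", "confident"),
                          excluded = character(0)) {
  stage <- match.arg(stage)
  stopifnot(inherits(members, "seq_set"))
  structure(list(stage = stage, members = members,
                 excluded = as.character(excluded)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set [", x$stage, "]: ", nrow(x$members), " members",
      if (length(x$excluded)) paste0(" (", length(x$excluded),
                                     " manually excluded)") else "",
      "\n", sep = "")
  invisible(x)
}

#' Filter sequences by length (inclusive bounds)
#'
#' Both bounds are inclusive: a 300-residue protein passes `max_len =
#' 300`, a 499-residue protein fails `min_len = 500`.
#'
#' @param records a [seq_set()].
#' @param min_len,max_len inclusive bounds.
#' @return the filtered [seq_set()].
#' @export
length_filter <- function(records, min_len = 1L, max_len = Inf) {
  stopifnot(inherits(records, "seq_set"))
  if (min_len > max_len) stop("min_len must be <= max_len")
  n <- nchar(records$residues)
  out <- records[n >= min_len & n <= max_len, , drop = FALSE]
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Cysteine-spacing motif predicate
#'
#' TRUE when the sequence contains two cysteines separated by
#' `min_gap`..`max_gap` non-cysteine residues (the C-x(9-11)-C family
#' motif; equivalently, a pair of consecutive cysteines in the C-position
#' list whose index difference minus one lies in the gap range).  Setting
#' `count_intervening_cys = TRUE` switches to pure index spacing, where
#' further cysteines may fall between the pair.
#'
#' @param record a 1-row [seq_set()] or a character string.
#' @param min_gap,max_gap inclusive bounds on the number of residues
#'   strictly between the two cysteines.
#' @param count_intervening_cys alternative spacing semantics (see above).
#' @return logical scalar.
#' @export
cysteine_spacing_filter <- function(record, min_gap = 9L, max_gap = 11L,
                                    count_intervening_cys = FALSE) {
  s <- as_single_seq(record)$residues
  cpos <- which(strsplit(s, "", fixed = TRUE)[[1]] == "C")
  if (length(cpos) < 2L) return(FALSE)
  gaps <- if (count_intervening_cys) {
    as.vector(outer(cpos, cpos, "-")) - 1L
  } else {
    diff(cpos) - 1L
  }
  any(gaps >= min_gap & gaps <= max_gap)
}

#' Refine a relaxed candidate set to the confident set
#'
#' Keeps relaxed members passing [cysteine_spacing_filter()], then drops
#' any ids on the manual exclusion list (mirroring alignment-based visual
#' curation; exclusions are recorded in the result's provenance).
#'
#' @param relaxed a [candidate_set()] at stage `"relaxed"`.
#' @param exclusions character vector of member ids to drop; ids not in
#'   the relaxed set produce a warning and are ignored.
#' @param min_gap,max_gap cysteine spacing bounds.
#' @return a [candidate_set()] at stage `"confident"`.
#' @export
refine_confident <- function(relaxed, exclusions = character(0),
                             min_gap = 9L, max_gap = 11L) {
  stopifnot(inherits(relaxed, "candidate_set"))
  mem <- relaxed$members
  keep <- vapply(seq_len(nrow(mem)), function(i)
    cysteine_spacing_filter(mem$residues[i], min_gap, max_gap), logical(1))
  out <- mem[keep, , drop = FALSE]
  unknown <- setdiff(exclusions, out$id)
  if (length(unknown))
    warning("exclusion id(s) not in the relaxed set: ",
            paste(unknown, collapse = ", "))
  out <- out[!out$id %in% exclusions, , drop = FALSE]
  class(out) <- c("seq_set", "data.frame")
  candidate_set(out, "confident", excluded = intersect(exclusions, mem$id))
}

#' Heuristic signal-peptide prediction
#'
#' Rule-based secretion-tag call: within the first 30 residues the
#' sequence must carry at least one K/R in positions 1-5 (n-region) and
#' an 8-residue window of mean Kyte-Doolittle hydropathy >= 1.8
#' (h-region).  The cleavage site is the first position after the
#' hydrophobic core whose -3 and -1 residues are small (A, G, S, C, T,
#' V).  Returns `NULL` when any condition fails.
#'
#' @param record a 1-row [seq_set()] or character string.
#' @param max_search furthest residue considered for the cleavage site.
#' @return `NULL`, or a list with `sp_end` (last residue of the signal
#'   peptide), `core` (start of the hydrophobic window) and `score`
#'   (mean hydropathy of the core window).
#' @export
predict_signal_peptide <- function(record, max_search = 45L) {
  s <- as_single_seq(record)$residues
  if (nchar(s) < 25L) return(NULL)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!any(ch[1:5] %in% c("K", "R"))) return(NULL)
  head_len <- min(30L, length(ch))
  kd <- unname(KD_SCALE[ch[seq_len(head_len)]])
  win <- sliding_mean(kd, 8L)
  hits <- which(win >= 1.8)
  if (!length(hits)) return(NULL)
  core_start <- hits[1]
  core_end <- core_start + 7L
  upper <- min(max_search, length(ch))
  if (core_end + 2L > upper) return(NULL)
  for (p in seq(core_end + 2L, upper)) {
    if (p - 2L < 1L) next
    if (ch[p] %in% SMALL_RESIDUES && ch[p - 2L] %in% SMALL_RESIDUES) {
      return(list(sp_end = p, core = core_start,
                  score = win[core_start]))
    }
  }
  NULL
}

#' Transmembrane segmentation by hydropathy
#'
#' Sliding Kyte-Doolittle window (width 19) with mean >= 1.6 marks
#' candidate membrane spans; overlapping windows are merged and each
#' merged span is trimmed to its maximal run of positive-hydropathy
#' residues, which recovers engineered TM stretches exactly.  Non-TM
#' spans are labelled alternately, with the N-terminal side extracellular
#' (type-I receptor topology; apply after signal-peptide removal).
#'
#' @param record a 1-row [seq_set()] or character string.
#' @param window window width.
#' @param threshold mean-hydropathy cutoff.
#' @return data frame of class `domain_segmentation` with columns
#'   `segment` (`transmembrane` / `extracellular` / `intracellular`),
#'   `start`, `end` (1-based inclusive, non-overlapping, covering the
#'   sequence).
#' @export
tm_segments <- function(record, window = 19L, threshold = 1.6) {
  s <- as_single_seq(record)$residues
  n <- nchar(s)
  kd <- kd_values(s)
  win <- sliding_mean(kd, window)
  marked <- rep(FALSE, n)
  for (i in which(win >= threshold)) marked[i:(i + window - 1L)] <- TRUE
  # merge marked runs, then trim each to its positive-hydropathy core
  r <- rle(marked)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  tm <- list()
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    while (a <= b && kd[a] <= 0) a <- a + 1L
    while (b >= a && kd[b] <= 0) b <- b - 1L
    if (a <= b) tm[[length(tm) + 1L]] <- c(a, b)
  }
  segs <- list()
  side <- "extracellular"   # N-terminal side after SP removal
  pos <- 1L
  for (t in tm) {
    if (t[1] > pos)
      segs[[length(segs) + 1L]] <- data.frame(segment = side, start = pos,
                                              end = t[1] - 1L)
    segs[[length(segs) + 1L]] <- data.frame(segment = "transmembrane",
                                            start = t[1], end = t[2])
    side <- if (side == "extracellular") "intracellular" else "extracellular"
    pos <- t[2] + 1L
  }
  if (pos <= n)
    segs[[length(segs) + 1L]] <- data.frame(segment = side, start = pos,
                                            end = n)
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  class(out) <- c("domain_segmentation", "data.frame")
  out
}

#' Extract the ectodomain (longest extracellular segment)
#'
#' Applies the longest-extracellular-domain rule; ties are broken
#' N-terminal-most.  The record must already have its signal peptide
#' removed, and `segmentation` must come from [tm_segments()] on that
#' same mature sequence.
#'
#' @param record mature protein (1-row [seq_set()] or string).
#' @param segmentation a [tm_segments()] result.
#' @return a 1-row [seq_set()] with the ectodomain residues, id suffixed
#'   by the extracted range.
#' @export
extract_ectodomain <- function(record, segmentation) {
  g <- as_single_seq(record)
  ext <- segmentation[segmentation$segment == "extracellular", , drop = FALSE]
  if (nrow(ext) == 0L) stop("no extracellular segment for ", g$id)
  len <- ext$end - ext$start + 1L
  best <- ext[which.max(len), ]   # which.max takes the first on ties
  extract_fragment(record, best$start, best$end)
}

#' Extract a residue range from a precursor
#'
#' 1-based inclusive; the result id is the input id suffixed with the
#' range (`id_start-end`).
#'
#' @param precursor a 1-row [seq_set()] or character string.
#' @param start,end inclusive residue coordinates.
#' @return a 1-row [seq_set()].
#' @export
extract_fragment <- function(precursor, start, end) {
  g <- as_single_seq(precursor)
  n <- nchar(g$residues)
  if (!(start >= 1L && start <= end && end <= n))
    stop("fragment range ", start, "-", end,
         " out of bounds for sequence of length ", n)
  sp <- if (inherits(precursor, "seq_set")) precursor$species else "unknown"
  src <- if (inherits(precursor, "seq_set")) precursor$source else "annotated"
  seq_set(paste0(g$id, "_", start, "-", end),
          substr(g$residues, start, end), species = sp, source = src)
}

#' Detect a protein-kinase domain by its ordered motifs
#'
#' Looks for the ordered chain GxGxxG (glycine-rich loop), a lysine
#' within 30 residues (VAIK position), HRD, and DFG within 60 residues
#' of HRD.  A positive call requires at least 3 of the 4 motifs in
#' order; the score is the motif count (0-4).
#'
#' @param record a 1-row [seq_set()] or character string.
#' @return list with `positive`, `score`, `range` (minimal span of the
#'   matched motifs, or `NULL`).
#' @export
detect_kinase_domain <- function(record) {
  s <- as_single_seq(record)$residues
  g_pos <- gregexpr("G.G..G", s)[[1]]
  g_pos <- if (g_pos[1] == -1L) integer(0) else as.integer(g_pos)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  k_pos <- which(ch == "K")
  hrd_pos <- gregexpr("HRD", s, fixed = TRUE)[[1]]
  hrd_pos <- if (hrd_pos[1] == -1L) integer(0) else as.integer(hrd_pos)
  dfg_pos <- gregexpr("DFG", s, fixed = TRUE)[[1]]
  dfg_pos <- if (dfg_pos[1] == -1L) integer(0) else as.integer(dfg_pos)

  # best ordered chain over the four motif classes with the two window
  # constraints (G..K <= 30 from the end of the G motif; HRD..DFG <= 60)
  best <- list(score = 0L, first = NA_integer_, last = NA_integer_)
  consider <- function(score, first, last) {
    if (score > best$score ||
        (score == best$score && !is.na(first) &&
         (is.na(best$first) || first < best$first)))
      best <<- list(score = score, first = first, last = last)
  }
  g_opts <- c(NA_integer_, g_pos)
  for (g in g_opts) {
    ks <- if (is.na(g)) k_pos else
      k_pos[k_pos > g + 5L & k_pos <= g + 5L + 30L]
    k_opts <- c(NA_integer_, ks)
    for (k in k_opts) {
      after_k <- if (is.na(k)) if (is.na(g)) 0L else g + 5L else k
      hs <- hrd_pos[hrd_pos > after_k]
      h_opts <- c(NA_integer_, hs)
      for (h in h_opts) {
        ds <- if (is.na(h)) dfg_pos[dfg_pos > after_k] else
          dfg_pos[dfg_pos > h + 2L & dfg_pos <= h + 2L + 60L]
        d_opts <- c(NA_integer_, ds)
        for (d in d_opts) {
          score <- sum(!is.na(c(g, k, h, d)))
          if (score == 0L) next
          span <- range(stats::na.omit(c(g, g + 5L, k, h, h + 2L, d, d + 2L)))
          consider(score, span[1], span[2])
        }
      }
    }
  }
  list(positive = best$score >= 3L, score = best$score,
       range = if (best$score > 0L) c(best$first, best$last) else NULL)
}

#' Detect leucine-rich repeats
#'
#' Slides the LxxLxLxxNxL consensus along the sequence, scoring the five
#' conserved positions (L-positions accept L/I/V/F; position 9 must be
#' N).  Windows with at least 4 of 5 conserved positions matched are
#' called and reduced by greedy left-to-right non-overlapping selection.
#'
#' @param record a 1-row [seq_set()] or character string.
#' @param min_matches conserved-position matches needed to call a window.
#' @return list with `count` and `ranges` (data frame start/end/matches).
#' @export
detect_lrr <- function(record, min_matches = 4L) {
  s <- as_single_seq(record)$residues
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 11L) return(list(count = 0L, ranges = data.frame(
    start = integer(), end = integer(), matches = integer())))
  l_ok <- ch %in% c("L", "I", "V", "F")
  starts <- seq_len(n - 10L)
  m <- l_ok[starts] + l_ok[starts + 3L] + l_ok[starts + 5L] +
    (ch[starts + 8L] == "N") + l_ok[starts + 10L]
  called <- which(m >= min_matches)
  sel <- integer(0)
  last_end <- 0L
  for (p in called) {
    if (p > last_end) { sel <- c(sel, p); last_end <- p + 10L }
  }
  list(count = length(sel),
       ranges = data.frame(start = sel, end = sel + 10L,
                           matches = m[sel]))
}

#' Receptor-kinase candidate filter
#'
#' Retains sequences of at least `min_len` residues that carry at least
#' `min_lrr` leucine-rich repeats and a positive kinase-domain call.
#'
#' @param records a [seq_set()].
#' @param min_len minimum length (inclusive).
#' @param min_lrr minimum LRR count.
#' @return the filtered [seq_set()].
#' @export
rk_filter <- function(records, min_len = 500L, min_lrr = 4L) {
  stopifnot(inherits(records, "seq_set"))
  records <- length_filter(records, min_len = min_len)
  if (nrow(records) == 0L) return(records)
  keep <- vapply(seq_len(nrow(records)), function(i) {
    detect_lrr(records$residues[i])$count >= min_lrr &&
      detect_kinase_domain(records$residues[i])$positive
  }, logical(1))
  out <- records[keep, , drop = FALSE]
  class(out) <- c("seq_set", "data.frame")
  out
}
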