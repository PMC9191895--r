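# Core sequence containers and readers/writers for the plain-text formats
# the pipeline touches: FASTA (protein / nucleotide), newick trees and a
# minimal 5-column tab-delimited interval table.  Coordinates are 1-based
# and inclusive at every interface.

#' Amino-acid alphabet used throughout the package
#'
#' The 20 standard residues plus `X` for ambiguity.  `X` is scored as
#' background frequency by every scoring routine.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

#' Nucleotide alphabet (`N` = ambiguity)
#' @export
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a sequence set
#'
#' A `seq_set` is the package's basic sequence container: a data frame with
#' one row per sequence and columns `id`, `species`, `residues`, `moltype`
#' and `source`.  `source` records provenance: `annotated` (from a
#' proteome), `denovo` (rescued from genomic DNA), `seed` (user-supplied
#' query) or `decoy`.
#'
#' @param id character vector of unique, non-empty identifiers.
#' @param residues character vector of sequences (uppercased on input).
#' @param species species label(s), recycled.
#' @param moltype `"protein"` or `"dna"`, recycled.
#' @param source provenance label(s), recycled.
#' @return a data frame of class `seq_set`.
#' @export
seq_set <- function(id, residues, species = "unknown",
                    moltype = "protein", source = "annotated") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  n <- length(id)
  stopifnot(length(residues) == n)
  x <- data.frame(id = id,
                  species = rep_len(as.character(species), n),
                  residues = residues,
                  moltype = rep_len(as.character(moltype), n),
                  source = rep_len(as.character(source), n),
                  stringsAsFactors = FALSE)
  class(x) <- c("seq_set", "data.frame")
  validate_seq_set(x)
  x
}

validate_seq_set <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!nzchar(x$id))) stop("sequence ids must be non-empty")
  dup <- x$id[duplicated(x$id)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!nzchar(x$residues))) {
    bad <- x$id[!nzchar(x$residues)]
    stop("empty sequence(s): ", paste(bad, collapse = ", "))
  }
  bad_mol <- setdiff(unique(x$moltype), c("protein", "dna"))
  if (length(bad_mol)) stop("unknown moltype: ", paste(bad_mol, collapse = ", "))
  for (mt in unique(x$moltype)) {
    alph <- if (mt == "protein") AA_ALPHABET else DNA_ALPHABET
    rows <- which(x$moltype == mt)
    chars <- unique(unlist(strsplit(x$residues[rows], "", fixed = TRUE)))
    off <- setdiff(chars, alph)
    if (length(off))
      stop("residues outside the ", mt, " alphabet: ",
           paste(off, collapse = ", "))
  }
  bad_src <- setdiff(unique(x$source), c("annotated", "denovo", "seed", "decoy"))
  if (length(bad_src)) stop("unknown source: ", paste(bad_src, collapse = ", "))
  invisible(x)
}

seq_lengths <- function(x) nchar(x$residues)

#' Read a FASTA file or literal FASTA text
#'
#' The first whitespace-delimited header token is the record id; any
#' further `key=value` tokens (`species=`, `source=`) written by
#' [write_fasta()] are parsed back so that a write/read round trip is an
#' identity.  Wrapped sequence lines are concatenated and residues are
#' uppercased.
#'
#' @param path a file path, or a character string containing FASTA text
#'   (anything with a newline or leading `>` is treated as text).
#' @param moltype `"protein"` or `"dna"`.
#' @param species default species for records without a `species=` tag.
#' @param source default provenance for records without a `source=` tag.
#' @return a [seq_set()].
#' @export
read_fasta <- function(path, moltype = "protein", species = "unknown",
                       source = "annotated") {
  if (length(path) == 1L && (grepl("\n", path) || startsWith(path, ">"))) {
    tmp <- tempfile(fileext = ".fa")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(sub("\n$", "", path), tmp)
    path <- tmp
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  headers <- names(ss)
  toks <- strsplit(headers, "\\s+")
  ids <- vapply(toks, `[[`, character(1), 1L)
  meta_of <- function(tk, key, default) {
    hit <- grep(paste0("^", key, "="), tk, value = TRUE)
    if (length(hit)) sub(paste0("^", key, "="), "", hit[1]) else default
  }
  sp <- vapply(toks, meta_of, character(1), key = "species", default = species)
  src <- vapply(toks, meta_of, character(1), key = "source", default = source)
  seq_set(id = ids, residues = as.character(ss), species = sp,
          moltype = moltype, source = src)
}

#' Write a sequence set as FASTA
#'
#' @param x a [seq_set()].
#' @param path optional output file; when `NULL` the FASTA text is returned.
#' @param line_width residues per sequence line.
#' @param with_meta write `species=`/`source=` tokens into the header so
#'   the record metadata round-trips through [read_fasta()].
#' @return the FASTA text, invisibly when `path` is given.
#' @export
write_fasta <- function(x, path = NULL, line_width = 60L, with_meta = TRUE) {
  stopifnot(inherits(x, "seq_set"), nrow(x) > 0L, line_width >= 1L)
  hdr <- if (with_meta) {
    paste0(">", x$id, " species=", x$species, " source=", x$source)
  } else paste0(">", x$id)
  wrap <- function(s) {
    n <- nchar(s)
    starts <- seq.int(1L, n, by = line_width)
    substring(s, starts, pmin(starts + line_width - 1L, n))
  }
  lines <- unlist(lapply(seq_len(nrow(x)), function(i) {
    c(hdr[i], wrap(x$residues[i]))
  }))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(lines, path)
  invisible(txt)
}

#' Read / write the 5-column interval annotation table
#'
#' Tab-delimited columns: `seq_id`, `start`, `end`, `strand`, `feature`,
#' with 1-based inclusive coordinates.  This is the minimal dialect the
#' pipeline needs for annotation masking; [gff_to_intervals()] maps GFF3
#' columns 1, 4, 5, 7, 3 onto it.
#'
#' @param path file path (or for `write_intervals`, the table to write).
#' @return a data frame with the five columns above.
#' @export
read_intervals <- function(path) {
  x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  validate_intervals(x)
}

#' @rdname read_intervals
#' @param x interval data frame.
#' @export
write_intervals <- function(x, path) {
  validate_intervals(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_intervals <- function(x) {
  need <- c("seq_id", "start", "end", "strand", "feature")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("interval table lacks column(s): ",
                         paste(miss, collapse = ", "))
  x <- x[, need]
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  if (nrow(x)) {
    if (any(x$start < 1L) || any(x$start > x$end))
      stop("intervals must satisfy 1 <= start <= end")
    if (any(!x$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'")
  }
  x
}

#' @rdname read_intervals
#' @export
gff_to_intervals <- function(path) {
  g <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  validate_intervals(data.frame(seq_id = g[[1]], start = g[[4]], end = g[[5]],
                                strand = g[[7]], feature = g[[3]],
                                stringsAsFactors = FALSE))
}

#' Construct a multiple sequence alignment object
#'
#' An `msa` stores an ordered set of equal-length aligned strings with
#' `-` as the gap symbol.  Degapping any row recovers the input sequence.
#'
#' @param id character vector of row ids.
#' @param aln character vector of aligned strings (equal lengths).
#' @return an object of class `msa`.
#' @export
msa <- function(id, aln) {
  id <- as.character(id); aln <- toupper(as.character(aln))
  stopifnot(length(id) == length(aln), length(id) >= 1L)
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned strings must all have equal length")
  if (anyDuplicated(id)) stop("duplicate msa row ids")
  structure(list(id = id, aln = aln), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", length(x$id), " sequences x ", nchar(x$aln[1]), " columns\n",
      sep = "")
  invisible(x)
}

msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$aln, "", fixed = TRUE))
}

degap <- function(s) gsub("-", "", s, fixed = TRUE)

msa_ncol <- function(m) nchar(m$aln[1])

#' Read and write newick trees
#'
#' Thin wrappers over \pkg{ape} that add the validation the pipeline
#' relies on: unique leaf labels, and missing branch lengths defaulting
#' to zero.
#'
#' @param text newick string (terminating `;`).
#' @return an \pkg{ape} `phylo` object.
#' @export
read_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(tr)) stop("malformed newick (check parentheses)")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf name(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 12)
}
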