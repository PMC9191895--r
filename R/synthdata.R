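# Deterministic generator of multi-species synthetic benchmarks: a planted
# secreted-peptide family with a conserved C-x(9-11)-C motif, a fraction of
# members present only in genomic DNA, decoy short proteins, a planted
# LRR receptor-kinase family, and an elicitor-induction expression table.
# Every generator is bit-reproducible under its seed, and signal-peptide /
# transmembrane / motif geometry is engineered so that the package's own
# rule-based detectors recover the planted truth exactly -- which is what
# makes recall/precision of the full pipeline testable at 1.0.

# residue pools used by the generators; chosen so that each engineered
# region keeps the hydropathy / size properties its detector looks for
SP_BASIC <- c("K", "R")
SP_CORE <- c("L", "I", "F")              # hydrophobic, none "small"
SP_SMALL <- c("A", "G", "S", "T")        # small residues at -3/-1
SP_LINKER <- c("N", "Q", "E", "D", "K", "R", "H", "W", "Y") # never small
TM_POOL <- c("L", "I", "V", "F")
POLAR_POOL <- c("S", "T", "N", "Q", "E", "D", "K", "R", "G", "P", "H")
CHARGED_POOL <- c("D", "E", "K", "R", "N", "Q")
# secreted-peptide mature regions are hydrophilic-biased (no C, no M: the
# cysteine pair is planted explicitly and internal methionines would start
# nested open reading frames in the synthetic genomes)
MATURE_POOL <- c(rep(c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "P",
                       "H", "Y"), 2),
                 "A", "V", "L", "I", "F", "W")

#' Specification of a synthetic peptide-family benchmark
#'
#' The defaults define the package's reference benchmark: 8 species with
#' 3 family members each, a quarter of the members present only in
#' genomic DNA, and 40 decoy short proteins per species.
#'
#' @param n_species number of species.
#' @param members_per_species planted family members per species.
#' @param precursor_length_range total precursor length range (signal
#'   peptide included); one length is drawn for the ancestor.
#' @param sp_length signal-peptide length (>= 20).
#' @param cys_gap_range range of the number of residues strictly between
#'   the two conserved cysteines.
#' @param subst_prob per-site substitution probability applied to each
#'   member relative to the ancestor (cysteines never mutate).
#' @param fraction_unannotated fraction of planted members omitted from
#'   the proteome and annotation table (present only in the genome).
#' @param decoys_per_species decoy short proteins per species.
#' @param rng_seed integer seed; fixed seed means bit-identical output.
#' @return object of class `family_spec`.
#' @export
family_spec <- function(n_species = 8L, members_per_species = 3L,
                        precursor_length_range = c(60L, 120L),
                        sp_length = 25L, cys_gap_range = c(9L, 11L),
                        subst_prob = 0.1, fraction_unannotated = 0.25,
                        decoys_per_species = 40L, rng_seed = 1L) {
  stopifnot(n_species >= 1L, members_per_species >= 1L,
            length(precursor_length_range) == 2L,
            precursor_length_range[1] <= precursor_length_range[2],
            sp_length >= 20L,
            length(cys_gap_range) == 2L,
            cys_gap_range[1] <= cys_gap_range[2], cys_gap_range[1] >= 1L,
            subst_prob >= 0, subst_prob <= 1,
            fraction_unannotated >= 0, fraction_unannotated <= 1,
            decoys_per_species >= 0L)
  structure(list(n_species = as.integer(n_species),
                 members_per_species = as.integer(members_per_species),
                 precursor_length_range = as.integer(precursor_length_range),
                 sp_length = as.integer(sp_length),
                 cys_gap_range = as.integer(cys_gap_range),
                 subst_prob = subst_prob,
                 fraction_unannotated = fraction_unannotated,
                 decoys_per_species = as.integer(decoys_per_species),
                 rng_seed = as.integer(rng_seed)),
            class = "family_spec")
}

# engineered signal peptide: Met start, 2 basic residues, a 12-residue
# hydrophobic core, a linker free of small residues, and small residues at
# the -3/-1 cleavage positions -- the unique first site the SP heuristic
# can call
make_sp_block <- function(sp_length = 25L) {
  stopifnot(sp_length >= 20L)
  linker_len <- sp_length - 18L
  c("M",
    sample(SP_BASIC, 2L, replace = TRUE),
    sample(SP_CORE, 12L, replace = TRUE),
    sample(SP_LINKER, linker_len, replace = TRUE),
    sample(SP_SMALL, 1L),
    sample(SP_LINKER, 1L),
    sample(SP_SMALL, 1L))
}

sp_block_classes <- function(sp_length = 25L) {
  linker_len <- sp_length - 18L
  c("fixed", rep("basic", 2L), rep("core", 12L),
    rep("linker", linker_len), "small", "linker", "small")
}

mutate_by_class <- function(res, classes, p) {
  pools <- list(basic = SP_BASIC, core = SP_CORE, small = SP_SMALL,
                linker = SP_LINKER, mature = MATURE_POOL,
                tm = TM_POOL, polar = POLAR_POOL, charged = CHARGED_POOL,
                anchor = TM_POOL)
  hit <- which(stats::runif(length(res)) < p & classes != "fixed")
  for (i in hit) {
    pool <- setdiff(unique(pools[[classes[i]]]), res[i])
    if (length(pool)) res[i] <- sample(pool, 1L)
  }
  res
}

#' Generate the planted peptide family
#'
#' Builds one ancestral precursor (signal peptide + hydrophilic mature
#' region carrying exactly one C-x(g)-C motif in the C-terminal half of
#' the mature region, g drawn from `cys_gap_range`) and derives each
#' species' members by i.i.d. per-site substitution.  Substitutions are
#' class-preserving inside the engineered signal peptide and never touch
#' the cysteines.  Decoy short proteins are generated alongside; decoys
#' never contain a cysteine pair at the planted spacing.
#'
#' @param spec a [family_spec()].
#' @return list with `seed` (ancestor, a 1-row [seq_set()]), `members`,
#'   `decoys`, and `truth` (one row per planted member: id, species,
#'   mature-region coordinates, residues; genomic fields are filled in by
#'   [generate_genomes()]).
#' @export
generate_family <- function(spec = family_spec()) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(spec$rng_seed, {
    len <- sample(seq(spec$precursor_length_range[1],
                      spec$precursor_length_range[2]), 1L)
    mat_len <- len - spec$sp_length
    g <- sample(seq(spec$cys_gap_range[1], spec$cys_gap_range[2]), 1L)
    if (mat_len < g + 2L)
      stop("impossible geometry: cysteine motif longer than the mature region")
    half <- ceiling(mat_len / 2)
    c1_max <- mat_len - g - 1L
    if (c1_max < half)
      stop("impossible geometry: no room for the motif in the C-terminal half")
    c1 <- if (c1_max == half) half else sample(seq(half, c1_max), 1L)
    c2 <- c1 + g + 1L

    sp_cls <- sp_block_classes(spec$sp_length)
    mature_cls <- rep("mature", mat_len)
    mature_cls[c(c1, c2)] <- "fixed"
    classes <- c(sp_cls, mature_cls)

    anc_mat <- sample(MATURE_POOL, mat_len, replace = TRUE)
    anc_mat[c(c1, c2)] <- "C"
    ancestor <- c(make_sp_block(spec$sp_length), anc_mat)

    species <- paste0("sp", seq_len(spec$n_species))
    ids <- character(0); seqs <- character(0); sp_col <- character(0)
    for (s in species) {
      for (k in seq_len(spec$members_per_species)) {
        m <- mutate_by_class(ancestor, classes, spec$subst_prob)
        ids <- c(ids, paste0(s, "_fam", k))
        seqs <- c(seqs, paste(m, collapse = ""))
        sp_col <- c(sp_col, s)
      }
    }
    members <- seq_set(ids, seqs, species = sp_col, source = "annotated")

    d_ids <- character(0); d_seqs <- character(0); d_sp <- character(0)
    for (s in species) {
      for (k in seq_len(spec$decoys_per_species)) {
        dl <- sample(40:160, 1L)
        d <- sample(MATURE_POOL, dl, replace = TRUE)
        if (k %% 2L == 0L && dl > spec$sp_length + 15L)
          d[seq_len(spec$sp_length)] <- make_sp_block(spec$sp_length)
        d_ids <- c(d_ids, paste0(s, "_dec", k))
        d_seqs <- c(d_seqs, paste(d, collapse = ""))
        d_sp <- c(d_sp, s)
      }
    }
    decoys <- if (length(d_ids))
      seq_set(d_ids, d_seqs, species = d_sp, source = "decoy")
    else seq_set(character(0), character(0))[0, ]

    truth <- data.frame(id = ids, species = sp_col, family = TRUE,
                        annotated = NA, seq_id = NA_character_,
                        start = NA_integer_, end = NA_integer_,
                        strand = NA_character_,
                        mature_start = spec$sp_length + 1L,
                        mature_end = len, residues = seqs,
                        stringsAsFactors = FALSE)
    list(seed = seq_set("ancestor", paste(ancestor, collapse = ""),
                        species = "ancestral", source = "seed"),
         members = members, decoys = decoys, truth = truth)
  })
}

# ---- genomes -------------------------------------------------------------

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

revcomp_dna <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

reverse_translate <- function(protein, ct = codon_table()) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(res, function(a) {
    opts <- ct[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", a)
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste(c(codons, stop_codon), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Embed the planted family in synthetic genomes
#'
#' Each member's coding sequence (uniform synonymous codon choice, ATG
#' start, stop codon) is embedded in random background DNA, half of the
#' genes on the minus strand.  A same-frame stop codon is placed
#' immediately upstream of every gene so that open-reading-frame
#' extraction recovers exactly the planted interval.  A deterministic
#' subset of members -- `round(fraction_unannotated * total)` overall,
#' spread across species -- is omitted from both the proteome and the
#' annotation table while remaining present in the genome.
#'
#' @param fam result of [generate_family()].
#' @param spec the [family_spec()] used to generate `fam`.
#' @return list with `genomes` (one DNA [seq_set()] record per species),
#'   `annotations` (interval table for annotated members), `proteome`
#'   (annotated members plus decoys), and the completed `truth` table.
#' @export
generate_genomes <- function(fam, spec = family_spec()) {
  truth <- fam$truth
  n_total <- nrow(truth)
  withr::with_seed(spec$rng_seed + 1L, {
    n_unannot <- round(spec$fraction_unannotated * n_total)
    # spread unannotated members over species: one per species in seeded
    # order until the global quota is filled
    species <- unique(truth$species)
    truth$annotated <- TRUE
    if (n_unannot > 0L) {
      pick <- integer(0)
      sp_order <- sample(species)
      k <- 0L
      while (length(pick) < n_unannot) {
        s <- sp_order[(k %% length(sp_order)) + 1L]
        cand <- setdiff(which(truth$species == s), pick)
        if (length(cand)) pick <- c(pick, cand[sample.int(length(cand), 1L)])
        k <- k + 1L
        if (k > 10L * n_total) break
      }
      truth$annotated[pick] <- FALSE
    }

    ct <- codon_table()
    g_ids <- character(0); g_seqs <- character(0)
    ann <- list()
    for (s in species) {
      rows <- which(truth$species == s)
      chrom_id <- paste0(s, "_chr1")
      pos <- 1L
      parts <- character(0)
      spacer <- random_dna(sample(200:400, 1L))
      parts <- c(parts, spacer); pos <- pos + nchar(spacer)
      for (i in rows) {
        cds <- reverse_translate(truth$residues[i], ct)
        strand <- sample(c("+", "-"), 1L)
        cassette_plus <- paste0("TAA", cds)
        cassette <- if (strand == "+") cassette_plus else
          revcomp_dna(cassette_plus)
        if (strand == "+") {
          cds_start <- pos + 3L
          cds_end <- pos + nchar(cassette) - 1L
        } else {
          cds_start <- pos
          cds_end <- pos + nchar(cds) - 1L
        }
        truth$seq_id[i] <- chrom_id
        truth$start[i] <- cds_start
        truth$end[i] <- cds_end
        truth$strand[i] <- strand
        if (truth$annotated[i]) {
          ann[[length(ann) + 1L]] <- data.frame(
            seq_id = chrom_id, start = cds_start, end = cds_end,
            strand = strand, feature = "CDS", stringsAsFactors = FALSE)
        }
        parts <- c(parts, cassette); pos <- pos + nchar(cassette)
        spacer <- random_dna(sample(200:400, 1L))
        parts <- c(parts, spacer); pos <- pos + nchar(spacer)
      }
      g_ids <- c(g_ids, chrom_id)
      g_seqs <- c(g_seqs, paste(parts, collapse = ""))
    }
    genomes <- seq_set(g_ids, g_seqs,
                       species = species, moltype = "dna",
                       source = "annotated")
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(seq_id = character(), start = integer(), end = integer(),
                 strand = character(), feature = character(),
                 stringsAsFactors = FALSE)
    keep <- truth$annotated
    proteome <- rbind(fam$members[keep, , drop = FALSE], fam$decoys)
    class(proteome) <- c("seq_set", "data.frame")
    list(genomes = genomes, annotations = annotations,
         proteome = proteome, truth = truth)
  })
}

#' Generate an elicitor-induction expression table
#'
#' Planted family transcripts receive log2 fold-changes drawn from
#' `Normal(induction_log2fc, noise_sd)`, decoys from `Normal(0,
#' noise_sd)`.  Only annotated genes get a row: unannotated members have
#' no transcript model, which is exactly the annotation gap the genomic
#' rescue stage exists to close.
#'
#' @param truth truth table (from [generate_family()] or
#'   [generate_genomes()]; when the `annotated` flag is still `NA` all
#'   members are treated as annotated).
#' @param decoy_ids character vector of decoy gene ids.
#' @param induction_log2fc mean induction of family transcripts (> 0).
#' @param noise_sd standard deviation of the noise (>= 0).
#' @param rng_seed integer seed.
#' @param column name of the fold-change column.
#' @return data frame with columns `id` and `column`.
#' @export
generate_expression <- function(truth, decoy_ids, induction_log2fc = 4,
                                noise_sd = 0.5, rng_seed = 1L,
                                column = "flg22_90min") {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (induction_log2fc <= 0) stop("induction_log2fc must be > 0")
  fam_ids <- truth$id[is.na(truth$annotated) | truth$annotated]
  withr::with_seed(as.integer(rng_seed), {
    fc_fam <- stats::rnorm(length(fam_ids), induction_log2fc, noise_sd)
    fc_dec <- stats::rnorm(length(decoy_ids), 0, noise_sd)
  })
  out <- data.frame(id = c(fam_ids, as.character(decoy_ids)),
                    fc = c(fc_fam, fc_dec), stringsAsFactors = FALSE)
  names(out)[2] <- column
  out
}

# ---- receptor kinases ----------------------------------------------------

#' Generate a planted LRR receptor-kinase family
#'
#' Each receptor is at least 500 residues: an engineered signal peptide,
#' `n_lrr` tandem copies of the LxxLxLxxNxL leucine-rich-repeat consensus
#' in a hydrophilic ectodomain, a single 19-23 residue transmembrane
#' stretch of mean Kyte-Doolittle hydropathy well above 1.8, and a kinase
#' segment carrying the ordered GxGxxG / VAIK-lysine / HRD / DFG motifs.
#' Optional decoys are length-matched hydrophilic random proteins without
#' any planted structure.
#'
#' @param n_species number of species.
#' @param members_per_species receptors per species.
#' @param n_lrr number of tandem LRR units (>= 4).
#' @param subst_prob per-site substitution probability per member
#'   (class-preserving; motif anchors never mutate).
#' @param n_decoys number of decoy long proteins (total, spread over
#'   species).
#' @param rng_seed integer seed.
#' @return list with `members` (a [seq_set()]), `decoys`, `seed` (the
#'   family template, provenance `seed`) and `truth` (per member: TM
#'   range, LRR region, kinase region, signal-peptide end).
#' @export
generate_rk_family <- function(n_species = 4L, members_per_species = 2L,
                               n_lrr = 12L, subst_prob = 0.05,
                               n_decoys = 0L, rng_seed = 1L) {
  stopifnot(members_per_species >= 1L, n_lrr >= 4L)
  withr::with_seed(as.integer(rng_seed), {
    sp_len <- 25L
    sp_cls <- sp_block_classes(sp_len)
    sp_blk <- make_sp_block(sp_len)

    lrr_unit <- function() {
      u <- sample(POLAR_POOL, 11L, replace = TRUE)
      u[c(1, 4, 6, 11)] <- sample(TM_POOL, 4L, replace = TRUE)
      u[9] <- "N"
      u
    }
    lrr_cls_unit <- c("anchor", "polar", "polar", "anchor", "polar",
                      "anchor", "polar", "polar", "fixed", "polar", "anchor")
    pad1 <- sample(POLAR_POOL, 30L, replace = TRUE)
    lrrs <- unlist(replicate(n_lrr, lrr_unit(), simplify = FALSE))
    pad2 <- sample(POLAR_POOL, 20L, replace = TRUE)
    tm_len <- sample(19:23, 1L)
    tm <- sample(TM_POOL, tm_len, replace = TRUE)
    pad3 <- sample(CHARGED_POOL, 15L, replace = TRUE)

    kin_fill <- function(n) sample(POLAR_POOL, n, replace = TRUE)
    g_motif <- c("G", sample(POLAR_POOL, 1L), "G",
                 sample(POLAR_POOL, 2L), "G")
    kinase <- c(kin_fill(8L), g_motif, kin_fill(10L), "K", kin_fill(50L),
                "H", "R", "D", kin_fill(25L), "D", "F", "G", kin_fill(60L))
    kin_cls <- c(rep("polar", 8L),
                 c("fixed", "polar", "fixed", "polar", "polar", "fixed"),
                 rep("polar", 10L), "fixed", rep("polar", 50L),
                 rep("fixed", 3L), rep("polar", 25L), rep("fixed", 3L),
                 rep("polar", 60L))

    template <- c(sp_blk, pad1, lrrs, pad2, tm, pad3, kinase)
    classes <- c(sp_cls, rep("polar", 30L),
                 rep(lrr_cls_unit, n_lrr), rep("polar", 20L),
                 rep("tm", tm_len), rep("charged", 15L), kin_cls)
    # pad the C-terminal tail until comfortably past the 500-residue floor
    if (length(template) < 520L) {
      extra <- 520L - length(template)
      template <- c(template, sample(POLAR_POOL, extra, replace = TRUE))
      classes <- c(classes, rep("polar", extra))
    }

    lrr_start <- sp_len + 30L + 1L
    lrr_end <- lrr_start + 11L * n_lrr - 1L
    tm_start <- lrr_end + 20L + 1L
    tm_end <- tm_start + tm_len - 1L
    kin_start <- tm_end + 15L + 1L
    kin_end <- kin_start + length(kinase) - 1L

    species <- paste0("sp", seq_len(n_species))
    ids <- character(0); seqs <- character(0); sp_col <- character(0)
    for (s in species) for (k in seq_len(members_per_species)) {
      m <- mutate_by_class(template, classes, subst_prob)
      ids <- c(ids, paste0(s, "_rk", k))
      seqs <- c(seqs, paste(m, collapse = ""))
      sp_col <- c(sp_col, s)
    }
    members <- seq_set(ids, seqs, species = sp_col, source = "annotated")
    truth <- data.frame(id = ids, species = sp_col, family = TRUE,
                        sp_end = sp_len, lrr_start = lrr_start,
                        lrr_end = lrr_end, tm_start = tm_start,
                        tm_end = tm_end, kinase_start = kin_start,
                        kinase_end = kin_end, n_lrr = n_lrr,
                        residues = seqs, stringsAsFactors = FALSE)

    decoys <- NULL
    if (n_decoys > 0L) {
      d_ids <- paste0("dec_rk", seq_len(n_decoys))
      d_seqs <- vapply(seq_len(n_decoys), function(i) {
        dl <- sample(500:700, 1L)
        pool <- c(rep(POLAR_POOL, 3L), "A", "V", "L", "I", "F", "W", "Y", "M")
        paste(sample(pool, dl, replace = TRUE), collapse = "")
      }, character(1))
      decoys <- seq_set(d_ids, d_seqs,
                        species = rep_len(species, n_decoys),
                        source = "decoy")
    } else {
      decoys <- seq_set(character(0), character(0))[0, ]
    }
    list(members = members, decoys = decoys,
         seed = seq_set("rk_template", paste(template, collapse = ""),
                        species = "ancestral", source = "seed"),
         truth = truth)
  })
}

#' Generate the full reference benchmark
#'
#' Convenience wrapper running [generate_family()], [generate_genomes()]
#' and [generate_expression()] with one spec, returning everything the
#' end-to-end pipeline needs plus the ground truth.
#'
#' @param spec a [family_spec()].
#' @param induction_log2fc,noise_sd expression-table parameters.
#' @return list with `spec`, `seeds`, `proteome`, `genomes`,
#'   `annotations`, `expression`, `truth`, `decoy_ids`.
#' @export
generate_benchmark <- function(spec = family_spec(), induction_log2fc = 4,
                               noise_sd = 0.5) {
  fam <- generate_family(spec)
  gen <- generate_genomes(fam, spec)
  expr <- generate_expression(gen$truth, fam$decoys$id,
                              induction_log2fc = induction_log2fc,
                              noise_sd = noise_sd,
                              rng_seed = spec$rng_seed + 2L)
  list(spec = spec, seeds = fam$seed, members = fam$members,
       decoy_ids = fam$decoys$id, proteome = gen$proteome,
       genomes = gen$genomes, annotations = gen$annotations,
       expression = expr, truth = gen$truth)
}
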