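# End-to-end orchestration of the two discovery procedures: peptide-family
# mining (screen -> iterative search -> similarity-network communities ->
# genomic rescue -> relaxed/confident refinement -> phylogeny -> logo) and
# receptor-kinase delineation (length filter -> profile search -> 50%
# network -> LRR+kinase filter -> domain segmentation -> three
# phylogenies).  Every run is deterministic under its seed and echoes its
# full resolved configuration in a manifest.

#' Pipeline configuration
#'
#' All tunable thresholds of both procedures with their published-procedure
#' presets: `preset = "ctnip"` is the peptide configuration (length < 150
#' screen, <= 300 search space, 20% network, C-x(9-11)-C, age cutoff 9),
#' `preset = "rk"` the receptor configuration (>= 500 length, 50% network,
#' age cutoff 5.5).
#'
#' @param preset `"ctnip"` or `"rk"`.
#' @param ... named overrides of individual fields.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("ctnip", "rk"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    screen.max_len = 150L,
    screen.column = "flg22_90min",
    peptide.max_len = 300L,
    peptide.min_len = 25L,
    rk.min_len = 500L,
    rk.min_lrr = 4L,
    network.threshold_pct = if (preset == "ctnip") 20 else 50,
    cys.min_gap = 9L,
    cys.max_gap = 11L,
    clade.age_cutoff = if (preset == "ctnip") 9 else 5.5,
    logo.occupancy_min = 0.05,
    search.inclusion_evalue = if (preset == "ctnip") 1e-5 else 1e-10,
    search.rounds = 5L,
    search.min_pct = 20,
    search.min_score = 50,
    bootstrap.n = 1000L,
    rng_seed = 1L,
    manual_exclusions = character(0),
    preset = preset)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$screen.max_len > 0, cfg$peptide.max_len > 0,
            cfg$rk.min_len > 0, cfg$network.threshold_pct >= 0,
            cfg$cys.min_gap <= cfg$cys.max_gap,
            cfg$clade.age_cutoff >= 0,
            cfg$logo.occupancy_min >= 0, cfg$logo.occupancy_min <= 1,
            cfg$search.inclusion_evalue > 0, cfg$search.rounds >= 1)
  structure(cfg, class = "pipeline_config")
}

write_manifest <- function(out_dir, cfg, stage_counts) {
  if (is.null(out_dir)) return(invisible(NULL))
  manifest <- list(config = unclass(cfg), stage_counts = stage_counts,
                   package_version = as.character(utils::packageVersion("pepfam")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Run the peptide-family discovery pipeline
#'
#' Executes the full procedure: expression screen, iterative
#' profile search from the seed sequences, similarity-network community
#' selection anchored on the seeds, six-frame genomic rescue of
#' unannotated members, merge into the relaxed set, cysteine-spacing
#' refinement into the confident set, phylogeny of the relaxed set with
#' outgroup (or midpoint) rooting and age-cutoff clades, and an
#' occupancy-trimmed logo of the confident alignment.
#'
#' @param proteome protein [seq_set()] (all species merged).
#' @param genomes DNA [seq_set()] (may be empty / `NULL`: protein-only run).
#' @param annotations interval table for annotation masking.
#' @param seeds seed [seq_set()] (provenance `seed`).
#' @param expression expression table for the screen.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for intermediates and the manifest.
#' @return list with `screen`, `search`, `graph`, `partition`,
#'   `protein_candidates`, `rescue`, `relaxed`, `confident`, `tree`
#'   (rooted), `clades`, `logo`, `msa_relaxed`, `msa_confident`,
#'   `stage_counts`.
#' @export
run_peptide_discovery <- function(proteome, genomes, annotations, seeds,
                                  expression,
                                  config = pipeline_config("ctnip"),
                                  out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  scheme <- scoring_scheme()
  stage <- function(name, n) message(sprintf("[%s] %d candidates", name, n))
  counts <- list()

  scr <- screen_short_secreted(proteome, expression,
                               column = config$screen.column,
                               max_len = config$screen.max_len)
  counts$screen <- nrow(scr)
  stage("screen", nrow(scr))

  db <- length_filter(proteome, max_len = config$peptide.max_len)
  search <- iterative_search(seeds, db, scheme,
                             rounds = config$search.rounds,
                             inclusion_evalue = config$search.inclusion_evalue,
                             min_pct = config$search.min_pct,
                             min_score = config$search.min_score,
                             rng_seed = config$rng_seed)
  counts$protein_search <- nrow(search$included)
  stage("protein search", nrow(search$included))

  net_in <- rbind(seeds, search$included[!search$included$id %in% seeds$id, ,
                                         drop = FALSE])
  class(net_in) <- c("seq_set", "data.frame")
  graph <- build_similarity_graph(net_in, scheme,
                                  threshold_pct = config$network.threshold_pct)
  part <- louvain(graph, rng_seed = config$rng_seed)
  sel_ids <- select_seed_communities(graph, part, seeds$id)
  protein_candidates <- net_in[net_in$id %in% setdiff(sel_ids, seeds$id), ,
                               drop = FALSE]
  class(protein_candidates) <- c("seq_set", "data.frame")
  counts$community_selected <- nrow(protein_candidates)
  stage("seed communities", nrow(protein_candidates))

  # profile for the genomic rescue, built from the selected protein set
  rescue <- NULL
  dna_records <- seq_set("x", "M")[0, ]
  if (!is.null(genomes) && inherits(genomes, "seq_set") &&
      nrow(genomes) > 0L) {
    prof_in <- if (nrow(protein_candidates) >= 2L) protein_candidates else
      net_in
    aln <- progressive_msa(prof_in, scheme)
    profile <- build_profile(aln)
    rescue <- dna_rescue(genomes, annotations, profile,
                         min_len = config$peptide.min_len,
                         max_len = config$peptide.max_len,
                         evalue_max = config$search.inclusion_evalue,
                         rng_seed = config$rng_seed)
    dna_records <- rescue$records
  }
  counts$dna_rescued <- nrow(dna_records)
  stage("dna rescue", nrow(dna_records))

  relaxed <- merge_candidates(protein_candidates, dna_records)
  counts$relaxed <- nrow(relaxed$members)
  stage("relaxed", nrow(relaxed$members))

  confident <- refine_confident(relaxed, config$manual_exclusions,
                                min_gap = config$cys.min_gap,
                                max_gap = config$cys.max_gap)
  counts$confident <- nrow(confident$members)
  stage("confident", nrow(confident$members))

  # phylogeny of the relaxed set (plus seeds as outgroup anchor)
  tree <- NULL; clades <- NULL; msa_rel <- NULL
  tree_in <- rbind(relaxed$members, seeds)
  class(tree_in) <- c("seq_set", "data.frame")
  if (nrow(tree_in) >= 3L) {
    msa_rel <- progressive_msa(tree_in, scheme)
    D <- msa_distance(msa_rel)
    tr <- nj_tree(D)
    tree <- root_tree(tr, outgroup = seeds$id[1])
    clades <- clades_by_age(tree, config$clade.age_cutoff)
  }

  logo <- NULL; msa_conf <- NULL
  if (nrow(confident$members) >= 1L) {
    msa_conf <- if (nrow(confident$members) >= 2L)
      progressive_msa(confident$members, scheme)
    else msa(confident$members$id, confident$members$residues)
    logo <- sequence_logo(msa_conf,
                          occupancy_min = config$logo.occupancy_min)
  }

  if (!is.null(out_dir)) {
    if (nrow(relaxed$members))
      write_fasta(relaxed$members, file.path(out_dir, "relaxed.fasta"))
    if (nrow(confident$members))
      write_fasta(confident$members, file.path(out_dir, "confident.fasta"))
    if (!is.null(tree))
      writeLines(write_newick(tree), file.path(out_dir, "relaxed_tree.nwk"))
    if (!is.null(logo))
      write_logo_tsv(logo, file.path(out_dir, "confident_logo.tsv"))
    utils::write.table(scr, file.path(out_dir, "screen.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_manifest(out_dir, config, counts)
  }

  list(screen = scr, search = search, graph = graph, partition = part,
       protein_candidates = protein_candidates, rescue = rescue,
       relaxed = relaxed, confident = confident, tree = tree,
       clades = clades, logo = logo, msa_relaxed = msa_rel,
       msa_confident = msa_conf, stage_counts = counts, config = config)
}

#' Run the receptor-kinase delineation pipeline
#'
#' Minimum-length filter, profile search from the receptor seeds,
#' similarity network at the receptor threshold, seed-community
#' selection, LRR + kinase-domain filtering, signal-peptide removal,
#' transmembrane segmentation, ectodomain and kinase-domain extraction,
#' and phylogenies of the full-length, ectodomain and kinase-domain
#' sequences with age-cutoff clades.
#'
#' @param proteome protein [seq_set()].
#' @param seeds receptor seed [seq_set()].
#' @param config a [pipeline_config()] (use preset `"rk"`).
#' @param out_dir optional output directory.
#' @return list with `retained` (final receptor set), `segmentation`
#'   (list per receptor), `ectodomains`, `kinase_domains`, `trees`
#'   (full / ectodomain / kinase), `clades`, `stage_counts`.
#' @export
run_rk_discovery <- function(proteome, seeds,
                             config = pipeline_config("rk"),
                             out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  scheme <- scoring_scheme()
  counts <- list()

  db <- length_filter(proteome, min_len = config$rk.min_len)
  counts$length_filtered <- nrow(db)
  if (nrow(db) == 0L) stop("no protein passes the minimum-length filter")

  seed_aln <- progressive_msa(seeds, scheme)
  profile <- build_profile(seed_aln)
  hits <- profile_search(profile, db,
                         evalue_max = config$search.inclusion_evalue,
                         rng_seed = config$rng_seed)
  included <- db[db$id %in% hits$target, , drop = FALSE]
  class(included) <- c("seq_set", "data.frame")
  counts$profile_hits <- nrow(included)

  net_in <- rbind(seeds, included[!included$id %in% seeds$id, , drop = FALSE])
  class(net_in) <- c("seq_set", "data.frame")
  graph <- build_similarity_graph(net_in, scheme,
                                  threshold_pct = config$network.threshold_pct)
  part <- louvain(graph, rng_seed = config$rng_seed)
  sel_ids <- select_seed_communities(graph, part, seeds$id)
  candidates <- net_in[net_in$id %in% setdiff(sel_ids, seeds$id), ,
                       drop = FALSE]
  class(candidates) <- c("seq_set", "data.frame")
  counts$community_selected <- nrow(candidates)

  retained <- rk_filter(candidates, min_len = config$rk.min_len,
                        min_lrr = config$rk.min_lrr)
  counts$retained <- nrow(retained)

  # domain segmentation and extraction per retained receptor
  segs <- list(); ecto <- list(); kin <- list()
  for (i in seq_len(nrow(retained))) {
    rec <- retained[i, , drop = FALSE]
    sp <- predict_signal_peptide(rec)
    mat_start <- if (is.null(sp)) 1L else sp$sp_end + 1L
    mature <- extract_fragment(rec, mat_start, nchar(rec$residues))
    mature$id <- rec$id  # keep the receptor id for downstream leaf labels
    seg <- tm_segments(mature)
    segs[[rec$id]] <- seg
    e <- tryCatch(extract_ectodomain(mature, seg), error = function(err) NULL)
    if (!is.null(e)) { e$id <- rec$id; ecto[[rec$id]] <- e }
    kd <- detect_kinase_domain(mature)
    if (kd$positive) {
      kfrag <- extract_fragment(mature, kd$range[1],
                                min(nchar(mature$residues), kd$range[2]))
      kfrag$id <- rec$id
      kin[[rec$id]] <- kfrag
    }
  }
  bind_sets <- function(lst) {
    if (!length(lst)) return(seq_set("x", "M")[0, ])
    out <- do.call(rbind, lst)
    class(out) <- c("seq_set", "data.frame")
    out
  }
  ecto_set <- bind_sets(ecto)
  kin_set <- bind_sets(kin)

  make_tree <- function(records) {
    if (nrow(records) < 3L) return(NULL)
    aln <- progressive_msa(records, scheme)
    root_tree(nj_tree(msa_distance(aln)), outgroup = NULL)
  }
  trees <- list(full = make_tree(retained), ectodomain = make_tree(ecto_set),
                kinase = make_tree(kin_set))
  clades <- if (!is.null(trees$full))
    clades_by_age(trees$full, config$clade.age_cutoff) else NULL

  if (!is.null(out_dir)) {
    if (nrow(retained))
      write_fasta(retained, file.path(out_dir, "receptors.fasta"))
    for (nm in names(trees)) {
      if (!is.null(trees[[nm]]))
        writeLines(write_newick(trees[[nm]]),
                   file.path(out_dir, paste0("rk_", nm, "_tree.nwk")))
    }
    write_manifest(out_dir, config, counts)
  }

  list(retained = retained, segmentation = segs, ectodomains = ecto_set,
       kinase_domains = kin_set, trees = trees, clades = clades,
       stage_counts = counts, config = config, graph = graph,
       partition = part)
}

#' Evaluate a discovery run against planted truth
#'
#' Members are matched to truth rows by species and exact sequence.
#' Returns per-set recall and precision, the identities of false
#' positives and negatives, and the unannotated fraction among the true
#' positives (the quantity the genomic-rescue stage exists to recover).
#'
#' @param members a [seq_set()] or [candidate_set()] (e.g. the confident
#'   set of [run_peptide_discovery()]).
#' @param truth truth table from the synthetic generator.
#' @return list: `recall`, `precision`, `n_found`, `false_negatives`,
#'   `false_positives`, `unannotated_fraction`.
#' @export
evaluate_candidates <- function(members, truth) {
  if (inherits(members, "candidate_set")) members <- members$members
  stopifnot(inherits(members, "seq_set"))
  key <- function(sp, res) paste(sp, res, sep = "\r")
  truth_keys <- key(truth$species, truth$residues)
  found_keys <- key(members$species, members$residues)
  tp <- truth_keys %in% found_keys
  fp <- !found_keys %in% truth_keys
  recall <- if (nrow(truth)) mean(tp) else NA_real_
  precision <- if (nrow(members)) mean(!fp) else NA_real_
  unannot <- if (any(tp) && "annotated" %in% names(truth))
    mean(!truth$annotated[tp]) else NA_real_
  list(recall = recall, precision = precision, n_found = sum(!fp),
       false_negatives = truth$id[!tp],
       false_positives = members$id[fp],
       unannotated_fraction = unannot)
}
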