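test_that("profile probabilities follow the pseudocount formula", {
  # column counts {A:3, C:1}, alpha = 1, uniform background 0.05
  m <- msa(paste0("s", 1:4), c("A", "A", "A", "C"))
  p <- build_profile(m, alpha = 1)
  expect_equal(unname(p$probs[1, "A"]), (3 + 0.05) / 5)
  expect_equal(unname(p$logodds[1, "A"]), log2(0.61 / 0.05))
  expect_equal(sum(p$probs[1, ]), 1)

  # a uniform column against a uniform background has zero log-odds
  std <- setdiff(AA_ALPHABET, "X")
  mu <- msa(paste0("s", 1:20), std)
  pu <- build_profile(mu, alpha = 1)
  expect_true(all(abs(pu$logodds[1, std]) < 1e-12))

  # single sequence, alpha -> 0: consensus is the sequence itself and
  # log-odds approach log2(1/b) at observed residues
  m1 <- msa("s1", "MKV")
  p1 <- build_profile(m1, alpha = 1e-9)
  expect_equal(p1$consensus, "MKV")
  expect_equal(unname(p1$logodds[1, "M"]), log2(20), tolerance = 1e-6)
})

test_that("low-occupancy columns are dropped and all-gap input errors", {
  m <- msa(paste0("s", 1:5), c("M-K", "M-K", "MAK", "MA-", "M--"))
  # col2 occupancy 0.4 dropped, col1 1.0 kept, col3 0.6 kept
  p <- build_profile(m)
  expect_equal(p$columns, c(1L, 3L))
  expect_error(build_profile(msa(c("a", "b"), c("--", "--"))), "occupancy")
})

test_that("E-value calibration obeys the Gumbel identities", {
  b <- get_small_bench()
  aln <- progressive_msa(b$members)
  prof <- build_profile(aln)
  model <- calibrate_evalue(prof, b$proteome, n_shuffles = 150,
                            rng_seed = 4)
  # P(S >= mu) = 1 - exp(-1)
  expect_equal(evalue_pval(model, model$mu), 1 - exp(-1), tolerance = 1e-9)
  # monotone decreasing in score
  s <- seq(model$mu - 10, model$mu + 40, length.out = 50)
  expect_true(all(diff(evalue(model, s)) <= 0))
  # doubling the database size doubles every E exactly
  expect_equal(evalue(model, s, n_db = 600), 2 * evalue(model, s, n_db = 300))
  # determinism under seed
  model2 <- calibrate_evalue(prof, b$proteome, n_shuffles = 150,
                             rng_seed = 4)
  expect_identical(model, model2)
  # degenerate nulls (all scores equal) raise an error
  same <- seq_set(c("u", "v"), c("AAAAAAAAAA", "AAAAAAAAAA"))
  expect_error(calibrate_evalue(prof, same, n_shuffles = 100), "variance")
})

test_that("profile search finds itself first and members at tiny E", {
  b <- get_small_bench()
  aln <- progressive_msa(b$members[1:3, ])
  prof <- build_profile(aln)
  hits <- profile_search(prof, b$members, rng_seed = 2)
  expect_equal(hits$target[1], hits$target[which.min(hits$evalue)])
  expect_true(hits$target[1] %in% b$members$id[1:3])
  # remaining members found at E <= 1e-5
  others <- setdiff(b$members$id, b$members$id[1:3])
  strong <- hits$target[hits$evalue <= 1e-5]
  expect_true(all(others %in% strong))
  expect_error(profile_search(prof, b$members, calibrate = FALSE),
               "calibration")
})

test_that("iterative search grows monotonically and gains from profiles", {
  spec <- family_spec(n_species = 3, members_per_species = 3,
                      decoys_per_species = 15, rng_seed = 7)
  fam <- generate_family(spec)
  # divergent member: heavy uniform mutation of the ancestor's mature
  # region (fixture parameters chosen to sit below the round-one pairwise
  # cutoff but within reach of the family profile)
  div <- withr::with_seed(7, {
    anc <- strsplit(fam$seed$residues, "")[[1]]
    idx <- 26:length(anc)
    mut <- idx[stats::runif(length(idx)) < 0.55]
    pool <- unique(pepfam:::MATURE_POOL)
    for (i in mut) anc[i] <- sample(setdiff(pool, anc[i]), 1)
    paste(anc, collapse = "")
  })
  div_rec <- seq_set("spX_div", div, species = "spX")
  no_sp_decoys <- fam$decoys[seq(1, nrow(fam$decoys), by = 2), ]
  db <- rbind(fam$members, div_rec, no_sp_decoys)
  class(db) <- c("seq_set", "data.frame")

  r1 <- iterative_search(fam$seed, db, rounds = 1, min_pct = 75,
                         min_score = 50)
  expect_setequal(r1$included$id, fam$members$id)
  expect_false("spX_div" %in% r1$included$id)
  # rounds = 1 equals the plain seed search
  direct <- all_vs_seed_search(db, fam$seed, min_pct = 75, min_score = 50)
  expect_setequal(r1$included$id, unique(direct$query))

  r3 <- iterative_search(fam$seed, db, rounds = 4, min_pct = 75,
                         min_score = 50, inclusion_evalue = 1e-6,
                         rng_seed = 7)
  expect_true("spX_div" %in% r3$included$id)
  expect_true(all(r1$included$id %in% r3$included$id))
  # fixpoint: re-running from the converged set adds nothing
  r3b <- iterative_search(r3$included, db, rounds = 3,
                          min_pct = 75, min_score = 50,
                          inclusion_evalue = 1e-6, rng_seed = 7)
  expect_setequal(r3b$included$id, r3$included$id)
})

test_that("genomic rescue recovers exactly the unannotated members", {
  b <- get_small_bench()
  aln <- progressive_msa(b$members[b$truth$annotated, ])
  prof <- build_profile(aln)
  res <- dna_rescue(b$genomes, b$annotations, prof, rng_seed = 3)
  tru <- b$truth[!b$truth$annotated, ]
  # every unannotated member rescued with its exact genomic interval
  expect_equal(nrow(res$hits), nrow(tru))
  key <- function(d) paste(d$seq_id, d$start, d$end, d$strand)
  expect_setequal(key(res$hits), key(tru))
  expect_setequal(res$records$residues, tru$residues)

  # a genome containing only annotated genes yields zero rescues
  ann_all <- b$truth[, c("seq_id", "start", "end", "strand")]
  ann_all$feature <- "CDS"
  res0 <- dna_rescue(b$genomes, ann_all, prof, rng_seed = 3)
  expect_equal(nrow(res0$hits), 0L)

  # a missing annotation table warns and rescues the annotated copies too
  expect_warning(res_all <- dna_rescue(b$genomes, NULL, prof, rng_seed = 3),
                 "annotation")
  expect_true(all(b$truth$residues %in% res_all$records$residues))
})

test_that("rescue is invariant under reverse-complementing the genome", {
  b <- get_small_bench()
  aln <- progressive_msa(b$members[b$truth$annotated, ])
  prof <- build_profile(aln)
  r1 <- dna_rescue(b$genomes, b$annotations, prof, rng_seed = 3)

  g2 <- b$genomes
  L <- nchar(g2$residues)
  g2$residues <- pepfam:::revcomp_dna(g2$residues)
  ann2 <- b$annotations
  Lmap <- L[match(ann2$seq_id, g2$id)]
  new_start <- Lmap - ann2$end + 1L
  ann2$end <- Lmap - ann2$start + 1L
  ann2$start <- new_start
  ann2$strand <- ifelse(ann2$strand == "+", "-", "+")
  r2 <- dna_rescue(g2, ann2, prof, rng_seed = 3)
  expect_identical(sort(r1$records$residues), sort(r2$records$residues))
  expect_equal(sort(r1$hits$evalue), sort(r2$hits$evalue))
})

test_that("merging deduplicates by species and sequence", {
  a <- seq_set(c("m1", "m2"), c("MKVLLIDE", "MKVLLADE"),
               species = "sp1", source = "annotated")
  d <- seq_set(c("g1", "g2"), c("MKVLLIDE", "MPPPQQQW"),
               species = "sp1", source = "denovo")
  merged <- merge_candidates(a, d)
  expect_equal(merged$stage, "relaxed")
  expect_equal(nrow(merged$members), 3L)
  kept <- merged$members[merged$members$residues == "MKVLLIDE", ]
  expect_equal(kept$source, "annotated")   # annotated provenance wins

  disjoint <- merge_candidates(a, seq_set("g3", "MWWWYYYF",
                                          species = "sp1",
                                          source = "denovo"))
  expect_equal(nrow(disjoint$members), 3L)
})
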