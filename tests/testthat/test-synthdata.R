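test_that("the family generator is bit-reproducible and motif-exact", {
  spec <- family_spec(n_species = 4, members_per_species = 3,
                      decoys_per_species = 8, rng_seed = 5)
  f1 <- generate_family(spec)
  f2 <- generate_family(spec)
  expect_identical(write_fasta(f1$members), write_fasta(f2$members))
  expect_identical(f1, f2)

  # every planted member carries exactly one cysteine pair at the planted
  # spacing, and every member passes the spacing filter
  for (s in f1$members$residues) {
    cpos <- which(strsplit(s, "")[[1]] == "C")
    expect_length(cpos, 2L)
    expect_true(diff(cpos) - 1 >= 9 && diff(cpos) - 1 <= 11)
    expect_true(cysteine_spacing_filter(s))
  }
  # decoys never pass it
  expect_false(any(vapply(f1$decoys$residues, cysteine_spacing_filter,
                          logical(1))))
})

test_that("planted precursors satisfy the package's own SP heuristic", {
  fam <- generate_family(family_spec(n_species = 3, rng_seed = 2))
  for (i in seq_len(nrow(fam$members))) {
    sp <- predict_signal_peptide(fam$members$residues[i])
    expect_false(is.null(sp))
    expect_equal(sp$sp_end, 25L)
    # removing the called SP leaves exactly the truth mature region
    mature <- substr(fam$members$residues[i], sp$sp_end + 1L,
                     nchar(fam$members$residues[i]))
    tru <- fam$truth[i, ]
    expect_equal(mature, substr(tru$residues, tru$mature_start,
                                tru$mature_end))
  }
})

test_that("zero substitution probability reproduces the ancestor", {
  fam <- generate_family(family_spec(n_species = 2, members_per_species = 2,
                                     subst_prob = 0, rng_seed = 3))
  expect_true(all(fam$members$residues == fam$seed$residues))
})

test_that("genome embedding is translation-exact on both strands", {
  b <- get_small_bench()
  for (i in seq_len(nrow(b$truth))) {
    tr <- b$truth[i, ]
    g <- b$genomes[b$genomes$id == tr$seq_id, ]
    cds <- substr(g$residues, tr$start, tr$end)
    if (tr$strand == "-") cds <- pepfam:::revcomp_dna(cds)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_identical(sub("\\*$", "", aa), tr$residues)
  }
  # both strands are exercised
  expect_setequal(unique(b$truth$strand), c("+", "-"))
  # annotation rows exist exactly for annotated members
  ann_key <- paste(b$annotations$seq_id, b$annotations$start)
  tru_key <- paste(b$truth$seq_id, b$truth$start)
  expect_setequal(ann_key, tru_key[b$truth$annotated])
})

test_that("the unannotated quota follows the requested fraction", {
  spec <- family_spec()   # 8 x 3, fraction 0.25
  b <- generate_genomes(generate_family(spec), spec)
  expect_equal(sum(!b$truth$annotated), round(0.25 * 24))
  expect_equal(mean(!b$truth$annotated), 0.25)
  # proteome = annotated members + decoys
  expect_setequal(setdiff(b$truth$id, b$proteome$id),
                  b$truth$id[!b$truth$annotated])

  spec0 <- family_spec(n_species = 2, fraction_unannotated = 0,
                       rng_seed = 4)
  b0 <- generate_genomes(generate_family(spec0), spec0)
  expect_true(all(b0$truth$annotated))

  # 4 members at fraction 0.25: exactly one member missing overall
  spec4 <- family_spec(n_species = 1, members_per_species = 4,
                       fraction_unannotated = 0.25, rng_seed = 4)
  b4 <- generate_genomes(generate_family(spec4), spec4)
  expect_equal(sum(!b4$truth$annotated), 1L)
})

test_that("expression tables separate family from decoys as specified", {
  fam <- generate_family(family_spec(n_species = 4, members_per_species = 5,
                                     decoys_per_species = 50, rng_seed = 1))
  e0 <- generate_expression(fam$truth, fam$decoys$id, induction_log2fc = 4,
                            noise_sd = 0, rng_seed = 1)
  expect_true(all(e0$flg22_90min[e0$id %in% fam$truth$id] == 4))
  expect_true(all(e0$flg22_90min[e0$id %in% fam$decoys$id] == 0))
  expect_error(generate_expression(fam$truth, fam$decoys$id,
                                   noise_sd = -1), "noise_sd")
  expect_error(generate_expression(fam$truth, fam$decoys$id,
                                   induction_log2fc = 0), "induction")

  # 20 family + 200 decoys, induction 4, noise 0.5: family ranks top 25
  e <- generate_expression(fam$truth, fam$decoys$id, induction_log2fc = 4,
                           noise_sd = 0.5, rng_seed = 1)
  ord <- e$id[order(-e$flg22_90min)]
  expect_true(all(fam$truth$id %in% ord[1:25]))
})

test_that("planted receptor kinases satisfy their own detectors", {
  rk <- get_rk_bench()
  expect_true(all(nchar(rk$members$residues) >= 500))
  for (i in seq_len(nrow(rk$members))) {
    s <- rk$members$residues[i]
    expect_gte(detect_lrr(s)$count, rk$truth$n_lrr[i] - 1L)
    kd <- detect_kinase_domain(s)
    expect_true(kd$positive)
    expect_equal(kd$score, 4L)
  }
  # determinism
  rk2 <- generate_rk_family(n_species = 4, members_per_species = 2,
                            n_lrr = 12, n_decoys = 100, rng_seed = 1)
  expect_identical(rk$members, rk2$members)
})
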