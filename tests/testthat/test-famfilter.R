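test_that("length filters are inclusive at the bounds", {
  recs <- seq_set(paste0("p", 1:4),
                  vapply(c(299, 300, 301, 499), random_protein,
                         character(1)))
  expect_setequal(length_filter(recs, max_len = 300)$id, c("p1", "p2"))
  expect_setequal(length_filter(recs, min_len = 500)$id, character(0))
  expect_setequal(length_filter(recs, min_len = 300, max_len = 301)$id,
                  c("p2", "p3"))
  expect_error(length_filter(recs, min_len = 10, max_len = 5), "min_len")
})

test_that("the cysteine-spacing filter matches the regex oracle exactly", {
  pad <- function(core) paste0("MKLA", core, "GSDE")
  expect_true(cysteine_spacing_filter(pad(paste0(
    "C", random_protein(9, pool = c("A", "D", "E")), "C"))))
  expect_false(cysteine_spacing_filter("MKLACGSDE"))       # one cysteine
  expect_false(cysteine_spacing_filter(random_protein(50,
    pool = setdiff(AA_ALPHABET, c("C", "X")))))

  # intervening-cysteine semantics: C at 1, 5 and 12; the 1..12 pair has
  # spacing 10 but a cysteine in between
  s <- "CDDDCDDDDDDC"
  expect_false(cysteine_spacing_filter(s))
  expect_true(cysteine_spacing_filter(s, count_intervening_cys = TRUE))
  expect_false(cys_regex_oracle(s))

  set.seed(31)
  pool <- c(rep(setdiff(AA_ALPHABET, "X"), 1), rep("C", 4))  # C-enriched
  for (k in 1:2000) {
    s <- random_protein(sample(15:90, 1), pool = pool)
    expect_identical(cysteine_spacing_filter(s), cys_regex_oracle(s))
  }
})

test_that("confident refinement is a subset, idempotent and logs
           exclusions", {
  b <- get_small_bench()
  relaxed <- candidate_set(b$members, "relaxed")
  conf <- refine_confident(relaxed)
  expect_equal(conf$stage, "confident")
  expect_setequal(conf$members$id, relaxed$members$id)  # all motif-positive

  again <- refine_confident(candidate_set(conf$members, "relaxed"))
  expect_setequal(again$members$id, conf$members$id)

  drop1 <- refine_confident(relaxed, exclusions = b$members$id[1])
  expect_equal(nrow(drop1$members), nrow(b$members) - 1L)
  expect_equal(drop1$excluded, b$members$id[1])
  expect_warning(refine_confident(relaxed, exclusions = "ghost"), "ghost")

  # a decoy mixed into the relaxed set is removed by the motif filter
  mixed <- candidate_set(rbind(b$members, b$proteome[
    b$proteome$source == "decoy", ][1:5, ]), "relaxed")
  conf2 <- refine_confident(mixed)
  expect_setequal(conf2$members$id, b$members$id)
})

test_that("signal-peptide calls require the engineered architecture", {
  expect_null(predict_signal_peptide(paste(rep("D", 60), collapse = "")))
  # basic n-region but no hydrophobic core
  expect_null(predict_signal_peptide(paste0("MKK",
    random_protein(50, pool = c("D", "E", "N", "Q")))))
  b <- get_small_bench()
  calls <- lapply(b$members$residues, predict_signal_peptide)
  expect_true(all(!vapply(calls, is.null, logical(1))))
  expect_true(all(vapply(calls, `[[`, numeric(1), "sp_end") == 25))
})

test_that("hydropathy segmentation recovers planted membrane spans", {
  allI <- paste(rep("I", 40), collapse = "")
  seg <- tm_segments(allI)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$segment, "transmembrane")
  expect_equal(c(seg$start, seg$end), c(1L, 40L))

  # soluble planted peptides have no TM span in their mature region
  # (segmentation is defined on SP-removed sequences: an SP hydrophobic
  # core is itself a membrane-like stretch)
  b <- get_small_bench()
  n_tm <- vapply(seq_len(nrow(b$members)), function(i) {
    tru <- b$truth[i, ]
    mature <- substr(b$members$residues[i], tru$mature_start,
                     tru$mature_end)
    sum(tm_segments(mature)$segment == "transmembrane")
  }, numeric(1))
  expect_true(all(n_tm == 0))

  rk <- get_rk_bench()
  for (i in seq_len(nrow(rk$members))) {
    r <- rk$members[i, , drop = FALSE]
    sp <- predict_signal_peptide(r)
    mature <- extract_fragment(r, sp$sp_end + 1L, nchar(r$residues))
    seg <- tm_segments(mature)
    tm <- seg[seg$segment == "transmembrane", ]
    tru <- rk$truth[i, ]
    expect_equal(nrow(tm), 1L)
    expect_lte(abs(tm$start + sp$sp_end - tru$tm_start), 3)
    expect_lte(abs(tm$end + sp$sp_end - tru$tm_end), 3)
    # segments are non-overlapping and cover the sequence
    expect_equal(seg$start[1], 1L)
    expect_equal(seg$end[nrow(seg)], nchar(mature$residues))
    expect_true(all(seg$start[-1] == utils::head(seg$end, -1) + 1L))
  }
})

test_that("the longest extracellular segment is the ectodomain", {
  seg <- data.frame(segment = c("extracellular", "transmembrane",
                                "extracellular"),
                    start = c(1L, 401L, 421L), end = c(400L, 420L, 455L))
  s <- random_protein(455)
  ecto <- extract_ectodomain(s, seg)
  expect_equal(nchar(ecto$residues), 400L)
  expect_equal(ecto$residues, substr(s, 1, 400))

  # tie broken N-terminal-most
  seg_tie <- data.frame(segment = c("extracellular", "transmembrane",
                                    "extracellular"),
                        start = c(1L, 21L, 41L), end = c(20L, 40L, 60L))
  ecto_tie <- extract_ectodomain(random_protein(60), seg_tie)
  expect_match(ecto_tie$id, "_1-20$")

  allI <- paste(rep("I", 40), collapse = "")
  expect_error(extract_ectodomain(allI, tm_segments(allI)),
               "extracellular")

  rk <- get_rk_bench()
  r <- rk$members[1, , drop = FALSE]
  sp <- predict_signal_peptide(r)
  mature <- extract_fragment(r, sp$sp_end + 1L, nchar(r$residues))
  ecto <- extract_ectodomain(mature, tm_segments(mature))
  expect_gte(detect_lrr(ecto$residues)$count, rk$truth$n_lrr[1] - 1L)
})

test_that("kinase and LRR detectors separate structure from noise", {
  rk <- get_rk_bench()
  s <- rk$members$residues[1]
  kd <- detect_kinase_domain(s)
  expect_true(kd$positive)
  expect_equal(kd$score, 4L)

  b <- get_small_bench()
  expect_false(any(vapply(b$members$residues, function(x)
    detect_kinase_domain(x)$positive, logical(1))))

  # shuffling destroys the motif order in nearly all cases
  set.seed(17)
  shuf_pos <- vapply(1:100, function(i) {
    detect_kinase_domain(pepfam:::shuffle_residues(s))$positive
  }, logical(1))
  expect_gte(sum(!shuf_pos), 95)

  # tandem exact LRR consensus
  unit <- "LSTLDLSSNKL"
  expect_gte(detect_lrr(paste(rep(unit, 6), collapse = ""))$count, 5)
  # random sequences of the same length at background composition rarely
  # score (a shuffle of the repeat itself keeps its extreme leucine
  # content, which is signal, not noise)
  set.seed(18)
  rand_counts <- vapply(1:100, function(i)
    detect_lrr(random_protein(66))$count, numeric(1))
  expect_gte(mean(rand_counts <= 1), 0.95)
})

test_that("the receptor filter keeps exactly the planted receptors", {
  rk <- get_rk_bench()
  pool <- rbind(rk$members, rk$decoys)
  class(pool) <- c("seq_set", "data.frame")
  kept <- rk_filter(pool)
  expect_setequal(kept$id, rk$members$id)
})

test_that("fragment extraction is coordinate-exact", {
  s <- random_protein(70)
  frag <- extract_fragment(s, 48, 70)
  expect_equal(nchar(frag$residues), 23L)   # the C-terminal 23 residues
  expect_equal(frag$residues, substr(s, 48, 70))
  expect_equal(nchar(extract_fragment(s, 10, 10)$residues), 1L)
  expect_equal(extract_fragment(s, 1, 70)$residues, s)
  expect_error(extract_fragment(s, 0, 10), "out of bounds")
  expect_error(extract_fragment(s, 60, 71), "out of bounds")
})
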