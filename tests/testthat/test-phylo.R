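test_that("alignment distances follow the stated models", {
  m <- msa(c("a", "b"), c("MKVL", "MKVL"))
  D <- msa_distance(m, model = "p")
  expect_equal(unname(D["a", "b"]), 0)

  half <- msa(c("a", "b"), c("MKVLMKVL", "MKVLWYFH"))
  expect_equal(unname(msa_distance(half, model = "p")["a", "b"]), 0.5)
  expect_equal(unname(msa_distance(half, model = "poisson")["a", "b"]),
               log(2))

  # gaps and X are excluded pairwise
  gx <- msa(c("a", "b"), c("MK-LX", "MKVLW"))
  expect_equal(unname(msa_distance(gx, model = "p")["a", "b"]), 0)
  expect_error(msa_distance(msa(c("a", "b"), c("MK--", "--VL"))),
               "a.*b|shared")

  set.seed(2)
  r <- msa(paste0("s", 1:5),
           vapply(1:5, function(i) random_protein(30), character(1)))
  Dr <- msa_distance(r)
  expect_equal(unclass(Dr)[, ], t(unclass(Dr)[, ]))
  expect_true(all(diag(unclass(Dr)) == 0))
})

test_that("neighbor joining inverts additive matrices exactly", {
  # ((a:1,b:2):1,(c:3,d:4)) by hand
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"),
                              c("a", "b", "c", "d")))
  tr <- nj_tree(D)
  expect_equal(phangorn::RF.dist(tr, ape::read.tree(
    text = "((a:1,b:2):1,(c:3,d:4):0);")), 0)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)

  # three taxa: closed-form star resolution
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(D3)
  bl <- stats::setNames(tr3$edge.length, tr3$tip.label[tr3$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3|symmetric")
  Dasym <- D; Dasym[1, 2] <- 99
  expect_error(nj_tree(Dasym), "symmetric")

  set.seed(8)
  for (k in 1:10) {
    n <- sample(5:16, 1)
    ref <- ape::rtree(n, br = function(x) stats::runif(x, 0.1, 1))
    Dk <- ape::cophenetic.phylo(ref)
    Dk <- Dk[sort(rownames(Dk)), sort(rownames(Dk))]
    mine <- nj_tree(Dk)
    expect_equal(phangorn::RF.dist(ape::unroot(ref), mine), 0)
    expect_lt(max(abs(ape::cophenetic.phylo(mine)[rownames(Dk),
                                                  colnames(Dk)] - Dk)),
              1e-9)
    # cross-check against the established NJ implementation
    expect_equal(phangorn::RF.dist(mine, ape::nj(Dk)), 0)
  }
})

test_that("rooting preserves path lengths and splits on the outgroup", {
  set.seed(4)
  tr <- ape::rtree(8, br = function(x) stats::runif(x, 0.2, 1))
  tr <- ape::unroot(tr)
  D0 <- ape::cophenetic.phylo(tr)
  rooted <- root_tree(tr, outgroup = tr$tip.label[1])
  expect_true(ape::is.rooted(rooted))
  expect_equal(ape::cophenetic.phylo(rooted)[rownames(D0), colnames(D0)],
               D0, tolerance = 1e-9)
  # the root separates the outgroup from everything else
  og <- which(rooted$tip.label == tr$tip.label[1])
  root_children <- rooted$edge[rooted$edge[, 1] ==
                                 length(rooted$tip.label) + 1L, 2]
  expect_true(og %in% root_children)
  expect_error(root_tree(tr, outgroup = "absent"), "absent")

  # midpoint of ((a:1,b:1):0,c:4) lies on c's pendant edge
  mid <- root_tree(ape::read.tree(text = "((a:1,b:1):0,c:4);"))
  dm <- ape::cophenetic.phylo(mid)
  depth <- ape::node.depth.edgelength(mid)
  expect_equal(depth[which(mid$tip.label == "c")], 2.5)
  expect_equal(depth[which(mid$tip.label == "a")], 2.5)
})

test_that("age-cutoff clades partition the leaves and coarsen", {
  cat_tr <- ape::read.tree(
    text = "((((a:1,b:1):1,c:1):1,d:1):1,e:1);")
  cl <- clades_by_age(cat_tr, 1.5)
  members <- attr(cl, "members")
  expect_setequal(vapply(members, paste, character(1), collapse = ","),
                  c("a,b", "c", "d", "e"))

  # cutoff 0: singletons; cutoff >= height: one clade
  cl0 <- clades_by_age(cat_tr, 0)
  expect_equal(sort(unlist(attr(cl0, "members"))), sort(cat_tr$tip.label))
  expect_true(all(cl0$n_members == 1))
  clA <- clades_by_age(cat_tr, 100)
  expect_equal(nrow(clA), 1L)
  expect_setequal(attr(clA, "members")[[1]], cat_tr$tip.label)

  # partition property + monotone coarsening on a random tree
  set.seed(5)
  rt <- ape::rtree(12)
  cuts <- c(0, 0.5, 1, 2, 100)
  prev <- NULL
  for (ct in cuts) {
    cl <- clades_by_age(rt, ct)
    mem <- attr(cl, "members")
    expect_setequal(unlist(mem), rt$tip.label)
    expect_equal(sum(lengths(mem)), length(rt$tip.label))
    if (!is.null(prev)) {
      # every earlier clade is contained in exactly one current clade
      for (p in prev) {
        hits <- vapply(mem, function(mm) all(p %in% mm), logical(1))
        expect_equal(sum(hits), 1L)
      }
    }
    prev <- mem
  }
  expect_error(clades_by_age(ape::unroot(ape::rtree(5)), 1), "rooted")
})

test_that("bootstrap support is certain for clean block structure", {
  blockA <- "MKVLMKVLMKVLMKVL"
  blockB <- "WYFHWYFHWYFHWYFH"
  mut <- function(s, i, to) { substr(s, i, i) <- to; s }
  aln <- msa(paste0("s", 1:8),
             c(blockA, mut(blockA, 1, "I"), mut(blockA, 5, "I"),
               mut(blockA, 9, "I"),
               blockB, mut(blockB, 2, "D"), mut(blockB, 6, "D"),
               mut(blockB, 10, "D")))
  bs <- bootstrap_support(aln, n_replicates = 50, rng_seed = 2)
  expect_true(all(bs$support >= 0 & bs$support <= 1))
  # the A-vs-B bipartition is in every replicate
  mrca <- ape::getMRCA(bs$tree, paste0("s", 1:4))
  n_tip <- length(bs$tree$tip.label)
  if (mrca == n_tip + 1L) mrca <- ape::getMRCA(bs$tree, paste0("s", 5:8))
  expect_equal(unname(bs$support[mrca - n_tip]), 1)

  one <- bootstrap_support(aln, n_replicates = 1, rng_seed = 3)
  expect_true(all(one$support %in% c(0, 1)))
  expect_error(bootstrap_support(msa(c("a", "b", "c"),
                                     c("MK", "MK", "MK")), 10), "4")
})

test_that("logo matrices obey the closed forms and trimming boundary", {
  aln <- msa(paste0("s", 1:20), rep("A", 20))
  lg <- sequence_logo(aln)
  expect_equal(lg$ic, log2(20))

  std <- setdiff(AA_ALPHABET, "X")
  uni <- sequence_logo(msa(paste0("s", 1:20), std))
  expect_equal(uni$ic, 0)

  # occupancy exactly 5% (1 of 20) is retained: strict "less than"
  rows <- c(paste0("AK"), rep("A-", 19))
  lg5 <- sequence_logo(msa(paste0("s", 1:20), rows), occupancy_min = 0.05)
  expect_equal(lg5$columns, c(1L, 2L))
  # below the threshold (1 of 25) the column is trimmed
  rows25 <- c(paste0("AK"), rep("A-", 24))
  lg4 <- sequence_logo(msa(paste0("s", 1:25), rows25), occupancy_min = 0.05)
  expect_equal(lg4$columns, 1L)
  expect_error(sequence_logo(msa(c("a", "b"), c("--", "--"))), "trimmed")

  # trimming is idempotent
  trimmed <- pepfam:::trim_msa_occupancy(msa(paste0("s", 1:25), rows25))
  expect_identical(pepfam:::trim_msa_occupancy(trimmed), trimmed)
  expect_true(all(lg5$ic >= 0 & lg5$ic <= log2(20)))
})
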