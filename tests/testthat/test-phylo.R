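test_that("complete deletion keeps exactly the gap-free columns", {
  aln <- alignment(c(a = "AC-E", b = "ACDE"))
  cd <- complete_deletion(aln)
  expect_equal(n_columns(cd), 3L)
  expect_equal(aln_strings(cd), c(a = "ACE", b = "ACE"))

  gapless <- alignment(c(a = "ACDE", b = "MCDE"))
  expect_equal(aln_strings(complete_deletion(gapless)), aln_strings(gapless))

  expect_error(complete_deletion(alignment(c(a = "-A", b = "A-"))),
               "degenerate")
})

test_that("p and Poisson distances match hand values; X always mismatches", {
  aln <- alignment(c(x = "ACDE", y = "ACDF"))
  expect_equal(distance_matrix(aln, "p")["x", "y"], 0.25)
  expect_equal(distance_matrix(aln, "poisson")["x", "y"], -log(0.75),
               tolerance = 1e-12)

  same <- alignment(c(x = "MKVW", y = "MKVW"))
  expect_equal(distance_matrix(same, "p")["x", "y"], 0)

  withx <- alignment(c(x = "XKVW", y = "XKVW"))
  expect_equal(distance_matrix(withx, "p")["x", "y"], 0.25)

  sat <- alignment(c(x = "AAAA", y = "CCCC"))
  expect_error(distance_matrix(sat, "poisson"), "saturated pair.*'x', 'y'")
  expect_equal(distance_matrix(sat, "p")["x", "y"], 1)
})

test_that("Poisson correction dominates p-distance pointwise", {
  fam <- simulate_family(n_per_clade = 4, n_sites = 120, seed = 11)
  dp <- distance_matrix(fam$alignment, "p")
  dpois <- distance_matrix(fam$alignment, "poisson")
  expect_true(all(dpois >= dp))
  expect_true(all(abs(dpois - t(dpois)) < 1e-12))
  expect_true(all(diag(dpois) == 0))
})

test_that("NJ solves the 3-taxon star in closed form", {
  dm <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3 taxa")
})

test_that("NJ recovers additive 4-taxon trees exactly", {
  # generating tree ((A:1,B:2):1,(C:3,D:4))
  lab <- c("A", "B", "C", "D")
  d4 <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d4["A", "B"] <- 3; d4["A", "C"] <- 5; d4["A", "D"] <- 6
  d4["B", "C"] <- 6; d4["B", "D"] <- 7; d4["C", "D"] <- 7
  d4 <- pmax(d4, t(d4))
  tr <- nj_tree(d4)
  expect_equal(unname(ape::cophenetic.phylo(tr)[lab, lab]), unname(d4),
               tolerance = 1e-10)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(truth), tr), structure(0),
               ignore_attr = TRUE)
})

test_that("NJ is invariant to input label order", {
  ad <- random_additive(6, seed = 42)
  perm <- sample(rownames(ad$dm))
  t1 <- nj_tree(ad$dm)
  t2 <- nj_tree(ad$dm[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), structure(0), ignore_attr = TRUE)
  lab <- rownames(ad$dm)
  expect_equal(ape::cophenetic.phylo(t1)[lab, lab],
               ape::cophenetic.phylo(t2)[lab, lab], tolerance = 1e-10)
})

test_that("NJ equals the brute-force least-squares tree on additive matrices", {
  for (case in list(c(n = 5, seed = 1), c(n = 5, seed = 2),
                    c(n = 6, seed = 3), c(n = 6, seed = 4))) {
    ad <- random_additive(case[["n"]], seed = case[["seed"]])
    tr <- nj_tree(ad$dm)
    ls <- oracle_ls_tree(ad$dm)
    expect_lt(ls$rss, 1e-12)  # generating tree is attainable
    expect_equal(ape::dist.topo(tr, ls$tree), structure(0), ignore_attr = TRUE)
    lab <- rownames(ad$dm)
    expect_equal(ape::cophenetic.phylo(tr)[lab, lab], ad$dm, tolerance = 1e-8)
    # cross-check against an independent NJ implementation
    expect_equal(ape::dist.topo(tr, ape::nj(as.dist(ad$dm))),
                 structure(0), ignore_attr = TRUE)
  }
})

test_that("bootstrap gives full support to an overwhelming split", {
  # two clades separated by 50 fixed differences
  blockA <- strrep("A", 50); blockC <- strrep("C", 50); shared <- strrep("G", 30)
  aln <- alignment(c(
    a1 = paste0(blockA, shared), a2 = paste0(blockA, shared),
    b1 = paste0(blockC, shared), b2 = paste0(blockC, shared),
    b3 = paste0(blockC, shared)
  ))
  tr <- bootstrap_support(aln, n_reps = 100, seed = 5, model = "p")
  expect_true(all(node_supports(tr) == 100))
})

test_that("bootstrap is reproducible under a seed and {0,100} at one replicate", {
  fam <- simulate_family(n_per_clade = 3, n_sites = 80, seed = 9)
  t1 <- bootstrap_support(fam$alignment, n_reps = 30, seed = 4)
  t2 <- bootstrap_support(fam$alignment, n_reps = 30, seed = 4)
  expect_identical(write_newick(t1), write_newick(t2))
  s <- node_supports(t1)
  expect_true(all(s >= 0 & s <= 100))

  t3 <- bootstrap_support(fam$alignment, n_reps = 1, seed = 4)
  expect_true(all(node_supports(t3) %in% c(0, 100)))
})

test_that("pairwise identity/similarity match hand alignment and are symmetric", {
  s <- tidy(align_pair("MKV", "MRI"))
  expect_equal(s$identity, 100 / 3, tolerance = 1e-9)   # only M identical
  expect_equal(s$similarity, 100)                       # K~R (QHRK), V~I (MILV)
  expect_equal(s$aligned_pairs, 3L)

  same <- tidy(align_pair("MKVW", "MKVW"))
  expect_equal(same$identity, 100)
  expect_equal(same$similarity, 100)

  a <- "MKVLLYWDDAGGR"; b <- "MKILFYWDEGGR"
  expect_equal(tidy(align_pair(a, b))[c("identity", "similarity")],
               tidy(align_pair(b, a))[c("identity", "similarity")])
  expect_error(align_pair("", "MK"), "non-empty")
})

test_that("identity never exceeds similarity and both lie in [0, 100]", {
  set.seed(3)
  for (i in 1:10) {
    recs <- random_seqs(2, len_range = c(10, 30), seed = i + 100)
    s <- tidy(align_pair(gsub("X", "A", recs$seq[1]), gsub("X", "A", recs$seq[2])))
    expect_lte(s$identity, s$similarity)
    expect_gte(s$identity, 0)
    expect_lte(s$similarity, 100)
  }
})

test_that("branch rates and rate ratios follow the calibration arithmetic", {
  r <- branch_rate(0.5, 50)
  expect_equal(r$rate, 0.01)
  expect_equal(rate_ratio(r, r), 1)
  # a branch twice as long over a tenfold shorter time: 20x faster
  expect_equal(rate_ratio(branch_rate(2, 50), branch_rate(1, 500)), 20)
  expect_error(branch_rate(0.5, 0), "time must be > 0")
})
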