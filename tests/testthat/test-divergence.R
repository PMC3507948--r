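mk_aln <- function(cols_a, cols_b, n_a = 5, n_b = 5) {
  # build an alignment whose clade members repeat the given column strings
  strings <- c(
    setNames(rep(cols_a, n_a), sprintf("a%d", seq_len(n_a))),
    setNames(rep(cols_b, n_b), sprintf("b%d", seq_len(n_b)))
  )
  alignment(strings)
}

test_that("clade consensus handles ties, gaps and all-gap columns", {
  aln <- alignment(c(m1 = "AAC-", m2 = "ACC-", m3 = "CAG-", m4 = "CAGT"))
  expect_equal(clade_consensus(aln, c("m1", "m2", "m3", "m4"), 2)$residue, "A")
  cc <- clade_consensus(aln, c("m1", "m2"), 2)  # A vs C tie -> A
  expect_equal(cc$residue, "A")
  expect_equal(cc$freq, 0.5)
  gapped <- clade_consensus(aln, c("m1", "m2", "m3"), 4)
  expect_true(is.na(gapped$residue))
  expect_error(clade_consensus(aln, "m1", 9), "outside")
  expect_error(clade_consensus(aln, "zz", 1), "not in alignment")
})

test_that("a perfect 5+5 split scores p = 2/252 in exact mode", {
  aln <- mk_aln("VCD", "LCD")
  pr <- type2_site_scores(aln, sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  expect_true(attr(pr, "exact"))
  expect_equal(pr$p[1], 2 / 252, tolerance = 1e-12)
  expect_equal(pr$score[1], -log10(2 / 252), tolerance = 1e-9)
  # identical columns carry no signal
  expect_equal(pr$stat[2:3], c(0, 0))
  expect_equal(pr$p[2:3], c(1, 1))
  expect_equal(pr$score[2:3], c(0, 0))
})

test_that("type-II scores are invariant to clade swap and member order", {
  fam <- simulate_family(n_per_clade = 4, n_sites = 40, frac_type2 = 0.2,
                         seed = 21)
  aln <- fam$alignment
  p1 <- type2_site_scores(aln, fam$truth$clade_a, fam$truth$clade_b)
  p2 <- type2_site_scores(aln, fam$truth$clade_b, fam$truth$clade_a)
  expect_equal(p1$p, p2$p, tolerance = 1e-12)
  expect_equal(p1$stat, p2$stat, tolerance = 1e-12)

  shuf <- alignment(sample(aln_strings(aln)))
  p3 <- type2_site_scores(shuf, fam$truth$clade_a, fam$truth$clade_b)
  expect_equal(p1$p, p3$p, tolerance = 1e-12)
})

test_that("exact-mode p agrees with the sampled estimate within 3 SE", {
  aln <- mk_aln("VACDE", "LACDF", n_a = 4, n_b = 4)  # C(8,4) = 70: exact
  exact <- type2_site_scores(aln, sprintf("a%d", 1:4), sprintf("b%d", 1:4))
  expect_true(attr(exact, "exact"))
  sampled <- type2_site_scores(aln, sprintf("a%d", 1:4), sprintf("b%d", 1:4),
                               n_perm = 9999, seed = 7, exact_limit = 1)
  expect_false(attr(sampled, "exact"))
  se <- sqrt(exact$p * (1 - exact$p) / 9999)
  expect_true(all(abs(sampled$p - exact$p) <= 3 * se + 2e-4))
})

test_that("sampled runs require a seed and are reproducible given one", {
  aln <- mk_aln("VCD", "LCD")
  expect_error(
    type2_site_scores(aln, sprintf("a%d", 1:5), sprintf("b%d", 1:5),
                      exact_limit = 1),
    "seed is required"
  )
  s1 <- type2_site_scores(aln, sprintf("a%d", 1:5), sprintf("b%d", 1:5),
                          n_perm = 499, seed = 3, exact_limit = 1)
  s2 <- type2_site_scores(aln, sprintf("a%d", 1:5), sprintf("b%d", 1:5),
                          n_perm = 499, seed = 3, exact_limit = 1)
  expect_identical(s1$p, s2$p)
})

test_that("divergent_sites applies the score>threshold (p<10^-threshold) cut", {
  fam <- simulate_family(n_per_clade = 5, n_sites = 60, frac_type2 = 0.1,
                         clade_sub_prob = 0, seed = 2)
  pr <- type2_site_scores(fam$alignment, fam$truth$clade_a, fam$truth$clade_b)
  hits <- divergent_sites(pr, threshold = 2)
  expect_true(all(hits$p < 10^-2))
  expect_setequal(hits$column,
                  pr$column[!is.na(pr$p) & pr$p < 10^-2])
})

test_that("reference positions map through gaps to alignment columns", {
  aln <- alignment(c(r = "M-KV", q = "MAKV"))
  expect_equal(map_reference_positions(aln, "r", 1:3), c(1L, 3L, 4L))
  expect_equal(map_reference_positions(aln, "q", 2), 2L)
  expect_error(map_reference_positions(aln, "r", 0), "outside")
  expect_error(map_reference_positions(aln, "r", 4), "outside")
})

test_that("scorecards count present residues and flag inconsistent references", {
  aln <- alignment(c(ref = "MKVDW", qry = "MKADW", far = "MAADW"))
  dset <- diagnostic_set(c(2, 3, 5), c("K", "V", "W"), "ref")
  sc <- diagnostic_scorecard(aln, dset, "qry")
  expect_equal(attr(sc, "n_present"), 2L)
  expect_equal(sc$present, c(TRUE, FALSE, TRUE))
  expect_equal(glance(sc)$n_present, 2L)

  self <- diagnostic_scorecard(aln, dset, "ref")
  expect_equal(attr(self, "n_present"), 3L)  # reference scores full marks

  bad <- diagnostic_set(c(2, 3), c("K", "L"), "ref")  # ref has V at 3, not L
  expect_warning(sc2 <- diagnostic_scorecard(aln, bad, "qry"),
                 "disagrees.*position\\(s\\) 3")
  expect_false(sc2$reference_consistent[2])
  expect_equal(attr(sc2, "n_total"), 2L)
})

test_that("windowed enrichment matches the closed form on the worked case", {
  res <- neighborhood_enrichment(10, critical = 5, predicted = c(4, 9),
                                 window = 1)
  expect_equal(res$k_window, 3L)
  expect_equal(res$x_overlap, 1L)
  expect_equal(res$p, 24 / 45, tolerance = 1e-12)

  off <- neighborhood_enrichment(20, critical = 1, predicted = c(10, 15),
                                 window = 1)
  expect_equal(off$x_overlap, 0L)
  expect_equal(off$p, 1)
  expect_error(neighborhood_enrichment(10, critical = 11, predicted = 1),
               "outside")
})

test_that("hypergeometric enrichment equals brute-force enumeration (N <= 12)", {
  cases <- list(
    list(N = 10, critical = 5, predicted = c(4, 9), w = 1),
    list(N = 12, critical = c(2, 3, 9), predicted = c(1, 4, 8, 10), w = 1),
    list(N = 12, critical = c(4, 8), predicted = c(4, 8, 9), w = 0),
    list(N = 11, critical = c(1, 2), predicted = c(2, 3, 5, 7), w = 2),
    list(N = 9, critical = c(5, 6), predicted = c(5, 6), w = 1)
  )
  for (cs in cases) {
    got <- neighborhood_enrichment(cs$N, cs$critical, cs$predicted, cs$w)$p
    want <- oracle_enrichment_p(cs$N, cs$critical, cs$predicted, cs$w)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("window unions do not double-count clustered critical residues", {
  # two critical residues 1 apart: windows overlap, union is 4 not 6
  res <- neighborhood_enrichment(20, critical = c(10, 11), predicted = 1,
                                 window = 1)
  expect_equal(res$k_window, 4L)
})
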