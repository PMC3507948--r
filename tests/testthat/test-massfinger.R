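test_that("tryptic digest applies the K/R-not-before-P rule", {
  expect_equal(tryptic_digest("GGAGG")$sequence, "GGAGG")
  d <- tryptic_digest("AKRPGR")
  expect_equal(d$sequence, c("AK", "RPGR"))
  expect_equal(d$start, c(1L, 3L))
  expect_equal(d$end, c(2L, 6L))
  d1 <- tryptic_digest("MKAKG", max_missed = 1)
  expect_setequal(d1$sequence, c("MK", "AK", "G", "MKAK", "AKG"))
})

test_that("digest agrees with the pattern-scan oracle on fuzzed proteins", {
  set.seed(14)
  aa <- c("A", "G", "K", "R", "P", "M", "Q", "S", "W")
  for (i in 1:12) {
    prot <- paste(sample(aa, sample(8:30, 1), replace = TRUE), collapse = "")
    for (mm in 0:2) {
      got <- tryptic_digest(prot, max_missed = mm)
      got <- got[order(got$start, got$end), ]
      want <- oracle_digest(prot, mm)
      expect_equal(got$start, want$start, info = prot)
      expect_equal(got$end, want$end, info = prot)
      expect_equal(got$sequence, want$sequence, info = prot)
    }
  }
})

test_that("zero-missed digests partition the parent exactly", {
  set.seed(15)
  aa <- c("A", "G", "K", "R", "P", "M", "L", "E")
  for (i in 1:10) {
    prot <- paste(sample(aa, sample(10:40, 1), replace = TRUE), collapse = "")
    d <- tryptic_digest(prot, max_missed = 0)
    expect_equal(paste(d$sequence, collapse = ""), prot)
    expect_equal(d$start[-1], d$end[-length(d$end)] + 1L)
    expect_equal(d$start[1], 1L)
    expect_equal(d$end[nrow(d)], nchar(prot))
  }
})

test_that("every residue mass constant matches the elemental oracle", {
  for (r in names(RESIDUE_FORMULA)) {
    expect_equal(mono_mass(r), oracle_peptide_mono(r), tolerance = 1e-4,
                 info = paste("mono", r))
    expect_equal(average_mw(r) * 1000, oracle_protein_avg(r), tolerance = 0.01,
                 info = paste("avg", r))
  }
  expect_equal(mono_mass("GG"), 132.0535, tolerance = 1e-4)
  expect_equal(mono_mass("GG"), oracle_peptide_mono("GG"), tolerance = 1e-4)
  expect_equal(average_mw("G") * 1000, 75.07, tolerance = 0.01)
})

test_that("mass additivity (condensation identity) holds on fuzzed peptides", {
  set.seed(16)
  aa <- setdiff(names(RESIDUE_FORMULA), character(0))
  for (i in 1:15) {
    a <- paste(sample(aa, sample(1:12, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(1:12, 1), replace = TRUE), collapse = "")
    expect_equal(mono_mass(paste0(a, b)),
                 mono_mass(a) + mono_mass(b) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("masses are undefined for X or empty input and grow monotonically", {
  expect_error(mono_mass("GXG"), "mass undefined.*'X'")
  expect_error(mono_mass(""), "empty")
  expect_error(average_mw(""), "empty")
  expect_gt(average_mw("GG"), average_mw("G"))
  expect_gt(mono_mass("GGA"), mono_mass("GG"))
})

test_that("modification forms respect admissibility rules and deltas", {
  # no Q start, no M, start > 1: only the unmodified form
  d <- tibble::tibble(parent_id = "p", start = 5L, end = 7L,
                      sequence = "AGA", missed = 0L)
  f <- modification_forms(d)
  expect_equal(nrow(f), 1L)
  expect_equal(f$mods, "")

  # Q-start peptide gains a pyroGlu form at -17.026549 Da
  dq <- tibble::tibble(parent_id = "p", start = 5L, end = 7L,
                       sequence = "QAK", missed = 0L)
  fq <- modification_forms(dq)
  expect_equal(nrow(fq), 2L)
  expect_equal(diff(sort(fq$mono_mass)), 17.026549, tolerance = 1e-6)

  # protein-initial peptide with two Met: acetyl x oxidation count forms
  dm <- tibble::tibble(parent_id = "p", start = 1L, end = 4L,
                       sequence = "MMAK", missed = 0L)
  fm <- modification_forms(dm)
  expect_equal(nrow(fm), 6L)  # {0,1,2 ox} x {none, acetyl}
  ox1 <- fm$mono_mass[fm$n_oxidation == 1 & !fm$acetyl]
  ox0 <- fm$mono_mass[fm$n_oxidation == 0 & !fm$acetyl]
  expect_equal(ox1 - ox0, 15.994915, tolerance = 1e-6)

  # pyroGlu must not be requested for a non-Q peptide
  expect_error(mono_mass("AK", pyroglu = TRUE), "N-terminal glutamine")
  expect_error(mono_mass("AK", n_oxidation = 1), "methionines")
})

test_that("peak matching picks the nearest form and breaks ties low", {
  th <- tibble::tibble(start = c(1L, 3L), end = c(2L, 4L),
                       sequence = c("GG", "GG"),
                       mono_mass = c(100.00, 100.06))
  near <- match_peaks(th, tibble::tibble(mass = 100.05), tol = 0.1,
                      parent_length = 4)
  expect_equal(tidy(near)$theoretical, 100.06)

  tie <- match_peaks(th, tibble::tibble(mass = 100.03), tol = 0.1,
                     parent_length = 4)
  expect_equal(tidy(tie)$theoretical, 100.00)  # equidistant -> smaller mass

  none <- match_peaks(th, tibble::tibble(mass = double()), tol = 0.1,
                      parent_length = 4)
  expect_equal(glance(none)$coverage, 0)
  expect_equal(glance(none)$n_matched_peaks, 0L)
})

test_that("peak matching is idempotent on its matched subset", {
  dig <- modification_forms(tryptic_digest("MKAYRGGDSWQKLMNPRSTVK",
                                           max_missed = 1))
  pk <- simulate_peaklist(dig, detect_prob = 0.7, mass_sd = 0.01,
                          n_contaminants = 4, seed = 8)
  r1 <- match_peaks(dig, pk, tol = 0.1)
  again <- match_peaks(dig, dplyr::select(tidy(r1), mass = "observed",
                                          "intensity"), tol = 0.1)
  expect_equal(tidy(again)$theoretical, tidy(r1)$theoretical)
  expect_equal(glance(again)$coverage, glance(r1)$coverage)
})

test_that("coverage is the union of inclusive ranges over the parent length", {
  rng <- tibble::tibble(start = c(1L, 5L), end = c(10L, 15L))
  expect_equal(peptide_coverage(rng, 20), 0.75)
  expect_equal(peptide_coverage(rng[0, ], 20), 0)
  expect_error(peptide_coverage(tibble::tibble(start = 1L, end = 30L), 20),
               "outside")
})
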