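# Seeded generators producing inputs with the statistical structure each
# pipeline stage assumes: two-clade protein families with planted type-II
# sites, noisy centroid peak lists from a digest, and paired hit tables with
# and without true orthologs. All are bit-reproducible given a seed, via
# named substreams of the master seed.

#' Simulate a two-clade protein family with planted type-II sites
#'
#' Two clades descend from a duplication. Site classes: *conserved* columns
#' carry one residue family-wide; *type-II* columns are fixed for residue
#' `r_a` within clade A and a different residue `r_b` within clade B, each
#' member deviating with probability `clade_sub_prob`; *neutral* columns
#' start from a family-wide root residue from which every member deviates
#' independently with probability `sub_prob` (one terminal branch per
#' member), so members are exchangeable at neutral sites and only planted
#' columns carry between-clade signal. No indels are simulated, so the
#' alignment is gap-free.
#'
#' @param n_per_clade Members per clade (>= 2; default 10).
#' @param n_sites Alignment columns (default 200).
#' @param frac_type2 Fraction of columns with a planted type-II shift
#'   (default 0.05).
#' @param frac_conserved Fraction of fully conserved columns (default 0.25).
#' @param sub_prob Per-member (terminal-branch) substitution probability of
#'   neutral columns (default 0.2).
#' @param clade_sub_prob Within-clade deviation probability at planted
#'   type-II columns (default 0.02; kept small so the planted signal is a
#'   strong within-clade conservation, <= 0.05).
#' @param seed Integer master seed.
#' @return A list with `alignment` (an `aa_alignment`; members `A01...`,
#'   `B01...`) and `truth` (clade assignment, planted `type2_columns`,
#'   `conserved_columns`, `neutral_columns`, the generating tree as Newick
#'   text, the seed and parameters).
#' @export
simulate_family <- function(n_per_clade = 10L, n_sites = 200L,
                            frac_type2 = 0.05, frac_conserved = 0.25,
                            sub_prob = 0.2, clade_sub_prob = 0.02,
                            seed = 1L) {
  if (n_per_clade < 2L) stop_domain("n_per_clade must be >= 2")
  if (frac_type2 < 0 || frac_conserved < 0 || frac_type2 + frac_conserved > 1) {
    stop_domain("site-class fractions must be non-negative and sum to <= 1")
  }
  if (sub_prob < 0 || sub_prob > 1 || clade_sub_prob < 0 || clade_sub_prob > 1) {
    stop_domain("substitution probabilities must lie in [0, 1]")
  }
  aa20 <- setdiff(AA_ALPHABET, "X")
  local_seed(substream_seed(seed, "family"))

  n_t2 <- round(frac_type2 * n_sites)
  n_cons <- round(frac_conserved * n_sites)
  classes <- sample(rep(c("type2", "conserved", "neutral"),
                        c(n_t2, n_cons, n_sites - n_t2 - n_cons)))
  ids_a <- sprintf("A%02d", seq_len(n_per_clade))
  ids_b <- sprintf("B%02d", seq_len(n_per_clade))
  m <- matrix("", nrow = 2L * n_per_clade, ncol = n_sites,
              dimnames = list(c(ids_a, ids_b), NULL))

  mutate_res <- function(res, prob) {
    hit <- runif(length(res)) < prob
    res[hit] <- vapply(res[hit], function(r) sample(setdiff(aa20, r), 1L),
                       character(1))
    res
  }
  for (c in seq_len(n_sites)) {
    if (classes[c] == "conserved") {
      m[, c] <- sample(aa20, 1L)
    } else if (classes[c] == "type2") {
      rab <- sample(aa20, 2L)
      m[ids_a, c] <- mutate_res(rep(rab[1], n_per_clade), clade_sub_prob)
      m[ids_b, c] <- mutate_res(rep(rab[2], n_per_clade), clade_sub_prob)
    } else {
      root <- sample(aa20, 1L)
      m[, c] <- mutate_res(rep(root, 2L * n_per_clade), sub_prob)
    }
  }

  tree_txt <- sprintf("((%s):1,(%s):1);",
                      paste0(ids_a, ":0.2", collapse = ","),
                      paste0(ids_b, ":0.2", collapse = ","))
  list(
    alignment = new_alignment_from_matrix(m),
    truth = list(
      clade_a = ids_a, clade_b = ids_b,
      type2_columns = which(classes == "type2"),
      conserved_columns = which(classes == "conserved"),
      neutral_columns = which(classes == "neutral"),
      tree = tree_txt, seed = seed,
      params = list(n_per_clade = n_per_clade, n_sites = n_sites,
                    frac_type2 = frac_type2, frac_conserved = frac_conserved,
                    sub_prob = sub_prob, clade_sub_prob = clade_sub_prob)
    )
  )
}

#' Simulate a noisy centroid peak list from theoretical peptides
#'
#' Each theoretical form is detected with probability `detect_prob`; a
#' detected centroid mass is the true mass plus Gaussian error of standard
#' deviation `mass_sd`; `n_contaminants` extra peaks are drawn uniformly
#' over the theoretical mass span. Intensities are log-normal.
#'
#' @param theoretical A tibble with a `mono_mass` column (e.g. from
#'   [modification_forms()]).
#' @param detect_prob Detection probability in (0, 1].
#' @param mass_sd Gaussian mass-error SD in Da (>= 0).
#' @param n_contaminants Number of contaminant peaks (>= 0).
#' @param seed Integer master seed.
#' @return A peak-list tibble (`mass` ascending, `intensity`).
#' @export
simulate_peaklist <- function(theoretical, detect_prob = 0.8, mass_sd = 0.01,
                              n_contaminants = 5L, seed = 1L) {
  if (detect_prob <= 0 || detect_prob > 1) stop_domain("detect_prob must be in (0, 1]")
  if (mass_sd < 0) stop_domain("mass_sd must be >= 0")
  if (n_contaminants < 0) stop_domain("n_contaminants must be >= 0")
  local_seed(substream_seed(seed, "peaklist"))
  detected <- runif(nrow(theoretical)) < detect_prob
  mass <- theoretical$mono_mass[detected] +
    rnorm(sum(detected), 0, mass_sd)
  if (n_contaminants > 0L) {
    span <- range(theoretical$mono_mass)
    mass <- c(mass, runif(n_contaminants, span[1], span[2]))
  }
  intensity <- rlnorm(length(mass), meanlog = 2, sdlog = 1)
  ord <- order(mass)
  tibble(mass = mass[ord], intensity = intensity[ord])
}

#' Simulate paired hit tables with a planted ortholog map
#'
#' Genes `a1..aN` in species A and their counterparts in species B. A
#' fraction of A genes has a true one-to-one ortholog: the true pair scores
#' top in both directions, exceeding every decoy hit by at least
#' `score_gap * (1 - noise)`. The remaining genes (emulating lineage-specific
#' losses) receive only decoy hits. Decoy hits of query `i` target the
#' cyclically following genes `i+1, ..., i+n_decoys` on the other side --
#' mirroring real cross-proteome searches, where a lost gene still finds
#' homologs whose own best hits point back to their true orthologs, never
#' back to the lost gene -- so decoys cannot reciprocate when
#' `n_genes > 2 * n_decoys`. E-values are derived from bitscores.
#'
#' @param n_genes Number of A-side genes.
#' @param ortholog_fraction Fraction with a true ortholog (in `[0, 1]`).
#' @param score_gap Minimum bitscore margin of true over decoy hits (> 0).
#' @param noise In `[0, 1)`: shrinks the guaranteed margin and jitters decoy
#'   scores.
#' @param n_decoys Decoy hits per query.
#' @param seed Integer master seed.
#' @return A list with hit tables `ab` and `ba`, and `truth` (tibble
#'   `query`, `partner` with `NA` for genes without an ortholog).
#' @export
simulate_hit_tables <- function(n_genes = 20L, ortholog_fraction = 0.8,
                                score_gap = 50, noise = 0, n_decoys = 3L,
                                seed = 1L) {
  if (score_gap <= 0) stop_domain("score_gap must be > 0")
  if (noise < 0 || noise >= 1) stop_domain("noise must be in [0, 1)")
  if (ortholog_fraction < 0 || ortholog_fraction > 1) {
    stop_domain("ortholog_fraction must be in [0, 1]")
  }
  local_seed(substream_seed(seed, "hits"))
  a_ids <- sprintf("a%03d", seq_len(n_genes))
  b_ids <- sprintf("b%03d", seq_len(n_genes))
  n_orth <- round(ortholog_fraction * n_genes)
  has_orth <- seq_len(n_genes) <= n_orth

  base <- runif(n_genes, 300, 500)
  decoy_ceiling <- base - score_gap * (1 - noise)
  if (n_genes <= 2L * n_decoys) {
    stop_domain("n_genes must exceed 2 * n_decoys (= %d)", 2L * n_decoys)
  }
  one_side <- function(q_ids, s_ids) {
    rows <- purrr::map(seq_len(n_genes), function(i) {
      decoys <- (i - 1L + seq_len(n_decoys)) %% n_genes + 1L
      ds <- pmax(decoy_ceiling[i] - runif(n_decoys, 0, 50) +
                   noise * rnorm(n_decoys, 0, 5), 1)
      tab <- tibble(query = q_ids[i], subject = s_ids[decoys], bitscore = ds)
      if (has_orth[i]) {
        tab <- dplyr::bind_rows(
          tibble(query = q_ids[i], subject = s_ids[i], bitscore = base[i]),
          tab
        )
      }
      tab
    })
    out <- dplyr::bind_rows(rows)
    out$evalue <- 10^(-out$bitscore / 10)
    validate_hit_table(out)
  }
  list(
    ab = one_side(a_ids, b_ids),
    ba = one_side(b_ids, a_ids),
    truth = tibble(query = a_ids,
                   partner = ifelse(has_orth, b_ids, NA_character_))
  )
}
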