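---
title: "Methods: detecting the origin of a new protein function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting the origin of a new protein function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gainscan)
```

This vignette documents the statistical models behind `gainscan`, the
assumptions they make, the defaults and why they were chosen, and what the
package's tests do and do not demonstrate. The running example is the
vertebrate visual cycle: RPE65 arising from carotenoid-oxygenase (BCMO)
ancestors, and LRAT within the N1pC/P60 superfamily — but every component is
generic over any duplicated protein family suspected of harbouring a
function gain.

## Distances and trees

Protein distances are computed after **complete deletion**: every alignment
column containing at least one gap in any member is removed before any
distance is taken, so all pairwise distances are estimated on the same
column set. The **p-distance** is the fraction of differing residue pairs;
the default **Poisson correction** `d = -ln(1 - p)` accounts for multiple
substitutions at one site under the simplest rate-homogeneous model. The
correction assumes all sites exchange at the same rate and all residue pairs
are equally exchangeable; it is the standard surrogate when a full empirical
rate matrix is not warranted. A saturated pair (`p = 1`) has no Poisson
distance and is reported as an error naming the pair. The unknown residue
`X` is conservatively counted as mismatching everything, including itself.

**Neighbor joining** follows the Saitou–Nei Q-criterion. Two contract
details matter for reproducibility:

* ties in Q are broken by joining the lexicographically smallest
  (label-sorted) pair, so the output never depends on input row order;
* a negative estimated branch length is clamped to zero with the deficit
  moved to its sister branch from the same join, preserving the pair's
  summed length.

On an additive matrix NJ provably recovers the generating topology and
branch lengths; the test suite checks this against a brute-force
least-squares search over *all* unrooted topologies for up to six taxa, and
against an independent NJ implementation.

**Bootstrap support** resamples the complete-deletion columns with
replacement, rebuilds an NJ tree per pseudoreplicate, and reports for each
internal edge of the point-estimate tree the percentage of replicates whose
tree contains the same bipartition. Supports are attached to the point tree
(not a consensus tree), which is how published trees usually annotate
values. Runs are bit-reproducible given `seed`. The conventional published
depth is 1,000 pseudoreplicates; the package tests use 30–200 on small
alignments, which is ample to separate a fully supported split from noise
while keeping the default test run fast.

**Rate calibration** converts a branch length (substitutions/site) and an
external divergence-time calibration (million years) into an absolute rate;
`rate_ratio()` compares two lineages. The interesting pattern for a
function gain is a short-time lineage carrying a long branch: a branch
about twice as long as its descendant lineage's, spanning 50 My against
500 My, is a 20-fold acceleration. The package computes the ratio strictly
from its inputs and makes no attempt to reproduce any rounded published
fold-change.

## Pairwise identity and similarity

`align_pair()` is a global alignment with affine gaps and free end gaps
(BLOSUM62, gap open 10, gap extend 0.5 — an approximation of CLUSTAL W
protein defaults), delegated to Biostrings. Percentages are defined over
**aligned pairs** — columns with a residue in both sequences — which makes
the identity figure well-defined independent of end-gap handling:
`identity = identical pairs / aligned pairs`, and similarity additionally
counts pairs within one of the CLUSTAL "strong" groups (STA, NEQK, NHQK,
NDEQ, QHRK, MILV, MILF, HY, FYW). Both figures are symmetric in their
arguments and reported as percentages; published comparisons are quoted to
the integer percent.

## Type-II divergence sites

A type-II (cluster-specific) functionally diverged site is conserved
*within* each of two clades but fixed for *different* residues *between*
them. The per-column statistic is

> `T = f_A · f_B · [c_A ≠ c_B]`

where `c_A`, `f_A` are the modal residue and its frequency among clade A's
non-gap characters (alphabetical tie-break), likewise for B. `T` is 1 for a
perfect type-II column and 0 wherever the clades share a consensus.

Significance comes from label re-partitioning: the pooled members of the
two clades are re-split into groups of the original two sizes, and the
fraction of re-partitions with `T* ≥ T_obs` gives p. When the number of
distinct partitions `C(n_A + n_B, n_A)` is at most 10,000 the enumeration is
exhaustive (*exact mode*: `p = #{T* ≥ T_obs}/#partitions` — for a perfect
5+5 split, 2 of the 252 partitions reproduce it, so `p = 2/252 ≈ 0.0079`);
otherwise `n_perm` partitions are sampled (default 9,999, seed required)
and `p = (1 + #{T* ≥ T_obs})/(n_perm + 1)`, whose smallest attainable value
is 1e-4. The reported `score = -log10(p)` gives the traditional
"divergence value > 3" cut the exact meaning `p < 0.001`; the threshold is
an argument, not a constant. The permutation loop is implemented in C++
(Rcpp), since it is the pipeline's only hot spot.

This statistic is a deliberately transparent surrogate for model-based
functional-divergence scores whose internals are not published: its null is
*exchangeability of members across the two clades*. That assumption is
violated by residual phylogenetic correlation within clades; for deeply
diverged, well-sampled clades the approximation is standard, but scores on
families with strong within-clade structure should be read as descriptive
rankings rather than calibrated p-values.

## Critical-residue neighborhood enrichment

Given `n` predicted positions on a protein of length `N` and a set of
independently known critical residues, the package asks whether predictions
fall within ±w of critical residues more often than chance. `K` is the size
of the **union** of the clipped windows (clustered critical residues are not
double-counted), `x` the number of predictions inside it, and

> `p = Σ_{i ≥ x} C(K, i) · C(N − K, n − i) / C(N, n)`

the one-sided upper-tail hypergeometric (Fisher) probability, computed with
`stats::phyper` and verified against exhaustive enumeration for `N ≤ 12`.
The population size defaults to the reference protein's ungapped length;
published analyses of this kind do not always state `N`, so exact
reproduction of any particular published p requires knowing both `N` and
the critical-residue list. The default window `w = 1` residue encodes the
"closest neighbor" notion of evolutionary coupling between adjacent sites.

## Diagnostic-residue scorecards

A `diagnostic_set()` fixes (position, expected residue) pairs on a
reference's ungapped coordinates; `diagnostic_scorecard()` maps each
position through the alignment (1-based everywhere; gaps excluded from the
bijection) and scores any member by how many expected residues it retains —
the "7 of 7" versus "1 of 7" style of argument. A gap or mismatch counts as
absent; if the *reference itself* disagrees with the set, the row is flagged
and a warning raised, since that signals an alignment/set mismatch rather
than divergence.

## Peptide mass fingerprinting

`tryptic_digest()` cleaves after K or R except before P and enumerates
peptides spanning up to `max_missed` uncut sites (default 0; published
digests typically consider 1). Monoisotopic masses are sums of the standard
residue masses plus one water (18.010565 Da); every constant is unit-tested
against an elemental-composition oracle built from atomic masses.
Modification forms are enumerated per peptide: N-terminal pyroglutamate
(−17.026549 Da) only for N-terminal Gln; N-terminal acetylation
(+42.010565 Da) only for the protein's first peptide; Met oxidation
(+15.994915 Da) tracked by count, not site, because fingerprinting cannot
localise it. The two N-terminal states are mutually exclusive, and a
combinatorial cap (16 forms/peptide) bounds pathological Met-rich peptides.

`match_peaks()` assigns each observed centroid to the nearest theoretical
mass within an **absolute** tolerance (default 0.1 Da, matching the usual
MALDI-TOF acceptance band; ppm mode is out of scope), ties broken toward the
smaller theoretical mass. A theoretical form may collect several peaks but
each peak matches at most one form. Observed masses are treated as neutral;
`charge_adduct = TRUE` subtracts one proton (1.007276 Da) when the peak list
is singly-protonated m/z. **Sequence coverage** is the union of matched
peptide ranges over the parent length — the packaged published fingerprint
table's 14 distinct ranges cover 156/537 = 29% — and the report exposes
matched-peak, matched-form and matched-range counts separately, since
published "peptides matched" counts do not always state which convention
they use.

## Reciprocal-best-hit orthology

Hits are ranked by descending bitscore (database-size independent), ties by
ascending e-value then subject id; self-hits are excluded. `strict` means
mutual rank-1; `relaxed` means reciprocation within the top k both ways
(default k = 3, the usual relaxation when one proteome is fragmentary);
`absent` otherwise. Increasing k can only move calls away from `absent`
(monotonicity, tested). A gene family is called absent only when every
member is absent — the form of argument used for photoisomerase
(RGR/peropsin) loss. No minimum-bitscore filter is applied by default
because published searches rarely state theirs; `dplyr::filter` on the hit
table achieves any desired cutoff before calling.

## What the generators emulate — and what they do not

`simulate_family()` produces a gap-free alignment of two clades descending
from a duplication. Conserved columns are fixed family-wide; planted
type-II columns are fixed for different residues per clade with a small
within-clade deviation probability (default 0.02, i.e. strong within-clade
conservation); neutral columns give every member an independent deviation
(probability 0.2 per member) from a family-wide root residue. Neutral sites
are therefore *exchangeable across members by construction* — the
permutation test's null — so the false-positive rate of the detector is
interpretable; the corollary is that these simulations do not probe
robustness to within-clade phylogenetic correlation, rate heterogeneity,
empirical exchangeabilities, or indels (no gaps are simulated). Passing the
recovery test (sensitivity ≥ 0.9, FPR ≤ 0.01 at score > 3 over 20 seeds,
10+10 members × 200 sites with 5% planted sites) shows the statistic and
its permutation machinery are correct under their own model, not that real
alignments behave this way.

`simulate_peaklist()` models detection dropout (Bernoulli per form),
Gaussian centroid mass error, uniform contaminant masses over the
theoretical span, and log-normal intensities — enough to exercise matching,
tie-breaking and coverage; it does not model isotope envelopes, adducts,
detector saturation or mass-dependent error. `simulate_hit_tables()` plants
a one-to-one ortholog map whose reciprocal scores exceed all decoys by a
margin; decoy hits point at the cyclically next genes so that non-ortholog
genes can never reciprocate — mirroring real searches, where a lost gene's
homologs reciprocate to their own orthologs — which makes the planted truth
exactly recoverable at zero noise.

All generators draw from named substreams of a single master seed, so
composed pipelines are bit-reproducible end to end.

## Numerical and interface choices

* Coordinates are 1-based with inclusive ranges everywhere, matching how
  peptides ("360–366") and residue positions ("L49") are quoted in the
  field.
* The gap character is `-` only; `.` is rejected. Alphabet: the 20
  canonical residues plus `X`.
* Newick branch lengths are written with 10 significant digits, enough for
  exact re-serialisation in the round-trip tests.
* Exact-mode permutation p has no +1 correction (the observed partition is
  one of the enumerated ones); sampled mode uses the standard
  `(1 + count)/(n_perm + 1)` estimator.
* Comparisons of `T* ≥ T_obs` use a 1e-12 slack so ties are not lost to
  floating-point noise.
* The accession-dependent checks (digest of the deposited lamprey RPE65,
  its 61.4 kDa average mass, the 72%/92% identity/similarity to human
  RPE65) need the deposited sequences; `scripts/fetch_accessions.R`
  retrieves them once and the library itself never performs network access.

## Problem sizes

The shipped tests run alignments of 4–20 members × 30–200 columns,
bootstrap depths of 30–200 replicates, permutation depths of 252 (exact) to
9,999 (sampled), brute-force tree searches to 6 taxa and enrichment
enumerations to N = 12 — sizes chosen so every oracle comparison is exact
and the default suite completes in well under a minute, while the
acceptance script's 20-family recovery experiment (40,000 column tests)
exercises the compiled permutation kernel at production depth.

## Known limitations

* The NJ implementation is quadratic-memory and cubic-time — appropriate
  for the tens-of-taxa superfamily trees it serves, not for thousands of
  taxa.
* Maximum-likelihood and parsimony tree inference are out of scope by
  design; the package's trees are distance-based.
* The divergence statistic detects type-II shifts only; type-I divergence
  (rate shifts with conserved consensus) will not score.
* PMF matching is mass-only; it does not compute probabilistic
  identification scores and cannot distinguish isobaric peptides.
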