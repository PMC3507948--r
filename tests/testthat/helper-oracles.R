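# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# --- elemental-composition mass oracle ---------------------------------------
# Monoisotopic atomic masses (most abundant isotope) and standard atomic
# weights; residue formulas are for the dehydrated in-chain residue.
ATOM_MONO <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)
ATOM_AVG <- c(H = 1.00794, C = 12.0107, N = 14.0067, O = 15.9994, S = 32.065)

RESIDUE_FORMULA <- list(
  G = c(C = 2, H = 3, N = 1, O = 1), A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2), P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1), T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1), L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1), N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3), Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1), E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1), H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1), R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2), W = c(C = 11, H = 10, N = 2, O = 1)
)

formula_mass <- function(formula, atoms) {
  sum(atoms[names(formula)] * formula)
}

oracle_peptide_mono <- function(sequence) {
  cc <- strsplit(sequence, "")[[1]]
  sum(vapply(cc, function(r) formula_mass(RESIDUE_FORMULA[[r]], ATOM_MONO),
             numeric(1))) +
    formula_mass(c(H = 2, O = 1), ATOM_MONO)
}

oracle_protein_avg <- function(sequence) {
  cc <- strsplit(sequence, "")[[1]]
  sum(vapply(cc, function(r) formula_mass(RESIDUE_FORMULA[[r]], ATOM_AVG),
             numeric(1))) +
    formula_mass(c(H = 2, O = 1), ATOM_AVG)
}

# --- brute-force windowed hypergeometric enrichment --------------------------
oracle_enrichment_p <- function(n_total, critical, predicted, w) {
  win <- sort(unique(unlist(lapply(critical, function(c) {
    max(1, c - w):min(n_total, c + w)
  }))))
  x_obs <- length(intersect(predicted, win))
  subsets <- utils::combn(n_total, length(predicted))
  overlaps <- apply(subsets, 2, function(s) sum(s %in% win))
  mean(overlaps >= x_obs)
}

# --- independent pattern-scan tryptic digest ---------------------------------
# Enumerates every (start, end) whose boundaries are cleavage boundaries and
# whose interior holds at most max_missed uncut sites.
oracle_digest <- function(sequence, max_missed) {
  cc <- strsplit(sequence, "")[[1]]
  n <- length(cc)
  sites <- Filter(function(i) cc[i] %in% c("K", "R") && i < n && cc[i + 1] != "P",
                  seq_len(n))
  sites <- unlist(sites)
  bounds <- c(0, sites, n)
  peps <- list()
  for (s in bounds[-length(bounds)]) {
    for (e in bounds[bounds > s]) {
      internal <- sum(sites > s & sites < e)
      if (internal <= max_missed) {
        peps[[length(peps) + 1]] <- c(start = s + 1, end = e)
      }
    }
  }
  df <- as.data.frame(do.call(rbind, peps))
  df$sequence <- substring(sequence, df$start, df$end)
  df[order(df$start, df$end), ]
}

# --- least-squares tree search over all topologies (n <= 6) ------------------
# For each unrooted topology, ordinary least-squares branch lengths are fit
# to the distance matrix; the topology with minimal RSS is returned. On an
# additive matrix the generating tree has RSS 0 and is the unique optimum.
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

ls_fit_topology <- function(tree, dm) {
  labels <- rownames(dm)
  ntip <- length(tree$tip.label)
  pairs <- utils::combn(ntip, 2)
  tipidx <- match(tree$tip.label, labels)
  A <- matrix(0, ncol(pairs), nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    below <- tips_below(tree, tree$edge[e, 2])
    side <- seq_len(ntip) %in% below
    for (p in seq_len(ncol(pairs))) {
      if (side[pairs[1, p]] != side[pairs[2, p]]) A[p, e] <- 1
    }
  }
  d <- apply(pairs, 2, function(ij) dm[tipidx[ij[1]], tipidx[ij[2]]])
  fit <- qr.solve(A, d)
  rss <- sum((A %*% fit - d)^2)
  tree$edge.length <- pmax(fit, 0)
  list(tree = tree, rss = rss)
}

oracle_ls_tree <- function(dm) {
  labels <- rownames(dm)
  tops <- phangorn::allTrees(length(labels), rooted = FALSE,
                             tip.label = labels)
  fits <- lapply(tops, ls_fit_topology, dm = dm)
  fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]
}

# random additive tree + its exact distance matrix
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 1))
  dm <- ape::cophenetic.phylo(tr)
  dm <- dm[order(rownames(dm)), order(colnames(dm))]
  list(tree = tr, dm = dm)
}

# random gap-containing alignment tibble for IO fuzzing
random_seqs <- function(n, len_range = c(5, 40), seed = 1) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
          "N", "P", "Q", "R", "S", "T", "V", "W", "X", "Y")
  tibble::tibble(
    id = sprintf("seq%02d", seq_len(n)),
    desc = ifelse(seq_len(n) %% 2 == 0, sprintf("random record %d", seq_len(n)), ""),
    seq = vapply(seq_len(n), function(i) {
      paste(sample(aa, sample(len_range[1]:len_range[2], 1), replace = TRUE),
            collapse = "")
    }, character(1))
  )
}
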