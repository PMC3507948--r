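# Type-II functional-divergence site detection between two clades of a
# protein family, with a windowed hypergeometric enrichment test relating the
# detected sites to independently known critical residues.

#' Modal residue of a clade at one alignment column
#'
#' @param aln An `aa_alignment`.
#' @param clade Character vector of member ids.
#' @param column 1-based alignment column.
#' @return A one-row tibble with `residue` (modal residue among the clade's
#'   non-gap characters; alphabetical tie-break), `freq` (its fraction of the
#'   non-gap characters) and `n` (non-gap count). `residue` is `NA` when the
#'   clade is entirely gapped at the column.
#' @export
clade_consensus <- function(aln, clade, column) {
  check_clade_ids(aln, clade, "clade")
  if (column < 1L || column > ncol(aln)) {
    stop_domain("column %d outside 1..%d", column, ncol(aln))
  }
  chars <- unclass(aln)[clade, column]
  chars <- chars[chars != GAP_CHAR]
  if (length(chars) == 0L) {
    return(tibble(residue = NA_character_, freq = NA_real_, n = 0L))
  }
  tab <- table(factor(chars, levels = AA_ALPHABET))
  residue <- names(tab)[which.max(tab)]  # levels are alphabetical: ties -> smallest
  tibble(residue = residue, freq = max(tab) / length(chars), n = length(chars))
}

check_clade_ids <- function(aln, ids, what) {
  missing <- setdiff(ids, rownames(aln))
  if (length(missing)) {
    stop_domain("%s id(s) not in alignment: %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(ids)
}

#' Per-column type-II functional-divergence scores
#'
#' Scores every alignment column for a type-II (cluster-specific) shift
#' between two clades: conserved within each clade but fixed for different
#' residues between them. The statistic is
#' `T = freq_a * freq_b * [consensus_a != consensus_b]`, where `freq_a` and
#' `freq_b` are the modal-residue frequencies within each clade (gaps
#' excluded). Significance comes from re-partitioning the pooled member
#' labels into groups of the same two sizes: exhaustively when the number of
#' distinct partitions is at most `exact_limit` (*exact mode*,
#' `p = #\{T* >= T_obs\} / #partitions`), otherwise by `n_perm` sampled
#' re-partitions with `p = (1 + #\{T* >= T_obs\}) / (n_perm + 1)`. The
#' reported `score = -log10(p)`, so `score > 3` means exactly `p < 0.001`.
#'
#' @param aln An `aa_alignment` (columns where either clade is fully gapped
#'   are skipped and reported with `NA` statistics).
#' @param clade_a,clade_b Disjoint sets of member ids, each of size >= 2.
#' @param n_perm Number of sampled re-partitions when exact mode is not
#'   engaged (>= 99).
#' @param seed Integer seed; required whenever sampling is used.
#' @param exact_limit Partition-count bound below which exhaustive
#'   enumeration replaces sampling.
#' @return A `site_divergence` tibble with one row per column: `column`,
#'   `consensus_a`, `freq_a`, `consensus_b`, `freq_b`, `stat`, `p`, `score`.
#'   Attribute `exact` records the mode.
#' @seealso [divergent_sites()], [neighborhood_enrichment()]
#' @export
type2_site_scores <- function(aln, clade_a, clade_b, n_perm = 9999L,
                              seed = NULL, exact_limit = 10000L) {
  check_clade_ids(aln, clade_a, "clade_a")
  check_clade_ids(aln, clade_b, "clade_b")
  if (length(intersect(clade_a, clade_b))) stop_domain("clades must be disjoint")
  if (length(clade_a) < 2L || length(clade_b) < 2L) {
    stop_domain("each clade needs at least 2 members")
  }

  members <- c(clade_a, clade_b)
  m <- unclass(aln)[members, , drop = FALSE]
  codes <- matrix(match(m, AA_ALPHABET, nomatch = 0L), nrow = nrow(m))
  codes[m == GAP_CHAR] <- 0L

  na <- length(clade_a); nb <- length(clade_b); nu <- na + nb
  obs <- observed_type2(codes, seq_len(na), na + seq_len(nb))

  n_assign <- choose(nu, na)
  exact <- n_assign <= exact_limit
  if (exact) {
    grp <- t(combn(nu, na))
  } else {
    if (n_perm < 99L) stop_domain("n_perm must be >= 99")
    if (is.null(seed)) stop_domain("a seed is required for sampled permutation runs")
    local_seed(substream_seed(seed, "type2"))
    grp <- t(vapply(seq_len(n_perm), function(i) sample.int(nu, na),
                    integer(na)))
  }
  counts <- type2_perm_counts(codes, grp, obs$stat)
  p <- if (exact) counts / nrow(grp) else (1 + counts) / (n_perm + 1)
  p[is.na(obs$stat)] <- NA_real_

  out <- tibble(
    column = seq_len(ncol(aln)),
    consensus_a = obs$cons_a, freq_a = obs$freq_a,
    consensus_b = obs$cons_b, freq_b = obs$freq_b,
    stat = obs$stat, p = p, score = -log10(p)
  )
  structure(out, class = c("site_divergence", class(out)),
            exact = exact, n_perm = if (exact) nrow(grp) else n_perm,
            clade_sizes = c(a = na, b = nb))
}

# observed per-column consensus/frequency/statistic from integer codes
observed_type2 <- function(codes, rows_a, rows_b) {
  n_col <- ncol(codes)
  summarise_group <- function(rows) {
    cons <- character(n_col); freq <- rep(NA_real_, n_col)
    for (c in seq_len(n_col)) {
      v <- codes[rows, c]
      v <- v[v > 0L]
      if (length(v) == 0L) { cons[c] <- NA_character_; next }
      tab <- tabulate(v, nbins = 21L)
      cons[c] <- AA_ALPHABET[which.max(tab)]
      freq[c] <- max(tab) / length(v)
    }
    list(cons = cons, freq = freq)
  }
  a <- summarise_group(rows_a); b <- summarise_group(rows_b)
  stat <- ifelse(is.na(a$cons) | is.na(b$cons), NA_real_,
                 a$freq * b$freq * (a$cons != b$cons))
  list(cons_a = a$cons, freq_a = a$freq,
       cons_b = b$cons, freq_b = b$freq, stat = stat)
}

#' Columns exceeding a divergence score threshold
#'
#' @param profile A `site_divergence` tibble from [type2_site_scores()].
#' @param threshold Score cut; `score > threshold` is equivalent to
#'   `p < 10^(-threshold)` (default 3, i.e. p < 0.001).
#' @return The rows of `profile` with `score > threshold`.
#' @export
divergent_sites <- function(profile, threshold = 3) {
  dplyr::filter(as_tibble(profile), !is.na(.data$score),
                .data$score > threshold)
}

#' Map ungapped reference positions to alignment columns
#'
#' Residue positions quoted on one member's ungapped coordinates (e.g. "L49"
#' of a reference protein) are translated to alignment columns.
#'
#' @param aln An `aa_alignment`.
#' @param reference_id Member id carrying the coordinates.
#' @param positions 1-based ungapped positions on the reference.
#' @return Integer vector of alignment columns, one per position.
#' @export
map_reference_positions <- function(aln, reference_id, positions) {
  map <- ungapped_to_col(aln, reference_id)
  if (any(positions < 1L) || any(positions > length(map))) {
    bad <- positions[positions < 1L | positions > length(map)][1]
    stop_domain("position %d outside the reference's ungapped length %d",
                bad, length(map))
  }
  map[positions]
}

#' Build a diagnostic residue set
#'
#' A set of (ungapped reference position, expected residue) pairs used to
#' score other family members for retention of function-diagnostic residues.
#'
#' @param positions Strictly increasing 1-based positions.
#' @param residues Expected one-letter residues (canonical).
#' @param reference_id Id of the member whose coordinates are used.
#' @return A tibble with columns `position`, `residue` and attribute
#'   `reference_id`.
#' @export
diagnostic_set <- function(positions, residues, reference_id) {
  if (any(diff(positions) <= 0)) stop_domain("positions must be strictly increasing")
  residues <- toupper(residues)
  if (any(!residues %in% setdiff(AA_ALPHABET, "X"))) {
    stop_domain("expected residues must be canonical amino acids")
  }
  structure(tibble(position = as.integer(positions), residue = residues),
            reference_id = reference_id)
}

#' Score a query against a diagnostic residue set
#'
#' For each entry the query is marked present iff its residue in the mapped
#' alignment column equals the expected residue; a gap or mismatch counts as
#' absent. If the reference itself disagrees with the expected residue at a
#' position, the row is flagged (`reference_consistent = FALSE`) and a
#' warning is raised, but the row still counts.
#'
#' @param aln An `aa_alignment` containing both reference and query.
#' @param dset A [diagnostic_set()].
#' @param query_id Member to score.
#' @param reference_id Coordinate-bearing member; defaults to the set's
#'   `reference_id` attribute.
#' @return A `scorecard` tibble (one row per entry: `position`, `expected`,
#'   `column`, `reference_residue`, `query_residue`, `present`,
#'   `reference_consistent`) with attributes `n_present`, `n_total`;
#'   `glance()` summarises them.
#' @export
diagnostic_scorecard <- function(aln, dset, query_id,
                                 reference_id = attr(dset, "reference_id")) {
  check_clade_ids(aln, c(reference_id, query_id), "scorecard")
  cols <- map_reference_positions(aln, reference_id, dset$position)
  ref_res <- unclass(aln)[reference_id, cols]
  qry_res <- unclass(aln)[query_id, cols]
  consistent <- ref_res == dset$residue
  if (any(!consistent)) {
    warn(sprintf("reference '%s' disagrees with the diagnostic set at position(s) %s",
                 reference_id,
                 paste(dset$position[!consistent], collapse = ", ")))
  }
  out <- tibble(
    position = dset$position, expected = dset$residue, column = cols,
    reference_residue = unname(ref_res), query_residue = unname(qry_res),
    present = unname(qry_res == dset$residue),
    reference_consistent = unname(consistent)
  )
  structure(out, class = c("scorecard", class(out)),
            n_present = sum(out$present), n_total = nrow(out),
            query_id = query_id, reference_id = reference_id)
}

#' @rdname diagnostic_scorecard
#' @param x A `scorecard`.
#' @param ... Unused.
#' @method glance scorecard
#' @export
glance.scorecard <- function(x, ...) {
  tibble(query_id = attr(x, "query_id"), reference_id = attr(x, "reference_id"),
         n_present = attr(x, "n_present"), n_total = attr(x, "n_total"))
}

#' Windowed critical-residue enrichment of predicted sites
#'
#' Tests whether predicted (e.g. divergence-detected) residue positions fall
#' near independently known critical residues more often than chance. The
#' neighborhood is the union of the windows `[c - w, c + w]` around each
#' critical position, clipped to `[1, n_total]` (a union, so clustered
#' critical residues are not double-counted); the p-value is the one-sided
#' upper-tail hypergeometric (Fisher) probability of observing at least the
#' attained overlap when `|predicted|` positions are drawn uniformly without
#' replacement from the `n_total` positions.
#'
#' @param n_total Protein length (number of residue positions).
#' @param critical Positions of known critical residues (1-based).
#' @param predicted Predicted positions to test.
#' @param window Window half-width `w` in residues (default 1).
#' @return A one-row `enrichment_result` tibble: `n_total`, `n_critical`,
#'   `window`, `k_window` (size of the window union), `n_predicted`,
#'   `x_overlap`, `p`.
#' @examples
#' neighborhood_enrichment(10, critical = 5, predicted = c(4, 9), window = 1)
#' @export
neighborhood_enrichment <- function(n_total, critical, predicted, window = 1L) {
  if (length(critical) == 0L || length(predicted) == 0L) {
    stop_domain("critical and predicted position sets must be non-empty")
  }
  pos <- c(critical, predicted)
  if (any(pos < 1L) || any(pos > n_total)) {
    stop_domain("position %d outside 1..%d", pos[pos < 1L | pos > n_total][1],
                n_total)
  }
  critical <- unique(as.integer(critical))
  predicted <- unique(as.integer(predicted))
  win <- IRanges::reduce(IRanges::IRanges(
    start = pmax(critical - window, 1L), end = pmin(critical + window, n_total)
  ))
  k <- sum(IRanges::width(win))
  in_window <- IRanges::overlapsAny(IRanges::IRanges(predicted, predicted), win)
  x <- sum(in_window)
  p <- phyper(x - 1, k, n_total - k, length(predicted), lower.tail = FALSE)
  out <- tibble(
    n_total = as.integer(n_total), n_critical = length(critical),
    window = as.integer(window), k_window = as.integer(k),
    n_predicted = length(predicted), x_overlap = as.integer(x), p = p
  )
  structure(out, class = c("enrichment_result", class(out)),
            in_window = predicted[in_window])
}
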