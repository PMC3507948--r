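#' Remove all gap-containing columns from an alignment
#'
#' The "complete deletion" treatment used before distance and tree
#' computation: every column containing at least one gap in any member is
#' dropped; member order is preserved.
#'
#' @param aln An `aa_alignment`.
#' @return An `aa_alignment` with only gap-free columns.
#' @export
complete_deletion <- function(aln) {
  m <- unclass(aln)
  keep <- colSums(m == GAP_CHAR) == 0L
  if (!any(keep)) {
    stop_domain("complete deletion removed every column: alignment is degenerate")
  }
  new_alignment_from_matrix(m[, keep, drop = FALSE])
}

#' Pairwise protein distances from an alignment
#'
#' Computes the p-distance (proportion of differing residue pairs per column)
#' or the Poisson-corrected distance `-ln(1 - p)` between every pair of
#' members. The alignment must already be gap-free (apply
#' [complete_deletion()] first). The unknown residue `X` counts as a
#' mismatch against every residue including itself.
#'
#' @param aln A gap-free `aa_alignment`.
#' @param model `"poisson"` (default) or `"p"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by member
#'   id, in substitutions per site.
#' @export
distance_matrix <- function(aln, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- unclass(aln)
  if (any(m == GAP_CHAR)) {
    stop_domain("alignment contains gaps; apply complete_deletion() first")
  }
  n <- nrow(m)
  ids <- rownames(m)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diffs <- m[i, ] != m[j, ] | m[i, ] == "X" | m[j, ] == "X"
      p <- mean(diffs)
      if (model == "poisson") {
        if (p >= 1) {
          stop_domain("saturated pair ('%s', '%s'): p = 1 has no Poisson distance",
                      ids[i], ids[j])
        }
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}
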