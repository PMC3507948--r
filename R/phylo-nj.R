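# Neighbor-joining with deterministic tie-breaking, plus column-bootstrap
# support on the point-estimate tree's bipartitions.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (Q criterion) producing an unrooted
#' tree. Two determinism/sanity rules are part of the contract:
#' \itemize{
#'   \item When several pairs share the minimal Q value, the pair whose
#'     (label-sorted) key is lexicographically smallest is joined, so the
#'     result does not depend on input order.
#'   \item A negative estimated branch length is clamped to 0 and the deficit
#'     moved to the sister branch of the same join, preserving their sum.
#' }
#' On an additive distance matrix the generating topology and branch lengths
#' are recovered exactly.
#'
#' @param dm A labelled symmetric distance matrix (as from
#'   [distance_matrix()]) over at least 3 taxa.
#' @return An unrooted ape `phylo` tree.
#' @export
nj_tree <- function(dm) {
  labels <- rownames(dm)
  if (is.null(labels)) stop_domain("distance matrix needs row/column labels")
  n <- length(labels)
  if (n < 3L) stop_domain("neighbor joining needs at least 3 taxa, got %d", n)
  if (any(abs(dm - t(dm)) > 1e-9)) stop_domain("distance matrix is not symmetric")

  D <- unname(dm)
  # subtree Newick fragments and sort keys (smallest contained leaf label)
  frag <- labels
  key <- labels

  clamp_pair <- function(li, lj) {
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    c(max(li, 0), max(lj, 0))
  }

  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest label-sorted pair
    ck <- apply(cand, 1, function(ij) {
      paste(sort(c(key[ij[1]], key[ij[2]])), collapse = "\r")
    })
    pick <- cand[order(ck)[1], ]
    i <- pick[1]; j <- pick[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    ll <- clamp_pair(li, lj)
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], ll[1], frag[j], ll[2])
    new_key <- min(key[i], key[j])
    dk <- pmax((D[i, ] + D[j, ] - D[i, j]) / 2, 0)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    key <- c(key[keep], new_key)
  }

  # final trifurcation (closed form)
  lx <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  ly <- D[1, 2] - lx
  lz <- D[1, 3] - lx
  ls <- pmax(c(lx, ly, lz), 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1], ls[1], frag[2], ls[2], frag[3], ls[3])
  ape::read.tree(text = txt)
}

#' Canonical non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the taxa into two sides; the canonical key is
#' the sorted side not containing the alphabetically first taxon, collapsed
#' with "|". Used to transfer bootstrap counts onto the point-estimate tree.
#'
#' @param tree An ape `phylo`.
#' @return A character vector of bipartition keys, named by the internal
#'   node defining each (as character).
#' @keywords internal
tree_bipartitions <- function(tree) {
  universe <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  nodes <- seq_len(tree$Nnode) + length(tree$tip.label)
  keys <- character(0)
  for (k in seq_along(parts)) {
    side <- tree$tip.label[parts[[k]]]
    if (length(side) < 2L || length(side) > length(universe) - 2L) next
    if (universe[1] %in% side) side <- setdiff(universe, side)
    if (length(side) < 2L || length(side) > length(universe) - 2L) next
    keys[as.character(nodes[k])] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' Neighbor-joining tree with column-bootstrap support
#'
#' Applies [complete_deletion()], builds the point-estimate NJ tree, then
#' resamples alignment columns with replacement `n_reps` times, rebuilds an
#' NJ tree per pseudoreplicate, and labels each internal edge of the point
#' tree with the percentage of replicates containing the same bipartition.
#'
#' @param aln An `aa_alignment`.
#' @param n_reps Number of bootstrap pseudoreplicates (>= 1).
#' @param seed Integer seed; the run is bit-reproducible given the seed.
#' @param model Distance model passed to [distance_matrix()].
#' @return The point-estimate `phylo` with supports (percent, 0-100) in
#'   `node.label` (empty for the root and trivial splits).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = 1L,
                              model = c("poisson", "p")) {
  model <- match.arg(model)
  if (n_reps < 1L) stop_domain("n_reps must be >= 1")
  filtered <- complete_deletion(aln)
  point <- nj_tree(distance_matrix(filtered, model = model))
  point_keys <- tree_bipartitions(point)
  counts <- setNames(rep(0L, length(point_keys)), unname(point_keys))
  m <- unclass(filtered)

  local_seed(substream_seed(seed, "bootstrap"))
  n_ok <- 0L
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- new_alignment_from_matrix(m[, cols, drop = FALSE])
    rep_tree <- tryCatch(nj_tree(distance_matrix(rep_aln, model = model)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) next
    n_ok <- n_ok + 1L
    hit <- unique(tree_bipartitions(rep_tree))
    hit <- hit[hit %in% names(counts)]
    counts[hit] <- counts[hit] + 1L
  }
  if (n_ok == 0L) stop_domain("no bootstrap replicate produced a tree")

  node_label <- rep("", point$Nnode)
  ids <- seq_len(point$Nnode) + length(point$tip.label)
  for (nd in names(point_keys)) {
    pct <- 100 * counts[[point_keys[[nd]]]] / n_ok
    node_label[match(as.integer(nd), ids)] <- format(pct, digits = 4)
  }
  point$node.label <- node_label
  attr(point, "n_replicates") <- n_ok
  point
}

#' Extract numeric bootstrap supports from a tree
#'
#' @param tree A `phylo` with supports in `node.label`.
#' @return A named numeric vector (internal node id -> percent), dropping
#'   unlabeled nodes.
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(setNames(numeric(0), character(0)))
  ids <- seq_len(tree$Nnode) + length(tree$tip.label)
  lab <- tree$node.label
  keep <- nzchar(lab)
  setNames(as.numeric(lab[keep]), ids[keep])
}
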