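# Pairwise global protein alignment summaries (percent identity/similarity).

# CLUSTAL's "strong" conservation groups, used for the similarity count.
STRONG_GROUPS <- c("STA", "NEQK", "NHQK", "NDEQ", "QHRK",
                   "MILV", "MILF", "HY", "FYW")

#' Globally align two protein sequences and summarise identity/similarity
#'
#' Needleman-Wunsch global alignment with affine gap costs and free end gaps
#' (BLOSUM62, gap open 10, gap extend 0.5 by default, approximating CLUSTAL W
#' protein defaults), computed with \pkg{Biostrings}. Percentages are taken
#' over *aligned pairs* -- columns holding a residue in both sequences:
#' identity = identical pairs / aligned pairs; similarity additionally counts
#' pairs falling in a common CLUSTAL strong group
#' (STA, NEQK, NHQK, NDEQ, QHRK, MILV, MILF, HY, FYW).
#' The unknown residue `X` matches nothing, including itself.
#'
#' @param a,b Protein sequences: plain strings, or one-row tibbles with
#'   `id`/`seq` columns (as from [read_fasta()]).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param matrix Name of the substitution matrix shipped with
#'   \pkg{Biostrings} (default `"BLOSUM62"`).
#' @return A `pairwise_summary` object; `tidy()` returns its one-row tibble
#'   with `identity`, `similarity` (percent), `aligned_cols`,
#'   `aligned_pairs`, `identical_pairs`, `similar_pairs`.
#' @examples
#' align_pair("MKV", "MRI")
#' @export
align_pair <- function(a, b, gap_open = 10, gap_extend = 0.5,
                       matrix = "BLOSUM62") {
  seq_of <- function(x, nm) {
    if (is.data.frame(x)) x <- x$seq[1]
    if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
      stop_domain("argument '%s' must be a single non-empty protein sequence", nm)
    }
    toupper(x)
  }
  sa <- seq_of(a, "a"); sb <- seq_of(b, "b")
  check_residues(c(a = sa, b = sb))

  submat <- get(data(list = matrix, package = "Biostrings",
                     envir = environment()), envir = environment())
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = submat, gapOpening = gap_open,
    gapExtension = gap_extend, type = "overlap"
  )
  ga <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]

  both <- ga != "-" & gb != "-"
  ident <- both & ga == gb & ga != "X"
  similar <- ident
  for (grp in STRONG_GROUPS) {
    g <- strsplit(grp, "")[[1]]
    similar <- similar | (both & ga %in% g & gb %in% g)
  }
  np <- sum(both)
  structure(list(
    stats = tibble(
      identity = 100 * sum(ident) / np,
      similarity = 100 * sum(similar) / np,
      aligned_cols = length(ga),
      aligned_pairs = np,
      identical_pairs = sum(ident),
      similar_pairs = sum(similar)
    ),
    aligned_a = paste(ga, collapse = ""),
    aligned_b = paste(gb, collapse = ""),
    score = Biostrings::score(pa)
  ), class = "pairwise_summary")
}

#' @export
print.pairwise_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<pairwise_summary: %.1f%% identity / %.1f%% similarity over %d aligned pairs (%d columns)>\n",
              s$identity, s$similarity, s$aligned_pairs, s$aligned_cols))
  invisible(x)
}

#' @rdname align_pair
#' @param x A `pairwise_summary`.
#' @param ... Unused.
#' @method tidy pairwise_summary
#' @export
tidy.pairwise_summary <- function(x, ...) x$stats

#' @rdname align_pair
#' @method glance pairwise_summary
#' @export
glance.pairwise_summary <- function(x, ...) {
  dplyr::mutate(x$stats, score = x$score)
}
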