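# The alignment container: a character matrix (members x columns) of single
# characters with member ids as rownames, class "aa_alignment". Columns are
# 1-based; the gap character is '-' only.

#' Construct a protein multiple alignment
#'
#' @param x A named character vector of equal-length gapped sequences
#'   (alphabet: the 20 canonical residues, `X`, and the gap `-`), or a
#'   tibble with columns `id` and `seq`.
#' @return An `aa_alignment`: a character matrix with one row per member and
#'   one column per alignment position.
#' @details Invariants enforced at construction: at least two members, unique
#'   non-empty ids, identical lengths, and no column consisting entirely of
#'   gaps.
#' @examples
#' aln <- alignment(c(a = "AC-E", b = "ACDE"))
#' n_columns(aln)
#' @export
alignment <- function(x) {
  if (is.data.frame(x)) x <- setNames(x$seq, x$id)
  if (!is.character(x)) stop_domain("alignment() expects a named character vector or a tibble")
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids))) stop_domain("all alignment members need non-empty ids")
  if (anyDuplicated(ids)) stop_domain("duplicate member id '%s'", ids[duplicated(ids)][1])
  if (length(x) < 2L) stop_domain("an alignment needs at least 2 members, got %d", length(x))
  lens <- nchar(x)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != max(lens)]
    stop_format("ragged alignment: members differ in length (%s)",
                paste(off, collapse = ", "))
  }
  check_residues(x, what = "member", allow_gap = TRUE)
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(m) <- ids
  all_gap <- colSums(m != GAP_CHAR) == 0L
  if (any(all_gap)) {
    stop_format("column(s) %s consist entirely of gaps",
                paste(which(all_gap), collapse = ", "))
  }
  structure(m, class = c("aa_alignment", class(m)))
}

new_alignment_from_matrix <- function(m) {
  structure(m, class = c("aa_alignment", "matrix", "array"))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("<aa_alignment: %d members x %d columns>\n", nrow(x), ncol(x)))
  strings <- aln_strings(x)
  shown <- head(strings, 10)
  shown <- ifelse(nchar(shown) > 60, paste0(substr(shown, 1, 57), "..."), shown)
  cat(sprintf("  %-12s %s\n", names(shown), shown), sep = "")
  if (nrow(x) > 10) cat(sprintf("  ... and %d more members\n", nrow(x) - 10))
  invisible(x)
}

#' Alignment accessors
#'
#' `n_columns()` returns the number of alignment columns, `member_ids()` the
#' ordered member ids, and `aln_strings()` the gapped sequences as a named
#' character vector.
#'
#' @param aln An `aa_alignment`.
#' @return See description.
#' @export
n_columns <- function(aln) ncol(aln)

#' @rdname n_columns
#' @export
member_ids <- function(aln) rownames(aln)

#' @rdname n_columns
#' @export
aln_strings <- function(aln) {
  setNames(apply(unclass(aln), 1, paste, collapse = ""), rownames(aln))
}

#' Read a protein multiple alignment
#'
#' Reads an aligned FASTA file or a CLUSTAL-format file (the interleaved
#' dialect written by CLUSTAL W, with an optional header line and conservation
#' lines, which are discarded) into an [alignment()].
#'
#' @param path Path to the alignment file.
#' @param dialect `"fasta"` or `"clustal"`.
#' @return An `aa_alignment`.
#' @export
read_alignment <- function(path, dialect = c("fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_format("file does not exist: %s", path)
  if (dialect == "fasta") {
    recs <- parse_fasta_lines(readLines(path, warn = FALSE),
                              what = basename(path), allow_gap = TRUE)
    alignment(setNames(recs$seq, recs$id))
  } else {
    # normalise header spacing (exactly two blank lines after the CLUSTAL
    # line) so slightly trimmed files are still accepted
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !grepl("^CLUSTAL", lines[1])) {
      stop_format("%s: missing CLUSTAL header line", basename(path))
    }
    body <- lines[-1]
    while (length(body) && !nzchar(trimws(body[1]))) body <- body[-1]
    norm <- tempfile(fileext = ".aln")
    on.exit(unlink(norm), add = TRUE)
    writeLines(c(lines[1], "", "", body), norm)
    msa <- Biostrings::readAAMultipleAlignment(norm, format = "clustal")
    strings <- toupper(as.character(Biostrings::unmasked(msa)))
    strings <- gsub(".", "-", strings, fixed = TRUE)
    alignment(strings)
  }
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An `aa_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  strings <- aln_strings(aln)
  write_fasta(tibble(id = names(strings), seq = unname(strings)), path)
}

#' Map between alignment columns and ungapped residue positions
#'
#' Every member of an alignment induces a bijection between its ungapped
#' residue positions (1-based) and the alignment columns where those residues
#' sit. `ungapped_to_col()` returns, for one member, the column of each
#' ungapped position; `col_to_ungapped()` returns, for each alignment column,
#' the member's ungapped position there (`NA` at gaps).
#'
#' @param aln An `aa_alignment`.
#' @param id A member id.
#' @return An integer vector (see description).
#' @export
ungapped_to_col <- function(aln, id) {
  chars <- member_chars(aln, id)
  which(chars != GAP_CHAR)
}

#' @rdname ungapped_to_col
#' @export
col_to_ungapped <- function(aln, id) {
  chars <- member_chars(aln, id)
  res <- cumsum(chars != GAP_CHAR)
  res[chars == GAP_CHAR] <- NA_integer_
  as.integer(res)
}

member_chars <- function(aln, id) {
  if (!id %in% rownames(aln)) stop_domain("no alignment member named '%s'", id)
  unclass(aln)[id, ]
}
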