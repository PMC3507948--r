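#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-line) protein FASTA file into a tibble with one
#' row per record. Sequences are uppercased, whitespace is removed, and a
#' single terminal stop codon `*` is stripped. Validation is strict: only the
#' 20 canonical one-letter residues plus `X` are accepted, duplicate record
#' ids are an error, and format errors name the offending line and character.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `desc` (remainder of the header, possibly empty) and `seq`.
#'   An empty file yields a zero-row tibble.
#' @seealso [write_fasta()], [read_alignment()]
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "MKV", ">b", "GGR"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  parse_fasta_lines(lines, what = basename(path))
}

parse_fasta_lines <- function(lines, what = "input", allow_gap = FALSE) {
  allowed <- if (allow_gap) c(AA_ALPHABET, GAP_CHAR) else AA_ALPHABET
  keep <- !grepl("^\\s*$", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(tibble(id = character(), desc = character(), seq = character()))
  }
  is_header <- startsWith(lines, ">")
  if (!is_header[1]) {
    stop_format("%s: line %d: expected a '>' header before sequence data",
                what, line_no[1])
  }
  rec <- cumsum(is_header)
  ids <- character(max(rec)); descs <- character(max(rec)); seqs <- character(max(rec))
  for (r in seq_len(max(rec))) {
    idx <- which(rec == r)
    header <- sub("^>", "", lines[idx[1]])
    tok <- stringr::str_match(header, "^(\\S*)\\s*(.*)$")
    ids[r] <- tok[2]
    descs[r] <- tok[3]
    if (ids[r] == "") stop_format("%s: line %d: empty record id", what, line_no[idx[1]])
    body_idx <- idx[-1]
    body <- gsub("\\s", "", lines[body_idx])
    s <- toupper(paste(body, collapse = ""))
    s <- sub("\\*$", "", s)
    if (nchar(s) == 0L) {
      stop_format("%s: record '%s' has an empty sequence", what, ids[r])
    }
    cc <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!cc %in% allowed)
    if (length(bad)) {
      # locate the line holding the first bad character
      off <- cumsum(nchar(body))
      ln <- body_idx[which(off >= bad[1])[1]]
      stop_format("%s: line %d: illegal character '%s' in record '%s'",
                  what, line_no[ln], cc[bad[1]], ids[r])
    }
    seqs[r] <- s
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_format("%s: duplicate record id '%s'", what, dup[1])
  tibble(id = ids, desc = descs, seq = seqs)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs A tibble or data frame with columns `id` and `seq`, and
#'   optionally `desc` (as returned by [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  seqs <- as_tibble(seqs)
  desc <- if ("desc" %in% names(seqs)) seqs$desc else rep("", nrow(seqs))
  headers <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  out <- purrr::map2(headers, seqs$seq, function(h, s) {
    body <- stringr::str_sub(s, seq(1, nchar(s), width),
                             pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    c(paste0(">", h), body)
  })
  writeLines(unlist(out), path)
  invisible(path)
}
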