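# Tabular inputs: BLAST-style hit tables and MALDI centroid peak lists.
# Both are headerless TSV with '#' comment lines; numeric fields are
# validated row by row so format errors carry the offending row number.

read_tsv_rows <- function(path, what) {
  if (!file.exists(path)) stop_format("file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(rows = strsplit(lines[keep], "\t", fixed = TRUE), line_no = which(keep))
}

num_field <- function(x, row, col, what) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    stop_format("%s: row %d: non-numeric value '%s' in column %d",
                what, row, x[is.na(v)][1], col)
  }
  v
}

#' Read a BLAST-style tabular hit list
#'
#' Expects headerless tab-separated rows `query, subject, bitscore, evalue`
#' (a subset of BLAST `-outfmt 6`); lines starting with `#` are skipped.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `query`, `subject`, `bitscore` (finite,
#'   non-negative) and `evalue` (non-negative). Duplicate (query, subject)
#'   pairs are an error.
#' @export
read_hit_table <- function(path) {
  parsed <- read_tsv_rows(path, what = basename(path))
  if (length(parsed$rows) == 0L) {
    return(tibble(query = character(), subject = character(),
                  bitscore = double(), evalue = double()))
  }
  what <- basename(path)
  nf <- lengths(parsed$rows)
  if (any(nf != 4L)) {
    i <- which(nf != 4L)[1]
    stop_format("%s: row %d: expected 4 tab-separated fields, got %d",
                what, parsed$line_no[i], nf[i])
  }
  m <- do.call(rbind, parsed$rows)
  bits <- purrr::map2_dbl(m[, 3], parsed$line_no, ~ num_field(.x, .y, 3L, what))
  eval <- purrr::map2_dbl(m[, 4], parsed$line_no, ~ num_field(.x, .y, 4L, what))
  tab <- tibble(query = m[, 1], subject = m[, 2], bitscore = bits, evalue = eval)
  validate_hit_table(tab, what)
}

validate_hit_table <- function(tab, what = "hit table") {
  if (any(!is.finite(tab$bitscore)) || any(tab$bitscore < 0)) {
    stop_format("%s: bitscores must be finite and non-negative", what)
  }
  if (any(tab$evalue < 0)) stop_format("%s: e-values must be non-negative", what)
  dup <- duplicated(tab[, c("query", "subject")])
  if (any(dup)) {
    stop_format("%s: duplicate (query, subject) pair ('%s', '%s')",
                what, tab$query[dup][1], tab$subject[dup][1])
  }
  tab
}

#' Read a centroid peak list
#'
#' Expects headerless tab-separated rows `mass` or `mass, intensity`
#' (centroid mass in Da, relative intensity in arbitrary units); `#` comment
#' lines are skipped. A missing intensity column defaults to 0.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `mass` (strictly positive, sorted ascending)
#'   and `intensity` (>= 0).
#' @export
read_peaklist <- function(path) {
  parsed <- read_tsv_rows(path, what = basename(path))
  what <- basename(path)
  if (length(parsed$rows) == 0L) {
    return(tibble(mass = double(), intensity = double()))
  }
  nf <- lengths(parsed$rows)
  if (any(nf > 2L)) {
    i <- which(nf > 2L)[1]
    stop_format("%s: row %d: expected 1-2 tab-separated fields, got %d",
                what, parsed$line_no[i], nf[i])
  }
  mass <- purrr::map2_dbl(purrr::map_chr(parsed$rows, 1), parsed$line_no,
                          ~ num_field(.x, .y, 1L, what))
  intensity <- purrr::map2_dbl(parsed$rows, parsed$line_no, function(r, ln) {
    if (length(r) < 2L) 0 else num_field(r[2], ln, 2L, what)
  })
  if (any(mass <= 0)) {
    stop_format("%s: row %d: centroid mass must be strictly positive",
                what, parsed$line_no[which(mass <= 0)[1]])
  }
  if (any(intensity < 0)) {
    stop_format("%s: row %d: intensity must be non-negative",
                what, parsed$line_no[which(intensity < 0)[1]])
  }
  ord <- order(mass)
  tibble(mass = mass[ord], intensity = intensity[ord])
}
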