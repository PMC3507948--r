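# In-silico trypsin digestion, peptide masses with modification forms, and
# matching of theoretical masses against observed MALDI-TOF centroid peaks.

#' In-silico tryptic digest of a protein
#'
#' Cleaves after every K or R not followed by P, and enumerates the peptides
#' spanning up to `max_missed` internal (uncut) cleavage sites.
#'
#' @param protein A protein sequence: a plain string or a one-row tibble with
#'   `id`/`seq` columns (as from [read_fasta()]).
#' @param max_missed Maximum number of missed cleavages (>= 0).
#' @param parent_id Id recorded in the output (taken from the tibble when
#'   available).
#' @return A tibble with one row per peptide: `parent_id`, `start`, `end`
#'   (1-based inclusive), `sequence`, `missed`.
#' @examples
#' tryptic_digest("AKRPGR")
#' tryptic_digest("MKAKG", max_missed = 1)
#' @export
tryptic_digest <- function(protein, max_missed = 0L, parent_id = NULL) {
  if (is.data.frame(protein)) {
    parent_id <- parent_id %||% protein$id[1]
    protein <- protein$seq[1]
  }
  parent_id <- parent_id %||% "protein"
  if (max_missed < 0L) stop_domain("max_missed must be >= 0")
  protein <- toupper(protein)
  check_residues(setNames(protein, parent_id), allow_gap = FALSE)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # cut after position i when chars[i] is K/R and chars[i+1] is not P
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n & chars[pmin(cuts + 1L, n)] != "P"]
  bounds <- c(0L, cuts, n)  # fragment f spans bounds[f]+1 .. bounds[f+1]
  nf <- length(bounds) - 1L
  out <- purrr::map(seq_len(nf), function(f) {
    last <- min(nf, f + max_missed)
    tibble(
      parent_id = parent_id,
      start = bounds[f] + 1L,
      end = bounds[(f + 1L):(last + 1L)],
      missed = 0L:(last - f)
    )
  })
  out <- dplyr::bind_rows(out)
  out$sequence <- substring(protein, out$start, out$end)
  dplyr::select(out, "parent_id", "start", "end", "sequence", "missed")
}

#' Monoisotopic mass of a peptide, with optional modifications
#'
#' Sum of standard residue monoisotopic masses plus one water (18.010565 Da),
#' plus modification deltas: +15.994915 per Met oxidation, -17.026549 for
#' N-terminal Gln to pyroglutamate, +42.010565 for N-terminal acetylation.
#'
#' @param sequence Peptide sequence(s); canonical residues only (`X` has no
#'   defined mass and is an error).
#' @param n_oxidation Number of oxidised methionines (vectorised).
#' @param pyroglu,acetyl Logical; apply the N-terminal modification.
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @examples
#' mono_mass("GG")
#' @export
mono_mass <- function(sequence, n_oxidation = 0L, pyroglu = FALSE,
                      acetyl = FALSE) {
  base <- residue_mass_sum(sequence, MONO_RESIDUE) + MONO_WATER
  n_m <- stringr::str_count(sequence, "M")
  if (any(n_oxidation > n_m)) {
    stop_domain("more oxidations requested than methionines present")
  }
  if (any(pyroglu & !startsWith(sequence, "Q"))) {
    stop_domain("pyroGlu requires an N-terminal glutamine")
  }
  base + n_oxidation * MOD_DELTAS[["oxidation"]] +
    pyroglu * MOD_DELTAS[["pyroglu"]] + acetyl * MOD_DELTAS[["acetyl"]]
}

residue_mass_sum <- function(sequence, table) {
  vapply(sequence, function(s) {
    if (!nzchar(s)) stop_domain("mass of an empty sequence is undefined")
    cc <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    mm <- table[cc]
    if (anyNA(mm)) {
      stop_domain("mass undefined for residue '%s'", cc[is.na(mm)][1])
    }
    sum(mm)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Average molecular weight of a protein
#'
#' @param protein Protein sequence (string or `id`/`seq` tibble row).
#' @return The average (isotope-abundance-weighted) molecular weight in kDa.
#' @export
average_mw <- function(protein) {
  if (is.data.frame(protein)) protein <- protein$seq[1]
  (residue_mass_sum(protein, AVG_RESIDUE) + AVG_WATER) / 1000
}

#' Enumerate modification forms of digest peptides
#'
#' Expands each peptide into its admissible modification forms: N-terminal
#' pyroglutamate only when the peptide starts with Q; N-terminal acetylation
#' only for the protein's first peptide (`start == 1`); Met oxidation
#' enumerated by count from 0 to the number of methionines (peptide mass
#' fingerprinting cannot localise the oxidised site, so only the count is
#' tracked). The two N-terminal states are mutually exclusive. At most
#' `max_forms` forms are kept per peptide.
#'
#' @param peptides A digest tibble from [tryptic_digest()].
#' @param enabled Subset of `c("acetyl", "pyroglu", "oxidation")`.
#' @param max_forms Combinatorial cap per peptide (default 16).
#' @return The digest tibble expanded with `n_oxidation`, `pyroglu`,
#'   `acetyl`, a human-readable `mods` label, and `mono_mass` (Da).
#' @export
modification_forms <- function(peptides,
                               enabled = c("acetyl", "pyroglu", "oxidation"),
                               max_forms = 16L) {
  bad <- setdiff(enabled, c("acetyl", "pyroglu", "oxidation"))
  if (length(bad)) stop_domain("unknown modification '%s'", bad[1])
  expand_one <- function(row) {
    n_m <- if ("oxidation" %in% enabled) stringr::str_count(row$sequence, "M") else 0L
    nterm <- "none"
    if ("pyroglu" %in% enabled && startsWith(row$sequence, "Q")) {
      nterm <- c(nterm, "pyroglu")
    }
    if ("acetyl" %in% enabled && row$start == 1L) nterm <- c(nterm, "acetyl")
    forms <- tidyr::expand_grid(n_oxidation = 0L:n_m, nterm = nterm)
    forms <- head(forms, max_forms)
    dplyr::bind_cols(row[rep(1L, nrow(forms)), ], forms)
  }
  out <- dplyr::bind_rows(purrr::map(seq_len(nrow(peptides)),
                                     function(i) expand_one(peptides[i, ])))
  out$pyroglu <- out$nterm == "pyroglu"
  out$acetyl <- out$nterm == "acetyl"
  out$nterm <- NULL
  out$mods <- mods_label(out$n_oxidation, out$pyroglu, out$acetyl)
  out$mono_mass <- mono_mass(out$sequence, out$n_oxidation, out$pyroglu,
                             out$acetyl)
  out
}

mods_label <- function(n_ox, pyroglu, acetyl) {
  lab <- purrr::pmap_chr(list(n_ox, pyroglu, acetyl), function(o, p, a) {
    parts <- c(if (a) "acetyl", if (p) "pyroGlu",
               if (o > 0) paste0(o, "xMetOx"))
    paste(parts, collapse = "+")
  })
  ifelse(nzchar(lab), lab, "")
}

#' Match observed centroid peaks against theoretical peptide masses
#'
#' Each observed peak is assigned to the nearest theoretical mass within an
#' absolute tolerance (ties broken toward the smaller theoretical mass). A
#' theoretical form may collect several peaks, but each peak matches at most
#' one form. Sequence coverage is the fraction of the parent protein inside
#' the union of matched peptide ranges.
#'
#' @param theoretical A tibble of theoretical forms with columns `start`,
#'   `end`, `sequence`, `mono_mass` (e.g. from [modification_forms()] or
#'   [tryptic_digest()] piped through [modification_forms()]).
#' @param observed A peak list tibble (`mass`, optionally `intensity`), as
#'   from [read_peaklist()].
#' @param tol Absolute matching tolerance in Da (default 0.1).
#' @param parent_length Parent protein length for the coverage denominator;
#'   defaults to `max(theoretical$end)`.
#' @param charge_adduct Set `TRUE` when the peak list holds singly-protonated
#'   m/z values: 1.007276 Da is subtracted from each observed mass first.
#' @return A `match_report`: `tidy()` gives the match table (`observed`,
#'   `intensity`, `theoretical`, `difference` = observed - theoretical, and
#'   the peptide columns); `glance()` gives `coverage`, `n_matched_peaks`,
#'   `n_matched_forms`, `n_matched_ranges`, `n_unmatched`.
#' @export
match_peaks <- function(theoretical, observed, tol = 0.1,
                        parent_length = NULL, charge_adduct = FALSE) {
  if (tol <= 0) stop_domain("tolerance must be > 0")
  if (!"mono_mass" %in% names(theoretical)) {
    theoretical <- dplyr::mutate(theoretical, mono_mass = mono_mass(.data$sequence))
  }
  parent_length <- parent_length %||% max(theoretical$end)
  obs_mass <- observed$mass - if (charge_adduct) PROTON_MASS else 0
  intensity <- if ("intensity" %in% names(observed)) observed$intensity else rep(0, nrow(observed))

  hit <- integer(nrow(observed))
  for (i in seq_along(obs_mass)) {
    delta <- abs(theoretical$mono_mass - obs_mass[i])
    ok <- which(delta <= tol)
    if (length(ok) == 0L) { hit[i] <- NA_integer_; next }
    best <- ok[order(delta[ok], theoretical$mono_mass[ok])][1]
    hit[i] <- best
  }

  matched <- which(!is.na(hit))
  theo_mass <- theoretical$mono_mass[hit[matched]]
  matches <- dplyr::bind_cols(
    tibble(observed = obs_mass[matched], intensity = intensity[matched],
           theoretical = theo_mass,
           difference = obs_mass[matched] - theo_mass),
    theoretical[hit[matched], setdiff(names(theoretical), "mono_mass")]
  )
  unmatched <- tibble(observed = obs_mass[is.na(hit)],
                      intensity = intensity[is.na(hit)])
  cov <- if (nrow(matches)) {
    peptide_coverage(matches, parent_length)
  } else 0

  structure(list(
    matches = matches, unmatched_observed = unmatched, coverage = cov,
    parent_length = parent_length, tol = tol,
    n_matched_peaks = nrow(matches),
    n_matched_forms = nrow(dplyr::distinct(matches, .data$theoretical)),
    n_matched_ranges = nrow(dplyr::distinct(matches, .data$start, .data$end))
  ), class = "match_report")
}

#' Sequence coverage of a set of peptide ranges
#'
#' @param ranges A tibble/data frame with 1-based inclusive `start` and `end`
#'   columns.
#' @param parent_length Length of the parent protein.
#' @return Fraction in `[0, 1]`: size of the union of ranges over
#'   `parent_length`.
#' @export
peptide_coverage <- function(ranges, parent_length) {
  if (nrow(ranges) == 0L) return(0)
  if (any(ranges$start < 1L) || any(ranges$end > parent_length) ||
      any(ranges$end < ranges$start)) {
    stop_domain("peptide range outside 1..%d", parent_length)
  }
  covered <- IRanges::reduce(IRanges::IRanges(ranges$start, ranges$end))
  sum(IRanges::width(covered)) / parent_length
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report: %d peaks matched (%d forms, %d ranges), %d unmatched; coverage %.1f%% of %d aa at +/-%g Da>\n",
              x$n_matched_peaks, x$n_matched_forms, x$n_matched_ranges,
              nrow(x$unmatched_observed), 100 * x$coverage,
              x$parent_length, x$tol))
  invisible(x)
}

#' @rdname match_peaks
#' @param x A `match_report`.
#' @param ... Unused.
#' @method tidy match_report
#' @export
tidy.match_report <- function(x, ...) x$matches

#' @rdname match_peaks
#' @method glance match_report
#' @export
glance.match_report <- function(x, ...) {
  tibble(coverage = x$coverage, n_matched_peaks = x$n_matched_peaks,
         n_matched_forms = x$n_matched_forms,
         n_matched_ranges = x$n_matched_ranges,
         n_unmatched = nrow(x$unmatched_observed),
         parent_length = x$parent_length, tol = x$tol)
}
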