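#' Published MALDI-TOF fingerprint of the lamprey RPE65 band
#'
#' Loads the packaged table of published centroid masses, theoretical tryptic
#' monoisotopic masses, mass differences, relative intensities and peptide
#' positions for the trypsinized sea lamprey RPE65 immunoreactive band
#' (537-residue protein).
#'
#' @return A tibble with columns `centroid_mass`, `theoretical_mass`,
#'   `difference`, `intensity`, `start`, `end`, `modification`.
#' @export
lamprey_rpe65_pmf <- function() {
  path <- system.file("extdata", "lamprey_rpe65_pmf.tsv", package = "gainscan")
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           centroid_mass = "d", theoretical_mass = "d",
                           difference = "d", intensity = "d",
                           start = "i", end = "i", modification = "c"
                         ))
  out$modification[is.na(out$modification)] <- ""
  out
}

#' Path to the packaged accession FASTA files, if fetched
#'
#' The package never downloads sequences itself; `scripts/fetch_accessions.R`
#' (in the source repository) retrieves the deposited accessions from NCBI
#' when network access is available and stores them under
#' `inst/extdata/accessions/`. This helper returns the installed path of one
#' such file, or `""` when it has not been fetched.
#'
#' @param accession Accession token, e.g. `"JX115001"` (lamprey RPE65) or
#'   `"NP_000320"` (human RPE65).
#' @return File path or `""`.
#' @export
accession_fasta <- function(accession) {
  system.file("extdata", "accessions", paste0(accession, ".fasta"),
              package = "gainscan")
}
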