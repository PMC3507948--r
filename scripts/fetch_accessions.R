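#!/usr/bin/env Rscript
# Fetch the deposited protein accessions used by the accession-dependent
# integration checks and store them as plain FASTA under
# inst/extdata/accessions/. Run from the package source root, with network
# access:
#
#     Rscript scripts/fetch_accessions.R
#
# The package library itself never touches the network; this helper is the
# only downloader. Protein accessions are fetched from the NCBI protein
# database; nucleotide accessions via their CDS translation.

eutils <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"

fetch <- function(id, db, rettype) {
  url <- sprintf("%s?db=%s&id=%s&rettype=%s&retmode=text", eutils, db, id, rettype)
  txt <- tryCatch(readLines(url, warn = FALSE), error = function(e) character())
  if (!length(txt) || !startsWith(txt[1], ">")) {
    stop(sprintf("could not fetch %s from NCBI %s", id, db))
  }
  txt
}

dir.create("inst/extdata/accessions", recursive = TRUE, showWarnings = FALSE)

protein_accessions <- c("NP_000320", "AAH31053")
nucleotide_accessions <- c("JX115000", "JX115001", "JX115002", "JX115003")

for (acc in protein_accessions) {
  writeLines(fetch(acc, "protein", "fasta"),
             file.path("inst/extdata/accessions", paste0(acc, ".fasta")))
  message("fetched ", acc)
}
for (acc in nucleotide_accessions) {
  txt <- fetch(acc, "nuccore", "fasta_cds_aa")
  # normalise the CDS header to the bare accession token
  txt[1] <- paste0(">", acc, " ", sub("^>", "", txt[1]))
  writeLines(txt, file.path("inst/extdata/accessions", paste0(acc, ".fasta")))
  message("fetched ", acc)
}
message("done")
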