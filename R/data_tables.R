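# Published summary tables for the five Cyrtodactylus mitogenomes,
# shipped as plain TSVs. These are inputs for desk-scale reproduction of
# the reported skew and domain-size arithmetic without downloading the
# accessions.

.read_extdata <- function(file) {
  read.delim(system.file("extdata", file, package = "mitocr"),
             comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Reported whole-mitogenome composition of five Cyrtodactylus species
#'
#' Per-accession (DDBJ AP018114-AP018118) genome size, control-region
#' size, per-base percentages and heavy-strand AT/GC skews as reported
#' for the five sequenced Cyrtodactylus mitogenomes.
#'
#' @return data.frame with one row per accession.
#' @export
cyrtodactylus_composition <- function() {
  .read_extdata("cyrtodactylus_mitogenome_composition.tsv")
}

#' Reported control-region domain sizes of five Cyrtodactylus species
#'
#' Per-accession CR, ETAS, CCR and CSB domain sizes (bp), per-domain A+T%
#' and the CSB-F/CSB-1/CSB-2/CSB-3 block sizes.
#'
#' @return data.frame with one row per accession.
#' @export
cyrtodactylus_cr_domains <- function() {
  .read_extdata("cyrtodactylus_cr_domains.tsv")
}
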