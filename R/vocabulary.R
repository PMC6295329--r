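# Controlled vocabulary for mitochondrial gene naming.
#
# Canonical tokens: 13 protein-coding genes, 22 tRNAs (Ser/Leu disambiguated
# by codon family), rrnS/rrnL, OL and CR. Synonym handling is
# case/punctuation-insensitive; the shipped synonym table
# (inst/extdata/gene_vocabulary.tsv) can be extended by the user.

MITO_VOCAB <- c(
  "ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6",
  "COI", "COII", "COIII", "ATP6", "ATP8", "Cytb",
  "rrnS", "rrnL", "OL", "CR",
  "trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH", "trnI", "trnK",
  "trnM", "trnN", "trnP", "trnQ", "trnR", "trnT", "trnV", "trnW", "trnY",
  "trnL(UUR)", "trnL(CUN)", "trnS(UCN)", "trnS(AGY)",
  # recognized but codon-family-ambiguous forms
  "trnL", "trnS"
)

.AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# anticodons distinguishing the duplicated Ser/Leu tRNAs
.ANTICODON_CLASS <- c(
  TGA = "UCN", UGA = "UCN", GCT = "AGY", GCU = "AGY",
  TAA = "UUR", UAA = "UUR", TAG = "CUN", UAG = "CUN"
)

.vocab_env <- new.env(parent = emptyenv())

.squeeze <- function(x) gsub("[^A-Z0-9]", "", toupper(x))

.load_vocab_table <- function() {
  if (!is.null(.vocab_env$tab)) return(.vocab_env$tab)
  path <- system.file("extdata", "gene_vocabulary.tsv", package = "mitocr")
  tab <- read.delim(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  .vocab_env$tab <- setNames(tab$token, .squeeze(tab$synonym))
  .vocab_env$tab
}

#' Normalize a raw gene label into the controlled vocabulary
#'
#' Maps the heterogeneous gene names found in submitted annotations
#' (`"COX1"`, `"CO1"`, `"COI"`; `"ATPase8"`; `"D-loop"`, `"control region"`;
#' `"tRNA-Ser"` with a `UCN` note, ...) onto a fixed token set. The mapping
#' is case- and punctuation-insensitive and total: anything unrecognized
#' yields `"unknown"`. Serine and leucine tRNAs are disambiguated by codon
#' family (`UCN`/`AGY`, `UUR`/`CUN`) or by anticodon (`TGA`, `GCT`, `TAA`,
#' `TAG`) when that information is present in `raw`; a bare `"tRNA-Ser"`
#' normalizes to the ambiguous token `"trnS"`.
#'
#' @param raw character vector of raw labels.
#' @param extra optional named character vector of additional synonym ->
#'   token mappings (names are matched after squeezing case/punctuation).
#' @return character vector of vocabulary tokens (`"unknown"` for
#'   unrecognized input). Idempotent: tokens map to themselves.
#' @export
normalize_label <- function(raw, extra = NULL) {
  vapply(raw, function(x) .normalize_one(x, extra), character(1),
         USE.NAMES = FALSE)
}

.normalize_one <- function(raw, extra = NULL) {
  if (is.na(raw) || !nzchar(raw)) return("unknown")
  key <- .squeeze(raw)
  if (!nzchar(key)) return("unknown")
  if (!is.null(extra)) {
    ek <- .squeeze(names(extra))
    hit <- match(key, ek)
    if (!is.na(hit)) return(unname(extra[hit]))
  }
  tab <- .load_vocab_table()
  if (!is.na(tab[key])) return(unname(tab[key]))
  # tRNA forms: trnX, tRNA-Xxx, optionally with codon family or anticodon
  m <- regmatches(key, regexec("^TRNA?(.+)$", key))[[1]]
  if (length(m) == 2L) {
    rest <- m[2]
    codon <- NA_character_
    for (fam in c("UCN", "AGY", "UUR", "CUN")) {
      if (grepl(fam, rest, fixed = TRUE)) {
        codon <- fam
        rest <- sub(fam, "", rest, fixed = TRUE)
        break
      }
    }
    aa <- NA_character_
    if (rest %in% names(.AA3_TO_1)) {
      aa <- .AA3_TO_1[[rest]]
    } else if (nchar(rest) == 1L && rest %in% .AA3_TO_1) {
      aa <- rest
    } else {
      # one-letter aa followed by an anticodon, e.g. "STGA", "SERGCT"
      m2 <- regmatches(rest, regexec("^([A-Z]{1,3})([TUAGC]{3})$", rest))[[1]]
      if (length(m2) == 3L) {
        base <- m2[2]
        anti <- m2[3]
        aa0 <- if (base %in% names(.AA3_TO_1)) .AA3_TO_1[[base]]
               else if (nchar(base) == 1L && base %in% .AA3_TO_1) base
               else NA_character_
        if (!is.na(aa0) && aa0 %in% c("S", "L") &&
            anti %in% names(.ANTICODON_CLASS)) {
          aa <- aa0
          codon <- .ANTICODON_CLASS[[anti]]
        }
      }
    }
    if (!is.na(aa)) {
      if (aa %in% c("S", "L")) {
        if (!is.na(codon)) return(sprintf("trn%s(%s)", aa, codon))
        return(paste0("trn", aa))
      }
      tok <- paste0("trn", aa)
      if (tok %in% MITO_VOCAB) return(tok)
    }
  }
  "unknown"
}
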