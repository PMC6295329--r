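#' @importFrom stats setNames sd rnorm runif
#' @importFrom utils adist head tail read.delim write.table
NULL

# IUPAC nucleotide code -> set of concrete bases
IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_CODES)

# complement map covering all IUPAC codes
.COMP_FROM <- "ACGTRYSWKMBDHVN"
.COMP_TO   <- "TGCAYRSWMKVHDBN"

#' Reverse-complement a DNA string
#'
#' Handles the full IUPAC alphabet (R<->Y, K<->M, B<->V, D<->H; S, W, N are
#' self-complementary).
#'
#' @param x a single DNA string.
#' @return the reverse complement, same case-insensitive alphabet, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  paste(rev(strsplit(chartr(.COMP_FROM, .COMP_TO, x), "", fixed = TRUE)[[1]]),
        collapse = "")
}

.valid_iupac <- function(chars) all(chars %in% IUPAC_LETTERS)

#' DNA sequence with optional circular topology
#'
#' The basic sequence container consumed by every analysis stage: an
#' identifier, an uppercase residue string over the IUPAC alphabet, and a
#' circularity flag. Circular sequences expose rotation without mutation via
#' [rotate()].
#'
#' @param id sequence identifier.
#' @param residues DNA string (any case; validated against the IUPAC alphabet).
#' @param circular logical; is the molecule circular?
#' @return an object of class `nuc_sequence`.
#' @export
nuc_sequence <- function(id, residues, circular = FALSE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L,
            is.logical(circular), length(circular) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("sequence '", id, "' is empty")
  chars <- unique(strsplit(residues, "", fixed = TRUE)[[1]])
  if (!.valid_iupac(chars)) {
    stop("sequence '", id, "' contains non-IUPAC characters: ",
         paste(setdiff(chars, IUPAC_LETTERS), collapse = ", "))
  }
  structure(list(id = id, residues = residues, circular = circular),
            class = "nuc_sequence")
}

#' @export
print.nuc_sequence <- function(x, ...) {
  cat(sprintf("<nuc_sequence> %s: %d bp (%s)\n", x$id, nchar(x$residues),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

seq_length <- function(x) nchar(x$residues)

#' Rotate a circular sequence
#'
#' Returns a copy whose origin is moved forward by `offset` bases; the
#' original object is untouched.
#'
#' @param x a circular [nuc_sequence()].
#' @param offset number of bases to rotate by (any integer; reduced modulo
#'   the sequence length).
#' @return a rotated `nuc_sequence`.
#' @export
rotate <- function(x, offset) {
  stopifnot(inherits(x, "nuc_sequence"))
  if (!x$circular) stop("rotation is only defined for circular sequences")
  n <- seq_length(x)
  k <- ((as.integer(offset) %% n) + n) %% n
  if (k == 0L) return(x)
  nuc_sequence(x$id,
               paste0(substr(x$residues, k + 1L, n), substr(x$residues, 1L, k)),
               circular = TRUE)
}

# 0-based half-open subsequence with circular wrap when start >= end
subseq0 <- function(residues, start, end, circular = FALSE) {
  n <- nchar(residues)
  if (start < 0L || end > n || (!circular && start > end))
    stop("subsequence [", start, ", ", end, ") out of range for length ", n)
  if (start <= end) {
    if (start == end) return("")
    return(substr(residues, start + 1L, end))
  }
  # wraps across the origin
  paste0(substr(residues, start + 1L, n), substr(residues, 1L, end))
}
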