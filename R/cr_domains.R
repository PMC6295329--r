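# Control-region extraction and domain partitioning.
#
# The CR of the canonical arrangement lies between trnP and trnF. It is
# partitioned into three consecutive domains: ETAS (carrying TAS motifs,
# usually inside a tandem-repeat array), the central conserved region (CCR,
# carrying CSB-F) and the CSB domain (CSB-1/2/3, often with microsatellites).
# Domain boundaries are placed from motif/array evidence: the ETAS/CCR
# boundary at the end of the last TAS-bearing tandem array, the CCR/CSB
# boundary at the start of the best CSB-1 hit. The exact anchoring rule is
# configurable; the enforced invariant is the exact three-way partition
# (ETAS + CCR + CSB = CR, no gaps, no overlaps).

#' Degenerate consensus motif definition
#'
#' @param name motif name (`"TAS"`, `"CSB-F"`, `"CSB-1"`, `"CSB-2"`,
#'   `"CSB-3"` or a user-chosen name).
#' @param pattern IUPAC string.
#' @param max_mismatch maximum Hamming mismatches tolerated in a hit.
#' @return an object of class `motif_def`.
#' @export
motif_def <- function(name, pattern, max_mismatch = 0L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(pattern), length(pattern) == 1L, nzchar(pattern),
            max_mismatch >= 0L)
  pattern <- toupper(pattern)
  chars <- unique(strsplit(pattern, "", fixed = TRUE)[[1]])
  if (!.valid_iupac(chars))
    stop("invalid IUPAC code(s) in pattern: ",
         paste(setdiff(chars, IUPAC_LETTERS), collapse = ", "))
  structure(list(name = name, pattern = pattern,
                 max_mismatch = as.integer(max_mismatch)),
            class = "motif_def")
}

#' Default control-region motif set
#'
#' The TAS pentanucleotide (`TACAT`, exact) plus the four conserved-block
#' consensus motifs used to annotate gecko lizard control regions:
#' CSB-F `CHCGRGAAACCAKCRACCCS`, CSB-1 `KTTMATGCTCGAWRGACATAY`,
#' CSB-2 `AAACCCCCCTTACCCCCC` and CSB-3 `CGCCAAACCCCTAAAACG`. Mismatch
#' budgets default to 0/3/3/2/2 respectively — looser for CSB-1, whose
#' sequence is the least conserved of the three CSB blocks.
#'
#' @return named list of [motif_def()] objects.
#' @export
default_motifs <- function() {
  list(
    TAS     = motif_def("TAS",   "TACAT", 0L),
    `CSB-F` = motif_def("CSB-F", "CHCGRGAAACCAKCRACCCS", 3L),
    `CSB-1` = motif_def("CSB-1", "KTTMATGCTCGAWRGACATAY", 3L),
    `CSB-2` = motif_def("CSB-2", "AAACCCCCCTTACCCCCC", 2L),
    `CSB-3` = motif_def("CSB-3", "CGCCAAACCCCTAAAACG", 2L)
  )
}

#' Extract the control region from an annotated genome
#'
#' Returns the heavy-strand subsequence strictly between the end of trnP
#' and the start of trnF, wrapping across the circular origin when
#' necessary.
#'
#' @param g a [mito_genome()] with trnP and trnF features.
#' @return list with `sequence` (a [nuc_sequence()]) and `span`
#'   (0-based half-open genome coordinates `c(start, end)`; `end < start`
#'   indicates wrap across the origin).
#' @export
extract_cr <- function(g) {
  stopifnot(inherits(g, "mito_genome"))
  f <- g$features
  for (need in c("trnP", "trnF")) {
    if (!(need %in% f$label))
      stop("cannot extract control region: genome lacks a ", need, " feature")
  }
  n <- seq_length(g$sequence)
  # re-join a flank that rotation split across the circular origin
  flank_span <- function(lab) {
    rows <- f[f$label == lab, , drop = FALSE]
    if (nrow(rows) == 2L && any(rows$end == n) && any(rows$start == 0L))
      return(c(rows$start[rows$end == n], rows$end[rows$start == 0L]))
    c(rows$start[1L], rows$end[1L])
  }
  e0 <- flank_span("trnP")[2L]
  s0 <- flank_span("trnF")[1L]
  res <- subseq0(g$sequence$residues, e0, s0, circular = g$sequence$circular)
  if (!nzchar(res)) stop("control region between trnP and trnF is empty")
  list(sequence = nuc_sequence(paste0(g$sequence$id, "_CR"), res),
       span = c(start = e0, end = s0))
}

# per-position IUPAC-aware match lookup: pattern code x sequence base.
# A sequence position matches iff its base is concrete (A/C/G/T) and lies
# in the pattern code's set; N or any ambiguity code in the sequence never
# matches exactly.
.match_tab_env <- new.env(parent = emptyenv())
.iupac_match_table <- function() {
  if (is.null(.match_tab_env$tab)) {
    tab <- matrix(FALSE, nrow = length(IUPAC_LETTERS),
                  ncol = length(IUPAC_LETTERS),
                  dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
    for (p in IUPAC_LETTERS)
      for (s in c("A", "C", "G", "T"))
        tab[p, s] <- s %in% IUPAC_CODES[[p]]
    .match_tab_env$tab <- tab
  }
  .match_tab_env$tab
}

.scan_one_strand <- function(chars, pat_chars, max_mm) {
  n <- length(chars); m <- length(pat_chars)
  nw <- n - m + 1L
  if (nw < 1L) return(integer(0))
  tab <- .iupac_match_table()
  mm <- integer(nw)
  for (j in seq_len(m)) {
    ok <- tab[pat_chars[j], chars[j:(j + nw - 1L)]]
    mm <- mm + as.integer(!ok)
    # early exit impossible vectorized; m is short so this is cheap
  }
  mm
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every window whose IUPAC-aware Hamming distance to the pattern
#' is at most the motif's mismatch budget. A window position matches when
#' the sequence base is one of the concrete bases in the pattern code's
#' set; an N (or any ambiguity code) in the sequence never matches exactly
#' and consumes mismatch budget instead. Hits are sorted by position, then
#' by mismatch count. With `strand = "both"` the reverse complement is also
#' scanned and hit coordinates are mapped back onto the forward strand.
#'
#' @param seq a [nuc_sequence()] or DNA string.
#' @param motif a [motif_def()].
#' @param strand `"H"` (forward only) or `"both"`.
#' @param max_mismatch optional override of the motif's budget.
#' @return data.frame with columns `motif`, `start`, `end` (0-based
#'   half-open), `mismatches`, `strand`.
#' @export
iupac_scan <- function(seq, motif, strand = c("H", "both"),
                       max_mismatch = NULL) {
  strand <- match.arg(strand)
  stopifnot(inherits(motif, "motif_def"))
  res <- if (inherits(seq, "nuc_sequence")) seq$residues else toupper(seq)
  max_mm <- if (is.null(max_mismatch)) motif$max_mismatch
            else as.integer(max_mismatch)
  m <- nchar(motif$pattern)
  n <- nchar(res)
  if (n < m) return(.empty_hits())
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  pat <- strsplit(motif$pattern, "", fixed = TRUE)[[1]]

  mmH <- .scan_one_strand(chars, pat, max_mm)
  hitH <- which(mmH <= max_mm)
  out <- data.frame(motif = rep(motif$name, length(hitH)),
                    start = hitH - 1L, end = hitH - 1L + m,
                    mismatches = mmH[hitH], strand = rep("H", length(hitH)),
                    stringsAsFactors = FALSE)
  if (strand == "both") {
    rc <- strsplit(revcomp(res), "", fixed = TRUE)[[1]]
    mmL <- .scan_one_strand(rc, pat, max_mm)
    hitL <- which(mmL <= max_mm)
    if (length(hitL) > 0L) {
      # window [s, s+m) on the reverse strand maps to [n-s-m, n-s) forward
      s0 <- hitL - 1L
      outL <- data.frame(motif = rep(motif$name, length(hitL)),
                         start = n - s0 - m, end = n - s0,
                         mismatches = mmL[hitL],
                         strand = rep("L", length(hitL)),
                         stringsAsFactors = FALSE)
      out <- rbind(out, outL)
    }
  }
  out <- out[order(out$start, out$mismatches), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(motif = character(), start = integer(), end = integer(),
             mismatches = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Scan a sequence with a full motif set
#'
#' Convenience wrapper running [iupac_scan()] for each motif in a set and
#' row-binding the hits.
#'
#' @param seq a [nuc_sequence()] or DNA string.
#' @param motifs named list of [motif_def()] (default [default_motifs()]).
#' @param strand passed to [iupac_scan()].
#' @return combined hit data.frame.
#' @export
scan_motifs <- function(seq, motifs = default_motifs(), strand = "H") {
  out <- do.call(rbind, lapply(motifs, function(m)
    iupac_scan(seq, m, strand = strand)))
  if (is.null(out)) out <- .empty_hits()
  rownames(out) <- NULL
  out
}

#' Partition a control region into ETAS, CCR and CSB domains
#'
#' Places the ETAS/CCR boundary `e` at the end of the last tandem array
#' containing a TAS hit (fallback: end of the last TAS hit in the 5' half;
#' fallback: `default_etas_fraction` of the CR). Places the CCR/CSB
#' boundary `c` at the start of the best CSB-1 hit — fewest mismatches,
#' leftmost on ties — falling back to CSB-2. The result is an exact
#' three-way partition `[0,e) [e,c) [c,len)` with per-domain A+T%.
#'
#' @param cr a [nuc_sequence()] (the control region).
#' @param arrays list of tandem arrays from [find_tandem_repeats()]; may be
#'   empty.
#' @param hits motif hit data.frame from [scan_motifs()]/[iupac_scan()];
#'   must contain at least one CSB-1 or CSB-2 hit.
#' @param default_etas_fraction fallback ETAS fraction of the CR length
#'   when no TAS evidence exists.
#' @param cr_span optional genome-coordinate span of the CR (from
#'   [extract_cr()]).
#' @return a `cr_partition`: list with `cr_span`, `etas`, `ccr`, `csb`
#'   (0-based half-open CR-local intervals), `hits`,
#'   `domain_at_content` and `boundary_evidence`.
#' @export
partition_cr <- function(cr, arrays = list(), hits,
                         default_etas_fraction = 0.33, cr_span = NULL) {
  stopifnot(inherits(cr, "nuc_sequence"), is.data.frame(hits))
  n <- seq_length(cr)

  # --- ETAS/CCR boundary -------------------------------------------------
  tas_hits <- hits[hits$motif == "TAS", , drop = FALSE]
  e <- NA_integer_; e_how <- NA_character_
  if (length(arrays) > 0L && nrow(tas_hits) > 0L) {
    bearing <- vapply(arrays, function(a)
      any(tas_hits$start >= a$start & tas_hits$end <= a$end), logical(1))
    if (any(bearing)) {
      e <- max(vapply(arrays[bearing], function(a) a$end, numeric(1)))
      e_how <- "end of last TAS-bearing tandem array"
    }
  }
  if (is.na(e) && nrow(tas_hits) > 0L) {
    in5 <- tas_hits[tas_hits$end <= n / 2, , drop = FALSE]
    if (nrow(in5) > 0L) {
      e <- max(in5$end)
      e_how <- "end of last TAS hit in the 5' half"
    }
  }
  if (is.na(e)) {
    e <- as.integer(round(default_etas_fraction * n))
    e_how <- sprintf("default fraction (%.2f) of CR length",
                     default_etas_fraction)
  }
  e <- as.integer(e)

  # --- CCR/CSB boundary --------------------------------------------------
  pick_best <- function(name) {
    h <- hits[hits$motif == name & hits$strand == "H", , drop = FALSE]
    if (nrow(h) == 0L) return(NULL)
    h <- h[order(h$mismatches, h$start), , drop = FALSE]
    h[1L, , drop = FALSE]
  }
  best <- pick_best("CSB-1"); c_how <- "start of best CSB-1 hit"
  if (is.null(best)) { best <- pick_best("CSB-2"); c_how <- "start of best CSB-2 hit (CSB-1 absent)" }
  if (is.null(best))
    stop("partition failure: no CSB-1 or CSB-2 hit in the control region; ",
         "cannot anchor the CCR/CSB boundary")
  cpos <- as.integer(best$start)

  if (e <= 0L || cpos >= n || e >= cpos)
    stop("boundary conflict: ETAS end (", e, ") must fall strictly before ",
         "the CSB start (", cpos, ") within the CR [0, ", n, ")")

  at_pct <- function(s0, e0)
    compute_composition(substr(cr$residues, s0 + 1L, e0))$at_content
  part <- structure(list(
    cr_span = cr_span,
    etas = c(start = 0L, end = e),
    ccr  = c(start = e, end = cpos),
    csb  = c(start = cpos, end = n),
    hits = hits,
    domain_at_content = c(ETAS = at_pct(0L, e), CCR = at_pct(e, cpos),
                          CSB = at_pct(cpos, n), CR = at_pct(0L, n)),
    boundary_evidence = c(etas_ccr = e_how, ccr_csb = c_how)),
    class = "cr_partition")
  stopifnot((part$etas[["end"]] - part$etas[["start"]]) +
              (part$ccr[["end"]] - part$ccr[["start"]]) +
              (part$csb[["end"]] - part$csb[["start"]]) == n)
  part
}

#' @export
print.cr_partition <- function(x, ...) {
  n <- x$csb[["end"]]
  cat(sprintf("<cr_partition> CR %d bp: ETAS [0,%d) %d bp | CCR [%d,%d) %d bp | CSB [%d,%d) %d bp\n",
              n, x$etas[["end"]], x$etas[["end"]],
              x$ccr[["start"]], x$ccr[["end"]],
              x$ccr[["end"]] - x$ccr[["start"]],
              x$csb[["start"]], n, n - x$csb[["start"]]))
  cat(sprintf("  A+T%%: ETAS %.1f | CCR %.1f | CSB %.1f | CR %.1f\n",
              x$domain_at_content[["ETAS"]], x$domain_at_content[["CCR"]],
              x$domain_at_content[["CSB"]], x$domain_at_content[["CR"]]))
  invisible(x)
}
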