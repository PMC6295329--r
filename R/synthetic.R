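# Synthetic mitogenome generator with ground truth.
#
# Emulates the canonical gecko mitogenome layout: a circular ~16.8 kb
# molecule carrying the 37 genes + OL + CR in Type I order (or edited into
# Types II-VI), with a control region assembled as
#   [TAS-bearing tandem array (ETAS)] [CCR with one CSB-F] [CSB segment
#   with CSB-1/2/3 and optional microsatellite runs].
# Gene "sequences" are random placeholders at realistic lengths (ND5
# longest, ATP8 shortest); no codon structure is attempted. Every planted
# coordinate is returned in a truth record that matches the emitted
# annotation exactly, and output is deterministic given the seed.

# realistic vertebrate mitochondrial gene lengths (bp)
.GENE_LENGTHS <- c(
  trnF = 70, rrnS = 950, trnV = 70, rrnL = 1540, `trnL(UUR)` = 72,
  ND1 = 960, trnI = 70, trnQ = 71, trnM = 69, ND2 = 1035, trnW = 69,
  trnA = 68, trnN = 72, OL = 35, trnC = 66, trnY = 68, COI = 1545,
  `trnS(UCN)` = 70, trnD = 68, COII = 684, trnK = 72, ATP8 = 165,
  ATP6 = 684, COIII = 784, trnG = 68, ND3 = 348, trnR = 67, ND4L = 297,
  ND4 = 1370, trnH = 69, `trnS(AGY)` = 66, `trnL(CUN)` = 71, ND5 = 1815,
  ND6 = 520, trnE = 68, Cytb = 1140, trnT = 70, trnP = 69)

#' Specification for a synthetic mitogenome
#'
#' @param seed RNG seed; the generator is deterministic given the spec.
#' @param genome_length target genome size in bp (intergenic spacers are
#'   distributed to approach it; the realized length is reported in the
#'   truth record).
#' @param order_type rearrangement type to emulate (`"I"`..`"VI"`), or a
#'   list of explicit events for a novel arrangement (see [apply_event()]).
#' @param etas_unit_len tandem-repeat unit length in the ETAS domain (bp).
#' @param etas_copies number of unit copies (>= 2).
#' @param etas_divergence per-copy divergence (substitution fraction,
#'   in `[0, 0.5]`); each copy additionally receives a single 1-3 bp indel
#'   with probability 0.1.
#' @param etas_pad extra ETAS bases 3' of the array (bp).
#' @param ccr_len,csb_len CCR and CSB domain lengths (bp).
#' @param microsats list of microsatellite runs to plant in the CSB
#'   domain, each `list(motif=, repeats=)`.
#' @param base_composition named target fractions for A/T/G/C (must sum
#'   to 1).
#' @param unit_sub_divergence for 225-bp-style composite units: divergence
#'   applied between the base 75-mers making up one unit (`NA` for a plain
#'   random unit).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, genome_length = 16800L,
                           order_type = "I",
                           etas_unit_len = 75L, etas_copies = 6L,
                           etas_divergence = 0.05, etas_pad = 40L,
                           ccr_len = 310L, csb_len = 650L,
                           microsats = list(list(motif = "TA", repeats = 6L),
                                            list(motif = "CA", repeats = 5L)),
                           base_composition = c(A = 0.30, T = 0.22,
                                                G = 0.155, C = 0.325),
                           unit_sub_divergence = NA_real_) {
  stopifnot(etas_copies >= 2L, etas_divergence >= 0, etas_divergence <= 0.5,
            abs(sum(base_composition) - 1) < 1e-6)
  if (is.character(order_type))
    stopifnot(order_type %in% c("I", "II", "III", "IV", "V", "VI"))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 order_type = order_type,
                 etas_unit_len = as.integer(etas_unit_len),
                 etas_copies = as.integer(etas_copies),
                 etas_divergence = etas_divergence,
                 etas_pad = as.integer(etas_pad),
                 ccr_len = as.integer(ccr_len),
                 csb_len = as.integer(csb_len),
                 microsats = microsats,
                 base_composition = base_composition,
                 unit_sub_divergence = unit_sub_divergence),
            class = "synthetic_spec")
}

.rand_dna <- function(n, comp) {
  if (n <= 0L) return("")
  paste(sample(names(comp), n, replace = TRUE, prob = comp), collapse = "")
}

# concrete instantiation of an IUPAC pattern
.instantiate_iupac <- function(pattern) {
  paste(vapply(strsplit(pattern, "", fixed = TRUE)[[1]], function(ch) {
    set <- IUPAC_CODES[[ch]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1)), collapse = "")
}

.mutate_copy <- function(unit, divergence, indel_prob = 0.1) {
  chars <- strsplit(unit, "", fixed = TRUE)[[1]]
  nmut <- rbinom(1L, length(chars), divergence)
  if (nmut > 0L) {
    pos <- sample(length(chars), nmut)
    for (p in pos)
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  if (runif(1) < indel_prob && length(chars) > 6L) {
    w <- sample(1:3, 1L)
    if (runif(1) < 0.5) {
      at <- sample(length(chars) - w, 1L)
      chars <- chars[-(at:(at + w - 1L))]
    } else {
      at <- sample(length(chars), 1L)
      ins <- sample(c("A", "C", "G", "T"), w, replace = TRUE)
      chars <- append(chars, ins, after = at)
    }
  }
  paste(chars, collapse = "")
}

# build the ETAS tandem array; TAS (TACAT) planted inside every copy at a
# fixed unit-local offset so divergence never erases it
.build_array_seq <- function(spec, comp) {
  ul <- spec$etas_unit_len
  if (!is.na(spec$unit_sub_divergence) && ul %% 3L == 0L && ul >= 150L) {
    # composite unit: three base-length sub-units, the first two close,
    # the third diverged (a "box-like" member)
    base <- ul %/% 3L
    s1 <- .rand_dna(base, comp)
    tas_at <- sample(3:(base - 8L), 1L)
    substr(s1, tas_at, tas_at + 4L) <- "TACAT"
    s2 <- .mutate_copy(s1, 0.05, indel_prob = 0)
    s3 <- .mutate_copy(s1, spec$unit_sub_divergence, indel_prob = 0)
    unit <- paste0(s1, s2, s3)
  } else {
    unit <- .rand_dna(ul, comp)
    tas_at <- sample(3:(ul - 8L), 1L)
    substr(unit, tas_at, tas_at + 4L) <- "TACAT"
  }
  copies <- vapply(seq_len(spec$etas_copies), function(i) {
    if (i == 1L) unit else .mutate_copy(unit, spec$etas_divergence)
  }, character(1))
  list(seq = paste(copies, collapse = ""), unit = unit, copies = copies)
}

#' Generate a synthetic annotated mitogenome with ground truth
#'
#' Lays the 37 genes + OL + CR out in the Type I order, edits the order
#' according to `spec$order_type` (via [apply_event()] operators), draws
#' gene and spacer sequence from the target base composition, and
#' assembles the control region as a TAS-bearing tandem array (ETAS), a
#' CCR containing one CSB-F instance, and a CSB segment containing
#' CSB-1/2/3 plus any requested microsatellite runs. All planted
#' coordinates are reported in the truth record.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `genome` (a [mito_genome()]) and `truth` (list:
#'   realized `genome_length`, `order` labels, applied `events`, CR-local
#'   `etas_end`/`csb_start`, `array` (start, unit, unit_length, copies),
#'   `motifs` (CR-local data.frame), `microsats`, `cr_span`,
#'   `base_composition` realized fractions).
#' @export
build_mock_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  comp <- spec$base_composition

  # ---- gene order -------------------------------------------------------
  ord <- canonical_type1_order()
  events <- list()
  if (is.character(spec$order_type)) {
    events <- switch(spec$order_type,
      I = list(),
      II = list(list(kind = "duplication", labels = "trnQ"),
                list(kind = "duplication", labels = "ND4")),
      III = list(list(kind = "extra_OL")),
      IV = list(list(kind = "translocation", labels = "trnE",
                     before = "trnP")),
      V = list(list(kind = "deletion", labels = "trnE")),
      VI = list(list(kind = "duplication",
                     labels = c("ND4", "trnH", "trnS(AGY)", "trnL(CUN)",
                                "ND5", "ND6", "trnE", "Cytb", "trnT"))))
  } else {
    events <- spec$order_type
  }
  for (ev in events) ord <- apply_event(ord, ev)

  # ---- control region ---------------------------------------------------
  motifs <- default_motifs()
  arr <- .build_array_seq(spec, comp)
  etas_seq <- paste0(arr$seq, .rand_dna(spec$etas_pad, comp))
  etas_end <- nchar(etas_seq)
  array_start <- 0L
  array_end <- nchar(arr$seq)

  csbF <- .instantiate_iupac(motifs$`CSB-F`$pattern)
  ccr_bg <- spec$ccr_len - nchar(csbF)
  stopifnot(ccr_bg >= 10L)
  f_at <- sample(5L:(ccr_bg - 5L), 1L)
  ccr_seq <- paste0(.rand_dna(f_at, comp), csbF, .rand_dna(ccr_bg - f_at, comp))

  csb1 <- .instantiate_iupac(motifs$`CSB-1`$pattern)
  csb2 <- motifs$`CSB-2`$pattern
  csb3 <- motifs$`CSB-3`$pattern
  ms_seqs <- vapply(spec$microsats, function(m)
    strrep(toupper(m$motif), m$repeats), character(1))
  fixed_len <- nchar(csb1) + nchar(csb2) + nchar(csb3) + sum(nchar(ms_seqs))
  gaps <- spec$csb_len - fixed_len
  stopifnot(gaps >= 12L)
  # CSB-1 opens the domain; microsat 1 between CSB-1 and CSB-2; remaining
  # microsats after CSB-3 (before trnF), mirroring observed placements
  n_ms <- length(ms_seqs)
  pieces <- c(csb1,
              if (n_ms >= 1L) ms_seqs[1L],
              csb2, csb3,
              if (n_ms >= 2L) ms_seqs[-1L])
  ngap <- length(pieces)
  cuts <- sort(sample(0:gaps, ngap, replace = TRUE))
  gap_sizes <- diff(c(0L, cuts, gaps))  # ngap + 1 gaps around pieces
  # keep CSB-1 flush at the domain start so the boundary is sharp
  gap_sizes[2L] <- gap_sizes[2L] + gap_sizes[1L]
  gap_sizes[1L] <- 0L
  csb_parts <- character(0)
  ms_pos <- list()
  cursor <- 0L
  piece_names <- c("CSB-1",
                   if (n_ms >= 1L) paste0("MS", 1L),
                   "CSB-2", "CSB-3",
                   if (n_ms >= 2L) paste0("MS", 2:n_ms))
  motif_rows <- list()
  for (i in seq_along(pieces)) {
    g <- .rand_dna(gap_sizes[i], comp)
    csb_parts <- c(csb_parts, g, pieces[i])
    cursor <- cursor + gap_sizes[i]
    start0 <- cursor
    cursor <- cursor + nchar(pieces[i])
    motif_rows[[i]] <- data.frame(name = piece_names[i], start = start0,
                                  end = cursor, stringsAsFactors = FALSE)
  }
  csb_seq <- paste0(paste(csb_parts, collapse = ""),
                    .rand_dna(gap_sizes[length(gap_sizes)], comp))
  stopifnot(nchar(csb_seq) == spec$csb_len)

  cr_seq <- paste0(etas_seq, ccr_seq, csb_seq)
  csb_start <- nchar(etas_seq) + nchar(ccr_seq)
  cr_motifs <- do.call(rbind, motif_rows)
  cr_motifs$start <- cr_motifs$start + csb_start
  cr_motifs$end <- cr_motifs$end + csb_start
  cr_motifs <- rbind(
    data.frame(name = "CSB-F", start = etas_end + f_at,
               end = etas_end + f_at + nchar(csbF), stringsAsFactors = FALSE),
    cr_motifs)

  # ---- assemble the genome ---------------------------------------------
  labels <- ord$labels
  lens <- integer(length(labels))
  for (i in seq_along(labels)) {
    lens[i] <- if (labels[i] == "CR") nchar(cr_seq)
               else .GENE_LENGTHS[[labels[i]]]
  }
  core <- sum(lens)
  n_spacers <- length(labels)
  spacer_total <- max(0L, spec$genome_length - core)
  base_sp <- spacer_total %/% n_spacers
  extra <- spacer_total %% n_spacers
  spacers <- rep(base_sp, n_spacers)
  if (extra > 0L) spacers[seq_len(extra)] <- spacers[seq_len(extra)] + 1L

  seqs <- character(length(labels))
  for (i in seq_along(labels)) {
    seqs[i] <- if (labels[i] == "CR") cr_seq else .rand_dna(lens[i], comp)
  }
  parts <- character(0)
  feat_rows <- list()
  cursor <- 0L
  for (i in seq_along(labels)) {
    parts <- c(parts, seqs[i])
    feat_rows[[i]] <- gene_feature(labels[i], cursor, cursor + lens[i],
                                   strand = ord$strands[i])
    cursor <- cursor + lens[i]
    sp <- .rand_dna(spacers[i], comp)
    parts <- c(parts, sp)
    cursor <- cursor + spacers[i]
  }
  residues <- paste(parts, collapse = "")
  feats <- do.call(rbind, feat_rows)
  gid <- sprintf("SYN%06d", spec$seed %% 1000000L)
  genome <- mito_genome(nuc_sequence(gid, residues, circular = TRUE), feats,
                        source_id = gid)

  cr_row <- feats[feats$label == "CR", , drop = FALSE]
  realized <- compute_composition(genome$sequence)
  truth <- list(
    genome_length = nchar(residues),
    order = ord$labels, strands = ord$strands, events = events,
    order_type = if (is.character(spec$order_type)) spec$order_type
                 else "novel-spec",
    cr_span = c(start = cr_row$start[1L], end = cr_row$end[1L]),
    cr_length = nchar(cr_seq),
    etas_end = etas_end, csb_start = csb_start,
    array = list(start = array_start, end = array_end,
                 unit = arr$unit, unit_length = nchar(arr$unit),
                 copies = spec$etas_copies, copy_seqs = arr$copies),
    motifs = cr_motifs,
    microsats = spec$microsats,
    base_composition = c(A = realized$pctA, T = realized$pctT,
                         G = realized$pctG, C = realized$pctC) / 100,
    features = feats)
  list(genome = genome, truth = truth)
}

#' Apply a rearrangement event to a gene order
#'
#' Pure editing operators mirroring the recognized event classes:
#' `duplication` (tandem, in place, of a label or contiguous block),
#' `translocation` (move a label immediately before another),
#' `deletion` (remove a label) and `extra_OL` (insert a second
#' light-strand origin inside the WANCY cluster, between trnN and trnC).
#'
#' @param order a [gene_order()].
#' @param event list with `kind` (one of `"duplication"`,
#'   `"translocation"`, `"deletion"`, `"extra_OL"`), `labels` (the
#'   affected label or contiguous block) and, for translocation, `before`
#'   (the label the moved gene is reinserted in front of).
#' @return an edited copy of the order; the input is untouched.
#' @export
apply_event <- function(order, event) {
  stopifnot(inherits(order, "gene_order"), is.list(event))
  labels <- order$labels; strands <- order$strands
  kind <- event$kind
  if (kind == "extra_OL") {
    iN <- which(labels == "trnN")[1L]
    if (is.na(iN)) stop("extra_OL: no trnN in order")
    iOL <- which(labels == "OL")
    iOL <- iOL[iOL > iN][1L]
    at <- if (!is.na(iOL)) iOL else iN
    labels <- append(labels, "OL", after = at)
    strands <- append(strands, "H", after = at)
    return(gene_order(labels, strands, order$origin))
  }
  labs <- event$labels
  if (is.null(labs) || any(!(labs %in% labels)))
    stop(kind, ": label(s) absent from order: ",
         paste(setdiff(labs, labels), collapse = ", "))
  if (kind == "duplication") {
    if (length(labs) == 1L) {
      i <- which(labels == labs)[1L]
      labels <- append(labels, labels[i], after = i)
      strands <- append(strands, strands[i], after = i)
    } else {
      # contiguous block: locate it, duplicate in tandem
      i <- which(labels == labs[1L])[1L]
      idx <- i:(i + length(labs) - 1L)
      if (max(idx) > length(labels) ||
          !identical(labels[idx], labs))
        stop("duplication: block is not contiguous at ", labs[1L])
      labels <- append(labels, labels[idx], after = max(idx))
      strands <- append(strands, strands[idx], after = max(idx))
    }
  } else if (kind == "deletion") {
    for (lab in labs) {
      i <- which(labels == lab)[1L]
      labels <- labels[-i]; strands <- strands[-i]
    }
  } else if (kind == "translocation") {
    stopifnot(length(labs) == 1L, !is.null(event$before))
    i <- which(labels == labs)[1L]
    s <- strands[i]
    labels <- labels[-i]; strands <- strands[-i]
    j <- which(labels == event$before)[1L]
    if (is.na(j)) stop("translocation: target label absent: ", event$before)
    labels <- append(labels, labs, after = j - 1L)
    strands <- append(strands, s, after = j - 1L)
  } else stop("unknown event kind: ", kind)
  gene_order(labels, strands, order$origin)
}
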