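# Gene-order linearization and rearrangement typing.
#
# Circular gene orders are canonicalized to start at trnF and compared
# against the canonical vertebrate (Type I) template. Six rearrangement
# classes are recognized: the canonical order (I), in-place duplication of
# trnQ and ND4 (II), supernumerary light-strand origins inside the WANCY
# tRNA cluster (III), translocation of trnE to immediately 5' of trnP (IV),
# outright loss of trnE (V), and tandem duplication of a large block
# overlapping the ND4..trnI span (VI). Anything else is reported as "novel"
# together with the raw differences.

.TYPE1_LABELS <- c(
  "trnF", "rrnS", "trnV", "rrnL", "trnL(UUR)", "ND1", "trnI", "trnQ", "trnM",
  "ND2", "trnW", "trnA", "trnN", "OL", "trnC", "trnY", "COI", "trnS(UCN)",
  "trnD", "COII", "trnK", "ATP8", "ATP6", "COIII", "trnG", "ND3", "trnR",
  "ND4L", "ND4", "trnH", "trnS(AGY)", "trnL(CUN)", "ND5", "ND6", "trnE",
  "Cytb", "trnT", "trnP", "CR")

.TYPE1_L_STRAND <- c("trnQ", "trnA", "trnN", "trnC", "trnY", "trnS(UCN)",
                     "ND6", "trnE", "trnP")

# circular forward span from ND4 through the control region to trnI, used to
# recognize the large block duplication (Type VI)
.ND4_TO_TRNI_SPAN <- {
  i <- match("ND4", .TYPE1_LABELS); j <- match("trnI", .TYPE1_LABELS)
  .TYPE1_LABELS[c(i:length(.TYPE1_LABELS), 1:j)]
}

#' Construct a gene order
#'
#' @param labels character vector of vocabulary tokens, in order along the
#'   linearized heavy strand.
#' @param strands character vector (`"H"`/`"L"`), recycled if length 1.
#' @param origin rotation anchor label (default `"trnF"`).
#' @return an object of class `gene_order`.
#' @export
gene_order <- function(labels, strands = "H", origin = "trnF") {
  stopifnot(length(labels) >= 1L)
  strands <- rep_len(strands, length(labels))
  stopifnot(all(strands %in% c("H", "L")))
  structure(list(labels = as.character(labels), strands = strands,
                 origin = origin),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("<gene_order> %d tokens, anchored at %s\n", length(x$labels),
              x$origin))
  cat(" ", paste(ifelse(x$strands == "L", paste0("-", x$labels), x$labels),
                 collapse = " "), "\n")
  invisible(x)
}

#' The canonical vertebrate (Type I) mitochondrial gene order
#'
#' Returns the 39-token template — 37 genes plus the light-strand
#' replication origin and the control region — beginning at trnF, with the
#' nine minority-strand assignments (trnQ, trnA, trnN, trnC, trnY,
#' trnS(UCN), ND6, trnE, trnP).
#'
#' @return a [gene_order()] of length 39.
#' @export
canonical_type1_order <- function() {
  gene_order(.TYPE1_LABELS,
             ifelse(.TYPE1_LABELS %in% .TYPE1_L_STRAND, "L", "H"))
}

rotate_order <- function(order, k) {
  n <- length(order$labels)
  k <- ((k %% n) + n) %% n
  if (k == 0L) return(order)
  idx <- c((k + 1L):n, 1L:k)
  gene_order(order$labels[idx], order$strands[idx], order$origin)
}

# deterministic, rotation-invariant canonical form: among rotations starting
# at the anchor label (all rotations if the anchor is absent), pick the
# lexicographically smallest label/strand string
canonicalize_order <- function(order) {
  n <- length(order$labels)
  starts <- which(order$labels == order$origin)
  if (length(starts) == 0L) starts <- seq_len(n)
  if (length(starts) == 1L) return(rotate_order(order, starts[1L] - 1L))
  cands <- lapply(starts - 1L, function(k) rotate_order(order, k))
  keys <- vapply(cands, function(o)
    paste(o$labels, o$strands, collapse = "|"), character(1))
  cands[[which.min(rank(keys, ties.method = "first"))]]
}

orders_equal <- function(a, b) {
  identical(a$labels, b$labels) && identical(a$strands, b$strands)
}

#' Extract the linear gene order from an annotated genome
#'
#' Sorts features by start position and rotates the circle so that trnF
#' (or, if absent, the first feature, with a warning) comes first. Strand
#' assignments are carried through.
#'
#' @param g a [mito_genome()].
#' @return a [gene_order()].
#' @export
extract_gene_order <- function(g) {
  stopifnot(inherits(g, "mito_genome"))
  f <- g$features
  if (nrow(f) == 0L) stop("genome has no features")
  # merge origin-split fragments of the same label (rotation artifacts)
  if (anyDuplicated(f$label)) {
    n <- seq_length(g$sequence)
    drop <- logical(nrow(f))
    for (lab in unique(f$label[duplicated(f$label)])) {
      idx <- which(f$label == lab)
      if (length(idx) == 2L && f$end[max(idx)] == n && f$start[min(idx)] == 0L)
        drop[min(idx)] <- TRUE
    }
    f <- f[!drop, , drop = FALSE]
  }
  ord <- gene_order(f$label, f$strand)
  if (!("trnF" %in% ord$labels)) {
    warning("no trnF feature; anchoring gene order on the first feature")
    ord$origin <- ord$labels[1L]
  }
  canonicalize_order(ord)
}

# multiset delta of labels vs the Type I template (+ extra, - missing)
.template_delta <- function(labels) {
  all_labs <- union(labels, .TYPE1_LABELS)
  obs <- table(factor(labels, levels = all_labs))
  tmp <- table(factor(.TYPE1_LABELS, levels = all_labs))
  d <- as.integer(obs) - as.integer(tmp)
  names(d) <- all_labs
  d[d != 0L]
}

# can `order` be turned into the template by deleting one contiguous
# circular segment of length L? returns the segment labels or NULL
.find_removable_block <- function(ord, tmpl) {
  n <- length(ord$labels)
  L <- n - length(tmpl$labels)
  if (L <= 0L) return(NULL)
  for (s in seq_len(n)) {
    seg <- ((s - 1L) + seq_len(L) - 1L) %% n + 1L
    rest <- setdiff(seq_len(n), seg)  # already in ascending (circular) order
    cand <- gene_order(ord$labels[rest], ord$strands[rest], ord$origin)
    if (orders_equal(canonicalize_order(cand), tmpl))
      return(ord$labels[seg])
  }
  NULL
}

# is `lab` duplicated as an adjacent (tandem, in-place) pair?
.tandem_pair <- function(labels, lab) {
  idx <- which(labels == lab)
  length(idx) == 2L && (diff(idx) == 1L ||
                          (idx[1] == 1L && idx[2] == length(labels)))
}

#' Classify a gene order into rearrangement Types I-VI
#'
#' Compares the rotation-canonicalized order against the Type I template
#' and matches event signatures in fixed precedence: identity (I);
#' duplication of exactly trnQ and ND4, each in place (II); more than one
#' light-strand origin between trnN and trnC in the WANCY cluster (III);
#' trnE moved from its position 3' of ND6 to immediately 5' of trnP (IV);
#' trnE absent (V); a contiguous duplicated block whose labels intersect
#' the circular ND4..trnI span (VI). Orders matching none of these
#' signatures — including compound edits — are reported as `"novel"` with
#' the raw multiset differences. Unknown labels are dropped before
#' classification and flagged.
#'
#' @param order a [gene_order()].
#' @return a `rearrangement_call`: list with `type` (`"I"`..`"VI"` or
#'   `"novel"`), `events` (list of `kind` + `labels`), `template_diff`
#'   (named multiset delta) and `flags`.
#' @export
classify_rearrangement <- function(order) {
  stopifnot(inherits(order, "gene_order"), length(order$labels) >= 1L)
  flags <- character()
  known <- order$labels != "unknown" & order$labels %in% MITO_VOCAB
  if (!all(known)) {
    flags <- c(flags, sprintf("ignored %d unknown label(s)", sum(!known)))
    order <- gene_order(order$labels[known], order$strands[known],
                        order$origin)
  }
  ord <- canonicalize_order(order)
  tmpl <- canonicalize_order(canonical_type1_order())
  delta <- .template_delta(ord$labels)
  call_obj <- function(type, events) {
    structure(list(type = type, events = events, template_diff = delta,
                   flags = flags), class = "rearrangement_call")
  }

  if (orders_equal(ord, tmpl)) return(call_obj("I", list()))

  extra <- delta[delta > 0L]
  missing <- -delta[delta < 0L]

  # Type II: trnQ and ND4 each duplicated in place
  if (length(missing) == 0L && length(extra) == 2L &&
      setequal(names(extra), c("trnQ", "ND4")) && all(extra == 1L) &&
      .tandem_pair(ord$labels, "trnQ") && .tandem_pair(ord$labels, "ND4")) {
    rest <- ord$labels
    str  <- ord$strands
    for (lab in c("trnQ", "ND4")) {
      i <- which(rest == lab)[1L]
      rest <- rest[-i]; str <- str[-i]
    }
    if (orders_equal(canonicalize_order(gene_order(rest, str)), tmpl))
      return(call_obj("II", list(
        list(kind = "duplication", labels = "trnQ"),
        list(kind = "duplication", labels = "ND4"))))
  }

  # Type III: extra OL copies within the WANCY cluster
  if (length(missing) == 0L && length(extra) == 1L &&
      names(extra) == "OL") {
    iN <- which(ord$labels == "trnN")[1L]
    iC <- which(ord$labels == "trnC")
    iC <- iC[iC > iN][1L]
    if (!is.na(iN) && !is.na(iC) && iC - iN >= 2L) {
      between <- ord$labels[(iN + 1L):(iC - 1L)]
      if (sum(between == "OL") >= 2L) {
        ol <- which(ord$labels == "OL")
        rest_idx <- seq_along(ord$labels)[-ol[-1L]]
        cand <- gene_order(ord$labels[rest_idx], ord$strands[rest_idx])
        if (orders_equal(canonicalize_order(cand), tmpl))
          return(call_obj("III", list(
            list(kind = "extra_OL", labels = rep("OL", unname(extra))))))
      }
    }
  }

  # Types IV/V hinge on trnE placement
  if (length(extra) == 0L && length(missing) == 0L) {
    iE <- which(ord$labels == "trnE")
    iP <- which(ord$labels == "trnP")
    i6 <- which(ord$labels == "ND6")
    if (length(iE) == 1L && length(iP) == 1L && length(i6) == 1L) {
      n <- length(ord$labels)
      succ <- function(i) (i %% n) + 1L
      if (succ(iE) == iP && succ(i6) != iE) {
        # move trnE back to 3' of ND6 and test for template identity
        labs <- ord$labels[-iE]; strs <- ord$strands[-iE]
        j <- which(labs == "ND6")
        labs <- append(labs, "trnE", after = j)
        strs <- append(strs, ord$strands[iE], after = j)
        if (orders_equal(canonicalize_order(gene_order(labs, strs)), tmpl))
          return(call_obj("IV", list(
            list(kind = "translocation", labels = "trnE"))))
      }
    }
  }

  # Type V: trnE deleted
  if (length(extra) == 0L && length(missing) == 1L &&
      names(missing) == "trnE") {
    keep <- .TYPE1_LABELS != "trnE"
    tmplV <- canonicalize_order(gene_order(
      .TYPE1_LABELS[keep],
      ifelse(.TYPE1_LABELS[keep] %in% .TYPE1_L_STRAND, "L", "H")))
    if (orders_equal(ord, tmplV))
      return(call_obj("V", list(list(kind = "deletion", labels = "trnE"))))
  }

  # Type VI: a contiguous duplicated block intersecting ND4..trnI
  if (length(missing) == 0L && length(extra) >= 1L) {
    block <- .find_removable_block(ord, tmpl)
    if (!is.null(block)) {
      ev <- list(list(kind = "duplication", labels = block))
      if (any(block %in% .ND4_TO_TRNI_SPAN)) return(call_obj("VI", ev))
      return(call_obj("novel", ev))
    }
  }

  # fall through: novel, with raw differences as events
  ev <- list()
  if (length(extra) > 0L)
    ev <- c(ev, list(list(kind = "duplication",
                          labels = rep(names(extra), extra))))
  if (length(missing) > 0L)
    ev <- c(ev, list(list(kind = "deletion",
                          labels = rep(names(missing), missing))))
  if (length(ev) == 0L) {
    moved <- if (length(ord$labels) == length(tmpl$labels))
      ord$labels[ord$labels != tmpl$labels] else character()
    ev <- list(list(kind = "translocation",
                    labels = if (length(moved) > 0L) moved else "unresolved"))
  }
  call_obj("novel", ev)
}

#' @export
print.rearrangement_call <- function(x, ...) {
  cat(sprintf("<rearrangement_call> Type %s (%d event%s)\n", x$type,
              length(x$events), if (length(x$events) == 1L) "" else "s"))
  for (e in x$events)
    cat(sprintf("  %s: %s\n", e$kind, paste(e$labels, collapse = " ")))
  if (length(x$flags) > 0L) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tabulate rearrangement types across a cohort
#'
#' @param calls non-empty list of `rearrangement_call` objects (or a
#'   character vector of type labels).
#' @return data.frame with `type`, `count` and `percent` (one decimal).
#' @export
type_census <- function(calls) {
  if (length(calls) == 0L) stop("empty call list")
  types <- if (is.character(calls)) calls else
    vapply(calls, function(x) x$type, character(1))
  types <- types[!is.na(types) & nzchar(types)]
  if (length(types) == 0L) stop("no classified calls to tabulate")
  lv <- c("I", "II", "III", "IV", "V", "VI", "novel")
  tab <- table(factor(types, levels = union(lv, unique(types))))
  tab <- tab[tab > 0L]
  data.frame(type = names(tab), count = as.integer(tab),
             percent = round(100 * as.integer(tab) / length(types), 1),
             stringsAsFactors = FALSE, row.names = NULL)
}
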