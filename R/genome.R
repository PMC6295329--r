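#' Gene feature on a linearized mitogenome
#'
#' Builds the feature table row used by [mito_genome()]: a vocabulary label,
#' 0-based half-open coordinates on the linearized heavy strand, and the
#' encoding strand (`"H"` majority / `"L"` minority).
#'
#' @param label vocabulary token (see [normalize_label()]); labels outside
#'   the vocabulary are kept verbatim and flagged unknown.
#' @param start,end 0-based half-open interval on the linearized sequence.
#' @param strand `"H"` or `"L"`.
#' @param raw the submitter's original label (defaults to `label`).
#' @return a one-row data.frame with columns `label`, `start`, `end`,
#'   `strand`, `raw`, `unknown`.
#' @export
gene_feature <- function(label, start, end, strand = "H", raw = label) {
  stopifnot(length(label) == 1L, length(start) == 1L, length(end) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (!(strand %in% c("H", "L"))) stop("strand must be 'H' or 'L'")
  if (start < 0L || start >= end)
    stop("feature '", label, "': need 0 <= start < end (got [",
         start, ", ", end, "))")
  unknown <- !(label %in% MITO_VOCAB)
  data.frame(label = label, start = start, end = end, strand = strand,
             raw = raw, unknown = unknown, stringsAsFactors = FALSE)
}

#' Annotated mitochondrial genome
#'
#' Couples a (usually circular) [nuc_sequence()] with an ordered gene feature
#' table. Features are sorted by start position; intervals must lie within
#' the linearized sequence; at most one control-region feature is allowed.
#'
#' @param sequence a [nuc_sequence()].
#' @param features a data.frame of rows built by [gene_feature()] (or
#'   rbind-compatible).
#' @param source_id accession or other provenance text.
#' @return an object of class `mito_genome`.
#' @export
mito_genome <- function(sequence, features, source_id = sequence$id) {
  stopifnot(inherits(sequence, "nuc_sequence"), is.data.frame(features))
  need <- c("label", "start", "end", "strand")
  if (!all(need %in% names(features)))
    stop("features must have columns: ", paste(need, collapse = ", "))
  if (!"raw" %in% names(features)) features$raw <- features$label
  if (!"unknown" %in% names(features))
    features$unknown <- !(features$label %in% MITO_VOCAB)
  n <- seq_length(sequence)
  bad <- features$start < 0L | features$end > n | features$start >= features$end
  if (any(bad))
    stop("feature interval(s) out of range: ",
         paste(features$label[bad], collapse = ", "))
  if (sum(features$label == "CR") > 1L)
    stop("more than one control-region feature")
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(sequence = sequence, features = features,
                 source_id = source_id),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp (%s), %d features (%d unknown)\n",
              x$source_id, seq_length(x$sequence),
              if (x$sequence$circular) "circular" else "linear",
              nrow(x$features), sum(x$features$unknown)))
  invisible(x)
}

#' Rotate an annotated circular genome
#'
#' Moves the linearization origin forward by `offset` bases; features
#' crossing the new origin are split into two rows sharing a label (they
#' are re-joined logically by [extract_gene_order()]).
#'
#' @param g a circular [mito_genome()].
#' @param offset bases to rotate by.
#' @return a rotated `mito_genome`.
#' @export
rotate_genome <- function(g, offset) {
  stopifnot(inherits(g, "mito_genome"))
  n <- seq_length(g$sequence)
  k <- ((as.integer(offset) %% n) + n) %% n
  if (k == 0L) return(g)
  seq2 <- rotate(g$sequence, k)
  f <- g$features
  ns <- (f$start - k) %% n
  ne <- ns + (f$end - f$start)
  rows <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    if (ne[i] <= n) {
      rows[[i]] <- data.frame(label = f$label[i], start = ns[i], end = ne[i],
                              strand = f$strand[i], raw = f$raw[i],
                              unknown = f$unknown[i], stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        label = rep(f$label[i], 2L), start = c(ns[i], 0L),
        end = c(n, ne[i] - n), strand = rep(f$strand[i], 2L),
        raw = rep(f$raw[i], 2L), unknown = rep(f$unknown[i], 2L),
        stringsAsFactors = FALSE)
    }
  }
  feats <- do.call(rbind, rows)
  # a split CR would trip the single-CR invariant; keep the larger fragment
  if (sum(feats$label == "CR") > 1L) {
    cr <- which(feats$label == "CR")
    drop <- cr[which.min(feats$end[cr] - feats$start[cr])]
    feats <- feats[-drop, , drop = FALSE]
  }
  mito_genome(seq2, feats, g$source_id)
}
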