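# Uncorrected p-distances on aligned sequences and cohort divergence
# summaries. p-distance = mismatches / compared sites; sites with a gap or
# ambiguity in either member of a pair (pairwise deletion) or in any row
# (complete deletion) are excluded.

#' Multiple sequence alignment container
#'
#' @param rows named character vector of equal-length gapped sequences over
#'   `{A,C,G,T,N,-}` (other ambiguity codes are tolerated and treated like
#'   N), or a `Biostrings::DNAStringSet`.
#' @return an object of class `alignment` (list with `ids` and a character
#'   matrix `mat` of single residues).
#' @export
alignment <- function(rows) {
  if (methods::is(rows, "XStringSet")) {
    nm <- names(rows)
    rows <- as.character(rows)
    names(rows) <- nm
  }
  stopifnot(is.character(rows), length(rows) >= 2L)
  if (is.null(names(rows)) || any(!nzchar(names(rows))))
    names(rows) <- paste0("seq", seq_along(rows))
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  rownames(mat) <- names(rows)
  structure(list(ids = names(rows), mat = mat), class = "alignment")
}

#' Read an aligned FASTA file
#'
#' @param path aligned FASTA file.
#' @return an [alignment()].
#' @export
read_alignment <- function(path) {
  alignment(Biostrings::readBStringSet(path))
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d sequences x %d sites\n", length(x$ids),
              ncol(x$mat)))
  invisible(x)
}

#' Uncorrected pairwise p-distances
#'
#' For each pair of rows, `distance = mismatches / compared sites`.
#' Under pairwise deletion a site is compared when both members of the pair
#' carry an unambiguous base (A/C/G/T); under complete deletion only sites
#' unambiguous in every row are used. A pair with zero comparable sites
#' gets `NA`.
#'
#' @param aln an [alignment()].
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return a symmetric, zero-diagonal numeric matrix with sequence ids as
#'   dimnames.
#' @export
p_distance <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  stopifnot(inherits(aln, "alignment"))
  mat <- aln$mat
  valid <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  if (deletion == "complete") {
    keep <- colSums(valid) == nrow(mat)
    mat <- mat[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  k <- nrow(mat)
  d <- matrix(0, k, k, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- valid[i, ] & valid[j, ]
      nok <- sum(ok)
      d[i, j] <- d[j, i] <- if (nok == 0L) NA_real_ else
        sum(mat[i, ok] != mat[j, ok]) / nok
    }
  }
  d
}

#' Within-group divergence summary
#'
#' Mean p-distance over unordered within-group pairs, with a standard
#' error estimated by a site bootstrap: alignment columns are resampled
#' with replacement, the group mean recomputed per replicate, and the SE
#' taken as the standard deviation of replicate means. Singleton groups
#' get `NA` mean and SE.
#'
#' @param aln an [alignment()].
#' @param groups named character/factor vector mapping sequence ids to
#'   group labels.
#' @param deletion passed to [p_distance()].
#' @param n_boot number of site-bootstrap replicates.
#' @param seed RNG seed for the bootstrap (optional).
#' @return data.frame with `group`, `n`, `mean`, `se`.
#' @export
divergence_summary <- function(aln, groups, deletion = "pairwise",
                               n_boot = 500L, seed = NULL) {
  stopifnot(inherits(aln, "alignment"))
  if (is.null(names(groups))) {
    stopifnot(length(groups) == length(aln$ids))
    names(groups) <- aln$ids
  }
  groups <- groups[aln$ids]
  glabs <- unique(as.character(groups))

  group_means <- function(d) {
    vapply(glabs, function(g) {
      ids <- aln$ids[groups == g]
      if (length(ids) < 2L) return(NA_real_)
      sub <- d[ids, ids]
      mean(sub[upper.tri(sub)], na.rm = TRUE)
    }, numeric(1))
  }
  obs <- group_means(p_distance(aln, deletion))

  ns <- ncol(aln$mat)
  if (!is.null(seed)) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
  }
  reps <- replicate(n_boot, {
    cols <- sample.int(ns, ns, replace = TRUE)
    a2 <- structure(list(ids = aln$ids,
                         mat = aln$mat[, cols, drop = FALSE]),
                    class = "alignment")
    group_means(p_distance(a2, deletion))
  })
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1L,
                                         dimnames = list(glabs, NULL))
  se <- apply(reps, 1L, sd)
  counts <- vapply(glabs, function(g) sum(groups == g), integer(1))
  data.frame(group = glabs, n = counts, mean = unname(obs[glabs]),
             se = ifelse(counts < 2L, NA_real_, unname(se[glabs])),
             stringsAsFactors = FALSE, row.names = NULL)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
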