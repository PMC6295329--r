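# Base composition and strand-asymmetry (skew) statistics, computed on the
# heavy-strand orientation: AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C).

.new_composition_stats <- function(a, t, g, c, other = 0) {
  total <- a + t + g + c + other
  if (total <= 0) stop("empty composition")
  pct <- function(x) 100 * x / total
  at <- a + t; gc <- g + c
  structure(list(
    counts = c(A = a, T = t, G = g, C = c, other = other),
    pctA = pct(a), pctT = pct(t), pctG = pct(g), pctC = pct(c),
    pctOther = pct(other),
    at_content = pct(at), gc_content = pct(gc),
    at_skew = if (at > 0) (a - t) / at else NA_real_,
    gc_skew = if (gc > 0) (g - c) / gc else NA_real_),
    class = "composition_stats")
}

#' Base composition and AT/GC skew of a sequence
#'
#' Tallies A/T/G/C on the given (heavy-strand) orientation and derives
#' percentage contents and the compositional skews
#' `AT-skew = (A - T)/(A + T)` and `GC-skew = (G - C)/(G + C)`. Ambiguity
#' codes (including N) are counted in `other` and excluded from the skews;
#' a skew is `NA` when its denominator is zero.
#'
#' @param seq a [nuc_sequence()] or a plain DNA string.
#' @return a `composition_stats` object with counts, percentages,
#'   `at_content`, `gc_content`, `at_skew` and `gc_skew`.
#' @export
compute_composition <- function(seq) {
  res <- if (inherits(seq, "nuc_sequence")) seq$residues else toupper(seq)
  if (!nzchar(res)) stop("empty sequence")
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  tab <- table(factor(chars, levels = IUPAC_LETTERS))
  .new_composition_stats(
    a = as.integer(tab[["A"]]), t = as.integer(tab[["T"]]),
    g = as.integer(tab[["G"]]), c = as.integer(tab[["C"]]),
    other = length(chars) - sum(tab[c("A", "T", "G", "C")]))
}

#' Composition statistics from base counts or percentages
#'
#' Builds the same statistics object as [compute_composition()] directly
#' from tallies. Because the skews are ratios, published per-base
#' percentages can be passed as `a`, `t`, `g`, `c` to recompute skews from
#' a printed composition table.
#'
#' @param a,t,g,c non-negative counts (or percentages).
#' @param other count of ambiguous residues (excluded from skews).
#' @return a `composition_stats` object.
#' @export
composition_from_counts <- function(a, t, g, c, other = 0) {
  stopifnot(all(c(a, t, g, c, other) >= 0))
  .new_composition_stats(a, t, g, c, other)
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "<composition_stats> A %.1f%% T %.1f%% G %.1f%% C %.1f%% | A+T %.1f%% G+C %.1f%% | AT-skew %.4f GC-skew %.4f\n",
    x$pctA, x$pctT, x$pctG, x$pctC, x$at_content, x$gc_content,
    x$at_skew, x$gc_skew))
  invisible(x)
}

#' Cohort mean and dispersion of composition metrics
#'
#' Summarizes a list of `composition_stats` across sequences: arithmetic
#' mean, sample standard deviation (n - 1) and standard error
#' (`SD / sqrt(n)`) for each metric. Undefined (NA) skews are excluded
#' metric-wise. Published "mean +/- x" summaries of this kind are ambiguous
#' between SD and SE, so both are reported.
#'
#' @param stats a non-empty list of `composition_stats` objects.
#' @return a data.frame with columns `metric`, `n`, `mean`, `sd`, `se`
#'   (`sd`/`se` are `NA` when fewer than two defined values exist).
#' @export
cohort_summary <- function(stats) {
  if (length(stats) == 0L) stop("empty cohort")
  stopifnot(all(vapply(stats, inherits, logical(1), "composition_stats")))
  metrics <- c("pctA", "pctT", "pctG", "pctC", "at_content", "gc_content",
               "at_skew", "gc_skew")
  rows <- lapply(metrics, function(m) {
    v <- vapply(stats, function(s) as.numeric(s[[m]]), numeric(1))
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(metric = m, n = n,
               mean = if (n > 0) mean(v) else NA_real_,
               sd = if (n > 1) sd(v) else NA_real_,
               se = if (n > 1) sd(v) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
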