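# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force tallies, quadratic DP, exhaustive
# pattern expansion.

rand_dna <- function(n, prob = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
}

# quadratic dynamic-programming Levenshtein distance
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

# exhaustive IUPAC scan oracle: expand the pattern into every literal
# string, Hamming-test each window against each literal, report the
# minimum mismatch count per window (sequence ambiguity codes never match)
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

expand_iupac <- function(pattern) {
  sets <- iupac_sets[strsplit(pattern, "", fixed = TRUE)[[1]]]
  grid <- do.call(expand.grid, c(sets, stringsAsFactors = FALSE))
  apply(grid, 1L, paste, collapse = "")
}

oracle_iupac_scan <- function(seq, pattern, max_mismatch) {
  literals <- expand_iupac(pattern)
  m <- nchar(pattern); n <- nchar(seq)
  if (n < m) return(data.frame(start = integer(), mismatches = integer()))
  lit_chars <- strsplit(literals, "", fixed = TRUE)
  out <- lapply(0:(n - m), function(s) {
    win <- strsplit(substr(seq, s + 1L, s + m), "", fixed = TRUE)[[1]]
    mm <- min(vapply(lit_chars, function(l) sum(l != win), numeric(1)))
    if (mm <= max_mismatch) data.frame(start = s, mismatches = mm) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(start = integer(), mismatches = integer())
  else out
}

# position-by-position p-distance recount
oracle_p_distance <- function(rows) {
  mats <- strsplit(toupper(rows), "", fixed = TRUE)
  k <- length(rows)
  d <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    x <- mats[[i]]; y <- mats[[j]]
    acgt <- c("A", "C", "G", "T")
    mism <- 0L; comp <- 0L
    for (s in seq_along(x)) {
      if (x[s] %in% acgt && y[s] %in% acgt) {
        comp <- comp + 1L
        if (x[s] != y[s]) mism <- mism + 1L
      }
    }
    d[i, j] <- d[j, i] <- if (comp == 0L) NA_real_ else mism / comp
  }
  d
}

# brute-force single-pass composition recount
oracle_composition <- function(res) {
  ch <- strsplit(toupper(res), "", fixed = TRUE)[[1]]
  a <- sum(ch == "A"); t <- sum(ch == "T")
  g <- sum(ch == "G"); c <- sum(ch == "C")
  list(at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
       gc_skew = if (g + c > 0) (g - c) / (g + c) else NA_real_,
       at_content = 100 * (a + t) / length(ch))
}

# plant a diverged tandem array inside random flanks; returns sequence + truth
plant_array <- function(unit_len, copies, divergence, flank = 60,
                        comp = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  unit <- rand_dna(unit_len, comp)
  mutate <- function(u) {
    ch <- strsplit(u, "", fixed = TRUE)[[1]]
    nm <- rbinom(1L, length(ch), divergence)
    if (nm > 0) {
      pos <- sample(length(ch), nm)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    paste(ch, collapse = "")
  }
  body <- paste(vapply(seq_len(copies), function(i)
    if (i == 1) unit else mutate(unit), character(1)), collapse = "")
  left <- rand_dna(flank, comp); right <- rand_dna(flank, comp)
  list(seq = paste0(left, body, right), start = flank,
       unit_len = unit_len, copies = copies)
}
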