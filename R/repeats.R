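# VNTR tandem-array detection and decomposition, microsatellite runs, and
# inverted-repeat stems.
#
# The tandem detector is a seed-and-extend scheme: exact k-mer recurrence
# distances propose candidate periods, each candidate is extended while the
# edit-distance identity between consecutive period-sized windows stays
# above the threshold, and overlapping candidates are merged keeping the
# highest-scoring representative. Copy-to-copy identity is edit-distance
# based (1 - edits / unit length) because real VNTR copies vary in length.

#' Edit-distance identity between two subsequences
#'
#' `1 - edit_distance(a, b) / max(nchar(a), nchar(b))`; symmetric, 1 for
#' identical strings, tolerant of indels.
#'
#' @param a,b non-empty DNA strings.
#' @return identity fraction in `[0, 1]`.
#' @export
unit_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  1 - as.integer(adist(a, b)) / max(nchar(a), nchar(b))
}

.window_identity <- function(res, i, p) {
  # identity between res[i, i+p) and res[i+p, i+2p), 0-based i
  a <- substr(res, i + 1L, i + p)
  b <- substr(res, i + p + 1L, i + 2L * p)
  1 - as.integer(adist(a, b)) / p
}

#' Detect tandem-repeat arrays
#'
#' Seed-and-extend detector for variable-number tandem repeats: (1)
#' candidate periods are seeded from recurrence distances of exact k-mers;
#' (2) each candidate is extended left and right while consecutive
#' period-sized windows match at `min_identity` (edit-distance identity,
#' so diverged copies with small indels still chain); (3) overlapping
#' extensions are merged into regions, and each region's period is taken
#' as the mode of the exact k-mer recurrence distances inside it (ties
#' towards the smaller period) — the mode is robust both to harmonic
#' periods (a 75-bp array also chains at 150/225 bp) and to +/-1 bp jitter
#' from indels; (4) the reported phase is anchored at the array start; a
#' trailing copy shortened by at most 20% (small indels) still counts as
#' complete, and any shorter partial copy is reported as `tail_length`.
#'
#' @param seq a [nuc_sequence()] or DNA string.
#' @param min_unit,max_unit candidate unit-length range (bp).
#' @param min_identity minimum adjacent-copy identity to extend an array.
#' @param min_copies minimum number of complete copies to report.
#' @param seed_k exact k-mer length used for seeding.
#' @return list of `tandem_array` objects: `start`, `end` (0-based
#'   half-open, full copies only), `unit_length`, `copy_number`,
#'   `tail_length` (partial trailing copy), `units` (copy subsequences),
#'   `adjacent_identity`, `mean_identity`, `consensus` (majority string).
#' @export
find_tandem_repeats <- function(seq, min_unit = 10L, max_unit = 300L,
                                min_identity = 0.7, min_copies = 2L,
                                seed_k = 8L) {
  if (min_unit > max_unit) stop("config error: min_unit > max_unit")
  res <- if (inherits(seq, "nuc_sequence")) seq$residues else toupper(seq)
  n <- nchar(res)
  if (n < 2L * min_unit)
    stop("sequence (", n, " bp) shorter than two minimum units")
  k <- min(seed_k, min_unit)

  # ---- seeds: recurrence distances of exact k-mers ----------------------
  starts <- seq_len(n - k + 1L)
  kmers <- substring(res, starts, starts + k - 1L)
  occ <- split(starts, kmers)
  cand <- list()
  for (pos in occ) {
    if (length(pos) < 2L) next
    d <- diff(pos)
    ok <- d >= min_unit & d <= max_unit
    if (any(ok))
      cand[[length(cand) + 1L]] <- cbind(pos = pos[which(ok)],
                                         period = d[ok])
  }
  if (length(cand) == 0L) return(list())
  cand <- unique(do.call(rbind, cand))
  cand <- cand[order(cand[, "period"], cand[, "pos"]), , drop = FALSE]

  # ---- extend, skipping seeds already covered at the same period --------
  arrays <- list()
  covered <- list()  # per period: matrix of (start, end), 1-based
  for (r in seq_len(nrow(cand))) {
    p <- unname(cand[r, "period"]); i0 <- unname(cand[r, "pos"])
    key <- as.character(p)
    cov <- covered[[key]]
    if (!is.null(cov) &&
        any(i0 >= cov[, 1L] & i0 <= cov[, 2L])) next
    ext <- .extend_at_period(res, i0, p, min_identity)
    covered[[key]] <- rbind(cov, c(ext$start1, ext$end1))
    if (is.null(ext$ok) || !ext$ok) next
    if ((ext$end1 - ext$start1 + 1L) %/% p < min_copies) next
    arrays[[length(arrays) + 1L]] <- list(start1 = ext$start1,
                                          end1 = ext$end1, period = p)
  }
  if (length(arrays) == 0L) return(list())

  # ---- merge overlapping spans into regions ----------------------------
  ord <- order(vapply(arrays, `[[`, numeric(1), "start1"))
  arrays <- arrays[ord]
  regions <- list(); cur <- arrays[[1L]][c("start1", "end1")]
  for (a in arrays[-1L]) {
    if (a$start1 <= cur$end1) cur$end1 <- max(cur$end1, a$end1)
    else { regions[[length(regions) + 1L]] <- cur
           cur <- a[c("start1", "end1")] }
  }
  regions[[length(regions) + 1L]] <- cur

  # ---- per region: period = mode of seed recurrence distances ----------
  out <- list()
  for (rg in regions) {
    inside <- cand[, "pos"] >= rg$start1 &
      (cand[, "pos"] + cand[, "period"] + k - 1L) <= rg$end1 + 3L
    dists <- cand[inside, "period"]
    if (length(dists) == 0L) dists <- vapply(
      arrays[vapply(arrays, function(a)
        a$start1 >= rg$start1 && a$end1 <= rg$end1, logical(1))],
      `[[`, numeric(1), "period")
    tab <- table(dists)
    # mode; ties towards the smaller period
    p <- as.integer(names(tab)[tab == max(tab)][1L])
    i0 <- min(cand[inside & cand[, "period"] == p, "pos"])
    ext <- .extend_at_period(res, i0, p, min_identity)
    built <- NULL
    if (isTRUE(ext$ok))
      built <- .build_array(res, ext$start1, ext$end1, p, min_identity,
                            min_copies)
    if (is.null(built)) {
      # fall back to the best extension found inside the region
      inreg <- arrays[vapply(arrays, function(a)
        a$start1 >= rg$start1 && a$end1 <= rg$end1, logical(1))]
      cand_built <- lapply(inreg, function(a)
        .build_array(res, a$start1, a$end1, a$period, min_identity,
                     min_copies))
      cand_built <- cand_built[!vapply(cand_built, is.null, logical(1))]
      if (length(cand_built) == 0L) next
      score <- vapply(cand_built, function(a)
        a$copy_number * a$unit_length * a$mean_identity, numeric(1))
      built <- cand_built[[which.max(score)]]
    }
    out[[length(out) + 1L]] <- structure(built, class = "tandem_array")
  }
  out[order(vapply(out, `[[`, numeric(1), "start"))]
}

# greedy left/right extension of an array at fixed period from seed i0.
# A window chains if it matches its neighbour OR the running majority
# consensus of accepted copies: copies diverge independently from a common
# ancestor, so the consensus is closer to every copy than neighbours are to
# each other, which keeps short diverged units from breaking the chain.
.extend_at_period <- function(res, i0, p, min_identity) {
  n <- nchar(res)
  if (i0 + 2L * p - 1L > n || .window_identity(res, i0 - 1L, p) < min_identity)
    return(list(start1 = i0, end1 = min(n, i0 + 2L * p - 1L), ok = FALSE))
  win <- function(s1) substr(res, s1, s1 + p - 1L)
  units <- c(win(i0), win(i0 + p))
  j <- i0 + p
  while (j + 2L * p - 1L <= n) {
    w <- win(j + p)
    if (!(unit_identity(w, units[length(units)]) >= min_identity ||
          unit_identity(w, .majority_consensus(units)) >= min_identity))
      break
    units <- c(units, w)
    j <- j + p
  }
  i <- i0
  while (i - p >= 1L) {
    w <- win(i - p)
    if (!(unit_identity(w, units[1L]) >= min_identity ||
          unit_identity(w, .majority_consensus(units)) >= min_identity))
      break
    units <- c(w, units)
    i <- i - p
  }
  list(start1 = i, end1 = j + p - 1L, ok = TRUE)
}

.build_array <- function(res, start1, end1, p, min_identity, min_copies) {
  n <- nchar(res)
  # boundary polish: stride extension from an arbitrary seed phase can
  # leave partial copies outside [start1, end1]; reclaim the longest
  # flanking fragment still matching the terminal copy at min_identity
  first_unit <- substr(res, start1, start1 + p - 1L)
  last_unit <- substr(res, end1 - p + 1L, end1)
  avail <- min(p - 1L, start1 - 1L)
  if (avail >= 4L) {
    for (t in avail:4L) {
      frag <- substr(res, start1 - t, start1 - 1L)
      ref <- substr(first_unit, p - t + 1L, p)
      if (1 - as.integer(adist(frag, ref)) / t >= min_identity) {
        start1 <- start1 - t
        break
      }
    }
  }
  avail <- min(p - 1L, n - end1)
  if (avail >= 4L) {
    for (t in avail:4L) {
      frag <- substr(res, end1 + 1L, end1 + t)
      ref <- substr(last_unit, 1L, t)
      if (1 - as.integer(adist(frag, ref)) / t >= min_identity) {
        end1 <- end1 + t
        break
      }
    }
  }
  span <- end1 - start1 + 1L
  copies <- span %/% p
  rem <- span %% p
  # a trailing copy shortened by small indels still counts as complete
  short_last <- rem >= ceiling(0.8 * p)
  if (short_last) copies <- copies + 1L
  if (copies < max(2L, min_copies)) return(NULL)
  cut_start <- start1 + (seq_len(copies) - 1L) * p
  cut_end <- pmin(start1 - 1L + seq_len(copies) * p, end1)
  units <- substring(res, cut_start, cut_end)
  ids <- vapply(seq_len(copies - 1L), function(ci)
    unit_identity(units[ci], units[ci + 1L]), numeric(1))
  mi <- mean(ids)
  if (mi < min_identity) return(NULL)
  end_full <- cut_end[copies]
  # fractional trailing copy: a next partial window still matching the unit
  tail_len <- 0L
  if (!short_last && end_full < n) {
    avail <- min(p - 1L, n - end_full)
    if (avail >= 4L) {
      frag <- substr(res, end_full + 1L, end_full + avail)
      pid <- 1 - as.integer(adist(frag, substr(units[copies], 1L, avail))) /
        max(avail, 1L)
      if (pid >= min_identity) tail_len <- avail
    }
  }
  cons <- .majority_consensus(units[nchar(units) == p])
  list(start = start1 - 1L, end = end_full, unit_length = p,
       copy_number = copies, tail_length = tail_len, units = units,
       adjacent_identity = ids, mean_identity = mi, consensus = cons)
}

.majority_consensus <- function(units) {
  if (length(units) == 0L) return("")
  m <- do.call(rbind, strsplit(units, "", fixed = TRUE))
  paste(apply(m, 2L, function(col) {
    tb <- sort(table(col), decreasing = TRUE)
    names(tb)[1L]
  }), collapse = "")
}

#' @export
print.tandem_array <- function(x, ...) {
  cat(sprintf("<tandem_array> [%d,%d) unit %d bp x %d copies (+%d bp tail), mean adjacent identity %.3f\n",
              x$start, x$end, x$unit_length, x$copy_number, x$tail_length,
              x$mean_identity))
  invisible(x)
}

#' Decompose a long repeat unit into base-unit multiples
#'
#' Cuts a unit into `floor(len / base_length)` consecutive sub-units plus a
#' remainder, and reports pairwise edit-distance identities among the
#' sub-units (and against a reference unit if supplied). A sub-unit is
#' annotated "box-like" when its best identity against the other sub-units
#' (or the reference) falls below `boxlike_threshold` yet stays above
#' `random_floor`, the level expected for unrelated sequence.
#'
#' @param unit DNA string, at least `base_length` long.
#' @param base_length base-unit size in bp.
#' @param reference optional reference unit to compare sub-units against.
#' @param boxlike_threshold identity below which a sub-unit is "box-like"
#'   rather than a clear family member.
#' @param random_floor identity at/below which a sub-unit is considered
#'   unrelated.
#' @return a `decomposition_result`: `sub_units`, `remainder`,
#'   `base_length`, `pairwise_identity` (matrix including the reference as
#'   last row/column when given), `classification` per sub-unit
#'   (`"member"`, `"box-like"` or `"unrelated"`).
#' @export
decompose_unit <- function(unit, base_length, reference = NULL,
                           boxlike_threshold = 0.65, random_floor = 0.52) {
  if (base_length <= 0L) stop("base_length must be positive")
  len <- nchar(unit)
  if (len < base_length)
    stop("unit (", len, " bp) shorter than base_length (", base_length, ")")
  k <- len %/% base_length
  sub_units <- substring(unit, (seq_len(k) - 1L) * base_length + 1L,
                         seq_len(k) * base_length)
  remainder <- if (len %% base_length > 0L)
    substr(unit, k * base_length + 1L, len) else ""
  all_seqs <- c(sub_units, if (!is.null(reference)) reference)
  nm <- c(paste0("sub", seq_len(k)), if (!is.null(reference)) "reference")
  pid <- matrix(1, length(all_seqs), length(all_seqs), dimnames = list(nm, nm))
  if (length(all_seqs) > 1L) {
    for (i in seq_len(length(all_seqs) - 1L))
      for (j in (i + 1L):length(all_seqs)) {
        pid[i, j] <- pid[j, i] <- unit_identity(all_seqs[i], all_seqs[j])
      }
  }
  classification <- vapply(seq_len(k), function(i) {
    others <- setdiff(seq_along(all_seqs), i)
    if (length(others) == 0L) return("member")
    best <- max(pid[i, others])
    if (best >= boxlike_threshold) "member"
    else if (best > random_floor) "box-like"
    else "unrelated"
  }, character(1))
  structure(list(unit = unit, base_length = as.integer(base_length),
                 sub_units = sub_units, remainder = remainder,
                 pairwise_identity = pid, classification = classification),
            class = "decomposition_result")
}

#' Scan for perfect microsatellite runs
#'
#' Reports maximal non-extendable perfect runs of each motif with at least
#' `min_repeats` copies. Runs of different motifs may overlap and are
#' reported independently.
#'
#' @param seq a [nuc_sequence()] or DNA string.
#' @param motifs character vector of repeat motifs (default TA and CA).
#' @param min_repeats minimum copy number (default 4).
#' @return data.frame with `motif`, `start`, `end` (0-based half-open),
#'   `repeat_count`.
#' @export
microsat_scan <- function(seq, motifs = c("TA", "CA"), min_repeats = 4L) {
  res <- if (inherits(seq, "nuc_sequence")) seq$residues else toupper(seq)
  rows <- list()
  for (mot in toupper(motifs)) {
    L <- nchar(mot)
    m <- gregexpr(paste0("(?:", mot, ")+"), res)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    reps <- len %/% L
    keep <- reps >= min_repeats
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      motif = mot, start = as.integer(m[keep]) - 1L,
      end = as.integer(m[keep]) - 1L + reps[keep] * L,
      repeat_count = reps[keep], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), repeat_count = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find inverted-repeat stems (hairpin arms)
#'
#' Enumerates all placements of two arms separated by a loop in which the
#' left arm and the reverse complement of the right arm match at
#' `min_arm_identity` (fraction of complementary positions). This is a
#' purely sequence-based stem detector; no thermodynamic folding is
#' attempted.
#'
#' @param unit DNA string (at least two minimum arms long).
#' @param min_arm minimum arm length (bp).
#' @param max_loop maximum loop length (bp).
#' @param min_arm_identity minimum fraction of complementary arm positions.
#' @param min_loop minimum loop length (bp).
#' @return data.frame with `arm_start` (0-based), `arm_length`,
#'   `loop_length`, `identity`, sorted by arm length (desc) then identity
#'   (desc) then position.
#' @export
find_stems <- function(unit, min_arm = 6L, max_loop = 30L,
                       min_arm_identity = 0.8, min_loop = 3L) {
  res <- if (inherits(unit, "nuc_sequence")) unit$residues else toupper(unit)
  n <- nchar(res)
  if (n < 2L * min_arm + min_loop)
    return(data.frame(arm_start = integer(), arm_length = integer(),
                      loop_length = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  chars <- strsplit(res, "", fixed = TRUE)[[1]]
  comp <- strsplit(chartr(.COMP_FROM, .COMP_TO, res), "", fixed = TRUE)[[1]]
  rows <- list()
  max_arm <- (n - min_loop) %/% 2L
  for (a in min_arm:max_arm) {
    for (l in min_loop:min(max_loop, n - 2L * a)) {
      span <- 2L * a + l
      ns <- n - span + 1L
      if (ns < 1L) next
      s <- seq_len(ns)                      # 1-based left-arm starts
      match_count <- integer(ns)
      for (o in 0:(a - 1L)) {
        # left arm position o pairs with right arm position (a-1-o)
        match_count <- match_count +
          as.integer(chars[s + o] == comp[s + 2L * a + l - 1L - o])
      }
      ident <- match_count / a
      keep <- ident >= min_arm_identity
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          arm_start = s[keep] - 1L, arm_length = a, loop_length = l,
          identity = ident[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(arm_start = integer(), arm_length = integer(),
                      loop_length = integer(), identity = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$arm_length, -out$identity, out$arm_start,
                   out$loop_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}
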