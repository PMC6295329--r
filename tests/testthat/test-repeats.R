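# Tandem-array detection, unit decomposition, microsatellites, stems.

test_that("an exact repeat is recovered with unit 4 x 10 copies", {
  arr <- find_tandem_repeats(strrep("ACGT", 10), min_unit = 2, max_unit = 30,
                             min_copies = 2)
  expect_length(arr, 1L)
  a <- arr[[1]]
  expect_equal(a$unit_length, 4L)
  expect_equal(a$copy_number, 10L)
  expect_true(all(a$adjacent_identity == 1))
  expect_equal(a$start, 0L)
  expect_equal(a$end, 40L)
})

test_that("a planted diverged 75-bp x 6 array is detected", {
  set.seed(7)
  tr <- plant_array(75, 6, 0.05)
  arr <- find_tandem_repeats(tr$seq)
  expect_gte(length(arr), 1L)
  a <- arr[[which.max(vapply(arr, function(x)
    x$copy_number * x$unit_length, numeric(1)))]]
  expect_equal(a$unit_length, 75L)
  expect_equal(a$copy_number, 6L)
  expect_lte(abs(a$start - tr$start), 75L)  # phase-insensitive
})

test_that("a 225-bp unit of diverged 75-mers is reported as 225 x 2", {
  set.seed(31)
  base <- rand_dna(75)
  mk_sub <- function(d) {
    ch <- strsplit(base, "", fixed = TRUE)[[1]]
    pos <- sample(75, round(75 * d))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  unit <- paste0(base, mk_sub(0.3), mk_sub(0.35))
  seqs <- paste0(rand_dna(50), unit, unit, rand_dna(50))
  arr <- find_tandem_repeats(seqs, min_unit = 10, max_unit = 300)
  best <- arr[[which.max(vapply(arr, function(x)
    x$copy_number * x$unit_length, numeric(1)))]]
  expect_equal(best$unit_length, 225L)
  expect_equal(best$copy_number, 2L)
})

test_that("unit_identity matches the DP edit-distance oracle", {
  expect_equal(unit_identity(strrep("ACGTA", 15), strrep("ACGTA", 15)), 1)
  expect_equal(unit_identity("AAAA", "AATA"), 0.75)
  set.seed(3)
  for (case in 1:25) {
    a <- rand_dna(sample(10:60, 1))
    b <- rand_dna(sample(10:60, 1))
    expect_equal(unit_identity(a, b),
                 1 - dp_edit_distance(a, b) / max(nchar(a), nchar(b)),
                 info = paste("case", case))
  }
})

test_that("unit_identity is symmetric with identity(a, a) = 1", {
  set.seed(5)
  for (case in 1:10) {
    a <- rand_dna(40); b <- rand_dna(sample(30:50, 1))
    expect_equal(unit_identity(a, b), unit_identity(b, a))
    expect_equal(unit_identity(a, a), 1)
  }
})

test_that("decompose_unit cuts 225 bp into three 75-mers, no remainder", {
  set.seed(17)
  unit <- rand_dna(225)
  d <- decompose_unit(unit, 75)
  expect_length(d$sub_units, 3L)
  expect_equal(d$remainder, "")
  expect_equal(paste0(paste(d$sub_units, collapse = ""), d$remainder), unit)
})

test_that("decompose_unit reports the remainder and reconstructs exactly", {
  set.seed(19)
  for (len in c(80, 151, 225, 300)) {
    unit <- rand_dna(len)
    d <- decompose_unit(unit, 75)
    expect_length(d$sub_units, len %/% 75)
    expect_equal(nchar(d$remainder), len %% 75)
    expect_equal(paste0(paste(d$sub_units, collapse = ""), d$remainder),
                 unit)
  }
  expect_error(decompose_unit("ACGT", 0), "positive")
})

test_that("a diverged third sub-unit is flagged box-like", {
  set.seed(23)
  s1 <- rand_dna(75)
  mutate_frac <- function(u, d) {
    ch <- strsplit(u, "", fixed = TRUE)[[1]]
    pos <- sample(length(ch), round(length(ch) * d))
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    paste(ch, collapse = "")
  }
  s2 <- mutate_frac(s1, 0.04)
  s3 <- mutate_frac(s1, 0.45)
  d <- decompose_unit(paste0(s1, s2, s3), 75)
  expect_gte(d$pairwise_identity["sub1", "sub2"], 0.9)
  expect_equal(d$classification[1:2], c("member", "member"))
  expect_equal(d$classification[3], "box-like")
})

test_that("microsat_scan reports maximal perfect runs only", {
  hits <- microsat_scan("GGTATATATAGG")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$motif, "TA")
  expect_equal(hits$repeat_count, 4L)
  expect_equal(c(hits$start, hits$end), c(2L, 10L))
  # below threshold
  expect_equal(nrow(microsat_scan("CACACA")), 0L)
  expect_equal(nrow(microsat_scan("CACACA", min_repeats = 3L)), 1L)
})

test_that("a planted (CA)7 run is recovered exactly", {
  set.seed(5)
  left <- gsub("C?A", "G", rand_dna(100))  # scrub accidental CA dimers
  seqs <- paste0(left, strrep("CA", 7), "GG", rand_dna(0))
  hits <- microsat_scan(seqs)
  ca <- hits[hits$motif == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$repeat_count, 7L)
  expect_equal(ca$end - ca$start, 14L)
})

test_that("reported microsatellite runs cannot be extended by a copy", {
  set.seed(27)
  for (case in 1:20) {
    s <- rand_dna(300, prob = c(A = .35, C = .15, G = .15, T = .35))
    hits <- microsat_scan(s, min_repeats = 3L)
    for (i in seq_len(nrow(hits))) {
      mot <- hits$motif[i]; L <- nchar(mot)
      before <- substr(s, hits$start[i] - L + 1L, hits$start[i])
      after <- substr(s, hits$end[i] + 1L, hits$end[i] + L)
      if (nchar(before) == L) expect_false(before == mot)
      if (nchar(after) == L) expect_false(after == mot)
    }
  }
})

test_that("find_stems detects a constructed palindrome and not homopolymers", {
  hits <- find_stems("GGGGCAAAAGCCCC", min_arm = 4, min_loop = 3)
  expect_gte(nrow(hits), 1L)
  top <- hits[1, ]
  expect_equal(top$arm_length, 5L)
  expect_equal(top$arm_start, 0L)
  expect_equal(top$loop_length, 4L)
  expect_equal(top$identity, 1)
  expect_equal(nrow(find_stems(strrep("A", 12), min_arm = 4)), 0L)
})

test_that("find_stems equals an exhaustive all-placements oracle", {
  set.seed(9)
  oracle_stems <- function(s, min_arm, max_loop, min_id, min_loop) {
    n <- nchar(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rows <- list()
    for (st in 0:(n - 1)) for (a in min_arm:floor((n - min_loop) / 2)) {
      for (l in min_loop:max_loop) {
        if (st + 2 * a + l > n) next
        left <- ch[(st + 1):(st + a)]
        right <- ch[(st + a + l + 1):(st + 2 * a + l)]
        id <- mean(left == comp[rev(right)])
        if (id >= min_id)
          rows[[length(rows) + 1]] <- data.frame(
            arm_start = st, arm_length = a, loop_length = l, identity = id)
      }
    }
    if (length(rows) == 0) return(data.frame(arm_start = integer()))
    do.call(rbind, rows)
  }
  for (case in 1:5) {
    stem <- rand_dna(10)
    s <- paste0(rand_dna(20), stem, rand_dna(6), revcomp(stem), rand_dna(20))
    got <- find_stems(s, min_arm = 6, max_loop = 15, min_arm_identity = 0.9)
    exp <- oracle_stems(s, 6, 15, 0.9, 3)
    key <- function(d) paste(d$arm_start, d$arm_length, d$loop_length)
    expect_setequal(key(got), key(exp))
    # the planted 10-bp stem is among the hits
    expect_true(any(got$arm_length == 10 & got$arm_start == 20 &
                      got$loop_length == 6))
  }
})

test_that("tandem detector rejects inconsistent configuration", {
  expect_error(find_tandem_repeats("ACGTACGT", min_unit = 50, max_unit = 10),
               "config")
  expect_error(find_tandem_repeats("ACG", min_unit = 10), "shorter")
})
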