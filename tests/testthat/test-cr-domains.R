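# Control-region extraction, degenerate motif scanning and domain
# partitioning.

test_that("extract_cr returns the span strictly between trnP and trnF", {
  res <- rand_dna(240)
  g <- mito_genome(
    nuc_sequence("toy", res, circular = TRUE),
    rbind(gene_feature("trnP", 0, 70, strand = "L"),
          gene_feature("CR", 70, 170),
          gene_feature("trnF", 170, 240)))
  cr <- extract_cr(g)
  expect_equal(nchar(cr$sequence$residues), 100L)
  expect_equal(cr$sequence$residues, substr(res, 71, 170))
  expect_equal(unname(cr$span), c(70, 170))
})

test_that("extract_cr handles a CR wrapping the circular origin", {
  res <- rand_dna(240)
  g <- mito_genome(
    nuc_sequence("toy", res, circular = TRUE),
    rbind(gene_feature("trnP", 0, 70, strand = "L"),
          gene_feature("CR", 70, 170),
          gene_feature("trnF", 170, 240)))
  ref <- extract_cr(g)$sequence$residues
  for (off in c(100L, 139L, 200L)) {
    rot <- rotate_genome(g, off)
    expect_equal(extract_cr(rot)$sequence$residues, ref,
                 info = paste("offset", off))
  }
})

test_that("extract_cr names the missing flanking tRNA in its error", {
  g <- mito_genome(nuc_sequence("toy", rand_dna(100), circular = TRUE),
                   gene_feature("trnF", 0, 70))
  expect_error(extract_cr(g), "trnP")
})

test_that("iupac_scan finds exact and self-matching hits", {
  tas <- motif_def("TAS", "TACAT", 0L)
  hits <- iupac_scan("TTACATT", tas)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 1L)
  expect_equal(hits$end, 6L)
  expect_equal(hits$mismatches, 0L)

  csb2 <- default_motifs()$`CSB-2`
  self <- iupac_scan(csb2$pattern, csb2, max_mismatch = 0L)
  expect_equal(nrow(self), 1L)
  expect_equal(self$mismatches, 0L)
  expect_equal(self$end - self$start, nchar(csb2$pattern))
})

test_that("iupac_scan equals the exhaustive-expansion oracle", {
  set.seed(42)
  csbf <- default_motifs()$`CSB-F`
  res <- rand_dna(500)
  got <- iupac_scan(res, csbf, max_mismatch = 2L)
  exp <- oracle_iupac_scan(res, csbf$pattern, 2L)
  expect_equal(got$start, exp$start)
  expect_equal(got$mismatches, exp$mismatches)

  # randomized property: random degenerate patterns, random budgets
  codes <- c("A", "C", "G", "T", "R", "Y", "W", "K", "M", "H", "N")
  for (case in 1:60) {
    pat <- paste(sample(codes, sample(4:8, 1), replace = TRUE,
                        prob = c(rep(5, 4), rep(1, 7))), collapse = "")
    mm <- sample(0:2, 1)
    s <- rand_dna(sample(30:80, 1))
    got <- iupac_scan(s, motif_def("user", pat, mm))
    exp <- oracle_iupac_scan(s, pat, mm)
    expect_equal(got$start, exp$start, info = paste("case", case, pat))
    expect_equal(got$mismatches, exp$mismatches,
                 info = paste("case", case, pat))
  }
})

test_that("iupac_scan agrees with Biostrings degenerate matching", {
  set.seed(9)
  res <- rand_dna(400)
  csb1 <- default_motifs()$`CSB-1`
  got <- iupac_scan(res, csb1, max_mismatch = 3L)
  bs <- Biostrings::matchPattern(
    Biostrings::DNAString(csb1$pattern), Biostrings::DNAString(res),
    max.mismatch = 3L, fixed = c(pattern = FALSE, subject = TRUE))
  expect_equal(got$start, Biostrings::start(bs) - 1L)
})

test_that("N in the sequence never matches exactly", {
  tas <- motif_def("TAS", "TACAT", 0L)
  expect_equal(nrow(iupac_scan("TANAT", tas)), 0L)
  expect_equal(nrow(iupac_scan("TANAT", tas, max_mismatch = 1L)), 1L)
  n5 <- motif_def("user", "NNNNN", 0L)
  expect_equal(nrow(iupac_scan("NNNNN", n5)), 0L)
  expect_equal(nrow(iupac_scan("ACGTA", n5)), 1L)
})

test_that("strand scanning mirrors coordinates", {
  set.seed(13)
  core <- rand_dna(60)
  pat <- "TACGGAT"
  res <- paste0(core, revcomp(pat), rand_dna(20))
  m <- motif_def("user", pat, 0L)
  both <- iupac_scan(res, m, strand = "both")
  lhit <- both[both$strand == "L", ]
  expect_equal(nrow(lhit), 1L)
  expect_equal(lhit$start, 60L)
  expect_equal(lhit$end, 67L)
  # forward-only scan misses it
  expect_equal(nrow(iupac_scan(res, m, strand = "H")), 0L)
})

test_that("partition recovers synthetic boundaries within one unit phase", {
  for (seed in c(1, 7, 23)) {
    mk <- build_mock_mitogenome(synthetic_spec(seed = seed))
    cr <- extract_cr(mk$genome)
    hits <- scan_motifs(cr$sequence)
    arrays <- find_tandem_repeats(cr$sequence)
    part <- partition_cr(cr$sequence, arrays, hits)
    ulen <- mk$truth$array$unit_length
    expect_lte(abs(part$etas[["end"]] - mk$truth$etas_end), ulen)
    expect_lte(abs(part$csb[["start"]] - mk$truth$csb_start), ulen)
    # exact three-way partition
    n <- nchar(cr$sequence$residues)
    expect_equal(part$etas[["start"]], 0L)
    expect_equal(part$etas[["end"]], part$ccr[["start"]])
    expect_equal(part$ccr[["end"]], part$csb[["start"]])
    expect_equal(part$csb[["end"]], n)
    sizes <- c(part$etas[["end"]] - part$etas[["start"]],
               part$ccr[["end"]] - part$ccr[["start"]],
               part$csb[["end"]] - part$csb[["start"]])
    expect_equal(sum(sizes), n)
  }
})

test_that("partition fails loudly on degenerate boundary evidence", {
  cr <- nuc_sequence("cr", rand_dna(300))
  # no CSB-family hit at all
  expect_error(partition_cr(cr, list(), mitocr:::.empty_hits()),
               "CSB")
  # CSB-1 hit at position 0 forces an empty ETAS: boundary conflict
  hits <- data.frame(motif = "CSB-1", start = 0L, end = 21L,
                     mismatches = 0L, strand = "H",
                     stringsAsFactors = FALSE)
  expect_error(partition_cr(cr, list(), hits), "boundary conflict")
})

test_that("motif definitions reject invalid IUPAC codes", {
  expect_error(motif_def("bad", "ACXGT", 1L), "IUPAC")
  expect_equal(nchar(default_motifs()$`CSB-1`$pattern), 21L)
})
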