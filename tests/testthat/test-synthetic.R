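# Synthetic mitogenome generator: determinism, truth consistency,
# composition targeting, event operators.

test_that("identical spec and seed give byte-identical GenBank output", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genbank(build_mock_mitogenome(synthetic_spec(seed = 11))$genome, f1)
  write_genbank(build_mock_mitogenome(synthetic_spec(seed = 11))$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth coordinates match the emitted annotation exactly", {
  mk <- build_mock_mitogenome(synthetic_spec(seed = 6))
  g <- mk$genome; tr <- mk$truth
  expect_equal(tr$features[, c("label", "start", "end", "strand")],
               g$features[, c("label", "start", "end", "strand")])
  expect_equal(nchar(g$sequence$residues), tr$genome_length)
  cr_row <- g$features[g$features$label == "CR", ]
  expect_equal(unname(tr$cr_span), c(cr_row$start, cr_row$end))
  # planted CR content is really there
  cr <- extract_cr(g)$sequence$residues
  expect_equal(nchar(cr), tr$cr_length)
  unit1 <- tr$array$copy_seqs[1]
  expect_equal(substr(cr, tr$array$start + 1, tr$array$start + nchar(unit1)),
               unit1)
  # every planted motif instance scans positive at its recorded position
  motifs <- default_motifs()
  for (i in seq_len(nrow(tr$motifs))) {
    nm <- tr$motifs$name[i]
    if (!(nm %in% names(motifs))) next   # microsatellite rows
    sub <- substr(cr, tr$motifs$start[i] + 1, tr$motifs$end[i])
    hit <- iupac_scan(sub, motifs[[nm]])
    expect_gte(nrow(hit), 1L)
    expect_equal(hit$start[1], 0L)
  }
})

test_that("realized base composition is within one point of the target", {
  comp <- c(A = 0.32, T = 0.21, G = 0.15, C = 0.32)
  mk <- build_mock_mitogenome(synthetic_spec(seed = 9,
                                             base_composition = comp))
  expect_true(all(abs(mk$truth$base_composition - comp) < 0.01))
  expect_gte(mk$truth$genome_length, 10000L)
})

test_that("a Type V spec emits a genome without trnE", {
  mk <- build_mock_mitogenome(synthetic_spec(seed = 4, order_type = "V"))
  expect_false("trnE" %in% mk$genome$features$label)
  expect_equal(classify_rearrangement(extract_gene_order(mk$genome))$type,
               "V")
})

test_that("the full pipeline inverts every generated rearrangement type", {
  for (ty in c("I", "II", "III", "IV", "V", "VI")) {
    mk <- build_mock_mitogenome(synthetic_spec(seed = 15, order_type = ty))
    call <- classify_rearrangement(extract_gene_order(mk$genome))
    expect_equal(call$type, ty, info = paste("type", ty))
  }
})

test_that("end-to-end recovery of the planted repeat structure", {
  mk <- build_mock_mitogenome(synthetic_spec(seed = 1))
  cr <- extract_cr(mk$genome)$sequence
  arr <- find_tandem_repeats(cr)
  best <- arr[[which.max(vapply(arr, function(a)
    a$copy_number * a$unit_length, numeric(1)))]]
  expect_equal(best$unit_length, 75L)
  expect_equal(best$copy_number, 6L)
})

test_that("apply_event operators are pure and invertible by the classifier", {
  tmpl <- canonical_type1_order()
  before <- tmpl$labels
  out <- apply_event(tmpl, list(kind = "deletion", labels = "trnE"))
  expect_length(out$labels, 38L)
  expect_equal(tmpl$labels, before)  # input untouched
  expect_error(apply_event(tmpl, list(kind = "deletion", labels = "nope")),
               "absent")
  dup <- apply_event(apply_event(tmpl, list(kind = "duplication",
                                            labels = "trnQ")),
                     list(kind = "duplication", labels = "ND4"))
  expect_equal(classify_rearrangement(dup)$type, "II")
  tr <- apply_event(tmpl, list(kind = "translocation", labels = "trnE",
                               before = "trnP"))
  expect_equal(classify_rearrangement(tr)$type, "IV")
})

test_that("composite 225-bp units produce a box-like third sub-unit", {
  sp <- synthetic_spec(seed = 8, etas_unit_len = 225L, etas_copies = 2L,
                       etas_divergence = 0.03, unit_sub_divergence = 0.35)
  mk <- build_mock_mitogenome(sp)
  cr <- extract_cr(mk$genome)$sequence
  arr <- find_tandem_repeats(cr, min_unit = 10, max_unit = 300)
  best <- arr[[which.max(vapply(arr, function(a)
    a$copy_number * a$unit_length, numeric(1)))]]
  expect_equal(best$unit_length, 225L)
  expect_equal(best$copy_number, 2L)
  d <- decompose_unit(best$units[1], 75)
  expect_length(d$sub_units, 3L)
  expect_gte(d$pairwise_identity["sub1", "sub2"], 0.85)
  expect_lt(d$pairwise_identity["sub1", "sub3"], 0.85)
})

test_that("spec validation rejects infeasible parameters", {
  expect_error(synthetic_spec(etas_copies = 1L))
  expect_error(synthetic_spec(etas_divergence = 0.9))
  expect_error(synthetic_spec(order_type = "VII"))
})
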