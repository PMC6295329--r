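# Canonical template, order extraction and rearrangement classification.

tmpl <- canonical_type1_order()

test_that("the canonical template has 28 H-strand and 9 L-strand genes", {
  genes <- tmpl$labels[!(tmpl$labels %in% c("OL", "CR"))]
  strands <- tmpl$strands[!(tmpl$labels %in% c("OL", "CR"))]
  expect_length(genes, 37L)
  expect_equal(sum(strands == "H"), 28L)
  expect_equal(sum(strands == "L"), 9L)
})

test_that("the control region is flanked by trnP and trnF", {
  n <- length(tmpl$labels)
  i <- which(tmpl$labels == "CR")
  expect_equal(tmpl$labels[i - 1L], "trnP")
  expect_equal(tmpl$labels[(i %% n) + 1L], "trnF")
})

test_that("extract_gene_order is invariant under genome rotation", {
  mk <- build_mock_mitogenome(synthetic_spec(seed = 5))
  ref <- extract_gene_order(mk$genome)
  n <- nchar(mk$genome$sequence$residues)
  for (off in c(1L, 5000L, n - 3L)) {
    rot <- extract_gene_order(rotate_genome(mk$genome, off))
    expect_equal(rot$labels, ref$labels)
    expect_equal(rot$strands, ref$strands)
  }
})

test_that("rotation invariance holds on a toy 6-gene circle", {
  labs <- c("trnF", "rrnS", "ND1", "COI", "trnP", "CR")
  lens <- c(70, 900, 950, 1500, 69, 800)
  starts <- cumsum(c(0, head(lens, -1)))
  res <- rand_dna(sum(lens))
  g <- mito_genome(nuc_sequence("toy", res, circular = TRUE),
                   do.call(rbind, Map(gene_feature, labs, starts,
                                      starts + lens)))
  ref <- extract_gene_order(g)$labels
  for (off in seq(1, sum(lens) - 1, by = 457)) {
    expect_equal(extract_gene_order(rotate_genome(g, off))$labels, ref)
  }
})

test_that("a genome missing trnE yields an order of length 38", {
  mk <- build_mock_mitogenome(synthetic_spec(seed = 2, order_type = "V"))
  ord <- extract_gene_order(mk$genome)
  expect_length(ord$labels, 38L)
  expect_false("trnE" %in% ord$labels)
})

test_that("the template classifies as Type I with no events", {
  call <- classify_rearrangement(tmpl)
  expect_equal(call$type, "I")
  expect_length(call$events, 0L)
  expect_length(call$template_diff, 0L)
})

test_that("each defined event signature is recovered by the classifier", {
  t2 <- apply_event(apply_event(tmpl, list(kind = "duplication", labels = "trnQ")),
                    list(kind = "duplication", labels = "ND4"))
  expect_equal(classify_rearrangement(t2)$type, "II")

  t3 <- apply_event(tmpl, list(kind = "extra_OL"))
  expect_equal(classify_rearrangement(t3)$type, "III")

  t4 <- apply_event(tmpl, list(kind = "translocation", labels = "trnE",
                               before = "trnP"))
  c4 <- classify_rearrangement(t4)
  expect_equal(c4$type, "IV")
  expect_equal(c4$events[[1]]$kind, "translocation")

  t5 <- apply_event(tmpl, list(kind = "deletion", labels = "trnE"))
  c5 <- classify_rearrangement(t5)
  expect_equal(c5$type, "V")
  expect_equal(c5$events[[1]]$kind, "deletion")

  block <- c("ND4", "trnH", "trnS(AGY)", "trnL(CUN)", "ND5", "ND6", "trnE",
             "Cytb", "trnT")
  t6 <- apply_event(tmpl, list(kind = "duplication", labels = block))
  c6 <- classify_rearrangement(t6)
  expect_equal(c6$type, "VI")
  expect_setequal(c6$events[[1]]$labels, block)
})

test_that("classification is invariant under all rotations of the order", {
  variants <- list(
    I = tmpl,
    II = apply_event(apply_event(tmpl, list(kind = "duplication", labels = "trnQ")),
                     list(kind = "duplication", labels = "ND4")),
    III = apply_event(tmpl, list(kind = "extra_OL")),
    IV = apply_event(tmpl, list(kind = "translocation", labels = "trnE",
                                before = "trnP")),
    V = apply_event(tmpl, list(kind = "deletion", labels = "trnE")),
    VI = apply_event(tmpl, list(kind = "duplication",
                                labels = c("ND4", "trnH", "trnS(AGY)"))))
  for (ty in names(variants)) {
    ord <- variants[[ty]]
    n <- length(ord$labels)
    types <- vapply(seq_len(n) - 1L, function(k)
      classify_rearrangement(mitocr:::rotate_order(ord, k))$type,
      character(1))
    expect_equal(unique(types), ty, info = paste("type", ty))
  }
})

test_that("compound edits are reported as novel, not silently matched", {
  # extra OL plus trnE deletion: neither pure III nor pure V
  t35 <- apply_event(apply_event(tmpl, list(kind = "extra_OL")),
                     list(kind = "deletion", labels = "trnE"))
  expect_equal(classify_rearrangement(t35)$type, "novel")
  # duplication of a block outside the ND4..trnI span
  tq <- apply_event(tmpl, list(kind = "duplication",
                               labels = c("COII", "trnK")))
  expect_equal(classify_rearrangement(tq)$type, "novel")
})

test_that("unknown labels are dropped and flagged before classification", {
  labs <- append(tmpl$labels, "weird_orf", after = 10L)
  strs <- append(tmpl$strands, "H", after = 10L)
  call <- classify_rearrangement(gene_order(labs, strs))
  expect_equal(call$type, "I")
  expect_match(call$flags, "unknown")
})

test_that("type_census counts and percentages are exact", {
  calls <- rep("I", 4L)
  cz <- type_census(calls)
  expect_equal(cz$count, 4L)
  expect_equal(cz$percent, 100)
  cz2 <- type_census(c("I", "I", "I", "II", "V"))
  expect_equal(cz2$count[cz2$type == "I"], 3L)
  expect_equal(cz2$percent[cz2$type == "I"], 60)
  expect_error(type_census(character()), "empty")
})
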