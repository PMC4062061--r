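# Coding classification: the worked stop-codon cases, stop-scan behaviour,
# and oracle equivalence against an independent translation route.

test_that("an SNV turning the stop codon TGA into TGG is stop-loss", {
  g <- fixture_genome()
  tx <- fixture_tx()
  v <- snv(114L, "A", "G")    # third base of the terminal TGA
  expect_equal(classify_coding(v, tx, g, a_style_regime())$term,
               "stoploss_SNV")
  expect_equal(classify_coding(v, tx, g, v_style_regime())$term, "stop_lost")
})

test_that("a single-base insertion that leaves the stop codon TGA intact is
          synonymous / stop-retained, not frameshift, not stop-loss", {
  g <- fixture_genome()
  tx <- fixture_tx()
  ins <- indel(114L, "", "A")  # TGA -> TG[A]A: first three bases still TGA
  a <- classify_coding(ins, tx, g, a_style_regime())
  v <- classify_coding(ins, tx, g, v_style_regime())
  expect_equal(a$term, "synonymous_SNV")
  expect_equal(v$term, "stop_retained_variant")
  expect_false(grepl("frameshift", a$term))
  expect_false(grepl("frameshift", v$term))
  expect_false(a$term %in% c("stoploss_SNV", "stop_lost"))
  # without stop-retained detection the same insertion is a frameshift
  expect_equal(classify_coding(ins, tx, g,
                               a_style_regime(stop_retained_detection = FALSE,
                                              stop_scan_indels = FALSE))$term,
               "frameshift_insertion")
})

test_that("frameshifting deletions follow the stop-scan switch", {
  g <- fixture_genome()
  tx <- fixture_tx()
  # deleting CDS bases 9-10 ("CA" of CAT) shifts the frame onto ...TCC GGA
  # TAA..., a premature stop three codons downstream
  del <- indel(25L, "CA", "")
  expect_equal(classify_coding(del, tx, g, a_style_regime())$term,
               "stopgain_SNV")
  expect_equal(classify_coding(del, tx, g,
                               a_style_regime(stop_scan_indels = FALSE))$term,
               "frameshift_deletion")
  expect_equal(classify_coding(del, tx, g, v_style_regime())$term,
               "frameshift_variant")
})

test_that("SNV coding classes come out of the codon comparison", {
  g <- fixture_genome()
  tx <- fixture_tx()
  cases <- list(
    # TTG -> TTA, both leucine (CDS base 9, genomic 24)
    list(snv(24L, "G", "A"), "synonymous_SNV", "synonymous_variant"),
    # GCT -> GAT, Ala -> Asp (CDS base 5, genomic 20)
    list(snv(20L, "C", "A"), "nonsynonymous_SNV", "missense_variant"),
    # AAA -> TAA premature stop (CDS base 19, genomic 103)
    list(snv(103L, "A", "T"), "stopgain_SNV", "stop_gained"),
    # ATG -> ACG start loss (CDS base 2, genomic 17)
    list(snv(17L, "T", "C"), "nonsynonymous_SNV", "initiator_codon_variant"),
    # TGA -> TAA stays a stop: stop-retained
    list(snv(113L, "G", "A"), "synonymous_SNV", "stop_retained_variant"))
  for (cs in cases) {
    expect_equal(classify_coding(cs[[1]], tx, g, a_style_regime())$term,
                 cs[[2]], info = cs[[1]]$variant_id)
    expect_equal(classify_coding(cs[[1]], tx, g, v_style_regime())$term,
                 cs[[3]], info = cs[[1]]$variant_id)
  }
})

test_that("in-frame indels keep the frame and the stop", {
  g <- fixture_genome()
  tx <- fixture_tx()
  del3 <- indel(28L, "CCG", "")             # whole codon 5
  expect_equal(classify_coding(del3, tx, g, a_style_regime())$term,
               "nonframeshift_deletion")
  expect_equal(classify_coding(del3, tx, g, v_style_regime())$term,
               "inframe_deletion")
  ins3 <- indel(28L, "", "GAC")             # codon inserted at a boundary
  expect_equal(classify_coding(ins3, tx, g, a_style_regime())$term,
               "nonframeshift_insertion")
  expect_equal(classify_coding(ins3, tx, g, v_style_regime())$term,
               "inframe_insertion")
})

test_that("N-containing codons give an indeterminate call", {
  g <- genome_sequence(c(chrT = paste0(
    strrep("A", 10), "ACACAC", "ATGGCTTTGCANCCG",
    "GT", strrep("CT", 32), "C", "AG",
    "GATAAACACGAATGA", "GTGTGT", strrep("TGCA", 20))))
  tx <- fixture_tx()
  v <- snv(27L, "N", "T")   # inside the N-containing codon
  expect_error(classify_coding(v, tx, g, a_style_regime()), NA)
  expect_equal(classify_coding(v, tx, g, a_style_regime())$term, "unknown")
})

test_that("coding terms agree with the brute-force translation oracle", {
  run <- get_truth_run()
  vt <- run$vt
  sim <- run$sim
  coding_classes <- c("stop_loss_snv", "stop_retained_insertion",
                      "stop_gain_snv", "frameshift_indel", "inframe_indel",
                      "missense_snv", "synonymous_snv", "initiator_codon_snv",
                      "stopgain_via_indel")
  tr <- vt$truth[vt$truth$class %in% coding_classes, ]
  expect_gte(nrow(tr), 100)
  for (i in seq_len(nrow(tr))) {
    v <- vt$variants[vt$variants$variant_id == tr$variant_id[i], ]
    tx <- sim$set_a$transcripts[[tr$target_transcript[i]]]
    for (r in list(a_style_regime(), v_style_regime())) {
      got <- classify_coding(v, tx, sim$genome, r)$term
      lab <- oracle_coding_label(v, tx, sim$genome, r)
      expect_true(term_matches_label(got, lab),
                  info = sprintf("%s %s: engine %s vs oracle %s",
                                 r$name, v$variant_id, got, lab))
    }
  }
})

test_that("coding classification is invariant under strand mirroring", {
  g <- fixture_genome()
  tx <- fixture_tx()
  N <- nchar(unclass(g)[["chrT"]])
  gm <- mirror_genome(g)
  txm <- mirror_tx(tx, N)
  vars <- list(snv(114L, "A", "G"), indel(114L, "", "A"), indel(25L, "CA", ""),
               snv(24L, "G", "A"), snv(20L, "C", "A"), snv(103L, "A", "T"),
               snv(17L, "T", "C"), indel(28L, "CCG", ""), indel(28L, "", "GAC"))
  for (v in vars) {
    vm <- mirror_variant(v, N, gm)
    for (r in list(a_style_regime(), v_style_regime()))
      expect_equal(classify_coding(vm, txm, gm, r)$term,
                   classify_coding(v, tx, g, r)$term,
                   info = paste(r$name, v$variant_id))
  }
})
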