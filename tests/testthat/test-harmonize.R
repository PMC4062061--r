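# Category harmonization and exact/category match typing.

test_that("high-level categories follow the documented map", {
  expect_equal(term_category("splicing", "A_style"), "LOF")
  expect_equal(term_category("splice_region_variant", "V_style"), "MISSENSE")
  expect_equal(term_category("splice_donor_variant", "V_style"), "LOF")
  expect_equal(term_category("synonymous_SNV", "A_style"),
               "SYNONYMOUS_OTHER")
  expect_equal(term_category("initiator_codon_variant", "V_style"),
               "MISSENSE")
  expect_equal(term_category("stop_retained_variant", "V_style"),
               "SYNONYMOUS_OTHER")
  expect_error(term_category("nonsense_term", "A_style"), "not in")
  # every emittable term of both vocabularies has exactly one category
  for (voc in c("A_style", "V_style")) {
    cm <- category_map(voc)
    expect_setequal(names(cm), vocabulary_terms(voc))
    expect_true(all(cm %in% CATEGORY_LEVELS))
  }
})

test_that("match typing distinguishes exact, category and mismatch", {
  expect_equal(match_type("frameshift_deletion", "frameshift_variant",
                          "A_style", "V_style"), "exact")
  expect_equal(match_type("frameshift_deletion", "stop_gained",
                          "A_style", "V_style"), "category")
  expect_equal(match_type("synonymous_SNV", "intron_variant",
                          "A_style", "V_style"), "mismatch")
  expect_equal(match_type("splicing", "splice_region_variant",
                          "A_style", "V_style"), "exact")
  expect_equal(match_type("absent", "missense_variant",
                          "A_style", "V_style"), "mismatch")
  # same-vocabulary runs use plain term equality
  expect_equal(match_type("splicing", "splicing", "A_style", "A_style"),
               "exact")
  expect_equal(match_type("stopgain_SNV", "stoploss_SNV",
                          "A_style", "A_style"), "category")
  # unknown never matches across vocabularies, not even itself
  expect_equal(match_type("unknown", "unknown", "A_style", "V_style"),
               "mismatch")
})

test_that("exact equivalents stay within one family and rollup group", {
  for (a in names(EQUIVALENCE_A_TO_V)) {
    for (v in EQUIVALENCE_A_TO_V[[a]]) {
      expect_equal(match_type(a, v, "A_style", "V_style"), "exact")
      expect_equal(term_family(a, "A_style"), term_family(v, "V_style"),
                   info = paste(a, v))
      expect_equal(rollup_group(a, "A_style"), rollup_group(v, "V_style"),
                   info = paste(a, v))
    }
  }
})

test_that("terms exclusive to the fine vocabulary have no exact partner", {
  # structural zeros: initiator codon, stop retained, other coding
  for (v in c("initiator_codon_variant", "stop_retained_variant",
              "coding_sequence_variant")) {
    for (a in vocabulary_terms("A_style"))
      expect_false(match_type(a, v, "A_style", "V_style") == "exact",
                   info = paste(a, v))
  }
})

test_that("category matching restricted to exonic terms is symmetric and
          transitive within each category", {
  a_terms <- vocabulary_terms("A_style")
  v_terms <- vocabulary_terms("V_style")
  for (a in a_terms) {
    for (v in v_terms) {
      ab <- match_type(a, v, "A_style", "V_style")
      ba <- match_type(v, a, "V_style", "A_style")
      expect_equal(ab, ba, info = paste(a, v))
      if (ab == "category")
        expect_equal(term_category(a, "A_style"),
                     term_category(v, "V_style"))
    }
  }
})

test_that("the shipped harmonization config matches the built-in maps", {
  h <- load_harmonization()
  for (voc in c("A_style", "V_style"))
    expect_identical(h$category[[voc]][vocabulary_terms(voc)],
                     category_map(voc)[vocabulary_terms(voc)])
  expect_identical(lapply(h$equivalence, unlist),
                   lapply(EQUIVALENCE_A_TO_V, unlist))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("category:", "  A_style: {splicing: LOF}",
               "  V_style: {stop_gained: LOF}", "equivalence: {}"), bad)
  expect_error(load_harmonization(bad), "misses")
})
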