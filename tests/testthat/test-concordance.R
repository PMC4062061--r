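# Comparison records, report arithmetic and matrix normalization.

mk_run <- function(ids, terms, txs = NULL) {
  if (is.null(txs)) txs <- rep("T1", length(ids))
  data.frame(variant_id = ids, term = terms, transcript_id = txs,
             stringsAsFactors = FALSE)
}

test_that("comparison records are a full outer join with absent markers", {
  a <- mk_run(sprintf("v%d", 1:10), rep("intronic", 10))
  b <- mk_run(sprintf("v%d", 3:12), rep("intronic", 10))
  rec <- build_comparison(a, b)
  expect_equal(nrow(rec), length(union(a$variant_id, b$variant_id)))
  expect_equal(sum(rec$term_a == "absent"), 2)
  expect_equal(sum(rec$term_b == "absent"), 2)
  expect_true(all(rec$term_a[rec$variant_id %in% sprintf("v%d", 3:10)] ==
                    "intronic"))
  expect_error(build_comparison(rbind(a, a[1, ]), b), "duplicate variant key")
})

test_that("identical runs give a perfect report and diagonal crosstab", {
  terms <- c("stopgain_SNV", "intronic", "synonymous_SNV", "splicing",
             "nonsynonymous_SNV")
  a <- mk_run(sprintf("v%d", 1:15), rep(terms, 3))
  rep_ <- summarize_concordance(build_comparison(a, a), "A_style", "A_style")
  rated <- rep_[!is.na(rep_$rate_a), ]
  expect_true(all(abs(rated$rate_a - 100) < 1e-12))
  expect_true(all(abs(rated$overall_exact - 100) < 1e-12))
  M <- crosstab(build_comparison(a, a))
  expect_true(all(M[row(M) != col(M)] == 0))
  expect_equal(sum(M), 15)
})

test_that("fine-row arithmetic follows the union identity", {
  # 4 variants termed x in run a, 5 in run b, 3 in both
  ta <- c("stopgain_SNV", "stopgain_SNV", "stopgain_SNV", "stopgain_SNV",
          "intronic", "intronic", "synonymous_SNV")
  tb <- c("stopgain_SNV", "stopgain_SNV", "stopgain_SNV", "intronic",
          "stopgain_SNV", "stopgain_SNV", "synonymous_SNV")
  rec <- build_comparison(mk_run(sprintf("v%d", 1:7), ta),
                          mk_run(sprintf("v%d", 1:7), tb))
  rep_ <- summarize_concordance(rec, "A_style", "A_style")
  r <- rep_[rep_$row == "stopgain_SNV", ]
  expect_equal(r$count_a, 4)
  expect_equal(r$count_b, 5)
  expect_equal(r$exact_match, 3)
  expect_equal(r$union_count, 4 + 5 - 3)
  expect_equal(r$rate_a, 100 * 3 / 4)
  expect_equal(r$rate_b, 100 * 3 / 5)
  expect_equal(r$overall_exact, 100 * 3 / 6)
})

test_that("every report row satisfies the union identity and rate bounds", {
  run <- get_scenario()$run
  rep_ <- run$report
  grp_rows <- paste0(c("LOF", "MISSENSE", "SYNONYMOUS_OTHER"), "_total")
  for (i in seq_len(nrow(rep_))) {
    r <- rep_[i, ]
    m_union <- if (!is.na(r$category_match)) r$category_match else
      r$exact_match
    if (r$row_type == "fine" || r$row %in% grp_rows)
      expect_equal(r$union_count, r$count_a + r$count_b - m_union,
                   info = r$row)
    if (r$row_type == "all")
      expect_equal(r$union_count, nrow(run$records))
    expect_lte(r$exact_match, min(r$count_a, r$count_b))
    for (cc in c("rate_a", "rate_b", "overall_exact", "overall_category")) {
      if (!is.na(r[[cc]])) {
        expect_gte(r[[cc]], 0)
        expect_lte(r[[cc]], 100)
      }
    }
    if (!is.na(r$category_match))
      expect_gte(r$category_match, r$exact_match)
  }
  # combined rollups are sums of their member group rows
  g <- rep_[match(grp_rows, rep_$row), ]
  for (col in c("union_count", "count_a", "count_b", "exact_match"))
    expect_equal(rep_[rep_$row == "ALL_EXONIC", ][[col]], sum(g[[col]]))
})

test_that("crosstab counts annotation pairs with documented margins", {
  rec <- build_comparison(
    mk_run(c("v1", "v2", "v3"), c("UTR5", "UTR5", "UTR3")),
    mk_run(c("v1", "v2", "v3"), c("UTR5", "UTR3", "UTR3")))
  M <- crosstab(rec)
  expect_equal(M["UTR5", "UTR5"], 1L)
  expect_equal(M["UTR5", "UTR3"], 1L)
  expect_equal(M["UTR3", "UTR3"], 1L)
  expect_equal(sum(M), 3L)
  # row sums equal per-term run-a counts among doubly annotated variants
  run <- get_scenario()$run
  M2 <- crosstab(run$records)
  both <- run$records[run$records$term_a != "absent" &
                        run$records$term_b != "absent", ]
  keep <- setdiff(rownames(M2), "absent")
  cols <- setdiff(colnames(M2), "absent")
  for (t in keep)
    expect_equal(sum(M2[t, cols]), sum(both$term_a == t), info = t)
  expect_equal(sum(M2[keep, cols]), nrow(both))
})

test_that("log/z normalization matches direct arithmetic", {
  M <- matrix(c(9, 0, 99, 9), 2, byrow = TRUE,
              dimnames = list(c("x", "y"), c("x", "y")))
  # log10(M+1) = [[1,0],[2,1]]; each row standardizes to (1, -1)
  Z <- normalize_crosstab(M, "row")
  expect_equal(unname(Z), matrix(c(1, -1, 1, -1), 2, byrow = TRUE))
  # column normalization of the transpose mirrors row normalization
  expect_equal(normalize_crosstab(t(M), "column"), t(Z))
  # zero-variance rows map to zeros; a zero count enters as log10(1) = 0
  M2 <- rbind(M, z = c(5, 5))
  Z2 <- normalize_crosstab(M2, "row")
  expect_equal(unname(Z2["z", ]), c(0, 0))
})

test_that("normalized matrices have per-axis mean 0 and sd 1", {
  M <- get_scenario()$run$crosstab
  for (axis in c("row", "column")) {
    Z <- normalize_crosstab(M, axis)
    T_ <- log10(M + 1)
    v <- if (axis == "row") apply(T_, 1, stats::sd) else
      apply(T_, 2, stats::sd)
    nonconst <- v > 0
    mu <- if (axis == "row") rowMeans(Z) else colMeans(Z)
    sdp <- if (axis == "row") sqrt(rowMeans(Z^2) - mu^2) else
      sqrt(colMeans(Z^2) - mu^2)
    expect_true(all(abs(mu[nonconst]) < 1e-9))
    expect_true(all(abs(sdp[nonconst] - 1) < 1e-9))
    const_rows <- if (axis == "row") Z[!nonconst, , drop = FALSE] else
      t(Z[, !nonconst, drop = FALSE])
    expect_true(all(const_rows == 0))
  }
})
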