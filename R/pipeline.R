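# End-to-end orchestration: annotate two sides, harmonize, compute the
# concordance report and cross-tabulations, and write a fixed output layout.
# Also the arithmetic validator for transcribed published-style summary
# tables.

resolve_regime <- function(x) {
  if (inherits(x, "vc_regime")) return(x)
  if (is.character(x))
    return(switch(x, a_style = a_style_regime(), v_style = v_style_regime(),
                  stop("unknown regime name: ", x)))
  stop("regime must be a vc_regime or 'a_style'/'v_style'")
}

resolve_tset <- function(x, name) {
  if (inherits(x, "vc_transcript_set")) return(x)
  if (is.character(x)) return(read_transcripts(x, name))
  stop("transcript set must be a vc_transcript_set or a GTF path")
}

#' Run a two-sided annotation comparison
#'
#' Comparison modes mirror the two study designs: `two_transcript_sets`
#' (one regime, two transcript sets) and `two_regimes` (one transcript set,
#' two regimes). Each side is annotated with most-severe reporting, the
#' runs are joined, and the concordance report plus raw and row/column
#' normalized cross-tabulations are computed (and written under `outdir`
#' when given, with a run manifest).
#'
#' @param genome `vc_genome` or FASTA path.
#' @param variants variant data.frame (see [read_variants()]) or VCF path.
#' @param mode `"two_transcript_sets"` or `"two_regimes"`.
#' @param tset_a,tset_b transcript sets (objects or GTF paths); in
#'   `two_regimes` mode only `tset_a` is used.
#' @param regime_a,regime_b regimes (objects or `"a_style"`/`"v_style"`);
#'   in `two_transcript_sets` mode only `regime_a` is used.
#' @param outdir optional output directory; fixed filenames
#'   (`side_a_annotation.tsv`, `side_b_annotation.tsv`, `comparison.tsv`,
#'   `report.tsv`, `report.json`, `crosstab.tsv`, `crosstab_rownorm.tsv`,
#'   `crosstab_colnorm.tsv`, `manifest.json`).
#' @return list with `calls_a`, `calls_b`, `records`, `report`, `crosstab`,
#'   `crosstab_rownorm`, `crosstab_colnorm`, `manifest`, invisibly when
#'   `outdir` is written.
#' @export
run_comparison <- function(genome, variants,
                           mode = c("two_transcript_sets", "two_regimes"),
                           tset_a, tset_b = NULL,
                           regime_a = "a_style", regime_b = "v_style",
                           outdir = NULL) {
  mode <- match.arg(mode)
  if (!inherits(genome, "vc_genome") && is.character(genome))
    genome <- read_genome(genome)
  if (is.character(variants)) variants <- read_variants(variants, genome)
  tset_a <- resolve_tset(tset_a, "setA")
  regime_a <- resolve_regime(regime_a)
  if (mode == "two_transcript_sets") {
    if (is.null(tset_b)) stop("two_transcript_sets mode needs tset_b")
    tset_b <- resolve_tset(tset_b, "setB")
    regime_b <- regime_a                    # both sides share one regime
  } else {
    regime_b <- resolve_regime(regime_b)
    tset_b <- tset_a                        # both sides share one set
  }
  calls_a <- annotate_variants(variants, tset_a, genome, regime_a)
  calls_b <- annotate_variants(variants, tset_b, genome, regime_b)
  records <- build_comparison(calls_a, calls_b)
  report <- summarize_concordance(records, regime_a$vocabulary,
                                  regime_b$vocabulary)
  M <- crosstab(records)
  out <- list(calls_a = calls_a, calls_b = calls_b, records = records,
              report = report, crosstab = M,
              crosstab_rownorm = normalize_crosstab(M, "row"),
              crosstab_colnorm = normalize_crosstab(M, "column"),
              manifest = list(
                mode = mode,
                regime_a = regime_a$name, regime_b = regime_b$name,
                tset_a = tset_a$name, tset_b = tset_b$name,
                n_variants = nrow(variants),
                n_annotated_a = sum(calls_a$term != "absent"),
                n_annotated_b = sum(calls_b$term != "absent"),
                n_compared = nrow(records)))
  if (!is.null(outdir)) write_comparison_outputs(out, outdir)
  invisible(out)
}

write_tsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

write_matrix_tsv <- function(M, path) {
  df <- data.frame(term_a = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write the fixed output layout of a comparison run
#'
#' Percentages in `report.tsv` are presented rounded half-up to 2 decimal
#' places (undefined rates as `-`); `report.json` keeps full precision.
#'
#' @param run result of [run_comparison()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_comparison_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(run$calls_a, file.path(outdir, "side_a_annotation.tsv"))
  write_tsv(run$calls_b, file.path(outdir, "side_b_annotation.tsv"))
  write_tsv(run$records, file.path(outdir, "comparison.tsv"))
  rep2 <- as.data.frame(run$report)
  for (cc in c("rate_a", "rate_b", "overall_exact", "overall_category"))
    rep2[[cc]] <- ifelse(is.na(rep2[[cc]]), "-",
                         sprintf("%.2f", round_half_up(rep2[[cc]], 2)))
  write_tsv(rep2, file.path(outdir, "report.tsv"))
  jsonlite::write_json(as.data.frame(run$report),
                       file.path(outdir, "report.json"),
                       dataframe = "rows", na = "null", digits = NA)
  write_matrix_tsv(run$crosstab, file.path(outdir, "crosstab.tsv"))
  write_matrix_tsv(round(run$crosstab_rownorm, 6),
                   file.path(outdir, "crosstab_rownorm.tsv"))
  write_matrix_tsv(round(run$crosstab_colnorm, 6),
                   file.path(outdir, "crosstab_colnorm.tsv"))
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Validate a transcribed summary-statistics table
#'
#' Recomputes, for every row of a transcribed comparison table, the union
#' count and all match-rate columns from the count columns and compares
#' them with the printed values after 2-dp half-up rounding. The union
#' identity is `union = count_a + count_b - match`, where `match` is the
#' category-match count when that column is present and the exact-match
#' count otherwise; complete-annotation rows (union equals both side
#' counts, i.e. every variant annotated by both runs) are checked on rates
#' only. `-` (NA) cells are skipped.
#'
#' @param path TSV with columns `row`, `union_count`, `count_a`, `count_b`,
#'   `exact_match`, optional `category_match`, `rate_a`, `rate_b`,
#'   `overall_exact`, optional `overall_category`. Two such transcriptions
#'   ship in `system.file("extdata", ..., package = "varconcord")`:
#'   `table_same_tool_two_sets.tsv` and `table_two_tools_one_set.tsv`.
#' @return data.frame, one row per table row, logical columns per checked
#'   cell plus overall `pass`.
#' @export
validate_printed_tables <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           na.strings = c("NA", "-", ""),
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("row", "union_count", "count_a", "count_b", "exact_match")
  if (!all(need %in% names(tab)))
    stop("fixture table lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  has_cat <- "category_match" %in% names(tab)
  eq2 <- function(printed, num, den) {
    if (is.na(printed)) return(NA)
    if (is.na(den) || den == 0) return(NA)
    abs(round_half_up(100 * num / den, 2) - printed) < 5e-7
  }
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    m_union <- if (has_cat && !is.na(r$category_match)) r$category_match
               else r$exact_match
    exp_union <- r$count_a + r$count_b - m_union
    complete <- !is.na(r$union_count) &&
      r$union_count == r$count_a && r$union_count == r$count_b
    union_ok <- r$union_count == exp_union || complete
    checks <- c(
      union_ok = union_ok,
      rate_a_ok = eq2(r$rate_a %||% NA, r$exact_match, r$count_a),
      rate_b_ok = eq2(r$rate_b %||% NA, r$exact_match, r$count_b),
      overall_exact_ok = eq2(r$overall_exact %||% NA, r$exact_match,
                             r$union_count),
      overall_category_ok = if (has_cat)
        eq2(r$overall_category %||% NA, r$category_match, r$union_count)
      else NA)
    cbind(data.frame(row = r$row, stringsAsFactors = FALSE),
          as.data.frame(as.list(checks)),
          data.frame(pass = all(unlist(checks), na.rm = TRUE)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
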