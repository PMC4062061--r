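# Concordance statistics for a pair of annotation runs: comparison records,
# per-term and rolled-up match rates, and normalized cross-tabulations.
#
# Accounting conventions (derived so that every published-table identity
# holds; see the methods vignette):
#   * fine rows are equivalence families (for two runs sharing a vocabulary,
#     a family is a single term); match = both runs report that family AND
#     the pair is an exact (cross-vocabulary equivalent) match;
#     union = count_a + count_b - match.
#   * rollup rows (LOF/MISSENSE/SYNONYMOUS_OTHER totals) count rollup-group
#     membership; the category-match column counts records whose two terms
#     both fall in the row's group; union = count_a + count_b - category
#     match for cross-vocabulary runs, - exact match otherwise.
#   * combined rollups (ALL_LOF_AND_MISSENSE, ALL_EXONIC) are sums of their
#     member group rows; the ALL row spans every record (union = number of
#     records, not count_a + count_b - match, since both runs annotate every
#     variant).

#' Join two annotation runs into per-variant comparison records
#'
#' Full outer join on variant id; a variant unannotated in one run carries
#' the explicit marker `"absent"` for that side. Each run must report one
#' call per variant (most-severe reporting).
#'
#' @param calls_a,calls_b annotation data.frames from [annotate_variants()]
#'   (one row per variant).
#' @return data.frame with columns `variant_id`, `term_a`, `term_b`,
#'   `transcript_a`, `transcript_b`, `same_transcript`.
#' @export
build_comparison <- function(calls_a, calls_b) {
  for (nm in list(list(calls_a, "a"), list(calls_b, "b"))) {
    d <- nm[[1]]$variant_id[duplicated(nm[[1]]$variant_id)]
    if (length(d))
      stop("duplicate variant key(s) in run ", nm[[2]], ": ",
           paste(unique(d), collapse = ", "))
  }
  keys <- sort(union(calls_a$variant_id, calls_b$variant_id))
  ia <- match(keys, calls_a$variant_id)
  ib <- match(keys, calls_b$variant_id)
  term_a <- ifelse(is.na(ia), "absent", calls_a$term[ia])
  term_b <- ifelse(is.na(ib), "absent", calls_b$term[ib])
  ta <- calls_a$transcript_id[ia]
  tb <- calls_b$transcript_id[ib]
  data.frame(variant_id = keys, term_a = term_a, term_b = term_b,
             transcript_a = ta, transcript_b = tb,
             same_transcript = !is.na(ta) & !is.na(tb) & ta == tb,
             stringsAsFactors = FALSE)
}

report_row <- function(label, type, count_a, count_b, exact, category,
                       union_count = NULL, cross = TRUE) {
  m_union <- if (cross && !is.na(category)) category else exact
  u <- union_count %||% (count_a + count_b - m_union)
  rate <- function(num, den) if (is.na(den) || den == 0) NA_real_
                             else 100 * num / den
  data.frame(
    row = label, row_type = type,
    union_count = u, count_a = count_a, count_b = count_b,
    exact_match = exact, category_match = category,
    rate_a = rate(exact, count_a), rate_b = rate(exact, count_b),
    overall_exact = rate(exact, u),
    overall_category = if (is.na(category)) NA_real_ else rate(category, u),
    stringsAsFactors = FALSE)
}

#' Summarize comparison records into a concordance report
#'
#' Produces fine (per equivalence family) rows and the high-level rollups
#' `LOF_total`, `MISSENSE_total`, `SYNONYMOUS_OTHER_total`,
#' `ALL_LOF`, `ALL_LOF_AND_MISSENSE`, `ALL_EXONIC` and `ALL`, with match
#' counts, union counts and percentage match rates (stored at full
#' precision; printing rounds half-up to 2 decimal places).
#'
#' @param records output of [build_comparison()].
#' @param vocab_a,vocab_b vocabularies of the two runs.
#' @return data.frame of class `vc_concordance_report`.
#' @export
summarize_concordance <- function(records, vocab_a, vocab_b) {
  cross <- vocab_a != vocab_b
  pa <- records$term_a != "absent"
  pb <- records$term_b != "absent"
  mt <- match_type(records$term_a, records$term_b, vocab_a, vocab_b)
  exact <- mt == "exact"

  fam_a <- rep(NA_character_, nrow(records))
  fam_b <- rep(NA_character_, nrow(records))
  fam_a[pa] <- term_family(records$term_a[pa], vocab_a, cross = cross)
  fam_b[pb] <- term_family(records$term_b[pb], vocab_b, cross = cross)
  grp_a <- rep(NA_character_, nrow(records))
  grp_b <- rep(NA_character_, nrow(records))
  grp_a[pa] <- rollup_group(records$term_a[pa], vocab_a)
  grp_b[pb] <- rollup_group(records$term_b[pb], vocab_b)

  fams <- unique(c(fam_a[pa], fam_b[pb]))
  # stable presentation order: severity order of first appearance per side
  fams <- fams[order(match(fams, unique(c(
    term_family(if (vocab_a == "A_style") A_STYLE_SEVERITY else V_STYLE_SEVERITY,
                vocab_a, cross = cross),
    term_family(if (vocab_b == "A_style") A_STYLE_SEVERITY else V_STYLE_SEVERITY,
                vocab_b, cross = cross)))))]
  rows <- lapply(fams, function(f) {
    ca <- sum(fam_a == f, na.rm = TRUE)
    cb <- sum(fam_b == f, na.rm = TRUE)
    m <- sum(exact & !is.na(fam_a) & fam_a == f &
               !is.na(fam_b) & fam_b == f)
    report_row(f, "fine", ca, cb, m, NA_real_, cross = cross)
  })

  groups <- c("LOF", "MISSENSE", "SYNONYMOUS_OTHER")
  grows <- lapply(groups, function(g) {
    ca <- sum(grp_a == g, na.rm = TRUE)
    cb <- sum(grp_b == g, na.rm = TRUE)
    both <- !is.na(grp_a) & grp_a == g & !is.na(grp_b) & grp_b == g
    ex <- sum(exact & both)
    cm <- if (cross) sum(both) else NA_real_
    report_row(paste0(g, "_total"), "rollup", ca, cb, ex, cm, cross = cross)
  })
  gdf <- do.call(rbind, grows)
  combine <- function(label, members) {
    sub <- gdf[gdf$row %in% paste0(members, "_total"), , drop = FALSE]
    report_row(label, "rollup", sum(sub$count_a), sum(sub$count_b),
               sum(sub$exact_match),
               if (cross) sum(sub$category_match) else NA_real_,
               union_count = sum(sub$union_count), cross = cross)
  }
  all_row <- report_row("ALL", "all", sum(pa), sum(pb), sum(exact),
                        if (cross) sum(mt != "mismatch") else NA_real_,
                        union_count = nrow(records), cross = cross)
  out <- rbind(do.call(rbind, rows), gdf,
               combine("ALL_LOF", "LOF"),
               combine("ALL_LOF_AND_MISSENSE", c("LOF", "MISSENSE")),
               combine("ALL_EXONIC", c("LOF", "MISSENSE", "SYNONYMOUS_OTHER")),
               all_row)
  rownames(out) <- NULL
  class(out) <- c("vc_concordance_report", class(out))
  attr(out, "vocab_a") <- vocab_a
  attr(out, "vocab_b") <- vocab_b
  out
}

#' @export
print.vc_concordance_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (cc in c("rate_a", "rate_b", "overall_exact", "overall_category"))
    y[[cc]] <- ifelse(is.na(y[[cc]]), NA,
                      sprintf("%.2f", round_half_up(y[[cc]], 2)))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Cross-tabulate the annotation terms of two runs
#'
#' Dense count matrix over the union of observed terms; the `"absent"`
#' marker keeps its own row/column when `include_absent` (cells restricted
#' to real terms sum to the number of variants annotated in both runs).
#'
#' @param records output of [build_comparison()].
#' @param include_absent keep the absent marker as a row/column.
#' @return integer matrix, run-A terms as rows, run-B terms as columns.
#' @export
crosstab <- function(records, include_absent = TRUE) {
  r <- records
  if (!include_absent)
    r <- r[r$term_a != "absent" & r$term_b != "absent", , drop = FALSE]
  ra <- sort(unique(r$term_a)); rb <- sort(unique(r$term_b))
  ra <- c(setdiff(ra, "absent"), intersect("absent", ra))
  rb <- c(setdiff(rb, "absent"), intersect("absent", rb))
  M <- matrix(0L, length(ra), length(rb), dimnames = list(ra, rb))
  tab <- table(factor(r$term_a, levels = ra), factor(r$term_b, levels = rb))
  M[] <- as.integer(tab)
  M
}

#' Log/z-normalize a cross-tabulation matrix
#'
#' Applies `log10(count + 1)` elementwise, then centres and scales each row
#' (or column) to mean 0 and standard deviation 1 (population formula,
#' divide by n). Zero-variance axes map to all zeros.
#'
#' @param M non-negative count matrix.
#' @param axis `"row"` or `"column"`.
#' @return numeric matrix, same dimnames.
#' @export
normalize_crosstab <- function(M, axis = c("row", "column")) {
  axis <- match.arg(axis)
  T_ <- log10(M + 1)
  if (axis == "column") T_ <- t(T_)
  mu <- rowMeans(T_)
  sdp <- sqrt(rowMeans((T_ - mu)^2))
  Z <- (T_ - mu) / ifelse(sdp == 0, 1, sdp)
  Z[sdp == 0, ] <- 0
  if (axis == "column") Z <- t(Z)
  Z
}

#' Heatmap of a (normalized) cross-tabulation
#'
#' Thin wrapper over pheatmap with clustering disabled so the term order is
#' preserved (severity order as produced by [crosstab()]).
#'
#' @param M matrix, typically from [normalize_crosstab()].
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
concordance_heatmap <- function(M, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("concordance_heatmap() needs the pheatmap package")
  invisible(pheatmap::pheatmap(M, cluster_rows = FALSE, cluster_cols = FALSE,
                               ...))
}
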