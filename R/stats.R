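## Statistical calls: repression vs negative controls, allelic-skew (emVar)
## testing, enrichment, ChIP-overlap annotation and cofactor delta-median
## categorization.

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' [stats::p.adjust()]), with input validation.
#'
#' @param pvalues numeric vector in \[0, 1\] (NAs tolerated and propagated).
#' @return adjusted p-values.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Call repression against the empirical negative-control distribution
#'
#' Each construct's aggregate activity is converted to
#' `z = (activity - mean(null)) / sd(null)` with a normal-tail p-value;
#' Benjamini-Hochberg correction is applied within strata (e.g. cell type x
#' E element), and constructs are called at the given FDR.
#'
#' @param activities an `activity_table` (or a named numeric vector of
#'   aggregate activities).
#' @param null_ids construct ids of the null (negative-control) set (>= 20).
#' @param alternative `"less"` (repression), `"greater"` or `"two.sided"`.
#' @param fdr calling threshold on adjusted p (default 0.01).
#' @param strata optional factor over constructs; BH is applied within each
#'   level (default: one stratum).
#' @return data.frame with `construct_id`, `z`, `p`, `padj`, `called`.
#' @export
repression_call <- function(activities, null_ids,
                            alternative = c("less", "greater", "two.sided"),
                            fdr = 0.01, strata = NULL) {
  alternative <- match.arg(alternative)
  if (inherits(activities, "activity_table")) {
    act <- setNames(activities$activity, activities$constructs$construct_id)
  } else {
    act <- activities
  }
  null_act <- act[names(act) %in% null_ids]
  if (length(null_act) < 20L) stop("need >= 20 null constructs")
  mu <- mean(null_act); s <- sd(null_act)
  if (s == 0) stop("null distribution has zero standard deviation")
  z <- (act - mu) / s
  p <- switch(alternative,
              less = pnorm(z),
              greater = pnorm(z, lower.tail = FALSE),
              two.sided = 2 * pnorm(-abs(z)))
  strata <- strata %||% rep("all", length(act))
  padj <- rep(NA_real_, length(p))
  for (lv in unique(strata)) {
    ix <- strata == lv
    padj[ix] <- benjamini_hochberg(p[ix])
  }
  data.frame(construct_id = names(act), z = unname(z), p = unname(p),
             padj = padj, called = padj <= fdr, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Mann-Whitney U comparison of two activity groups
#'
#' Exact enumeration when both groups have at most 8 observations and no
#' ties; otherwise the normal approximation with tie and continuity
#' correction (delegates to [stats::wilcox.test()]).
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param alternative test sidedness.
#' @return list with `U` and `p`.
#' @export
group_compare <- function(group_a, group_b,
                          alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && length(group_a) <= 8L && length(group_b) <= 8L
  wt <- suppressWarnings(wilcox.test(group_a, group_b,
                                     alternative = alternative,
                                     exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Allelic-skew (emVar) test for one variant
#'
#' Per-replicate skew `d_i = alt_i - ref_i` (replicates aligned/paired),
#' tested with a two-sided one-sample Student's t against 0. When every
#' `d_i` is zero the t statistic is undefined; skew 0 with p = 1 is
#' reported.
#'
#' @param ref_activities,alt_activities aligned replicate-level log2
#'   activities (>= 3 replicates).
#' @return list with `allelic_skew`, `t`, `p`, `d`.
#' @export
emvar_test <- function(ref_activities, alt_activities) {
  stopifnot(length(ref_activities) == length(alt_activities),
            length(ref_activities) >= 3L)
  d <- alt_activities - ref_activities
  if (all(d == 0)) {
    return(list(allelic_skew = 0, t = NA_real_, p = 1, d = d))
  }
  if (sd(d) == 0) {  # constant nonzero skew: infinitely strong evidence
    return(list(allelic_skew = mean(d), t = sign(mean(d)) * Inf, p = 0, d = d))
  }
  tt <- t.test(d)
  list(allelic_skew = mean(d), t = unname(tt$statistic), p = tt$p.value, d = d)
}

#' emVar testing across a variant set with BH correction
#'
#' @param ref_matrix,alt_matrix variants x replicates activity matrices with
#'   aligned rows and columns.
#' @param variant_id row identifiers.
#' @param fdr emVar flag threshold on adjusted p (default 0.01).
#' @return data.frame with `variant_id`, `allelic_skew`, `t`, `p`, `padj`,
#'   `emvar`.
#' @export
emvar_table <- function(ref_matrix, alt_matrix,
                        variant_id = rownames(ref_matrix), fdr = 0.01) {
  stopifnot(all(dim(ref_matrix) == dim(alt_matrix)))
  res <- lapply(seq_len(nrow(ref_matrix)), function(i) {
    emvar_test(ref_matrix[i, ], alt_matrix[i, ])
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  padj <- benjamini_hochberg(p)
  data.frame(variant_id = variant_id %||% seq_along(res),
             allelic_skew = vapply(res, `[[`, numeric(1), "allelic_skew"),
             t = vapply(res, `[[`, numeric(1), "t"),
             p = p, padj = padj, emvar = padj <= fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' The odds ratio reported is the sample odds ratio `ad/bc` (infinite or zero
#' at empty cells); the two-sided p-value comes from the hypergeometric
#' enumeration of [stats::fisher.test()].
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_enrichment <- function(table) {
  m <- as.matrix(table)
  stopifnot(all(dim(m) == 2L), all(m >= 0), all(m == round(m)))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate margin in 2x2 table")
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(odds_ratio = or, p = fisher.test(m)$p.value)
}

## normalize interval input to a data.frame(chrom, start, end) in 0-based
## half-open coordinates, validating end > start
as_intervals <- function(x, what = "intervals") {
  if (inherits(x, "GRanges")) {
    x <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                    start = GenomicRanges::start(x) - 1L,
                    end = GenomicRanges::end(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (any(x$end <= x$start)) stop(sprintf("malformed %s: end <= start", what))
  x
}

#' Annotate element/TF binding by reciprocal-50% peak overlap
#'
#' An element is bound by a TF when it overlaps a peak by at least 50% of the
#' element length or at least 50% of the peak length (either-rule, the
#' bedtools `-F 0.5 -f 0.5 -e` convention). Coordinates are 0-based
#' half-open.
#'
#' @param elements data.frame (`chrom`, `start`, `end`, optional `id`) or
#'   `GRanges`.
#' @param peaks named list of peak interval sets (one per TF), each a
#'   data.frame or `GRanges`.
#' @return logical matrix, elements x TFs.
#' @export
annotate_tf_binding <- function(elements, peaks) {
  el <- as_intervals(elements, "elements")
  ids <- el$id %||% sprintf("el%04d", seq_len(nrow(el)))
  if (is.null(names(peaks))) names(peaks) <- sprintf("TF%d", seq_along(peaks))
  gr_el <- GenomicRanges::GRanges(el$chrom,
                                  IRanges::IRanges(el$start + 1L, el$end))
  out <- vapply(peaks, function(pk) {
    pk <- as_intervals(pk, "peaks")
    gr_pk <- GenomicRanges::GRanges(pk$chrom,
                                    IRanges::IRanges(pk$start + 1L, pk$end))
    ov <- GenomicRanges::findOverlaps(gr_el, gr_pk)
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      gr_el[S4Vectors::queryHits(ov)], gr_pk[S4Vectors::subjectHits(ov)]))
    frac_el <- w / GenomicRanges::width(gr_el[S4Vectors::queryHits(ov)])
    frac_pk <- w / GenomicRanges::width(gr_pk[S4Vectors::subjectHits(ov)])
    bound <- logical(nrow(el))
    hit <- S4Vectors::queryHits(ov)[frac_el >= 0.5 | frac_pk >= 0.5]
    bound[unique(hit)] <- TRUE
    bound
  }, logical(nrow(el)))
  rownames(out) <- ids
  out
}

#' Categorize cofactor TFs by median activity differences
#'
#' For each TF, elements are split into four groups by TF binding and REST
#' binding. `delta_with` is `median(TF+/REST+) - median(TF-/REST+)` and
#' `delta_without` the analogue among REST-unbound elements; each contrast is
#' tested with [group_compare()] and BH-corrected across TFs. Category 2
#' (REST-dependent repressor) requires a significant negative `delta_with`
#' while the without-REST contrast is non-negative or non-significant;
#' category 1 (activator) requires a significant positive `delta_with`.
#'
#' @param activities numeric vector of element activities.
#' @param tf_matrix logical matrix (elements x TFs) from
#'   [annotate_tf_binding()].
#' @param rest logical vector: REST-bound per element.
#' @param min_group_size all four groups must reach this size (default 10).
#' @param alpha significance threshold on adjusted p (default 0.05).
#' @return data.frame with per-TF medians, deltas, adjusted p-values and
#'   `category` in {1, 2, NA}; skipped TFs carry the reason.
#' @export
delta_median_categorize <- function(activities, tf_matrix, rest,
                                    min_group_size = 10L, alpha = 0.05) {
  stopifnot(length(activities) == nrow(tf_matrix),
            length(rest) == nrow(tf_matrix))
  tfs <- colnames(tf_matrix) %||% sprintf("TF%d", seq_len(ncol(tf_matrix)))
  rows <- lapply(seq_len(ncol(tf_matrix)), function(j) {
    tf <- tf_matrix[, j]
    g <- list(pp = activities[tf & rest], mp = activities[!tf & rest],
              pm = activities[tf & !rest], mm = activities[!tf & !rest])
    if (any(lengths(g) < min_group_size)) {
      return(data.frame(tf_name = tfs[j], delta_with = NA_real_,
                        delta_without = NA_real_, p_with = NA_real_,
                        p_without = NA_real_, category = NA_integer_,
                        skipped = sprintf("group below %d", min_group_size),
                        stringsAsFactors = FALSE))
    }
    data.frame(tf_name = tfs[j],
               delta_with = median(g$pp) - median(g$mp),
               delta_without = median(g$pm) - median(g$mm),
               p_with = group_compare(g$pp, g$mp)$p,
               p_without = group_compare(g$pm, g$mm)$p,
               category = NA_integer_, skipped = NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj_with <- benjamini_hochberg(out$p_with)
  out$padj_without <- benjamini_hochberg(out$p_without)
  sig_with <- !is.na(out$padj_with) & out$padj_with <= alpha
  sig_without <- !is.na(out$padj_without) & out$padj_without <= alpha
  cat2 <- sig_with & out$delta_with < 0 &
    (out$delta_without >= 0 | !sig_without)
  cat1 <- sig_with & out$delta_with > 0
  out$category[which(cat2)] <- 2L
  out$category[which(cat1)] <- 1L
  out
}
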