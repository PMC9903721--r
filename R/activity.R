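## From counts to normalized per-construct activities: filters, size
## factors, log2 RNA/DNA ratios, summit-shift and quantile normalization.

#' Construct-level count table
#'
#' @param constructs data.frame with `construct_id`, `S_id`, `E_id`,
#'   `orientation`, `n_barcodes`.
#' @param counts integer matrix (constructs x samples), non-negative.
#' @param samples data.frame with `sample`, `type` (`"DNA"`/`"RNA"`),
#'   `replicate`.
#' @return an object of class `count_table`.
#' @export
count_table <- function(constructs, counts, samples) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(constructs),
            ncol(counts) == nrow(samples),
            all(counts >= 0),
            all(samples$type %in% c("DNA", "RNA")))
  structure(list(constructs = constructs, counts = counts, samples = samples),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d constructs x %d samples (%d DNA, %d RNA)\n",
              nrow(x$counts), ncol(x$counts), sum(x$samples$type == "DNA"),
              sum(x$samples$type == "RNA")))
  invisible(x)
}

#' Filter constructs on barcode multiplicity and mean DNA count
#'
#' Rows are kept only if the number of contributing barcodes reaches
#' `min_barcodes` and the mean raw DNA count across replicates reaches
#' `min_dna_mean`. Presets: 20 / 100 for benchmark-scale libraries, 10 / 20
#' for genome-scale ones.
#'
#' @param table a [count_table()] with at least one DNA sample.
#' @param min_barcodes,min_dna_mean filter thresholds.
#' @return the filtered [count_table()], with kept/dropped tallies in
#'   `attr(, "filter_tallies")`.
#' @export
filter_constructs <- function(table, min_barcodes = 20L, min_dna_mean = 100) {
  stopifnot(inherits(table, "count_table"))
  dna <- table$samples$type == "DNA"
  if (!any(dna)) stop("count table has no DNA sample")
  dna_mean <- rowMeans(table$counts[, dna, drop = FALSE])
  keep <- table$constructs$n_barcodes >= min_barcodes & dna_mean >= min_dna_mean
  if (!any(keep)) warning("all constructs fell below the filter thresholds")
  out <- count_table(table$constructs[keep, , drop = FALSE],
                     table$counts[keep, , drop = FALSE], table$samples)
  attr(out, "filter_tallies") <- list(
    kept = sum(keep), dropped = sum(!keep),
    dropped_barcodes = sum(table$constructs$n_barcodes < min_barcodes),
    dropped_dna = sum(dna_mean < min_dna_mean))
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over rows of `count / geometric row mean`,
#' computed over rows with no zero count.
#'
#' @param table a [count_table()] or a plain count matrix.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(table) {
  m <- if (inherits(table, "count_table")) table$counts else as.matrix(table)
  pos <- rowSums(m <= 0) == 0L
  if (!any(pos)) {
    stop("no row with all-positive counts; consider adding a pseudocount before size-factor estimation")
  }
  mp <- m[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(mp)))
  f <- apply(mp / geo, 2, median)
  setNames(f, colnames(m))
}

#' Per-construct normalized log2 activity table
#'
#' Counts are divided by their sample size factors; DNA is pooled as the mean
#' of the normalized DNA replicates (the plasmid pool is shared across
#' transfections); each RNA replicate yields
#' `log2((rna_norm + pseudocount) / (dna_norm_mean + pseudocount))`, and the
#' aggregate activity is the replicate mean.
#'
#' @param table a [count_table()].
#' @param factors per-sample size factors (default [size_factors()]).
#' @param pseudocount added to normalized counts (default 1).
#' @return an object of class `activity_table`: `constructs`,
#'   `rep_activity` (constructs x RNA replicates), `activity` (aggregate),
#'   `se`, `mean_dna` (raw mean DNA count), `samples`.
#' @export
log2_activity <- function(table, factors = size_factors(table),
                          pseudocount = 1) {
  stopifnot(inherits(table, "count_table"))
  dna <- table$samples$type == "DNA"
  rna <- table$samples$type == "RNA"
  if (!any(dna) || !any(rna)) stop("need at least one DNA and one RNA sample")
  norm <- sweep(table$counts, 2, factors[colnames(table$counts)], "/")
  dna_norm <- rowMeans(norm[, dna, drop = FALSE])
  if (pseudocount == 0 && any(dna_norm == 0)) {
    stop("zero normalized DNA with pseudocount 0")
  }
  rep_act <- log2(sweep(norm[, rna, drop = FALSE] + pseudocount, 1,
                        dna_norm + pseudocount, "/"))
  colnames(rep_act) <- table$samples$sample[rna]
  agg <- rowMeans(rep_act)
  se <- apply(rep_act, 1, sd) / sqrt(ncol(rep_act))
  structure(list(constructs = table$constructs, rep_activity = rep_act,
                 activity = agg, se = se,
                 mean_dna = rowMeans(table$counts[, dna, drop = FALSE]),
                 samples = table$samples[rna, , drop = FALSE],
                 size_factors = factors, shift = NULL),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat(sprintf("activity_table: %d constructs, %d replicates%s\n",
              length(x$activity), ncol(x$rep_activity),
              if (!is.null(x$shift)) sprintf(", summit shift %.4f applied", x$shift) else ""))
  invisible(x)
}

## KDE mode with Silverman bandwidth on a 512-point grid over the data range
kde_mode <- function(x) {
  if (diff(range(x)) == 0) return(x[1])  # degenerate: all mass at one point
  d <- density(x, bw = "nrd0", n = 512L, from = min(x), to = max(x))
  d$x[which.max(d$y)]
}

#' Summit-shift normalization
#'
#' Estimates the mode of the negative-control aggregate activities (Gaussian
#' kernel density, Silverman bandwidth, 512-point grid over the negatives'
#' range) and subtracts it from every activity, so that the negative-control
#' mode sits at zero.
#'
#' @param activities an [log2_activity()] table.
#' @param negative_ids construct ids of the negative controls (>= 20 must be
#'   present).
#' @return the shifted `activity_table`; the shift is recorded in `$shift`.
#' @export
summit_shift <- function(activities, negative_ids) {
  stopifnot(inherits(activities, "activity_table"))
  neg <- activities$activity[activities$constructs$construct_id %in% negative_ids]
  if (length(neg) < 20L) {
    stop(sprintf("only %d negative controls present; >= 20 needed for a stable mode", length(neg)))
  }
  shift <- kde_mode(neg)
  activities$activity <- activities$activity - shift
  activities$rep_activity <- activities$rep_activity - shift
  activities$shift <- (activities$shift %||% 0) + shift
  activities
}

#' Quantile normalization across libraries
#'
#' Classic rank-based algorithm: each column is sorted, values are averaged
#' across columns at each rank, and reassigned by the original ranks; tied
#' observations receive the mean of their tied ranks' values. Afterwards all
#' columns share the same sorted values.
#'
#' @param matrix numeric matrix (activities x libraries), complete rows only.
#' @return the normalized matrix.
#' @export
quantile_normalize <- function(matrix) {
  m <- as.matrix(matrix)
  if (anyNA(m)) stop("missing values: subset to complete rows before quantile normalization")
  if (ncol(m) < 2L) stop("need at least two columns")
  target <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    (target[floor(r)] + target[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Write an activity table to TSV
#'
#' @param activities an `activity_table`.
#' @param path output file.
#' @export
write_activity_table <- function(activities, path) {
  df <- data.frame(activities$constructs,
                   mean_dna = activities$mean_dna,
                   activities$rep_activity,
                   activity = activities$activity, se = activities$se,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
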