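mk_ct <- function(counts, n_barcodes = NULL, types = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  }
  types <- types %||% rep("RNA", ncol(counts))
  count_table(
    data.frame(construct_id = sprintf("c%03d", seq_len(n)),
               S_id = NA_character_, E_id = NA_character_,
               orientation = "single-S",
               n_barcodes = n_barcodes %||% rep(30L, n),
               stringsAsFactors = FALSE),
    counts,
    data.frame(sample = colnames(counts), type = types,
               replicate = seq_len(ncol(counts))))
}
`%||%` <- mpraduo:::`%||%`

test_that("construct filters apply both thresholds with preset values", {
  ct <- mk_ct(cbind(DNA_1 = c(150, 90, 200, 30), RNA_1 = c(5, 5, 5, 5)),
              n_barcodes = c(25L, 25L, 9L, 20L), types = c("DNA", "RNA"))
  # benchmark preset: >= 20 barcodes and mean DNA >= 100
  f <- filter_constructs(ct, 20, 100)
  expect_equal(f$constructs$construct_id, "c001")
  # genome-scale preset: >= 10 barcodes and mean DNA >= 20
  f2 <- filter_constructs(ct, 10, 20)
  expect_equal(f2$constructs$construct_id, c("c001", "c002", "c004"))
  expect_equal(attr(f2, "filter_tallies")$dropped_barcodes, 1L)
  expect_warning(filter_constructs(ct, 100, 1e6), "below the filter")
})

test_that("size factors are the median of ratios to geometric row means", {
  m <- cbind(a = c(1, 2, 4), b = c(2, 4, 8))
  f <- size_factors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  expect_equal(unname(f), c(0.7071, 1.4142), tolerance = 1e-4)
  # scale equivariance and row-permutation invariance
  set.seed(201)
  m2 <- matrix(rpois(300, 50) + 1, ncol = 3)
  f2 <- size_factors(m2)
  expect_equal(size_factors(m2[sample(nrow(m2)), ]), f2)
  # doubling one sample doubles its factor relative to the others
  m3 <- m2; m3[, 2] <- m3[, 2] * 2
  f3 <- size_factors(m3)
  expect_equal(f3[2] / f3[1], 2 * f2[2] / f2[1], tolerance = 1e-10)
  # single-row table: factor is count over its geometric mean
  one <- matrix(c(4, 16), nrow = 1)
  expect_equal(unname(size_factors(one)), c(0.5, 2))
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "pseudocount")
})

test_that("log2 activities are normalized RNA over pooled DNA ratios", {
  ct <- mk_ct(cbind(DNA_1 = c(100, 100), DNA_2 = c(100, 100),
                    RNA_1 = c(100, 400)),
              types = c("DNA", "DNA", "RNA"))
  f <- setNames(c(1, 1, 1), c("DNA_1", "DNA_2", "RNA_1"))
  act <- log2_activity(ct, f, pseudocount = 0)
  expect_equal(unname(act$activity), c(0, 2))
  expect_equal(unname(act$mean_dna), c(100, 100))
  # equal normalized RNA and DNA give activity 0 whatever the pseudocount
  act1 <- log2_activity(ct, f, pseudocount = 1)
  expect_equal(unname(act1$activity[1]), 0)
  expect_error(log2_activity(mk_ct(cbind(DNA_1 = 0, RNA_1 = 5),
                                   types = c("DNA", "RNA")),
                             setNames(c(1, 1), c("DNA_1", "RNA_1")),
                             pseudocount = 0), "zero normalized DNA")
})

test_that("activities recover simulated truth at low dispersion", {
  d <- sim_design(n_E = 3L, n_S = 150L, n_neg = 40L, depth = 150L,
                  n_replicates = 3L, nb_dispersion = 0.01, seed = 211)
  lib <- make_library(d)
  ct <- simulate_counts(lib$library, lib$truth, d)
  act <- log2_activity(filter_constructs(ct, 10, 20))
  m <- match(act$constructs$construct_id, lib$truth$constructs$construct_id)
  r <- cor(act$activity, lib$truth$constructs$true_activity[m])
  expect_gte(r, 0.95)
})

test_that("summit shift zeroes the negative-control mode and is idempotent", {
  set.seed(202)
  n_neg <- 500
  neg_ids <- sprintf("c%03d", 1:n_neg)
  counts <- cbind(DNA_1 = rep(1000L, n_neg + 50),
                  RNA_1 = c(as.integer(1000 * 2^rnorm(n_neg, 1.5, 0.3)),
                            as.integer(1000 * 2^rnorm(50, -1, 0.5))))
  ct <- count_table(
    data.frame(construct_id = sprintf("c%03d", seq_len(n_neg + 50)),
               S_id = NA, E_id = NA, orientation = "single-S",
               n_barcodes = 30L),
    counts,
    data.frame(sample = colnames(counts), type = c("DNA", "RNA"),
               replicate = 1:2))
  act <- log2_activity(ct, setNames(c(1, 1), colnames(counts)))
  shifted <- summit_shift(act, neg_ids)
  # the KDE mode of a Normal(1.5, 0.3) sample sits near 1.5
  expect_lt(abs(shifted$shift - 1.5), 0.1)
  # pairwise differences preserved exactly
  expect_equal(diff(shifted$activity), diff(act$activity))
  # re-running on the shifted table moves (almost) nothing
  again <- summit_shift(shifted, neg_ids)
  expect_lt(abs(again$shift - shifted$shift), 0.05)
  # constant negatives shift by exactly their value
  flat <- act
  flat$activity[seq_len(n_neg)] <- 0.75
  expect_equal(summit_shift(flat, neg_ids)$shift, 0.75)
  expect_error(summit_shift(act, neg_ids[1:10]), ">= 20")
})

test_that("quantile normalization equalizes column distributions", {
  expect_equal(quantile_normalize(cbind(c(1, 3), c(4, 2))),
               cbind(c(1.5, 3.5), c(3.5, 1.5)))
  # identical columns are unchanged
  m <- cbind(a = c(3, 1, 2), b = c(3, 1, 2))
  expect_equal(quantile_normalize(m), m)
  # tie-free input: identical sorted values per column afterwards
  set.seed(203)
  x <- matrix(stats::rnorm(300), ncol = 3)
  q <- quantile_normalize(x)
  expect_equal(apply(q, 2, sort), matrix(rep(sort(q[, 1]), 3), ncol = 3))
  # tied observations receive the mean of their tied ranks' values
  xt <- cbind(c(2, 2, 5), c(1, 3, 9))
  qt <- quantile_normalize(xt)
  target <- rowMeans(cbind(sort(xt[, 1]), sort(xt[, 2])))
  expect_equal(qt[1:2, 1], rep(mean(target[1:2]), 2))
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "missing")
  expect_error(quantile_normalize(matrix(1:3, ncol = 1)), "two columns")
  # agrees with the standard implementation where both are defined
  y <- matrix(stats::rnorm(300), ncol = 3)
  expect_equal(unname(quantile_normalize(y)),
               unname(limma::normalizeQuantiles(y)), tolerance = 1e-10)
})
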