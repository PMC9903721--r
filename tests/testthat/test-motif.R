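test_that("JASPAR parsing produces the expected probabilities and scores", {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(">TOY2 toy", "A [ 4 0 ]", "C [ 0 4 ]", "G [ 0 0 ]", "T [ 0 0 ]"),
             path)
  pwm <- read_jaspar(path)
  expect_equal(pwm$length, 2L)
  expect_equal(pwm$consensus, "AC")
  # total pseudocount 1 spread by the uniform background: p_max = 4.25/5
  expect_equal(pwm$max_score, 2 * log2((4.25 / 5) / 0.25))

  # uniform matrix: zero log-odds everywhere, every word scores 0
  writeLines(c(">U uniform", "A [ 1 1 1 ]", "C [ 1 1 1 ]", "G [ 1 1 1 ]",
               "T [ 1 1 1 ]"), path)
  u <- read_jaspar(path)
  expect_true(all(abs(u$log_odds) < 1e-12))
  expect_equal(scan_pwm("ACGTACGT", u, 0)$score, rep(0, 12))

  writeLines(c(">B bad", "A [ 1 1 ]", "C [ 1 ]", "G [ 1 1 ]", "T [ 1 1 ]"),
             path)
  expect_error(read_jaspar(path), "length mismatch")
})

test_that("scanning matches brute-force enumeration and is strand-symmetric", {
  set.seed(401)
  for (i in 1:25) {
    counts <- matrix(sample(0:9, 16, replace = TRUE) + 1, nrow = 4)
    pwm <- toy_pwm(counts)
    seq <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
    thr <- runif(1, -2, 2)
    got <- scan_pwm(seq, pwm, thr)
    want <- oracle_scan(seq, pwm, thr)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)

    # reverse complement: same score multiset, strands swapped
    rc_hits <- scan_pwm(rc_chr(seq), pwm, thr)
    expect_equal(sort(rc_hits$score), sort(got$score), tolerance = 1e-12)
    expect_equal(sum(rc_hits$strand == "+"), sum(got$strand == "-"))
  }
})

test_that("planted consensus is found at full score; high thresholds empty", {
  pwm <- re1_pwm()
  seq <- paste0(strrep("A", 30), pwm$consensus, strrep("A", 30))
  hits <- scan_pwm(seq, pwm, pwm$max_score - 1e-9)
  expect_equal(hits$start, 31L)
  expect_equal(hits$score, pwm$max_score)
  expect_equal(nrow(scan_pwm(seq, pwm, pwm$max_score + 1)), 0L)
  # too-short sequence
  expect_equal(nrow(scan_pwm("ACGT", pwm, 0)), 0L)
})

test_that("strength classification uses a strict boundary and is monotone", {
  cfg <- motif_config()
  expect_equal(classify_strength(c(21.0, 19.0, 20.86), cfg),
               c("strong", "weak", "weak"))
  scores <- seq(15, 30, by = 0.5)
  cls <- classify_strength(scores, cfg)
  expect_true(all(diff(cls == "strong") >= 0))  # monotone in score
})

test_that("motif planting hits its target score and only alters the span", {
  pwm <- re1_pwm()
  set.seed(402)
  host <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  for (target in c(15, 18.3, 21, 24.7, 28, 30)) {
    planted <- as.character(plant_motif(host, pwm, target, 91))
    expect_equal(substr(planted, 1, 90), substr(host, 1, 90))
    expect_equal(substr(planted, 112, 200), substr(host, 112, 200))
    hits <- scan_pwm(planted, pwm, target - 0.5 - 1e-9)
    best <- hits[which.max(hits$score), ]
    expect_equal(best$start, 91L)
    expect_lte(abs(best$score - target), 0.5)
  }
  # extremes force consensus / anti-consensus
  at_max <- as.character(plant_motif(host, pwm, pwm$max_score, 91))
  expect_equal(substr(at_max, 91, 111), pwm$consensus)
  at_min <- as.character(plant_motif(host, pwm, pwm$min_score, 91))
  anti <- paste(c("A", "C", "G", "T")[apply(pwm$log_odds, 2, which.min)],
                collapse = "")
  expect_equal(substr(at_min, 91, 111), anti)
  expect_error(plant_motif(host, pwm, pwm$max_score + 1, 91),
               "maximum achievable")
})

test_that("half sites split the matrix at columns 1-9 and 12-21", {
  pwm <- re1_pwm()
  seq <- paste0(strrep("A", 30), pwm$consensus, strrep("A", 30))
  hs <- half_sites(seq, pwm, half_site_threshold = 5)
  expect_equal(hs$left_pwm$length, 9L)
  expect_equal(hs$right_pwm$length, 10L)
  lf <- hs$left[hs$left$strand == "+", ]
  rf <- hs$right[hs$right$strand == "+", ]
  expect_true(31L %in% lf$start)        # left half at the motif start
  expect_equal(lf$end[lf$start == 31L], 39L)
  expect_true(42L %in% rf$start)        # right half after the 2-bp spacer
  # same pair appears on the minus strand of the reverse complement
  hs_rc <- half_sites(rc_chr(seq), pwm, 5)
  expect_true(any(hs_rc$left$strand == "-") && any(hs_rc$right$strand == "-"))
  expect_equal(sort(c(hs_rc$left$score, hs_rc$right$score)),
               sort(c(hs$left$score, hs$right$score)), tolerance = 1e-12)
})

test_that("half-site pairs are classified by spacer and orientation", {
  pwm <- re1_pwm()
  left_cons <- substr(pwm$consensus, 1, 9)
  right_cons <- substr(pwm$consensus, 12, 21)
  cfg <- motif_config(m_value = 20.86)
  classify_seq <- function(seq) {
    hs <- half_sites(seq, pwm, 5)
    pair_half_sites(hs$left, hs$right, cfg)
  }

  canonical <- classify_seq(paste0(strrep("A", 20), left_cons, "GT", right_cons,
                                   strrep("A", 20)))
  expect_equal(canonical$orientation_class, "canonical")
  expect_equal(canonical$spacer, 2L)
  # spacer columns of the matrix are uniform, so the pair score equals the
  # full-motif score at consensus
  expect_equal(canonical$pair_score, pwm$max_score, tolerance = 1e-9)

  atyp <- classify_seq(paste0(strrep("A", 20), left_cons, strrep("A", 8),
                              right_cons, strrep("A", 20)))
  expect_equal(atyp$orientation_class, "atypically_spaced")
  expect_equal(atyp$spacer, 8L)

  flip <- classify_seq(paste0(strrep("A", 20), right_cons, strrep("A", 5),
                              left_cons, strrep("A", 20)))
  expect_equal(flip$orientation_class, "flipped")

  conv <- classify_seq(paste0(strrep("A", 20), left_cons, strrep("A", 5),
                              rc_chr(right_cons), strrep("A", 20)))
  expect_equal(conv$orientation_class, "convergent")

  div <- classify_seq(paste0(strrep("A", 20), rc_chr(left_cons), strrep("A", 5),
                             right_cons, strrep("A", 20)))
  expect_equal(div$orientation_class, "divergent")

  # pairs separated by >= 100 nt are not emitted; hits become singles
  far <- classify_seq(paste0(strrep("A", 10), left_cons, strrep("A", 120),
                             right_cons, strrep("A", 10)))
  expect_equal(nrow(far), 0L)
  expect_true(nrow(attr(far, "singles")) >= 2L)
})

test_that("scrambling preserves the base multiset and honors rejection", {
  pwm <- re1_pwm()
  set.seed(403)
  host <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  seq <- as.character(plant_motif(host, pwm, 28, 91))
  for (i in 1:50) {
    out <- scramble_motif(seq, c(91, 111), pwm, rejection_threshold = 5,
                          rejection_window = c(75, 110), seed = i)
    expect_equal(sort(strsplit(substr(out, 91, 111), "")[[1]]),
                 sort(strsplit(substr(seq, 91, 111), "")[[1]]))
    expect_equal(substr(out, 1, 90), substr(seq, 1, 90))
    hits <- scan_pwm(out, pwm, 5)
    expect_false(any(hits$start >= 75 & hits$start <= 110))
  }
  # permutation-invariant span cannot escape a self-matching model
  poly_pwm <- pwm_model(rbind(A = rep(9, 6), C = rep(0, 6), G = rep(0, 6),
                              T = rep(0, 6)))
  poly_seq <- paste0(strrep("C", 79), strrep("A", 21), strrep("C", 100))
  expect_error(scramble_motif(poly_seq, c(80, 100), poly_pwm,
                              rejection_threshold = 1, seed = 1),
               "attempts")
})

test_that("motif contribution is the scrambled-minus-native difference", {
  expect_equal(motif_contribution(0, 0), 0)
  expect_equal(motif_contribution(-2, 0), 2)
  expect_equal(motif_contribution(c(1, -1), c(0.5, 0.5)), c(-0.5, 1.5))
})

test_that("allele delta scoring finds each allele's best overlapping hit", {
  pwm <- toy_pwm()
  set.seed(404)
  # identical contexts give delta 0
  ctx <- paste(sample(c("A", "C", "G", "T"), 41, replace = TRUE), collapse = "")
  same <- allele_delta_score(ctx, ctx, pwm, threshold = 2)
  expect_equal(same$delta, 0)
  expect_error(allele_delta_score(ctx, substr(ctx, 1, 40), pwm),
               "equal length")
  # against exhaustive enumeration on random ref/alt pairs
  for (i in 1:30) {
    ref <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    alt <- ref
    substr(alt, 5, 5) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(ref, 5, 5)), 1)
    got <- allele_delta_score(ref, alt, pwm, threshold = 2)
    best_oracle <- function(ctx) {
      h <- oracle_scan(ctx, pwm, -Inf)
      h <- h[h$start <= 5 & h$start + pwm$length - 1 >= 5, ]
      max(h$score)
    }
    expect_equal(got$best_ref, best_oracle(ref), tolerance = 1e-12)
    expect_equal(got$best_alt, best_oracle(alt), tolerance = 1e-12)
    expect_equal(got$passes,
                 max(got$best_ref, got$best_alt) >= 2)
  }
})
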