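# Shared fixtures: toy PWMs, small designs, and brute-force oracles used to
# cross-check the vectorized implementations.

toy_pwm <- function(counts = NULL, name = "toy") {
  if (is.null(counts)) {
    counts <- rbind(A = c(8, 0, 1, 0), C = c(0, 8, 0, 1),
                    G = c(1, 0, 7, 0), T = c(0, 1, 1, 8))
  }
  pwm_model(counts, name = name)
}

re1_pwm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_jaspar(synthetic_re1_pfm())
    cache
  }
})

small_design <- function(seed = 1L, ...) {
  sim_design(n_E = 3L, n_S = 30L, n_neg = 25L, depth = 60L,
             n_replicates = 3L, seed = seed, ...)
}

rc_chr <- function(x) {
  paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = "")
}

# per-offset scoring loop, written independently of the package's vectorized
# column-sweep scanner
oracle_scan <- function(sequence, pwm, threshold) {
  lo <- pwm$log_odds
  L <- ncol(lo)
  score_word <- function(word) {
    chars <- strsplit(word, "")[[1]]
    s <- 0
    for (j in seq_len(L)) {
      b <- chars[j]
      s <- s + if (b %in% rownames(lo)) lo[b, j] else 0
    }
    s
  }
  out <- NULL
  n <- nchar(sequence) - L + 1
  for (i in seq_len(max(0, n))) {
    word <- substr(sequence, i, i + L - 1)
    sf <- score_word(word)
    if (sf >= threshold) out <- rbind(out, data.frame(start = i, strand = "+", score = sf))
    sr <- score_word(rc_chr(word))
    if (sr >= threshold) out <- rbind(out, data.frame(start = i, strand = "-", score = sr))
  }
  if (is.null(out)) {
    return(data.frame(start = integer(0), strand = character(0), score = numeric(0)))
  }
  out[order(out$start, out$strand), ]
}

# exact one-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_less <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  splits <- utils::combn(length(pooled), n)
  us <- apply(splits, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mean(us <= u_obs + 1e-9)
}

# two-sided Fisher p by hypergeometric enumeration (tables with probability
# at most the observed one, with the customary relative tolerance)
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
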