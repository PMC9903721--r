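#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef density lm median p.adjust pnorm pt qnorm rbinom
#'   rnbinom rpois runif sd setNames t.test vcov wilcox.test fisher.test
#'   complete.cases quantile
#' @importFrom utils adist head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named random stream seed from a master seed
#'
#' All stochastic operations in the package draw their seed from one master
#' seed plus a stream name, so that sub-operations are reproducible and
#' decoupled: changing how many draws one stage makes does not perturb the
#' next stage.
#'
#' @param seed master integer seed.
#' @param name character stream name.
#' @return an integer seed in \[0, 2^31).
#' @export
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483587)
}

## uniform random DNA strings (not necessarily unique)
rand_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## unique random k-mers (for barcodes); retries collisions
rand_kmers_unique <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- unique(rand_dna(n, len))
  while (length(out) < n) {
    out <- unique(c(out, rand_dna(n - length(out) + 10L, len)))
  }
  out[seq_len(n)]
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## best approximate (Hamming) occurrence of `pattern` in `read`;
## returns c(start, mismatches) or NULL if none within budget
best_hamming_hit <- function(read, pattern, max_mismatch) {
  ## fast path: exact match
  p <- regexpr(pattern, read, fixed = TRUE)[1]
  if (p > 0) return(c(start = p, mismatches = 0L))
  if (max_mismatch < 1L) return(NULL)
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  pv <- strsplit(pattern, "", fixed = TRUE)[[1]]
  L <- length(pv)
  n <- length(rv) - L + 1L
  if (n < 1L) return(NULL)
  best <- NULL
  best_mm <- max_mismatch + 1L
  for (i in seq_len(n)) {
    mm <- sum(rv[i:(i + L - 1L)] != pv)
    if (mm < best_mm) {
      best_mm <- mm
      best <- i
      if (mm == 0L) break
    }
  }
  if (best_mm > max_mismatch) return(NULL)
  c(start = best, mismatches = best_mm)
}

## vectorized anchor location over many reads: exact regexpr first, then a
## per-read approximate fallback for the residue. Returns integer start
## positions (NA where not found within budget).
locate_anchor <- function(reads, pattern, max_mismatch) {
  pos <- regexpr(pattern, reads, fixed = TRUE)
  pos <- ifelse(pos > 0, pos, NA_integer_)
  if (max_mismatch > 0L && anyNA(pos)) {
    idx <- which(is.na(pos))
    for (i in idx) {
      hit <- best_hamming_hit(reads[i], pattern, max_mismatch)
      if (!is.null(hit)) pos[i] <- hit[["start"]]
    }
  }
  as.integer(pos)
}

## inject per-base substitution errors at `rate` into reads (no indels)
inject_errors <- function(reads, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 0.05)
  if (rate == 0) return(reads)
  if (!is.null(seed)) set.seed(seed)
  vapply(reads, function(r) {
    n <- nchar(r)
    k <- rbinom(1L, n, rate)
    if (k == 0L) return(r)
    pos <- sample.int(n, k)
    chars <- strsplit(r, "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
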