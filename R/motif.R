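## PWM handling and motif-level computation.
##
## Scores are log2-odds sums over columns: sum_j log2(p_j(base)/bg(base)),
## with a total pseudocount of 1 distributed by the background (0.25/base
## under the uniform default). N bases contribute 0 (scored as background).

#' Construct a position weight matrix model
#'
#' @param counts 4 x L numeric matrix of per-column base counts (rows A,C,G,T)
#'   or column probabilities.
#' @param name model identifier.
#' @param pseudocount total pseudocount added per column, distributed by the
#'   background frequencies.
#' @param background length-4 base frequencies (A,C,G,T), summing to 1.
#' @return an object of class `pwm_model` with elements `counts`, `probs`,
#'   `log_odds` (4 x L, log2 scale), `length`, `max_score`, `min_score`,
#'   `consensus`.
#' @export
pwm_model <- function(counts, name = "pwm", pseudocount = 1,
                      background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, all(counts >= 0), length(background) == 4L,
            abs(sum(background) - 1) < 1e-8, pseudocount >= 0)
  rownames(counts) <- DNA_BASES
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("every PWM column needs positive total count")
  probs <- sweep(counts, 2, tot, "/")
  probs <- sweep(probs * rep(tot, each = 4) + pseudocount * background,
                 2, tot + pseudocount, "/")
  log_odds <- log2(probs / background)
  cons <- apply(log_odds, 2, which.max)
  structure(list(
    name = name, counts = counts, probs = probs, log_odds = log_odds,
    length = ncol(counts), pseudocount = pseudocount, background = background,
    max_score = sum(apply(log_odds, 2, max)),
    min_score = sum(apply(log_odds, 2, min)),
    consensus = paste(DNA_BASES[cons], collapse = "")
  ), class = "pwm_model")
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("pwm_model '%s': %d columns, score range [%.2f, %.2f], consensus %s\n",
              x$name, x$length, x$min_score, x$max_score, x$consensus))
  invisible(x)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Parses the JASPAR 2016+ PFM dialect: a `>ID NAME` header followed by four
#' rows `A [ 4 19 0 ... ]` (brackets optional).
#'
#' @inheritParams pwm_model
#' @param path path to the PFM file.
#' @return a [pwm_model()].
#' @export
read_jaspar <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!startsWith(lines[1], ">")) stop("JASPAR file must start with a '>' header")
  header <- strsplit(sub("^>", "", lines[1]), "\\s+")[[1]]
  name <- paste(header, collapse = " ")
  rows <- lines[2:5]
  parse_row <- function(ln) {
    ln <- sub("^\\s*[ACGTacgt]\\s*", "", ln)
    ln <- gsub("\\[|\\]", " ", ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
  }
  base_tags <- toupper(substr(trimws(rows), 1, 1))
  if (!identical(base_tags, DNA_BASES)) stop("expected rows in A, C, G, T order")
  vals <- lapply(rows, parse_row)
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("row length mismatch: %s", paste(lens, collapse = "/")))
  }
  pwm_model(do.call(rbind, vals), name = name, pseudocount = pseudocount,
            background = background)
}

## encode a sequence as row indices into the log-odds matrix (NA for N etc.)
encode_seq <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], DNA_BASES)
}

## score all offsets of an encoded sequence on the given strand's matrix
score_all_offsets <- function(idx, log_odds) {
  L <- ncol(log_odds)
  n <- length(idx) - L + 1L
  if (n < 1L) return(numeric(0))
  s <- numeric(n)
  for (j in seq_len(L)) {
    v <- log_odds[, j][idx[j:(j + n - 1L)]]
    v[is.na(v)] <- 0  # N scores as background
    s <- s + v
  }
  s
}

#' Scan a sequence with a PWM
#'
#' Every offset (and optionally both strands) is scored as the log2-odds sum
#' over columns; hits at or above `threshold` are returned sorted by start
#' position then strand. Minus-strand hits are reported in forward
#' coordinates (start < end on the forward strand).
#'
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param pwm a [pwm_model()].
#' @param threshold minimum log2-odds score to report.
#' @param strands `"both"` or `"forward"`.
#' @return data.frame with columns `start`, `end` (1-based, inclusive),
#'   `strand`, `score`, `match` (forward-strand subsequence).
#' @export
scan_pwm <- function(sequence, pwm, threshold, strands = c("both", "forward")) {
  strands <- match.arg(strands)
  stopifnot(inherits(pwm, "pwm_model"), length(sequence) == 1L)
  L <- pwm$length
  slen <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      match = character(0), stringsAsFactors = FALSE)
  if (slen < L) return(empty)
  idx <- encode_seq(sequence)
  fwd <- score_all_offsets(idx, pwm$log_odds)
  keep_f <- which(fwd >= threshold)
  hits <- data.frame(start = keep_f, score = fwd[keep_f],
                     strand = rep("+", length(keep_f)),
                     stringsAsFactors = FALSE)
  if (strands == "both") {
    rc <- revcomp(sequence)
    rev_scores <- score_all_offsets(encode_seq(rc), pwm$log_odds)
    keep <- which(rev_scores >= threshold)
    if (length(keep)) {
      ## position p on the reverse complement covers forward bases
      ## [slen - p - L + 2, slen - p + 1]
      hits <- rbind(hits, data.frame(start = slen - keep - L + 2L,
                                     score = rev_scores[keep],
                                     strand = "-", stringsAsFactors = FALSE))
    }
  }
  if (!nrow(hits)) return(empty)
  hits$end <- hits$start + L - 1L
  hits$match <- substring(sequence, hits$start, hits$end)
  hits <- hits[order(hits$start, hits$strand), c("start", "end", "strand", "score", "match")]
  rownames(hits) <- NULL
  hits
}

#' Motif strength configuration
#'
#' Holds the empirically derived score boundaries: the m-value (change point
#' of the score-vs-repression relationship, default 20.86) used to delineate
#' weak from strong motifs, and the genome-scan reporting threshold
#' (default 20.89). The two defaults are kept separate deliberately.
#'
#' @param m_value log2-odds boundary between weak and strong motifs.
#' @param scan_threshold log2-odds threshold for genome-wide scans.
#' @param half_site_threshold log2-odds threshold for half-site hits.
#' @export
motif_config <- function(m_value = 20.86, scan_threshold = 20.89,
                         half_site_threshold = 5) {
  stopifnot(m_value > 0)
  structure(list(m_value = m_value, scan_threshold = scan_threshold,
                 half_site_threshold = half_site_threshold),
            class = "motif_config")
}

#' Classify motif strength against the m-value boundary
#'
#' Strong means strictly above the boundary; a score exactly at the m-value
#' is classified weak.
#'
#' @param score numeric vector of log2-odds scores.
#' @param config a [motif_config()].
#' @return character vector `"weak"`/`"strong"`.
#' @export
classify_strength <- function(score, config = motif_config()) {
  ifelse(score > config$m_value, "strong", "weak")
}

## sub-model over a span of columns
pwm_slice <- function(pwm, cols, suffix) {
  pwm_model(pwm$counts[, cols, drop = FALSE],
            name = paste0(pwm$name, suffix),
            pseudocount = pwm$pseudocount, background = pwm$background)
}

#' Scan for the two half sites of a composite motif
#'
#' The left half-site model is columns 1-9 of the full matrix and the right
#' half-site model is columns 12-21 (the canonical arrangement separates the
#' halves by a 2-bp spacer). Both are scanned on both strands.
#'
#' @param sequence nucleotide string.
#' @param full_pwm full-length [pwm_model()] (>= 21 columns).
#' @param half_site_threshold log2-odds threshold applied to each half site.
#' @return list with `left` and `right` hit data.frames (see [scan_pwm()])
#'   and the `left_pwm`/`right_pwm` sub-models.
#' @export
half_sites <- function(sequence, full_pwm, half_site_threshold = 5) {
  stopifnot(full_pwm$length >= 21L)
  left_pwm <- pwm_slice(full_pwm, 1:9, "_left")
  right_pwm <- pwm_slice(full_pwm, 12:21, "_right")
  list(left = scan_pwm(sequence, left_pwm, half_site_threshold),
       right = scan_pwm(sequence, right_pwm, half_site_threshold),
       left_pwm = left_pwm, right_pwm = right_pwm)
}

## orientation of one L/R hit pair; spacer = downstream.start - upstream.end - 1
pair_orientation <- function(l, r) {
  if (l$strand == r$strand) {
    if (l$strand == "+") {
      if (l$start <= r$start) {
        sp <- r$start - l$end - 1L
        cls <- if (sp == 2L) "canonical" else "atypically_spaced"
      } else {
        sp <- l$start - r$end - 1L
        cls <- "flipped"
      }
    } else {
      ## minus strand: roles mirror — R upstream of L reads L-then-R on '-'
      if (r$start <= l$start) {
        sp <- l$start - r$end - 1L
        cls <- if (sp == 2L) "canonical" else "atypically_spaced"
      } else {
        sp <- r$start - l$end - 1L
        cls <- "flipped"
      }
    }
  } else {
    up <- if (l$start <= r$start) l else r
    dn <- if (l$start <= r$start) r else l
    sp <- dn$start - up$end - 1L
    cls <- if (up$strand == "+") "convergent" else "divergent"
  }
  list(spacer = sp, class = cls)
}

#' Pair half-site hits into composite binding-site candidates
#'
#' All left/right hit pairs with a spacer in \[0, `max_spacer`) and a summed
#' pair score above the m-value are emitted with an orientation class:
#' `canonical` (left then right, same strand, 2-bp spacer),
#' `atypically_spaced` (same arrangement, other spacer), `flipped`
#' (right before left, same strand), `convergent` / `divergent`
#' (opposite strands, facing inward/outward). Half-site hits that enter no
#' pair are returned as singles.
#'
#' @param left_hits,right_hits hit data.frames from [half_sites()].
#' @param config a [motif_config()]; `m_value` gates the pair score.
#' @param max_spacer pairs at or beyond this spacer are not considered.
#' @return data.frame of pairs with left/right coordinates, `spacer`,
#'   `orientation_class` and `pair_score`; unpaired hits in
#'   `attr(, "singles")`.
#' @export
pair_half_sites <- function(left_hits, right_hits, config = motif_config(),
                            max_spacer = 100L) {
  cols <- c("left_start", "left_end", "left_strand", "left_score",
            "right_start", "right_end", "right_strand", "right_score",
            "spacer", "orientation_class", "pair_score")
  out <- list()
  used_l <- logical(nrow(left_hits))
  used_r <- logical(nrow(right_hits))
  if (nrow(left_hits) && nrow(right_hits)) {
    for (i in seq_len(nrow(left_hits))) {
      for (j in seq_len(nrow(right_hits))) {
        l <- left_hits[i, ]; r <- right_hits[j, ]
        o <- pair_orientation(l, r)
        ps <- l$score + r$score
        if (o$spacer >= 0L && o$spacer < max_spacer && ps > config$m_value) {
          used_l[i] <- TRUE; used_r[j] <- TRUE
          out[[length(out) + 1L]] <- data.frame(
            left_start = l$start, left_end = l$end, left_strand = l$strand,
            left_score = l$score, right_start = r$start, right_end = r$end,
            right_strand = r$strand, right_score = r$score,
            spacer = o$spacer, orientation_class = o$class, pair_score = ps,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  singles <- rbind(
    if (any(!used_l)) cbind(left_hits[!used_l, , drop = FALSE], half = "left"),
    if (any(!used_r)) cbind(right_hits[!used_r, , drop = FALSE], half = "right"))
  attr(pairs, "singles") <- singles
  pairs
}

#' Scramble a motif span with rejection re-sampling
#'
#' The bases inside `span` are permuted uniformly (base multiset preserved).
#' The scrambled sequence is rescanned with `pwm`; if any hit starting inside
#' `rejection_window` scores at or above `rejection_threshold`, the original
#' span is re-permuted, up to `max_attempts` tries.
#'
#' @param sequence nucleotide string.
#' @param span length-2 vector, 1-based inclusive interval to scramble.
#' @param pwm [pwm_model()] used for the rejection rescan.
#' @param rejection_threshold score at/above which a windowed hit rejects.
#' @param rejection_window length-2 vector of hit start positions to police.
#' @param max_attempts maximum permutations before giving up.
#' @param seed optional integer seed for the permutation stream.
#' @return the sequence with the span scrambled.
#' @export
scramble_motif <- function(sequence, span, pwm, rejection_threshold = 5,
                           rejection_window = c(75L, 110L),
                           max_attempts = 100L, seed = NULL) {
  stopifnot(length(span) == 2L, span[1] >= 1L, span[2] <= nchar(sequence),
            span[1] <= span[2])
  if (!is.null(seed)) set.seed(seed)
  orig <- strsplit(substring(sequence, span[1], span[2]), "", fixed = TRUE)[[1]]
  for (attempt in seq_len(max_attempts)) {
    perm <- sample(orig)  # re-permute from the original span each attempt
    cand <- paste0(substring(sequence, 1L, span[1] - 1L),
                   paste(perm, collapse = ""),
                   substring(sequence, span[2] + 1L, nchar(sequence)))
    hits <- scan_pwm(cand, pwm, rejection_threshold)
    bad <- nrow(hits) && any(hits$start >= rejection_window[1] &
                               hits$start <= rejection_window[2])
    if (!bad) return(cand)
  }
  stop(sprintf("scramble rejected after %d attempts: span permutations keep a hit >= %.2f in window [%d, %d]",
               max_attempts, rejection_threshold,
               rejection_window[1], rejection_window[2]))
}

#' Motif contribution from a native/scrambled activity pair
#'
#' `scrambled - native` on the log2 activity scale: positive values mean the
#' intact motif was repressive.
#'
#' @param native_activity,scrambled_activity log2 activities on a shared
#'   normalized scale.
#' @export
motif_contribution <- function(native_activity, scrambled_activity) {
  scrambled_activity - native_activity
}

#' Score the best motif hit for each allele of a variant
#'
#' Both allele contexts (identical except at the centered variant base) are
#' scanned without a threshold; the best hit overlapping the variant position
#' on either strand is retained per allele. A variant passes when the better
#' of the two best scores reaches `threshold`.
#'
#' @param context_ref,context_alt equal-length contexts with the variant base
#'   at the center position.
#' @param pwm [pwm_model()].
#' @param threshold pass threshold on the better allele (default 20.89).
#' @return list with `best_ref`, `best_alt`, `delta` (alt - ref) and
#'   `passes`.
#' @export
allele_delta_score <- function(context_ref, context_alt, pwm,
                               threshold = 20.89) {
  if (nchar(context_ref) != nchar(context_alt)) {
    stop("allele contexts must have equal length")
  }
  center <- (nchar(context_ref) + 1L) %/% 2L
  best_over <- function(ctx) {
    hits <- scan_pwm(ctx, pwm, -Inf)
    hits <- hits[hits$start <= center & hits$end >= center, , drop = FALSE]
    if (!nrow(hits)) return(NA_real_)
    max(hits$score)
  }
  best_ref <- best_over(context_ref)
  best_alt <- best_over(context_alt)
  list(best_ref = best_ref, best_alt = best_alt,
       delta = best_alt - best_ref,
       passes = isTRUE(max(best_ref, best_alt, na.rm = TRUE) >= threshold))
}

#' Write a target-score motif into a sequence
#'
#' Starts from the consensus (maximum-score) word and downgrades single
#' bases: columns are visited in random order and each picks the base whose
#' score reduction best matches the remaining gap to `target_score`, with
#' random restarts until the achieved score is within `tol` of the target.
#' Only the motif span is altered.
#'
#' @param sequence host nucleotide string.
#' @param pwm [pwm_model()].
#' @param target_score desired log2-odds score.
#' @param position 1-based start of the motif span.
#' @param tol acceptable |achieved - target| (default 0.5).
#' @param max_iter maximum coordinate moves.
#' @return the sequence with the motif written at `position`; the achieved
#'   score is attached as `attr(, "score")`.
#' @export
plant_motif <- function(sequence, pwm, target_score, position, tol = 0.5,
                        max_iter = 2000L) {
  lo <- pwm$log_odds
  L <- pwm$length
  if (position < 1L || position + L - 1L > nchar(sequence)) {
    stop("motif span does not fit in the sequence at that position")
  }
  if (target_score > pwm$max_score + 1e-9) {
    stop(sprintf("target score %.3f exceeds the PWM maximum achievable score %.3f",
                 target_score, pwm$max_score))
  }
  if (target_score < pwm$min_score - 1e-9) {
    stop(sprintf("target score %.3f is below the PWM minimum score %.3f",
                 target_score, pwm$min_score))
  }
  ## constructive randomized best-fit: starting from the consensus, walk the
  ## columns in random order and at each pick the base whose score reduction
  ## best matches the remaining deficit; restart with a fresh column order
  ## until within tolerance
  cons <- apply(lo, 2, which.max)
  deficit <- pwm$max_score - target_score
  best_idx <- cons
  best_err <- abs(deficit)
  n_restarts <- max(1L, max_iter %/% L)
  for (rs in seq_len(n_restarts)) {
    if (best_err <= tol) break
    idx <- cons
    rem <- deficit
    for (j in sample.int(L)) {
      if (abs(rem) <= tol) break
      red <- lo[cons[j], j] - lo[, j]   # per-base reduction, >= 0
      b <- which.min(abs(rem - red))
      idx[j] <- b
      rem <- rem - red[b]
    }
    if (abs(rem) < best_err) {
      best_err <- abs(rem)
      best_idx <- idx
    }
  }
  base_idx <- best_idx
  cur <- sum(lo[cbind(base_idx, seq_len(L))])
  if (abs(cur - target_score) > tol) {
    stop(sprintf("could not reach target score %.3f within %.2f (achieved %.3f; PWM max %.3f)",
                 target_score, tol, cur, pwm$max_score))
  }
  word <- paste(DNA_BASES[base_idx], collapse = "")
  out <- paste0(substring(sequence, 1L, position - 1L), word,
                substring(sequence, position + L, nchar(sequence)))
  attr(out, "score") <- cur
  out
}

#' Path to the synthetic RE1-like PFM shipped with the package
#'
#' A 21-column synthetic position frequency matrix shaped like the canonical
#' RE1 motif: two informative 9/10-column half sites flanking two exactly
#' uniform spacer columns (10-11). It is a constructed stand-in, not a
#' database matrix.
#'
#' @return file path.
#' @export
synthetic_re1_pfm <- function() {
  system.file("extdata", "synthetic_RE1_21bp.jaspar", package = "mpraduo",
              mustWork = TRUE)
}
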