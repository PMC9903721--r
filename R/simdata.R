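## Synthetic dual-element reporter experiments with known ground truth.
##
## The generator emulates the benchmark-style study design: silencer
## candidates (S, 200 nt) carrying a centrally planted RE1-like motif at
## positions 91-111, activating elements (E, 150 nt), motif-free negative
## controls, optional ref/alt variant element pairs with a planted allelic
## skew, negative-binomial DNA/RNA counts, and linker-delimited association
## and tag reads.

#' Design of a synthetic dual-element reporter experiment
#'
#' Defaults are the study conditions used throughout the package's own
#' validation: 500 silencer candidates with motif scores spanning 15-30
#' log2-odds units around a true change point of 20.86, 5 activating
#' elements, 100 negative controls, mean plasmid depth 100, negative-binomial
#' dispersion 0.05 and 5 replicates, with duo activities composed by the
#' log-additive model `b0 + bS*aS + bE*aE + bSE*aS*aE`.
#'
#' @param n_E number of activating (E) elements.
#' @param n_S number of silencer-candidate (S) elements.
#' @param n_neg number of motif-free negative controls.
#' @param motif_score_range interval (log2-odds) of planted motif scores.
#' @param true_changepoint score boundary above which silencing switches on;
#'   must lie strictly inside `motif_score_range`.
#' @param silencer_slope log2-activity change per score unit above the change
#'   point (negative = repression).
#' @param log_additive_betas named vector `(beta0, betaS, betaE, betaSE)`
#'   composing duo activities from single activities.
#' @param nb_dispersion negative-binomial dispersion `alpha` with variance
#'   `m + alpha * m^2` (0 degenerates to Poisson).
#' @param depth mean DNA count per construct.
#' @param n_replicates number of DNA and RNA replicates.
#' @param allelic_effects named numeric vector: variant id -> true allelic
#'   skew (alt - ref) in log2 units.
#' @param barcodes_per_S,barcodes_per_E inclusive ranges of barcodes assigned
#'   per oligo.
#' @param multi_frac fraction of barcodes deliberately assigned to a second
#'   oligo (exercises the ambiguous-barcode drop rule).
#' @param umi_length UMI length in association reads.
#' @param seed master seed; all sub-operations derive named streams from it.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_E = 5L, n_S = 500L, n_neg = 100L,
                       motif_score_range = c(15, 30),
                       true_changepoint = 20.86,
                       silencer_slope = -0.5,
                       log_additive_betas = c(beta0 = -0.03, betaS = 0.86,
                                              betaE = 0.68, betaSE = -0.06),
                       nb_dispersion = 0.05, depth = 100L,
                       n_replicates = 5L, allelic_effects = numeric(0),
                       barcodes_per_S = c(20L, 40L),
                       barcodes_per_E = c(10L, 20L),
                       multi_frac = 0.01, umi_length = 8L, seed = 1L) {
  stopifnot(n_E > 0, n_S > 0, n_neg > 0, depth > 0, n_replicates > 0,
            length(motif_score_range) == 2L,
            motif_score_range[1] < motif_score_range[2],
            nb_dispersion >= 0, multi_frac >= 0, multi_frac < 1)
  if (true_changepoint <= motif_score_range[1] ||
      true_changepoint >= motif_score_range[2]) {
    stop("true_changepoint must lie strictly inside motif_score_range")
  }
  if (length(log_additive_betas) != 4L) {
    stop("log_additive_betas must have 4 entries (beta0, betaS, betaE, betaSE)")
  }
  names(log_additive_betas) <- c("beta0", "betaS", "betaE", "betaSE")
  if (length(allelic_effects) && is.null(names(allelic_effects))) {
    names(allelic_effects) <- sprintf("var%03d", seq_along(allelic_effects))
  }
  structure(list(
    n_E = as.integer(n_E), n_S = as.integer(n_S), n_neg = as.integer(n_neg),
    motif_score_range = motif_score_range,
    true_changepoint = true_changepoint, silencer_slope = silencer_slope,
    log_additive_betas = log_additive_betas,
    nb_dispersion = nb_dispersion, depth = depth,
    n_replicates = as.integer(n_replicates),
    allelic_effects = allelic_effects,
    barcodes_per_S = as.integer(barcodes_per_S),
    barcodes_per_E = as.integer(barcodes_per_E),
    multi_frac = multi_frac, umi_length = as.integer(umi_length),
    seed = as.integer(seed)), class = "sim_design")
}

## true single-element activity of a silencer candidate given its motif score
silencer_activity <- function(score, design) {
  design$silencer_slope * pmax(0, score - design$true_changepoint)
}

duo_truth <- function(aS, aE, betas) {
  betas[["beta0"]] + betas[["betaS"]] * aS + betas[["betaE"]] * aE +
    betas[["betaSE"]] * aS * aE
}

#' Generate the oligo library and its ground truth
#'
#' S elements are 200 nt with a motif planted at positions 91-111 (1-based)
#' at scores drawn uniformly from the design's range; E elements are 150 nt;
#' negative controls are 200 nt and audited to carry no hit at or above the
#' scan threshold. Barcodes (20 nt for S-module oligos, 10 nt for E) are
#' assigned per oligo, with a `multi_frac` fraction deliberately mapped to a
#' second oligo. Variant pairs share a backbone sequence differing at one
#' base outside the motif; the alt allele's true activity is ref + skew.
#'
#' @param design a [sim_design()].
#' @param pwm [pwm_model()] used for motif planting (default: the shipped
#'   synthetic RE1-like matrix).
#' @param scan_threshold negatives are regenerated until they have no hit at
#'   or above this score.
#' @return list with `library` (data.frame: oligo_id, module, class,
#'   sequence, motif_start, motif_end, motif_score) and `truth` (class
#'   `sim_truth`: `elements`, `constructs`, `barcodes`, `variants`,
#'   `design`).
#' @export
make_library <- function(design, pwm = read_jaspar(synthetic_re1_pfm()),
                         scan_threshold = 20.89) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(stream_seed(design$seed, "make_library"))
  rng <- design$motif_score_range

  ## --- S elements: planted motif at 91-111
  s_ids <- sprintf("S%04d", seq_len(design$n_S))
  s_scores <- runif(design$n_S, rng[1], rng[2])
  s_seq <- rand_dna(design$n_S, 200L)
  planted <- numeric(design$n_S)
  for (i in seq_len(design$n_S)) {
    s <- plant_motif(s_seq[i], pwm, s_scores[i], position = 91L)
    planted[i] <- attr(s, "score")
    s_seq[i] <- as.character(s)
  }

  ## --- E elements: activators, 150 nt
  e_ids <- sprintf("E%02d", seq_len(design$n_E))
  e_seq <- rand_dna(design$n_E, 150L)
  e_act <- runif(design$n_E, 0.5, 2)

  ## --- negative controls: 200 nt, no hit at/above the scan threshold
  n_ids <- sprintf("NEG%03d", seq_len(design$n_neg))
  n_seq <- rand_dna(design$n_neg, 200L)
  for (i in seq_len(design$n_neg)) {
    while (nrow(scan_pwm(n_seq[i], pwm, scan_threshold)) > 0L) {
      n_seq[i] <- rand_dna(1L, 200L)
    }
  }

  ## --- variant ref/alt pairs (S-module oligos)
  n_var <- length(design$allelic_effects)
  var_ids <- names(design$allelic_effects)
  v_ref_ids <- v_alt_ids <- character(0)
  v_ref_seq <- v_alt_seq <- character(0)
  v_scores <- numeric(0)
  if (n_var) {
    v_ref_ids <- paste0(var_ids, "_ref")
    v_alt_ids <- paste0(var_ids, "_alt")
    v_scores <- runif(n_var, rng[1], rng[2])
    v_ref_seq <- rand_dna(n_var, 200L)
    for (i in seq_len(n_var)) {
      v_ref_seq[i] <- as.character(plant_motif(v_ref_seq[i], pwm, v_scores[i], 91L))
    }
    ## alt differs at position 50, outside the motif span
    v_alt_seq <- vapply(v_ref_seq, function(s) {
      b <- substr(s, 50L, 50L)
      paste0(substr(s, 1L, 49L), sample(setdiff(DNA_BASES, b), 1L),
             substr(s, 51L, nchar(s)))
    }, character(1), USE.NAMES = FALSE)
  }

  library <- data.frame(
    oligo_id = c(s_ids, e_ids, n_ids, v_ref_ids, v_alt_ids),
    module = c(rep("S", design$n_S), rep("E", design$n_E),
               rep("S", design$n_neg), rep("S", 2L * n_var)),
    class = c(rep("silencer", design$n_S), rep("activator", design$n_E),
              rep("negative", design$n_neg),
              rep("variant_ref", n_var), rep("variant_alt", n_var)),
    sequence = c(s_seq, e_seq, n_seq, v_ref_seq, v_alt_seq),
    motif_start = c(rep(91L, design$n_S), rep(NA_integer_, design$n_E + design$n_neg),
                    rep(91L, 2L * n_var)),
    motif_end = c(rep(111L, design$n_S), rep(NA_integer_, design$n_E + design$n_neg),
                  rep(111L, 2L * n_var)),
    motif_score = c(planted, rep(NA_real_, design$n_E + design$n_neg),
                    v_scores, v_scores),
    stringsAsFactors = FALSE)

  ## --- element truth
  v_ref_act <- silencer_activity(v_scores, design)
  elements <- data.frame(
    oligo_id = library$oligo_id, module = library$module,
    class = library$class, motif_score = library$motif_score,
    true_activity = c(silencer_activity(planted, design), e_act,
                      rep(0, design$n_neg), v_ref_act,
                      v_ref_act + unname(design$allelic_effects)),
    stringsAsFactors = FALSE)

  ## --- barcode assignment (20 nt for S module, 10 nt for E)
  assign_bc <- function(ids, k_range, len) {
    k <- sample(seq(k_range[1], k_range[2]), length(ids), replace = TRUE)
    bcs <- rand_kmers_unique(sum(k), len)
    data.frame(barcode = bcs, oligo_id = rep(ids, k),
               stringsAsFactors = FALSE)
  }
  s_mod_ids <- library$oligo_id[library$module == "S"]
  bc_S <- assign_bc(s_mod_ids, design$barcodes_per_S, 20L)
  bc_E <- assign_bc(e_ids, design$barcodes_per_E, 10L)
  bc <- rbind(cbind(bc_S, module = "S"), cbind(bc_E, module = "E"))
  bc$second_oligo <- NA_character_
  if (design$multi_frac > 0) {
    for (mod in c("S", "E")) {
      rows <- which(bc$module == mod)
      n_amb <- max(1L, round(design$multi_frac * length(rows)))
      pick <- sample(rows, n_amb)
      pool <- if (mod == "S") s_mod_ids else e_ids
      bc$second_oligo[pick] <- vapply(bc$oligo_id[pick], function(o) {
        sample(setdiff(pool, o), 1L)
      }, character(1))
    }
  }
  bc$ambiguous <- !is.na(bc$second_oligo)

  ## --- constructs: all S-module x E duos (ES orientation) + all singles
  aS <- setNames(elements$true_activity, elements$oligo_id)
  duo <- expand.grid(S_id = c(s_ids, n_ids, v_ref_ids, v_alt_ids),
                     E_id = e_ids, stringsAsFactors = FALSE)
  constructs <- rbind(
    data.frame(construct_id = paste(duo$S_id, duo$E_id, "ES", sep = ":"),
               S_id = duo$S_id, E_id = duo$E_id, orientation = "ES",
               true_activity = duo_truth(aS[duo$S_id], aS[duo$E_id],
                                         design$log_additive_betas),
               stringsAsFactors = FALSE),
    data.frame(construct_id = paste0(e_ids, ":single-E"),
               S_id = NA_character_, E_id = e_ids, orientation = "single-E",
               true_activity = unname(aS[e_ids]), stringsAsFactors = FALSE),
    data.frame(construct_id = paste0(c(s_ids, n_ids, v_ref_ids, v_alt_ids),
                                     ":single-S"),
               S_id = c(s_ids, n_ids, v_ref_ids, v_alt_ids),
               E_id = NA_character_, orientation = "single-S",
               true_activity = unname(aS[c(s_ids, n_ids, v_ref_ids, v_alt_ids)]),
               stringsAsFactors = FALSE))
  rownames(constructs) <- NULL

  variants <- if (n_var) {
    data.frame(variant_id = var_ids, ref_id = v_ref_ids, alt_id = v_alt_ids,
               skew = unname(design$allelic_effects), stringsAsFactors = FALSE)
  } else {
    data.frame(variant_id = character(0), ref_id = character(0),
               alt_id = character(0), skew = numeric(0))
  }

  truth <- structure(list(elements = elements, constructs = constructs,
                          barcodes = bc, variants = variants,
                          design = design), class = "sim_truth")
  list(library = library, truth = truth)
}

#' Simulate DNA and RNA count tables from ground truth
#'
#' DNA counts are negative binomial with mean `depth`; RNA replicate counts
#' are negative binomial with mean `depth * 2^true_activity * size factor`,
#' the per-replicate size factors drawn log-uniformly in \[0.5, 2\].
#' Dispersion `alpha` gives variance `m + alpha * m^2`; `alpha = 0`
#' degenerates to Poisson.
#'
#' @param library,truth from [make_library()].
#' @param design the [sim_design()] (defaults to the one in `truth`).
#' @return a [count_table()] with `n_replicates` DNA and RNA samples; the
#'   drawn RNA size factors are attached as `attr(, "true_size_factors")`.
#' @export
simulate_counts <- function(library, truth, design = truth$design) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(stream_seed(design$seed, "simulate_counts"))
  cons <- truth$constructs
  n <- nrow(cons)
  R <- design$n_replicates
  draw <- function(mu) {
    if (design$nb_dispersion < 1e-12) rpois(n, mu)
    else rnbinom(n, mu = mu, size = 1 / design$nb_dispersion)
  }
  dna <- vapply(seq_len(R), function(j) draw(rep(design$depth, n)), numeric(n))
  sf <- 2^runif(R, log2(0.5), log2(2))
  rna <- vapply(seq_len(R), function(j) {
    draw(design$depth * 2^cons$true_activity * sf[j])
  }, numeric(n))
  counts <- cbind(dna, rna)
  colnames(counts) <- c(sprintf("DNA_%d", seq_len(R)), sprintf("RNA_%d", seq_len(R)))

  ## barcode multiplicities: number of (unambiguous) barcodes assigned to the
  ## S oligo for S-containing rows, to the E oligo for single-E rows
  bc_n <- table(truth$barcodes$oligo_id[!truth$barcodes$ambiguous])
  n_bar <- ifelse(is.na(cons$S_id), as.integer(bc_n[cons$E_id]),
                  as.integer(bc_n[cons$S_id]))
  constructs <- data.frame(cons[, c("construct_id", "S_id", "E_id", "orientation")],
                           n_barcodes = n_bar, stringsAsFactors = FALSE)
  samples <- data.frame(sample = colnames(counts),
                        type = rep(c("DNA", "RNA"), each = R),
                        replicate = rep(seq_len(R), 2L),
                        stringsAsFactors = FALSE)
  ct <- count_table(constructs, counts, samples)
  attr(ct, "true_size_factors") <- sf
  ct
}

## fixed tag-read layout (see tag_layout())
.tag_spacer <- paste(rep(c("GATTACAGGC"), 9L), collapse = "")

#' Simulate association and tag reads
#'
#' Association reads follow the amplicon layout `UMI + barcode +
#' upstream-linker + oligo + downstream-linker`, with the module-specific
#' linker pairs (vector A for S-module oligos, vector P for E). Ambiguous
#' barcodes emit reads for both of their assigned oligos. Tag reads follow
#' [tag_layout()]: duo reads place both barcodes at least 110 nt of payload
#' after the GFP-tail anchor, single reads fewer than 110 nt.
#'
#' For each label in `samples` (columns of `counts`), tag reads are emitted
#' so that every construct contributes exactly its count, spread over
#' `min(count, n_barcodes)` distinct barcode (pairs). The realized
#' per-construct truth is returned alongside the reads.
#'
#' @param library,truth from [make_library()].
#' @param error_rate per-base substitution error rate in \[0, 0.05\].
#' @param seed integer seed.
#' @param counts optional [count_table()]; defaults to
#'   [simulate_counts()] on the truth's design.
#' @param samples character vector of sample labels to emit tag reads for.
#' @param reads_per_barcode association reads emitted per barcode-oligo
#'   assignment.
#' @param layout a [tag_layout()].
#' @return list with `association` (list of character vectors `S` and `E`),
#'   `tags` (named list per sample label), and `tag_truth` (data.frame:
#'   sample, construct_id, count, n_barcodes actually encoded in the reads).
#' @export
simulate_reads <- function(library, truth, error_rate = 0, seed = 1L,
                           counts = NULL, samples = "DNA_1",
                           reads_per_barcode = 2L, layout = tag_layout()) {
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  set.seed(stream_seed(seed, "simulate_reads"))
  design <- truth$design
  if (is.null(counts)) counts <- simulate_counts(library, truth, design)
  seq_of <- setNames(library$sequence, library$oligo_id)
  bc <- truth$barcodes

  ## --- association reads, per module
  assoc <- lapply(c(S = "S", E = "E"), function(mod) {
    b <- bc[bc$module == mod, ]
    tgt <- c(b$oligo_id, b$second_oligo[!is.na(b$second_oligo)])
    bcs <- c(b$barcode, b$barcode[!is.na(b$second_oligo)])
    tgt <- rep(tgt, each = reads_per_barcode)
    bcs <- rep(bcs, each = reads_per_barcode)
    spec <- linker_spec(mod, umi_length = design$umi_length)
    umis <- rand_dna(length(bcs), design$umi_length)
    paste0(umis, bcs, spec$upstream_linker, seq_of[tgt], spec$downstream_linker)
  })

  ## --- tag reads per sample
  uniq <- bc[!bc$ambiguous, ]
  bc_by_oligo <- split(uniq$barcode, uniq$oligo_id)
  cons <- counts$constructs
  tail_seq <- rand_dna(1L, layout$tail_length)
  tags <- list()
  tag_truth <- list()
  for (smp in samples) {
    cnt <- counts$counts[, smp]
    reads <- vector("list", nrow(cons))
    mult <- integer(nrow(cons))
    for (i in seq_len(nrow(cons))) {
      k <- as.integer(cnt[i])
      if (k == 0L) next
      ori <- cons$orientation[i]
      if (ori %in% c("ES", "SE")) {
        bs <- bc_by_oligo[[cons$S_id[i]]]
        be <- bc_by_oligo[[cons$E_id[i]]]
        m <- min(k, cons$n_barcodes[i], length(bs))
        pair_s <- bs[seq_len(m)]
        pair_e <- sample(be, m, replace = TRUE)
        pick <- c(seq_len(m), sample.int(m, k - m, replace = TRUE))
        reads[[i]] <- paste0(layout$anchor, pair_e[pick], .tag_spacer,
                             pair_s[pick], tail_seq)
        mult[i] <- as.integer(m)
      } else {
        oid <- if (ori == "single-S") cons$S_id[i] else cons$E_id[i]
        b <- bc_by_oligo[[oid]]
        m <- min(k, cons$n_barcodes[i], length(b))
        pick <- c(seq_len(m), sample.int(m, k - m, replace = TRUE))
        reads[[i]] <- paste0(layout$anchor, b[pick], tail_seq)
        mult[i] <- as.integer(m)
      }
    }
    tags[[smp]] <- unlist(reads) %||% character(0)
    tag_truth[[smp]] <- data.frame(sample = smp,
                                   construct_id = cons$construct_id,
                                   count = as.integer(cnt),
                                   n_barcodes = mult,
                                   stringsAsFactors = FALSE)
  }

  if (error_rate > 0) {
    assoc <- lapply(assoc, inject_errors, rate = error_rate)
    tags <- lapply(tags, inject_errors, rate = error_rate)
  }
  list(association = assoc, tags = tags,
       tag_truth = do.call(rbind, c(tag_truth, list(make.row.names = FALSE))))
}

#' Draw random substitution variants over a sequence set
#'
#' Each base mutates independently with probability `rate`; the alternate
#' base is drawn from a 12-entry substitution spectrum (names like `"A>C"`),
#' whose three entries per reference base must sum to 1.
#'
#' @param sequences named character vector of reference sequences.
#' @param rate per-base substitution probability (> 0).
#' @param substitution_proportions named 12-entry numeric vector; default
#'   uniform (1/3 per alternate).
#' @param seed integer seed.
#' @return data.frame with `seq_id`, `pos`, `ref`, `alt`.
#' @export
random_substitutions <- function(sequences, rate,
                                 substitution_proportions = NULL,
                                 seed = 1L) {
  if (rate <= 0) stop("substitution rate must be positive")
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%03d", seq_along(sequences))
  }
  if (is.null(substitution_proportions)) {
    nm <- unlist(lapply(DNA_BASES, function(b) {
      paste0(b, ">", setdiff(DNA_BASES, b))
    }))
    substitution_proportions <- setNames(rep(1 / 3, 12L), nm)
  }
  stopifnot(length(substitution_proportions) == 12L)
  for (b in DNA_BASES) {
    s <- sum(substitution_proportions[paste0(b, ">", setdiff(DNA_BASES, b))])
    if (abs(s - 1) > 1e-8) {
      stop(sprintf("substitution proportions for reference base %s sum to %.4f, not 1", b, s))
    }
  }
  set.seed(stream_seed(seed, "random_substitutions"))
  out <- list()
  for (id in names(sequences)) {
    chars <- strsplit(sequences[[id]], "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < rate)
    if (!length(hit)) next
    ref <- chars[hit]
    alt <- vapply(ref, function(b) {
      alts <- setdiff(DNA_BASES, b)
      sample(alts, 1L, prob = substitution_proportions[paste0(b, ">", alts)])
    }, character(1), USE.NAMES = FALSE)
    out[[id]] <- data.frame(seq_id = id, pos = hit, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Simulate hinge-shaped change-point data
#'
#' `y = intercept + slope_below * x + slope_change * max(0, x - psi) + noise`
#' with `x` uniform over `xrange`.
#'
#' @param n points. @param psi true break point. @param slope_below slope
#'   left of the break. @param slope_change slope increment above the break.
#' @param sd residual standard deviation. @param xrange x interval.
#' @param intercept intercept. @param seed integer seed.
#' @return data.frame with `x`, `y`.
#' @export
sim_changepoint_data <- function(n, psi, slope_below = 0, slope_change = 0.5,
                                 sd = 0.5, xrange = c(15, 30), intercept = 0,
                                 seed = 1L) {
  set.seed(stream_seed(seed, "sim_changepoint"))
  x <- runif(n, xrange[1], xrange[2])
  y <- intercept + slope_below * x + slope_change * pmax(0, x - psi) +
    stats::rnorm(n, 0, sd)
  data.frame(x = x, y = y)
}

#' Simulate replicate-level allelic activities for variants
#'
#' Reference replicate activities are normal around a per-variant baseline;
#' alternate replicates add the planted skew.
#'
#' @param n_variants number of variants. @param skew true allelic skew
#'   (scalar or per-variant vector). @param sd replicate-level standard
#'   deviation. @param n_replicates replicates per allele. @param seed seed.
#' @return list with matrices `ref` and `alt` (variants x replicates) and
#'   vector `skew`.
#' @export
sim_allelic_replicates <- function(n_variants, skew = 0, sd = 0.2,
                                   n_replicates = 5L, seed = 1L) {
  set.seed(stream_seed(seed, "sim_allelic"))
  skew <- rep_len(skew, n_variants)
  base <- stats::rnorm(n_variants, 0, 1)
  ref <- base + matrix(stats::rnorm(n_variants * n_replicates, 0, sd),
                       n_variants, n_replicates)
  alt <- (base + skew) + matrix(stats::rnorm(n_variants * n_replicates, 0, sd),
                                n_variants, n_replicates)
  rownames(ref) <- rownames(alt) <- sprintf("var%04d", seq_len(n_variants))
  list(ref = ref, alt = alt, skew = skew)
}

#' Write an oligo library to FASTA
#'
#' @param library data.frame from [make_library()].
#' @param path output file.
#' @export
write_library_fasta <- function(library, path) {
  x <- Biostrings::DNAStringSet(library$sequence)
  names(x) <- library$oligo_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write reads to FASTQ with constant Phred-33 quality
#'
#' @param reads character vector.
#' @param path output file.
#' @param ids optional read names.
#' @export
write_reads_fastq <- function(reads, path, ids = NULL) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids %||% sprintf("read%06d", seq_along(reads))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(
                                strrep("I", nchar(reads))))
  invisible(path)
}
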