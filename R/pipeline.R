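## End-to-end wiring: one config object drives simulate -> match -> count ->
## activity -> calls -> m-value, with JSON sidecar metadata per run.

#' Run configuration with library presets
#'
#' Presets resolve the filter thresholds: `benchmark` requires >= 20 barcodes
#' and mean DNA >= 100 per construct; `whole_genome` requires >= 10 and
#' >= 20. Every threshold used by the pipeline stages is a field here.
#'
#' @param preset `"benchmark"`, `"whole_genome"` or `"custom"`.
#' @param min_barcodes,min_dna_mean filter thresholds (required for
#'   `"custom"`, derived otherwise).
#' @param fdr FDR for repression and emVar calls.
#' @param m_value,scan_threshold motif score boundaries (see
#'   [motif_config()]).
#' @param pseudocount for [log2_activity()].
#' @param psi0 initial break point for [fit_piecewise()].
#' @param seed master seed.
#' @param design a [sim_design()] for simulation-driven runs.
#' @return an object of class `run_config`.
#' @export
run_config <- function(preset = c("benchmark", "whole_genome", "custom"),
                       min_barcodes = NULL, min_dna_mean = NULL,
                       fdr = 0.01, m_value = 20.86, scan_threshold = 20.89,
                       pseudocount = 1, psi0 = 20, seed = 1L,
                       design = sim_design(seed = seed)) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     benchmark = c(20L, 100),
                     whole_genome = c(10L, 20),
                     custom = c(NA, NA))
  min_barcodes <- min_barcodes %||% defaults[1]
  min_dna_mean <- min_dna_mean %||% defaults[2]
  if (is.na(min_barcodes) || is.na(min_dna_mean)) {
    stop("custom preset requires explicit min_barcodes and min_dna_mean")
  }
  structure(list(preset = preset, min_barcodes = as.integer(min_barcodes),
                 min_dna_mean = min_dna_mean, fdr = fdr, m_value = m_value,
                 scan_threshold = scan_threshold, pseudocount = pseudocount,
                 psi0 = psi0, seed = as.integer(seed), design = design),
            class = "run_config")
}

#' Load a run configuration from a JSON or YAML file
#'
#' The file holds any subset of [run_config()]'s scalar arguments plus an
#' optional `design` block of [sim_design()] arguments; unknown keys are
#' rejected.
#'
#' @param path config file (`.json`, `.yaml` or `.yml`).
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  design_args <- raw$design %||% list()
  raw$design <- NULL
  known <- setdiff(names(formals(run_config)), "design")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  bad_d <- setdiff(names(design_args), names(formals(sim_design)))
  if (length(bad_d)) stop("unknown design keys: ", paste(bad_d, collapse = ", "))
  if (!"seed" %in% names(design_args) && "seed" %in% names(raw)) {
    design_args$seed <- raw$seed
  }
  do.call(run_config, c(raw, list(design = do.call(sim_design, design_args))))
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2^28
  sprintf("%07x", h)
}

#' Run the full simulated pipeline
#'
#' Executes, in order: library + truth simulation, association-read
#' generation and dictionary construction per module (`match`), tag-read
#' counting per sample (`count`), filtering / size factors / log2 activities
#' / summit shift (`activity`), repression calls against the negative
#' controls (`call`), emVar testing when the design plants variants
#' (`emvar`), and per-E-element change-point fits pooled into an m-value
#' estimate (`mvalue`). Results are written as TSV plus a JSON sidecar
#' carrying the config hash, seed, package version and stage tallies. Any
#' stage failure aborts with the stage name.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created; default: tempdir subdirectory
#'   named by the config hash).
#' @param count_from_reads simulate tag reads and count them through the
#'   dictionaries (slower, exercises the read path) rather than taking the
#'   simulated count table directly.
#' @return invisibly, a list with the per-stage results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, count_from_reads = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% file.path(tempdir(), paste0("mpraduo_", config_hash(config)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  meta <- list(config_hash = config_hash(config), seed = config$seed,
               preset = config$preset,
               package_version = as.character(utils::packageVersion("mpraduo")),
               stages = list())
  result <- withCallingHandlers(
    tryCatch({
      design <- config$design
      pwm <- read_jaspar(synthetic_re1_pfm())
      lib <- make_library(design, pwm, scan_threshold = config$scan_threshold)
      write_library_fasta(lib$library, file.path(out_dir, "library.fasta"))

      stage <- "match"
      reads <- simulate_reads(lib$library, lib$truth, seed = design$seed,
                              samples = if (count_from_reads)
                                sprintf("%s_%d", rep(c("DNA", "RNA"), each = design$n_replicates),
                                        rep(seq_len(design$n_replicates), 2L))
                              else "DNA_1")
      maps <- list(
        S = build_dictionary(reads$association$S, linker_spec("S"),
                             lib$library[lib$library$module == "S", ]),
        E = build_dictionary(reads$association$E, linker_spec("E"),
                             lib$library[lib$library$module == "E", ]))
      write_barcode_map(maps$S, file.path(out_dir, "dictionary_S.tsv"))
      write_barcode_map(maps$E, file.path(out_dir, "dictionary_E.tsv"))
      meta$stages$match <- list(S = maps$S$stats, E = maps$E$stats)

      stage <- "count"
      if (count_from_reads) {
        per_sample <- lapply(names(reads$tags), function(smp) {
          count_tags(reads$tags[[smp]], maps$S, maps$E, sample = smp)
        })
        counts <- combine_count_tables(per_sample)
        counts$samples$type <- ifelse(grepl("^DNA", counts$samples$sample),
                                      "DNA", "RNA")
      } else {
        counts <- simulate_counts(lib$library, lib$truth, design)
      }
      if (nrow(counts$counts) == 0L) stop("empty count table")
      meta$stages$count <- list(n_constructs = nrow(counts$counts),
                                n_samples = ncol(counts$counts))

      stage <- "activity"
      filtered <- filter_constructs(counts, config$min_barcodes,
                                    config$min_dna_mean)
      factors <- size_factors(filtered)
      act <- log2_activity(filtered, factors, config$pseudocount)
      tc <- lib$truth$constructs
      neg_ids <- tc$construct_id[!is.na(tc$S_id) & grepl("^NEG", tc$S_id) &
                                   tc$orientation == "single-S"]
      act <- summit_shift(act, neg_ids)
      write_activity_table(act, file.path(out_dir, "activities.tsv"))
      meta$stages$activity <- c(attr(filtered, "filter_tallies"),
                                list(summit_shift = act$shift,
                                     size_factors = as.list(factors)))

      stage <- "call"
      calls <- repression_call(act, neg_ids, alternative = "less",
                               fdr = config$fdr,
                               strata = act$constructs$orientation)
      write.table(calls, file.path(out_dir, "repression_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      meta$stages$call <- list(n_called = sum(calls$called, na.rm = TRUE))

      stage <- "emvar"
      emvars <- NULL
      if (nrow(lib$truth$variants)) {
        v <- lib$truth$variants
        key <- function(ids) match(paste0(ids, ":single-S"),
                                   act$constructs$construct_id)
        ri <- key(v$ref_id); ai <- key(v$alt_id)
        ok <- !is.na(ri) & !is.na(ai)
        if (any(ok)) {
          emvars <- emvar_table(act$rep_activity[ri[ok], , drop = FALSE],
                                act$rep_activity[ai[ok], , drop = FALSE],
                                variant_id = v$variant_id[ok],
                                fdr = config$fdr)
          write.table(emvars, file.path(out_dir, "emvars.tsv"), sep = "\t",
                      quote = FALSE, row.names = FALSE)
          meta$stages$emvar <- list(n_tested = nrow(emvars),
                                    n_emvar = sum(emvars$emvar))
        }
      }

      stage <- "mvalue"
      score_of <- setNames(lib$truth$elements$motif_score,
                           lib$truth$elements$oligo_id)
      cons <- act$constructs
      fits <- list()
      for (e in unique(stats::na.omit(cons$E_id))) {
        ix <- which(cons$orientation == "ES" & !is.na(cons$E_id) &
                      cons$E_id == e & !is.na(cons$S_id) &
                      grepl("^S", cons$S_id))
        if (length(ix) < 10L) next
        ## repression attributable to the S element, against its motif score
        fits[[e]] <- fit_piecewise(score_of[cons$S_id[ix]], -act$activity[ix],
                                   psi0 = config$psi0)
      }
      mv <- if (length(fits) >= 2L) {
        tryCatch(estimate_m_value(fits), error = function(e) NULL)
      }
      if (!is.null(mv)) {
        meta$stages$mvalue <- list(m_value = mv$m_value, sd = mv$sd,
                                   included = mv$included,
                                   excluded = as.list(mv$excluded))
      }

      list(library = lib$library, truth = lib$truth, maps = maps,
           counts = counts, activities = act, calls = calls,
           emvars = emvars, fits = fits, m_value = mv, out_dir = out_dir)
    }, error = function(e) {
      stop(sprintf("pipeline aborted in stage '%s': %s", stage,
                   conditionMessage(e)), call. = FALSE)
    }),
    warning = function(w) invokeRestart("muffleWarning"))
  write_json_sidecar(meta, file.path(out_dir, "run_metadata.json"))
  invisible(result)
}
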