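## Barcode -> oligo dictionary construction from merged association amplicons.
##
## Amplicon layout: UMI + barcode + upstream linker + oligo + downstream
## linker. The linker pairs are the published cloning-vector adapters:
## vector A (S module, 20-nt barcodes) and vector P (E module, 10-nt
## barcodes). Linker location allows substitutions but no indels; once the
## anchors are found the segments are positional.

#' Linker specification for association amplicons
#'
#' @param module `"S"` (vector A adapters, 20-nt barcode) or `"E"` (vector P
#'   adapters, 10-nt barcode); ignored when linkers are given explicitly.
#' @param upstream_linker,downstream_linker 15-nt adapter sequences flanking
#'   the oligo.
#' @param barcode_length 10 or 20.
#' @param umi_length UMI length preceding the barcode.
#' @param max_linker_mismatches substitution budget per linker.
#' @return an object of class `linker_spec`.
#' @export
linker_spec <- function(module = c("S", "E"), upstream_linker = NULL,
                        downstream_linker = NULL, barcode_length = NULL,
                        umi_length = 8L, max_linker_mismatches = 2L) {
  module <- match.arg(module)
  if (is.null(upstream_linker)) {
    if (module == "S") {
      upstream_linker <- "ACTGGCCGCTTGACG"; downstream_linker <- "CACTGCGGCTCCTGC"
      barcode_length <- barcode_length %||% 20L
    } else {
      upstream_linker <- "ACTGGCCTCGCTTGC"; downstream_linker <- "CCCTGGCCGACCTGG"
      barcode_length <- barcode_length %||% 10L
    }
  }
  stopifnot(nzchar(upstream_linker), nzchar(downstream_linker),
            barcode_length %in% c(10L, 20L), umi_length >= 0)
  structure(list(module = module, upstream_linker = upstream_linker,
                 downstream_linker = downstream_linker,
                 barcode_length = as.integer(barcode_length),
                 umi_length = as.integer(umi_length),
                 max_linker_mismatches = as.integer(max_linker_mismatches)),
            class = "linker_spec")
}

#' Parse one association amplicon into UMI, barcode and oligo
#'
#' Locates the best approximate occurrence of each linker (at most
#' `max_linker_mismatches` substitutions, no indels); the barcode is the
#' `barcode_length` bases before the upstream linker, the UMI the
#' `umi_length` bases before the barcode, and the oligo the span between the
#' linkers.
#'
#' @param read nucleotide string.
#' @param spec a [linker_spec()].
#' @return list with `status` (`"ok"` or `"unparseable"`) and, when ok,
#'   `umi`, `barcode`, `oligo_seq`.
#' @export
parse_amplicon <- function(read, spec) {
  fail <- list(status = "unparseable")
  up <- best_hamming_hit(read, spec$upstream_linker, spec$max_linker_mismatches)
  if (is.null(up)) return(fail)
  up_start <- up[["start"]]
  up_end <- up_start + nchar(spec$upstream_linker) - 1L
  tail_part <- substring(read, up_end + 1L)
  dn <- best_hamming_hit(tail_part, spec$downstream_linker,
                         spec$max_linker_mismatches)
  if (is.null(dn)) return(fail)
  dn_start <- up_end + dn[["start"]]
  bc_start <- up_start - spec$barcode_length
  umi_start <- bc_start - spec$umi_length
  if (umi_start < 1L || dn_start <= up_end + 1L) return(fail)
  list(status = "ok",
       umi = substring(read, umi_start, bc_start - 1L),
       barcode = substring(read, bc_start, up_start - 1L),
       oligo_seq = substring(read, up_end + 1L, dn_start - 1L))
}

## vectorized amplicon parsing; returns data.frame(barcode, oligo_seq) plus
## a tally of unparseable reads
parse_amplicons <- function(reads, spec) {
  up_pos <- locate_anchor(reads, spec$upstream_linker, spec$max_linker_mismatches)
  ok <- !is.na(up_pos) & up_pos > spec$barcode_length + spec$umi_length
  up_end <- up_pos + nchar(spec$upstream_linker) - 1L
  tails <- ifelse(ok, substring(reads, up_end + 1L), "")
  dn_pos <- rep(NA_integer_, length(reads))
  dn_pos[ok] <- locate_anchor(tails[ok], spec$downstream_linker,
                              spec$max_linker_mismatches)
  ok <- ok & !is.na(dn_pos) & dn_pos > 1L
  res <- data.frame(
    barcode = substring(reads, up_pos - spec$barcode_length, up_pos - 1L),
    oligo_seq = substring(reads, up_end + 1L, up_end + dn_pos - 1L),
    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  attr(res, "n_unparseable") <- sum(!ok)
  res
}

#' Index an oligo library for approximate matching
#'
#' Builds an exact sequence hash plus a 15-mer seed index (all overlapping
#' reference 15-mers) used to shortlist candidates for Levenshtein scoring.
#'
#' @param library data.frame with `oligo_id` and `sequence`.
#' @param k seed length.
#' @return an object of class `oligo_index`.
#' @export
index_library <- function(library, k = 15L) {
  stopifnot(all(c("oligo_id", "sequence") %in% names(library)))
  exact <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(library))) {
    s <- library$sequence[i]
    exact[[s]] <- c(exact[[s]], library$oligo_id[i])
  }
  seeds <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(library))) {
    s <- library$sequence[i]
    n <- nchar(s) - k + 1L
    if (n < 1L) next
    for (km in unique(substring(s, seq_len(n), seq_len(n) + k - 1L))) {
      seeds[[km]] <- c(seeds[[km]], i)
    }
  }
  structure(list(library = library, exact = exact, seeds = seeds, k = k),
            class = "oligo_index")
}

#' Map an oligo sequence to its reference oligo
#'
#' Exact hash hits return immediately; otherwise candidates sharing at least
#' one non-overlapping query seed are scored by Levenshtein identity
#' (`1 - dist / max(length)`). A unique best candidate at or above
#' `min_identity` maps; ties are ambiguous; nothing at threshold is unmapped.
#'
#' @param oligo_seq query sequence.
#' @param index an [index_library()] object (a plain library data.frame is
#'   indexed on the fly).
#' @param min_identity minimum Levenshtein identity (default 0.95).
#' @return list with `status` (`"mapped"`, `"ambiguous"`, `"unmapped"`),
#'   `oligo_id` and `identity`.
#' @export
map_oligo <- function(oligo_seq, index, min_identity = 0.95) {
  if (!nzchar(oligo_seq)) stop("empty oligo sequence")
  if (!inherits(index, "oligo_index")) index <- index_library(index)
  hit <- index$exact[[oligo_seq]]
  if (!is.null(hit)) {
    if (length(unique(hit)) > 1L) {
      return(list(status = "ambiguous", oligo_id = NA_character_, identity = 1))
    }
    return(list(status = "mapped", oligo_id = hit[1], identity = 1))
  }
  k <- index$k
  n <- nchar(oligo_seq)
  starts <- seq.int(1L, max(1L, n - k + 1L), by = k)  # non-overlapping seeds
  cand <- integer(0)
  for (km in unique(substring(oligo_seq, starts, pmin(starts + k - 1L, n)))) {
    if (nchar(km) == k) cand <- c(cand, index$seeds[[km]])
  }
  cand <- unique(cand)
  if (!length(cand)) return(list(status = "unmapped", oligo_id = NA_character_,
                                 identity = NA_real_))
  refs <- index$library$sequence[cand]
  d <- as.numeric(adist(oligo_seq, refs))
  ident <- 1 - d / pmax(nchar(oligo_seq), nchar(refs))
  best <- max(ident)
  if (best < min_identity) {
    return(list(status = "unmapped", oligo_id = NA_character_, identity = best))
  }
  top <- which(abs(ident - best) < 1e-12)
  if (length(unique(index$library$oligo_id[cand[top]])) > 1L) {
    return(list(status = "ambiguous", oligo_id = NA_character_, identity = best))
  }
  list(status = "mapped", oligo_id = index$library$oligo_id[cand[top[1]]],
       identity = best)
}

#' Build the barcode -> oligo dictionary from association reads
#'
#' Reads are parsed with [parse_amplicon()] and their oligo segments mapped
#' with [map_oligo()]. A barcode is kept only if all of its mapped reads
#' agree on one oligo and its support reaches `min_reads`; barcodes whose
#' reads map to more than one oligo are dropped as ambiguous (strict rule, no
#' majority vote).
#'
#' @param reads character vector of merged association amplicons.
#' @param spec a [linker_spec()].
#' @param library oligo library data.frame (or an [index_library()]).
#' @param min_reads minimum supporting reads per kept barcode.
#' @param min_identity passed to [map_oligo()].
#' @return an object of class `barcode_map`: `entries` (data.frame barcode,
#'   oligo_id, n_reads), `dropped_ambiguous` (character), `module`, and a
#'   `stats` tally list.
#' @export
build_dictionary <- function(reads, spec, library, min_reads = 1L,
                             min_identity = 0.95) {
  parsed <- parse_amplicons(reads, spec)
  if (!nrow(parsed)) stop("no parseable association reads")
  index <- if (inherits(library, "oligo_index")) library else index_library(library)
  ## map each distinct oligo segment once
  useq <- unique(parsed$oligo_seq)
  mapped <- vapply(useq, function(s) {
    m <- map_oligo(s, index, min_identity)
    if (m$status == "mapped") m$oligo_id else NA_character_
  }, character(1))
  parsed$oligo_id <- mapped[parsed$oligo_seq]
  n_unmapped <- sum(is.na(parsed$oligo_id))
  hit <- parsed[!is.na(parsed$oligo_id), , drop = FALSE]
  by_bc <- split(hit$oligo_id, hit$barcode)
  n_oligos <- vapply(by_bc, function(x) length(unique(x)), integer(1))
  support <- lengths(by_bc)
  ambiguous <- names(by_bc)[n_oligos > 1L]
  keep <- n_oligos == 1L & support >= min_reads
  entries <- data.frame(
    barcode = names(by_bc)[keep],
    oligo_id = vapply(by_bc[keep], `[[`, character(1), 1L),
    n_reads = unname(support[keep]),
    stringsAsFactors = FALSE, row.names = NULL)
  entries <- entries[order(entries$barcode), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(
    entries = entries,
    dropped_ambiguous = sort(ambiguous),
    module = spec$module,
    stats = list(n_reads = length(reads),
                 n_unparseable = attr(parsed, "n_unparseable"),
                 n_unmapped = n_unmapped,
                 n_barcodes_kept = nrow(entries),
                 n_barcodes_dropped_ambiguous = length(ambiguous),
                 n_barcodes_below_min_reads = sum(n_oligos == 1L & support < min_reads))),
    class = "barcode_map")
}

#' @export
print.barcode_map <- function(x, ...) {
  cat(sprintf("barcode_map (%s module): %d barcodes kept, %d dropped ambiguous, %d/%d reads unparseable\n",
              x$module, nrow(x$entries), length(x$dropped_ambiguous),
              x$stats$n_unparseable, x$stats$n_reads))
  invisible(x)
}

#' Write a barcode dictionary to TSV (plus dropped barcodes and a JSON summary)
#'
#' @param map a [build_dictionary()] result.
#' @param path output TSV (barcode, oligo_id, n_reads); the dropped-barcode
#'   list goes to `<path>.dropped.tsv` and the run summary to `<path>.json`.
#' @export
write_barcode_map <- function(map, path) {
  write.table(map$entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(barcode = map$dropped_ambiguous),
              paste0(path, ".dropped.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_json_sidecar(c(list(module = map$module), map$stats),
                     paste0(path, ".json"))
  invisible(path)
}
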