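## Tag-read classification and construct-level counting.
##
## Tag reads carry one (single) or two (duo) barcodes downstream of the
## GFP-tail anchor. The single/duo call is positional: fewer than 110 nt of
## payload between the anchor end and the read 3' end means single.

#' Tag-read layout configuration
#'
#' Describes the fixed geometry of tag reads: a GFP-tail anchor, then for duo
#' reads the E barcode (10 nt), a constant inter-barcode spacer, and the S
#' barcode (20 nt); single reads carry one barcode immediately after the
#' anchor. The exact geometry is vector-specific and therefore externalized
#' here.
#'
#' @param anchor GFP-tail anchor sequence.
#' @param e_barcode_length,s_barcode_length barcode lengths (10 / 20 nt).
#' @param duo_spacer_length constant bases between the two barcodes of a duo
#'   read.
#' @param tail_length constant bases after the last barcode.
#' @param anchor_max_mismatches substitution budget when locating the anchor.
#' @param single_duo_boundary payload lengths below this are singles.
#' @export
tag_layout <- function(anchor = "ACGGTCTCAGATGCA",
                       e_barcode_length = 10L, s_barcode_length = 20L,
                       duo_spacer_length = 90L, tail_length = 10L,
                       anchor_max_mismatches = 2L,
                       single_duo_boundary = 110L) {
  structure(list(anchor = anchor,
                 e_barcode_length = as.integer(e_barcode_length),
                 s_barcode_length = as.integer(s_barcode_length),
                 duo_spacer_length = as.integer(duo_spacer_length),
                 tail_length = as.integer(tail_length),
                 anchor_max_mismatches = as.integer(anchor_max_mismatches),
                 single_duo_boundary = as.integer(single_duo_boundary)),
            class = "tag_layout")
}

#' Classify a tag read as single or duo
#'
#' The distance from the end of the GFP-tail anchor to the read 3' end
#' decides: strictly fewer than the boundary (default 110 nt) means single,
#' at or above means duo. Reads without the anchor are unclassifiable.
#'
#' @param read nucleotide string.
#' @param layout a [tag_layout()].
#' @return `"single"`, `"duo"` or `"unclassifiable"`.
#' @export
classify_tag_read <- function(read, layout = tag_layout()) {
  hit <- best_hamming_hit(read, layout$anchor, layout$anchor_max_mismatches)
  if (is.null(hit)) return("unclassifiable")
  anchor_end <- hit[["start"]] + nchar(layout$anchor) - 1L
  dist <- nchar(read) - anchor_end
  if (dist < layout$single_duo_boundary) "single" else "duo"
}

#' Extract barcode tags from a classified read
#'
#' Extraction is at fixed offsets from the anchor. Duo reads yield both
#' barcodes. For single reads the module is not encoded positionally, so both
#' length candidates are returned (`barcode_E`: first 10 nt, `barcode_S`:
#' first 20 nt after the anchor); [count_tags()] resolves the module against
#' the dictionaries.
#'
#' @param read nucleotide string.
#' @param classification `"single"` or `"duo"` (from [classify_tag_read()]).
#' @param layout a [tag_layout()].
#' @return list with `status` and, when ok, `barcode_E` and/or `barcode_S`.
#' @export
extract_tags <- function(read, classification, layout = tag_layout()) {
  hit <- best_hamming_hit(read, layout$anchor, layout$anchor_max_mismatches)
  if (is.null(hit)) return(list(status = "unparseable"))
  a_end <- hit[["start"]] + nchar(layout$anchor) - 1L
  if (classification == "duo") {
    need <- a_end + layout$e_barcode_length + layout$duo_spacer_length +
      layout$s_barcode_length
    if (nchar(read) < need) return(list(status = "unparseable"))
    s_start <- a_end + layout$e_barcode_length + layout$duo_spacer_length + 1L
    list(status = "ok",
         barcode_E = substring(read, a_end + 1L, a_end + layout$e_barcode_length),
         barcode_S = substring(read, s_start,
                               s_start + layout$s_barcode_length - 1L))
  } else {
    if (nchar(read) < a_end + layout$e_barcode_length) {
      return(list(status = "unparseable"))
    }
    out <- list(status = "ok",
                barcode_E = substring(read, a_end + 1L,
                                      a_end + layout$e_barcode_length))
    if (nchar(read) >= a_end + layout$s_barcode_length) {
      out$barcode_S <- substring(read, a_end + 1L,
                                 a_end + layout$s_barcode_length)
    }
    out
  }
}

#' Count classified tag reads into a construct-level table
#'
#' Duo reads are counted only when both barcodes are present in their
#' dictionaries; single reads only when exactly one of the two length
#' candidates matches its dictionary. Every rejection reason is tallied, so
#' that counted reads plus tallies always equal the input reads.
#'
#' @param reads character vector of tag reads.
#' @param map_S,map_E [build_dictionary()] results for the S and E modules.
#' @param sample sample label for the emitted count column.
#' @param orientation construct orientation label for duo rows (`"ES"` or
#'   `"SE"`; a sample-level property of the sequenced library).
#' @param layout a [tag_layout()].
#' @return a [count_table()] with one sample column; rejection tallies in
#'   `attr(, "tallies")`.
#' @export
count_tags <- function(reads, map_S, map_E, sample = "sample1",
                       orientation = "ES", layout = tag_layout()) {
  stopifnot(inherits(map_S, "barcode_map"), inherits(map_E, "barcode_map"))
  if (!nrow(map_S$entries) || !nrow(map_E$entries)) {
    stop("both barcode dictionaries must be non-empty")
  }
  s_of <- setNames(map_S$entries$oligo_id, map_S$entries$barcode)
  e_of <- setNames(map_E$entries$oligo_id, map_E$entries$barcode)

  anchor_pos <- locate_anchor(reads, layout$anchor, layout$anchor_max_mismatches)
  a_end <- anchor_pos + nchar(layout$anchor) - 1L
  dist <- nchar(reads) - a_end
  cls <- ifelse(is.na(anchor_pos), "unclassifiable",
                ifelse(dist < layout$single_duo_boundary, "single", "duo"))

  tallies <- c(unclassifiable = sum(cls == "unclassifiable"),
               truncated = 0L, duo_unknown_S = 0L, duo_unknown_E = 0L,
               duo_unknown_both = 0L, single_unknown = 0L,
               single_ambiguous_module = 0L)
  keys <- character(0); s_ids <- character(0); e_ids <- character(0)
  oris <- character(0); bc_key <- character(0)

  is_duo <- which(cls == "duo")
  if (length(is_duo)) {
    need <- a_end[is_duo] + layout$e_barcode_length +
      layout$duo_spacer_length + layout$s_barcode_length
    short <- nchar(reads[is_duo]) < need
    tallies["truncated"] <- tallies["truncated"] + sum(short)
    ix <- is_duo[!short]
    be <- substring(reads[ix], a_end[ix] + 1L,
                    a_end[ix] + layout$e_barcode_length)
    s_start <- a_end[ix] + layout$e_barcode_length + layout$duo_spacer_length + 1L
    bs <- substring(reads[ix], s_start, s_start + layout$s_barcode_length - 1L)
    kS <- bs %in% names(s_of); kE <- be %in% names(e_of)
    tallies["duo_unknown_S"] <- sum(!kS & kE)
    tallies["duo_unknown_E"] <- sum(kS & !kE)
    tallies["duo_unknown_both"] <- sum(!kS & !kE)
    ok <- kS & kE
    if (any(ok)) {
      sid <- unname(s_of[bs[ok]]); eid <- unname(e_of[be[ok]])
      keys <- c(keys, paste(sid, eid, orientation, sep = ":"))
      s_ids <- c(s_ids, sid); e_ids <- c(e_ids, eid)
      oris <- c(oris, rep(orientation, sum(ok)))
      bc_key <- c(bc_key, paste(bs[ok], be[ok], sep = "|"))
    }
  }

  is_single <- which(cls == "single")
  if (length(is_single)) {
    short <- nchar(reads[is_single]) < a_end[is_single] + layout$e_barcode_length
    tallies["truncated"] <- tallies["truncated"] + sum(short)
    ix <- is_single[!short]
    cand_e <- substring(reads[ix], a_end[ix] + 1L,
                        a_end[ix] + layout$e_barcode_length)
    cand_s <- substring(reads[ix], a_end[ix] + 1L,
                        a_end[ix] + layout$s_barcode_length)
    cand_s[nchar(reads[ix]) < a_end[ix] + layout$s_barcode_length] <- ""
    kE <- cand_e %in% names(e_of)
    kS <- cand_s %in% names(s_of)
    both <- kE & kS
    tallies["single_ambiguous_module"] <- sum(both)
    tallies["single_unknown"] <- sum(!kE & !kS)
    okE <- kE & !both; okS <- kS & !both
    if (any(okE)) {
      eid <- unname(e_of[cand_e[okE]])
      keys <- c(keys, paste0(eid, ":single-E"))
      s_ids <- c(s_ids, rep(NA_character_, sum(okE)))
      e_ids <- c(e_ids, eid)
      oris <- c(oris, rep("single-E", sum(okE)))
      bc_key <- c(bc_key, cand_e[okE])
    }
    if (any(okS)) {
      sid <- unname(s_of[cand_s[okS]])
      keys <- c(keys, paste0(sid, ":single-S"))
      s_ids <- c(s_ids, sid)
      e_ids <- c(e_ids, rep(NA_character_, sum(okS)))
      oris <- c(oris, rep("single-S", sum(okS)))
      bc_key <- c(bc_key, cand_s[okS])
    }
  }

  if (!length(keys)) {
    warning("no tag reads passed the dictionaries; empty count table")
    constructs <- data.frame(construct_id = character(0), S_id = character(0),
                             E_id = character(0), orientation = character(0),
                             n_barcodes = integer(0), stringsAsFactors = FALSE)
    counts <- matrix(integer(0), ncol = 1L, dimnames = list(NULL, sample))
  } else {
    ord <- order(keys)
    keys <- keys[ord]; s_ids <- s_ids[ord]; e_ids <- e_ids[ord]
    oris <- oris[ord]; bc_key <- bc_key[ord]
    firsts <- !duplicated(keys)
    counts <- matrix(as.integer(table(factor(keys, levels = keys[firsts]))),
                     ncol = 1L, dimnames = list(NULL, sample))
    mult <- vapply(split(bc_key, factor(keys, levels = keys[firsts])),
                   function(x) length(unique(x)), integer(1))
    constructs <- data.frame(construct_id = keys[firsts], S_id = s_ids[firsts],
                             E_id = e_ids[firsts], orientation = oris[firsts],
                             n_barcodes = unname(mult), stringsAsFactors = FALSE)
  }
  samp <- data.frame(sample = sample,
                     type = if (grepl("^DNA", sample)) "DNA" else "RNA",
                     replicate = 1L, stringsAsFactors = FALSE)
  ct <- count_table(constructs, counts, samp)
  attr(ct, "tallies") <- as.list(tallies)
  ct
}

#' Combine per-sample count tables on shared construct keys
#'
#' Full outer join on construct identity with zero fill; the per-row barcode
#' multiplicity is the maximum observed across samples.
#'
#' @param tables list of single-sample [count_table()]s.
#' @param sample_info optional data.frame (sample, type, replicate) overriding
#'   the concatenated per-table sample metadata.
#' @return a [count_table()].
#' @export
combine_count_tables <- function(tables, sample_info = NULL) {
  stopifnot(length(tables) >= 1L)
  all_cons <- unique(do.call(rbind, lapply(tables, function(t) t$constructs[
    , c("construct_id", "S_id", "E_id", "orientation")])))
  all_cons <- all_cons[order(all_cons$construct_id), , drop = FALSE]
  rownames(all_cons) <- NULL
  counts <- matrix(0L, nrow(all_cons), sum(vapply(tables, function(t)
    ncol(t$counts), integer(1))))
  mult <- integer(nrow(all_cons))
  col <- 0L
  samples <- list()
  for (t in tables) {
    i <- match(t$constructs$construct_id, all_cons$construct_id)
    for (j in seq_len(ncol(t$counts))) {
      col <- col + 1L
      counts[i, col] <- t$counts[, j]
    }
    mult[i] <- pmax(mult[i], t$constructs$n_barcodes)
    samples[[length(samples) + 1L]] <- t$samples
  }
  samples <- sample_info %||% do.call(rbind, samples)
  colnames(counts) <- samples$sample
  count_table(cbind(all_cons, n_barcodes = mult), counts, samples)
}
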