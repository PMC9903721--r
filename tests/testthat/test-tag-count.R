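test_that("single/duo classification uses the 110-nt payload boundary", {
  layout <- tag_layout()
  mk <- function(payload) paste0(layout$anchor, strrep("A", payload))
  expect_equal(classify_tag_read(mk(109), layout), "single")
  expect_equal(classify_tag_read(mk(110), layout), "duo")
  expect_equal(classify_tag_read(mk(300), layout), "duo")
  expect_equal(classify_tag_read(strrep("G", 150), layout), "unclassifiable")
  # anchor found despite 2 substitutions
  mut <- mk(120)
  substr(mut, 2, 2) <- "T"; substr(mut, 5, 5) <- "T"
  expect_equal(classify_tag_read(mut, layout), "duo")
})

test_that("tag extraction returns fixed-offset barcodes", {
  layout <- tag_layout()
  bcE <- strrep("AC", 5); bcS <- strrep("GT", 10)
  spacer <- mpraduo:::.tag_spacer
  duo <- paste0(layout$anchor, bcE, spacer, bcS, strrep("T", 10))
  got <- extract_tags(duo, "duo", layout)
  expect_equal(got$barcode_E, bcE)
  expect_equal(got$barcode_S, bcS)
  single <- paste0(layout$anchor, bcS, strrep("T", 10))
  gs <- extract_tags(single, "single", layout)
  expect_equal(gs$barcode_S, bcS)
  expect_equal(gs$barcode_E, substr(bcS, 1, 10))  # both candidates offered
  # truncated before the barcode end
  expect_equal(extract_tags(substr(duo, 1, 40), "duo", layout)$status,
               "unparseable")
})

mk_maps <- function() {
  entry <- function(bc, id) data.frame(barcode = bc, oligo_id = id,
                                       n_reads = 5L, stringsAsFactors = FALSE)
  mapS <- structure(list(entries = entry(c(strrep("G", 20), strrep("T", 20)),
                                         c("S1", "S2")),
                         dropped_ambiguous = character(0), module = "S",
                         stats = list()), class = "barcode_map")
  mapE <- structure(list(entries = entry(c(strrep("A", 10), strrep("C", 10)),
                                         c("E1", "E2")),
                         dropped_ambiguous = character(0), module = "E",
                         stats = list()), class = "barcode_map")
  list(S = mapS, E = mapE)
}

test_that("counting requires all barcodes of a read to be known", {
  layout <- tag_layout()
  maps <- mk_maps()
  spacer <- mpraduo:::.tag_spacer
  duo <- function(be, bs) paste0(layout$anchor, be, spacer, bs, strrep("T", 10))
  single <- function(b) paste0(layout$anchor, b, strrep("T", 10))
  reads <- c(rep(duo(strrep("A", 10), strrep("G", 20)), 2),  # S1:E1 x2
             duo(strrep("C", 10), strrep("G", 20)),          # S1:E2
             duo(strrep("A", 10), strrep("AC", 10)),         # unknown S
             duo(strrep("GT", 5), strrep("G", 20)),          # unknown E
             single(strrep("T", 20)),                        # single-S S2
             single(strrep("C", 10)),                        # single-E E2
             single(strrep("TG", 10)),                       # unknown single
             strrep("A", 130))                               # no anchor
  ct <- count_tags(reads, maps$S, maps$E, sample = "RNA_1")
  tal <- attr(ct, "tallies")
  expect_equal(sum(ct$counts) + sum(unlist(tal)), length(reads))
  expect_equal(tal$duo_unknown_S, 1L)
  expect_equal(tal$duo_unknown_E, 1L)
  expect_equal(tal$single_unknown, 1L)
  get <- function(id) unname(ct$counts[ct$constructs$construct_id == id, 1])
  expect_equal(get("S1:E1:ES"), 2L)
  expect_equal(get("S1:E2:ES"), 1L)
  expect_equal(get("S2:single-S"), 1L)
  expect_equal(get("E2:single-E"), 1L)
  # counting is permutation invariant
  ct2 <- count_tags(sample(reads), maps$S, maps$E, sample = "RNA_1")
  expect_identical(ct$constructs, ct2$constructs)
  expect_identical(ct$counts, ct2$counts)
})

test_that("multiplicity counts distinct barcode combinations, not reads", {
  layout <- tag_layout()
  maps <- mk_maps()
  # give S1 a second barcode
  maps$S$entries <- rbind(maps$S$entries,
                          data.frame(barcode = strrep("GA", 10), oligo_id = "S1",
                                     n_reads = 3L))
  spacer <- mpraduo:::.tag_spacer
  duo <- function(be, bs) paste0(layout$anchor, be, spacer, bs, strrep("T", 10))
  reads <- c(duo(strrep("A", 10), strrep("G", 20)),
             duo(strrep("A", 10), strrep("G", 20)),
             duo(strrep("A", 10), strrep("GA", 10)))
  ct <- count_tags(reads, maps$S, maps$E)
  expect_equal(unname(ct$counts[1, 1]), 3L)
  expect_equal(ct$constructs$n_barcodes, 2L)
})

test_that("error-free simulated tag reads reproduce the truth counts exactly", {
  d <- small_design(seed = 121)
  lib <- make_library(d)
  samples <- c("DNA_1", "RNA_2")
  reads <- simulate_reads(lib$library, lib$truth, error_rate = 0, seed = 121,
                          samples = samples)
  maps <- lapply(c(S = "S", E = "E"), function(mod)
    build_dictionary(reads$association[[mod]],
                     linker_spec(mod, umi_length = d$umi_length),
                     lib$library[lib$library$module == mod, ]))
  for (smp in samples) {
    ct <- count_tags(reads$tags[[smp]], maps$S, maps$E, sample = smp)
    truth <- reads$tag_truth[reads$tag_truth$sample == smp &
                              reads$tag_truth$count > 0, ]
    m <- match(truth$construct_id, ct$constructs$construct_id)
    expect_false(anyNA(m))
    expect_equal(ct$counts[m, 1], truth$count)
    expect_equal(ct$constructs$n_barcodes[m], truth$n_barcodes)
    expect_equal(nrow(ct$constructs), nrow(truth))
    # conservation: every read is counted or tallied
    expect_equal(sum(ct$counts) + sum(unlist(attr(ct, "tallies"))),
                 length(reads$tags[[smp]]))
  }
})

test_that("count tables combine across samples with zero fill", {
  cons <- function(ids) data.frame(
    construct_id = ids, S_id = ids, E_id = NA_character_,
    orientation = "single-S", n_barcodes = rep(3L, length(ids)),
    stringsAsFactors = FALSE)
  t1 <- count_table(cons(c("a", "b")), matrix(c(5L, 2L), ncol = 1,
                                              dimnames = list(NULL, "DNA_1")),
                    data.frame(sample = "DNA_1", type = "DNA", replicate = 1))
  t2 <- count_table(cons(c("b", "c")), matrix(c(7L, 1L), ncol = 1,
                                              dimnames = list(NULL, "RNA_1")),
                    data.frame(sample = "RNA_1", type = "RNA", replicate = 1))
  comb <- combine_count_tables(list(t1, t2))
  expect_equal(comb$constructs$construct_id, c("a", "b", "c"))
  expect_equal(comb$counts[, "DNA_1"], c(5L, 2L, 0L))
  expect_equal(comb$counts[, "RNA_1"], c(0L, 7L, 1L))
})
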