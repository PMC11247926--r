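test_that("candidate enumeration honours spacing and composition filters", {
  seq50 <- random_dna(50000, seed = 301)
  # no composition filters, non-overlapping: one candidate per 30 nt
  cand <- extract_candidate_targets(seq50, k = 30, min_gap = 30,
                                    gc_range = NULL, max_homopolymer = NULL)
  expect_equal(nrow(cand), 1666L)  # floor(50000 / 30)
  expect_true(all(diff(cand$offset) >= 30))
  expect_true(all(nchar(cand$sequence) == 30))
  expect_true(all(grepl("^[ACGT]+$", cand$sequence)))

  expect_warning(short <- extract_candidate_targets(random_dna(29, seed = 1)),
                 "shorter than")
  expect_equal(nrow(short), 0L)

  allA <- strrep("A", 500)
  expect_equal(nrow(extract_candidate_targets(allA, max_homopolymer = 10,
                                              gc_range = NULL)), 0L)

  # windows containing non-ACGT letters are skipped
  seqN <- paste0(random_dna(40, seed = 5), "N", random_dna(40, seed = 6))
  candN <- extract_candidate_targets(seqN, gc_range = NULL,
                                     max_homopolymer = NULL)
  expect_false(any(grepl("N", candN$sequence)))
})

test_that("repeat filter agrees with brute-force genome scanning", {
  set.seed(302)
  # toy genome: 12 kb unique + a 1 kb block duplicated 5x
  unique_part <- random_dna(12000)
  block <- random_dna(1000)
  genome <- paste0(substr(unique_part, 1, 6000), block,
                   substr(unique_part, 6001, 12000),
                   strrep(block, 4))
  idx <- build_kmer_index(genome, sub_k = 17)
  cand <- extract_candidate_targets(substr(genome, 1, 8000),
                                    gc_range = NULL, max_homopolymer = NULL)
  kept <- filter_repetitive(cand, idx, max_hits = 1)
  # oracle: per candidate, worst sub-17-mer occurrence count by direct scan
  worst <- vapply(cand$sequence, function(s) {
    max(oracle_subkmer_hits(s, genome, 17))
  }, 0L, USE.NAMES = FALSE)
  expect_setequal(kept$offset, cand$offset[worst <= 1])
  # candidates overlapping the duplicated block (6000..6999) by at least one
  # full sub-k-mer are gone; shorter overlaps carry no repeated 17-mer
  overlap <- pmin(cand$offset + 30, 7000) - pmax(cand$offset, 6000)
  expect_false(any(kept$offset %in% cand$offset[overlap >= 17]))
  # recorded worst-hit counts match the oracle on the retained set
  expect_equal(kept$max_subkmer_hits, worst[worst <= 1])

  # unique genome: everything retained
  g2 <- random_dna(5000, seed = 303)
  idx2 <- build_kmer_index(g2, sub_k = 17)
  cand2 <- extract_candidate_targets(g2, gc_range = NULL,
                                     max_homopolymer = NULL)
  expect_equal(nrow(filter_repetitive(cand2, idx2)), nrow(cand2))

  # a mutated candidate absent from the genome: retained with 0 hits
  mut <- cand2[1, ]
  mut$sequence <- paste0(strrep("ACGT", 7), "AC")
  mutated <- filter_repetitive(mut, idx2)
  if (nrow(mutated) == 1L) expect_equal(mutated$max_subkmer_hits, 0L)

  expect_error(filter_repetitive(cand2, structure(list(counts = integer(0),
                                                       sub_k = 17),
                                                  class = "kmer_index")),
               "empty")
})

test_that("even-spacing selection is deterministic and size-correct", {
  seq50 <- random_dna(50000, seed = 304)
  cand <- extract_candidate_targets(seq50, gc_range = NULL,
                                    max_homopolymer = NULL)
  sel <- select_probes(cand, 500)
  expect_equal(nrow(sel), 500L)
  expect_identical(sel, select_probes(cand, 500))  # byte-identical rerun
  # even spacing beats a worst-case contiguous choice by construction
  expect_gt(min(diff(sel$offset)), 0)

  expect_warning(few <- select_probes(cand[1:100, ], 500), "only 100")
  expect_equal(nrow(few), 100L)
})

test_that("template oligos obey the 130-nt six-part grammar", {
  pool <- generate_readout_pool(5, seed = 305)
  target <- data.frame(segment_index = 3L, offset = 120L,
                       sequence = random_dna(30, seed = 306))
  oligo <- assemble_template_oligo(target, pool[1], pool[2],
                                   pool[c(3, 4, 5)])
  expect_equal(nchar(oligo$full_sequence), 130L)
  expect_equal(vapply(oligo$parts, nchar, 0L, USE.NAMES = FALSE),
               c(20L, 20L, 30L, 20L, 20L, 20L))
  # grammar round-trip: slicing the full sequence recovers the parts
  parsed <- parse_template_oligo(oligo$full_sequence)
  expect_identical(parsed, oligo$parts)
  # reverse-primer site is the reverse complement of the reverse primer
  expect_equal(oligo$parts$rev_primer_site,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(pool[2]))))
  expect_error(assemble_template_oligo(target, "ACGT", pool[2], pool[3:5]),
               "fwd_primer")
  bad_target <- target; bad_target$sequence <- "ACGT"
  expect_error(assemble_template_oligo(bad_target, pool[1], pool[2], pool[3:5]),
               "target")
})

test_that("adapter oligos bridge template readout sites to common readouts", {
  pool <- generate_readout_pool(4, seed = 307)
  ad <- design_adapter_oligo(pool[1], pool[2], segment_index = 7L)
  expect_equal(nchar(ad$full_sequence), 60L)
  # two identical readout-binding replicates
  expect_equal(substr(ad$full_sequence, 21, 40), substr(ad$full_sequence, 41, 60))
  # primary half reverse-complements the template's readout site
  expect_equal(ad$primary_binding,
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(pool[1]))))
  expect_error(design_adapter_oligo("ACGT", pool[2]), "20 nt")
})

test_that("full panel probe design emits consistent oligo sets", {
  panel <- toy_panel(n_segments = 3, segment_length = 3000)
  genome <- random_dna(3 * 3000, seed = 308)
  design <- design_panel_probes(panel, genome, n_per_segment = 20,
                                seed = 309)
  expect_equal(sort(unique(design$templates$segment_index)), 0:2)
  expect_true(all(nchar(design$templates$full_sequence) == 130L))
  expect_true(all(vapply(design$adapters, function(a) {
    nchar(a$full_sequence) == 60L
  }, TRUE)))
  # all oligos of a segment share the same three readout sites
  for (si in 0:2) {
    seqs <- design$templates$full_sequence[design$templates$segment_index == si]
    sites <- unique(vapply(seqs, function(s) {
      p <- parse_template_oligo(s)
      paste(p$readout_site_1, p$readout_site_2, p$readout_site_3)
    }, "", USE.NAMES = FALSE))
    expect_length(sites, 1L)
  }
  # segments sharing a round but not a channel use distinct readout handles
  expect_equal(anyDuplicated(unlist(design$readouts)), 0L)
  # FASTA export round-trips
  fa <- tempfile(fileext = ".fasta")
  write_oligos_fasta(design$templates, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(back), nrow(design$templates))
  expect_equal(as.character(back[[1]]), design$templates$full_sequence[1])
})

test_that("readout pool sequences are mutually dissimilar", {
  pool <- generate_readout_pool(10, seed = 310, min_hamming = 8)
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in 1:9) for (j in (i + 1):10) {
    expect_gte(hamming(pool[i], pool[j]), 8)
  }
  # identical seed reproduces the pool exactly
  expect_identical(pool, generate_readout_pool(10, seed = 310, min_hamming = 8))
})
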