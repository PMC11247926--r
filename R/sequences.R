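#' Seeded random DNA sequence
#'
#' @param n Length in nt.
#' @param seed Optional integer seed (set before drawing when supplied).
#' @param gc Target GC content of the generating distribution.
#' @return A single character string over A/C/G/T.
#' @export
random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

gc_fraction <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  sum(chars %in% c("G", "C")) / length(chars)
}

max_homopolymer_run <- function(seq) {
  r <- rle(strsplit(toupper(seq), "")[[1]])
  max(r$lengths)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# All length-k windows of a sequence as a character vector (upper case).
kmer_windows <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

#' Enumerate 30-nt candidate targeting sequences within a segment
#'
#' Scans the segment's plus-strand sequence left to right, emitting
#' non-overlapping (or `min_gap`-separated) k-nt windows that pass simple
#' composition filters. Windows containing non-ACGT characters are skipped.
#' A probe built on a plus-strand target hybridizes the minus strand.
#'
#' @param segment_sequence Character string, the segment's genomic sequence.
#' @param k Target length in nt (default 30).
#' @param min_gap Minimum offset difference between successive candidates
#'   (default `k`, i.e. non-overlapping).
#' @param gc_range Length-2 numeric, inclusive GC-fraction bounds; `NULL`
#'   disables the filter.
#' @param max_homopolymer Longest tolerated single-base run; `NULL` disables.
#' @param segment_index Segment ordinal recorded on each candidate.
#'
#' @return A data frame with columns `segment_index`, `offset` (0-based bp
#'   within the segment), `sequence`, `strand`, `gc_fraction`,
#'   `max_subkmer_hits` (NA until [filter_repetitive()] runs).
#' @examples
#' extract_candidate_targets(random_dna(200, seed = 1), k = 30)
#' @export
extract_candidate_targets <- function(segment_sequence, k = 30, min_gap = k,
                                      gc_range = c(0.30, 0.70),
                                      max_homopolymer = 6,
                                      segment_index = 0L) {
  stopifnot(is.character(segment_sequence), length(segment_sequence) == 1L)
  seq <- toupper(segment_sequence)
  n <- nchar(seq)
  empty <- data.frame(segment_index = integer(0), offset = integer(0),
                      sequence = character(0), strand = character(0),
                      gc_fraction = numeric(0), max_subkmer_hits = numeric(0))
  if (n < k) {
    warning(sprintf("sequence (%d nt) shorter than target length (%d nt)", n, k))
    return(empty)
  }
  chars <- strsplit(seq, "")[[1]]
  ok_base <- chars %in% c("A", "C", "G", "T")
  is_gc <- chars %in% c("G", "C")
  # run-length of identical bases ending at each position, for the
  # homopolymer filter without per-window rle() calls
  run <- integer(n)
  run[1] <- 1L
  for (i in seq_len(n - 1L) + 1L) {
    run[i] <- if (chars[i] == chars[i - 1L]) run[i - 1L] + 1L else 1L
  }
  starts <- integer(0)
  offsets <- integer(0)
  pos <- 1L
  while (pos + k - 1L <= n) {
    win <- pos:(pos + k - 1L)
    if (!all(ok_base[win])) { pos <- pos + 1L; next }
    if (!is.null(max_homopolymer) && max(run[win]) > max_homopolymer) {
      pos <- pos + 1L; next
    }
    if (!is.null(gc_range)) {
      gcf <- sum(is_gc[win]) / k
      if (gcf < gc_range[1] || gcf > gc_range[2]) { pos <- pos + 1L; next }
    }
    starts <- c(starts, pos)
    offsets <- c(offsets, pos - 1L)
    pos <- pos + max(as.integer(min_gap), 1L)
  }
  if (length(starts) == 0L) return(empty)
  seqs <- substring(seq, starts, starts + k - 1L)
  data.frame(
    segment_index = as.integer(segment_index),
    offset = offsets,
    sequence = seqs,
    strand = "+",
    gc_fraction = vapply(starts, function(s) sum(is_gc[s:(s + k - 1L)]) / k, 0),
    max_subkmer_hits = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Build a genome-wide sub-k-mer occurrence index
#'
#' Counts every length-`sub_k` word across all records of a genome (both
#' strands). Used to screen candidate targeting sequences against repeats:
#' a genuinely unique target contributes each of its sub-k-mers exactly once.
#'
#' @param genome Named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param sub_k Word size (default 17).
#' @return An object of class `kmer_index` (a named integer count table).
#' @export
build_kmer_index <- function(genome, sub_k = 17) {
  seqs <- load_genome(genome)
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) {
    stop("empty genome: cannot build k-mer index")
  }
  words <- unlist(lapply(unname(seqs), function(s) {
    c(kmer_windows(s, sub_k), kmer_windows(revcomp(s), sub_k))
  }), use.names = FALSE)
  words <- words[!grepl("[^ACGT]", words)]
  counts <- table(words)
  structure(list(sub_k = sub_k,
                 counts = setNames(as.integer(counts), names(counts))),
            class = "kmer_index")
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    return(setNames(as.character(genome), names(genome)))
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    return(setNames(as.character(ss), sub("\\s.*$", "", names(ss))))
  }
  if (is.character(genome)) return(toupper(genome))
  stop("'genome' must be sequences, a DNAStringSet, or a FASTA path")
}

kmer_count <- function(index, words) {
  hits <- index$counts[words]
  hits[is.na(hits)] <- 0L
  as.integer(hits)
}

#' Remove candidates hitting repetitive genome sequence
#'
#' A candidate is retained iff every length-`sub_k` window of it occurs at
#' most `max_hits` times genome-wide (both strands counted). This is the
#' package's deterministic stand-in for alignment-based repeat screening.
#' The worst (maximum) sub-k-mer hit count is recorded per candidate.
#'
#' @param candidates Data frame from [extract_candidate_targets()].
#' @param genome_kmer_index A `kmer_index` from [build_kmer_index()].
#' @param max_hits Maximum tolerated genome-wide occurrences (default 1,
#'   i.e. the target's own unique site only).
#' @return The retained candidates with `max_subkmer_hits` filled in.
#' @export
filter_repetitive <- function(candidates, genome_kmer_index, max_hits = 1) {
  stopifnot(inherits(genome_kmer_index, "kmer_index"))
  if (length(genome_kmer_index$counts) == 0L) stop("empty k-mer index")
  if (nrow(candidates) == 0L) return(candidates)
  sub_k <- genome_kmer_index$sub_k
  worst <- vapply(candidates$sequence, function(s) {
    max(kmer_count(genome_kmer_index, kmer_windows(s, sub_k)))
  }, 0L, USE.NAMES = FALSE)
  candidates$max_subkmer_hits <- worst
  candidates[worst <= max_hits, , drop = FALSE]
}

#' Select probes with even spacing across a segment
#'
#' Deterministically picks `n_per_segment` candidates spread as evenly as
#' possible over the candidate offsets: ideal anchor positions are laid out
#' uniformly over the offset range and each anchor takes the nearest
#' still-unused candidate (leftmost wins on ties). If fewer candidates than
#' requested exist, all are selected with a warning.
#'
#' @param candidates Data frame of candidates for one segment.
#' @param n_per_segment Number of probes to design per segment (default 500).
#' @return The selected candidates, ordered by offset.
#' @export
select_probes <- function(candidates, n_per_segment = 500) {
  if (nrow(candidates) == 0L) return(candidates)
  if (length(unique(candidates$segment_index)) > 1L) {
    stop("candidates must belong to a single segment")
  }
  candidates <- candidates[order(candidates$offset), , drop = FALSE]
  m <- nrow(candidates)
  if (m <= n_per_segment) {
    if (m < n_per_segment) {
      warning(sprintf("only %d candidates available for %d requested probes",
                      m, n_per_segment))
    }
    return(candidates)
  }
  # anchors uniform over the offset range; nearest-unused-candidate greedy,
  # leftmost candidate wins ties -> fully deterministic
  anchors <- seq(min(candidates$offset), max(candidates$offset),
                 length.out = n_per_segment)
  taken <- logical(m)
  pick <- integer(n_per_segment)
  for (a in seq_len(n_per_segment)) {
    d <- abs(candidates$offset - anchors[a])
    d[taken] <- Inf
    j <- which.min(d)  # which.min returns the first (leftmost) minimum
    pick[a] <- j
    taken[j] <- TRUE
  }
  candidates[sort(pick), , drop = FALSE]
}

#' Generate a pool of mutually dissimilar 20-nt handle sequences
#'
#' Primer and readout handles are drawn from a seeded random pool with
#' pairwise Hamming distance at least `min_hamming` and no sequence equal to
#' the reverse complement of another (or of itself), limiting cross-talk.
#'
#' @param n Number of sequences.
#' @param len Sequence length in nt (default 20).
#' @param seed Integer seed.
#' @param min_hamming Minimum pairwise Hamming distance (default 8).
#' @param max_tries Attempts before giving up.
#' @return Character vector of length `n`, named `RO000`, `RO001`, ...
#' @export
generate_readout_pool <- function(n, len = 20, seed = 1, min_hamming = 8,
                                  max_tries = 10000L) {
  set.seed(seed)
  pool <- character(0)
  pool_rc <- character(0)
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  tries <- 0L
  while (length(pool) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    rc <- revcomp(cand)
    if (cand == rc) next
    ok <- all(vapply(c(pool, pool_rc), function(p) {
      hamming(cand, p) >= min_hamming
    }, TRUE)) && !(rc %in% pool)
    if (ok) {
      pool <- c(pool, cand)
      pool_rc <- c(pool_rc, rc)
    }
  }
  if (length(pool) < n) stop("could not generate a dissimilar handle pool")
  setNames(pool, sprintf("RO%03d", seq_len(n) - 1L))
}

#' Assemble a 130-nt template oligo
#'
#' Concatenates, 5' to 3': a 20-nt forward priming sequence, a 20-nt readout
#' (secondary probe) binding site, the 30-nt genome targeting sequence, two
#' further 20-nt readout binding sites, and a 20-nt reverse priming site
#' (stored as the reverse complement of the reverse primer, so that PCR with
#' the stated primer pair amplifies the oligo).
#'
#' @param target One-row candidate data frame (or list) with `sequence` and
#'   `segment_index`.
#' @param fwd_primer 20-nt forward primer sequence.
#' @param rev_primer 20-nt reverse primer sequence.
#' @param readout_sites Character vector of three 20-nt readout binding
#'   sites shared by all oligos of the segment.
#' @return An object of class `template_oligo` with `parts` (named list) and
#'   `full_sequence` (130 nt).
#' @export
assemble_template_oligo <- function(target, fwd_primer, rev_primer,
                                    readout_sites) {
  check_len <- function(x, len, what) {
    if (!is.character(x) || length(x) != 1L || nchar(x) != len) {
      stop(sprintf("'%s' must be a single %d-nt sequence", what, len))
    }
    unname(toupper(x))
  }
  fwd <- check_len(fwd_primer, 20L, "fwd_primer")
  rev <- check_len(rev_primer, 20L, "rev_primer")
  if (length(readout_sites) != 3L) {
    stop("'readout_sites' must contain exactly three sequences")
  }
  ro <- vapply(seq_len(3L), function(i) {
    check_len(readout_sites[[i]], 20L, sprintf("readout_sites[%d]", i))
  }, "")
  tgt <- check_len(as.character(target$sequence), 30L, "target")
  parts <- list(fwd_primer = fwd, readout_site_1 = ro[1], target = tgt,
                readout_site_2 = ro[2], readout_site_3 = ro[3],
                rev_primer_site = revcomp(rev))
  structure(
    list(segment_index = as.integer(target$segment_index),
         offset = as.integer(target$offset %||% NA_integer_),
         parts = parts,
         full_sequence = paste(unlist(parts), collapse = "")),
    class = "template_oligo"
  )
}

#' Parse a 130-nt template oligo back into its six parts
#'
#' Applies the fixed (20, 20, 30, 20, 20, 20) grammar; the concatenation of
#' the returned parts always reproduces the input.
#'
#' @param full_sequence 130-nt sequence.
#' @return Named list of the six parts.
#' @export
parse_template_oligo <- function(full_sequence) {
  if (nchar(full_sequence) != 130L) {
    stop("template oligo must be exactly 130 nt, got ", nchar(full_sequence))
  }
  cuts <- cumsum(c(0L, 20L, 20L, 30L, 20L, 20L, 20L))
  parts <- substring(full_sequence, cuts[-7] + 1L, cuts[-1])
  setNames(as.list(parts),
           c("fwd_primer", "readout_site_1", "target", "readout_site_2",
             "readout_site_3", "rev_primer_site"))
}

#' Design the 60-nt adapter oligo for a segment
#'
#' The adapter bridges a segment's primary probes to the round's dye-labeled
#' common readout oligo: one 20-nt primary-binding half (reverse complement
#' of the segment's designated readout site on the template oligos) followed
#' by two identical copies of the 20-nt common readout binding sequence.
#'
#' @param segment_readout_site The 20-nt readout site carried by the
#'   segment's template oligos (as it appears on the template).
#' @param readout_binding The 20-nt common readout oligo binding sequence.
#' @param segment_index Segment ordinal.
#' @return An object of class `adapter_oligo` with a 60-nt `full_sequence`.
#' @export
design_adapter_oligo <- function(segment_readout_site, readout_binding,
                                 segment_index = 0L) {
  if (nchar(segment_readout_site) != 20L) {
    stop("'segment_readout_site' must be 20 nt")
  }
  if (nchar(readout_binding) != 20L) stop("'readout_binding' must be 20 nt")
  primary <- revcomp(toupper(segment_readout_site))
  rb <- toupper(readout_binding)
  structure(
    list(segment_index = as.integer(segment_index),
         primary_binding = primary, readout_binding = rb,
         full_sequence = paste0(primary, rb, rb)),
    class = "adapter_oligo"
  )
}

#' Design the full probe panel for a genome
#'
#' Runs the per-segment design chain — candidate enumeration, repeat
#' filtering, even-spacing selection, template and adapter assembly — for
#' every segment of the panel, drawing primer and readout handles from a
#' seeded dissimilar pool.
#'
#' @param panel A `segment_panel` with codebook set.
#' @param genome Genome sequences (see [build_kmer_index()]); segment
#'   sequences are sliced from the record matching the panel's chromosome.
#' @param n_per_segment Template oligos per segment (default 500).
#' @param sub_k,max_hits Repeat-filter parameters (see [filter_repetitive()]).
#' @param gc_range,max_homopolymer Composition filters
#'   (see [extract_candidate_targets()]).
#' @param seed Seed for the handle pool.
#' @return A list with `templates` (data frame of all emitted template
#'   oligos), `adapters` (one per segment), `readouts` (per-segment readout
#'   binding handles), `primers`, and `candidates_per_segment` counts.
#' @export
design_panel_probes <- function(panel, genome, n_per_segment = 500,
                                sub_k = 17, max_hits = 1,
                                gc_range = c(0.30, 0.70), max_homopolymer = 6,
                                seed = 1) {
  stopifnot(inherits(panel, "segment_panel"))
  if (is.na(panel$n_channels)) stop("panel codebook is unset")
  seqs <- load_genome(genome)
  chrom <- panel$region$chrom
  if (!chrom %in% names(seqs)) {
    if (length(seqs) == 1L) names(seqs) <- chrom else
      stop("genome has no record named ", chrom)
  }
  chromseq <- seqs[[chrom]]
  index <- build_kmer_index(seqs, sub_k = sub_k)
  nseg <- n_loci(panel)
  # handles: 2 primers + 3 readout sites/segment + 1 common readout binding
  # per segment; one readout site per segment is the adapter's anchor
  pool <- generate_readout_pool(2L + nseg * 2L, seed = seed)
  fwd <- pool[[1]]; rev <- pool[[2]]
  site_handles <- pool[2L + seq_len(nseg)]
  readout_handles <- pool[2L + nseg + seq_len(nseg)]

  templates <- vector("list", nseg)
  adapters <- vector("list", nseg)
  n_candidates <- integer(nseg)
  for (i in seq_len(nseg)) {
    seg <- panel$segments[i, ]
    rel_start <- seg$start - panel$region$start
    segseq <- substr(chromseq, rel_start + 1L, rel_start + panel$segment_length)
    cand <- extract_candidate_targets(segseq, segment_index = seg$index,
                                      gc_range = gc_range,
                                      max_homopolymer = max_homopolymer)
    cand <- filter_repetitive(cand, index, max_hits = max_hits)
    n_candidates[i] <- nrow(cand)
    sel <- select_probes(cand, n_per_segment)
    site <- site_handles[[i]]
    sites3 <- c(site, site, site)  # all three readout sites route to one adapter
    oligos <- lapply(seq_len(nrow(sel)), function(j) {
      assemble_template_oligo(sel[j, ], fwd, rev, sites3)
    })
    templates[[i]] <- data.frame(
      segment_index = seg$index,
      offset = sel$offset,
      round = seg$hyb_round,
      channel = seg$channel,
      full_sequence = vapply(oligos, `[[`, "", "full_sequence"),
      stringsAsFactors = FALSE
    )
    adapters[[i]] <- design_adapter_oligo(site, readout_handles[[i]],
                                          segment_index = seg$index)
  }
  list(
    templates = do.call(rbind, templates),
    adapters = adapters,
    readouts = readout_handles,
    primers = c(fwd = fwd, rev = rev),
    candidates_per_segment = n_candidates
  )
}

#' Write template or adapter oligos as FASTA
#'
#' Headers carry `segIdx|offset|round|channel` so downstream bookkeeping
#' survives a round trip through plain FASTA.
#'
#' @param oligos The `templates` data frame from [design_panel_probes()], or
#'   a list of `adapter_oligo` objects.
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
write_oligos_fasta <- function(oligos, path) {
  if (is.data.frame(oligos)) {
    names_ <- sprintf("seg%d|%d|%d|%s", oligos$segment_index, oligos$offset,
                      oligos$round, oligos$channel)
    seqs <- Biostrings::DNAStringSet(oligos$full_sequence)
  } else {
    names_ <- vapply(oligos, function(a) sprintf("adapter|seg%d", a$segment_index), "")
    seqs <- Biostrings::DNAStringSet(vapply(oligos, `[[`, "", "full_sequence"))
  }
  names(seqs) <- names_
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
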