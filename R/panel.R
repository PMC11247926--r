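#' Genomic interval (0-based, half-open)
#'
#' Lightweight interval container used to define the traced region. The
#' package follows the BED convention everywhere: `start` is 0-based and
#' inclusive, `end` is exclusive, so the interval length is `end - start`.
#'
#' @param chrom Chromosome name, e.g. `"chr15"`.
#' @param start 0-based inclusive start (bp), non-negative.
#' @param end Exclusive end (bp), strictly greater than `start`.
#' @param assembly Assembly label, e.g. `"hg38"`.
#'
#' @return An object of class `genomic_interval`.
#' @examples
#' genomic_interval("chr15", 23500000, 25600000)
#' @export
genomic_interval <- function(chrom, start, end, assembly = "hg38") {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  assert_scalar_number(start, "start", min = 0)
  assert_scalar_number(end, "end")
  if (end <= start) stop("'end' must be strictly greater than 'start'")
  structure(
    list(chrom = chrom, start = as.numeric(start), end = as.numeric(end),
         assembly = assembly),
    class = "genomic_interval"
  )
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%s-%s (%s, %s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              x$assembly, format(x$end - x$start, big.mark = ",")))
  invisible(x)
}

interval_length <- function(x) x$end - x$start

#' Default traced region of the 15q11.2-q13 imprinting domain
#'
#' The canonical target used throughout examples: a 2.1-Mb region on chr15
#' starting at 23,500,000 (hg38) that tiles into exactly 42 segments of 50 kb.
#'
#' @return A [genomic_interval()].
#' @export
default_tracing_region <- function() {
  genomic_interval("chr15", 23500000, 25600000, assembly = "hg38")
}

#' Partition a region into consecutive fixed-length segments
#'
#' Tiles the region from its start into consecutive, non-overlapping segments
#' of exactly `segment_length` bp. A trailing remainder shorter than one
#' segment is dropped and reported via a message and the `remainder_bp`
#' field of the returned panel.
#'
#' @param region A [genomic_interval()].
#' @param segment_length Segment size in bp (default 50 kb).
#'
#' @return A `segment_panel` object whose `segments` data frame has one row
#'   per tile with 0-based half-open coordinates. Hybridization rounds and
#'   channels are unset until [build_codebook()] is called.
#' @examples
#' panel <- partition_region(default_tracing_region(), 50000)
#' nrow(panel$segments)  # 42
#' @export
partition_region <- function(region, segment_length = 50000) {
  stopifnot(inherits(region, "genomic_interval"))
  assert_scalar_number(segment_length, "segment_length", min = 1)
  span <- interval_length(region)
  if (span < segment_length) {
    stop(sprintf("region (%d bp) is shorter than one segment (%d bp)",
                 span, segment_length))
  }
  n <- floor(span / segment_length)
  remainder <- span - n * segment_length
  if (remainder > 0) {
    message(sprintf("dropping %d bp trailing remainder (< one %d bp segment)",
                    remainder, segment_length))
  }
  starts <- region$start + (seq_len(n) - 1L) * segment_length
  segments <- data.frame(
    index = seq_len(n) - 1L,
    chrom = region$chrom,
    start = starts,
    end = starts + segment_length,
    hyb_round = NA_integer_,
    channel = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(
    list(region = region, segment_length = segment_length,
         segments = segments, remainder_bp = remainder,
         n_channels = NA_integer_, channel_names = NULL),
    class = "segment_panel"
  )
}

#' @export
print.segment_panel <- function(x, ...) {
  cat(sprintf("<segment_panel> %d segments of %s bp on %s\n",
              nrow(x$segments), format(x$segment_length, big.mark = ","),
              x$region$chrom))
  if (!is.na(x$n_channels)) {
    cat(sprintf("  codebook: %d rounds x %d channels (%s)\n",
                n_rounds(x), x$n_channels,
                paste(x$channel_names, collapse = ", ")))
  } else {
    cat("  codebook: unset (call build_codebook())\n")
  }
  invisible(x)
}

n_loci <- function(panel) nrow(panel$segments)

n_rounds <- function(panel) {
  if (is.na(panel$n_channels)) return(NA_integer_)
  as.integer(ceiling(nrow(panel$segments) / panel$n_channels))
}

#' Assign sequential-hybridization rounds and readout channels
#'
#' Builds the sequential readout codebook: segment `i` (0-based, genomic
#' order) is imaged in round `floor(i / n_channels)` on channel
#' `i %% n_channels`, so a 42-segment panel read on two dye channels needs
#' 21 rounds. Each segment occupies exactly one (round, channel) slot.
#'
#' @param panel A `segment_panel` from [partition_region()].
#' @param n_channels Number of readout channels per round (default 2,
#'   matching Cy5/Cy3 readout on the 647- and 560-nm lines).
#' @param channel_names Labels for the channels; defaults to
#'   `c("647", "560")` truncated/extended to `n_channels`.
#'
#' @return The panel with `hyb_round` and `channel` filled in.
#' @examples
#' panel <- build_codebook(partition_region(default_tracing_region()))
#' max(panel$segments$hyb_round) + 1  # 21 rounds
#' @export
build_codebook <- function(panel, n_channels = 2,
                           channel_names = NULL) {
  stopifnot(inherits(panel, "segment_panel"))
  if (!is_count(n_channels) || n_channels < 1) {
    stop("'n_channels' must be a positive integer")
  }
  n_channels <- as.integer(n_channels)
  if (is.null(channel_names)) {
    channel_names <- c("647", "560", paste0("ch", seq_len(max(0, n_channels - 2L)) + 2L))
  }
  channel_names <- channel_names[seq_len(n_channels)]
  i <- panel$segments$index
  panel$segments$hyb_round <- as.integer(i %/% n_channels)
  panel$segments$channel <- channel_names[(i %% n_channels) + 1L]
  panel$n_channels <- n_channels
  panel$channel_names <- channel_names
  panel
}

#' Export panel segments as BED6
#'
#' Writes one BED line per segment, named `Hyb_<round>_<channel>_seg<index>`
#' (rounds reported 1-based for readability, coordinates kept 0-based
#' half-open as BED requires).
#'
#' @param panel A `segment_panel` with codebook set.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "segment_panel"))
  s <- panel$segments
  name <- ifelse(is.na(s$hyb_round), paste0("seg", s$index),
                 sprintf("Hyb_%d_%s_seg%d", s$hyb_round + 1L, s$channel, s$index))
  bed <- data.frame(s$chrom, s$start, s$end, name, 0L, "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export the codebook as TSV
#'
#' @param panel A `segment_panel` with codebook set.
#' @param path Output file path.
#' @param readout_ids Optional character vector of per-segment readout
#'   identifiers (recycled from readout pool names when available).
#' @return Invisibly, the path.
#' @export
write_codebook <- function(panel, path, readout_ids = NULL) {
  stopifnot(inherits(panel, "segment_panel"))
  s <- panel$segments
  out <- data.frame(
    segment_index = s$index, chrom = s$chrom, start = s$start, end = s$end,
    round = s$hyb_round, channel = s$channel,
    readout_id = readout_ids %||% sprintf("RO%03d", s$index),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a codebook TSV back into a segment panel
#'
#' @param path Path written by [write_codebook()].
#' @param assembly Assembly label for the reconstructed region.
#' @return A `segment_panel`.
#' @export
read_codebook <- function(path, assembly = "hg38") {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  needed <- c("segment_index", "chrom", "start", "end", "round", "channel")
  if (!all(needed %in% names(tab))) {
    stop("codebook is missing columns: ",
         paste(setdiff(needed, names(tab)), collapse = ", "))
  }
  tab <- tab[order(tab$segment_index), , drop = FALSE]
  seg_len <- unique(tab$end - tab$start)
  if (length(seg_len) != 1L) stop("codebook segments are not equal width")
  region <- genomic_interval(tab$chrom[1], min(tab$start), max(tab$end),
                             assembly = assembly)
  panel <- partition_region(region, seg_len)
  panel$segments$hyb_round <- as.integer(tab$round)
  panel$segments$channel <- as.character(tab$channel)
  panel$channel_names <- unique(panel$segments$channel[order(panel$segments$index)])
  panel$n_channels <- length(panel$channel_names)
  panel
}
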