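new_contact_matrix <- function(m, bins, normalization = "none") {
  structure(list(matrix = m, bins = bins, normalization = normalization),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins of %d bp (%s normalization)\n",
              nrow(x$bins), x$bins$end[1] - x$bins$start[1], x$normalization))
  invisible(x)
}

check_contact_matrix <- function(m, bins, tol = 1e-6) {
  if (any(m < 0, na.rm = TRUE)) stop("contact matrix has negative entries")
  rel <- abs(m - t(m)) / pmax(abs(m) + abs(t(m)), .Machine$double.eps)
  if (any(rel > tol, na.rm = TRUE)) {
    stop("contact matrix is asymmetric beyond tolerance")
  }
  if (is.unsorted(bins$start)) stop("contact matrix bins are not sorted")
  if (length(unique(bins$end - bins$start)) != 1L) {
    stop("contact matrix bins are not equal width")
  }
  invisible(TRUE)
}

#' Read a binned contact matrix from TSV
#'
#' Two text dialects are supported. `dense_tsv`: a square matrix with
#' `chrom:start-end` labels as the header row and first column. `coo_tsv`:
#' a sparse upper-triangle table with columns `chrom`, `start1`, `start2`,
#' `value` plus a `bin_width`; the matrix is symmetrized from the listed
#' triangle. Asymmetric (beyond 1e-6 relative), negative, ragged or
#' unsorted input is rejected with a named error.
#'
#' @param path Input file.
#' @param format `"dense_tsv"` or `"coo_tsv"`.
#' @param bin_width Bin width for `coo_tsv` (inferred from dense labels).
#' @param normalization Label recorded on the result (e.g. `"SCALE"`).
#' @return A `contact_matrix` object.
#' @export
read_contact_matrix <- function(path, format = c("dense_tsv", "coo_tsv"),
                                bin_width = NULL, normalization = "none") {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE)
    m <- as.matrix(tab)
    if (nrow(m) != ncol(m)) stop("dense contact matrix is not square (ragged rows?)")
    lab <- rownames(m)
    parts <- regmatches(lab, regexec("^(.+):([0-9]+)-([0-9]+)$", lab))
    if (any(vapply(parts, length, 0L) != 4L)) {
      stop("bin labels must be chrom:start-end")
    }
    bins <- data.frame(
      chrom = vapply(parts, `[[`, "", 2L),
      start = as.numeric(vapply(parts, `[[`, "", 3L)),
      end = as.numeric(vapply(parts, `[[`, "", 4L))
    )
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    needed <- c("chrom", "start1", "start2", "value")
    if (!all(needed %in% names(tab))) {
      stop("coo contact file is missing columns: ",
           paste(setdiff(needed, names(tab)), collapse = ", "))
    }
    if (is.null(bin_width)) stop("'bin_width' is required for coo_tsv input")
    starts <- sort(unique(c(tab$start1, tab$start2)))
    starts <- seq(min(starts), max(starts), by = bin_width)
    bins <- data.frame(chrom = tab$chrom[1], start = starts,
                       end = starts + bin_width)
    n <- nrow(bins)
    m <- matrix(0, n, n)
    i <- match(tab$start1, starts); j <- match(tab$start2, starts)
    if (anyNA(i) || anyNA(j)) stop("coo starts are not multiples of bin_width")
    m[cbind(i, j)] <- tab$value
    m[cbind(j, i)] <- tab$value
  }
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  check_contact_matrix(m, bins)
  new_contact_matrix(m, bins, normalization)
}

#' Write a contact matrix as dense TSV
#' @param contact A `contact_matrix`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_contact_matrix <- function(contact, path) {
  m <- contact$matrix
  lab <- sprintf("%s:%d-%d", contact$bins$chrom, contact$bins$start,
                 contact$bins$end)
  dimnames(m) <- list(lab, lab)
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' Pair distance-matrix and contact-matrix entries on matched bins
#'
#' Bins are matched by (chrom, start) between the tracing panel and the
#' contact matrix (which must share the bin width); for every matched pair
#' of distinct bins (i < j), the (median distance, contact frequency) pair
#' is emitted where both are defined. Unmatched bins and incomplete entries
#' are dropped and counted.
#'
#' @param distance A `distance_matrix`.
#' @param contact A `contact_matrix`.
#' @param panel The `segment_panel` the distance matrix lives on.
#' @param min_separation Exclude pairs with `|i - j|` at or below this
#'   genomic-bin separation (default 0: only the diagonal is excluded).
#' @return A list: `pairs` data frame (`i`, `j`, `distance_nm`,
#'   `contact`), `n_excluded` (incomplete entries), `n_unmatched_bins`.
#' @export
align_bins <- function(distance, contact, panel, min_separation = 0) {
  stopifnot(inherits(distance, "distance_matrix"),
            inherits(contact, "contact_matrix"))
  seg <- panel$segments
  seg_width <- unique(seg$end - seg$start)
  bin_width <- unique(contact$bins$end - contact$bins$start)
  if (seg_width != bin_width) {
    stop(sprintf("bin widths differ: panel %d vs contact %d", seg_width,
                 bin_width))
  }
  key_panel <- paste(seg$chrom, seg$start)
  key_contact <- paste(contact$bins$chrom, contact$bins$start)
  map <- match(key_panel, key_contact)
  matched <- which(!is.na(map))
  if (length(matched) == 0L) stop("no overlapping bins between matrices")
  n_unmatched <- sum(is.na(map)) + sum(!(key_contact %in% key_panel))
  pairs <- list(); n_excluded <- 0L
  for (a in seq_along(matched)) {
    for (b in seq_along(matched)) {
      if (b <= a) next
      i <- matched[a]; j <- matched[b]
      if (abs(i - j) <= min_separation) next
      d <- distance$median_nm[i, j]
      c_ <- contact$matrix[map[i], map[j]]
      if (is.na(d) || is.na(c_)) { n_excluded <- n_excluded + 1L; next }
      pairs[[length(pairs) + 1L]] <- c(i, j, d, c_)
    }
  }
  pairs <- if (length(pairs)) {
    as.data.frame(do.call(rbind, pairs)) |>
      stats::setNames(c("i", "j", "distance_nm", "contact"))
  } else {
    data.frame(i = integer(0), j = integer(0), distance_nm = numeric(0),
               contact = numeric(0))
  }
  list(pairs = pairs, n_excluded = n_excluded,
       n_unmatched_bins = n_unmatched)
}

#' Correlate spatial distance with contact frequency
#'
#' Computes the concordance between imaged median distances and contact
#' frequencies over aligned locus pairs. Genuine chromatin structure gives
#' a strongly negative coefficient (close pairs touch often). With a log
#' transform, zero contacts (and non-positive distances under `log_both`)
#' are excluded and counted, never pseudocounted silently. A constant
#' vector makes the correlation undefined; the result is then flagged.
#'
#' @param pairs The `pairs` data frame from [align_bins()] (or any data
#'   frame with `distance_nm` and `contact`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform `"identity"` (default), `"log_contact"` (log10 contact
#'   vs raw distance) or `"log_both"`.
#' @return An object of class `concordance_result` with `r`, `method`,
#'   `transform`, `n_pairs`, `n_excluded`, `defined`.
#' @export
distance_contact_correlation <- function(pairs,
                                         method = c("pearson", "spearman"),
                                         transform = c("identity",
                                                       "log_contact",
                                                       "log_both")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  d <- pairs$distance_nm
  c_ <- pairs$contact
  n_excluded <- 0L
  if (transform %in% c("log_contact", "log_both")) {
    ok <- c_ > 0
    if (transform == "log_both") ok <- ok & d > 0
    n_excluded <- sum(!ok)
    d <- d[ok]; c_ <- c_[ok]
    c_ <- log10(c_)
    if (transform == "log_both") d <- log10(d)
  }
  if (length(d) < 3L) stop("need at least 3 pairs to correlate")
  defined <- stats::sd(d) > 0 && stats::sd(c_) > 0
  r <- if (defined) cor(d, c_, method = method) else NA_real_
  structure(
    list(r = r, method = method, transform = transform,
         n_pairs = length(d), n_excluded = n_excluded, defined = defined),
    class = "concordance_result"
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %s r = %s (%s, n = %d, %d excluded)%s\n",
              x$method, if (x$defined) sprintf("%.4f", x$r) else "undefined",
              x$transform, x$n_pairs, x$n_excluded,
              if (!x$defined) " [zero variance]" else ""))
  invisible(x)
}

#' Sign statistics of a fold-change map inside vs outside a locus block
#'
#' Quantifies a direction-reversed sub-region: the fraction of negative
#' (and positive) fold-change entries among pairs with both loci inside
#' the annotated block, versus pairs with both loci outside, with a seeded
#' percentile bootstrap CI on each fraction. Missing entries are excluded.
#'
#' @param fc A `fold_change_matrix`.
#' @param block Length-2 integer vector, 0-based inclusive locus range of
#'   the annotated sub-region.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @return A data frame with one row per region (`inside`, `outside`):
#'   entry counts, negative/positive fractions, and CI bounds on the
#'   negative fraction.
#' @export
fold_change_region_summary <- function(fc, block, n_boot = 1000, seed = 1) {
  stopifnot(inherits(fc, "fold_change_matrix"), length(block) == 2L)
  L <- nrow(fc$log2fc)
  lo <- block[1] + 1L; hi <- block[2] + 1L
  if (lo > hi || lo < 1L || hi > L) stop("empty or out-of-range block")
  idx <- seq_len(L)
  inside <- idx >= lo & idx <= hi
  if (!any(inside)) stop("empty block")
  ut <- upper.tri(fc$log2fc)
  sel_in <- outer(inside, inside, "&") & ut
  sel_out <- outer(!inside, !inside, "&") & ut
  set.seed(seed)
  one <- function(region, sel) {
    v <- fc$log2fc[sel]
    v <- v[!is.na(v)]
    if (length(v) == 0L) {
      return(data.frame(region = region, n = 0L, frac_negative = NA_real_,
                        frac_positive = NA_real_, neg_ci_lo = NA_real_,
                        neg_ci_hi = NA_real_))
    }
    boot <- replicate(n_boot, mean(sample(v, replace = TRUE) < 0))
    data.frame(region = region, n = length(v),
               frac_negative = mean(v < 0), frac_positive = mean(v > 0),
               neg_ci_lo = as.numeric(quantile(boot, 0.025)),
               neg_ci_hi = as.numeric(quantile(boot, 0.975)))
  }
  rbind(one("inside", sel_in), one("outside", sel_out))
}
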