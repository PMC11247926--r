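#' Median spatial-distance matrix of a set of traces
#'
#' Entry (i, j) is the median over traces — pairwise-complete, i.e. over
#' traces in which both loci were localized — of the 3D Euclidean distance
#' between loci i and j. Entries supported by fewer than `min_pairs`
#' observations are reported missing (NA) rather than noisy. The median of
#' an even number of observations is the midpoint of the two central
#' values. The diagonal is 0 and the matrix symmetric by construction.
#'
#' @param traces A `chromatin_traces` object (reconstructed or
#'   ground-truth via [ensemble_as_traces()]).
#' @param min_pairs Minimum observations per entry (default 10).
#' @return An object of class `distance_matrix`: `median_nm` and `n_obs`
#'   matrices plus the condition label.
#' @export
median_distance_matrix <- function(traces, min_pairs = 10) {
  if (inherits(traces, "conformation_ensemble")) {
    traces <- ensemble_as_traces(traces)
  }
  stopifnot(inherits(traces, "chromatin_traces"))
  n <- nrow(traces$present)
  if (n == 0L) stop("no traces supplied")
  L <- ncol(traces$present)
  med <- matrix(NA_real_, L, L)
  nobs <- matrix(0L, L, L)
  diag(med) <- 0
  diag(nobs) <- n
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      ok <- traces$present[, i] & traces$present[, j]
      nobs[i, j] <- nobs[j, i] <- sum(ok)
      if (sum(ok) >= max(min_pairs, 1L)) {
        d <- trace_pair_distances(traces$coords[ok, , , drop = FALSE], i, j)
        med[i, j] <- med[j, i] <- median(d)
      }
    }
  }
  structure(
    list(median_nm = med, n_obs = nobs, condition = traces$condition,
         n_traces = n, min_pairs = min_pairs),
    class = "distance_matrix"
  )
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %s: %d loci, %d traces, %d missing entries\n",
              x$condition %||% "?", nrow(x$median_nm), x$n_traces,
              sum(is.na(x$median_nm))))
  invisible(x)
}

#' Entrywise log2 fold change of two median-distance matrices
#'
#' Computes `log2(D_num / D_den)` where both entries are present and
#' positive; zero denominators are reported missing with a warning. The
#' result negates exactly under swapping the conditions. Negative entries
#' mean the numerator condition is more compact (smaller distances) at that
#' locus pair.
#'
#' @param d_num,d_den `distance_matrix` objects on the same panel.
#' @return An object of class `fold_change_matrix` with `log2fc`,
#'   `numerator` and `denominator` labels.
#' @export
log2_fold_change <- function(d_num, d_den) {
  stopifnot(inherits(d_num, "distance_matrix"),
            inherits(d_den, "distance_matrix"))
  if (!all(dim(d_num$median_nm) == dim(d_den$median_nm))) {
    stop("distance matrices are on different panels")
  }
  num <- d_num$median_nm; den <- d_den$median_nm
  bad_zero <- !is.na(den) & den == 0 & row(den) != col(den)
  if (any(bad_zero)) {
    warning(sum(bad_zero), " entries with zero denominator median set missing")
    den[bad_zero] <- NA_real_
  }
  fc <- log2(num / den)
  diag(fc) <- NA_real_
  structure(
    list(log2fc = fc, numerator = d_num$condition,
         denominator = d_den$condition),
    class = "fold_change_matrix"
  )
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  off <- x$log2fc[row(x$log2fc) != col(x$log2fc)]
  cat(sprintf("<fold_change_matrix> log2(%s / %s): median off-diagonal %.3f\n",
              x$numerator, x$denominator, median(off, na.rm = TRUE)))
  invisible(x)
}

#' Per-locus detection efficiency and completeness histogram
#'
#' @param traces A `chromatin_traces` object.
#' @return A list: `per_locus_efficiency` (fraction of traces in which each
#'   locus is present), `completeness` (per-trace fractions), and
#'   `completeness_hist` (counts over ten equal bins).
#' @export
detection_stats <- function(traces) {
  stopifnot(inherits(traces, "chromatin_traces"))
  eff <- colMeans(traces$present)
  comp <- rowMeans(traces$present)
  hist_counts <- table(cut(comp, breaks = seq(0, 1, 0.1),
                           include.lowest = TRUE))
  list(per_locus_efficiency = eff, completeness = comp,
       completeness_hist = hist_counts)
}

#' Compaction summaries: radius of gyration and median all-pairs distance
#'
#' The radius of gyration is the root-mean-square distance of a trace's
#' present loci from their centroid; traces with fewer than two present
#' loci are reported missing. Condition-level summaries come with seeded
#' percentile bootstrap confidence intervals over traces.
#'
#' @param traces A `chromatin_traces` object.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Bootstrap seed.
#' @return A list: `rg` (per trace, nm), `median_pairwise` (per trace, nm),
#'   and `summary` with medians and bootstrap CIs.
#' @export
compaction_score <- function(traces, n_boot = 1000, conf = 0.95, seed = 1) {
  stopifnot(inherits(traces, "chromatin_traces"))
  n <- nrow(traces$present)
  rg <- rep(NA_real_, n)
  mpd <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    pres <- traces$present[t, ]
    if (sum(pres) < 2L) next
    xyz <- traces$coords[t, pres, , drop = TRUE]
    ctr <- colMeans(xyz)
    rg[t] <- sqrt(mean(rowSums(sweep(xyz, 2L, ctr)^2)))
    mpd[t] <- median(stats::dist(xyz))
  }
  boot_ci <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(c(NA_real_, NA_real_))
    stat <- replicate(n_boot, median(sample(v, replace = TRUE)))
    as.numeric(quantile(stat, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  set.seed(seed)
  ci_rg <- boot_ci(rg)
  ci_mpd <- boot_ci(mpd)
  list(
    rg = rg, median_pairwise = mpd,
    summary = data.frame(
      condition = traces$condition %||% NA_character_,
      median_rg = median(rg, na.rm = TRUE),
      rg_ci_lo = ci_rg[1], rg_ci_hi = ci_rg[2],
      median_pairwise = median(mpd, na.rm = TRUE),
      mpd_ci_lo = ci_mpd[1], mpd_ci_hi = ci_mpd[2]
    )
  )
}

#' Write a distance (or fold-change) matrix as TSV with bin labels
#'
#' @param mat A `distance_matrix` or `fold_change_matrix`.
#' @param path Output path (`n_obs` written alongside as `<path>.nobs.tsv`
#'   for distance matrices).
#' @param panel Optional `segment_panel` providing `chr:start-end` labels.
#' @return Invisibly, the path.
#' @export
write_matrix_tsv <- function(mat, path, panel = NULL) {
  m <- if (inherits(mat, "distance_matrix")) mat$median_nm else mat$log2fc
  labels <- if (!is.null(panel)) {
    sprintf("%s:%d-%d", panel$segments$chrom, panel$segments$start,
            panel$segments$end)
  } else {
    sprintf("bin%02d", seq_len(nrow(m)) - 1L)
  }
  dimnames(m) <- list(labels, labels)
  write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  if (inherits(mat, "distance_matrix")) {
    n <- mat$n_obs
    dimnames(n) <- dimnames(m)
    write.table(n, paste0(path, ".nobs.tsv"), sep = "\t", quote = FALSE,
                col.names = NA)
  }
  invisible(path)
}

#' Heatmap of a distance or fold-change matrix
#'
#' Mirrors the usual orientation of imaging-based distance maps: loci in
#' genomic order on both axes. Requires ggplot2.
#'
#' @param mat A `distance_matrix` or `fold_change_matrix`.
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_matrix_heatmap <- function(mat, title = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  m <- if (inherits(mat, "distance_matrix")) mat$median_nm else mat$log2fc
  df <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- as.numeric(m)
  fill_lab <- if (inherits(mat, "distance_matrix")) "median d (nm)" else "log2 FC"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = if (fill_lab == "log2 FC") "magma" else "viridis",
                                  na.value = "grey85") +
    ggplot2::labs(x = "locus", y = "locus", fill = fill_lab, title = title) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
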