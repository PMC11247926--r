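#' Trace-linking configuration
#'
#' @param r_max Maximum focus-to-trace-center distance for a focus to
#'   compete for a locus, nm.
#' @param expected_traces_per_nucleus Traces to seed per nucleus (default 1,
#'   the hemizygous-deletion regime: one traceable allele).
#' @param intensity_weight Weight of `-log(intensity)` in the assignment
#'   cost (nm per log-intensity unit; 0 = purely spatial).
#' @param refit_radius Search radius around the interpolated expected
#'   position when refitting missing loci, nm.
#' @param refit_threshold_factor Intensity threshold multiplier for the
#'   relaxed refit candidate pool.
#' @param exhaustive_limit Maximum number of candidate combinations for
#'   which the exact (enumerative) assignment is used; larger instances
#'   fall back to iterative centroid refinement.
#' @return An object of class `linking_config`.
#' @export
linking_config <- function(r_max = 1500, expected_traces_per_nucleus = 1,
                           intensity_weight = 0, refit_radius = 500,
                           refit_threshold_factor = 0.5,
                           exhaustive_limit = 4096) {
  assert_scalar_number(r_max, "r_max", min = 1e-9)
  assert_scalar_number(refit_radius, "refit_radius", min = 1e-9)
  assert_scalar_number(refit_threshold_factor, "refit_threshold_factor",
                       min = 0)
  structure(
    list(r_max = r_max,
         expected_traces_per_nucleus = as.integer(expected_traces_per_nucleus),
         intensity_weight = intensity_weight, refit_radius = refit_radius,
         refit_threshold_factor = refit_threshold_factor,
         exhaustive_limit = exhaustive_limit),
    class = "linking_config"
  )
}

new_chromatin_traces <- function(coords, source, trace_id, nucleus_id,
                                 condition, assigned_focus = NULL) {
  present <- source != "missing"
  structure(
    list(coords = coords, present = present, source = source,
         trace_id = trace_id, nucleus_id = nucleus_id, condition = condition,
         assigned_focus = assigned_focus),
    class = "chromatin_traces"
  )
}

#' @export
print.chromatin_traces <- function(x, ...) {
  comp <- rowMeans(x$present)
  cat(sprintf("<chromatin_traces> %s: %d traces x %d loci, mean completeness %.2f\n",
              x$condition %||% "?", nrow(x$present), ncol(x$present),
              mean(comp)))
  invisible(x)
}

#' Per-trace completeness
#' @param traces A `chromatin_traces` object.
#' @return Numeric vector, fraction of loci present per trace.
#' @export
trace_completeness <- function(traces) rowMeans(traces$present)

# Assignment objective: sum over assigned loci of the distance to the
# centroid of the assigned foci, minus intensity_weight * log(intensity).
assignment_cost <- function(xyz, intensity, w) {
  ctr <- colMeans(xyz)
  sum(sqrt(rowSums(sweep(xyz, 2L, ctr)^2))) - w * sum(log(intensity))
}

# Exact assignment by enumeration of all candidate combinations.
# cand: list per locus of data frames (possibly 0-row). Returns integer
# vector of chosen row index per locus (NA = no candidate).
assign_exhaustive <- function(cand, w) {
  counts <- vapply(cand, nrow, 0L)
  active <- which(counts > 0L)
  if (length(active) == 0L) return(rep(NA_integer_, length(cand)))
  grid <- do.call(expand.grid, lapply(counts[active], seq_len))
  best <- NULL; best_cost <- Inf; best_int <- -Inf; best_round <- Inf
  for (g in seq_len(nrow(grid))) {
    pick <- as.integer(grid[g, ])
    xyz <- do.call(rbind, lapply(seq_along(active), function(a) {
      as.numeric(cand[[active[a]]][pick[a], c("x", "y", "z")])
    }))
    intensity <- vapply(seq_along(active), function(a) {
      cand[[active[a]]]$intensity[pick[a]]
    }, 0)
    cost <- assignment_cost(xyz, intensity, w)
    tot_int <- sum(intensity)
    tot_round <- sum(vapply(seq_along(active), function(a) {
      as.numeric(cand[[active[a]]]$round[pick[a]])
    }, 0))
    better <- cost < best_cost - 1e-9 ||
      (abs(cost - best_cost) <= 1e-9 &&
         (tot_int > best_int + 1e-9 ||
            (abs(tot_int - best_int) <= 1e-9 && tot_round < best_round)))
    if (better) {
      best <- pick; best_cost <- cost; best_int <- tot_int
      best_round <- tot_round
    }
  }
  out <- rep(NA_integer_, length(cand))
  out[active] <- best
  out
}

# Iterative assignment: per-locus greedy against an evolving centroid.
assign_iterative <- function(cand, w, center, max_iter = 10L) {
  counts <- vapply(cand, nrow, 0L)
  active <- which(counts > 0L)
  pick <- rep(NA_integer_, length(cand))
  for (it in seq_len(max_iter)) {
    new_pick <- pick
    for (a in active) {
      cc <- cand[[a]]
      cost <- sqrt((cc$x - center[1])^2 + (cc$y - center[2])^2 +
                     (cc$z - center[3])^2) - w * log(cc$intensity)
      # ties: higher intensity, then lower round
      ord <- order(cost, -cc$intensity, cc$round)
      new_pick[a] <- ord[1]
    }
    xyz <- do.call(rbind, lapply(active, function(a) {
      as.numeric(cand[[a]][new_pick[a], c("x", "y", "z")])
    }))
    center <- colMeans(xyz)
    if (identical(new_pick, pick)) break
    pick <- new_pick
  }
  pick
}

# Robust cluster center: coordinate-wise median, refined by trimming to an
# r_max ball twice.
robust_center <- function(xyz, r_max) {
  ctr <- apply(xyz, 2L, median)
  for (k in 1:2) {
    d <- sqrt(rowSums(sweep(xyz, 2L, ctr)^2))
    keep <- d <= r_max
    if (sum(keep) >= 3L) ctr <- apply(xyz[keep, , drop = FALSE], 2L, median)
  }
  ctr
}

#' Link registered foci into chromatin traces
#'
#' Per nucleus: foci are clustered around a robust trace center (when more
#' than one trace per nucleus is expected, average-linkage clustering splits
#' the foci first); for each panel locus, the foci of the locus's
#' (round, channel) within `r_max` of the center compete, and the
#' assignment minimizing total cost — summed distance to the centroid of
#' the assigned foci minus `intensity_weight * log(intensity)` — is chosen,
#' exactly (enumeration) when the instance is small and by iterative
#' centroid refinement otherwise. Loci with no admissible focus are marked
#' missing. Foci are never shared across traces, and foci from different
#' nuclei are never joined.
#'
#' @param registered_foci Registered foci table (from
#'   [apply_corrections()]); must carry `nucleus_id`, `round`, `channel`,
#'   `x`, `y`, `z`, `intensity`.
#' @param panel A `segment_panel` with codebook set.
#' @param config A [linking_config()].
#' @param condition Condition label stored on the result.
#' @return A `chromatin_traces` object. `assigned_focus` records, per trace
#'   and locus, the row index of the adopted focus in `registered_foci`.
#' @export
link_traces <- function(registered_foci, panel, config = linking_config(),
                        condition = "sim") {
  stopifnot(inherits(panel, "segment_panel"))
  if (is.na(panel$n_channels)) stop("panel codebook is unset")
  L <- n_loci(panel)
  seg <- panel$segments
  foci <- registered_foci
  foci$.row <- foci$focus_id %||% seq_len(nrow(foci))
  nuclei <- sort(unique(foci$nucleus_id))

  coords_list <- list(); source_list <- list(); focus_list <- list()
  nucleus_ids <- integer(0)
  for (nid in nuclei) {
    fn <- foci[foci$nucleus_id == nid, , drop = FALSE]
    if (nrow(fn) == 0L) next
    k <- config$expected_traces_per_nucleus
    if (k > 1L && nrow(fn) > k) {
      hc <- stats::hclust(stats::dist(coords_of(fn)), method = "average")
      cl <- stats::cutree(hc, k = k)
    } else {
      cl <- rep(1L, nrow(fn))
    }
    for (g in sort(unique(cl))) {
      fg <- fn[cl == g, , drop = FALSE]
      ctr <- robust_center(coords_of(fg), config$r_max)
      d <- sqrt((fg$x - ctr[1])^2 + (fg$y - ctr[2])^2 + (fg$z - ctr[3])^2)
      cand <- lapply(seq_len(L), function(i) {
        sel <- fg$round == seg$hyb_round[i] & fg$channel == seg$channel[i] &
          d <= config$r_max
        fg[sel, , drop = FALSE]
      })
      counts <- vapply(cand, nrow, 0L)
      combos <- prod(pmax(counts, 1))
      pick <- if (combos <= config$exhaustive_limit) {
        assign_exhaustive(cand, config$intensity_weight)
      } else {
        assign_iterative(cand, config$intensity_weight, ctr)
      }
      xyz <- matrix(NA_real_, L, 3)
      src <- rep("missing", L)
      frow <- rep(NA_integer_, L)
      for (i in seq_len(L)) {
        if (!is.na(pick[i])) {
          row <- cand[[i]][pick[i], ]
          xyz[i, ] <- as.numeric(row[c("x", "y", "z")])
          src[i] <- "assigned"
          frow[i] <- row$.row
        }
      }
      coords_list[[length(coords_list) + 1L]] <- xyz
      source_list[[length(source_list) + 1L]] <- src
      focus_list[[length(focus_list) + 1L]] <- frow
      nucleus_ids <- c(nucleus_ids, nid)
    }
  }
  nt <- length(coords_list)
  coords <- array(NA_real_, dim = c(nt, L, 3))
  source <- matrix("missing", nt, L)
  assigned <- matrix(NA_integer_, nt, L)
  for (t in seq_len(nt)) {
    coords[t, , ] <- coords_list[[t]]
    source[t, ] <- source_list[[t]]
    assigned[t, ] <- focus_list[[t]]
  }
  new_chromatin_traces(coords, source, seq_len(nt), nucleus_ids, condition,
                       assigned)
}

# Expected position of a missing locus by linear interpolation between the
# nearest present loci (linear extrapolation at the ends).
interpolate_missing <- function(xyz, present) {
  L <- nrow(xyz)
  out <- xyz
  idx <- which(present)
  if (length(idx) < 2L) return(out)
  for (i in which(!present)) {
    lo <- idx[idx < i]; hi <- idx[idx > i]
    if (length(lo) && length(hi)) {
      a <- max(lo); b <- min(hi)
      f <- (i - a) / (b - a)
      out[i, ] <- (1 - f) * xyz[a, ] + f * xyz[b, ]
    } else if (length(hi) >= 2L) {
      b1 <- hi[1]; b2 <- hi[2]
      out[i, ] <- xyz[b1, ] + (i - b1) / (b2 - b1) * (xyz[b2, ] - xyz[b1, ])
    } else if (length(lo) >= 2L) {
      a1 <- lo[length(lo) - 1L]; a2 <- lo[length(lo)]
      out[i, ] <- xyz[a2, ] + (i - a2) / (a2 - a1) * (xyz[a2, ] - xyz[a1, ])
    } else if (length(hi)) {
      out[i, ] <- xyz[hi[1], ]
    } else {
      out[i, ] <- xyz[max(lo), ]
    }
  }
  out
}

#' Refit missing loci from a relaxed candidate pool
#'
#' For every missing locus of every trace with at least two assigned loci,
#' the expected position is interpolated linearly between the nearest
#' present loci (extrapolated at the ends); the nearest candidate of the
#' correct (round, channel) in the trace's nucleus, with intensity at or
#' above `threshold * refit_threshold_factor` and within `refit_radius` of
#' the expected position, is adopted and flagged `refit`. Assigned loci are
#' never overwritten, foci already used by the trace's nucleus are not
#' reused, and a locus with no admissible candidate stays missing.
#'
#' @param traces A `chromatin_traces` object from [link_traces()].
#' @param candidate_pool Registered foci table including sub-threshold
#'   detections (i.e. unfiltered by the main intensity threshold).
#' @param panel The `segment_panel`.
#' @param config A [linking_config()].
#' @param intensity_threshold The main detection threshold whose relaxed
#'   multiple gates the refit pool.
#' @return The traces with recovered loci flagged `"refit"`.
#' @export
refit_missing <- function(traces, candidate_pool, panel,
                          config = linking_config(),
                          intensity_threshold = 300) {
  stopifnot(inherits(traces, "chromatin_traces"))
  L <- ncol(traces$present)
  seg <- panel$segments
  thr <- intensity_threshold * config$refit_threshold_factor
  ids <- candidate_pool$focus_id %||% seq_len(nrow(candidate_pool))
  keep_pool <- candidate_pool$intensity >= thr
  pool <- candidate_pool[keep_pool, , drop = FALSE]
  pool$.row <- ids[keep_pool]
  for (t in seq_len(nrow(traces$present))) {
    pres <- traces$present[t, ]
    if (sum(pres) < 2L || all(pres)) next
    expected <- interpolate_missing(traces$coords[t, , ], pres)
    used <- stats::na.omit(traces$assigned_focus[t, ])
    nid <- traces$nucleus_id[t]
    for (i in which(!pres)) {
      sel <- pool$nucleus_id == nid & pool$round == seg$hyb_round[i] &
        pool$channel == seg$channel[i] & !(pool$.row %in% used)
      if (!any(sel)) next
      cc <- pool[sel, , drop = FALSE]
      d <- sqrt((cc$x - expected[i, 1])^2 + (cc$y - expected[i, 2])^2 +
                  (cc$z - expected[i, 3])^2)
      ord <- order(d, -cc$intensity, cc$round)
      if (d[ord[1]] <= config$refit_radius) {
        j <- ord[1]
        traces$coords[t, i, ] <- as.numeric(cc[j, c("x", "y", "z")])
        traces$source[t, i] <- "refit"
        traces$present[t, i] <- TRUE
        traces$assigned_focus[t, i] <- cc$.row[j]
        used <- c(used, cc$.row[j])
      }
    }
  }
  traces
}

#' Filter traces by completeness and summarize quality control
#'
#' @param traces A `chromatin_traces` object.
#' @param min_completeness Minimum fraction of loci present to keep a trace.
#' @return A list with `traces` (the kept subset) and `report`: per-locus
#'   detection efficiency, refit fraction, and kept/dropped counts.
#' @export
trace_qc <- function(traces, min_completeness = 0.5) {
  comp <- trace_completeness(traces)
  keep <- comp >= min_completeness
  report <- list(
    n_input = length(comp),
    n_kept = sum(keep),
    n_dropped = sum(!keep),
    condition = traces$condition,
    per_locus_efficiency = colMeans(traces$present),
    refit_fraction = mean(traces$source == "refit"),
    completeness = comp
  )
  kept <- subset_traces(traces, keep)
  list(traces = kept, report = report)
}

subset_traces <- function(traces, sel) {
  new_chromatin_traces(
    traces$coords[sel, , , drop = FALSE],
    traces$source[sel, , drop = FALSE],
    traces$trace_id[sel], traces$nucleus_id[sel], traces$condition,
    if (!is.null(traces$assigned_focus)) {
      traces$assigned_focus[sel, , drop = FALSE]
    }
  )
}

#' Convert a ground-truth ensemble into a `chromatin_traces` object
#'
#' Ground-truth conformations and reconstructed traces share one container
#' so every distance statistic runs on either.
#'
#' @param ensemble A `conformation_ensemble`.
#' @return A `chromatin_traces` object with all loci flagged `assigned`.
#' @export
ensemble_as_traces <- function(ensemble) {
  n <- dim(ensemble$coords)[1]; L <- dim(ensemble$coords)[2]
  src <- matrix(ifelse(ensemble$present, "assigned", "missing"), n, L)
  new_chromatin_traces(ensemble$coords, src, seq_len(n),
                       ensemble$nucleus_of_trace, ensemble$condition)
}

#' Write traces as a long-format TSV
#'
#' One row per (trace, locus): `trace_id, nucleus_id, condition,
#' locus_index, x, y, z, source` with missing coordinates as NA.
#'
#' @param traces A `chromatin_traces` object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_traces <- function(traces, path) {
  n <- nrow(traces$present); L <- ncol(traces$present)
  out <- data.frame(
    trace_id = rep(traces$trace_id, each = L),
    nucleus_id = rep(traces$nucleus_id, each = L),
    condition = traces$condition,
    locus_index = rep(seq_len(L) - 1L, n),
    x = as.numeric(t(traces$coords[, , 1])),
    y = as.numeric(t(traces$coords[, , 2])),
    z = as.numeric(t(traces$coords[, , 3])),
    source = as.character(t(traces$source))
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read traces written by [write_traces()]
#' @param path TSV path.
#' @return A `chromatin_traces` object.
#' @export
read_traces <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ids <- unique(tab$trace_id)
  L <- max(tab$locus_index) + 1L
  n <- length(ids)
  coords <- array(NA_real_, c(n, L, 3))
  source <- matrix("missing", n, L)
  nucleus_id <- integer(n)
  for (t in seq_len(n)) {
    rows <- tab[tab$trace_id == ids[t], ]
    rows <- rows[order(rows$locus_index), ]
    coords[t, , ] <- as.matrix(rows[, c("x", "y", "z")])
    source[t, ] <- rows$source
    nucleus_id[t] <- rows$nucleus_id[1]
  }
  new_chromatin_traces(coords, source, ids, nucleus_id, tab$condition[1])
}
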