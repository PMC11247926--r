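#' Rigid/affine 3D transform
#'
#' @param translation Length-3 numeric (dx, dy, dz), nm.
#' @param linear Optional 3x3 matrix for affine mode (must be invertible).
#' @param from,to Frame labels.
#' @param rms Residual RMS of the fit that produced the transform, nm.
#' @param n_matches Number of point matches used.
#' @return An object of class `rigid_transform3d`. The transform maps
#'   `x_to = linear %*% x_from + translation` (linear defaults to identity).
#' @export
rigid_transform3d <- function(translation = c(0, 0, 0), linear = NULL,
                              from = "source", to = "reference",
                              rms = NA_real_, n_matches = NA_integer_) {
  stopifnot(length(translation) == 3L, is.numeric(translation))
  if (!is.null(linear)) {
    stopifnot(is.matrix(linear), all(dim(linear) == c(3L, 3L)))
    if (abs(det(linear)) < 1e-12) stop("affine linear part is not invertible")
  }
  structure(
    list(translation = as.numeric(translation), linear = linear,
         from = from, to = to, rms = rms, n_matches = n_matches),
    class = "rigid_transform3d"
  )
}

#' @export
print.rigid_transform3d <- function(x, ...) {
  cat(sprintf("<rigid_transform3d> %s -> %s: t = (%.2f, %.2f, %.2f) nm%s%s\n",
              x$from, x$to, x$translation[1], x$translation[2],
              x$translation[3],
              if (!is.null(x$linear)) " [affine]" else "",
              if (!is.na(x$rms)) sprintf(", rms %.2f nm", x$rms) else ""))
  invisible(x)
}

#' Apply a transform to an n x 3 coordinate matrix
#' @param transform A [rigid_transform3d()].
#' @param xyz Numeric matrix (n x 3) or data frame with x/y/z columns.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- as.matrix(xyz)
  if (!is.null(transform$linear)) xyz <- xyz %*% t(transform$linear)
  sweep(xyz, 2L, transform$translation, "+")
}

#' Invert a transform
#' @param transform A [rigid_transform3d()].
#' @return The inverse [rigid_transform3d()].
#' @export
invert_transform <- function(transform) {
  if (is.null(transform$linear)) {
    rigid_transform3d(-transform$translation, from = transform$to,
                      to = transform$from)
  } else {
    Ai <- solve(transform$linear)
    rigid_transform3d(-as.numeric(Ai %*% transform$translation), Ai,
                      from = transform$to, to = transform$from)
  }
}

# Mutual nearest-neighbor matching of two point sets within a gate radius.
# Returns an index matrix (i in a, j in b).
match_points <- function(a, b, gate = 500) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(cbind(integer(0), integer(0)))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  nn_ab <- apply(d2, 1L, which.min)
  nn_ba <- apply(d2, 2L, which.min)
  i <- seq_len(nrow(a))
  mutual <- nn_ba[nn_ab[i]] == i &
    sqrt(d2[cbind(i, nn_ab[i])]) <= gate
  cbind(i[mutual], nn_ab[i][mutual])
}

coords_of <- function(df) as.matrix(df[, c("x", "y", "z")])

#' Estimate the chromatic transform between two readout channels
#'
#' Matches multi-color calibration beads (mutual nearest neighbor within a
#' gate) between the offset channel and the reference channel and fits the
#' transform taking offset-channel coordinates into the reference frame.
#' `translation` mode fits the mean displacement; `affine` mode fits a full
#' 3x4 least-squares map and needs at least four non-coplanar matches.
#'
#' @param bead_foci_off Data frame of bead localizations on the channel to
#'   be corrected (x/y/z in nm).
#' @param bead_foci_ref Bead localizations on the reference channel.
#' @param mode `"translation"` (default) or `"affine"`.
#' @param gate Matching gate radius, nm.
#' @return A [rigid_transform3d()] mapping offset-channel into reference
#'   coordinates, with residual RMS recorded.
#' @export
estimate_chromatic_transform <- function(bead_foci_off, bead_foci_ref,
                                         mode = c("translation", "affine"),
                                         gate = 500) {
  mode <- match.arg(mode)
  a <- coords_of(bead_foci_off)
  b <- coords_of(bead_foci_ref)
  mt <- match_points(a, b, gate)
  need <- if (mode == "translation") 1L else 4L
  if (nrow(mt) < need) {
    stop(sprintf("chromatic estimation needs >= %d matched beads in %s mode, got %d",
                 need, mode, nrow(mt)))
  }
  src <- a[mt[, 1], , drop = FALSE]
  dst <- b[mt[, 2], , drop = FALSE]
  if (mode == "translation") {
    tr <- colMeans(dst - src)
    resid <- sweep(dst - src, 2L, tr)
    rigid_transform3d(tr, from = "offset_channel", to = "reference_channel",
                      rms = sqrt(mean(rowSums(resid^2))), n_matches = nrow(mt))
  } else {
    X <- cbind(src, 1)
    # guard against coplanar bead sets, where the affine fit is rank-deficient
    if (qr(X)$rank < 4L) stop("affine mode needs >= 4 non-coplanar matched beads")
    B <- solve(crossprod(X), crossprod(X, dst))  # 4 x 3
    A <- unname(t(B[1:3, , drop = FALSE]))
    tr <- as.numeric(B[4, ])
    fit <- X %*% B
    rigid_transform3d(tr, A, from = "offset_channel", to = "reference_channel",
                      rms = sqrt(mean(rowSums((dst - fit)^2))),
                      n_matches = nrow(mt))
  }
}

#' Estimate per-round stage drift from fiducial beads
#'
#' Matches the round's fiducials to the reference round (mutual nearest
#' neighbor within a gate) and returns the translation taking this round's
#' frame into the reference frame (the negated mean matched displacement).
#' The robust variant trims the 20% of matches with the largest residual
#' and refits.
#'
#' @param fiducials_round Fiducial localizations in the round to correct.
#' @param fiducials_reference Fiducial localizations in the reference round.
#' @param gate Matching gate radius, nm (should exceed the largest drift).
#' @param robust Trim the worst 20% of matches before the final estimate.
#' @return A [rigid_transform3d()] mapping round coordinates into the
#'   reference frame.
#' @export
estimate_drift <- function(fiducials_round, fiducials_reference,
                           gate = 2000, robust = FALSE) {
  a <- coords_of(fiducials_round)
  b <- coords_of(fiducials_reference)
  mt <- match_points(a, b, gate)
  if (nrow(mt) == 0L) stop("no matched fiducials within the gate radius")
  disp <- b[mt[, 2], , drop = FALSE] - a[mt[, 1], , drop = FALSE]
  tr <- colMeans(disp)
  if (robust && nrow(disp) >= 5L) {
    res <- sqrt(rowSums(sweep(disp, 2L, tr)^2))
    keep <- res <= quantile(res, 0.8)
    tr <- colMeans(disp[keep, , drop = FALSE])
    disp <- disp[keep, , drop = FALSE]
  }
  resid <- sweep(disp, 2L, tr)
  rigid_transform3d(tr, from = "round", to = "reference",
                    rms = sqrt(mean(rowSums(resid^2))), n_matches = nrow(disp))
}

#' Segment nuclei from a DAPI image or pass declared nuclei through
#'
#' Raster mode thresholds a 2D DAPI image (Otsu), labels connected
#' components, and drops components below `min_area` pixels; labels are
#' assigned in raster-scan order so they are stable and deterministic.
#' Vector mode passes a declared center+radius table through unchanged
#' (the simulator's output format).
#'
#' @param dapi_image 2D numeric matrix (raster mode), or `NULL`.
#' @param nuclei Data frame with `nucleus_id`, `cx`, `cy`, `cz`, `radius`
#'   (vector mode).
#' @param min_area Minimum component area in pixels (raster mode).
#' @return Raster mode: a list with `labels` (integer matrix) and `table`
#'   (id + centroid + area). Vector mode: the nuclei table.
#' @export
segment_nuclei <- function(dapi_image = NULL, nuclei = NULL, min_area = 20) {
  if (!is.null(nuclei)) {
    stopifnot(all(c("nucleus_id", "cx", "cy", "cz", "radius") %in% names(nuclei)))
    if (anyDuplicated(nuclei$nucleus_id)) stop("nucleus ids must be unique")
    return(nuclei)
  }
  stopifnot(is.matrix(dapi_image))
  if (max(dapi_image) <= min(dapi_image)) {
    return(list(labels = matrix(0L, nrow(dapi_image), ncol(dapi_image)),
                table = data.frame(nucleus_id = integer(0), cx = numeric(0),
                                   cy = numeric(0), area = integer(0))))
  }
  img <- (dapi_image - min(dapi_image)) / (max(dapi_image) - min(dapi_image))
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  lab <- EBImage::bwlabel(img > thr)
  lab <- EBImage::imageData(lab)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_area])
  lab[!(lab %in% keep)] <- 0L
  # relabel in raster-scan order of first appearance
  old <- unique(as.integer(lab[lab > 0]))
  new <- match(lab, old)
  new[is.na(new)] <- 0L
  lab <- matrix(as.integer(new), nrow(img), ncol(img))
  ids <- sort(unique(lab[lab > 0]))
  tab <- do.call(rbind, lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    data.frame(nucleus_id = id, cx = mean(w[, 1]), cy = mean(w[, 2]),
               area = nrow(w))
  }))
  list(labels = lab, table = tab %||% data.frame())
}

# squared-distance of foci to their nucleus center
in_nucleus <- function(foci, nuclei, slack = 1) {
  nc <- nuclei[match(foci$nucleus_id, nuclei$nucleus_id), ]
  d2 <- (foci$x - nc$cx)^2 + (foci$y - nc$cy)^2 + (foci$z - nc$cz)^2
  d2 <= (slack * nc$radius)^2
}

#' Fit 3D foci positions, restricted to nuclei
#'
#' Raster mode detects local maxima above `intensity_threshold` in a
#' rendered z-stack and refines each by least-squares fitting of a 3D
#' Gaussian (falling back to an intensity-weighted centroid, flagged, when
#' the fit does not converge). Vector mode filters a candidate detection
#' table by threshold and nucleus membership — the pass-through path used
#' with the simulator's foci tables. Foci outside every nucleus are
#' discarded in both modes.
#'
#' @param detections Candidate foci data frame (vector mode) with
#'   `nucleus_id`, `round`, `channel`, `x`, `y`, `z`, `intensity`.
#' @param zstack A list from [render_zstack()] (raster mode).
#' @param masks Nuclei table (vector mode) or labeled mask (raster mode;
#'   `NULL` keeps everything).
#' @param intensity_threshold Minimum intensity to report a focus.
#' @param mask_slack Multiple of the nucleus radius tolerated for
#'   membership in vector mode (localization noise and drift can push a
#'   genuine focus slightly outside the nominal sphere).
#' @param psf_sigma Initial PSF SD (nm) for the raster-mode Gaussian fit.
#' @return A `foci table` data frame; raster mode reports voxel-frame nm
#'   coordinates, `fit_quality` ("gaussian" or "centroid"), and intensity.
#' @export
fit_foci <- function(detections = NULL, zstack = NULL, masks = NULL,
                     intensity_threshold = 300, mask_slack = 1.2,
                     psf_sigma = c(150, 150, 300)) {
  if (!is.null(detections)) {
    out <- detections[detections$intensity >= intensity_threshold, ,
                      drop = FALSE]
    if (!is.null(masks) && nrow(out) > 0L) {
      out <- out[in_nucleus(out, masks, slack = mask_slack), , drop = FALSE]
    }
    out$fit_quality <- if (nrow(out)) "passthrough" else character(0)
    rownames(out) <- NULL
    return(out)
  }
  stopifnot(is.list(zstack), !is.null(zstack$image))
  img <- zstack$image
  vs <- zstack$voxel_size
  dims <- dim(img)
  cand <- which(img >= intensity_threshold, arr.ind = TRUE)
  # local maxima over the 26-neighborhood
  is_max <- apply(cand, 1L, function(v) {
    rng <- lapply(1:3, function(a) max(1, v[a] - 1):min(dims[a], v[a] + 1))
    img[v[1], v[2], v[3]] >= max(img[rng[[1]], rng[[2]], rng[[3]]])
  })
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      intensity = numeric(0), fit_quality = character(0)))
  }
  fit_one <- function(v) {
    rad <- pmax(1L, ceiling(2 * psf_sigma / vs))
    rng <- lapply(1:3, function(a) {
      max(1L, v[a] - rad[a]):min(dims[a], v[a] + rad[a])
    })
    sub <- img[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    ctr <- lapply(1:3, function(a) (rng[[a]] - 0.5) * vs[a])
    grid <- as.matrix(expand.grid(ctr[[1]], ctr[[2]], ctr[[3]]))
    w <- as.numeric(sub)
    centroid <- colSums(grid * w) / sum(w)
    obj <- function(p) {
      mu <- p[1:3]; amp <- exp(p[7]); sig <- exp(p[4:6])
      model <- amp * exp(-((grid[, 1] - mu[1])^2 / (2 * sig[1]^2) +
                             (grid[, 2] - mu[2])^2 / (2 * sig[2]^2) +
                             (grid[, 3] - mu[3])^2 / (2 * sig[3]^2)))
      sum((model - w)^2)
    }
    p0 <- c(centroid, log(psf_sigma), log(max(w)))
    fit <- tryCatch(optim(p0, obj, method = "BFGS",
                          control = list(maxit = 200)),
                    error = function(e) NULL)
    if (is.null(fit) || fit$convergence != 0) {
      c(centroid, sum(w), 0)  # centroid fallback, flagged
    } else {
      c(fit$par[1:3], sum(w), 1)
    }
  }
  res <- t(apply(cand, 1L, fit_one))
  data.frame(
    x = res[, 1], y = res[, 2], z = res[, 3], intensity = res[, 4],
    fit_quality = ifelse(res[, 5] == 1, "gaussian", "centroid"),
    stringsAsFactors = FALSE
  )
}

#' Apply chromatic and drift corrections to a foci table
#'
#' The chromatic transform is applied first (within-round, to foci of the
#' offset channel only), then each round's drift transform maps the foci
#' into the reference-round frame. Original coordinates are preserved in
#' `x_raw`/`y_raw`/`z_raw` and the `registered` flag is set. Row count,
#' intensities and round/channel labels are never altered.
#'
#' @param foci Foci table with `round`, `channel`, `x`, `y`, `z`.
#' @param chromatic A [rigid_transform3d()] for the offset channel (or
#'   `NULL` to skip).
#' @param drift_by_round Named list of transforms, one per round present
#'   (names = round index as character).
#' @param chromatic_channel Channel label the chromatic transform applies to.
#' @return The registered foci table.
#' @export
apply_corrections <- function(foci, chromatic = NULL, drift_by_round = list(),
                              chromatic_channel = "560") {
  rounds <- sort(unique(foci$round))
  missing_rounds <- setdiff(as.character(rounds), names(drift_by_round))
  if (length(missing_rounds) > 0L) {
    stop("no drift transform for round(s): ",
         paste(missing_rounds, collapse = ", "))
  }
  out <- foci
  # stable id so traces can reference foci across filtered sub-tables
  if (is.null(out$focus_id)) out$focus_id <- seq_len(nrow(out))
  out$x_raw <- foci$x; out$y_raw <- foci$y; out$z_raw <- foci$z
  xyz <- coords_of(out)
  if (!is.null(chromatic)) {
    sel <- out$channel == chromatic_channel
    if (any(sel)) {
      xyz[sel, ] <- apply_transform(chromatic, xyz[sel, , drop = FALSE])
    }
  }
  for (r in rounds) {
    sel <- out$round == r
    xyz[sel, ] <- apply_transform(drift_by_round[[as.character(r)]],
                                  xyz[sel, , drop = FALSE])
  }
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out$registered <- TRUE
  out
}

#' Estimate all corrections of an imaging experiment and register its foci
#'
#' Convenience wrapper chaining [estimate_chromatic_transform()] (from the
#' experiment's multi-color beads), [estimate_drift()] per round against
#' round 0, and [apply_corrections()].
#'
#' @param experiment An `imaging_experiment`.
#' @param mode Chromatic model, `"translation"` or `"affine"`.
#' @param robust Use the trimmed drift estimator.
#' @return A list with the registered `foci`, the `chromatic` transform,
#'   and `drift_by_round`.
#' @export
register_experiment <- function(experiment, mode = "translation",
                                robust = FALSE) {
  cb <- experiment$chromatic_beads
  chromatic <- estimate_chromatic_transform(
    cb[cb$channel == experiment$chromatic_channel, ],
    cb[cb$channel != experiment$chromatic_channel, ],
    mode = mode
  )
  fid <- experiment$fiducials
  ref <- fid[fid$round == 0L, ]
  drift_by_round <- lapply(seq_len(experiment$n_rounds) - 1L, function(r) {
    estimate_drift(fid[fid$round == r, ], ref, robust = robust)
  })
  names(drift_by_round) <- as.character(seq_len(experiment$n_rounds) - 1L)
  foci <- apply_corrections(experiment$foci, chromatic, drift_by_round,
                            chromatic_channel = experiment$chromatic_channel)
  list(foci = foci, chromatic = chromatic, drift_by_round = drift_by_round)
}
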