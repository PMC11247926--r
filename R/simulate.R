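#' Simulation configuration for the polymer/imaging generator
#'
#' Bundles every knob of the synthetic ground-truth generator. All lengths
#' are nanometers. Defaults describe a realistic sequential-FISH regime for
#' a 50-kb-per-locus panel in cultured fibroblasts: a 120-nm Gaussian-chain
#' step per 50-kb, 50/100-nm lateral/axial localization noise (axial worse
#' because of 200-nm z-stepping), 90% per-locus detection, 3 nonspecific
#' foci per nucleus per round, per-round rigid drift up to 300 nm per axis,
#' a (60, 40, 0)-nm chromatic offset on the 560-nm channel, 20 fiducial
#' beads, and a 6-um nucleus radius.
#'
#' @param seed Integer seed; all stage randomness derives from it.
#' @param n_traces Number of simulated nuclei (one traceable allele each,
#'   as in hemizygous-deletion patient lines).
#' @param step_sigma Gaussian-chain step standard deviation per axis, nm
#'   per 50-kb locus step.
#' @param scale Condition-level compaction factor multiplying `step_sigma`
#'   (smaller = more compact).
#' @param sub_block Optional `list(from, to, scale)`: 0-based inclusive
#'   locus range whose steps use a different compaction factor (used to
#'   plant a sub-region whose compaction change opposes the rest of the
#'   domain).
#' @param sigma_xy,sigma_z Localization noise SD, nm.
#' @param p_det Per-locus detection probability.
#' @param fp_rate Expected nonspecific foci per nucleus per round (Poisson).
#' @param drift_mag Per-round drift drawn uniform in `[-drift_mag, drift_mag]`
#'   per axis, nm; round 0 is the undrifted reference.
#' @param chromatic_offset Length-3 offset (nm) applied to foci imaged on
#'   `chromatic_channel`.
#' @param chromatic_channel Channel label receiving the chromatic offset.
#' @param n_fiducials Fiducial beads per field of view.
#' @param fiducial_jitter Per-round bead localization jitter SD, nm.
#' @param nucleus_radius Nucleus radius, nm.
#' @param intensity_meanlog,intensity_sdlog Lognormal brightness of true
#'   foci (arbitrary units); the lower tail supplies the sub-threshold
#'   candidates that missing-locus refitting recovers.
#' @param fp_meanlog,fp_sdlog Lognormal brightness of nonspecific foci.
#' @param n_alleles Traces planted per nucleus (default 1; raise to stress
#'   trace linking).
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1, n_traces = 100, step_sigma = 120,
                              scale = 1, sub_block = NULL,
                              sigma_xy = 50, sigma_z = 100, p_det = 0.9,
                              fp_rate = 3, drift_mag = 300,
                              chromatic_offset = c(60, 40, 0),
                              chromatic_channel = "560",
                              n_fiducials = 20, fiducial_jitter = 5,
                              nucleus_radius = 6000,
                              intensity_meanlog = log(1000),
                              intensity_sdlog = 0.9,
                              fp_meanlog = log(400), fp_sdlog = 0.7,
                              n_alleles = 1) {
  assert_scalar_number(p_det, "p_det", min = 0, max = 1)
  assert_scalar_number(step_sigma, "step_sigma", min = 1e-12)
  assert_scalar_number(scale, "scale", min = 1e-12)
  if (!is.null(sub_block)) {
    stopifnot(is.list(sub_block),
              all(c("from", "to", "scale") %in% names(sub_block)))
    if (sub_block$scale <= 0) stop("sub_block scale must be positive")
  }
  assert_scalar_number(fp_rate, "fp_rate", min = 0)
  assert_scalar_number(nucleus_radius, "nucleus_radius", min = 1)
  stopifnot(length(chromatic_offset) == 3L)
  structure(
    list(seed = as.integer(seed), n_traces = as.integer(n_traces),
         step_sigma = step_sigma, scale = scale, sub_block = sub_block,
         sigma_xy = sigma_xy, sigma_z = sigma_z, p_det = p_det,
         fp_rate = fp_rate, drift_mag = drift_mag,
         chromatic_offset = as.numeric(chromatic_offset),
         chromatic_channel = chromatic_channel,
         n_fiducials = as.integer(n_fiducials),
         fiducial_jitter = fiducial_jitter,
         nucleus_radius = nucleus_radius,
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog,
         fp_meanlog = fp_meanlog, fp_sdlog = fp_sdlog,
         n_alleles = as.integer(n_alleles)),
    class = "simulation_config"
  )
}

#' Noise-free variant of a simulation configuration
#'
#' Convenience for identity tests and demos: zero localization noise, drift,
#' chromatic offset, bead jitter and false positives, and full detection.
#'
#' @param config A [simulation_config()] to strip of noise terms.
#' @return The modified config.
#' @export
noiseless_config <- function(config = simulation_config()) {
  config$sigma_xy <- 0
  config$sigma_z <- 0
  config$p_det <- 1
  config$fp_rate <- 0
  config$drift_mag <- 0
  config$chromatic_offset <- c(0, 0, 0)
  config$fiducial_jitter <- 0
  config$intensity_sdlog <- 0  # brightness noise is noise too
  config
}

# Lay nuclei on a planar grid with generous spacing so traces from
# different nuclei can never be confused spatially.
nucleus_layout <- function(n, radius) {
  spacing <- 4 * radius
  ncol_ <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  data.frame(
    nucleus_id = seq_len(n),
    cx = (idx %% ncol_) * spacing,
    cy = (idx %/% ncol_) * spacing,
    cz = 0,
    radius = radius
  )
}

#' Simulate ground-truth chromatin conformations
#'
#' Generates one Gaussian-chain polymer per nucleus: locus positions are
#' cumulative sums of isotropic Gaussian steps with per-axis standard
#' deviation `scale * step_sigma`; steps inside an optional `sub_block` use
#' the block's own scale. The Gaussian chain gives the closed form
#' `E[d^2(i, j)] = 3 * (scale * step_sigma)^2 * |i - j|`, which the test
#' suite exploits.
#'
#' @param config A [simulation_config()].
#' @param panel A `segment_panel` defining the number of loci.
#' @param condition Condition label (e.g. `"PWS"`, `"AS"`).
#' @return An object of class `conformation_ensemble`: `coords` is an
#'   `n_traces x n_loci x 3` array (nm), `present` a logical matrix,
#'   `nuclei` the nucleus table, plus the config echo.
#' @export
simulate_conformations <- function(config, panel, condition = "sim") {
  stopifnot(inherits(config, "simulation_config"),
            inherits(panel, "segment_panel"))
  set.seed(stage_seed(config$seed, "conformations"))
  L <- n_loci(panel)
  n <- config$n_traces * config$n_alleles
  nuclei <- nucleus_layout(config$n_traces, config$nucleus_radius)
  # per-step sd: a step joins locus j-1 -> j (0-based); block override applies
  # when both endpoints lie inside the block
  step_sd <- rep(config$scale * config$step_sigma, L - 1L)
  if (!is.null(config$sub_block)) {
    b <- config$sub_block
    j <- seq_len(L - 1L)  # step j joins 0-based loci (j-1, j)
    inside <- (j - 1L) >= b$from & j <= b$to
    step_sd[inside] <- b$scale * config$step_sigma
  }
  coords <- array(NA_real_, dim = c(n, L, 3))
  nucleus_of_trace <- rep(seq_len(config$n_traces), each = config$n_alleles)
  for (t in seq_len(n)) {
    steps <- matrix(rnorm(3L * (L - 1L)), ncol = 3L) * step_sd
    walk <- rbind(c(0, 0, 0), apply(steps, 2L, cumsum))
    walk <- sweep(walk, 2L, colMeans(walk))  # center the polymer in its nucleus
    nc <- nuclei[nucleus_of_trace[t], c("cx", "cy", "cz")]
    coords[t, , ] <- sweep(walk, 2L, -as.numeric(nc))
  }
  structure(
    list(condition = condition, coords = coords,
         present = matrix(TRUE, n, L),
         nucleus_of_trace = nucleus_of_trace,
         nuclei = nuclei, panel_n_loci = L, config = config),
    class = "conformation_ensemble"
  )
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  cat(sprintf("<conformation_ensemble> %s: %d traces x %d loci (seed %d)\n",
              x$condition, dim(x$coords)[1], dim(x$coords)[2], x$config$seed))
  invisible(x)
}

trace_pair_distances <- function(coords, i, j) {
  sqrt(rowSums((coords[, i, , drop = FALSE] - coords[, j, , drop = FALSE])^2,
               dims = 1L))
}

#' Contact matrix of an ensemble at a capture radius
#'
#' Entry (i, j) is the fraction of traces in which loci i and j lie within
#' `capture_radius` of each other (among traces where both are present);
#' the diagonal is 1. This is the ensemble analog of a binned chromatin
#' contact frequency map.
#'
#' @param ensemble A `conformation_ensemble` (or a `chromatin_traces`
#'   object, whose missing loci are skipped pairwise).
#' @param capture_radius Contact threshold, nm.
#' @param panel Optional `segment_panel` supplying bin coordinates.
#' @return A `contact_matrix` object (see [read_contact_matrix()]).
#' @export
conformations_to_contact_matrix <- function(ensemble, capture_radius = 150,
                                            panel = NULL) {
  assert_scalar_number(capture_radius, "capture_radius", min = 1e-12)
  coords <- ensemble$coords
  present <- ensemble$present
  if (dim(coords)[1] == 0L) stop("ensemble is empty")
  L <- dim(coords)[2]
  m <- diag(1, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      ok <- present[, i] & present[, j]
      if (!any(ok)) { m[i, j] <- m[j, i] <- NA_real_; next }
      d <- trace_pair_distances(coords[ok, , , drop = FALSE], i, j)
      m[i, j] <- m[j, i] <- mean(d < capture_radius)
    }
  }
  new_contact_matrix(m, bins_from_panel(panel, L),
                     normalization = "ensemble_fraction")
}

bins_from_panel <- function(panel, L) {
  if (!is.null(panel)) {
    data.frame(chrom = panel$segments$chrom, start = panel$segments$start,
               end = panel$segments$end)
  } else {
    data.frame(chrom = "bin", start = (seq_len(L) - 1L) * 50000,
               end = seq_len(L) * 50000)
  }
}

runif_sphere <- function(n, radius) {
  # rejection-free: direction x radial CDF inverse
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * runif(n)^(1 / 3)
  u * r
}

#' Simulate a sequential-hybridization imaging experiment
#'
#' Renders an ensemble through the observation model the registration and
#' linking stages invert: per-round rigid drift (round 0 undrifted), a
#' chromatic offset on one channel, isotropic-in-xy localization noise with
#' inflated z, per-locus detection dropout, Poisson nonspecific foci uniform
#' in each nucleus, fiducial beads present every round in their own channel,
#' and multi-color registration beads seen in both readout channels. The
#' ground-truth linkage (focus to trace/locus) is retained for scoring.
#'
#' @param ensemble A `conformation_ensemble`.
#' @param panel A `segment_panel` with codebook set.
#' @param config The [simulation_config()] (defaults to the ensemble's).
#' @return An object of class `imaging_experiment` with `foci`,
#'   `fiducials`, `chromatic_beads`, `nuclei`, `drifts` (true, per round)
#'   and the true `chromatic_offset`.
#' @export
simulate_imaging <- function(ensemble, panel, config = ensemble$config) {
  stopifnot(inherits(ensemble, "conformation_ensemble"),
            inherits(panel, "segment_panel"))
  if (is.na(panel$n_channels)) stop("panel codebook is unset")
  set.seed(stage_seed(config$seed, "imaging"))
  L <- n_loci(panel)
  stopifnot(L == dim(ensemble$coords)[2])
  R <- n_rounds(panel)
  n <- dim(ensemble$coords)[1]
  nuclei <- ensemble$nuclei

  drifts <- matrix(runif(R * 3, -config$drift_mag, config$drift_mag),
                   nrow = R, dimnames = list(NULL, c("dx", "dy", "dz")))
  drifts[1, ] <- 0  # round 0 is the reference frame

  seg <- panel$segments
  # true foci: one candidate per (trace, locus), thinned by p_det
  idx <- expand.grid(trace = seq_len(n), locus = seq_len(L))
  keep <- runif(nrow(idx)) < config$p_det
  idx <- idx[keep, , drop = FALSE]
  tru <- data.frame(
    nucleus_id = ensemble$nucleus_of_trace[idx$trace],
    round = seg$hyb_round[idx$locus],
    channel = seg$channel[idx$locus],
    x = ensemble$coords[cbind(idx$trace, idx$locus, 1L)],
    y = ensemble$coords[cbind(idx$trace, idx$locus, 2L)],
    z = ensemble$coords[cbind(idx$trace, idx$locus, 3L)],
    intensity = rlnorm(nrow(idx), config$intensity_meanlog,
                       config$intensity_sdlog),
    is_truth = TRUE,
    truth_trace = idx$trace,
    truth_locus = idx$locus - 1L,  # reported 0-based like segment indices
    stringsAsFactors = FALSE
  )
  m <- nrow(tru)
  tru$x <- tru$x + rnorm(m, 0, config$sigma_xy)
  tru$y <- tru$y + rnorm(m, 0, config$sigma_xy)
  tru$z <- tru$z + rnorm(m, 0, config$sigma_z)

  # nonspecific foci, Poisson per nucleus per round, uniform in the nucleus
  nfp <- rpois(nrow(nuclei) * R, config$fp_rate)
  fp_nuc <- rep(rep(nuclei$nucleus_id, R), nfp)
  fp_round <- rep(rep(seq_len(R) - 1L, each = nrow(nuclei)), nfp)
  k <- length(fp_nuc)
  if (k > 0) {
    pos <- runif_sphere(k, config$nucleus_radius)
    spur <- data.frame(
      nucleus_id = fp_nuc, round = fp_round,
      channel = sample(panel$channel_names, k, replace = TRUE),
      x = nuclei$cx[fp_nuc] + pos[, 1], y = nuclei$cy[fp_nuc] + pos[, 2],
      z = nuclei$cz[fp_nuc] + pos[, 3],
      intensity = rlnorm(k, config$fp_meanlog, config$fp_sdlog),
      is_truth = FALSE, truth_trace = NA_integer_, truth_locus = NA_integer_,
      stringsAsFactors = FALSE
    )
    foci <- rbind(tru, spur)
  } else {
    foci <- tru
  }
  # imaging-frame displacement: drift of the focus's round, plus the
  # chromatic offset on the offset channel
  dr <- drifts[foci$round + 1L, , drop = FALSE]
  foci$x <- foci$x + dr[, 1]; foci$y <- foci$y + dr[, 2]
  foci$z <- foci$z + dr[, 3]
  on_off <- foci$channel == config$chromatic_channel
  foci$x[on_off] <- foci$x[on_off] + config$chromatic_offset[1]
  foci$y[on_off] <- foci$y[on_off] + config$chromatic_offset[2]
  foci$z[on_off] <- foci$z[on_off] + config$chromatic_offset[3]
  foci <- foci[order(foci$nucleus_id, foci$round, foci$channel), ]
  rownames(foci) <- NULL

  # fiducial beads: spread across the field, imaged in the 488 channel in
  # every round, displaced by that round's drift
  span <- max(nuclei$cx, nuclei$cy) + config$nucleus_radius
  base <- matrix(runif(config$n_fiducials * 3, 0, max(span, 1)),
                 ncol = 3)
  fid <- do.call(rbind, lapply(seq_len(R) - 1L, function(r) {
    jit <- matrix(rnorm(config$n_fiducials * 3, 0, config$fiducial_jitter),
                  ncol = 3)
    data.frame(bead_id = seq_len(config$n_fiducials), round = r,
               channel = "488",
               x = base[, 1] + drifts[r + 1L, 1] + jit[, 1],
               y = base[, 2] + drifts[r + 1L, 2] + jit[, 2],
               z = base[, 3] + drifts[r + 1L, 3] + jit[, 3])
  }))

  # multi-color beads for chromatic calibration, seen in both readout
  # channels of the reference round
  cb_jit <- function() matrix(rnorm(config$n_fiducials * 3, 0,
                                    config$fiducial_jitter), ncol = 3)
  j1 <- cb_jit(); j2 <- cb_jit()
  chromatic_beads <- rbind(
    data.frame(bead_id = seq_len(config$n_fiducials), channel = "647",
               x = base[, 1] + j1[, 1], y = base[, 2] + j1[, 2],
               z = base[, 3] + j1[, 3]),
    data.frame(bead_id = seq_len(config$n_fiducials), channel = config$chromatic_channel,
               x = base[, 1] + config$chromatic_offset[1] + j2[, 1],
               y = base[, 2] + config$chromatic_offset[2] + j2[, 2],
               z = base[, 3] + config$chromatic_offset[3] + j2[, 3])
  )

  structure(
    list(foci = foci, fiducials = fid, chromatic_beads = chromatic_beads,
         nuclei = nuclei, drifts = drifts,
         chromatic_offset = config$chromatic_offset,
         chromatic_channel = config$chromatic_channel,
         condition = ensemble$condition, n_rounds = R, config = config),
    class = "imaging_experiment"
  )
}

#' @export
print.imaging_experiment <- function(x, ...) {
  cat(sprintf(paste0("<imaging_experiment> %s: %d foci (%d true) over %d",
                     " rounds, %d nuclei\n"),
              x$condition, nrow(x$foci), sum(x$foci$is_truth), x$n_rounds,
              nrow(x$nuclei)))
  invisible(x)
}

#' Render foci into a synthetic z-stack
#'
#' Rasterizes point emitters onto a voxel grid as 3D Gaussian intensity
#' profiles (the z step of 200 nm makes axial sampling coarser than
#' lateral), optionally adding constant background and Poisson shot noise.
#' Foci outside the field of view are skipped with a warning.
#'
#' @param foci Data frame with `x`, `y`, `z` (nm) and `intensity`
#'   (total photons per focus).
#' @param psf_sigma Length-3 Gaussian PSF SD (nm); default c(150, 150, 300).
#' @param voxel_size Length-3 voxel pitch (nm); default c(108, 108, 200).
#' @param fov_shape Length-3 voxel counts (x, y, z).
#' @param background Constant background photons per voxel.
#' @param shot_noise Apply Poisson noise if `TRUE`.
#' @return A list with `image` (3D array, x-y-z), `voxel_size`, and
#'   `n_skipped`.
#' @export
render_zstack <- function(foci, psf_sigma = c(150, 150, 300),
                          voxel_size = c(108, 108, 200),
                          fov_shape = c(64, 64, 16),
                          background = 0, shot_noise = FALSE) {
  img <- array(background, dim = fov_shape)
  lims <- fov_shape * voxel_size
  inside <- foci$x >= 0 & foci$x < lims[1] &
    foci$y >= 0 & foci$y < lims[2] & foci$z >= 0 & foci$z < lims[3]
  if (any(!inside)) {
    warning(sum(!inside), " foci outside the field of view were skipped")
  }
  foci <- foci[inside, , drop = FALSE]
  centers <- lapply(1:3, function(a) (seq_len(fov_shape[a]) - 0.5) * voxel_size[a])
  for (f in seq_len(nrow(foci))) {
    mu <- c(foci$x[f], foci$y[f], foci$z[f])
    # evaluate on a +-4 sigma bounding box only
    rng <- lapply(1:3, function(a) {
      which(abs(centers[[a]] - mu[a]) <= 4 * psf_sigma[a])
    })
    if (any(vapply(rng, length, 0L) == 0L)) next
    gx <- stats::dnorm(centers[[1]][rng[[1]]], mu[1], psf_sigma[1]) * voxel_size[1]
    gy <- stats::dnorm(centers[[2]][rng[[2]]], mu[2], psf_sigma[2]) * voxel_size[2]
    gz <- stats::dnorm(centers[[3]][rng[[3]]], mu[3], psf_sigma[3]) * voxel_size[3]
    blob <- foci$intensity[f] * (gx %o% gy %o% gz)
    img[rng[[1]], rng[[2]], rng[[3]]] <- img[rng[[1]], rng[[2]], rng[[3]]] + blob
  }
  if (shot_noise) {
    img[] <- rpois(length(img), img)
  }
  list(image = img, voxel_size = voxel_size, n_skipped = sum(!inside))
}

#' Write an imaging experiment to TSV files
#'
#' Emits the foci table, fiducial tracks, chromatic beads, nucleus table,
#' and a JSON echo of the generating configuration under `dir`.
#'
#' @param experiment An `imaging_experiment`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_imaging_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  w(experiment$foci, "foci.tsv")
  w(experiment$fiducials, "fiducials.tsv")
  w(experiment$chromatic_beads, "chromatic_beads.tsv")
  w(experiment$nuclei, "nuclei.tsv")
  cfg <- experiment$config
  cfg$sub_block <- cfg$sub_block %||% NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
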