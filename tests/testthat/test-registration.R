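make_beads <- function(n, seed) {
  set.seed(seed)
  data.frame(x = runif(n, 0, 20000), y = runif(n, 0, 20000),
             z = runif(n, 0, 3000))
}

test_that("chromatic translation is recovered exactly from offset beads", {
  beads <- make_beads(15, 601)
  shifted <- beads
  shifted$x <- beads$x + 60; shifted$y <- beads$y + 40
  tf <- estimate_chromatic_transform(shifted, beads)
  expect_equal(tf$translation, c(-60, -40, 0))
  expect_equal(tf$rms, 0)
  expect_equal(tf$n_matches, 15L)

  # identical channels -> identity transform
  tf0 <- estimate_chromatic_transform(beads, beads)
  expect_equal(tf0$translation, c(0, 0, 0))
  expect_equal(tf0$rms, 0)

  expect_error(estimate_chromatic_transform(beads[0, ], beads),
               ">= 1 matched")
})

test_that("affine chromatic model recovers a planted linear map", {
  beads <- make_beads(10, 602)
  A <- matrix(c(1.002, 1e-4, 0, -2e-4, 0.999, 5e-5, 0, 1e-4, 1.001), 3, 3,
              byrow = TRUE)
  tvec <- c(55, -32, 8)
  src <- as.matrix(beads)
  dst <- sweep(src %*% t(A), 2, tvec, "+")
  # the planted map takes source beads into the reference frame
  tf <- estimate_chromatic_transform(beads, as.data.frame(dst) |>
                                       stats::setNames(c("x", "y", "z")),
                                     mode = "affine")
  expect_equal(tf$linear, A, tolerance = 1e-6)
  expect_equal(tf$translation, tvec, tolerance = 1e-6)
  expect_lt(tf$rms, 1e-6)
})

test_that("drift estimation is exact without noise and tight with it", {
  beads <- make_beads(20, 603)
  drift <- c(100, -50, 20)
  moved <- beads
  moved$x <- beads$x + drift[1]; moved$y <- beads$y + drift[2]
  moved$z <- beads$z + drift[3]
  tf <- estimate_drift(moved, beads)
  expect_equal(tf$translation, -drift)  # maps back into the reference frame

  # a round against itself: zero translation
  expect_equal(estimate_drift(beads, beads)$translation, c(0, 0, 0))

  # Gaussian jitter sigma = 10 nm on 20 beads: per-axis error < 3 sigma/sqrt(n)
  set.seed(604)
  jittered <- moved
  jittered$x <- jittered$x + rnorm(20, 0, 10)
  jittered$y <- jittered$y + rnorm(20, 0, 10)
  jittered$z <- jittered$z + rnorm(20, 0, 10)
  tfj <- estimate_drift(jittered, beads)
  expect_true(all(abs(tfj$translation + drift) <= 3 * 10 / sqrt(20)))

  expect_error(estimate_drift(moved[0, ], beads), "no matched")
})

test_that("drift estimation is translation-equivariant", {
  beads <- make_beads(12, 605)
  moved <- beads
  moved$x <- moved$x + 120; moved$z <- moved$z - 45
  t1 <- estimate_drift(moved, beads)$translation
  v <- c(5000, -3000, 800)
  shift <- function(df) {
    df$x <- df$x + v[1]; df$y <- df$y + v[2]; df$z <- df$z + v[3]; df
  }
  t2 <- estimate_drift(shift(moved), shift(beads))$translation
  expect_equal(t1, t2)
})

test_that("transform application and inversion round-trip", {
  tf <- rigid_transform3d(c(10, -20, 30),
                          matrix(c(1.01, 0, 0, 0, 0.99, 1e-3, 0, 0, 1), 3, 3,
                                 byrow = TRUE))
  xyz <- matrix(rnorm(30, 0, 500), ncol = 3)
  back <- apply_transform(invert_transform(tf), apply_transform(tf, xyz))
  expect_lt(max(abs(back - xyz)), 1e-9)
})

test_that("nucleus segmentation labels blobs deterministically", {
  img <- matrix(0, 60, 60)
  img[10:20, 10:20] <- 1
  img[40:52, 35:50] <- 1
  seg <- segment_nuclei(dapi_image = img)
  expect_equal(nrow(seg$table), 2L)
  expect_gt(seg$table$area[1], 100)
  # blank image -> no nuclei
  blank <- segment_nuclei(dapi_image = matrix(0, 30, 30))
  expect_equal(nrow(blank$table), 0L)
  # vector mode passes declared nuclei through
  nuc <- data.frame(nucleus_id = 1:2, cx = 0, cy = c(0, 100), cz = 0,
                    radius = 10)
  expect_identical(segment_nuclei(nuclei = nuc), nuc)
  expect_error(segment_nuclei(nuclei = nuc[c(1, 1), ]), "unique")
})

test_that("mask-recovered nuclei overlap planted disks (IoU >= 0.9)", {
  set.seed(606)
  truth <- matrix(FALSE, 80, 80)
  centers <- list(c(20, 25), c(60, 55))
  for (ctr in centers) {
    for (i in 1:80) for (j in 1:80) {
      if ((i - ctr[1])^2 + (j - ctr[2])^2 <= 10^2) truth[i, j] <- TRUE
    }
  }
  img <- ifelse(truth, 10, 0) + matrix(rnorm(6400, 0, 0.5), 80, 80)
  seg <- segment_nuclei(dapi_image = img)
  expect_equal(nrow(seg$table), 2L)
  found <- seg$labels > 0
  iou <- sum(found & truth) / sum(found | truth)
  expect_gte(iou, 0.9)
})

test_that("foci filtering respects threshold and nucleus masks", {
  nuc <- data.frame(nucleus_id = 1L, cx = 0, cy = 0, cz = 0, radius = 1000)
  det <- data.frame(
    nucleus_id = 1L, round = 0L, channel = "647",
    x = c(100, 200, 5000), y = 0, z = 0,
    intensity = c(1000, 100, 1000)
  )
  out <- fit_foci(detections = det, masks = nuc, intensity_threshold = 300,
                  mask_slack = 1)
  expect_equal(nrow(out), 1L)  # dim focus and out-of-mask focus removed
  expect_equal(out$x, 100)
})

test_that("corrections restore the reference frame and never alter rows", {
  panel <- toy_panel(n_segments = 10)
  cfg <- noiseless_config(simulation_config(seed = 607, n_traces = 5))
  cfg$drift_mag <- 300
  cfg$chromatic_offset <- c(60, 40, 0)
  ens <- simulate_conformations(cfg, panel)
  exp_ <- simulate_imaging(ens, panel, cfg)
  reg <- register_experiment(exp_)
  # planted transforms recovered exactly in the noiseless case
  expect_equal(reg$chromatic$translation, -cfg$chromatic_offset,
               tolerance = 1e-9)
  for (r in seq_len(exp_$n_rounds) - 1L) {
    expect_equal(reg$drift_by_round[[as.character(r)]]$translation,
                 -as.numeric(exp_$drifts[r + 1, ]), tolerance = 1e-9)
  }
  # registered foci coincide with ground truth
  tru <- reg$foci[reg$foci$is_truth, ]
  for (r in seq_len(nrow(tru))) {
    expect_equal(as.numeric(tru[r, c("x", "y", "z")]),
                 as.numeric(ens$coords[tru$truth_trace[r],
                                       tru$truth_locus[r] + 1L, ]),
                 tolerance = 1e-9)
  }
  # registration preserves counts, labels and intensities
  expect_equal(nrow(reg$foci), nrow(exp_$foci))
  expect_equal(reg$foci$intensity, exp_$foci$intensity)
  expect_equal(reg$foci$round, exp_$foci$round)
  expect_equal(reg$foci$channel, exp_$foci$channel)
  expect_true(all(reg$foci$registered))
  # raw coordinates preserved alongside
  expect_equal(reg$foci$x_raw, exp_$foci$x)

  expect_error(apply_corrections(exp_$foci, NULL, list()), "round")
})

test_that("registration reduces fiducial scatter on noisy data", {
  panel <- toy_panel(n_segments = 10)
  cfg <- simulation_config(seed = 608, n_traces = 5, fiducial_jitter = 10)
  ens <- simulate_conformations(cfg, panel)
  exp_ <- simulate_imaging(ens, panel, cfg)
  fid <- exp_$fiducials
  ref <- fid[fid$round == 0, ]
  pre <- post <- 0
  for (r in seq_len(exp_$n_rounds - 1)) {
    fr <- fid[fid$round == r, ]
    tf <- estimate_drift(fr, ref)
    d_pre <- as.matrix(fr[, c("x", "y", "z")]) -
      as.matrix(ref[, c("x", "y", "z")])
    d_post <- apply_transform(tf, fr[, c("x", "y", "z")]) -
      as.matrix(ref[, c("x", "y", "z")])
    pre <- pre + mean(rowSums(d_pre^2))
    post <- post + mean(rowSums(d_post^2))
  }
  expect_lt(post, pre)
})
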