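make_contact_fixture <- function(n = 4, chrom = "chrT", width = 50000) {
  m <- matrix(runif(n * n, 0.1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  bins <- data.frame(chrom = chrom, start = (seq_len(n) - 1L) * width,
                     end = seq_len(n) * width)
  chromtrace:::new_contact_matrix(m, bins)
}

test_that("contact matrices round-trip dense TSV and reject bad input", {
  set.seed(901)
  cm <- make_contact_fixture(3)
  path <- tempfile(fileext = ".tsv")
  write_contact_matrix(cm, path)
  back <- read_contact_matrix(path)
  expect_equal(back$matrix, cm$matrix)
  expect_equal(back$bins, cm$bins)
  # byte-stable second round trip
  path2 <- tempfile(fileext = ".tsv")
  write_contact_matrix(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # negative entries rejected
  bad <- cm; bad$matrix[1, 2] <- bad$matrix[2, 1] <- -0.1
  badpath <- tempfile(fileext = ".tsv")
  write_contact_matrix(bad, badpath)
  expect_error(read_contact_matrix(badpath), "negative")

  # asymmetric input rejected
  lines <- readLines(path)
  fields <- strsplit(lines[2], "\t")[[1]]
  fields[3] <- "99"
  lines[2] <- paste(fields, collapse = "\t")
  asympath <- tempfile(fileext = ".tsv")
  writeLines(lines, asympath)
  expect_error(read_contact_matrix(asympath), "asymmetric")
})

test_that("COO upper-triangle input is symmetrized", {
  coo <- data.frame(
    chrom = "chrT",
    start1 = c(0, 0, 50000),
    start2 = c(50000, 100000, 100000),
    value = c(5, 2, 7)
  )
  path <- tempfile(fileext = ".tsv")
  write.table(coo, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- read_contact_matrix(path, format = "coo_tsv", bin_width = 50000)
  expect_equal(dim(cm$matrix), c(3L, 3L))
  expect_equal(cm$matrix[1, 2], 5)
  expect_equal(cm$matrix[2, 1], 5)
  expect_equal(cm$matrix[3, 1], 2)
  expect_error(read_contact_matrix(path, format = "coo_tsv"), "bin_width")
})

test_that("bin alignment pairs matched loci and counts exclusions", {
  panel <- build_codebook(partition_region(default_tracing_region()))
  set.seed(902)
  coords <- array(rnorm(30 * 42 * 3, 0, 400), c(30, 42, 3))
  dm <- median_distance_matrix(traces_from_array(coords), min_pairs = 1)
  bins <- data.frame(chrom = "chr15",
                     start = panel$segments$start, end = panel$segments$end)
  m <- matrix(runif(42 * 42), 42, 42); m <- (m + t(m)) / 2; diag(m) <- 1
  cm <- chromtrace:::new_contact_matrix(m, bins)
  al <- align_bins(dm, cm, panel)
  expect_equal(nrow(al$pairs), 42 * 41 / 2)  # 861 candidate pairs
  expect_equal(al$n_excluded, 0L)

  # one missing distance entry -> excluded and counted
  dm2 <- dm; dm2$median_nm[3, 9] <- dm2$median_nm[9, 3] <- NA
  al2 <- align_bins(dm2, cm, panel)
  expect_equal(nrow(al2$pairs), 860L)
  expect_equal(al2$n_excluded, 1L)

  # disjoint grids -> error
  bins_off <- bins; bins_off$chrom <- "chr16"
  cm_off <- chromtrace:::new_contact_matrix(m, bins_off)
  expect_error(align_bins(dm, cm_off, panel), "no overlapping bins")

  # min_separation excludes near-diagonal pairs
  al3 <- align_bins(dm, cm, panel, min_separation = 1)
  expect_equal(nrow(al3$pairs), 861L - 41L)
})

test_that("correlation behaves analytically on constructed inputs", {
  # exact power law: log-log Pearson is exactly -1
  d <- seq(100, 1500, length.out = 50)
  pairs <- data.frame(distance_nm = d, contact = d^(-1.5))
  r <- distance_contact_correlation(pairs, "pearson", "log_both")
  expect_equal(r$r, -1)
  # Spearman is invariant under any monotone transform of either margin
  rs1 <- distance_contact_correlation(pairs, "spearman")
  pairs2 <- pairs; pairs2$contact <- sqrt(pairs$contact)
  pairs2$distance_nm <- pairs$distance_nm^3
  rs2 <- distance_contact_correlation(pairs2, "spearman")
  expect_equal(rs1$r, rs2$r)
  expect_equal(rs1$r, -1)
  # Pearson is invariant to affine rescaling of distances
  rp1 <- distance_contact_correlation(pairs, "pearson")
  pairs3 <- pairs; pairs3$distance_nm <- 2.5 * pairs$distance_nm + 100
  rp2 <- distance_contact_correlation(pairs3, "pearson")
  expect_equal(rp1$r, rp2$r)

  # constant contact vector -> undefined, flagged
  flat <- data.frame(distance_nm = d, contact = 1)
  rf <- distance_contact_correlation(flat)
  expect_false(rf$defined)
  expect_true(is.na(rf$r))

  # zero contacts excluded (and counted) under the log transform
  withz <- pairs; withz$contact[1:5] <- 0
  rz <- distance_contact_correlation(withz, "pearson", "log_contact")
  expect_equal(rz$n_excluded, 5L)
  expect_equal(rz$n_pairs, 45L)

  expect_error(distance_contact_correlation(pairs[1:2, ]), "at least 3")
})

test_that("simulated ensembles give strong distance-contact anticorrelation", {
  panel <- build_codebook(partition_region(default_tracing_region()))
  cfg <- simulation_config(seed = 903, n_traces = 1000)
  ens <- simulate_conformations(cfg, panel, "sim")
  dm <- median_distance_matrix(ensemble_as_traces(ens))
  cm <- conformations_to_contact_matrix(ens, capture_radius = 150,
                                        panel = panel)
  al <- align_bins(dm, cm, panel)
  r <- distance_contact_correlation(al$pairs, "spearman")
  expect_lte(r$r, -0.8)
  # sign is stable across capture radii
  for (radius in c(100, 300)) {
    cm2 <- conformations_to_contact_matrix(ens, capture_radius = radius,
                                           panel = panel)
    al2 <- align_bins(dm, cm2, panel)
    expect_lt(distance_contact_correlation(al2$pairs, "spearman")$r, 0)
  }
})

test_that("region summaries expose a planted sub-block reversal", {
  # all-negative matrix: both regions fully negative
  L <- 10
  m <- matrix(-0.3, L, L); diag(m) <- NA
  fc <- structure(list(log2fc = m, numerator = "A", denominator = "B"),
                  class = "fold_change_matrix")
  s <- fold_change_region_summary(fc, c(2, 5), n_boot = 100)
  expect_equal(s$frac_negative, c(1, 1))
  expect_equal(s$frac_positive, c(0, 0))
  # fractions sum to <= 1 under missing entries
  m2 <- m; m2[1, 2] <- m2[2, 1] <- NA; m2[7, 8] <- m2[8, 7] <- 0.4
  fc2 <- structure(list(log2fc = m2, numerator = "A", denominator = "B"),
                   class = "fold_change_matrix")
  s2 <- fold_change_region_summary(fc2, c(2, 5), n_boot = 100)
  expect_true(all(s2$frac_negative + s2$frac_positive <= 1))
  expect_error(fold_change_region_summary(fc, c(8, 3)), "empty")

  # simulator with a reversed sub-block: inside positive, outside negative
  panel <- toy_panel(n_segments = 16)
  ref <- simulate_conformations(
    simulation_config(seed = 904, n_traces = 400), panel, "ref")
  rev <- simulate_conformations(
    simulation_config(seed = 905, n_traces = 400, scale = 0.8,
                      sub_block = list(from = 4, to = 9, scale = 1.3)),
    panel, "rev")
  fc3 <- log2_fold_change(median_distance_matrix(ensemble_as_traces(rev)),
                          median_distance_matrix(ensemble_as_traces(ref)))
  s3 <- fold_change_region_summary(fc3, c(4, 9), n_boot = 200)
  expect_gt(s3$frac_negative[s3$region == "outside"], 0.5)
  expect_lt(s3$frac_negative[s3$region == "inside"], 0.5)
})
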