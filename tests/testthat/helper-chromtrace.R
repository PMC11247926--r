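# Shared fixtures and independent brute-force oracles.

toy_panel <- function(n_segments = 6, segment_length = 50000,
                      n_channels = 2) {
  region <- genomic_interval("chrT", 0, n_segments * segment_length,
                             assembly = "toy")
  build_codebook(partition_region(region, segment_length),
                 n_channels = n_channels)
}

# Occurrence count of every sub-k-mer of `candidate` in `genome` (character
# vector of sequences), both strands, by direct position-by-position
# comparison. Independent of the package's k-mer index.
oracle_subkmer_hits <- function(candidate, genome, sub_k) {
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  count_in <- function(word, seq) {
    n <- nchar(seq)
    if (n < nchar(word)) return(0L)
    pos <- seq_len(n - nchar(word) + 1L)
    sum(substring(seq, pos, pos + nchar(word) - 1L) == word)
  }
  words <- substring(candidate, seq_len(nchar(candidate) - sub_k + 1L),
                     seq_len(nchar(candidate) - sub_k + 1L) + sub_k - 1L)
  vapply(words, function(w) {
    sum(vapply(genome, function(g) {
      count_in(w, g) + count_in(w, rc(g))
    }, 0L))
  }, 0L, USE.NAMES = FALSE)
}

# Exhaustive minimum of the linking objective: for each combination of one
# candidate per locus (loci with no candidate skipped), cost = summed
# distance of the chosen foci to their own centroid minus w * sum(log I).
oracle_linking_cost <- function(cand, w) {
  counts <- vapply(cand, nrow, 0L)
  active <- which(counts > 0L)
  if (length(active) == 0L) return(list(cost = NA_real_, pick = NULL))
  grid <- do.call(expand.grid, lapply(counts[active], seq_len))
  best_cost <- Inf; best <- NULL
  for (g in seq_len(nrow(grid))) {
    pick <- as.integer(grid[g, ])
    xyz <- t(vapply(seq_along(active), function(a) {
      as.numeric(cand[[active[a]]][pick[a], c("x", "y", "z")])
    }, numeric(3)))
    ii <- vapply(seq_along(active), function(a) {
      cand[[active[a]]]$intensity[pick[a]]
    }, 0)
    ctr <- colMeans(xyz)
    cost <- sum(sqrt(rowSums(sweep(xyz, 2, ctr)^2))) - w * sum(log(ii))
    if (cost < best_cost) { best_cost <- cost; best <- pick }
  }
  list(cost = best_cost, pick = best)
}

# Random linking instance: n_loci loci, 1..max_cand candidates per locus,
# in a single-round-per-locus geometry compatible with link_traces.
random_linking_instance <- function(n_loci, max_cand, seed) {
  set.seed(seed)
  cand <- lapply(seq_len(n_loci), function(i) {
    k <- sample.int(max_cand, 1)
    data.frame(
      round = i - 1L, channel = "647",
      x = rnorm(k, 0, 400), y = rnorm(k, 0, 400), z = rnorm(k, 0, 400),
      intensity = rlnorm(k, log(800), 0.5)
    )
  })
  cand
}

# Brute-force median distance matrix straight from the definition.
oracle_median_matrix <- function(coords, present) {
  L <- ncol(present)
  m <- matrix(NA_real_, L, L)
  diag(m) <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    vals <- c()
    for (t in seq_len(nrow(present))) {
      if (present[t, i] && present[t, j]) {
        vals <- c(vals, sqrt(sum((coords[t, i, ] - coords[t, j, ])^2)))
      }
    }
    if (length(vals) >= 1L) m[i, j] <- median(vals)
  }
  m
}

oracle_rg <- function(xyz) {
  ctr <- colMeans(xyz)
  sqrt(sum(sweep(xyz, 2, ctr)^2) / nrow(xyz))
}

# Traces object built directly from a coordinate array (all loci present).
traces_from_array <- function(coords, condition = "test") {
  n <- dim(coords)[1]; L <- dim(coords)[2]
  src <- matrix("assigned", n, L)
  structure(
    list(coords = coords, present = matrix(TRUE, n, L), source = src,
         trace_id = seq_len(n), nucleus_id = seq_len(n),
         condition = condition, assigned_focus = NULL),
    class = "chromatin_traces"
  )
}

run_noiseless_chain <- function(seed, n_traces = 15, panel = NULL) {
  panel <- panel %||% build_codebook(partition_region(default_tracing_region()))
  cfg <- noiseless_config(simulation_config(seed = seed, n_traces = n_traces))
  ens <- simulate_conformations(cfg, panel, "demo")
  exp_ <- simulate_imaging(ens, panel, cfg)
  reg <- register_experiment(exp_)
  fitted <- fit_foci(detections = reg$foci, masks = exp_$nuclei)
  tr <- link_traces(fitted, panel, linking_config(), condition = "demo")
  tr <- refit_missing(tr, reg$foci, panel)
  list(panel = panel, config = cfg, ensemble = ens, experiment = exp_,
       registered = reg, traces = tr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
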