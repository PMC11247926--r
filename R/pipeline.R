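pipeline_defaults <- function() {
  list(
    seed = NULL,
    panel = list(chrom = "chr15", start = 23500000, end = 25600000,
                 assembly = "hg38", segment_length = 50000, n_channels = 2),
    conditions = list(A = list(scale = 1, n_traces = 100, sub_block = NULL)),
    simulation = list(step_sigma = 120, sigma_xy = 50, sigma_z = 100,
                      p_det = 0.9, fp_rate = 3, drift_mag = 300,
                      chromatic_offset = c(60, 40, 0), n_fiducials = 20,
                      fiducial_jitter = 5, nucleus_radius = 6000,
                      noiseless = FALSE),
    registration = list(mode = "translation", robust = FALSE,
                        intensity_threshold = 300),
    linking = list(r_max = 1500, intensity_weight = 0, refit_radius = 500,
                   refit_threshold_factor = 0.5, min_completeness = 0.5),
    stats = list(min_pairs = 10),
    concordance = list(capture_radius = 150, method = "spearman",
                       transform = "identity", reference_condition = NULL),
    comparisons = NULL
  )
}

merge_section <- function(defaults, user, where, errors) {
  unknown <- setdiff(names(user), names(defaults))
  for (k in unknown) {
    errors$msgs <- c(errors$msgs, sprintf("%s: unknown key '%s'", where, k))
  }
  for (k in intersect(names(user), names(defaults))) {
    defaults[[k]] <- user[[k]]
  }
  list(value = defaults, errors = errors)
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or an R list, fills in every default, and
#' rejects unknown keys and invalid values, reporting each problem with its
#' location. The seed is mandatory: all randomness in a run flows from it
#' through per-stage substreams.
#'
#' @param config A list, or path to a YAML document.
#' @return A validated `run_config` object (fully defaulted echo).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- pipeline_defaults()
  errors <- list(msgs = character(0))
  unknown <- setdiff(names(config), names(defaults))
  for (k in unknown) {
    errors$msgs <- c(errors$msgs, sprintf("top level: unknown key '%s'", k))
  }
  out <- defaults
  if (is.null(config$seed)) {
    errors$msgs <- c(errors$msgs, "top level: 'seed' is mandatory")
  } else {
    out$seed <- as.integer(config$seed)
  }
  for (sec in c("panel", "simulation", "registration", "linking", "stats",
                "concordance")) {
    if (!is.null(config[[sec]])) {
      m <- merge_section(defaults[[sec]], config[[sec]], sec, errors)
      out[[sec]] <- m$value; errors <- m$errors
    }
  }
  if (!is.null(config$conditions)) {
    conds <- list()
    for (nm in names(config$conditions)) {
      m <- merge_section(list(scale = 1, n_traces = 100, sub_block = NULL),
                         config$conditions[[nm]],
                         sprintf("conditions$%s", nm), errors)
      conds[[nm]] <- m$value; errors <- m$errors
      if (!is.null(conds[[nm]]$sub_block)) {
        sb <- conds[[nm]]$sub_block
        if (!all(c("from", "to", "scale") %in% names(sb))) {
          errors$msgs <- c(errors$msgs,
                           sprintf("conditions$%s$sub_block: needs from/to/scale", nm))
        }
      }
      if (conds[[nm]]$scale <= 0) {
        errors$msgs <- c(errors$msgs,
                         sprintf("conditions$%s: scale must be positive", nm))
      }
    }
    out$conditions <- conds
  }
  if (!is.null(config$comparisons)) out$comparisons <- config$comparisons
  if (out$panel$end <= out$panel$start) {
    errors$msgs <- c(errors$msgs, "panel: end must exceed start")
  }
  if (out$linking$r_max <= 0) {
    errors$msgs <- c(errors$msgs, "linking: r_max must be positive")
  }
  if (out$linking$refit_radius <= 0) {
    errors$msgs <- c(errors$msgs, "linking: refit_radius must be positive")
  }
  if (out$simulation$p_det < 0 || out$simulation$p_det > 1) {
    errors$msgs <- c(errors$msgs, "simulation: p_det must lie in [0, 1]")
  }
  if (is.null(out$comparisons) && length(out$conditions) > 1L) {
    ref <- names(out$conditions)[1]
    out$comparisons <- lapply(names(out$conditions)[-1], function(nm) {
      list(num = nm, den = ref)
    })
  }
  if (is.null(out$concordance$reference_condition)) {
    out$concordance$reference_condition <- names(out$conditions)[1]
  }
  if (length(errors$msgs) > 0L) {
    stop("invalid configuration:\n  ", paste(errors$msgs, collapse = "\n  "),
         call. = FALSE)
  }
  structure(out, class = "run_config")
}

condition_sim_config <- function(cfg, name, idx) {
  sim <- cfg$simulation
  cc <- cfg$conditions[[name]]
  sc <- simulation_config(
    seed = cfg$seed + idx, n_traces = cc$n_traces, step_sigma = sim$step_sigma,
    scale = cc$scale, sub_block = cc$sub_block, sigma_xy = sim$sigma_xy,
    sigma_z = sim$sigma_z, p_det = sim$p_det, fp_rate = sim$fp_rate,
    drift_mag = sim$drift_mag, chromatic_offset = sim$chromatic_offset,
    n_fiducials = sim$n_fiducials, fiducial_jitter = sim$fiducial_jitter,
    nucleus_radius = sim$nucleus_radius
  )
  if (isTRUE(sim$noiseless)) sc <- noiseless_config(sc)
  sc
}

#' Run the full chromatin-tracing pipeline on simulated data
#'
#' Orchestrates panel construction, per-condition polymer and imaging
#' simulation, registration, foci filtering, trace linking with refit and
#' QC, median-distance and fold-change statistics, and distance-vs-contact
#' concordance against the reference condition's ground-truth contact
#' matrix. Deterministic for a given configuration and seed.
#'
#' @param config A `run_config` from [validate_config()] (or a raw
#'   list/path, validated on the fly).
#' @param out_dir Optional directory for on-disk artifacts (matrices,
#'   traces, report JSON) laid out per stage.
#' @return A `run_report` list: per-stage record counts, QC summaries,
#'   distance/fold-change matrices, concordance results and timings.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  region <- genomic_interval(config$panel$chrom, config$panel$start,
                             config$panel$end, config$panel$assembly)
  panel <- build_codebook(partition_region(region, config$panel$segment_length),
                          n_channels = config$panel$n_channels)
  tick("panel")

  conditions <- names(config$conditions)
  ensembles <- list(); experiments <- list(); registered <- list()
  traces <- list(); qc <- list(); dmats <- list()
  counts <- list()
  for (i in seq_along(conditions)) {
    nm <- conditions[i]
    sc <- condition_sim_config(config, nm, i)
    ens <- simulate_conformations(sc, panel, condition = nm)
    ensembles[[nm]] <- ens
    exp_ <- simulate_imaging(ens, panel, sc)
    experiments[[nm]] <- exp_
    reg <- register_experiment(exp_, mode = config$registration$mode,
                               robust = config$registration$robust)
    registered[[nm]] <- reg
    fitted <- fit_foci(detections = reg$foci, masks = exp_$nuclei,
                       intensity_threshold = config$registration$intensity_threshold)
    lc <- linking_config(
      r_max = config$linking$r_max,
      intensity_weight = config$linking$intensity_weight,
      refit_radius = config$linking$refit_radius,
      refit_threshold_factor = config$linking$refit_threshold_factor
    )
    tr <- link_traces(fitted, panel, lc, condition = nm)
    tr <- refit_missing(tr, reg$foci, panel, lc,
                        intensity_threshold = config$registration$intensity_threshold)
    q <- trace_qc(tr, min_completeness = config$linking$min_completeness)
    traces[[nm]] <- q$traces
    qc[[nm]] <- q$report
    n_assigned <- sum(tr$source == "assigned")
    n_refit <- sum(tr$source == "refit")
    counts[[nm]] <- list(
      foci_simulated = nrow(exp_$foci),
      foci_registered = nrow(reg$foci),
      foci_above_threshold = nrow(fitted),
      loci_assigned = n_assigned,
      loci_refit = n_refit,
      loci_missing = sum(tr$source == "missing"),
      traces_kept = q$report$n_kept,
      traces_dropped = q$report$n_dropped
    )
    dmats[[nm]] <- median_distance_matrix(q$traces,
                                          min_pairs = config$stats$min_pairs)
  }
  tick("simulate_register_link")

  fold_changes <- list()
  for (cmp in config$comparisons %||% list()) {
    key <- sprintf("%s_vs_%s", cmp$num, cmp$den)
    fold_changes[[key]] <- log2_fold_change(dmats[[cmp$num]], dmats[[cmp$den]])
  }
  tick("stats")

  ref <- config$concordance$reference_condition
  contact <- conformations_to_contact_matrix(
    ensembles[[ref]], capture_radius = config$concordance$capture_radius,
    panel = panel
  )
  aligned <- align_bins(dmats[[ref]], contact, panel)
  concordance <- distance_contact_correlation(
    aligned$pairs, method = config$concordance$method,
    transform = config$concordance$transform
  )
  tick("concordance")

  report <- list(
    config = unclass(config),
    panel = list(n_segments = n_loci(panel), n_rounds = n_rounds(panel),
                 n_channels = panel$n_channels,
                 remainder_bp = panel$remainder_bp),
    counts = counts,
    qc = lapply(qc, function(q) q[c("n_input", "n_kept", "n_dropped",
                                    "refit_fraction")]),
    fold_change_summary = lapply(fold_changes, function(fc) {
      off <- fc$log2fc[upper.tri(fc$log2fc)]
      list(median_log2fc = median(off, na.rm = TRUE),
           frac_negative = mean(off < 0, na.rm = TRUE))
    }),
    concordance = unclass(concordance),
    timings = timings
  )
  result <- list(report = report, panel = panel, ensembles = ensembles,
                 traces = traces, distance_matrices = dmats,
                 fold_changes = fold_changes, contact = contact,
                 concordance = concordance)
  class(result) <- "run_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_panel_bed(panel, file.path(out_dir, "panel.bed"))
    write_codebook(panel, file.path(out_dir, "codebook.tsv"))
    for (nm in conditions) {
      write_traces(traces[[nm]], file.path(out_dir, sprintf("traces_%s.tsv", nm)))
      write_matrix_tsv(dmats[[nm]],
                       file.path(out_dir, sprintf("median_distance_%s.tsv", nm)),
                       panel = panel)
    }
    for (key in names(fold_changes)) {
      write_matrix_tsv(fold_changes[[key]],
                       file.path(out_dir, sprintf("log2fc_%s.tsv", key)),
                       panel = panel)
    }
    write_contact_matrix(contact, file.path(out_dir, "contact_matrix.tsv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }
  result
}

#' @export
print.run_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<run_result> %d segments, %d rounds; conditions: %s\n",
              r$panel$n_segments, r$panel$n_rounds,
              paste(names(x$traces), collapse = ", ")))
  for (key in names(r$fold_change_summary)) {
    cat(sprintf("  log2FC %s: median %.3f (%.0f%% entries negative)\n", key,
                r$fold_change_summary[[key]]$median_log2fc,
                100 * r$fold_change_summary[[key]]$frac_negative))
  }
  cat(sprintf("  distance-vs-contact %s r = %.4f (n = %d pairs)\n",
              r$concordance$method, r$concordance$r, r$concordance$n_pairs))
  invisible(x)
}
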