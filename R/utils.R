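#' @keywords internal
"_PACKAGE"

#' @importFrom stats median cor complete.cases rnorm runif rpois rlnorm
#'   quantile optim setNames aggregate
#' @importFrom utils read.table write.table head
NULL

# Deterministic per-stage substream: every stage of a run draws from its own
# seed derived from the single top-level seed, so editing one stage never
# perturbs another. Offsets are fixed small primes; result kept < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(
    panel = 101L, readouts = 211L, genome = 307L, conformations = 401L,
    imaging = 503L, linking = 601L, stats = 701L, concordance = 809L,
    zstack = 907L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown seed substream: ", stage)
  }
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= 0
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < min || x > max) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(min), format(max)), call. = FALSE)
  }
  invisible(x)
}
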