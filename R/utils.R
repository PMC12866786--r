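# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed per pipeline stage; stays below 2^31 - 1.
# The product stays under 2^53, so the double arithmetic is exact.
sub_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + k) %% 2147483647)
}

# Linear-interpolation percentile (order-statistic interpolation, the common
# numerical default; R quantile type 7).
percentile <- function(x, q) {
  unname(stats::quantile(x, probs = q / 100, type = 7, names = FALSE))
}

stop_param <- function(...) {
  stop(errorCondition(paste0(...), class = c("spotzone_param_error", "error")))
}

stop_geometry <- function(...) {
  stop(errorCondition(paste0(...), class = c("spotzone_geometry_error", "error")))
}

stop_no_region <- function(...) {
  stop(errorCondition(paste0(...), class = c("spotzone_no_region", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
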