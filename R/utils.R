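# Classed error conditions so callers and tests can discriminate failure modes.
ss_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "senoscreen_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_param      <- function(msg, ...) ss_stop("senoscreen_parameter_error", msg, ...)
stop_capacity   <- function(msg, ...) ss_stop("senoscreen_capacity_error", msg, ...)
stop_input      <- function(msg, ...) ss_stop("senoscreen_input_error", msg, ...)
stop_state      <- function(msg, ...) ss_stop("senoscreen_state_error", msg, ...)
stop_domain     <- function(msg, ...) ss_stop("senoscreen_domain_error", msg, ...)
stop_degenerate <- function(msg, ...) ss_stop("senoscreen_degenerate_error", msg, ...)
stop_config     <- function(msg, ...) ss_stop("senoscreen_config_error", msg, ...)
stop_control    <- function(msg, ...) ss_stop("senoscreen_insufficient_control_error", msg, ...)
stop_join       <- function(msg, ...) ss_stop("senoscreen_join_error", msg, ...)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_param("seed must be a single number or NULL")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic count policy: floor(n * frac), guarded against double roundoff
# (0.29 * 100 is 28.999... in binary floating point).
det_count <- function(n, frac) {
  as.integer(floor(n * frac + 1e-9))
}

# Strictly positive normal draws; values <= 0 are redrawn up to `cap` rounds.
rnorm_pos <- function(n, mean, sd, cap = 100L) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(cap)) {
    bad <- x <= 0
    if (!any(bad)) return(x)
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop_param(
    "could not draw strictly positive intensities from N(%g, %g) in %d redraws",
    mean, sd, cap
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
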