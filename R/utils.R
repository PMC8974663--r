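# Internal helpers: error signalling, RNG hygiene, small numerics.

abort_fracwk <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("fracwk_error_", class), "fracwk_error"), ...)
}

# Run `code` under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Uniform-grid check: spacing constant to `tol` relative to the mean step.
check_uniform_grid <- function(t, tol = 1e-9, what = "time grid") {
  if (length(t) < 2) {
    abort_fracwk(paste0(what, " must contain at least two samples"), "data")
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    abort_fracwk(paste0(what, " must be strictly increasing"), "grid")
  }
  step <- mean(dt)
  if (max(abs(dt - step)) > tol * step) {
    abort_fracwk(paste0(what, " is not uniform (max spacing deviation exceeds tolerance)"), "grid")
  }
  step
}

# Wrap angles to the principal branch (-pi, pi].
wrap_phase <- function(phi) {
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# Remove 2*pi jumps from a phase sequence (first element anchors the branch).
unwrap_phase <- function(phi) {
  if (length(phi) < 2) return(phi)
  cumsum(c(phi[1], wrap_phase(diff(phi))))
}
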