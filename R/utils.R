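# Small shared helpers: angle conversion, seeded evaluation, input checks.

deg2rad <- function(deg) deg * pi / 180
rad2deg <- function(rad) rad * 180 / pi

# Reduce an angle in degrees to [0, 360).
wrap_deg <- function(deg) ((deg %% 360) + 360) %% 360

# Signed circular distance between two angles, in degrees, in (-180, 180].
circ_dist_deg <- function(a, b) {
  d <- wrap_deg(a - b)
  ifelse(d > 180, d - 360, d)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_finite_numeric <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) == 0)
    stop(sprintf("`%s` must be a non-empty numeric vector", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
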