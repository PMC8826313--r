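# Internal helpers shared across the package.

#' Wrap angles to (-pi, pi]
#'
#' All phase arithmetic in the package uses this convention.
#'
#' @param x numeric vector or array of angles in radians.
#' @return values wrapped to the half-open interval (-pi, pi].
#' @export
wrap_phase <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  # floor() maps the upper boundary to -pi; fold it back to +pi
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

# mod into [0, 2*pi)
mod_2pi <- function(x) x %% (2 * pi)

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop with a classed condition so callers/tests can be specific
isi_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "isimap_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

isi_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

# deterministic child seed derived from a root seed and a stream label;
# kept below 2^31 so it is always a valid R integer
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + 12345) %% 2147483629)
}

# evaluate expr with a local RNG state (does not disturb the caller's RNG)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
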