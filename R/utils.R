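# Shared helpers: angle wrapping and deterministic seeding.

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @examples
#' wrap_degrees(c(350, -190, 180, -180))
#' @export
wrap_degrees <- function(x) {
  y <- ((x + 180) %% 360) - 180
  y[y == -180] <- 180
  y
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a master seed and small integer offsets,
# keeping the result inside the 32-bit integer range.
child_seed <- function(seed, ...) {
  offs <- c(...)
  as.integer((as.numeric(seed) + sum(offs * 1000^(seq_along(offs) - 1))) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
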