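# Internal helpers shared across modules.

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls do not perturb user-level streams.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Signed circular difference a - b mapped to (-180, 180].
circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

# Circular mean of hue angles in degrees, result in [0, 360).
circ_mean <- function(h) {
  r <- h * pi / 180
  (atan2(mean(sin(r)), mean(cos(r))) * 180 / pi) %% 360
}

# Condition constructors so callers can distinguish pipeline failures.
idc_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "idc_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L &&
    is.numeric(x) && all(is.finite(x)) && min(x) >= 0 && max(x) <= 1
}

assert_rgb_image <- function(x, what = "image") {
  if (!is_rgb_image(x)) {
    idc_error("idc_invalid_input", sprintf(
      "%s must be a numeric h x w x 3 array with intensities in [0, 1]", what
    ))
  }
  invisible(x)
}

# Quantize intensities in [0,1] to the 8-bit grid (k/255).
quantize8 <- function(x) round(x * 255) / 255
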