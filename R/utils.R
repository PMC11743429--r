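# Round half away from zero (commercial rounding). base::round() rounds
# half to even, which would make the boundary arithmetic depend on parity.
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Validate an H x W x 3 numeric image array. Accepts integers 0..255 or
# reals in [0, 1]; returns the array rescaled to [0, 1] doubles.
check_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort(sprintf("`%s` must be an H x W x 3 array", arg))
  }
  if (!is.numeric(img)) abort(sprintf("`%s` must be numeric", arg))
  if (anyNA(img)) abort(sprintf("`%s` contains missing values", arg))
  mx <- max(img)
  if (min(img) < 0 || mx > 255) {
    abort(sprintf("`%s` values must be in [0, 1] or integers in [0, 255]", arg))
  }
  if (mx > 1) img <- img / 255
  storage.mode(img) <- "double"
  img
}

check_labels <- function(labels) {
  labels <- unlist(labels)
  if (length(labels) != 5L) abort("labels must have length 5 (one per organ)")
  if (!all(labels %in% c(0, 1))) abort("labels must be binary 0/1")
  if (is.null(names(labels))) names(labels) <- ORGANS
  if (!setequal(names(labels), ORGANS)) {
    abort("labels must be named heart, lung, liver, spleen, kidney")
  }
  labels[ORGANS]
}

# Derive a child seed below 2^31 from a base seed and an index.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483629)
}
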