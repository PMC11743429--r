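#' Compute tongue-region boundaries from image dimensions
#'
#' Divides an `H` x `W` tongue image into the four diagnostic regions of
#' TCM tongue inspection: region A (tongue tip, heart/lung) is the bottom
#' fifth of the image over its full width; region B (lateral margins,
#' liver) is two vertical strips, each a fifth of the image width, spanning
#' the rows above A; region D (root, kidney) is the top two-fifths of the
#' central column band; region C (center, spleen) is the central band
#' between D and A. Boundaries are proportions of the image dimensions,
#' rounded half-up, with the right strip edge mirrored (`c_right = W -
#' c_left`) so the four regions always tile the image exactly.
#'
#' Coordinates are 0-based with half-open intervals `[start, stop)`; rows
#' increase downward.
#'
#' @param h,w Image height and width in pixels; both must be at least 5 or
#'   some region would be empty.
#' @return A `region_bounds` object: list with `r_mid` (top row of region
#'   C), `r_tip` (top row of region A), `c_left`/`c_right` (edges of the
#'   central column band), and the input `h`, `w`.
#' @examples
#' region_bounds(224, 224)
#' @export
region_bounds <- function(h, w) {
  if (!is_scalar_number(h) || !is_scalar_number(w)) {
    abort("`h` and `w` must be single numbers")
  }
  h <- as.integer(h); w <- as.integer(w)
  if (h < 5L || w < 5L) {
    abort(sprintf(
      "image %d x %d is too small to partition: need at least 5 x 5 or a region is empty",
      h, w))
  }
  b <- structure(list(
    r_mid   = as.integer(round_half_up(2 * h / 5)),
    r_tip   = as.integer(h - round_half_up(h / 5)),
    c_left  = as.integer(round_half_up(w / 5)),
    c_right = as.integer(w - round_half_up(w / 5)),
    h = h, w = w
  ), class = "region_bounds")
  stopifnot(b$r_mid > 0L, b$r_mid < b$r_tip, b$r_tip < h,
            b$c_left > 0L, b$c_left < b$c_right, b$c_right < w)
  b
}

#' @export
print.region_bounds <- function(x, ...) {
  cat(sprintf(
    "<region_bounds %d x %d>  r_mid=%d r_tip=%d c_left=%d c_right=%d\n",
    x$h, x$w, x$r_mid, x$r_tip, x$c_left, x$c_right))
  invisible(x)
}

#' Pixel area of each tongue region
#'
#' @param bounds A [region_bounds()] object.
#' @return A tibble with columns `region` (A, B, C, D) and `area` (pixels).
#'   Areas always sum to `h * w`.
#' @export
region_areas <- function(bounds) {
  stopifnot(inherits(bounds, "region_bounds"))
  wc <- bounds$c_right - bounds$c_left
  tibble(
    region = REGIONS,
    area = c(
      (bounds$h - bounds$r_tip) * bounds$w,
      bounds$r_tip * 2L * bounds$c_left,
      (bounds$r_tip - bounds$r_mid) * wc,
      bounds$r_mid * wc
    )
  )
}

# 1-based row/column index vectors for each region, as a list of
# list(rows, cols) (region B gets left and right column runs).
region_index <- function(bounds) {
  b <- bounds
  list(
    A = list(rows = (b$r_tip + 1L):b$h, cols = seq_len(b$w)),
    B = list(rows = seq_len(b$r_tip),
             cols = c(seq_len(b$c_left), (b$c_right + 1L):b$w)),
    C = list(rows = (b$r_mid + 1L):b$r_tip, cols = (b$c_left + 1L):b$c_right),
    D = list(rows = seq_len(b$r_mid), cols = (b$c_left + 1L):b$c_right)
  )
}

#' Partition a tongue image into the four organ regions
#'
#' Crops the image into regions A (tip), B (margins), C (center) and D
#' (root) at the boundaries from [region_bounds()]. The two margin strips
#' of region B are concatenated side by side (left strip then right strip)
#' into a single image so every region is one array. Pixel values are
#' copied unchanged; the four crops tile the input exactly, with no pixel
#' in two regions.
#'
#' @param image An `H` x `W` x 3 numeric array (RGB; reals in `[0, 1]` or
#'   integers 0-255).
#' @return A `region_partition` object: list with elements `A`, `B`, `C`,
#'   `D` (image arrays) and `bounds`.
#' @examples
#' img <- array(runif(30 * 40 * 3), c(30, 40, 3))
#' part <- partition_tongue(img)
#' vapply(part[c("A", "B", "C", "D")], function(r) prod(dim(r)[1:2]), 0)
#' @export
partition_tongue <- function(image) {
  image <- check_image(image)
  d <- dim(image)
  bounds <- region_bounds(d[1], d[2])
  idx <- region_index(bounds)
  crops <- lapply(idx, function(i) image[i$rows, i$cols, , drop = FALSE])
  structure(c(crops, list(bounds = bounds)), class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>\n")
  for (r in REGIONS) {
    d <- dim(x[[r]])
    cat(sprintf("  %s: %d x %d\n", r, d[1], d[2]))
  }
  print(x$bounds)
  invisible(x)
}

#' Reassemble a partition into the original image
#'
#' Inverse of [partition_tongue()]: places the four crops back at their
#' boundary coordinates. Useful to verify the exact-tiling property.
#'
#' @param part A `region_partition`.
#' @return An `H` x `W` x 3 array identical to the partitioned input.
#' @export
reassemble_partition <- function(part) {
  stopifnot(inherits(part, "region_partition"))
  b <- part$bounds
  out <- array(0, c(b$h, b$w, 3L))
  idx <- region_index(b)
  out[idx$A$rows, idx$A$cols, ] <- part$A
  # B was stored as left|right concatenation
  nl <- b$c_left
  out[idx$B$rows, seq_len(nl), ] <- part$B[, seq_len(nl), , drop = FALSE]
  out[idx$B$rows, (b$c_right + 1L):b$w, ] <- part$B[, nl + seq_len(nl), , drop = FALSE]
  out[idx$C$rows, idx$C$cols, ] <- part$C
  out[idx$D$rows, idx$D$cols, ] <- part$D
  out
}

#' Draw region boundary lines on a copy of an image
#'
#' Debug rendering of the diagnostic region map: draws the horizontal
#' boundaries at `r_mid` and `r_tip` and the vertical boundaries at
#' `c_left` and `c_right`. The input is never modified.
#'
#' @param image An `H` x `W` x 3 numeric array.
#' @param bounds Optional [region_bounds()]; computed from the image
#'   dimensions when missing.
#' @param color Length-3 RGB line color in `[0, 1]`.
#' @return A copy of the image with boundary lines drawn.
#' @export
region_overlay <- function(image, bounds = NULL, color = c(1, 1, 1)) {
  image <- check_image(image)
  d <- dim(image)
  if (is.null(bounds)) bounds <- region_bounds(d[1], d[2])
  stopifnot(inherits(bounds, "region_bounds"),
            bounds$h == d[1], bounds$w == d[2], length(color) == 3L)
  out <- image
  # boundary rows/cols are the first row/col of the lower/right interval
  # (0-based index k -> 1-based k + 1)
  for (ch in 1:3) {
    out[c(bounds$r_mid, bounds$r_tip) + 1L, , ch] <- color[ch]
    out[, c(bounds$c_left, bounds$c_right) + 1L, ch] <- color[ch]
  }
  out
}

#' Read and write tongue images
#'
#' Thin wrappers over PNG I/O returning/accepting `H` x `W` x 3 arrays in
#' `[0, 1]`. Grayscale and alpha-channel PNGs are expanded/truncated to 3
#' channels on read.
#'
#' @param path File path.
#' @param image An `H` x `W` x 3 array in `[0, 1]`.
#' @return `read_tongue_image()` returns an image array;
#'   `write_tongue_image()` invisibly returns `path`.
#' @export
read_tongue_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_tongue_image
#' @export
write_tongue_image <- function(image, path) {
  png::writePNG(clamp(check_image(image), 0, 1), path)
  invisible(path)
}

#' Write the four region crops of an image to disk
#'
#' Writes `<stem>_A.png` ... `<stem>_D.png` plus a `<stem>_bounds.json`
#' sidecar with the boundary coordinates.
#'
#' @param part A `region_partition`.
#' @param dir Output directory (created if needed).
#' @param stem Filename stem.
#' @return Invisibly, a tibble with columns `region` and `path`.
#' @export
write_partition <- function(part, dir, stem) {
  stopifnot(inherits(part, "region_partition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(REGIONS, function(r) {
    p <- file.path(dir, sprintf("%s_%s.png", stem, r))
    png::writePNG(clamp(part[[r]], 0, 1), p)
    p
  }, character(1))
  b <- part$bounds
  jsonlite::write_json(
    list(h = b$h, w = b$w, r_mid = b$r_mid, r_tip = b$r_tip,
         c_left = b$c_left, c_right = b$c_right),
    file.path(dir, sprintf("%s_bounds.json", stem)), auto_unbox = TRUE)
  invisible(tibble(region = REGIONS, path = unname(paths)))
}
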