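#' Gradient-weighted class activation map for one organ score
#'
#' Computes gradients of the organ's pre-sigmoid score with respect to
#' the chosen branch's last convolutional feature maps, weights each map
#' by its spatially averaged gradient, rectifies the weighted sum,
#' normalizes the maximum to 1 (an identically zero map is returned
#' unnormalized), and upsamples bilinearly to the branch input grid.
#' The map is invariant to positive rescaling of the score.
#'
#' @param model An `organnet` (or `organnet_fit`).
#' @param image An `H` x `W` x 3 image array.
#' @param organ One of heart, lung, liver, spleen, kidney.
#' @param branch `"full"` for the whole-image backbone (map aligned to
#'   the resized full image) or `"region"` for the organ's region
#'   backbone (map aligned to that region's crop). The requested branch
#'   must exist in the model and predict the organ: e.g. the kidney
#'   cannot be requested from the region-A branch.
#' @return A `cam_map`: list with `heatmap` (`input_size` square matrix
#'   in `[0, 1]`), `organ`, `branch` and the underlying `image`.
#' @export
gradcam <- function(model, image, organ, branch = c("full", "region")) {
  if (inherits(model, "organnet_fit")) model <- model$model
  stopifnot(inherits(model, "organnet"))
  organ <- match.arg(organ, ORGANS)
  branch <- match.arg(branch)
  region <- unname(ORGAN_REGION[[organ]])
  branch_name <- if (branch == "full") "full" else region
  if (!branch_name %in% names(model$branches)) {
    abort(sprintf("model has no '%s' branch", branch_name))
  }
  head_region <- region
  br <- model$branches[[branch_name]]
  if (!head_region %in% names(br$heads)) {
    abort(sprintf("branch '%s' does not predict organ '%s'",
                  branch_name, organ))
  }
  size <- model$config$input_size
  tensors <- image_tensors(image, size, branch_name)
  bf <- backbone_forward(br$backbone, tensors[[branch_name]], keep = TRUE)
  hf <- head_forward(br$heads[[head_region]], bf$feat, keep = TRUE)
  organs <- REGION_ORGANS[[head_region]]
  dz <- matrix(0, 1L, length(organs))
  dz[1L, match(organ, organs)] <- 1
  hb <- head_backward(br$heads[[head_region]], hf, dz)
  d <- bf$map_dim
  alpha <- hb$dfeat[1L, ] / (d[2] * d[3])       # spatially averaged gradient
  maps <- bf$maps[1L, , , , drop = TRUE]
  dim(maps) <- d[2:4]
  cam <- matrix(0, d[2], d[3])
  for (ch in seq_len(d[4])) cam <- cam + alpha[ch] * maps[, , ch]
  cam[cam < 0] <- 0
  mx <- max(cam)
  if (mx > 0) cam <- cam / mx
  if (d[2] != size || d[3] != size) {
    up <- EBImage::imageData(EBImage::resize(EBImage::Image(cam),
                                             w = size, h = size))
    cam <- clamp(matrix(up, size, size), 0, 1)
    mx <- max(cam)
    if (mx > 0) cam <- cam / mx    # keep the max-equals-one convention
  }
  structure(list(heatmap = cam, organ = organ, branch = branch_name,
                 image = resize_image(check_image(image), size)),
            class = "cam_map")
}

#' @export
print.cam_map <- function(x, ...) {
  cat(sprintf("<cam_map> organ %s, branch %s, %d x %d, mass %.3f\n",
              x$organ, x$branch, nrow(x$heatmap), ncol(x$heatmap),
              sum(x$heatmap)))
  invisible(x)
}

#' Fraction of activation mass inside one tongue region
#'
#' Quantifies localization: the sum of heatmap values inside the region
#' divided by the total heatmap sum. For a nonzero map the masses over
#' regions A-D sum to 1 (the regions tile the image). An all-zero map
#' returns 0 with attribute `zero_map = TRUE`.
#'
#' @param cam A `cam_map` (aligned to the full-image grid) or a plain
#'   matrix.
#' @param bounds [region_bounds()] matching the heatmap dimensions.
#' @param region One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @return A value in `[0, 1]`.
#' @export
cam_region_mass <- function(cam, bounds, region) {
  h <- if (inherits(cam, "cam_map")) cam$heatmap else cam
  stopifnot(inherits(bounds, "region_bounds"), is.matrix(h))
  region <- match.arg(region, REGIONS)
  if (nrow(h) != bounds$h || ncol(h) != bounds$w) {
    abort("heatmap dimensions do not match the region bounds")
  }
  total <- sum(h)
  if (total == 0) return(structure(0, zero_map = TRUE))
  idx <- region_index(bounds)[[region]]
  sum(h[idx$rows, idx$cols]) / total
}

#' Write a CAM heatmap as a PNG overlay
#'
#' Blends the heatmap (red channel) over the branch input image.
#'
#' @param cam A `cam_map`.
#' @param path Output PNG path.
#' @param alpha Maximum blend weight of the heatmap.
#' @return Invisibly, `path`.
#' @export
write_cam_overlay <- function(cam, path, alpha = 0.6) {
  stopifnot(inherits(cam, "cam_map"))
  img <- cam$image
  w <- alpha * cam$heatmap
  img[, , 1] <- img[, , 1] * (1 - w) + w
  img[, , 2] <- img[, , 2] * (1 - w)
  img[, , 3] <- img[, , 3] * (1 - w)
  png::writePNG(clamp(img, 0, 1), path)
  invisible(path)
}
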