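#' Configuration for a five-branch tongue-diagnosis network
#'
#' The network has up to five convolutional backbones with fully disjoint
#' weights: one for the whole tongue image and one per diagnostic region
#' (A tip, B margins, C center, D root). The full-image backbone feeds
#' four MLP heads (region-A head: 2 outputs for heart and lung; B: liver;
#' C: spleen; D: kidney); each region backbone feeds the single head of
#' matching output count. All scalar outputs pass through a logistic
#' squashing so scores are probabilities in `[0, 1]`.
#'
#' @param backbone Backbone family. `"tiny"` (the default) is a compact
#'   stack of stride-2 3x3 conv blocks sized for CPU runs; widths are
#'   controlled by `widths`.
#' @param input_size Side length every branch input is resized to
#'   (pixels, >= 32). The study-scale preset is 224; the test-scale
#'   default is 64.
#' @param widths Integer vector of conv channel counts, one per block.
#' @param head_hidden Hidden width of the 2-layer MLP heads.
#' @param threshold Decision threshold on the fused probability, in
#'   (0, 1). Predictions use the strict rule `fused > threshold`.
#' @return An `organnet_config` list.
#' @export
organnet_config <- function(backbone = "tiny", input_size = 64L,
                            widths = c(12L, 24L, 32L), head_hidden = 32L,
                            threshold = 0.5) {
  if (!identical(backbone, "tiny")) {
    abort(sprintf("unknown backbone '%s' (available: 'tiny')", backbone))
  }
  if (!is_scalar_number(input_size) || input_size < 32) {
    abort("`input_size` must be a single number >= 32")
  }
  if (!is_scalar_number(threshold) || threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be in (0, 1)")
  }
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 widths = as.integer(widths),
                 head_hidden = as.integer(head_hidden),
                 threshold = threshold),
            class = "organnet_config")
}

#' Build a five-branch tongue-diagnosis network
#'
#' Constructs the multi-backbone model of [organnet_config()]. Every
#' branch (full image plus one per requested region) gets its own
#' backbone and heads with independent, disjoint parameters — no weight
#' sharing anywhere. Single-branch subsets give the ablation variants:
#' `branches = "full"` is the whole-image baseline, `branches = "A"` the
#' region-A net, and so on.
#'
#' @param config An [organnet_config()].
#' @param branches Character subset of `c("full", "A", "B", "C", "D")`.
#' @param seed Integer seed for weight initialization (He-normal); the
#'   caller's RNG state is left untouched.
#' @return An `organnet` model object.
#' @examples
#' model <- build_organnet(organnet_config(), seed = 1)
#' model
#' @export
build_organnet <- function(config = organnet_config(),
                           branches = c("full", "A", "B", "C", "D"),
                           seed = 1L) {
  stopifnot(inherits(config, "organnet_config"))
  branches <- match.arg(branches, c("full", "A", "B", "C", "D"),
                        several.ok = TRUE)
  d_feat <- config$widths[length(config$widths)]
  build_branch <- function(regions) {
    bb <- new_backbone(config$widths)
    heads <- lapply(setNames(regions, regions), function(r) {
      new_head(d_feat, config$head_hidden, length(REGION_ORGANS[[r]]))
    })
    list(backbone = bb, heads = heads)
  }
  model <- with_seed(seed, {
    br <- list()
    for (b in branches) {
      br[[b]] <- if (b == "full") build_branch(REGIONS) else build_branch(b)
    }
    br
  })
  structure(list(config = config, branches = model, seed = as.integer(seed)),
            class = "organnet")
}

#' @export
print.organnet <- function(x, ...) {
  np <- sum(vapply(organnet_params(x), length, 0L))
  cat(sprintf(
    "<organnet> %s backbone, input %dx%d, branches: %s (%s parameters)\n",
    x$config$backbone, x$config$input_size, x$config$input_size,
    paste(names(x$branches), collapse = ", "), format(np, big.mark = ",")))
  invisible(x)
}

#' Flattened model parameters
#'
#' Returns every weight and bias array keyed by its path (for example
#' `"full/backbone/1/W"`). Paths are unique; arrays from different
#' branches are never shared.
#'
#' @param model An `organnet`.
#' @return Named list of numeric arrays.
#' @export
organnet_params <- function(model) {
  stopifnot(inherits(model, "organnet"))
  collect_params(model$branches)
}

#' Number of organs scored by a branch set
#' @noRd
branch_organs <- function(branch_names) {
  unique(unlist(REGION_ORGANS[intersect(branch_names, REGIONS)]))
}

# Resize an image array to size x size with bilinear interpolation.
resize_image <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(img, colormode = "Color"), w = size, h = size))
  dim(out) <- c(size, size, 3L)
  out
}

# Build the per-branch input tensors (N=1) for a single image.
image_tensors <- function(image, input_size, branches) {
  part <- partition_tongue(image)
  src <- list(full = check_image(image), A = part$A, B = part$B,
              C = part$C, D = part$D)
  lapply(setNames(branches, branches), function(b) {
    r <- resize_image(src[[b]], input_size)
    t1 <- array(0, c(1L, input_size, input_size, 3L))
    t1[1L, , , ] <- r
    t1
  })
}

# Forward all branches on prepared tensors. Returns matrices full_probs and
# region_probs (N x 5, NA where the branch is absent), plus caches when
# keep = TRUE (for training / Grad-CAM).
organnet_forward_batch <- function(model, tensors, keep = FALSE) {
  n <- dim(tensors[[1]])[1]
  full_probs <- matrix(NA_real_, n, 5L, dimnames = list(NULL, ORGANS))
  region_probs <- matrix(NA_real_, n, 5L, dimnames = list(NULL, ORGANS))
  caches <- list()
  for (b in names(model$branches)) {
    branch <- model$branches[[b]]
    bf <- backbone_forward(branch$backbone, tensors[[b]], keep = keep)
    hf <- list()
    for (r in names(branch$heads)) {
      h <- head_forward(branch$heads[[r]], bf$feat, keep = keep)
      p <- sigmoid(h$z)
      organs <- REGION_ORGANS[[r]]
      if (b == "full") full_probs[, organs] <- p else region_probs[, organs] <- p
      hf[[r]] <- h
    }
    caches[[b]] <- list(backbone = bf, heads = hf)
  }
  list(full = full_probs, region = region_probs,
       caches = if (keep) caches else NULL)
}

#' Per-organ score pairs for a tongue image
#'
#' Partitions the image, resizes the full image and each region crop to
#' the model input size, runs every branch, and returns for each organ
#' its whole-image-path and region-path probabilities. Region A's branch
#' supplies the region path for both heart and lung.
#'
#' @param model An `organnet` from [build_organnet()].
#' @param image An `H` x `W` x 3 image array.
#' @return A tibble with columns `organ`, `region`, `full_path`,
#'   `region_path` (five rows, canonical organ order). Paths whose branch
#'   is absent from the model are `NA`.
#' @seealso [fuse_scores()], [predict.organnet()]
#' @export
organ_scores <- function(model, image) {
  stopifnot(inherits(model, "organnet"))
  tensors <- image_tensors(image, model$config$input_size,
                           names(model$branches))
  fw <- organnet_forward_batch(model, tensors)
  tibble(organ = ORGANS, region = unname(ORGAN_REGION),
         full_path = unname(fw$full[1L, ]),
         region_path = unname(fw$region[1L, ]))
}

#' Average-voting fusion of a score pair
#'
#' Fuses the whole-image-path and region-path probabilities for an organ
#' by their arithmetic mean, `(full + region) / 2` — average voting over
#' the two contributing networks.
#'
#' @param full_path,region_path Probabilities in `[0, 1]` (vectorized).
#' @return The fused probabilities.
#' @examples
#' fuse(0.6, 0.8) # 0.7
#' @export
fuse <- function(full_path, region_path) {
  p <- c(full_path, region_path)
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("score components must be probabilities in [0, 1]")
  }
  (full_path + region_path) / 2
}

#' Add fused scores to a score table
#'
#' Applies [fuse()] rowwise to the output of [organ_scores()]. If only
#' one path is present (single-branch ablation models) the fused value is
#' that path's probability (average voting over one network).
#'
#' @param scores Tibble with `full_path` and `region_path` columns.
#' @return The tibble with a `fused` column appended.
#' @export
fuse_scores <- function(scores) {
  stopifnot(all(c("full_path", "region_path") %in% names(scores)))
  ok <- !is.na(scores$full_path) & !is.na(scores$region_path)
  fused <- rep(NA_real_, nrow(scores))
  fused[ok] <- fuse(scores$full_path[ok], scores$region_path[ok])
  only_full <- !is.na(scores$full_path) & is.na(scores$region_path)
  only_reg <- is.na(scores$full_path) & !is.na(scores$region_path)
  fused[only_full] <- scores$full_path[only_full]
  fused[only_reg] <- scores$region_path[only_reg]
  dplyr::mutate(scores, fused = fused)
}

#' Threshold fused scores into organ labels
#'
#' Applies the strict decision rule: an organ is called unhealthy (1)
#' if and only if its fused probability is strictly greater than the
#' threshold; a score exactly at the threshold maps to healthy (0).
#'
#' @param scores Tibble with a `fused` column (see [fuse_scores()]).
#' @param threshold Decision threshold, default 0.5.
#' @return The tibble with an integer `label` column appended.
#' @export
threshold_labels <- function(scores, threshold = 0.5) {
  stopifnot("fused" %in% names(scores))
  dplyr::mutate(scores, label = as.integer(.data$fused > threshold))
}

#' Predict organ health statuses for a tongue image
#'
#' Convenience wrapper chaining [organ_scores()], [fuse_scores()] and
#' [threshold_labels()] with the model's configured threshold.
#'
#' @param object An `organnet`.
#' @param image An `H` x `W` x 3 image array.
#' @param ... Unused.
#' @return A five-row tibble with per-organ score paths, fused score and
#'   binary `label` (0 healthy, 1 unhealthy).
#' @export
predict.organnet <- function(object, image, ...) {
  organ_scores(object, image) |>
    fuse_scores() |>
    threshold_labels(object$config$threshold)
}

#' Save / load a model checkpoint
#'
#' Single-file serialization with a format version tag.
#'
#' @param model An `organnet`.
#' @param path Checkpoint file path.
#' @return `load_organnet()` returns the model; `save_organnet()`
#'   invisibly returns `path`.
#' @export
save_organnet <- function(model, path) {
  stopifnot(inherits(model, "organnet"))
  saveRDS(list(format = "organnet-checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_organnet
#' @export
load_organnet <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "organnet-checkpoint")) {
    abort("not an organnet checkpoint file")
  }
  x$model
}

#' Read a model configuration from YAML
#'
#' The YAML keys mirror the [organnet_config()] arguments.
#'
#' @param path YAML file path.
#' @return An `organnet_config`.
#' @export
read_organnet_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(organnet_config, y[intersect(names(y), names(formals(organnet_config)))])
}
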