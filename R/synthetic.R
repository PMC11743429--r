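# Synthetic tongue scenes: a pink elliptical tongue body on a neutral
# background, with unhealthy diagnostic features (spots, cracks,
# toothmarks, fur patches, body-color patches) planted strictly inside
# the tongue region that indicates the affected organ. The generator is
# the package's stand-in for clinical data: labels drive rendering, so
# label-feature-region consistency holds by construction and is recorded
# in a per-sample ledger.

#' Per-organ unhealthy prevalences of the reference clinical cohort
#'
#' Marginal probabilities that each organ is labeled unhealthy, taken
#' from the reported label counts of a 4,645-participant tongue-diagnosis
#' cohort (heart 2,103; lung 2,739; liver 2,938; spleen 4,616; kidney
#' 3,111 unhealthy samples). These are the generator defaults, so
#' synthetic cohorts reproduce the strong class imbalance of clinical
#' data (the spleen is almost always flagged, the heart least often).
#'
#' @return Named numeric vector over the five organs, in `[0, 1]`.
#' @export
clinical_prevalences <- function() {
  c(heart = 2103, lung = 2739, liver = 2938, spleen = 4616, kidney = 3111) / 4645
}

#' Cohort recipe: size, label prevalences, splits, seed
#'
#' @param n Number of samples.
#' @param prevalence Named per-organ unhealthy prevalences in `[0, 1]`;
#'   defaults to [clinical_prevalences()].
#' @param split_counts Named integer vector `c(train=, val=, test=)`
#'   summing to `n`. Default: the reference cohort's 75/5/20 proportions,
#'   rounded (train gets the remainder).
#' @param seed Integer master seed; all randomness in label sampling and
#'   rendering derives from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n = 2000L, prevalence = clinical_prevalences(),
                        split_counts = NULL, seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  prevalence <- unlist(prevalence)
  if (is.null(names(prevalence))) names(prevalence) <- ORGANS
  if (!setequal(names(prevalence), ORGANS) ||
      any(prevalence < 0 | prevalence > 1)) {
    abort("`prevalence` must be 5 values in [0, 1] named after the organs")
  }
  if (is.null(split_counts)) {
    val <- round(0.05 * n); test <- round(0.20 * n)
    split_counts <- c(train = n - val - test, val = val, test = test)
  }
  split_counts <- as.integer(split_counts)
  names(split_counts) <- c("train", "val", "test")
  if (sum(split_counts) != n || any(split_counts < 0)) {
    abort("`split_counts` must be non-negative and sum to `n`")
  }
  structure(list(n = n, prevalence = prevalence[ORGANS],
                 split_counts = split_counts, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Study-scale cohort preset
#'
#' The reference cohort geometry: 4,645 samples split 3,455 / 295 / 895
#' (train/val/test) with the clinical prevalences.
#'
#' @param seed Master seed.
#' @return A `cohort_spec`.
#' @export
study_cohort_spec <- function(seed = 1L) {
  cohort_spec(4645L, clinical_prevalences(),
              c(train = 3455L, val = 295L, test = 895L), seed = seed)
}

#' Scene recipe for synthetic tongue rendering
#'
#' Controls image size, tongue-body geometry and color, background,
#' additive noise, and the per-organ menus of plantable unhealthy
#' features. Menus follow the diagnostic region-feature map of TCM
#' tongue inspection: spots and red patches at the tip (heart), spots
#' and fur patches in the front band (lung), toothmarks and spots on the
#' margins (liver), cracks and fur patches in the center (spleen) and at
#' the root (kidney). Heart features are restricted to the lower half of
#' region A (the tip proper) and lung features to its upper half, so the
#' two organs sharing region A remain visually separable.
#'
#' @param size Image side length in pixels (square images), >= 32.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise
#'   (intensity units on `[0, 1]`).
#' @param tongue_color,background Length-3 RGB base colors.
#' @param color_jitter Half-width of per-sample uniform jitter on the
#'   tongue base color.
#' @param features_per_organ Range (length-2 integer) of features planted
#'   per unhealthy organ.
#' @param menus Named list organ -> character vector of feature kinds;
#'   every organ's menu must be non-empty. Kinds: `spot`, `crack`,
#'   `toothmark`, `fur_patch`, `pale_patch`, `red_patch`.
#' @param localized When `TRUE` (default) every feature is planted inside
#'   the region that indicates its organ. `FALSE` is the negative-control
#'   preset: features keep their organ's appearance but land in a region
#'   chosen uniformly at random, so region branches carry no privileged
#'   signal.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(size = 64L, noise_sd = 0.02,
                       tongue_color = c(0.85, 0.57, 0.60),
                       background = c(0.76, 0.78, 0.82),
                       color_jitter = 0.04,
                       features_per_organ = c(1L, 3L),
                       menus = NULL, localized = TRUE) {
  size <- as.integer(size)
  if (size < 32L) abort("`size` must be >= 32")
  if (is.null(menus)) {
    menus <- list(
      heart = c("spot", "red_patch"),
      lung = c("spot", "fur_patch"),
      liver = c("toothmark", "spot"),
      spleen = c("crack", "fur_patch"),
      kidney = c("crack", "pale_patch")
    )
  }
  kinds <- c("spot", "crack", "toothmark", "fur_patch", "pale_patch", "red_patch")
  if (!setequal(names(menus), ORGANS) ||
      any(!vapply(menus, length, 0L)) ||
      !all(unlist(menus) %in% kinds)) {
    abort("`menus` must give every organ a non-empty subset of the feature kinds")
  }
  structure(list(size = size, noise_sd = noise_sd,
                 tongue_color = tongue_color, background = background,
                 color_jitter = color_jitter,
                 features_per_organ = as.integer(features_per_organ),
                 menus = menus[ORGANS], localized = isTRUE(localized)),
            class = "scene_spec")
}

#' Sample per-organ binary labels for a cohort
#'
#' Each organ's labels are independent Bernoulli draws at its configured
#' prevalence (the reported cohort gives marginals only, so organs are
#' sampled independently).
#'
#' @param cohort A [cohort_spec()].
#' @return An `n` x 5 tibble of 0/1 labels in canonical organ order,
#'   reproducible from the cohort seed.
#' @export
sample_labels <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  with_seed(child_seed(cohort$seed, 0L), {
    as_tibble(lapply(cohort$prevalence,
                     function(p) rbinom(cohort$n, 1L, p)))
  })
}

# --- feature renderers -----------------------------------------------------
# Each renderer draws inside a given 1-based inclusive box (r0:r1, c0:c1)
# on img and returns list(img, bbox) with the 0-based half-open bbox of
# what was actually touched.

# runif on a possibly-degenerate interval: midpoint when b <= a.
runif_in <- function(a, b) if (b <= a) (a + b) / 2 else runif(1, a, b)

blend_mask <- function(img, rows, cols, mask, color, alpha = 1) {
  for (ch in 1:3) {
    patch <- img[rows, cols, ch]
    img[rows, cols, ch] <- patch * (1 - alpha * mask) + color[ch] * alpha * mask
  }
  img
}

draw_disc <- function(img, cy, cx, radius, color, alpha = 1) {
  d <- dim(img)
  rows <- max(1L, floor(cy - radius)):min(d[1], ceiling(cy + radius))
  cols <- max(1L, floor(cx - radius)):min(d[2], ceiling(cx + radius))
  mask <- outer(rows, cols, function(r, c) ((r - cy)^2 + (c - cx)^2 <= radius^2) * 1)
  list(img = blend_mask(img, rows, cols, mask, color, alpha),
       rows = range(rows), cols = range(cols))
}

render_spot <- function(img, box) {
  rmax <- min((box$r1 - box$r0) / 2, (box$c1 - box$c0) / 2,
              max(1.5, 0.12 * min(box$r1 - box$r0, box$c1 - box$c0)))
  radius <- runif_in(min(1, rmax), rmax)
  cy <- runif_in(box$r0 + radius, box$r1 - radius)
  cx <- runif_in(box$c0 + radius, box$c1 - radius)
  color <- c(runif(1, 0.25, 0.45), runif(1, 0.02, 0.10), runif(1, 0.10, 0.30))
  out <- draw_disc(img, cy, cx, radius, color)
  list(img = out$img, bbox = c(out$rows[1] - 1L, out$rows[2], out$cols[1] - 1L, out$cols[2]))
}

render_crack <- function(img, box) {
  # jagged dark path: a clamped random walk of unit steps drawn as tiny discs
  len <- max(6L, round(0.8 * (box$r1 - box$r0)))
  r <- runif_in(box$r0 + 1, box$r1 - 1); c <- runif_in(box$c0 + 1, box$c1 - 1)
  color <- c(0.30, 0.12, 0.12)
  rmin <- r; rmax <- r; cmin <- c; cmax <- c
  for (i in seq_len(len)) {
    out <- draw_disc(img, r, c, 0.9, color, alpha = 0.9)
    img <- out$img
    rmin <- min(rmin, out$rows[1]); rmax <- max(rmax, out$rows[2])
    cmin <- min(cmin, out$cols[1]); cmax <- max(cmax, out$cols[2])
    r <- clamp(r + sample(c(-1, 0, 1), 1, prob = c(0.2, 0.2, 0.6)),
               box$r0 + 1, box$r1 - 1)
    c <- clamp(c + sample(c(-1, 0, 1), 1), box$c0 + 1, box$c1 - 1)
  }
  list(img = img, bbox = c(rmin - 1L, rmax, cmin - 1L, cmax))
}

render_patch <- function(img, box, color, alpha) {
  rymax <- min((box$r1 - box$r0) / 2, max(2, 0.35 * (box$r1 - box$r0)))
  rxmax <- min((box$c1 - box$c0) / 2, max(2, 0.35 * (box$c1 - box$c0)))
  ry <- runif_in(min(1.5, rymax), rymax)
  rx <- runif_in(min(1.5, rxmax), rxmax)
  cy <- runif_in(box$r0 + ry, box$r1 - ry)
  cx <- runif_in(box$c0 + rx, box$c1 - rx)
  rows <- max(1L, floor(cy - ry)):min(dim(img)[1], ceiling(cy + ry))
  cols <- max(1L, floor(cx - rx)):min(dim(img)[2], ceiling(cx + rx))
  mask <- outer(rows, cols,
                function(r, c) (((r - cy) / ry)^2 + ((c - cx) / rx)^2 <= 1) * 1)
  img <- blend_mask(img, rows, cols, mask, color, alpha)
  list(img = img,
       bbox = c(rows[1] - 1L, rows[length(rows)], cols[1] - 1L, cols[length(cols)]))
}

render_fur_patch <- function(img, box) {
  render_patch(img, box, c(runif(1, 0.82, 0.95), runif(1, 0.80, 0.92),
                           runif(1, 0.55, 0.75)), alpha = 0.85)
}

render_pale_patch <- function(img, box) {
  render_patch(img, box, c(0.93, 0.85, 0.86), alpha = 0.7)
}

render_red_patch <- function(img, box) {
  render_patch(img, box, c(0.75, 0.12, 0.18), alpha = 0.6)
}

render_toothmark <- function(img, box, edge) {
  # scalloped indentation: dark semicircle centered on the strip's outer edge
  radius <- runif_in(1.5, min((box$r1 - box$r0) / 2,
                              max(2, 0.5 * (box$c1 - box$c0))))
  cy <- runif_in(box$r0 + radius, box$r1 - radius)
  cx <- if (edge == "left") box$c0 else box$c1
  d <- dim(img)
  rows <- max(1L, floor(cy - radius)):min(d[1], ceiling(cy + radius))
  cols <- max(box$c0, floor(cx - radius)):min(box$c1, ceiling(cx + radius))
  mask <- outer(rows, cols, function(r, c) ((r - cy)^2 + (c - cx)^2 <= radius^2) * 1)
  img <- blend_mask(img, rows, cols, mask, c(0.45, 0.28, 0.30), alpha = 0.8)
  list(img = img,
       bbox = c(rows[1] - 1L, rows[length(rows)], cols[1] - 1L, cols[length(cols)]))
}

# Placement boxes (1-based inclusive, with a 1px inset) per organ, derived
# from the partition bounds. Region B gives one box per margin strip.
organ_boxes <- function(bounds) {
  b <- bounds
  half_a <- b$r_tip + ceiling((b$h - b$r_tip) / 2)
  inset <- function(r0, r1, c0, c1) {
    list(r0 = r0 + 1, r1 = r1 - 1, c0 = c0 + 1, c1 = c1 - 1)
  }
  list(
    heart = list(inset(half_a + 1, b$h, 1, b$w)),
    lung = list(inset(b$r_tip + 1, half_a, 1, b$w)),
    liver = list(inset(1, b$r_tip, 1, b$c_left),
                 inset(1, b$r_tip, b$c_right + 1, b$w)),
    spleen = list(inset(b$r_mid + 1, b$r_tip, b$c_left + 1, b$c_right)),
    kidney = list(inset(1, b$r_mid, b$c_left + 1, b$c_right))
  )
}

#' Render one synthetic tongue scene from its labels
#'
#' Draws the tongue body, then for each organ labeled unhealthy plants
#' one or more features from that organ's menu strictly inside the
#' tongue region that indicates it; healthy organs receive no features.
#' Additive Gaussian noise is applied last. Fully deterministic given
#' `(labels, spec, seed)`.
#'
#' @param labels Length-5 named binary vector (or 1-row tibble) of organ
#'   statuses.
#' @param spec A [scene_spec()].
#' @param seed Integer seed for this scene.
#' @return A `labeled_sample`: list with `image` (size x size x 3 array
#'   in `[0, 1]`), `labels`, and `ledger` — a tibble (feature, organ,
#'   region, row0, row1, col0, col1; 0-based half-open bounding boxes of
#'   every planted feature).
#' @export
render_scene <- function(labels, spec = scene_spec(), seed = 1L) {
  stopifnot(inherits(spec, "scene_spec"))
  labels <- check_labels(labels)
  s <- spec$size
  bounds <- region_bounds(s, s)
  boxes <- organ_boxes(bounds)
  with_seed(seed, {
    # background + tongue body
    img <- array(rep(spec$background + runif(3, -0.02, 0.02), each = s * s),
                 c(s, s, 3L))
    base <- clamp(spec$tongue_color +
                    runif(3, -spec$color_jitter, spec$color_jitter), 0, 1)
    cy <- s * 0.52; cx <- s * 0.5
    ry <- s * runif(1, 0.43, 0.47); rx <- s * runif(1, 0.40, 0.45)
    rr <- matrix(seq_len(s), s, s)
    cc <- matrix(seq_len(s), s, s, byrow = TRUE)
    inside <- ((rr - cy) / ry)^2 + ((cc - cx) / rx)^2 <= 1
    shade <- 1 - 0.15 * (((rr - cy) / ry)^2 + ((cc - cx) / rx)^2)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[inside] <- (base[ch] * shade)[inside]
      img[, , ch] <- plane
    }
    ledger <- list()
    for (organ in ORGANS) {
      if (labels[[organ]] != 1) next
      k <- sample(spec$features_per_organ[1]:spec$features_per_organ[2], 1)
      for (j in seq_len(k)) {
        kind <- sample(spec$menus[[organ]], 1)
        if (spec$localized) {
          host <- organ
        } else {
          host <- sample(ORGANS, 1)
          if (kind == "toothmark" && host != "liver") kind <- "spot"
        }
        obox_i <- sample(seq_along(boxes[[host]]), 1)
        box <- boxes[[host]][[obox_i]]
        out <- switch(kind,
          spot = render_spot(img, box),
          crack = render_crack(img, box),
          fur_patch = render_fur_patch(img, box),
          pale_patch = render_pale_patch(img, box),
          red_patch = render_red_patch(img, box),
          toothmark = render_toothmark(
            img, box, edge = if (box$c0 <= bounds$c_left) "left" else "right")
        )
        img <- out$img
        ledger[[length(ledger) + 1L]] <- tibble(
          feature = kind, organ = organ,
          region = unname(ORGAN_REGION[[host]]),
          row0 = out$bbox[1], row1 = out$bbox[2],
          col0 = out$bbox[3], col1 = out$bbox[4])
      }
    }
    if (spec$noise_sd > 0) {
      img <- clamp(img + rnorm(length(img), sd = spec$noise_sd), 0, 1)
    }
    ledger <- if (length(ledger)) dplyr::bind_rows(ledger) else
      tibble(feature = character(), organ = character(), region = character(),
             row0 = numeric(), row1 = numeric(),
             col0 = numeric(), col1 = numeric())
    structure(list(image = img, labels = labels, ledger = ledger),
              class = "labeled_sample")
  })
}

#' Generate a full synthetic cohort
#'
#' Samples labels with [sample_labels()], renders every scene (each with
#' a seed derived from the cohort seed and the sample index), assigns
#' train/val/test splits, and optionally writes PNGs plus a CSV manifest
#' (`filename,heart,lung,liver,spleen,kidney,split`) and per-sample JSON
#' feature ledgers.
#'
#' @param cohort A [cohort_spec()].
#' @param spec A [scene_spec()].
#' @param dir Output directory; when `NULL` images are kept in memory.
#' @param write_ledgers Also write `<stem>_ledger.json` sidecars.
#' @return A list with `manifest` (tibble), and when `dir` is `NULL`,
#'   `samples` (list of `labeled_sample`).
#' @export
generate_cohort <- function(cohort, spec = scene_spec(), dir = NULL,
                            write_ledgers = FALSE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  labels <- as.matrix(sample_labels(cohort))
  split <- rep(names(cohort$split_counts), cohort$split_counts)
  manifest <- dplyr::bind_cols(
    tibble(filename = sprintf("tongue_%05d.png", seq_len(cohort$n))),
    as_tibble(labels), tibble(split = split))
  samples <- NULL
  if (is.null(dir)) {
    samples <- vector("list", cohort$n)
    for (i in seq_len(cohort$n)) {
      samples[[i]] <- render_scene(labels[i, ], spec,
                                   seed = child_seed(cohort$seed, i))
    }
  } else {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(cohort$n)) {
      smp <- render_scene(labels[i, ], spec, seed = child_seed(cohort$seed, i))
      png::writePNG(smp$image, file.path(dir, manifest$filename[i]))
      if (write_ledgers) {
        jsonlite::write_json(
          smp$ledger,
          file.path(dir, sub("\\.png$", "_ledger.json", manifest$filename[i])),
          digits = NA)
      }
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  out <- list(manifest = manifest, cohort = cohort, spec = spec, dir = dir)
  if (!is.null(samples)) out$samples <- samples
  out
}

#' Read a cohort manifest CSV
#'
#' @param path Path to a `manifest.csv` in the generator's schema.
#' @return Tibble with filename, five organ label columns, and split.
#' @export
read_manifest <- function(path) {
  m <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("filename", ORGANS, "split")
  if (!all(need %in% names(m))) {
    abort("manifest must have columns filename, heart, lung, liver, spleen, kidney, split")
  }
  m[need]
}
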