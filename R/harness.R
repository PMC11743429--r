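# Training/evaluation harness. Datasets are materialized once into
# per-branch input tensors (full image + the four region crops, each
# resized to the model input size) so epochs are pure BLAS work.

#' Training configuration
#'
#' @param learning_rate AdamW learning rate (> 0). Default 5e-4.
#' @param batch_size Minibatch size (>= 1). Default 64.
#' @param epochs Number of passes over the training split.
#' @param augment_flip Random horizontal flip augmentation. Flips are
#'   applied to the cached region tensors; column-flipping the
#'   concatenated margin crop is equivalent to flipping the image before
#'   partitioning, so the left/right strip semantics stay consistent.
#' @param gamma,epsilon Asymmetric-loss parameters (see [asl_single()]).
#' @param weight_decay Decoupled weight decay on weight matrices.
#' @param patience Early-stopping patience on validation macro-F1;
#'   `Inf` (default) disables early stopping.
#' @param seed Integer seed governing shuffling and augmentation.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, batch_size = 64L, epochs = 6L,
                         augment_flip = TRUE, gamma = 2, epsilon = 1e-7,
                         weight_decay = 0.01, patience = Inf, seed = 1L) {
  if (!is_scalar_number(learning_rate) || learning_rate < 0) {
    abort("`learning_rate` must be >= 0")
  }
  if (!is_scalar_number(batch_size) || batch_size < 1) {
    abort("`batch_size` must be >= 1")
  }
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), augment_flip = augment_flip,
                 gamma = gamma, epsilon = epsilon,
                 weight_decay = weight_decay, patience = patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Read a training configuration from YAML
#' @param path YAML file whose keys mirror the [train_config()] arguments.
#' @return A `train_config`.
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(train_config, y[intersect(names(y), names(formals(train_config)))])
}

# Build the branch tensors for a list of images. Tensors are stored as
# n x (size*size*3) matrices (row = sample, columns in (row, col,
# channel) column-major order) so minibatch slicing is a cheap row
# subset and the 4-D view is a free reshape.
build_tensors <- function(images, input_size) {
  n <- length(images)
  tensors <- lapply(setNames(c("full", REGIONS), c("full", REGIONS)),
                    function(b) matrix(0, n, input_size * input_size * 3L))
  for (i in seq_len(n)) {
    part <- partition_tongue(images[[i]])
    tensors$full[i, ] <- resize_image(check_image(images[[i]]), input_size)
    for (r in REGIONS) {
      tensors[[r]][i, ] <- resize_image(part[[r]], input_size)
    }
  }
  tensors
}

new_tongue_dataset <- function(tensors, labels, split, manifest, input_size) {
  structure(list(tensors = tensors, labels = labels, split = split,
                 manifest = manifest, n = nrow(labels),
                 input_size = as.integer(input_size)),
            class = "tongue_dataset")
}

#' Retrieve one sample's full image from a dataset
#'
#' @param dataset A `tongue_dataset`.
#' @param i Sample index.
#' @return The cached (resized) full image as a size x size x 3 array.
#' @export
dataset_image <- function(dataset, i) {
  stopifnot(inherits(dataset, "tongue_dataset"), i >= 1, i <= dataset$n)
  s <- dataset$input_size
  img <- dataset$tensors$full[i, ]
  dim(img) <- c(s, s, 3L)
  img
}

#' Materialize a synthetic cohort as a training-ready dataset
#'
#' Renders every scene of the cohort and caches the five branch input
#' tensors (whole image plus region crops, resized to `input_size`)
#' together with the label matrix and split assignment.
#'
#' @param cohort A [cohort_spec()].
#' @param spec A [scene_spec()].
#' @param input_size Branch input side length in pixels.
#' @return A `tongue_dataset`.
#' @export
dataset_from_cohort <- function(cohort, spec = scene_spec(), input_size = 64L) {
  labels <- as.matrix(sample_labels(cohort))
  split <- rep(names(cohort$split_counts), cohort$split_counts)
  images <- vector("list", cohort$n)
  for (i in seq_len(cohort$n)) {
    images[[i]] <- render_scene(labels[i, ], spec,
                                seed = child_seed(cohort$seed, i))$image
  }
  manifest <- dplyr::bind_cols(
    tibble(filename = sprintf("tongue_%05d.png", seq_len(cohort$n))),
    as_tibble(labels), tibble(split = split))
  new_tongue_dataset(build_tensors(images, input_size), labels, split,
                     manifest, input_size)
}

#' Load a dataset from a directory of images plus a manifest
#'
#' Expects the generator's manifest schema
#' (`filename,heart,lung,liver,spleen,kidney,split`); real clinical data
#' drops in with the same manifest.
#'
#' @param dir Directory containing the images and `manifest.csv` (or pass
#'   `manifest` explicitly).
#' @param input_size Branch input side length in pixels.
#' @param manifest Optional manifest tibble (defaults to
#'   `dir/manifest.csv`).
#' @return A `tongue_dataset`.
#' @export
dataset_from_dir <- function(dir, input_size = 64L, manifest = NULL) {
  if (is.null(manifest)) manifest <- read_manifest(file.path(dir, "manifest.csv"))
  images <- lapply(file.path(dir, manifest$filename), read_tongue_image)
  new_tongue_dataset(build_tensors(images, input_size),
                     as.matrix(manifest[ORGANS]), manifest$split, manifest,
                     input_size)
}

#' @export
print.tongue_dataset <- function(x, ...) {
  cat(sprintf("<tongue_dataset> %d samples (%s), input %d px\n", x$n,
              paste(sprintf("%s %d", names(table(x$split)), table(x$split)),
                    collapse = ", "),
              x$input_size))
  invisible(x)
}

dataset_indices <- function(dataset, split) {
  if (is.null(split)) seq_len(dataset$n) else which(dataset$split %in% split)
}

slice_tensors <- function(tensors, branches, idx, size) {
  lapply(setNames(branches, branches), function(b) {
    y <- tensors[[b]][idx, , drop = FALSE]
    dim(y) <- c(length(idx), size, size, 3L)
    y
  })
}

flip_tensor_cols <- function(x, rows) {
  if (!length(rows)) return(x)
  s <- dim(x)[3]
  x[rows, , , ] <- x[rows, , s:1, , drop = FALSE]
  x
}

# Per-branch, per-head loss gradients: returns list(loss, dz per
# branch/region) for probabilities under the asymmetric loss, Eq-style
# normalization 1/n_batch, summed over all supervised head outputs.
batch_loss_grads <- function(model, fw, labels, config) {
  nb <- nrow(labels)
  loss <- 0
  dzs <- list()
  for (b in names(model$branches)) {
    dzs[[b]] <- list()
    for (r in names(model$branches[[b]]$heads)) {
      organs <- REGION_ORGANS[[r]]
      p <- sigmoid(fw$caches[[b]]$heads[[r]]$z)
      y <- labels[, organs, drop = FALSE]
      loss <- loss + sum(asl_single(as.vector(p), as.vector(y),
                                    config$gamma, config$epsilon)) / nb
      dp <- asl_grad(as.vector(p), as.vector(y), config$gamma, config$epsilon) / nb
      dz <- matrix(dp * as.vector(p) * (1 - as.vector(p)), nrow = nb)
      dzs[[b]][[r]] <- dz
    }
  }
  list(loss = loss, dzs = dzs)
}

# One optimizer step on a prepared batch; returns updated params/state/loss.
train_step <- function(model, tensors, labels, config, params, state) {
  fw <- organnet_forward_batch(model, tensors, keep = TRUE)
  lg <- batch_loss_grads(model, fw, labels, config)
  gradtree <- list()
  for (b in names(model$branches)) {
    branch <- model$branches[[b]]
    dfeat <- NULL
    heads_g <- list()
    for (r in names(branch$heads)) {
      hb <- head_backward(branch$heads[[r]], fw$caches[[b]]$heads[[r]],
                          lg$dzs[[b]][[r]])
      heads_g[[r]] <- hb$grads
      dfeat <- if (is.null(dfeat)) hb$dfeat else dfeat + hb$dfeat
    }
    bb_g <- backbone_backward(branch$backbone, fw$caches[[b]]$backbone, dfeat)
    names(bb_g) <- names(branch$backbone)
    gradtree[[b]] <- list(backbone = bb_g, heads = heads_g)
  }
  grads <- collect_grads(gradtree)
  upd <- adamw_step(params, grads, state, lr = config$learning_rate,
                    weight_decay = config$weight_decay)
  list(params = upd$params, state = upd$state, loss = lg$loss)
}

# Gradient trees store dW/db; rename to W/b paths to match organnet_params.
collect_grads <- function(x, path = character()) {
  out <- list()
  for (nm in names(x)) {
    el <- x[[nm]]
    if (nm %in% c("dW", "db")) {
      out[[paste(c(path, sub("^d", "", nm)), collapse = "/")]] <- el
    } else if (is.list(el)) {
      out <- c(out, collect_grads(el, c(path, nm)))
    }
  }
  out
}

#' Train a tongue-diagnosis network
#'
#' Optimizes the asymmetric loss summed over every head output of every
#' branch (each head supervised by its organs' labels; average-voting
#' fusion is used only at inference) with AdamW. Shuffling and flip
#' augmentation derive from the config seed, so runs are reproducible.
#'
#' @param model An `organnet` from [build_organnet()].
#' @param dataset A `tongue_dataset`.
#' @param config A [train_config()].
#' @param split Which split(s) to train on (default `"train"`).
#' @param val_split Split used for early stopping when `patience` is
#'   finite.
#' @return An `organnet_fit`: list with the trained `model` and
#'   `history`, a tibble of per-epoch training loss (and validation
#'   macro-F1 when early stopping is active).
#' @export
train_organnet <- function(model, dataset, config = train_config(),
                           split = "train", val_split = "val") {
  stopifnot(inherits(model, "organnet"), inherits(dataset, "tongue_dataset"),
            inherits(config, "train_config"))
  idx <- dataset_indices(dataset, split)
  if (!length(idx)) abort("training split is empty")
  branches <- names(model$branches)
  params <- organnet_params(model)
  state <- adamw_state(params)
  history <- list()
  best_f1 <- -Inf; bad_epochs <- 0L
  with_seed(child_seed(config$seed, 17L), {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(idx)
      starts <- seq(1L, length(ord), by = config$batch_size)
      epoch_loss <- 0
      for (s0 in starts) {
        bi <- ord[s0:min(s0 + config$batch_size - 1L, length(ord))]
        tensors <- slice_tensors(dataset$tensors, branches, bi,
                                 dataset$input_size)
        if (config$augment_flip) {
          flips <- which(runif(length(bi)) < 0.5)
          tensors <- lapply(tensors, flip_tensor_cols, rows = flips)
        }
        st <- train_step(model, tensors, dataset$labels[bi, , drop = FALSE],
                         config, params, state)
        params <- st$params; state <- st$state
        model$branches <- assign_params(model$branches, params)
        epoch_loss <- epoch_loss + st$loss * length(bi)
      }
      rec <- tibble(epoch = epoch, loss = epoch_loss / length(ord))
      if (is.finite(config$patience)) {
        vr <- evaluate_model(model, dataset, split = val_split)
        rec$val_macro_f1 <- attr(vr, "macro_f1")
        if (rec$val_macro_f1 > best_f1) {
          best_f1 <- rec$val_macro_f1; bad_epochs <- 0L
        } else bad_epochs <- bad_epochs + 1L
      }
      history[[epoch]] <- rec
      if (is.finite(config$patience) && bad_epochs >= config$patience) break
    }
  })
  structure(list(model = model, history = dplyr::bind_rows(history),
                 config = config),
            class = "organnet_fit")
}

#' @export
print.organnet_fit <- function(x, ...) {
  cat(sprintf("<organnet_fit> %d epochs, final loss %.4f\n",
              nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' @exportS3Method generics::tidy
#' @export
tidy.organnet_fit <- function(x, ...) x$history

#' @exportS3Method generics::glance
#' @export
glance.organnet_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history),
         final_loss = x$history$loss[nrow(x$history)])
}

#' Per-sample fused predictions over a dataset
#'
#' Runs forward + fusion + thresholding on every sample of the chosen
#' split(s), in evaluation mode (no augmentation).
#'
#' @param model An `organnet` (or `organnet_fit`).
#' @param dataset A `tongue_dataset`.
#' @param split Split name(s), or `NULL` for all samples.
#' @param threshold Decision threshold (strict `>` rule).
#' @param chunk Samples per forward chunk.
#' @return A tibble with `index`, `organ`, `full_path`, `region_path`,
#'   `fused`, `label` (prediction) and `truth`. Organs not scored by the
#'   model's branches are absent.
#' @export
predict_dataset <- function(model, dataset, split = "test", threshold = 0.5,
                            chunk = 256L) {
  if (inherits(model, "organnet_fit")) model <- model$model
  stopifnot(inherits(model, "organnet"), inherits(dataset, "tongue_dataset"))
  idx <- dataset_indices(dataset, split)
  if (!length(idx)) abort("no samples in the requested split")
  branches <- names(model$branches)
  full <- matrix(NA_real_, length(idx), 5L, dimnames = list(NULL, ORGANS))
  region <- matrix(NA_real_, length(idx), 5L, dimnames = list(NULL, ORGANS))
  for (s0 in seq(1L, length(idx), by = chunk)) {
    rows <- s0:min(s0 + chunk - 1L, length(idx))
    fw <- organnet_forward_batch(
      model, slice_tensors(dataset$tensors, branches, idx[rows],
                           dataset$input_size))
    full[rows, ] <- fw$full
    region[rows, ] <- fw$region
  }
  organs <- branch_organs_of(model)
  purrr::map_dfr(organs, function(o) {
    tibble(index = idx, organ = o,
           full_path = full[, o], region_path = region[, o]) |>
      fuse_scores() |>
      threshold_labels(threshold) |>
      dplyr::mutate(truth = dataset$labels[idx, o])
  })
}

branch_organs_of <- function(model) {
  bs <- names(model$branches)
  if ("full" %in% bs) ORGANS else
    ORGANS[ORGANS %in% unlist(REGION_ORGANS[intersect(bs, REGIONS)])]
}

#' Evaluate a model on a dataset split
#'
#' Forward + average-voting fusion + strict thresholding on every sample,
#' aggregated into per-organ confusion counts and metrics. For
#' single-branch ablation models only the organs the model scores are
#' reported.
#'
#' @inheritParams predict_dataset
#' @return A [metrics_report()] restricted to the organs the model
#'   scores (macro averages are over those organs).
#' @export
evaluate_model <- function(model, dataset, split = "test", threshold = 0.5) {
  preds <- predict_dataset(model, dataset, split = split, threshold = threshold)
  organs <- unique(preds$organ)
  pred_m <- matrix(NA_real_, length(unique(preds$index)), length(organs),
                   dimnames = list(NULL, organs))
  truth_m <- pred_m
  for (o in organs) {
    rows <- preds[preds$organ == o, ]
    pred_m[, o] <- rows$label
    truth_m[, o] <- rows$truth
  }
  report_organs(pred_m, truth_m, organs)
}

# metrics_report generalized to an organ subset.
report_organs <- function(pred, truth, organs) {
  rows <- purrr::map_dfr(seq_along(organs), function(i) {
    cc <- confusion_counts(pred[, i], truth[, i])
    dplyr::bind_cols(tibble(organ = organs[i]), cc,
                     metric_from_counts(cc$tp, cc$tn, cc$fp, cc$fn))
  })
  structure(rows, class = c("metrics_report", class(rows)),
            macro_accuracy = mean(rows$accuracy), macro_f1 = mean(rows$f1))
}

#' Ablation protocol: single branches versus the fused network
#'
#' Trains, under one identical configuration, the whole-image baseline,
#' the four single-region networks, and the full fused network; evaluates
#' each on the test split; and tabulates per-organ accuracy and F1
#' (cells are `NA` where a branch does not predict that organ).
#'
#' @param dataset A `tongue_dataset` with train/val/test splits.
#' @param config A [train_config()]; the same config (and its seed) is
#'   used for every constituent model.
#' @param model_config An [organnet_config()] shared by all variants.
#' @param threshold Decision threshold.
#' @return An `ablation_table`: tibble with one row per method
#'   (`baseline_full`, `region_A` ... `region_D`, `organnet`) and columns
#'   `<organ>_accuracy`, `<organ>_f1`, `macro_accuracy`, `macro_f1`.
#'   The trained fits are attached as attribute `fits`.
#' @export
run_ablation <- function(dataset, config = train_config(),
                         model_config = organnet_config(), threshold = 0.5) {
  variants <- list(baseline_full = "full", region_A = "A", region_B = "B",
                   region_C = "C", region_D = "D",
                   organnet = c("full", REGIONS))
  fits <- list()
  rows <- purrr::imap_dfr(variants, function(branches, nm) {
    model <- build_organnet(model_config, branches = branches,
                            seed = child_seed(config$seed, 101L))
    fit <- train_organnet(model, dataset, config)
    fits[[nm]] <<- fit
    rep <- evaluate_model(fit$model, dataset, threshold = threshold)
    row <- tibble(method = nm)
    for (o in ORGANS) {
      hit <- rep$organ == o
      row[[paste0(o, "_accuracy")]] <- if (any(hit)) rep$accuracy[hit] else NA_real_
      row[[paste0(o, "_f1")]] <- if (any(hit)) rep$f1[hit] else NA_real_
    }
    row$macro_accuracy <- attr(rep, "macro_accuracy")
    row$macro_f1 <- attr(rep, "macro_f1")
    row
  })
  structure(rows, class = c("ablation_table", class(rows)), fits = fits)
}
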