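# Shared fixtures, all generated in code.

ORGANS5 <- c("heart", "lung", "liver", "spleen", "kidney")

make_test_image <- function(h, w, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3), c(h, w, 3)))
}

# Independent binary cross-entropy oracle (kept separate from asl_single).
bce_oracle <- function(p, y, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# Brute-force confusion/metrics oracle using table-style counting.
metrics_oracle <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1); tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0); fn <- sum(pred == 0 & truth == 1)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(tp = tp, tn = tn, fp = fp, fn = fn,
       accuracy = (tp + tn) / length(pred), precision = prec, recall = rec,
       f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

# Small balanced dataset for harness tests, built once per test run.
.tiny_env <- new.env()
tiny_dataset <- function() {
  if (is.null(.tiny_env$ds)) {
    co <- cohort_spec(n = 96, prevalence = rep(0.5, 5),
                      split_counts = c(train = 64, val = 8, test = 24),
                      seed = 42)
    .tiny_env$ds <- dataset_from_cohort(co, scene_spec(), 64)
  }
  .tiny_env$ds
}

# Set every head's output layer to constants (used to pin probabilities).
set_head_outputs <- function(model, weight = 0, bias = 0) {
  for (b in names(model$branches)) {
    for (r in names(model$branches[[b]]$heads)) {
      h <- model$branches[[b]]$heads[[r]]
      h$fc2$W[] <- weight
      h$fc2$b[] <- bias
      model$branches[[b]]$heads[[r]] <- h
    }
  }
  model
}
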