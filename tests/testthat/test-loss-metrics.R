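test_that("asymmetric loss matches hand-evaluated reference points", {
  expect_lt(asl_single(1, 1, gamma = 2), 1e-6)
  expect_lt(asl_single(0, 0, gamma = 2), 1e-6)
  expect_equal(asl_single(0.5, 1, gamma = 0), log(2), tolerance = 1e-9)
  expect_equal(asl_single(0.5, 1, gamma = 2), 0.25 * log(2), tolerance = 1e-9)
  expect_equal(asl_single(0.5, 0, gamma = 2), 0.25 * log(2), tolerance = 1e-9)
  expect_error(asl_single(1.5, 1), "\\[0, 1\\]")
  expect_error(asl_single(0.5, 2), "binary")
  expect_error(asl_single(0.5, 1, gamma = -1), "gamma")
})

test_that("gamma = 0 recovers binary cross-entropy on a fine grid", {
  p <- seq(1e-6, 1 - 1e-6, length.out = 1000)
  for (y in c(0, 1)) {
    expect_equal(asl_single(p, rep(y, 1000), gamma = 0),
                 bce_oracle(p, rep(y, 1000)), tolerance = 1e-9)
  }
})

test_that("loss is monotone in p and non-negative", {
  p <- seq(0.001, 0.999, length.out = 2000)
  l1 <- asl_single(p, rep(1, length(p)), gamma = 2)
  l0 <- asl_single(p, rep(0, length(p)), gamma = 2)
  expect_true(all(diff(l1) < 0))   # decreasing for unhealthy truth
  expect_true(all(diff(l0) > 0))   # increasing for healthy truth
  expect_true(all(l1 >= 0) && all(l0 >= 0))
})

test_that("the analytic loss gradient matches finite differences", {
  withr::with_seed(3, {
    p <- runif(40, 0.02, 0.98)
    y <- rbinom(40, 1, 0.5)
  })
  eps <- 1e-6
  num <- (asl_single(p + eps, y) - asl_single(p - eps, y)) / (2 * eps)
  expect_equal(tonguenet:::asl_grad(p, y), num, tolerance = 1e-5)
})

test_that("batch loss is the per-sample mean of organ sums", {
  expect_equal(asl_batch(matrix(1, 1, 5), matrix(1, 1, 5)), 0,
               tolerance = 1e-6)
  withr::with_seed(7, {
    probs <- matrix(runif(15), 3, 5)
    labels <- matrix(rbinom(15, 1, 0.5), 3, 5)
  })
  # double-loop oracle
  acc <- 0
  for (j in 1:3) for (i in 1:5) {
    acc <- acc + asl_single(probs[j, i], labels[j, i])
  }
  expect_equal(asl_batch(probs, labels), acc / 3, tolerance = 1e-12)
  # duplicated rows leave the mean unchanged
  expect_equal(asl_batch(probs[c(1, 1), ], labels[c(1, 1), ]),
               asl_batch(probs[1, , drop = FALSE], labels[1, , drop = FALSE]))
  # concatenation is the sample-count-weighted mean of the parts
  a <- asl_batch(probs[1:2, ], labels[1:2, ])
  b <- asl_batch(probs[3, , drop = FALSE], labels[3, , drop = FALSE])
  expect_equal(asl_batch(probs, labels), (2 * a + 1 * b) / 3)
  expect_error(asl_batch(probs, labels[1:2, ]), "shape")
})

test_that("confusion counts follow the unhealthy-positive convention", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unlist(cc), c(tp = 2, tn = 2, fp = 0, fn = 0))
  cc2 <- confusion_counts(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                          c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0))
  expect_equal(unlist(cc2), c(tp = 3, tn = 4, fp = 1, fn = 2))
  expect_error(confusion_counts(integer(0), integer(0)), "zero samples")
  expect_error(confusion_counts(c(1, 0), c(1)), "lengths")
})

test_that("metric formulas reproduce the worked example", {
  counts <- tibble::tibble(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_equal(accuracy(counts), 0.7)
  expect_equal(precision(counts), 0.75)
  expect_equal(recall(counts), 0.6)
  expect_equal(f1_score(counts), 2 * 0.75 * 0.6 / 1.35)
  perfect <- tibble::tibble(tp = 5, tn = 5, fp = 0, fn = 0)
  expect_equal(c(accuracy(perfect), precision(perfect), recall(perfect),
                 f1_score(perfect)), rep(1, 4))
  # zero-denominator convention
  none <- tibble::tibble(tp = 0, tn = 3, fp = 0, fn = 2)
  expect_equal(precision(none), 0)
  expect_equal(f1_score(none), 0)
  expect_error(accuracy(tibble::tibble(tp = 0, tn = 0, fp = 0, fn = 0)),
               "zero")
})

test_that("metrics agree with a brute-force oracle on random vectors", {
  withr::with_seed(11, {
    for (rep in 1:50) {
      n <- sample(5:40, 1)
      pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
      truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
      o <- metrics_oracle(pred, truth)
      cc <- confusion_counts(pred, truth)
      expect_equal(unlist(cc), unlist(o[c("tp", "tn", "fp", "fn")]))
      expect_equal(accuracy(cc), o$accuracy)
      expect_equal(precision(cc), o$precision)
      expect_equal(recall(cc), o$recall)
      expect_equal(f1_score(cc), o$f1)
    }
  })
})

test_that("the report aggregates per organ with unweighted macro means", {
  withr::with_seed(13, {
    pred <- matrix(rbinom(100, 1, 0.5), 20, 5)
    truth <- matrix(rbinom(100, 1, 0.6), 20, 5)
  })
  rep <- metrics_report(pred, truth)
  expect_equal(rep$organ, ORGANS5)
  expect_equal(attr(rep, "macro_f1"), mean(rep$f1))
  expect_equal(attr(rep, "macro_accuracy"), mean(rep$accuracy))
  g <- glance(rep)
  expect_equal(g$macro_f1, mean(rep$f1))
  expect_s3_class(tidy(rep), "tbl_df")
  # serialization round trips
  csv <- withr::local_tempfile(fileext = ".csv")
  write_metrics(rep, csv)
  back <- read.csv(csv)
  expect_equal(back$f1, rep$f1)
  js <- withr::local_tempfile(fileext = ".json")
  write_metrics(rep, js)
  jj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(jj$macro_f1, attr(rep, "macro_f1"))
})
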