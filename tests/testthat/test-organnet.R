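cfg_small <- organnet_config(widths = c(6L, 8L), head_hidden = 8L)

test_that("branches hold disjoint parameter sets with ten scalar outputs", {
  m <- build_organnet(organnet_config(), seed = 1)
  params <- organnet_params(m)
  expect_false(any(duplicated(names(params))))
  # every branch owns its own arrays: modifying one leaves others untouched
  prefixes <- unique(sub("/.*", "", names(params)))
  expect_setequal(prefixes, c("full", "A", "B", "C", "D"))
  # head output widths: full path 2+1+1+1, region paths 2,1,1,1 -> 10
  out_dims <- integer()
  for (b in names(m$branches)) {
    for (r in names(m$branches[[b]]$heads)) {
      out_dims <- c(out_dims, length(m$branches[[b]]$heads[[r]]$fc2$b))
    }
  }
  expect_identical(sum(out_dims), 10L)
  expect_error(organnet_config(backbone = "resnet101"), "unknown backbone")
})

test_that("construction is deterministic given a seed", {
  m1 <- build_organnet(cfg_small, seed = 11)
  m2 <- build_organnet(cfg_small, seed = 11)
  expect_identical(organnet_params(m1), organnet_params(m2))
  m3 <- build_organnet(cfg_small, seed = 12)
  expect_false(identical(organnet_params(m1), organnet_params(m3)))
})

test_that("forward returns five probability pairs, deterministically", {
  m <- build_organnet(cfg_small, seed = 3)
  img <- render_scene(c(heart = 1, lung = 0, liver = 0, spleen = 1,
                        kidney = 0), scene_spec(), seed = 4)$image
  sc <- organ_scores(m, img)
  expect_equal(sc$organ, ORGANS5)
  expect_true(all(sc$full_path >= 0 & sc$full_path <= 1))
  expect_true(all(sc$region_path >= 0 & sc$region_path <= 1))
  expect_identical(sc, organ_scores(m, img))
})

test_that("zeroed output layers give probability one-half everywhere", {
  m <- set_head_outputs(build_organnet(cfg_small, seed = 5), 0, 0)
  img <- make_test_image(64, 64, seed = 6)
  sc <- organ_scores(m, img)
  expect_equal(sc$full_path, rep(0.5, 5))
  expect_equal(sc$region_path, rep(0.5, 5))
})

test_that("fusion is the two-way arithmetic mean with domain checks", {
  expect_equal(fuse(0.6, 0.8), 0.7)
  expect_equal(fuse(0.0, 1.0), 0.5)
  for (p in c(0, 0.25, 0.5, 1)) expect_equal(fuse(p, p), p)
  # symmetry and boundedness on random pairs
  withr::with_seed(1, {
    a <- runif(50); b <- runif(50)
    expect_equal(fuse(a, b), fuse(b, a))
    expect_true(all(fuse(a, b) >= pmin(a, b) & fuse(a, b) <= pmax(a, b)))
  })
  expect_error(fuse(1.2, 0.5), "probabilities")
  expect_error(fuse(0.5, -0.1), "probabilities")
})

test_that("the decision rule is strictly greater-than the threshold", {
  sc <- tibble::tibble(fused = c(0.7, 0.4, 0.5, 0.51, 0.0))
  expect_equal(threshold_labels(sc, 0.5)$label, c(1L, 0L, 0L, 1L, 0L))
  expect_equal(threshold_labels(tibble::tibble(fused = rep(1, 5)))$label,
               rep(1L, 5))
  expect_equal(threshold_labels(tibble::tibble(fused = c(0.01, 0.9)), 0)$label,
               c(1L, 1L))
})

test_that("each region branch feeds only its organs' region scores", {
  m <- build_organnet(cfg_small, seed = 7)
  img <- render_scene(c(heart = 0, lung = 0, liver = 0, spleen = 0,
                        kidney = 0), scene_spec(), seed = 8)$image
  tensors <- tonguenet:::image_tensors(img, 64, names(m$branches))
  base <- tonguenet:::organnet_forward_batch(m, tensors)
  for (reg in c("A", "B", "C", "D")) {
    t2 <- tensors
    t2[[reg]] <- t2[[reg]] + 0.1
    fw <- tonguenet:::organnet_forward_batch(m, t2)
    affected <- list(A = c("heart", "lung"), B = "liver", C = "spleen",
                     D = "kidney")[[reg]]
    expect_false(any(fw$region[, affected] == base$region[, affected]))
    others <- setdiff(ORGANS5, affected)
    expect_identical(fw$region[, others], base$region[, others])
    expect_identical(fw$full, base$full)
  }
})

test_that("predict chains scores, fusion and thresholding", {
  m <- build_organnet(cfg_small, seed = 9)
  img <- make_test_image(64, 64, seed = 10)
  out <- predict(m, img)
  expect_equal(out$fused, (out$full_path + out$region_path) / 2)
  expect_equal(out$label, as.integer(out$fused > 0.5))
})

test_that("checkpoints and YAML configs round-trip", {
  m <- build_organnet(cfg_small, seed = 13)
  path <- withr::local_tempfile(fileext = ".rds")
  save_organnet(m, path)
  m2 <- load_organnet(path)
  expect_identical(organnet_params(m), organnet_params(m2))
  not_ckpt <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), not_ckpt)
  expect_error(load_organnet(not_ckpt), "checkpoint")
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("input_size: 64", "head_hidden: 16", "threshold: 0.4"), ypath)
  cfg <- read_organnet_config(ypath)
  expect_equal(cfg$head_hidden, 16L)
  expect_equal(cfg$threshold, 0.4)
})
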