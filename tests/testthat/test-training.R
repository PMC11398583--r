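mk_samples <- function(labels) {
  lapply(labels, function(l) list(class_label = l))
}

test_that("stratified split keeps class proportions and is deterministic", {
  labels <- c(rep("full", 81), rep("partial", 14), rep("empty", 5))
  samples <- mk_samples(labels)
  sp <- stratified_split(samples, c(0.8, 0.1, 0.1), seed = 4)
  # split sizes within one sample per class of the proportional targets
  expect_lte(abs(length(sp$train) - 80L), 2L)
  expect_lte(abs(length(sp$val) - 10L), 2L)
  expect_lte(abs(length(sp$test) - 10L), 2L)
  expect_identical(length(sp$train) + length(sp$val) + length(sp$test), 100L)
  # disjoint, exhaustive
  idx <- attr(sp, "indices")
  expect_identical(sort(unlist(idx)), seq_along(samples))
  # per-class counts within 1 of the proportional target in every split
  for (j in 1:3) {
    cnt <- table(vapply(sp[[j]], function(s) s$class_label, ""))
    for (cl in names(cnt)) {
      target <- sum(labels == cl) * c(0.8, 0.1, 0.1)[j]
      expect_lte(abs(cnt[[cl]] - target), 1)
    }
  }
  sp2 <- stratified_split(samples, c(0.8, 0.1, 0.1), seed = 4)
  expect_identical(attr(sp2, "indices"), idx)
  all_train <- stratified_split(samples, c(1, 0, 0), seed = 1)
  expect_length(all_train$train, 100L)
  expect_length(all_train$val, 0L)
})

test_that("flips are involutions that preserve mask area; labels never change", {
  planes <- array(stats::runif(20 * 12 * 3), c(20, 12, 3))
  mask <- matrix(stats::runif(20 * 12) > 0.7, 20, 12)
  s <- list(input = planes, mask = mask, class_label = "full")
  cfg <- train_config(augment_rotate = FALSE, augment_contrast = FALSE)
  flipped_twice <- planes[, 12:1, , drop = FALSE][, 12:1, , drop = FALSE]
  expect_identical(flipped_twice, planes)
  a <- augment(s, cfg, seed = 2)
  expect_identical(sum(a$mask), sum(mask))
  expect_identical(a$class_label, "full")
  # rotation by zero degrees is the identity
  expect_identical(wormchip:::rotate_nn(planes[, , 1], 0), planes[, , 1])
  cfg2 <- train_config(augment_flip = FALSE, augment_contrast = FALSE,
                       max_rot_deg = 0)
  a2 <- augment(s, cfg2, seed = 3)
  expect_identical(a2$input, planes)
})

test_that("the joint loss obeys its closed forms and masking rules", {
  H <- 8L; W <- 8L
  mask <- matrix(FALSE, H, W); mask[3:6, 3:6] <- TRUE
  perfect <- array(0, c(H, W, 2))
  perfect[, , 2][mask] <- 1
  perfect[, , 1][!mask] <- 1
  out_perfect <- structure(list(
    seg_probs = perfect,
    class_probs = c(full = 1, partial = 0, empty = 0),
    seg_logits = NULL, class_logits = NULL), class = "model_output")
  l <- net_loss(out_perfect, list(class_label = "full", mask = mask))
  expect_equal(l$total, 0, tolerance = 1e-6)
  # empty-channel sample: segmentation contributes exactly zero
  out_uniform <- structure(list(
    seg_probs = array(0.5, c(H, W, 2)),
    class_probs = c(full = 1 / 3, partial = 1 / 3, empty = 1 / 3),
    seg_logits = NULL, class_logits = NULL), class = "model_output")
  le <- net_loss(out_uniform, list(class_label = "empty"))
  expect_identical(le$seg, 0)
  expect_equal(le$cls, log(3), tolerance = 1e-9)
  expect_error(net_loss(out_uniform, list(class_label = "full")),
               "without a mask")
})

test_that("decoder gradients are exactly zero without full-worm samples", {
  net <- net_init(tiny_net_config(), c(32L, 32L), seed = 1)
  x <- array(stats::rnorm(32 * 32 * 3), c(32, 32, 3))
  out <- net_forward(net, x, want_cache = TRUE)
  ls <- net_loss(out, list(class_label = "empty"), want_grads = TRUE)
  g <- net_backward(net, out$cache, ls$dseg_logits, ls$dcls_logits)
  dec_norm <- sum(abs(unlist(g$dec))) + sum(abs(unlist(g$head))) +
    sum(abs(unlist(g$dproj)))
  expect_identical(dec_norm, 0)
  # but classification gradients do reach the encoder
  expect_gt(sum(abs(unlist(g$stem))), 0)
})

test_that("warm restarts happen at the closed-form epochs", {
  cfg <- train_config(W0 = 10, F_mult = 2, lr0 = 2e-4)
  expect_identical(restart_epochs(cfg, 5L), c(0, 10, 30, 70, 150))
  expect_equal(lr_schedule(0, cfg), 2e-4)
  # just before a restart the rate is at the floor; at the restart, back at lr0
  expect_equal(lr_schedule(9.999, cfg), cfg$lr_min, tolerance = 1e-4)
  for (r in c(10, 30, 70, 150))
    expect_equal(lr_schedule(r, cfg), cfg$lr0)
  # one-cycle peaks at max_lr
  oc <- train_config(scheduler = "one_cycle", epochs = 100L, max_lr = 1e-3,
                     warmup_frac = 0.3)
  expect_equal(lr_schedule(30, oc), 1e-3)
  expect_lt(lr_schedule(99, oc), 1e-5)
})

test_that("zero-epoch training returns the initial weights; seeds reproduce
           histories", {
  net <- net_init(tiny_net_config(), c(32L, 32L), seed = 1)
  scn <- tiny_scene(fov_height_px = 32L, pixel_size_um = 8)
  samples <- make_labeled_channels(2, scn, seed = 3, target_width = 32L,
                                   classes = c("full", "empty"),
                                   width_frac = 0.2)
  cfg0 <- train_config(epochs = 0L, batch_size = 2L)
  fit0 <- train_model(net, list(train = samples), cfg0)
  expect_identical(fit0$model$params, net$params)
  cfg2 <- train_config(epochs = 2L, batch_size = 2L, lr0 = 1e-3, seed = 8,
                       augment_rotate = FALSE)
  h1 <- train_model(net, list(train = samples), cfg2)$history
  h2 <- train_model(net, list(train = samples), cfg2)$history
  expect_identical(h1, h2)
})

test_that("few-shot corpus mixes equal counts and validates inputs", {
  net <- net_init(tiny_net_config(), c(32L, 32L), seed = 1)
  scn <- tiny_scene(fov_height_px = 32L, pixel_size_um = 8)
  new_s <- make_labeled_channels(4, scn, seed = 5, target_width = 32L,
                                 classes = rep("full", 4), width_frac = 0.2)
  old_s <- make_labeled_channels(4, scn, seed = 9, target_width = 32L,
                                 classes = rep("full", 4), width_frac = 0.2)
  expect_identical(finetune_few_shot(net, new_s, old_s, 0L), net)
  expect_error(finetune_few_shot(net, new_s, old_s[1:2], 4L), "equal mixing")
  expect_error(finetune_few_shot(net, new_s, old_s, 10L), "exceeds")
  cfg <- train_config(scheduler = "one_cycle", epochs = 1L, batch_size = 8L,
                      max_lr = 1e-4, seed = 2, augment_rotate = FALSE)
  ft <- finetune_few_shot(net, new_s, old_s, 2L, cfg)
  expect_s3_class(ft, "wormnet")
  expect_false(identical(ft$params, net$params))
})
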