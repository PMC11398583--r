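test_that("binarize thresholds at 0.50 with ties as foreground and strips padding", {
  probs <- matrix(c(0.4, 0.6, 0.5, 0.1), 2, 2)
  m <- binarize(probs, pixel_size_um = 1)
  expect_identical(m$grid, matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2))
  expect_false(any(binarize(matrix(0, 3, 3), pixel_size_um = 1)$grid))
  inp <- structure(list(pad_left = 2L, pad_right = 1L, pixel_size_um = 1),
                   class = "input_tensor")
  wide <- matrix(1, 4, 7)
  cropped <- binarize(wide, input = inp)
  expect_identical(ncol(cropped$grid), 4L)
  expect_error(binarize(matrix(1.5, 2, 2)), "0, 1")
})

test_that("component filtering keeps only the single largest object", {
  g <- matrix(FALSE, 120, 120)
  g[10:109, 10:109] <- TRUE              # 10,000 px blob
  g[1:5, 115:119] <- TRUE                # specks
  g[115:119, 1:5] <- TRUE
  m <- filter_components(new_binary_mask(g, 1), min_area_px = 500)
  expect_identical(sum(m$grid), 10000L)
  # two blobs: largest-only rule
  g2 <- matrix(FALSE, 80, 80)
  g2[1:30, 1:30] <- TRUE   # 900
  g2[50:79, 40:69][1:800] <- TRUE
  m2 <- filter_components(new_binary_mask(g2, 1), min_area_px = 100)
  oracle <- oracle_largest_component(g2)
  expect_identical(m2$grid, oracle)
  expect_identical(sum(m2$grid), 900L)
  # empty in, empty + flagged out
  me <- filter_components(new_binary_mask(matrix(FALSE, 5, 5), 1), 10)
  expect_identical(me$qc_flags, "no_worm_detected")
  mu <- filter_components(new_binary_mask(g2, 1), min_area_px = 5000)
  expect_identical(mu$qc_flags, "no_worm_detected")
})

test_that("skeleton length: bar geometry, degenerate masks, and worm accuracy", {
  bar <- matrix(FALSE, 220, 20)
  bar[11:210, 6:15] <- TRUE
  bm <- new_binary_mask(bar, 1)
  len <- skeleton_length(bm)
  expect_gte(len, 185)
  expect_lte(len, 200)
  single <- new_binary_mask(matrix(c(TRUE, rep(FALSE, 24)), 5, 5), 1)
  expect_identical(skeleton_length(single), 0)
  expect_error(skeleton_length(new_binary_mask(matrix(FALSE, 5, 5), 1)),
               "empty")
  # sinuous synthetic worms: within 3% of the generated arc length
  scn <- tiny_scene(fov_height_px = 512L, pixel_size_um = 2)
  for (sd in 1:4) {
    w <- make_worm(600, max_width_um = 40, sinuosity = 0.4,
                   channel_width_um = 150, seed = sd)
    m <- filter_components(rasterize_worm(w, scn), 100)
    expect_lt(abs(skeleton_length(m) - w$arc_length_um) / w$arc_length_um,
              0.03)
  }
})

test_that("raw skeleton geodesics match the brute-force all-pairs oracle", {
  shapes <- list(
    {g <- matrix(FALSE, 30, 30); g[5:25, 10:14] <- TRUE; g},
    {g <- matrix(FALSE, 32, 32); g[5:27, 5:9] <- TRUE; g[23:27, 5:28] <- TRUE; g},
    random_blob_mask(24, 24, n_seeds = 1, grow = 120, seed = 3))
  for (g in shapes) {
    g <- oracle_largest_component(g)
    skel <- wormchip:::skeletonize_mask(g)
    if (sum(skel) < 2) next
    impl <- skeleton_length(new_binary_mask(g, 1), smooth = FALSE)
    expect_equal(impl, oracle_longest_geodesic(skel), tolerance = 1e-9)
  }
})

test_that("area and volume follow their arithmetic and scaling laws", {
  g <- matrix(FALSE, 20, 20)
  g[1:10, 1:10] <- TRUE
  expect_equal(body_area(new_binary_mask(g, 0.5)), 25)
  expect_equal(body_area(new_binary_mask(matrix(FALSE, 3, 3), 0.5)), 0)
  # scale equivariance: doubling the pixel doubles length, quadruples area
  bar <- matrix(FALSE, 60, 11); bar[6:55, 4:8] <- TRUE
  m1 <- new_binary_mask(bar, 1); m2 <- new_binary_mask(bar, 2)
  expect_equal(body_area(m2), 4 * body_area(m1))
  expect_equal(skeleton_length(m2), 2 * skeleton_length(m1))
  # dilation never decreases area or volume
  dil <- EBImage::dilate(bar * 1, EBImage::makeBrush(3, "box")) > 0
  geom <- channel_geometry(boundaries_um = c(0, 200), heights_um = 10)
  expect_gte(body_area(new_binary_mask(dil, 1)), body_area(m1))
  expect_gte(body_volume(new_binary_mask(dil, 1), geom),
             body_volume(m1, geom))
})

test_that("volume uses the piecewise channel-height lookup", {
  geom1 <- channel_geometry(boundaries_um = c(0, 1000), heights_um = 20)
  g <- matrix(FALSE, 100, 40); g[11:60, 11:30] <- TRUE  # 1000 px
  m <- new_binary_mask(g, 1)
  expect_equal(body_volume(m, geom1), body_area(m) * 20)
  # 60% of the area in a 30-um layer, 40% in a 20-um layer
  geom2 <- channel_geometry(boundaries_um = c(0, 40.5, 1000),
                            heights_um = c(30, 20))
  # rows 11..40 (30 rows, 600 px) in layer 1; rows 41..60 (400 px) in layer 2
  expect_equal(body_volume(m, geom2), 0.6 * 1000 * 30 + 0.4 * 1000 * 20)
  expect_equal(body_volume(new_binary_mask(matrix(FALSE, 5, 5), 1), geom1), 0)
  expect_error(body_volume(m, geom1, channel_origin_um = 990), "outside")
  expect_error(channel_geometry(boundaries_um = c(0, 10, 5),
                                heights_um = c(30, 20)), "increasing")
  expect_error(channel_geometry(boundaries_um = c(0, 10, 20),
                                heights_um = c(20, 30)), "decreasing")
})

test_that("near-perfect soft segmentations reproduce generator phenotypes", {
  scn <- tiny_scene(fov_height_px = 512L, pixel_size_um = 2)
  w <- make_worm(620, max_width_um = 45, channel_width_um = 150, seed = 6)
  truth <- rasterize_worm(w, scn)
  soft <- array(0, c(dim(truth$grid), 2))
  soft[, , 2] <- ifelse(truth$grid, 0.95, 0.05)
  soft[, , 1] <- 1 - soft[, , 2]
  m <- filter_components(binarize(soft, pixel_size_um = 2), 100)
  geom <- channel_geometry("3L")
  expect_lt(abs(skeleton_length(m) - w$arc_length_um) / w$arc_length_um, 0.05)
  expect_lt(abs(body_area(m) - body_area(truth)) / body_area(truth), 0.05)
  expect_lt(abs(body_volume(m, geom) - body_volume(truth, geom)) /
              body_volume(truth, geom), 0.05)
  # self ratios are exactly 1
  expect_identical(length_ratio(truth, truth), 1)
  expect_identical(volume_ratio(truth, truth, geom), 1)
})
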