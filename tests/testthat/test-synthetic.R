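test_that("make_worm hits the requested arc length and is deterministic", {
  w <- make_worm(1000, max_width_um = 60, sinuosity = 0.5,
                 channel_width_um = 150, seed = 7)
  poly_len <- sum(sqrt(diff(w$centerline[, 1])^2 + diff(w$centerline[, 2])^2))
  expect_lt(abs(poly_len - 1000) / 1000, 0.005)
  expect_equal(w$arc_length_um, poly_len)
  w2 <- make_worm(1000, max_width_um = 60, sinuosity = 0.5,
                  channel_width_um = 150, seed = 7)
  expect_identical(w, w2)
  expect_error(make_worm(500, max_width_um = 200, channel_width_um = 150),
               "does not fit")
})

test_that("zero-sinuosity worms are straight and vertical", {
  scn <- tiny_scene()
  w <- make_worm(300, max_width_um = 40, sinuosity = 0,
                 channel_width_um = 150, seed = 3)
  expect_equal(diff(range(w$centerline[, "x"])), 0)
  m <- rasterize_worm(w, scn)
  rows <- range(which(rowSums(m$grid) > 0))
  bbox_h <- diff(rows) + 1
  expect_lt(abs(bbox_h - 300 / scn$pixel_size_um) / (300 / scn$pixel_size_um), 0.1)
})

test_that("rasterization area matches the analytic capsule", {
  scn <- tiny_scene(fov_height_px = 512L, pixel_size_um = 2)
  w <- make_worm(400, max_width_um = 30, sinuosity = 0, taper = FALSE,
                 channel_width_um = 150, seed = 1)
  m <- rasterize_worm(w, scn)
  area <- sum(m$grid) * scn$pixel_size_um^2
  expect_lt(abs(area - 400 * 30) / (400 * 30), 0.05)
})

test_that("truncated worms touch a channel end; empty specs give empty masks", {
  scn <- tiny_scene()
  w <- make_worm(300, max_width_um = 40, channel_width_um = 150,
                 truncated = TRUE, seed = 4)
  m <- rasterize_worm(w, scn)
  expect_true(any(m$grid[1, ]) || any(m$grid[nrow(m$grid), ]))
  m0 <- rasterize_worm(NULL, scn)
  expect_false(any(m0$grid))
})

test_that("brightfield focus is recoverable and rendering is deterministic", {
  scn <- tiny_scene()
  w <- make_worm(280, max_width_um = 42, channel_width_um = 150, seed = 5)
  m <- rasterize_worm(w, scn)
  for (sd in c(5L, 6L)) {
    st <- render_channel_stack(m, w, scn, seed = sd)
    expect_identical(best_focal_plane(st), scn$focus_z)
  }
  s1 <- render_channel_stack(m, w, scn, seed = 9)
  s2 <- render_channel_stack(m, w, scn, seed = 9)
  expect_identical(s1$volume, s2$volume)
  # no noise, no blur: every z-slice identical
  scn0 <- tiny_scene(noise_sd = 0, blur_per_um = 0)
  st0 <- render_channel_stack(m, w, scn0, seed = 1)
  expect_equal(st0$volume[1, 1, , ], st0$volume[1, scn0$n_z, , ])
})

test_that("make_fov composes channels with consistent sidecar ground truth", {
  scn <- tiny_scene()
  specs <- list(make_worm(280, 40, channel_width_um = 150, seed = 1),
                NULL,
                make_worm(250, 38, channel_width_um = 150, truncated = TRUE,
                          seed = 2),
                make_worm(300, 42, channel_width_um = 150, seed = 3),
                NULL,
                make_worm(260, 40, channel_width_um = 150, seed = 6),
                make_worm(290, 40, channel_width_um = 150, seed = 7),
                make_worm(310, 44, channel_width_um = 150, seed = 8))
  fov <- make_fov(specs, scn, seed = 3)
  labels <- vapply(fov$ground_truth, function(g) g$class, "")
  expect_identical(labels, c("full", "empty", "partial", "full", "empty",
                             "full", "full", "full"))
  # label consistency with mask geometry
  for (g in fov$ground_truth) {
    touches <- any(g$mask$grid[1, ]) || any(g$mask$grid[nrow(g$mask$grid), ])
    if (g$class == "full") expect_true(any(g$mask$grid) && !touches)
    if (g$class == "partial") expect_true(touches)
    if (g$class == "empty") expect_false(any(g$mask$grid))
  }
  expect_error(make_fov(specs[1:5], scn), "expected 8")
})

test_that("sampled class frequencies match the configured mix", {
  scn <- tiny_scene()
  cls <- sample_channel_classes(1000, scn, seed = 3)
  freq <- table(factor(cls, levels = c("full", "partial", "empty"))) / 1000
  expect_lt(abs(freq[["full"]] - 0.81), 0.03)
  expect_lt(abs(freq[["partial"]] - 0.14), 0.03)
  expect_lt(abs(freq[["empty"]] - 0.05), 0.03)
  scn1 <- tiny_scene(class_mix = c(full = 1, partial = 0, empty = 0))
  expect_true(all(sample_channel_classes(50, scn1, seed = 3) == "full"))
})

test_that("fluorescence granules are dose-responsive and mask-confined", {
  scn <- tiny_scene(fov_height_px = 256L, pixel_size_um = 2)
  plan <- dose_plan()
  w <- make_worm(380, max_width_um = 50, channel_width_um = 150, seed = 5,
                 granule_density = 25)
  m <- rasterize_worm(w, scn)
  f0 <- max_projection(render_fluorescence_stack(m, w, 0, plan, scn, seed = 8))
  f9 <- max_projection(render_fluorescence_stack(m, w, 9, plan, scn, seed = 8))
  expect_gt(mean(f9[m$grid]), mean(f0[m$grid]))
  # zero granule density: in-mask indistinguishable from background
  w0 <- make_worm(380, max_width_um = 50, channel_width_um = 150, seed = 5,
                  granule_density = 0)
  fz <- max_projection(render_fluorescence_stack(m, w0, 9, plan, scn, seed = 8))
  p <- t.test(fz[m$grid], fz[!m$grid])$p.value
  expect_gt(p, 0.01)
  # empty mask: background only
  me <- rasterize_worm(NULL, scn)
  fe <- max_projection(render_fluorescence_stack(me, NULL, 9, plan, scn, seed = 8))
  expect_lt(max(fe), 0.1)
})

test_that("a full device emits 960 channel records with a deterministic layout", {
  scn <- tiny_scene()
  plan <- dose_plan()
  ds <- make_device_dataset(plan, scn, seed = 1, render = "none")
  expect_identical(nrow(ds$layout), 960L)
  expect_identical(length(unique(ds$layout$well)), 24L)
  ds2 <- make_device_dataset(plan, scn, seed = 1, render = "none")
  expect_identical(ds$layout, ds2$layout)
  # generating mean body length is non-increasing in dose (negative slope)
  mu_curve <- hill_curve(sort(plan$doses_um), plan$hill$top, plan$hill$bottom,
                         plan$hill$ec50, plan$hill$slope)
  expect_true(all(diff(mu_curve) <= 0))
  # and the sampled worm lengths follow it (plan scaled to the tiny scene)
  plan2 <- dose_plan(hill = list(top = 280, bottom = 190, ec50 = 2,
                                 slope = -2.5))
  ds3 <- make_device_dataset(plan2, scn, seed = 1, render = "none",
                             width_frac = 0.15)
  full <- ds3$layout$class != "empty"
  lens <- vapply(ds3$channels[full], function(ch) ch$true_length_um, 0)
  doses <- ds3$layout$dose_um[full]
  mu <- tapply(lens, doses, mean)
  mu <- mu[order(as.numeric(names(mu)))]
  expect_true(all(diff(mu) <= 5))
  expect_lt(mu[[length(mu)]], mu[[1]])
})
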