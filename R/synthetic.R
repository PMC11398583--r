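#' Scene configuration for the synthetic channel-image generator
#'
#' Describes one imaging field of view (FOV) of a microfluidic trapping
#' device: parallel vertical channels, a short brightfield z-stack per time
#' point, and a fiduciary cross mark used as the spatial reference for
#' channel centerlines. Defaults mirror the acquisition geometry the package
#' targets: 8 channels per FOV at 150 um pitch, 10 z-slices at 6 um steps,
#' 5 time points, channel crops 5,056 px tall and ~354 px wide.
#'
#' @param fov_height_px Image height in pixels (channel axis).
#' @param n_channels_per_fov Number of trapping channels per FOV.
#' @param channel_pitch_um Center-to-center channel spacing in micrometres.
#' @param n_z,z_step_um Number of z-slices and step between them.
#' @param n_timepoints Brightfield time points per channel.
#' @param pixel_size_um Pixel pitch; the default makes a 150 um channel
#'   section span 354 px.
#' @param class_mix Probabilities of (full, partial, empty) channels; must
#'   sum to 1.
#' @param contrast_range Range of per-worm brightfield contrast factors.
#' @param noise_sd Additive Gaussian pixel noise (intensities are in [0,1]).
#' @param blur_per_um Gaussian defocus sigma, in pixels per micrometre of
#'   distance from the focal plane.
#' @param focus_z Index of the in-focus slice (default: middle slice).
#' @param margin_px Lateral margin left and right of the channel block.
#' @param rng_seed Default seed used when an operation is not given one.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(fov_height_px = 5056L,
                         n_channels_per_fov = 8L,
                         channel_pitch_um = 150,
                         n_z = 10L,
                         z_step_um = 6,
                         n_timepoints = 5L,
                         pixel_size_um = 150 / 354,
                         class_mix = c(full = 0.81, partial = 0.14, empty = 0.05),
                         contrast_range = c(0.6, 1.0),
                         noise_sd = 0.01,
                         blur_per_um = 0.12,
                         focus_z = NULL,
                         margin_px = 60L,
                         rng_seed = 1L) {
  if (abs(sum(class_mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (n_z < 1L) stop("n_z must be >= 1")
  if (pixel_size_um <= 0) stop("pixel_size_um must be > 0")
  if (is.null(focus_z)) focus_z <- as.integer(ceiling(n_z / 2))
  scn <- list(fov_height_px = as.integer(fov_height_px),
              n_channels_per_fov = as.integer(n_channels_per_fov),
              channel_pitch_um = channel_pitch_um,
              n_z = as.integer(n_z), z_step_um = z_step_um,
              n_timepoints = as.integer(n_timepoints),
              pixel_size_um = pixel_size_um,
              class_mix = class_mix,
              contrast_range = contrast_range,
              noise_sd = noise_sd,
              blur_per_um = blur_per_um,
              focus_z = as.integer(focus_z),
              margin_px = as.integer(margin_px),
              rng_seed = as.integer(rng_seed))
  scn$pitch_px <- as.integer(round(channel_pitch_um / pixel_size_um))
  scn$fov_width_px <- as.integer(2L * scn$margin_px +
                                   scn$n_channels_per_fov * scn$pitch_px)
  scn$fiduciary_px <- c(x = 20L, y = 40L)
  class(scn) <- "scene_config"
  scn
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Dose-response plan for a synthetic device experiment
#'
#' Defines the doses loaded into the device wells and the (hidden) population
#' structure the generator draws from: mean body size follows a
#' four-parameter Hill curve of dose, gut autofluorescence follows a second
#' Hill curve, and individual worms vary around the well mean with a
#' biological coefficient of variation.
#'
#' The Hill curve used throughout is
#' `mu(d) = bottom + (top - bottom) / (1 + (d / ec50)^(-slope))`,
#' decreasing in dose for `slope < 0` and increasing for `slope > 0`.
#'
#' @param doses_um Dose levels in micromolar; must contain 0 (solvent
#'   control) and be non-negative. Default: control plus 11 log-spaced doses
#'   from 0.5 to 9.
#' @param wells_per_dose Number of replicate wells per dose level.
#' @param hill Named list `top, bottom, ec50, slope` for mean body length
#'   (um) versus dose; `slope < 0` (body size shrinks with dose).
#' @param af_hill Same structure for mean granule autofluorescence intensity
#'   (arbitrary units in [0,1]) versus dose; `slope > 0`.
#' @param biological_cv Worm-to-worm coefficient of variation of body length
#'   within a well.
#' @return A list of class `dose_plan`.
#' @export
dose_plan <- function(doses_um = c(0, round(exp(seq(log(0.5), log(9), length.out = 11)), 3)),
                      wells_per_dose = 2L,
                      hill = list(top = 1100, bottom = 600, ec50 = 2, slope = -2.5),
                      af_hill = list(top = 0.55, bottom = 0.25, ec50 = 3, slope = 3),
                      biological_cv = 0.04) {
  if (any(doses_um < 0)) stop("doses must be non-negative")
  if (!any(doses_um == 0)) stop("a control dose (0) must be present")
  if (biological_cv <= 0) stop("biological_cv must be > 0")
  structure(list(doses_um = doses_um,
                 wells_per_dose = as.integer(wells_per_dose),
                 hill = hill, af_hill = af_hill,
                 biological_cv = biological_cv),
            class = "dose_plan")
}

#' Four-parameter Hill curve
#'
#' `hill_curve(d) = bottom + (top - bottom) / (1 + (d / ec50)^(-slope))`;
#' decreasing in `d` when `slope < 0`. `d = 0` maps to `top` for negative
#' slopes and to `bottom` for positive slopes.
#'
#' @param d Dose (vectorised).
#' @param top,bottom,ec50,slope Curve parameters.
#' @export
hill_curve <- function(d, top, bottom, ec50, slope) {
  r <- (d / ec50)^(-slope)
  ifelse(is.infinite(r), bottom, bottom + (top - bottom) / (1 + r))
}

## ---- worm geometry ----------------------------------------------------------

#' Generate a synthetic worm body specification
#'
#' Builds a sinuous centerline of a requested arc length with a tapering
#' width profile, positioned inside one trapping-channel crop. The arc
#' length of the returned polyline matches `length_um` to within 0.5%.
#'
#' @param length_um Body length (arc length of the centerline).
#' @param max_width_um Maximal body width; must fit inside the channel.
#' @param sinuosity In [0, 1]: fraction of the available lateral room used
#'   by the sinusoidal body posture (0 = straight).
#' @param channel_width_um Width of the channel crop the worm must fit in.
#' @param truncated If `TRUE` the worm is translated across a channel end so
#'   that only part of the body is visible ("partial worm").
#' @param contrast Brightfield contrast factor in (0, 1].
#' @param granule_density Gut granules per 1000 um^2 of gut area (used by
#'   the fluorescence renderer).
#' @param taper Taper the width to ~0 at head and tail (default). With
#'   `taper = FALSE` the width profile is constant (calibration worms).
#' @param n_points Number of centerline vertices.
#' @param seed Integer seed; the same seed reproduces the same worm.
#' @return A list of class `worm_spec` with the centerline (um coordinates
#'   relative to the channel crop: x lateral, y axial), per-vertex widths,
#'   and the achieved arc length.
#' @export
make_worm <- function(length_um,
                      max_width_um = 65,
                      sinuosity = 0.4,
                      channel_width_um = 150,
                      truncated = FALSE,
                      contrast = 0.8,
                      granule_density = 15,
                      taper = TRUE,
                      n_points = 200L,
                      seed = 1L) {
  if (length_um <= 0 || max_width_um <= 0 || sinuosity < 0)
    stop("length, width and sinuosity must be non-negative (length, width > 0)")
  if (max_width_um >= channel_width_um)
    stop(sprintf("worm width (%.1f um) does not fit in a %.1f um wide channel",
                 max_width_um, channel_width_um))
  with_seed(seed, {
    amp_max <- (channel_width_um - max_width_um) / 2 - 2
    waves <- stats::runif(1, 1.2, 2.2)
    # lateral excursions must leave enough axial room for the arc length
    amp <- sinuosity * max(min(amp_max, 0.15 * length_um / waves), 0)
    phase <- stats::runif(1, 0, 2 * pi)
    s <- seq(0, 1, length.out = n_points)
    arc_of <- function(ly) {
      x <- amp * sin(2 * pi * waves * s + phase)
      y <- s * ly
      sum(sqrt(diff(x)^2 + diff(y)^2))
    }
    ly <- if (amp == 0) length_um else
      stats::uniroot(function(v) arc_of(v) - length_um,
                     c(length_um / 4, length_um), tol = 1e-6)$root
    x <- amp * sin(2 * pi * waves * s + phase)
    y <- s * ly
    arc <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
    widths <- if (taper) max_width_um * (4 * s * (1 - s))^0.3 else
      rep(max_width_um, n_points)
    spec <- list(length_um = length_um,
                 arc_length_um = arc[n_points],
                 max_width_um = max_width_um,
                 centerline = cbind(x = x + channel_width_um / 2, y = y),
                 widths = widths,
                 arc = arc,
                 taper = taper,
                 granule_density = granule_density,
                 contrast = contrast,
                 truncated = isTRUE(truncated))
    class(spec) <- "worm_spec"
    spec
  })
}

#' Rasterize a worm specification into a binary channel mask
#'
#' Stamps disks of the local body radius along a densely resampled
#' centerline. Full worms are placed centred along the channel axis; a
#' truncated worm is shifted across the channel top so that its mask touches
#' the image border.
#'
#' @param spec A `worm_spec`, or `NULL` for an empty channel.
#' @param scene A [scene_config()].
#' @return A `binary_mask` (logical `fov_height_px` x `pitch_px` matrix with
#'   a `pixel_size_um` field).
#' @export
rasterize_worm <- function(spec, scene) {
  H <- scene$fov_height_px
  W <- scene$pitch_px
  grid <- matrix(FALSE, H, W)
  if (is.null(spec)) return(new_binary_mask(grid, scene$pixel_size_um))
  px <- scene$pixel_size_um
  cl <- spec$centerline
  span <- max(cl[, "y"]) - min(cl[, "y"])
  y_off <- if (spec$truncated) -0.35 * span else (H * px - span) / 2
  ys <- cl[, "y"] - min(cl[, "y"]) + y_off
  xs <- cl[, "x"]
  # resample by arc length at ~1 px spacing
  arc <- spec$arc
  widths <- spec$widths
  if (!spec$taper) {
    r0 <- spec$max_width_um / 2
    keep <- arc >= r0 & arc <= arc[length(arc)] - r0  # inset end caps
    if (sum(keep) >= 2) {
      xs <- xs[keep]; ys <- ys[keep]; widths <- widths[keep]; arc <- arc[keep]
    }
  }
  tgt <- seq(arc[1], arc[length(arc)], by = px)
  xi <- stats::approx(arc, xs, tgt)$y
  yi <- stats::approx(arc, ys, tgt)$y
  wi <- stats::approx(arc, widths, tgt)$y
  disk_cache <- new.env()
  i <- 1L
  n <- length(tgt)
  while (i <= n) {
    r <- wi[i] / 2 / px
    if (r >= 0.5) {
      cx <- round(xi[i] / px)
      cy <- round(yi[i] / px)
      ri <- as.integer(ceiling(r))
      key <- as.character(ri)
      disk <- disk_cache[[key]]
      if (is.null(disk)) {
        off <- -ri:ri
        disk <- outer(off^2, off^2, `+`) <= r^2
        disk_cache[[key]] <- disk
      }
      rows <- cy + (-ri:ri)
      cols <- cx + (-ri:ri)
      rok <- rows >= 1L & rows <= H
      cok <- cols >= 1L & cols <= W
      if (any(rok) && any(cok)) {
        grid[rows[rok], cols[cok]] <-
          grid[rows[rok], cols[cok]] | disk[rok, cok, drop = FALSE]
      }
    }
    step <- max(1L, as.integer(floor(max(r, 1) / 2)))
    i <- i + step
  }
  new_binary_mask(grid, px)
}

#' Construct a binary mask
#'
#' @param grid Logical matrix (TRUE = worm).
#' @param pixel_size_um Pixel size in micrometres.
#' @param qc_flags Character vector of QC flags.
#' @return A list of class `binary_mask`.
#' @export
new_binary_mask <- function(grid, pixel_size_um, qc_flags = character()) {
  structure(list(grid = grid, pixel_size_um = pixel_size_um,
                 qc_flags = qc_flags),
            class = "binary_mask")
}

## ---- brightfield rendering --------------------------------------------------

# Sharp (in focus) brightfield rendering of one channel crop.
render_sharp_channel <- function(mask, spec, scene) {
  H <- nrow(mask$grid); W <- ncol(mask$grid)
  img <- matrix(0.62, H, W) +
    outer(seq(-0.015, 0.015, length.out = H), rep(1, W))
  wallw <- max(2L, as.integer(round(2 / scene$pixel_size_um)))
  img[, c(seq_len(wallw), W - seq_len(wallw) + 1L)] <- 0.30
  if (!is.null(spec) && any(mask$grid)) {
    ctr <- spec$contrast
    inside <- mask$grid
    img[inside] <- img[inside] - 0.22 * ctr
    # internal texture (gut granules, cuticle) gives in-focus high frequency
    tex <- matrix(stats::rnorm(H * W, sd = 0.05 * ctr), H, W)
    img[inside] <- img[inside] + tex[inside]
    edge <- inside & !shrink_mask(inside)
    img[edge] <- img[edge] - 0.18 * ctr
  }
  img
}

# 4-neighbour erosion by one pixel (used for boundary extraction).
shrink_mask <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- rbind(m[-1, , drop = FALSE], FALSE)
  dn <- rbind(FALSE, m[-H, , drop = FALSE])
  lf <- cbind(m[, -1, drop = FALSE], FALSE)
  rt <- cbind(FALSE, m[, -W, drop = FALSE])
  m & up & dn & lf & rt
}

#' Render a brightfield hyperstack for one channel
#'
#' Produces a `(T, Z, Y, X)` intensity volume. The slice at the scene's
#' focus index is rendered sharp; other slices are Gaussian-blurred with a
#' sigma proportional to their distance from the focal plane, so the focus
#' index is recoverable as the slice of maximal Laplacian energy. Seeded
#' Gaussian pixel noise is added per time point and slice.
#'
#' @param mask A `binary_mask` from [rasterize_worm()].
#' @param spec The `worm_spec` used for the mask (or `NULL`).
#' @param scene A [scene_config()].
#' @param seed Integer seed.
#' @param debris Number of small debris specks rendered outside the worm.
#' @return A list of class `channel_stack` with fields `volume`,
#'   `pixel_size_um`, `focus_z`, and provenance slots.
#' @export
render_channel_stack <- function(mask, spec, scene, seed = scene$rng_seed,
                                 debris = 2L) {
  with_seed(seed, {
    H <- nrow(mask$grid); W <- ncol(mask$grid)
    sharp <- render_sharp_channel(mask, spec, scene)
    if (debris > 0L) {
      for (k in seq_len(debris)) {
        dy <- sample.int(H - 8L, 1L); dx <- sample.int(W - 8L, 1L)
        patch <- mask$grid[dy + 0:7, dx + 0:7]
        if (!any(patch)) sharp[dy + 2:5, dx + 2:5] <- sharp[dy + 2:5, dx + 2:5] - 0.2
      }
    }
    vol <- array(0, c(scene$n_timepoints, scene$n_z, H, W))
    slices <- vector("list", scene$n_z)
    for (z in seq_len(scene$n_z)) {
      sig <- scene$blur_per_um * abs(z - scene$focus_z) * scene$z_step_um
      slices[[z]] <- if (sig > 0) EBImage::gblur(sharp, sigma = sig) else sharp
    }
    for (t in seq_len(scene$n_timepoints)) {
      for (z in seq_len(scene$n_z)) {
        sl <- slices[[z]]
        if (scene$noise_sd > 0)
          sl <- sl + matrix(stats::rnorm(H * W, sd = scene$noise_sd), H, W)
        vol[t, z, , ] <- sl
      }
    }
    structure(list(volume = vol, pixel_size_um = scene$pixel_size_um,
                   focus_z = scene$focus_z, well_id = NA_character_,
                   fov_index = NA_integer_, channel_index = NA_integer_,
                   centerline_x_px = NA_integer_,
                   fiduciary_offset_px = c(NA_integer_, NA_integer_)),
              class = "channel_stack")
  })
}

## ---- fluorescence -----------------------------------------------------------

#' Render a fluorescence z-stack with dose-dependent gut granules
#'
#' Punctate granules are placed only inside the gut region of the worm mask
#' (central 60% of the centerline, inner 50% of the local width). Mean
#' granule intensity follows the plan's autofluorescence Hill curve, so the
#' in-mask signal increases monotonically with dose. Background is low and
#' uniform.
#'
#' @param mask `binary_mask` of the worm (used for the "empty" check).
#' @param spec The `worm_spec` (or `NULL`).
#' @param dose_um Dose of the well the worm came from.
#' @param plan A [dose_plan()].
#' @param scene A [scene_config()].
#' @param seed Integer seed.
#' @return A list of class `fluor_stack` with a `(Z, Y, X)` volume.
#' @export
render_fluorescence_stack <- function(mask, spec, dose_um, plan, scene,
                                      seed = scene$rng_seed) {
  with_seed(seed, {
    H <- nrow(mask$grid); W <- ncol(mask$grid)
    bg <- 0.02
    base <- matrix(0, H, W)
    if (!is.null(spec) && spec$granule_density > 0 && any(mask$grid)) {
      px <- scene$pixel_size_um
      cl <- spec$centerline
      span <- max(cl[, "y"]) - min(cl[, "y"])
      y_off <- if (spec$truncated) -0.35 * span else (H * px - span) / 2
      s <- seq(0, 1, length.out = nrow(cl))
      gut <- s >= 0.2 & s <= 0.8
      gut_area_um2 <- sum(spec$widths[gut] * 0.5 *
                            c(0, diff(spec$arc))[gut])
      lambda <- spec$granule_density * gut_area_um2 / 1000
      n_g <- stats::rpois(1, lambda)
      af_mean <- hill_curve(dose_um, plan$af_hill$top, plan$af_hill$bottom,
                            plan$af_hill$ec50, plan$af_hill$slope)
      if (n_g > 0) {
        si <- sample(which(gut), n_g, replace = TRUE)
        lat <- stats::runif(n_g, -0.25, 0.25) * spec$widths[si]
        gx <- round((cl[si, "x"] + lat) / px)
        gy <- round((cl[si, "y"] - min(cl[, "y"]) + y_off) / px)
        amp <- af_mean * stats::rlnorm(n_g, sdlog = 0.25)
        for (g in seq_len(n_g)) {
          if (gy[g] < 2L || gy[g] > H - 1L || gx[g] < 2L || gx[g] > W - 1L) next
          rows <- gy[g] + (-1:1); cols <- gx[g] + (-1:1)
          kern <- amp[g] * matrix(c(.3, .6, .3, .6, 1, .6, .3, .6, .3), 3, 3)
          base[rows, cols] <- base[rows, cols] + kern
        }
      }
    }
    vol <- array(0, c(scene$n_z, H, W))
    for (z in seq_len(scene$n_z)) {
      sig <- scene$blur_per_um * abs(z - scene$focus_z) * scene$z_step_um
      sl <- if (sig > 0 && any(base > 0)) EBImage::gblur(base, sigma = sig) else base
      fade <- exp(-0.5 * ((z - scene$focus_z) / max(scene$n_z / 3, 1))^2)
      sl <- bg + sl * fade
      sl <- sl + matrix(stats::rnorm(H * W, sd = 0.005), H, W)
      vol[z, , ] <- sl
    }
    structure(list(volume = vol, pixel_size_um = scene$pixel_size_um,
                   dose_um = dose_um),
              class = "fluor_stack")
  })
}

## ---- FOV and device assembly ------------------------------------------------

#' Sample channel class labels from the scene's class mix
#'
#' @param n Number of channels.
#' @param scene A [scene_config()] (its `class_mix` is used).
#' @param seed Integer seed.
#' @return Character vector with values in `full`, `partial`, `empty`.
#' @export
sample_channel_classes <- function(n, scene, seed = scene$rng_seed) {
  with_seed(seed,
            sample(names(scene$class_mix), n, replace = TRUE,
                   prob = scene$class_mix))
}

worm_class <- function(spec) {
  if (is.null(spec)) "empty" else if (spec$truncated) "partial" else "full"
}

#' Compose a full field of view from per-channel worm specifications
#'
#' Renders each channel's hyperstack at the configured channel pitch, adds
#' the fiduciary cross mark at its known position, and returns per-channel
#' sidecar ground truth (mask and class label).
#'
#' @param worm_specs List of exactly `n_channels_per_fov` entries, each a
#'   `worm_spec` or `NULL` (empty channel).
#' @param scene A [scene_config()].
#' @param seed Integer seed.
#' @return A list of class `fov_hyperstack`: `volume` `(T, Z, Y, X)`,
#'   `ground_truth` (list of `list(mask, class)`), `channel_centers_px`,
#'   `fiduciary_px`.
#' @export
make_fov <- function(worm_specs, scene, seed = scene$rng_seed) {
  if (length(worm_specs) != scene$n_channels_per_fov)
    stop(sprintf("expected %d worm specs, got %d",
                 scene$n_channels_per_fov, length(worm_specs)))
  H <- scene$fov_height_px
  Wf <- scene$fov_width_px
  vol <- array(0.62, c(scene$n_timepoints, scene$n_z, H, Wf))
  centers <- as.integer(round(scene$margin_px +
                                (seq_len(scene$n_channels_per_fov) - 0.5) *
                                  scene$pitch_px))
  gt <- vector("list", scene$n_channels_per_fov)
  half <- scene$pitch_px %/% 2L
  for (k in seq_len(scene$n_channels_per_fov)) {
    spec <- worm_specs[[k]]
    mask <- rasterize_worm(spec, scene)
    st <- render_channel_stack(mask, spec, scene, seed = seed + 1000L * k)
    c0 <- centers[k] - half + 1L
    vol[, , , c0:(c0 + scene$pitch_px - 1L)] <- st$volume
    gt[[k]] <- list(mask = mask, class = worm_class(spec))
  }
  # fiduciary cross, sharp in every slice
  fx <- scene$fiduciary_px["x"]; fy <- scene$fiduciary_px["y"]
  arm <- 10L
  vol[, , fy + (-arm:arm), fx] <- 0.05
  vol[, , fy, fx + (-arm:arm)] <- 0.05
  structure(list(volume = vol, ground_truth = gt,
                 channel_centers_px = centers,
                 fiduciary_px = scene$fiduciary_px,
                 pixel_size_um = scene$pixel_size_um,
                 focus_z = scene$focus_z),
            class = "fov_hyperstack")
}

#' Generate a full synthetic device dataset
#'
#' Emulates one 24-well device run: `wells = doses x replicates`, 5 FOVs per
#' well, `n_channels_per_fov` channels per FOV. Channel classes are drawn
#' from the scene's class mix; each full or partial worm's length is drawn
#' from `Normal(mu(dose), biological_cv * mu(dose))` with `mu` the plan's
#' Hill curve.
#'
#' @param plan A [dose_plan()].
#' @param scene A [scene_config()].
#' @param seed Integer seed.
#' @param n_fovs_per_well FOVs per well (default 5).
#' @param render One of `"none"` (layout, specs and true phenotypes only),
#'   `"masks"` (adds ground-truth masks), or `"full"` (also renders
#'   brightfield hyperstacks and fluorescence z-stacks).
#' @param width_frac Body width as a fraction of body length (default 0.058,
#'   the adult proportion; scaled-down scenes may use wider bodies so the
#'   width in pixels stays realistic).
#' @return A list of class `device_dataset` with `layout` (data.frame:
#'   well, fov, channel, class, dose_um, seed), `channels` (per-channel
#'   records with `spec`, and, depending on `render`, `mask`, `stack`,
#'   `fluor`), `plan`, `scene`.
#' @export
make_device_dataset <- function(plan, scene, seed = scene$rng_seed,
                                n_fovs_per_well = 5L,
                                render = c("none", "masks", "full"),
                                width_frac = 0.058) {
  render <- match.arg(render)
  n_wells <- length(plan$doses_um) * plan$wells_per_dose
  wells <- sprintf("W%02d", seq_len(n_wells))
  well_dose <- rep(plan$doses_um, each = plan$wells_per_dose)
  nch <- scene$n_channels_per_fov
  layout <- expand.grid(channel = seq_len(nch),
                        fov = seq_len(n_fovs_per_well),
                        well = wells, stringsAsFactors = FALSE)
  layout <- layout[, c("well", "fov", "channel")]
  layout$dose_um <- well_dose[match(layout$well, wells)]
  n <- nrow(layout)
  layout$class <- sample_channel_classes(n, scene, seed = seed)
  layout$seed <- seed + seq_len(n)
  channels <- vector("list", n)
  chan_w_um <- scene$pitch_px * scene$pixel_size_um
  for (i in seq_len(n)) {
    cls <- layout$class[i]
    rec <- list(well = layout$well[i], fov = layout$fov[i],
                channel = layout$channel[i], dose_um = layout$dose_um[i],
                class = cls, spec = NULL)
    if (cls != "empty") {
      mu <- hill_curve(layout$dose_um[i], plan$hill$top, plan$hill$bottom,
                       plan$hill$ec50, plan$hill$slope)
      len <- with_seed(layout$seed[i],
                       stats::rnorm(1, mu, plan$biological_cv * mu))
      len <- max(len, 0.2 * mu)
      width <- width_frac * len
      fov_um <- scene$fov_height_px * scene$pixel_size_um
      len <- min(len, 0.9 * fov_um)
      rec$spec <- make_worm(len, max_width_um = min(width, 0.8 * chan_w_um),
                            channel_width_um = chan_w_um,
                            truncated = (cls == "partial"),
                            contrast = with_seed(layout$seed[i] + 1L,
                                                 stats::runif(1, scene$contrast_range[1],
                                                              scene$contrast_range[2])),
                            seed = layout$seed[i] + 2L)
      rec$true_length_um <- rec$spec$arc_length_um
    }
    if (render != "none") {
      rec$mask <- rasterize_worm(rec$spec, scene)
      if (!is.null(rec$spec)) {
        rec$true_area_um2 <- sum(rec$mask$grid) * scene$pixel_size_um^2
      }
    }
    if (render == "full") {
      rec$stack <- render_channel_stack(rec$mask, rec$spec, scene,
                                        seed = layout$seed[i] + 3L)
      rec$fluor <- render_fluorescence_stack(rec$mask, rec$spec,
                                             layout$dose_um[i], plan, scene,
                                             seed = layout$seed[i] + 4L)
    }
    channels[[i]] <- rec
  }
  structure(list(layout = layout, channels = channels, plan = plan,
                 scene = scene, seed = seed),
            class = "device_dataset")
}
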