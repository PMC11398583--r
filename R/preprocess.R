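#' Crop a field of view into per-channel stacks
#'
#' Channel centerlines are predicted from the fiduciary cross mark as
#' `fiduciary_x + offset + k * pitch` (k = 0..n-1, sub-pixel centers rounded
#' to the nearest integer), and each channel is clipped to one pitch-wide
#' (150 um) section centred on its centerline. Crops are non-overlapping and
#' ordered left to right.
#'
#' @param fov A `fov_hyperstack` from [make_fov()], or a `(T, Z, Y, X)`
#'   array.
#' @param scene The [scene_config()] describing the acquisition.
#' @param fiduciary_px Known fiduciary position `c(x, y)`; defaults to the
#'   generator's sidecar value when `fov` carries one.
#' @return A list of `channel_stack` objects, one per channel.
#' @export
crop_fov <- function(fov, scene, fiduciary_px = NULL) {
  vol <- if (inherits(fov, "fov_hyperstack")) fov$volume else fov
  if (is.null(fiduciary_px)) {
    if (inherits(fov, "fov_hyperstack")) fiduciary_px <- fov$fiduciary_px
    else stop("fiduciary_px must be supplied for raw arrays")
  }
  W <- dim(vol)[4]
  nch <- scene$n_channels_per_fov
  pitch <- scene$pitch_px
  if (W < nch * pitch)
    stop(sprintf("FOV width %d px cannot hold %d channels at %d px pitch",
                 W, nch, pitch))
  offset0 <- scene$margin_px - fiduciary_px[["x"]] + 0.5 * pitch
  centers <- as.integer(round(fiduciary_px[["x"]] + offset0 +
                                (seq_len(nch) - 1L) * pitch))
  half <- pitch %/% 2L
  lapply(seq_len(nch), function(k) {
    c0 <- centers[k] - half + 1L
    c1 <- c0 + pitch - 1L
    if (c0 < 1L || c1 > W) stop("channel crop exceeds FOV bounds")
    structure(list(volume = vol[, , , c0:c1, drop = FALSE],
                   pixel_size_um = scene$pixel_size_um,
                   focus_z = if (inherits(fov, "fov_hyperstack")) fov$focus_z else NA_integer_,
                   well_id = NA_character_, fov_index = NA_integer_,
                   channel_index = k,
                   centerline_x_px = centers[k],
                   fiduciary_offset_px = c(centers[k] - fiduciary_px[["x"]], 0L)),
              class = "channel_stack")
  })
}

# Variance of the 4-neighbour discrete Laplacian response of a slice.
laplacian_energy <- function(img) {
  H <- nrow(img); W <- ncol(img)
  if (H < 3L || W < 3L) return(0)
  core <- img[2:(H - 1), 2:(W - 1)]
  lap <- img[1:(H - 2), 2:(W - 1)] + img[3:H, 2:(W - 1)] +
    img[2:(H - 1), 1:(W - 2)] + img[2:(H - 1), 3:W] - 4 * core
  stats::var(as.vector(lap))
}

#' Find the best focal plane of a channel stack
#'
#' The in-focus slice is taken to be the one with the strongest
#' high-frequency content, measured as the variance of the discrete
#' Laplacian of each z-slice. Ties are broken toward the lowest z index.
#'
#' @param stack A `channel_stack` (or `(T, Z, Y, X)` array).
#' @param t Time point (1-based, default 1).
#' @return Integer z index (1-based).
#' @export
best_focal_plane <- function(stack, t = 1L) {
  vol <- if (inherits(stack, "channel_stack")) stack$volume else stack
  if (t > dim(vol)[1]) stop("time index out of range")
  nz <- dim(vol)[2]
  if (nz == 1L) return(1L)
  e <- vapply(seq_len(nz), function(z) laplacian_energy(vol[t, z, , ]), 0)
  which.max(e)  # which.max returns the first (lowest) index on ties
}

#' Assemble the 2.5D network input for one channel
#'
#' Takes the `2N+1` z-slices centred on the best focal plane (clamped by
#' edge replication at the stack boundary), pads the width symmetrically to
#' `target_width` by edge replication (odd remainder: extra column on the
#' right), and min-max normalises intensities to [0, 1] over the whole
#' tensor.
#'
#' @param stack A `channel_stack`.
#' @param t Time point used (default 1: segmentation considers the first
#'   time point only).
#' @param N Number of planes on each side of the focal plane.
#' @param target_width Padded width (default 384; must suit the network's
#'   downsampling factor).
#' @param normalize Min-max normalise to [0, 1] (default TRUE).
#' @return A list of class `input_tensor`: `planes` `(H, target_width,
#'   2N+1)`, `focus_index`, `pad_left`, `pad_right`, `source_width`.
#' @export
assemble_input <- function(stack, t = 1L, N = 1L, target_width = 384L,
                           normalize = TRUE) {
  vol <- stack$volume
  nz <- dim(vol)[2]
  if (2L * N + 1L > nz)
    stop(sprintf("2N+1 = %d planes requested but stack has only %d z-slices",
                 2L * N + 1L, nz))
  zstar <- best_focal_plane(stack, t)
  zs <- pmin(pmax(zstar + (-N:N), 1L), nz)  # edge replication in z
  H <- dim(vol)[3]; W <- dim(vol)[4]
  pad <- target_width - W
  if (pad < 0L) stop(sprintf("channel width %d exceeds target width %d", W, target_width))
  pl <- pad %/% 2L
  pr <- pad - pl
  planes <- array(0, c(H, target_width, 2L * N + 1L))
  for (j in seq_along(zs)) {
    sl <- vol[t, zs[j], , ]
    padded <- cbind(matrix(sl[, 1L], H, pl),
                    sl,
                    matrix(sl[, W], H, pr))
    planes[, , j] <- padded
  }
  if (normalize) {
    rng <- range(planes)
    if (diff(rng) > 0) planes <- (planes - rng[1]) / diff(rng)
    else planes <- planes * 0
  }
  structure(list(planes = planes, focus_index = zstar,
                 pad_left = pl, pad_right = pr, source_width = W,
                 pixel_size_um = stack$pixel_size_um),
            class = "input_tensor")
}
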