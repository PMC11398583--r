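#' Generate labeled training samples from the synthetic scene model
#'
#' Renders `n` single-channel scenes with classes drawn from the scene's
#' class mix (or as given), assembles each into a 2.5D network input, and
#' attaches the ground-truth mask (padded to the network width; full worms
#' only) and class label. This is the bridge between the scene generator
#' and the training loop.
#'
#' @param n Number of channels.
#' @param scene A [scene_config()].
#' @param seed Integer seed.
#' @param target_width Network input width (must suit the downsampling
#'   factor).
#' @param classes Optional explicit class vector (length `n`).
#' @param length_um_range Range worm lengths are drawn from (uniform).
#' @param width_frac Body width as a fraction of body length.
#' @param contrast_range Overrides the scene's contrast range when given.
#' @param N Planes each side of the focal plane.
#' @return A list of samples: `input` (`input_tensor`), `mask` (logical,
#'   `NULL` unless full), `class_label`, `spec`, `stack`, `true_mask`
#'   (unpadded `binary_mask`).
#' @export
make_labeled_channels <- function(n, scene, seed = 1L, target_width = 64L,
                                  classes = NULL,
                                  length_um_range = c(0.55, 0.8) *
                                    scene$fov_height_px * scene$pixel_size_um,
                                  width_frac = 0.085,
                                  contrast_range = NULL, N = 1L) {
  if (is.null(classes)) classes <- sample_channel_classes(n, scene, seed)
  if (length(classes) != n) stop("classes must have length n")
  if (is.null(contrast_range)) contrast_range <- scene$contrast_range
  chan_w_um <- scene$pitch_px * scene$pixel_size_um
  lapply(seq_len(n), function(i) {
    si <- seed + 37L * i
    spec <- NULL
    if (classes[i] != "empty") {
      pars <- with_seed(si, list(
        len = stats::runif(1, length_um_range[1], length_um_range[2]),
        ctr = stats::runif(1, contrast_range[1], contrast_range[2])))
      spec <- make_worm(pars$len,
                        max_width_um = min(width_frac * pars$len, 0.8 * chan_w_um),
                        channel_width_um = chan_w_um,
                        truncated = (classes[i] == "partial"),
                        contrast = pars$ctr, seed = si + 1L)
    }
    mask <- rasterize_worm(spec, scene)
    stack <- render_channel_stack(mask, spec, scene, seed = si + 2L)
    inp <- assemble_input(stack, N = N, target_width = target_width)
    padded <- NULL
    if (classes[i] == "full") {
      g <- mask$grid
      padded <- cbind(matrix(FALSE, nrow(g), inp$pad_left), g,
                      matrix(FALSE, nrow(g), inp$pad_right))
    }
    list(input = inp, mask = padded, class_label = classes[i],
         spec = spec, stack = stack, true_mask = mask)
  })
}
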