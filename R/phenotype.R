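#' Threshold a soft segmentation into a binary worm mask
#'
#' Foreground is where the worm-class probability is greater than or equal
#' to the threshold (ties at exactly the threshold are foreground). When the
#' soft segmentation came from a padded network input, the padding columns
#' are removed before any downstream measurement.
#'
#' @param soft_seg A `model_output`, an `(H, W, n_classes)` probability
#'   array, or an `(H, W)` worm-probability matrix.
#' @param threshold Probability threshold (default 0.50).
#' @param input An optional `input_tensor`; its `pad_left`/`pad_right` are
#'   cropped away.
#' @param pixel_size_um Pixel size attached to the mask (taken from `input`
#'   when available).
#' @return A `binary_mask`.
#' @export
binarize <- function(soft_seg, threshold = 0.50, input = NULL,
                     pixel_size_um = NULL) {
  if (inherits(soft_seg, "model_output")) soft_seg <- soft_seg$seg_probs
  prob <- if (length(dim(soft_seg)) == 3L) soft_seg[, , dim(soft_seg)[3]]
          else soft_seg
  if (any(prob < -1e-9 | prob > 1 + 1e-9)) stop("probabilities must lie in [0, 1]")
  grid <- prob >= threshold
  if (!is.null(input)) {
    keep <- (input$pad_left + 1L):(ncol(grid) - input$pad_right)
    grid <- grid[, keep, drop = FALSE]
    if (is.null(pixel_size_um)) pixel_size_um <- input$pixel_size_um
  }
  if (is.null(pixel_size_um)) pixel_size_um <- NA_real_
  new_binary_mask(grid, pixel_size_um)
}

#' Keep the single largest connected component of a mask
#'
#' Connected-component analysis (8-connectivity) identifies the worm body as
#' the largest binary object; everything else (eggs, debris, small larvae)
#' is removed. If no component reaches `min_area_px` the result is an empty
#' mask flagged `no_worm_detected`.
#'
#' @param mask A `binary_mask`.
#' @param min_area_px Minimum area in pixels for a component to count as a
#'   worm (default 2000 at the native pixel size; scale with the scene).
#' @return A `binary_mask` (possibly empty, with a QC flag).
#' @export
filter_components <- function(mask, min_area_px = 2000) {
  g <- mask$grid
  if (!any(g)) {
    return(new_binary_mask(g & FALSE, mask$pixel_size_um, "no_worm_detected"))
  }
  lab <- cpp_label8(g)
  sizes <- tabulate(lab[lab > 0])
  best <- which.max(sizes)
  if (sizes[best] < min_area_px) {
    return(new_binary_mask(g & FALSE, mask$pixel_size_um, "no_worm_detected"))
  }
  new_binary_mask(lab == best, mask$pixel_size_um, mask$qc_flags)
}

## ---- skeleton ---------------------------------------------------------------

# Zhang-Suen morphological thinning to a unit-width 8-connected skeleton.
skeletonize_mask <- function(grid) {
  img <- grid
  H <- nrow(img); W <- ncol(img)
  if (H < 3L || W < 3L) return(img)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- img
  img <- pad
  nbrs <- function(m) {
    h <- nrow(m); w <- ncol(m)
    list(p2 = rbind(FALSE, m[-h, ]),            # north
         p3 = cbind(rbind(FALSE, m[-h, ])[, -1], FALSE),  # ne
         p4 = cbind(m[, -1], FALSE),            # east
         p5 = cbind(rbind(m[-1, ], FALSE)[, -1], FALSE),  # se
         p6 = rbind(m[-1, ], FALSE),            # south
         p7 = cbind(FALSE, rbind(m[-1, ], FALSE)[, -w]),  # sw
         p8 = cbind(FALSE, m[, -w]),            # west
         p9 = cbind(FALSE, rbind(FALSE, m[-h, ])[, -w]))  # nw
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      nb <- nbrs(img)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seq9 <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- matrix(0L, nrow(img), ncol(img))
      for (i in 1:8) A <- A + (!seq9[[i]] & seq9[[i + 1]])
      if (step == 1L) {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- img & B >= 2 & B <= 6 & A == 1 &
          !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) {
        img[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(H + 1), 2:(W + 1)]
}

# Build the weighted 8-neighbour graph over skeleton pixels:
# weight 1 for axial steps, sqrt(2) for diagonal steps.
skeleton_graph <- function(skel) {
  idx <- which(skel, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("empty skeleton")
  key <- paste(idx[, 1], idx[, 2])
  id <- seq_len(n)
  names(id) <- key
  edges <- NULL
  wts <- NULL
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (k in 1:4) {
    nk <- paste(idx[, 1] + offs[k, 1], idx[, 2] + offs[k, 2])
    hit <- nk %in% key
    if (any(hit)) {
      edges <- c(edges, rbind(id[key[hit]], id[nk[hit]]))
      wts <- c(wts, rep(if (k <= 2) 1 else sqrt(2), sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, edges, weight = wts)
  list(graph = g, coords = idx)
}

#' Body length from the skeleton of a binary mask
#'
#' The mask is thinned to a unit-width skeleton and the body length is the
#' longest geodesic path through the skeleton's 8-neighbour graph (axial
#' steps weigh 1 px, diagonal steps sqrt(2) px), scaled by the pixel size.
#'
#' A pixel-grid geodesic systematically overestimates the length of a
#' smooth curve (the 8-connected path zigzags around it). With
#' `smooth = TRUE` (default) the longest path's pixel coordinates are
#' smoothed with a short moving average and the length is the Euclidean
#' length of the smoothed polyline; `smooth = FALSE` returns the raw
#' geodesic distance (useful for exact graph-oracle comparisons).
#'
#' @param mask A `binary_mask` with a single connected foreground component.
#' @param pixel_size_um Overrides the mask's pixel size if given.
#' @param smooth Smooth the longest path before measuring (default TRUE).
#' @param window Moving-average window (odd, in pixels).
#' @return Length in micrometres.
#' @export
skeleton_length <- function(mask, pixel_size_um = NULL, smooth = TRUE,
                            window = 9L) {
  if (is.null(pixel_size_um)) pixel_size_um <- mask$pixel_size_um
  if (!any(mask$grid)) stop("cannot measure length of an empty mask")
  if (sum(mask$grid) == 1L) return(0)
  skel <- skeletonize_mask(mask$grid)
  if (sum(skel) <= 1L) return(0)
  sg <- skeleton_graph(skel)
  g <- sg$graph
  deg <- igraph::degree(g)
  from <- which(deg <= 1L)
  if (length(from) == 0L) from <- seq_len(igraph::vcount(g))
  d <- igraph::distances(g, v = from)
  d[!is.finite(d)] <- -Inf
  if (!smooth) return(max(d) * pixel_size_um)
  best <- arrayInd(which.max(d), dim(d))
  path <- igraph::shortest_paths(g, from = from[best[1]], to = best[2],
                                 output = "vpath")$vpath[[1]]
  xy <- sg$coords[as.integer(path), , drop = FALSE]
  if (nrow(xy) < 3L) return(max(d) * pixel_size_um)
  w <- min(window, nrow(xy))
  if (w %% 2L == 0L) w <- w - 1L
  if (w >= 3L) {
    refl_pad <- function(v, pad) {
      n <- length(v)
      c(2 * v[1] - v[(pad + 1):2], v, 2 * v[n] - v[(n - 1):(n - pad)])
    }
    pad <- (w - 1L) %/% 2L
    sm <- function(v) {
      vp <- refl_pad(v, pad)
      as.numeric(stats::filter(vp, rep(1 / w, w), sides = 2))[pad + seq_along(v)]
    }
    xy <- cbind(sm(xy[, 1]), sm(xy[, 2]))
  }
  len_px <- sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
  len_px <- len_px + tip_extension(xy, mask$grid) +
    tip_extension(xy[rev(seq_len(nrow(xy))), , drop = FALSE], mask$grid)
  len_px * pixel_size_um
}

# Distance from the end of a (row, col) path to the mask boundary, stepping
# along the path's end direction; compensates skeleton end-erosion.
tip_extension <- function(xy, grid, max_px = 60) {
  n <- nrow(xy)
  k <- min(6L, n - 1L)
  dirv <- xy[n, ] - xy[n - k, ]
  nv <- sqrt(sum(dirv^2))
  if (nv < 1e-9) return(0)
  dirv <- dirv / nv
  p <- xy[n, ]
  s <- 0
  step <- 0.5
  H <- nrow(grid); W <- ncol(grid)
  while (s < max_px) {
    q <- p + dirv * (s + step)
    r <- round(q[1]); c <- round(q[2])
    if (r < 1 || r > H || c < 1 || c > W || !grid[r, c]) break
    s <- s + step
  }
  s
}

#' Body area of a binary mask
#'
#' @param mask A `binary_mask`.
#' @param pixel_size_um Overrides the mask's pixel size if given.
#' @return Area in square micrometres (foreground pixel count times pixel
#'   area).
#' @export
body_area <- function(mask, pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- mask$pixel_size_um
  sum(mask$grid) * pixel_size_um^2
}

#' Channel-height geometry for volume estimation
#'
#' The trapping channels taper in steps: a small number of layers of
#' strictly decreasing height toward the channel exit. Volume is estimated
#' by assigning each mask pixel the height of the layer it falls in, looked
#' up from its axial position relative to the fiduciary mark.
#'
#' The `"3L"` and `"4L"` presets carry nominal layer heights and boundaries;
#' real devices must be calibrated against the chip drawings before volumes
#' are interpreted in absolute units.
#'
#' @param preset `"3L"` or `"4L"`, or `NULL` when giving explicit values.
#' @param boundaries_um Axial layer boundaries (length `n_layers + 1`,
#'   strictly increasing, measured from the channel top).
#' @param heights_um One height per layer, strictly decreasing toward the
#'   exit.
#' @return A list of class `channel_geometry`.
#' @export
channel_geometry <- function(preset = c("3L", "4L"), boundaries_um = NULL,
                             heights_um = NULL) {
  if (is.null(boundaries_um) || is.null(heights_um)) {
    preset <- match.arg(preset)
    if (preset == "3L") {
      boundaries_um <- c(0, 1000, 2000, 3000)
      heights_um <- c(50, 40, 30)
    } else {
      boundaries_um <- c(0, 750, 1500, 2250, 3000)
      heights_um <- c(50, 40, 30, 22)
    }
  }
  if (length(boundaries_um) != length(heights_um) + 1L)
    stop("boundaries_um must have one more entry than heights_um")
  if (any(diff(boundaries_um) <= 0)) stop("boundaries must be strictly increasing")
  if (any(diff(heights_um) >= 0)) stop("heights must be strictly decreasing toward the exit")
  structure(list(boundaries_um = boundaries_um, heights_um = heights_um),
            class = "channel_geometry")
}

#' Channel-height-aware body volume
#'
#' `volume = sum over foreground pixels of pixel_area * height(layer at the
#' pixel's axial position)`.
#'
#' @param mask A `binary_mask`.
#' @param geometry A [channel_geometry()].
#' @param channel_origin_um Axial position (um) of the mask's first row
#'   relative to the geometry's origin.
#' @param pixel_size_um Overrides the mask's pixel size if given.
#' @return Volume in cubic micrometres.
#' @export
body_volume <- function(mask, geometry, channel_origin_um = 0,
                        pixel_size_um = NULL) {
  if (is.null(pixel_size_um)) pixel_size_um <- mask$pixel_size_um
  counts <- rowSums(mask$grid)
  rows <- which(counts > 0)
  if (length(rows) == 0L) return(0)
  y_um <- channel_origin_um + (rows - 0.5) * pixel_size_um
  b <- geometry$boundaries_um
  if (any(y_um < b[1] | y_um > b[length(b)]))
    stop(sprintf("mask rows at %.0f-%.0f um fall outside the geometry's %.0f-%.0f um span",
                 min(y_um), max(y_um), b[1], b[length(b)]))
  layer <- findInterval(y_um, b, rightmost.closed = TRUE)
  sum(counts[rows] * geometry$heights_um[layer]) * pixel_size_um^2
}

#' Run the full inference chain on one channel
#'
#' Preprocess (focal-plane selection, padding), forward pass, then, when the
#' predicted channel class is "full": threshold at 0.50, keep the largest
#' component, and measure length, area and volume. Other classes yield a
#' class-only record.
#'
#' @param stack A `channel_stack`.
#' @param model A trained `wormnet`.
#' @param geometry A [channel_geometry()].
#' @param N Planes each side of the focal plane (default 1).
#' @param threshold Binarisation threshold.
#' @param min_area_px Component-size cutoff (pixels).
#' @param channel_origin_um Axial origin passed to [body_volume()].
#' @return A one-row data.frame: class, class probabilities, length_um,
#'   area_um2, volume_um3, qc_flags.
#' @export
infer_channel <- function(stack, model, geometry = channel_geometry("3L"),
                          N = 1L, threshold = 0.5, min_area_px = 2000,
                          channel_origin_um = 0) {
  inp <- assemble_input(stack, t = 1L, N = N, target_width = model$hw[2])
  out <- net_forward(model, inp)
  cls <- names(out$class_probs)[which.max(out$class_probs)]
  rec <- data.frame(class = cls,
                    p_full = out$class_probs[["full"]],
                    p_partial = out$class_probs[["partial"]],
                    p_empty = out$class_probs[["empty"]],
                    length_um = NA_real_, area_um2 = NA_real_,
                    volume_um3 = NA_real_, qc_flags = "",
                    stringsAsFactors = FALSE)
  if (cls == "full") {
    mask <- binarize(out, threshold = threshold, input = inp)
    mask <- filter_components(mask, min_area_px = min_area_px)
    if (length(mask$qc_flags)) {
      rec$qc_flags <- paste(mask$qc_flags, collapse = ";")
    } else {
      rec$length_um <- skeleton_length(mask)
      rec$area_um2 <- body_area(mask)
      rec$volume_um3 <- body_volume(mask, geometry, channel_origin_um)
    }
  }
  rec
}

#' Batch inference over a device dataset
#'
#' Applies [infer_channel()] to every rendered channel of a
#' [make_device_dataset()] output. Each channel is isolated: a failure is
#' recorded in `qc_flags` and the run continues.
#'
#' @param dataset A `device_dataset` generated with `render = "full"`.
#' @param model A trained `wormnet`.
#' @param ... Passed to [infer_channel()].
#' @return A data.frame with one row per channel (well, fov, channel,
#'   dose_um, true class, predicted class, body measures).
#' @export
infer_device <- function(dataset, model, ...) {
  recs <- lapply(seq_along(dataset$channels), function(i) {
    ch <- dataset$channels[[i]]
    if (is.null(ch$stack))
      stop("dataset was not rendered with render = 'full'")
    base <- data.frame(well = ch$well, fov = ch$fov, channel = ch$channel,
                       dose_um = ch$dose_um, true_class = ch$class,
                       stringsAsFactors = FALSE)
    res <- tryCatch(infer_channel(ch$stack, model, ...),
                    error = function(e) {
                      data.frame(class = NA_character_, p_full = NA_real_,
                                 p_partial = NA_real_, p_empty = NA_real_,
                                 length_um = NA_real_, area_um2 = NA_real_,
                                 volume_um3 = NA_real_,
                                 qc_flags = paste0("error:", conditionMessage(e)),
                                 stringsAsFactors = FALSE)
                    })
    cbind(base, res)
  })
  do.call(rbind, recs)
}
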