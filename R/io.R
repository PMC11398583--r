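#' Write a channel hyperstack as a multi-page TIFF
#'
#' Pages are ordered with T outer and Z inner (page = (t-1) * n_z + z).
#' Intensities are clipped to [0, 1] and written as 16-bit.
#'
#' @param stack A `channel_stack` (or `(T, Z, Y, X)` array).
#' @param path Output file.
#' @export
write_channel_tiff <- function(stack, path) {
  vol <- if (inherits(stack, "channel_stack")) stack$volume else stack
  d <- dim(vol)
  pages <- vector("list", d[1] * d[2])
  k <- 0L
  for (t in seq_len(d[1])) {
    for (z in seq_len(d[2])) {
      k <- k + 1L
      pages[[k]] <- pmin(pmax(vol[t, z, , ], 0), 1)
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF back into a hyperstack
#'
#' @param path TIFF written by [write_channel_tiff()].
#' @param n_timepoints,n_z Page layout (T outer, Z inner).
#' @param pixel_size_um,focus_z Metadata to attach.
#' @return A `channel_stack`.
#' @export
read_channel_tiff <- function(path, n_timepoints, n_z, pixel_size_um = NA_real_,
                              focus_z = NA_integer_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != n_timepoints * n_z)
    stop(sprintf("expected %d pages, found %d", n_timepoints * n_z, length(pages)))
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  vol <- array(0, c(n_timepoints, n_z, H, W))
  k <- 0L
  for (t in seq_len(n_timepoints)) {
    for (z in seq_len(n_z)) {
      k <- k + 1L
      vol[t, z, , ] <- pages[[k]]
    }
  }
  structure(list(volume = vol, pixel_size_um = pixel_size_um,
                 focus_z = focus_z, well_id = NA_character_,
                 fov_index = NA_integer_, channel_index = NA_integer_,
                 centerline_x_px = NA_integer_,
                 fiduciary_offset_px = c(NA_integer_, NA_integer_)),
            class = "channel_stack")
}

#' Write / read a binary mask as an 8-bit TIFF (0/255)
#'
#' @param mask A `binary_mask`.
#' @param path File path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask$grid * 1, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @param pixel_size_um Pixel size to attach on read.
#' @export
read_mask_tiff <- function(path, pixel_size_um = NA_real_) {
  img <- tiff::readTIFF(path)
  new_binary_mask(img > 0.5, pixel_size_um)
}

#' Write a device dataset to a directory
#'
#' Writes the well/dose layout CSV (columns well, fov, channel, class,
#' dose_um, seed), a dataset manifest JSON, and, when the dataset was
#' rendered, per-channel mask/brightfield/fluorescence TIFFs.
#'
#' @param dataset A `device_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_device_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$layout[, c("well", "fov", "channel", "class",
                                      "dose_um", "seed")],
                   file.path(dir, "layout.csv"), row.names = FALSE)
  rendered <- !is.null(dataset$channels[[1]]$mask)
  full <- !is.null(dataset$channels[[1]]$stack)
  if (rendered) {
    mdir <- file.path(dir, "masks"); dir.create(mdir, showWarnings = FALSE)
    if (full) {
      bdir <- file.path(dir, "brightfield"); dir.create(bdir, showWarnings = FALSE)
      fdir <- file.path(dir, "fluorescence"); dir.create(fdir, showWarnings = FALSE)
    }
    for (ch in dataset$channels) {
      tag <- sprintf("%s_f%d_c%d", ch$well, ch$fov, ch$channel)
      write_mask_tiff(ch$mask, file.path(mdir, paste0(tag, ".tif")))
      if (full) {
        write_channel_tiff(ch$stack, file.path(bdir, paste0(tag, ".tif")))
        fv <- ch$fluor$volume
        write_channel_tiff(array(fv, c(1L, dim(fv))),
                           file.path(fdir, paste0(tag, ".tif")))
      }
    }
  }
  manifest <- list(
    format = "wormchip-device-dataset",
    version = as.character(utils::packageVersion("wormchip")),
    seed = dataset$seed,
    n_channels = nrow(dataset$layout),
    scene = dataset$scene[setdiff(names(dataset$scene), "fiduciary_px")],
    plan = unclass(dataset$plan),
    page_order = "T outer, Z inner",
    rendered = if (full) "full" else if (rendered) "masks" else "none")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Write the per-worm phenotype table
#'
#' @param phenotypes Data.frame from [infer_device()] (optionally with
#'   autofluorescence columns merged in).
#' @param path Output CSV path.
#' @export
write_phenotype_csv <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' Checkpoints embed the full network configuration, input geometry and all
#' weights in R's native serialization.
#'
#' @param model A `wormnet`.
#' @param path `.rds` path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "wormnet")) stop("not a wormnet checkpoint")
  model
}
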