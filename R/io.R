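# power-of-two exponent mapping intensities to integer sample values <= 2^30
pow2_exponent <- function(x) {
  as.integer(29 - ceiling(log2(max(1, max(x)))))
}

#' Write a multi-channel volume as multi-page TIFF plus a YAML sidecar
#'
#' Channels are stored as 32-bit multi-page TIFF (one page per z-plane),
#' either one file per channel (`layout = "per_channel"`, files
#' `<prefix>_<channel>.tif`) or one interleaved file (`<prefix>.tif`, pages
#' ordered plane-major with channels fastest). Each intensity is stored as
#' the integer `round(value * scale)` with a per-channel power-of-two scale
#' recorded in the sidecar (`<prefix>.yml`) together with the full
#' acquisition metadata. Loading divides the integers back by the scale, so
#' the roundtrip is bitwise-exact for intensities on the scale's dyadic grid
#' (noise-free renders, integer photon counts) and within 2^-30 relative
#' error otherwise.
#'
#' @param volume a [render_volume()] result.
#' @param prefix output path prefix (no extension).
#' @param layout `"per_channel"` or `"interleaved"`.
#' @return invisibly, the sidecar path.
#' @export
write_volume <- function(volume, prefix, layout = c("per_channel", "interleaved")) {
  layout <- match.arg(layout)
  acq <- volume$acquisition
  chn <- names(volume$channels)
  exps <- vapply(volume$channels, pow2_exponent, 0L)
  scales <- 2^exps
  # writeTIFF truncates value*(2^32-1); encoding the integer n as
  # (n + 0.5) / (2^32 - 1) makes that truncation recover n exactly
  as_pages <- function(arr, s) lapply(seq_len(dim(arr)[3]), function(k)
    (round(arr[, , k] * s) + 0.5) / (2^32 - 1))
  files <- character()
  if (layout == "per_channel") {
    for (ch in chn) {
      f <- paste0(prefix, "_", ch, ".tif")
      tiff::writeTIFF(as_pages(volume$channels[[ch]], scales[[ch]]), f,
                      bits.per.sample = 32L)
      files[ch] <- basename(f)
    }
  } else {
    pages <- list()
    for (k in seq_len(acq$shape_zyx[1]))
      for (ch in chn)
        pages[[length(pages) + 1L]] <-
          (round(volume$channels[[ch]][, , k] * scales[[ch]]) + 0.5) / (2^32 - 1)
    f <- paste0(prefix, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = 32L)
    files <- stats::setNames(rep(basename(f), length(chn)), chn)
  }
  sidecar <- paste0(prefix, ".yml")
  yaml::write_yaml(list(
    layout = layout,
    channels = as.list(files),
    intensity_scale_log2 = as.list(exps),
    condition = volume$condition %||% "unknown",
    region = volume$region %||% "unknown",
    acquisition = list(
      shape_zyx = as.integer(acq$shape_zyx),
      voxel_size_yx = acq$voxel_size_zyx[2],
      z_step = acq$z_step,
      psf_sigma_xy = acq$psf_sigma_xy,
      psf_sigma_z = acq$psf_sigma_z,
      photon_gain = acq$photon_gain,
      read_noise_sd = acq$read_noise_sd,
      background = as.list(acq$background)
    )
  ), sidecar, precision = 15)
  invisible(sidecar)
}

#' Load a multi-channel stack written by [write_volume()]
#'
#' Reads the YAML sidecar for layout, channel files, intensity scales and
#' acquisition metadata, then the TIFF pages. Validates that the page count
#' matches the declared channel count and z size, and that voxel sizes are
#' present.
#'
#' @param prefix path prefix used at write time (sidecar at `<prefix>.yml`).
#' @return a `multichannel_volume`.
#' @export
load_stack <- function(prefix) {
  sidecar <- paste0(prefix, ".yml")
  if (!file.exists(sidecar))
    stop("missing sidecar '", sidecar, "'; volumes need their YAML metadata",
         call. = FALSE)
  meta <- yaml::read_yaml(sidecar)
  am <- meta$acquisition
  if (is.null(am$voxel_size_yx) || is.null(am$z_step))
    stop("sidecar lacks voxel sizes; re-write the volume with its ",
         "acquisition metadata (voxel_size_yx, z_step)", call. = FALSE)
  acq <- acquisition_spec(shape_zyx = unlist(am$shape_zyx),
                          voxel_size_yx = am$voxel_size_yx,
                          z_step = am$z_step,
                          z_step_range = c(am$z_step, am$z_step),
                          psf_sigma_xy = am$psf_sigma_xy %||% 0,
                          psf_sigma_z = am$psf_sigma_z %||% 0,
                          photon_gain = am$photon_gain %||% 1,
                          read_noise_sd = am$read_noise_sd %||% 0,
                          background = unlist(am$background %||% 0))
  nz <- acq$shape_zyx[1]
  chn <- names(meta$channels)
  dirn <- dirname(prefix)
  channels <- list()
  if (meta$layout == "per_channel") {
    for (ch in chn) {
      pages <- tiff::readTIFF(file.path(dirn, meta$channels[[ch]]), all = TRUE,
                              as.is = TRUE)
      if (length(pages) != nz)
        stop(sprintf("channel %s: %d pages but sidecar declares %d z-planes",
                     ch, length(pages), nz), call. = FALSE)
      arr <- array(0, dim = c(dim(pages[[1]]), nz))
      for (k in seq_len(nz)) arr[, , k] <- pages[[k]]
      channels[[ch]] <- arr / 2^meta$intensity_scale_log2[[ch]]
    }
  } else {
    pages <- tiff::readTIFF(file.path(dirn, meta$channels[[1]]), all = TRUE,
                            as.is = TRUE)
    if (length(pages) != nz * length(chn))
      stop(sprintf("interleaved file has %d pages but sidecar declares %d channels x %d planes",
                   length(pages), length(chn), nz), call. = FALSE)
    for (ci in seq_along(chn)) {
      arr <- array(0, dim = c(dim(pages[[1]]), nz))
      for (k in seq_len(nz)) arr[, , k] <- pages[[(k - 1L) * length(chn) + ci]]
      channels[[chn[ci]]] <- arr / 2^meta$intensity_scale_log2[[chn[ci]]]
    }
  }
  structure(list(channels = channels, acquisition = acq,
                 condition = meta$condition, region = meta$region),
            class = "multichannel_volume")
}

#' Write / read a ground-truth cell roster as CSV
#'
#' One row per cell: id, class, centroid (z, y, x, um), nucleus semi-axes
#' (along/perpendicular, um), orientation unit vector, soma semi-axes and
#' distance to the nearest vessel surface.
#'
#' @param truth a [build_scene()] result.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  df <- truth$cells
  df$condition <- rep(truth$condition, nrow(df))
  df$region <- rep(truth$region, nrow(df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write per-region quantification results as CSV
#'
#' Long format, one row per analysed plane per region:
#' region, condition, plane, n_nuclei, n_mural, n_tdtomato, vessel_area_um2.
#'
#' @param quants a `region_quant` or list of them.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_region_quant <- function(quants, path) {
  if (inherits(quants, "region_quant")) quants <- list(quants)
  rows <- lapply(quants, function(q) {
    cbind(data.frame(region = q$region, condition = q$condition), q$per_plane)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write the parameter log of a quantification run as CSV
#'
#' Every analysis parameter (thresholds, broaden radius, minimum area,
#' overlap fraction, analysed planes) is logged per region so any run can be
#' re-executed.
#'
#' @param quants a `region_quant` or list of them.
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
write_quant_params <- function(quants, path) {
  if (inherits(quants, "region_quant")) quants <- list(quants)
  rows <- lapply(quants, function(q) {
    data.frame(region = q$region, condition = q$condition,
               fitc_threshold = q$params$fitc_threshold,
               tdtomato_threshold = q$params$tdtomato_threshold,
               broaden_radius_um = q$params$broaden_radius_um,
               min_area_um2 = q$params$min_area_um2,
               overlap_frac = q$params$overlap_frac,
               planes = paste(q$params$planes, collapse = ";"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
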