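#' Vessel mask from the FITC channel
#'
#' The vessel mask is exactly the set of voxels with FITC intensity strictly
#' above the threshold; per-plane vessel area is the in-plane voxel count
#' times the voxel area.
#'
#' @param volume a [render_volume()] result.
#' @param fitc_threshold a `channel_threshold` on the FITC channel (or a bare
#'   number, taken as a manual FITC threshold).
#' @return An object of class `vessel_mask`: logical array (ny, nx, nz),
#'   per-plane area in um^2, broadening state, and the voxel sizes.
#' @export
make_vessel_mask <- function(volume, fitc_threshold) {
  thr <- if (inherits(fitc_threshold, "channel_threshold")) fitc_threshold$value
         else as.numeric(fitc_threshold)
  mask <- volume$channels$FITC > thr
  vs <- volume$acquisition$voxel_size_zyx
  area <- apply(mask, 3L, sum) * vs[2] * vs[3]
  structure(list(mask = mask, area_per_plane_um2 = area, threshold = thr,
                 broadened = FALSE, broaden_radius_um = 0,
                 voxel_size_zyx = vs),
            class = "vessel_mask")
}

# exact Euclidean disk brush: offsets with dy^2 + dx^2 <= r^2
disk_kernel <- function(radius_px) {
  r <- as.integer(radius_px)
  if (r == 0L) return(matrix(1L, 1L, 1L))
  off <- -r:r
  k <- outer(off, off, function(dy, dx) as.integer(dy^2 + dx^2 <= r^2))
  k
}

#' Broaden a vessel mask in-plane
#'
#' Morphological dilation of every z-plane by a Euclidean disk of radius
#' `ceiling(radius_um / voxel_size)` pixels. This artificial broadening of the
#' vessel signal is what turns the vessel mask into a "proximal to vessel"
#' mask for identifying putative mural cells.
#'
#' @param mask a [make_vessel_mask()] result.
#' @param radius_um broadening radius in micrometres; 0 is the identity.
#' @return the broadened `vessel_mask` (superset of the input mask), with the
#'   `broadened` flag and radius recorded. The reported per-plane area remains
#'   the un-broadened vessel area.
#' @export
broaden_mask <- function(mask, radius_um) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (radius_um < 0) stop("broaden radius must be non-negative", call. = FALSE)
  out <- mask
  r_px <- ceiling(radius_um / mask$voxel_size_zyx[2])
  if (r_px > 0L) {
    kern <- disk_kernel(r_px)
    m <- mask$mask
    for (k in seq_len(dim(m)[3]))
      m[, , k] <- EBImage::dilate(m[, , k] * 1, kern) > 0
    out$mask <- m
  }
  out$broadened <- TRUE
  out$broaden_radius_um <- radius_um
  out
}

#' Binary mask of a non-FITC channel at a threshold
#'
#' @param volume a [render_volume()] result.
#' @param channel channel name.
#' @param threshold a `channel_threshold` or bare number.
#' @return logical array (ny, nx, nz) of voxels strictly above threshold.
#' @export
channel_mask <- function(volume, channel, threshold) {
  thr <- if (inherits(threshold, "channel_threshold")) threshold$value
         else as.numeric(threshold)
  volume$channels[[channel]] > thr
}
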