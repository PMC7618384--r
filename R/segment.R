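#' Segment nuclei on one z-plane of the DAPI channel
#'
#' Classical per-plane pipeline: Gaussian smoothing, IsoData automatic
#' threshold (or a supplied one), Euclidean distance transform and watershed
#' to split touching nuclei. The contract is segmentation-method agnostic:
#' any function returning non-overlapping labelled ROIs per plane can stand in
#' (the original analysis used a trained star-convex-polygon network; this
#' classical stand-in needs no trained weights and is deterministic).
#'
#' @param volume a [render_volume()] result.
#' @param plane 1-based z-plane index.
#' @param channel channel to segment, default `"DAPI"`.
#' @param blur_sigma_um Gaussian smoothing sigma in micrometres (0 disables).
#' @param threshold optional fixed intensity threshold; by default IsoData is
#'   computed once over the whole stack of the channel (a sparsely populated
#'   single plane has no reliable bimodal histogram of its own).
#' @param watershed_tolerance minimum object-depth in the distance transform
#'   for a watershed split (pixels).
#' @return list of `nucleus_roi` objects: `id`, `plane`, `pixels` (linear
#'   indices into the plane matrix), `area_um2`, `centroid_um` (y, x). A blank
#'   plane yields an empty list.
#' @export
segment_nuclei <- function(volume, plane, channel = "DAPI",
                           blur_sigma_um = 0.7, threshold = NULL,
                           watershed_tolerance = 1) {
  img <- volume$channels[[channel]]
  if (is.null(img)) stop("unknown channel '", channel, "'", call. = FALSE)
  if (plane < 1L || plane > dim(img)[3])
    stop("plane index out of range", call. = FALSE)
  vs <- volume$acquisition$voxel_size_zyx
  pl <- img[, , plane]
  if (max(pl) - min(pl) < .Machine$double.eps * 100) return(list())
  sigma_px <- blur_sigma_um / vs[2]
  # skip smoothing when the Gaussian brush would not fit the plane
  if (sigma_px > 1e-3 && 2 * ceiling(3 * sigma_px) + 1 <= min(dim(pl)))
    pl <- EBImage::gblur(pl, sigma = sigma_px)
  thr <- if (is.null(threshold)) {
    if (max(img) - min(img) < .Machine$double.eps * 100) return(list())
    isodata_threshold(img)
  } else if (inherits(threshold, "channel_threshold")) threshold$value
    else as.numeric(threshold)
  bin <- pl > thr
  if (!any(bin)) return(list())
  labels <- EBImage::watershed(EBImage::distmap(bin), tolerance = watershed_tolerance)
  labels <- as.integer(labels)
  dim(labels) <- dim(bin)
  px_area <- vs[2] * vs[3]
  ids <- sort(unique(labels[labels > 0L]))
  vc <- voxel_centers(volume$acquisition)
  lapply(seq_along(ids), function(i) {
    lin <- which(labels == ids[i])
    iy <- ((lin - 1L) %% nrow(bin)) + 1L
    ix <- ((lin - 1L) %/% nrow(bin)) + 1L
    structure(list(id = i, plane = plane, pixels = lin,
                   area_um2 = length(lin) * px_area,
                   centroid_um = c(y = mean(vc$y[iy]), x = mean(vc$x[ix]))),
              class = "nucleus_roi")
  })
}
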