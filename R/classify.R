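#' Classify nucleus ROIs by mask overlap and count them
#'
#' Implements the counting rules of the cleared-nerve quantification: ROIs
#' with area below `min_area_um2` are discarded before any counting; the
#' nucleus count is the number of surviving ROIs; the tdTomato+ count is the
#' number of surviving ROIs overlapping the tdTomato mask; the mural count is
#' the number overlapping tdTomato-FITC co-expression, i.e. the intersection
#' of the tdTomato mask with the broadened vessel mask.
#'
#' @param rois list of `nucleus_roi` from [segment_nuclei()] (one plane).
#' @param tdtomato_mask logical plane (ny, nx) of tdTomato-positive pixels.
#' @param broadened_vessel_mask logical plane (ny, nx) from the broadened
#'   vessel mask.
#' @param min_area_um2 minimum ROI area in um^2 (default 10).
#' @param overlap_frac minimum fraction of ROI pixels inside a mask for the
#'   ROI to count as overlapping; any value <= 0 means "at least one pixel".
#' @return list with `counts` (named: `n_nuclei`, `n_mural`, `n_tdtomato`) and
#'   `rois`, a data.frame with per-ROI area, centroid and classification flags.
#' @export
classify_and_count <- function(rois, tdtomato_mask, broadened_vessel_mask,
                               min_area_um2 = 10, overlap_frac = 0) {
  if (!identical(dim(tdtomato_mask), dim(broadened_vessel_mask)))
    stop("tdTomato and vessel masks must share the plane shape", call. = FALSE)
  if (length(rois) && max(vapply(rois, function(r) max(r$pixels), 0L)) >
      prod(dim(tdtomato_mask)))
    stop("ROI pixel indices exceed the mask shape", call. = FALSE)
  co_mask <- tdtomato_mask & broadened_vessel_mask
  keep <- Filter(function(r) r$area_um2 >= min_area_um2, rois)
  overlaps <- function(r, mask) {
    n <- sum(mask[r$pixels])
    if (overlap_frac > 0) n / length(r$pixels) >= overlap_frac else n >= 1L
  }
  df <- if (length(keep)) data.frame(
    id = vapply(keep, function(r) r$id, 0L),
    plane = vapply(keep, function(r) r$plane, 0L),
    area_um2 = vapply(keep, function(r) r$area_um2, 0),
    y_um = vapply(keep, function(r) r$centroid_um[["y"]], 0),
    x_um = vapply(keep, function(r) r$centroid_um[["x"]], 0),
    is_tdtomato = vapply(keep, overlaps, TRUE, mask = tdtomato_mask),
    is_mural = vapply(keep, overlaps, TRUE, mask = co_mask)
  ) else data.frame(id = integer(), plane = integer(), area_um2 = numeric(),
                    y_um = numeric(), x_um = numeric(),
                    is_tdtomato = logical(), is_mural = logical())
  list(counts = c(n_nuclei = nrow(df),
                  n_mural = sum(df$is_mural),
                  n_tdtomato = sum(df$is_tdtomato)),
       rois = df)
}

# resolve a planes specification against a stack
resolve_planes <- function(acq, planes_spec) {
  n_planes <- planes_spec$n_planes %||% 5L
  spacing <- planes_spec$spacing_um %||% 8
  start <- planes_spec$start
  step <- spacing / acq$z_step
  if (abs(step - round(step)) > 1e-9)
    stop(sprintf("plane spacing %g um is not a multiple of the stack z-step %g um",
                 spacing, acq$z_step), call. = FALSE)
  step <- as.integer(round(step))
  span <- (n_planes - 1L) * step
  if (span + 1L > acq$shape_zyx[1])
    stop(sprintf("%d planes %g um apart do not fit a %d-plane stack at z-step %g um",
                 n_planes, spacing, acq$shape_zyx[1], acq$z_step), call. = FALSE)
  if (is.null(start))
    start <- 1L + (acq$shape_zyx[1] - (span + 1L)) %/% 2L
  planes <- start + step * (seq_len(n_planes) - 1L)
  if (min(planes) < 1L || max(planes) > acq$shape_zyx[1])
    stop("requested planes fall outside the stack", call. = FALSE)
  planes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quantify one imaged nerve region
#'
#' Runs the full per-region measurement: vessel mask from the FITC threshold,
#' in-plane broadening, nucleus segmentation and overlap classification on
#' each of the selected z-planes (default five planes 8 um apart), then
#' averages the per-plane counts.
#'
#' @param volume a [render_volume()] or [load_stack()] result.
#' @param thresholds list with elements `fitc` and `tdtomato`, each a
#'   `channel_threshold` or bare number. Pass
#'   `tdtomato = compute_threshold(volume, "tdTomato", "cross", source_threshold = fitc)`
#'   to apply the FITC threshold to tdTomato.
#' @param broaden_radius_um in-plane vessel broadening radius (um); always
#'   recorded in the output parameters.
#' @param min_area_um2 minimum nucleus ROI area (um^2).
#' @param planes_spec list with `n_planes` (default 5), `spacing_um` (default
#'   8) and optional `start` plane; the spacing must be a multiple of the
#'   stack z-step.
#' @param overlap_frac minimum overlap fraction, see [classify_and_count()].
#' @param segment_args list of extra arguments for [segment_nuclei()].
#' @param region_id,condition labels carried into the output.
#' @return An object of class `region_quant`: per-plane counts and vessel
#'   area, their across-plane means, the per-ROI table (with plane z
#'   positions, for evaluation against ground truth) and all parameters used.
#' @export
quantify_region <- function(volume, thresholds, broaden_radius_um = 5,
                            min_area_um2 = 10,
                            planes_spec = list(n_planes = 5L, spacing_um = 8),
                            overlap_frac = 0, segment_args = list(),
                            region_id = volume$region %||% "region",
                            condition = volume$condition %||% "unknown") {
  acq <- volume$acquisition
  planes <- resolve_planes(acq, planes_spec)
  vm <- make_vessel_mask(volume, thresholds$fitc)
  vb <- broaden_mask(vm, broaden_radius_um)
  td <- channel_mask(volume, "tdTomato", thresholds$tdtomato)
  per_plane <- vector("list", length(planes))
  roi_tabs <- vector("list", length(planes))
  vc <- voxel_centers(acq)
  for (i in seq_along(planes)) {
    p <- planes[i]
    rois <- do.call(segment_nuclei, c(list(volume = volume, plane = p),
                                      segment_args))
    cc <- classify_and_count(rois, td[, , p], vb$mask[, , p],
                             min_area_um2 = min_area_um2,
                             overlap_frac = overlap_frac)
    per_plane[[i]] <- data.frame(plane = p, z_um = vc$z[p],
                                 n_nuclei = cc$counts[["n_nuclei"]],
                                 n_mural = cc$counts[["n_mural"]],
                                 n_tdtomato = cc$counts[["n_tdtomato"]],
                                 vessel_area_um2 = vm$area_per_plane_um2[p])
    if (nrow(cc$rois)) {
      cc$rois$z_um <- vc$z[p]
      roi_tabs[[i]] <- cc$rois
    }
  }
  per_plane <- do.call(rbind, per_plane)
  rois <- if (length(roi_tabs <- Filter(Negate(is.null), roi_tabs)))
    do.call(rbind, roi_tabs) else
    data.frame(id = integer(), plane = integer(), area_um2 = numeric(),
               y_um = numeric(), x_um = numeric(), is_tdtomato = logical(),
               is_mural = logical(), z_um = numeric())
  thr_vals <- vapply(thresholds, function(t)
    if (inherits(t, "channel_threshold")) t$value else as.numeric(t), 0)
  structure(list(
    region = region_id, condition = condition,
    per_plane = per_plane,
    means = colMeans(per_plane[c("n_nuclei", "n_mural", "n_tdtomato",
                                 "vessel_area_um2")]),
    rois = rois,
    params = list(fitc_threshold = thr_vals[["fitc"]],
                  tdtomato_threshold = thr_vals[["tdtomato"]],
                  broaden_radius_um = broaden_radius_um,
                  min_area_um2 = min_area_um2,
                  overlap_frac = overlap_frac,
                  planes = planes)
  ), class = "region_quant")
}

#' @export
print.region_quant <- function(x, ...) {
  cat(sprintf("Region '%s' (%s): mean nuclei %.2f, mural %.2f, tdTomato+ %.2f over %d planes\n",
              x$region, x$condition, x$means[["n_nuclei"]], x$means[["n_mural"]],
              x$means[["n_tdtomato"]], nrow(x$per_plane)))
  invisible(x)
}

#' Average several images of the same nerve region
#'
#' When two (or more) images were captured per nerve region, the per-image
#' across-plane averages are themselves averaged — mean over planes within an
#' image first, then mean over images.
#'
#' @param quants list of `region_quant` objects sharing a region id.
#' @return named numeric vector of region-level mean counts and vessel area.
#' @export
aggregate_region <- function(quants) {
  stopifnot(length(quants) >= 1L,
            all(vapply(quants, inherits, TRUE, "region_quant")))
  ids <- unique(vapply(quants, function(q) q$region, ""))
  if (length(ids) != 1L)
    stop("all images must share one region id; got: ",
         paste(ids, collapse = ", "), call. = FALSE)
  colMeans(do.call(rbind, lapply(quants, function(q) q$means)))
}

#' Ground-truth per-plane counts at the analysed planes
#'
#' The reference the quantification is judged against: a cell counts on a
#' plane when its rasterized nucleus cross-section there (same rasterizer as
#' the renderer) reaches `min_area_um2`. All simulated cells are tdTomato+.
#'
#' @param truth a [build_scene()] result.
#' @param acq the [acquisition_spec()] used for rendering.
#' @param planes integer plane indices.
#' @param min_area_um2 area filter matching the quantification.
#' @return data.frame with one row per plane: `plane`, `n_nuclei`, `n_mural`,
#'   `n_tdtomato`.
#' @export
truth_plane_counts <- function(truth, acq, planes, min_area_um2 = 10) {
  px_area <- acq$voxel_size_zyx[2] * acq$voxel_size_zyx[3]
  out <- lapply(planes, function(p) {
    n_mural <- 0L; n_all <- 0L
    for (i in seq_len(nrow(truth$cells))) {
      cell <- truth$cells[i, ]
      a <- nrow(spheroid_plane_pixels(cell, acq, p, "nucleus")) * px_area
      if (a >= min_area_um2) {
        n_all <- n_all + 1L
        if (cell$class == "mural") n_mural <- n_mural + 1L
      }
    }
    data.frame(plane = p, n_nuclei = n_all, n_mural = n_mural, n_tdtomato = n_all)
  })
  do.call(rbind, out)
}

# greedy one-to-one matching of predicted to true positions within a radius
greedy_match <- function(pred, truth, radius) {
  if (!nrow(pred) || !nrow(truth))
    return(list(tp = 0L, fp = nrow(pred), fn = nrow(truth)))
  d <- outer(seq_len(nrow(pred)), seq_len(nrow(truth)), function(i, j)
    sqrt((pred$y[i] - truth$y[j])^2 + (pred$x[i] - truth$x[j])^2 +
           (pred$z[i] - truth$z[j])^2))
  pairs <- which(d <= radius, arr.ind = TRUE)
  if (nrow(pairs)) pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_p <- logical(nrow(pred)); used_t <- logical(nrow(truth))
  tp <- 0L
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (used_p[i] || used_t[j]) next
    used_p[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L
  }
  list(tp = tp, fp = sum(!used_p), fn = sum(!used_t))
}

#' Evaluate quantified ROIs against simulated ground truth
#'
#' Matches predicted nuclei to true cells one-to-one (greedy, nearest first)
#' within `match_radius_um`, per class. The truth reference per plane is the
#' set of cells whose rasterized nucleus cross-section on that analysed plane
#' reaches the quantification's area filter — cells falling between analysed
#' planes are not expected to be recovered. Predicted mural ROIs are scored
#' against true mural cells, predicted non-mural tdTomato+ ROIs against true
#' fibroblasts.
#'
#' @param rq a [quantify_region()] result (its `rois` table is used).
#' @param truth the [build_scene()] ground truth the volume was rendered from.
#' @param acq the [acquisition_spec()] used for rendering.
#' @param match_radius_um maximum centroid distance for a match (um).
#' @return data.frame with one row per class (`mural`, `fibroblast`):
#'   `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
evaluate_against_truth <- function(rq, truth, acq, match_radius_um = 5) {
  stopifnot(inherits(rq, "region_quant"), inherits(truth, "ground_truth"))
  planes <- rq$params$planes
  min_area <- rq$params$min_area_um2
  px_area <- acq$voxel_size_zyx[2] * acq$voxel_size_zyx[3]
  vc <- voxel_centers(acq)
  # truth instances: one per (visible cell, plane)
  tr <- list()
  for (p in planes) for (i in seq_len(nrow(truth$cells))) {
    cell <- truth$cells[i, ]
    px <- spheroid_plane_pixels(cell, acq, p, "nucleus")
    if (nrow(px) * px_area >= min_area)
      tr[[length(tr) + 1L]] <- data.frame(class = cell$class, y = cell$cy,
                                          x = cell$cx, z = vc$z[p])
  }
  tr <- if (length(tr)) do.call(rbind, tr) else
    data.frame(class = character(), y = numeric(), x = numeric(), z = numeric())
  pred <- rq$rois
  res <- lapply(c("mural", "fibroblast"), function(cl) {
    p_sel <- if (cl == "mural") pred$is_mural else pred$is_tdtomato & !pred$is_mural
    pd <- data.frame(y = pred$y_um[p_sel], x = pred$x_um[p_sel],
                     z = pred$z_um[p_sel])
    td <- tr[tr$class == cl, , drop = FALSE]
    m <- greedy_match(pd, td, match_radius_um)
    precision <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else NA_real_
    recall <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else NA_real_
    f1 <- if (isTRUE(precision + recall > 0)) 2 * precision * recall /
      (precision + recall) else if (m$tp + m$fp + m$fn == 0) NA_real_ else 0
    data.frame(class = cl, tp = m$tp, fp = m$fp, fn = m$fn,
               precision = precision, recall = recall, f1 = f1)
  })
  do.call(rbind, res)
}
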