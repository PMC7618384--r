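#' Acquisition specification for a simulated confocal z-stack
#'
#' Describes the geometry and noise model of a multi-channel acquisition:
#' voxel grid, physical voxel sizes, z sampling interval, Gaussian PSF widths,
#' and the Poisson-Gaussian (shot + read) noise parameters.
#'
#' @param shape_zyx integer vector of length 3: number of z-planes, rows (y)
#'   and columns (x).
#' @param voxel_size_yx in-plane voxel edge length in micrometres. The default
#'   0.62 um corresponds to a typical 20x/0.8 NA confocal field.
#' @param z_step distance between acquired planes in micrometres; this is also
#'   the z voxel size. Must lie within `z_step_range`.
#' @param z_step_range admissible interval for `z_step` in micrometres.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF standard deviations in
#'   micrometres, in-plane and along z.
#' @param photon_gain expected detected photons per unit intensity; shot noise
#'   is Poisson at this gain.
#' @param read_noise_sd standard deviation of additive Gaussian read noise, in
#'   intensity units.
#' @param background per-channel baseline intensity, a named numeric vector
#'   with entries `FITC`, `tdTomato`, `DAPI` (recycled if length 1).
#'
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(shape_zyx = c(5L, 160L, 160L),
                             voxel_size_yx = 0.62,
                             z_step = 8,
                             z_step_range = c(2, 8),
                             psf_sigma_xy = 0.6,
                             psf_sigma_z = 2,
                             photon_gain = 100,
                             read_noise_sd = 0.01,
                             background = c(FITC = 0.02, tdTomato = 0.02, DAPI = 0.02)) {
  shape_zyx <- as.integer(shape_zyx)
  if (length(shape_zyx) != 3L || any(shape_zyx <= 0L))
    stop("'shape_zyx' must be three strictly positive voxel counts", call. = FALSE)
  if (voxel_size_yx <= 0) stop("'voxel_size_yx' must be positive", call. = FALSE)
  if (z_step < z_step_range[1] || z_step > z_step_range[2])
    stop(sprintf("'z_step' must lie in [%g, %g] um", z_step_range[1], z_step_range[2]),
         call. = FALSE)
  if (psf_sigma_xy < 0 || psf_sigma_z < 0)
    stop("PSF sigmas must be non-negative", call. = FALSE)
  if (read_noise_sd < 0) stop("'read_noise_sd' must be non-negative", call. = FALSE)
  if (length(background) == 1L)
    background <- c(FITC = unname(background), tdTomato = unname(background),
                    DAPI = unname(background))
  background <- background[c("FITC", "tdTomato", "DAPI")]
  if (anyNA(background) || any(background < 0))
    stop("'background' must give a non-negative value for FITC, tdTomato and DAPI",
         call. = FALSE)
  structure(list(
    shape_zyx = shape_zyx,
    voxel_size_zyx = c(z_step, voxel_size_yx, voxel_size_yx),
    z_step = z_step,
    psf_sigma_xy = psf_sigma_xy,
    psf_sigma_z = psf_sigma_z,
    photon_gain = photon_gain,
    read_noise_sd = read_noise_sd,
    background = background
  ), class = "acquisition_spec")
}

#' Physical extent of an acquisition in micrometres (z, y, x)
#' @param acq an [acquisition_spec()].
#' @return numeric length-3 vector of extents in micrometres.
#' @export
acq_extent_um <- function(acq) acq$shape_zyx * acq$voxel_size_zyx

.conditions <- c("sham-ipsi", "psnl-ipsi", "psnl-contra")
.regions <- c("lesion", "proximal", "distal", "away")

#' Define a vessel as a tube around a polyline centerline
#'
#' @param centerline numeric matrix with columns z, y, x (micrometres), one row
#'   per control point; consecutive points are joined by straight segments.
#' @param radius_um lumen radius in micrometres.
#' @param wall_offset_um distance from the lumen surface at which mural somata
#'   sit, in micrometres.
#' @param type free-text morphology label (e.g. "arteriole", "capillary");
#'   passed through unmodified.
#' @return A `vessel_spec` list.
#' @export
vessel_spec <- function(centerline, radius_um, wall_offset_um = 2, type = "capillary") {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 3L || nrow(centerline) < 2L)
    stop("'centerline' must be a matrix of >= 2 rows of (z, y, x) in um", call. = FALSE)
  if (radius_um <= 0) stop("vessel 'radius_um' must be positive", call. = FALSE)
  if (wall_offset_um < 0) stop("'wall_offset_um' must be non-negative", call. = FALSE)
  colnames(centerline) <- c("z", "y", "x")
  structure(list(centerline = centerline, radius_um = radius_um,
                 wall_offset_um = wall_offset_um, type = type),
            class = "vessel_spec")
}

vessel_length_um <- function(v) {
  d <- diff(v$centerline)
  sum(sqrt(rowSums(d^2)))
}

#' Scene specification for a synthetic cleared-nerve region
#'
#' Fixes the geometry and cell placement statistics for one simulated nerve
#' region: vessels, mural-cell density along vessels, fibroblast density in
#' the surrounding tissue, nucleus/soma sizes, and the experimental labels
#' (condition, region) whose effect multipliers scale the densities.
#'
#' @param extent_um physical extent (z, y, x) of the scene in micrometres;
#'   typically `acq_extent_um(acq)`.
#' @param vessels list of [vessel_spec()] objects.
#' @param mural_density mural cells per 100 um of vessel centerline.
#' @param fibroblast_density fibroblasts per 1e5 um^3 of non-vessel tissue.
#' @param nucleus_axes_range range (um) from which nucleus semi-axes are drawn;
#'   must admit in-plane cross-sections of at least 10 um^2.
#' @param mural_nucleus_elongation factor by which a mural nucleus is stretched
#'   along the vessel axis.
#' @param soma_semi_axes_um length-2 vector: soma semi-axis along the cell axis
#'   and perpendicular to it, in micrometres.
#' @param condition experimental condition, one of
#'   `"sham-ipsi"`, `"psnl-ipsi"`, `"psnl-contra"`.
#' @param region nerve region, one of `"lesion"`, `"proximal"`, `"distal"`,
#'   `"away"`.
#' @param effect_multipliers optional data.frame with columns `condition`,
#'   `region`, `mural`, `fibroblast` scaling the densities for matching
#'   (condition, region) pairs; unmatched pairs (including all contralateral
#'   and sham groups by default) use 1.0.
#' @param exclusion_margin_um fibroblasts are rejected closer than this to any
#'   vessel surface (um); guarantees an unambiguous ground-truth class margin.
#' @param seed integer seed making the scene reproducible.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(extent_um,
                       vessels,
                       mural_density = 20,
                       fibroblast_density = 8,
                       nucleus_axes_range = c(2.5, 3.5),
                       mural_nucleus_elongation = 1.4,
                       soma_semi_axes_um = c(8, 3.5),
                       condition = "sham-ipsi",
                       region = "away",
                       effect_multipliers = NULL,
                       exclusion_margin_um = 10,
                       seed = 1L) {
  if (length(extent_um) != 3L || any(extent_um <= 0))
    stop("'extent_um' must be three positive extents (z, y, x)", call. = FALSE)
  if (!length(vessels) || !all(vapply(vessels, inherits, TRUE, "vessel_spec")))
    stop("'vessels' must be a non-empty list of vessel_spec objects", call. = FALSE)
  if (mural_density < 0 || fibroblast_density < 0)
    stop("densities must be non-negative", call. = FALSE)
  if (diff(range(nucleus_axes_range)) < 0 || min(nucleus_axes_range) <= 0)
    stop("'nucleus_axes_range' must be positive", call. = FALSE)
  if (pi * min(nucleus_axes_range)^2 < 10)
    warning("nucleus_axes_range admits equatorial cross-sections below 10 um^2; ",
            "small nuclei may fall under the default area filter")
  condition <- match.arg(condition, .conditions)
  region <- match.arg(region, .regions)
  if (!is.null(effect_multipliers)) {
    need <- c("condition", "region", "mural", "fibroblast")
    if (!all(need %in% names(effect_multipliers)))
      stop("'effect_multipliers' needs columns condition, region, mural, fibroblast",
           call. = FALSE)
    bad <- setdiff(effect_multipliers$condition, .conditions)
    if (length(bad)) stop("unknown condition in effect_multipliers: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    bad <- setdiff(effect_multipliers$region, .regions)
    if (length(bad)) stop("unknown region in effect_multipliers: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  for (v in vessels) {
    if (2 * v$radius_um > min(extent_um[2:3]))
      stop("vessel radius exceeds the scene cross-section; impossible geometry",
           call. = FALSE)
  }
  structure(list(
    extent_um = as.numeric(extent_um),
    vessels = vessels,
    mural_density = mural_density,
    fibroblast_density = fibroblast_density,
    nucleus_axes_range = as.numeric(nucleus_axes_range),
    mural_nucleus_elongation = mural_nucleus_elongation,
    soma_semi_axes_um = as.numeric(soma_semi_axes_um),
    condition = condition,
    region = region,
    effect_multipliers = effect_multipliers,
    exclusion_margin_um = exclusion_margin_um,
    seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Default scene: one straight vessel spanning the field
#'
#' Convenience constructor used throughout the package: a single straight
#' vessel running along x at mid-height, with default densities.
#'
#' The default geometry emulates the vessels actually selected for imaging in
#' cleared-nerve stacks: a clearly visible arteriole-scale vessel whose lumen
#' spans the full analysed z-range, so the vessel mask is present on every
#' analysed plane.
#'
#' @param acq an [acquisition_spec()] fixing the scene extent.
#' @param radius_um vessel lumen radius (um).
#' @param ... further arguments passed to [scene_spec()].
#' @return A `scene_spec`.
#' @export
default_scene_spec <- function(acq, radius_um = 24, ...) {
  ext <- acq_extent_um(acq)
  cl <- rbind(c(ext[1] / 2, ext[2] / 2, 0),
              c(ext[1] / 2, ext[2] / 2, ext[3]))
  scene_spec(extent_um = ext,
             vessels = list(vessel_spec(cl, radius_um = radius_um,
                                        type = "arteriole")),
             ...)
}

# multiplier lookup for a (condition, region) pair; 1.0 when unlisted
effect_multiplier <- function(spec, what = c("mural", "fibroblast")) {
  what <- match.arg(what)
  em <- spec$effect_multipliers
  if (is.null(em)) return(1)
  hit <- em$condition == spec$condition & em$region == spec$region
  if (!any(hit)) return(1)
  as.numeric(em[[what]][which(hit)[1]])
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat("Acquisition:", paste(x$shape_zyx, collapse = " x "),
      "voxels (z y x);", sprintf("voxel %.3g x %.3g x %.3g um;", x$voxel_size_zyx[1],
                                 x$voxel_size_zyx[2], x$voxel_size_zyx[3]),
      sprintf("PSF sigma %.2g/%.2g um (xy/z); gain %g; read sd %g\n",
              x$psf_sigma_xy, x$psf_sigma_z, x$photon_gain, x$read_noise_sd))
  invisible(x)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("Scene %s/%s: %d vessel(s), mural %.3g / 100 um, fibroblast %.3g / 1e5 um^3, seed %d\n",
              x$condition, x$region, length(x$vessels), x$mural_density,
              x$fibroblast_density, x$seed))
  invisible(x)
}
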