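#' Derive a per-sample seed from a master seed
#'
#' Counter-based splitting: each (master, counter) pair maps deterministically
#' to a seed in \[1, 2147483587\], computed in exact double arithmetic.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index.
#' @return a single integer seed.
#' @export
derive_seed <- function(master, counter) {
  m <- as.numeric(master) %% 2147483587
  as.integer((m + as.numeric(counter) * 1000003) %% 2147483587 + 1)
}

# minimum distance from points (n x 3 matrix, um) to a polyline centerline
dist_to_centerline <- function(points, centerline) {
  d <- rep(Inf, nrow(points))
  for (i in seq_len(nrow(centerline) - 1L)) {
    a <- centerline[i, ]
    ab <- centerline[i + 1L, ] - a
    len2 <- sum(ab^2)
    dp <- sweep(points, 2L, a)
    t <- if (len2 > 0) pmin(1, pmax(0, (dp %*% ab)[, 1] / len2)) else 0
    res <- dp - outer(t, ab)
    d <- pmin(d, sqrt(rowSums(res^2)))
  }
  d
}

# point and unit tangent at arc length s along a polyline
point_on_centerline <- function(centerline, s) {
  seg <- diff(centerline)
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  s <- pmin(max(cum), pmax(0, s))
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(i, length(lens))
  t <- (s - cum[i]) / lens[i]
  list(point = centerline[i, , drop = FALSE] + seg[i, , drop = FALSE] * t,
       tangent = seg[i, , drop = FALSE] / lens[i])
}

# orthonormal frame perpendicular to a unit vector
perp_frame <- function(u) {
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  n1 <- ref - sum(ref * u) * u
  n1 <- n1 / sqrt(sum(n1^2))
  n2 <- c(u[2] * n1[3] - u[3] * n1[2],
          u[3] * n1[1] - u[1] * n1[3],
          u[1] * n1[2] - u[2] * n1[1])
  rbind(n1, n2)
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Build the ground-truth cell roster for a scene
#'
#' Draws mural-cell and fibroblast counts from Poisson laws with means
#' density x extent x effect multiplier, places mural cells on vessel
#' surfaces (soma centre at `wall_offset_um` outside the lumen, nucleus
#' elongated along the vessel axis) and fibroblasts uniformly in tissue at
#' least `exclusion_margin_um` away from every vessel surface. Fully
#' reproducible from `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return An object of class `ground_truth`: a list with `cells` (one row per
#'   cell: id, class, centroid, nucleus/soma semi-axes, orientation, distance
#'   to the nearest vessel surface), the vessel geometry, scene extent and
#'   labels.
#' @export
build_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  ext <- spec$extent_um
  nuc_rng <- spec$nucleus_axes_range
  soma <- spec$soma_semi_axes_um
  rows <- list()
  idx <- 0L

  m_mult <- effect_multiplier(spec, "mural")
  nuc_margin <- nuc_rng[2] * spec$mural_nucleus_elongation + 0.5
  for (v in spec$vessels) {
    L <- vessel_length_um(v)
    n <- stats::rpois(1L, spec$mural_density / 100 * L * m_mult)
    if (n == 0L) next
    s_margin <- min(soma[1], L / 2)
    for (j in seq_len(n)) {
      # surface positions whose nucleus leaves the volume (e.g. polar
      # positions on a vessel wider than the stack is deep) are resampled:
      # only the imaged part of the vessel wall carries cells
      ok <- FALSE
      for (try in seq_len(500L)) {
        s <- stats::runif(1, s_margin, L - s_margin)
        phi <- stats::runif(1, 0, 2 * pi)
        pc <- point_on_centerline(v$centerline, s)
        u <- as.numeric(pc$tangent)
        fr <- perp_frame(u)
        radial <- cos(phi) * fr[1, ] + sin(phi) * fr[2, ]
        ctr <- as.numeric(pc$point) + (v$radius_um + v$wall_offset_um) * radial
        if (all(ctr >= nuc_margin) && all(ctr <= ext - nuc_margin)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop("no part of the vessel surface fits inside the volume; ",
             "impossible geometry", call. = FALSE)
      a_perp <- stats::runif(1, nuc_rng[1], nuc_rng[2])
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        id = idx, class = "mural",
        cz = ctr[1], cy = ctr[2], cx = ctr[3],
        nuc_along = a_perp * spec$mural_nucleus_elongation,
        nuc_perp = a_perp,
        uz = u[1], uy = u[2], ux = u[3],
        soma_along = soma[1], soma_perp = soma[2],
        dist_surface_um = v$wall_offset_um)
    }
  }

  f_mult <- effect_multiplier(spec, "fibroblast")
  vol_vessels <- sum(vapply(spec$vessels,
                            function(v) pi * v$radius_um^2 * vessel_length_um(v), 0))
  vol_tissue <- max(0, prod(ext) - vol_vessels)
  n_fib <- stats::rpois(1L, spec$fibroblast_density / 1e5 * vol_tissue * f_mult)
  if (n_fib > 0L) {
    margin <- nuc_rng[2] + 0.5
    placed <- 0L
    tries <- 0L
    max_tries <- 10000L * n_fib
    while (placed < n_fib && tries < max_tries) {
      tries <- tries + 1L
      ctr <- stats::runif(3, margin, ext - margin)
      dsurf <- min(vapply(spec$vessels, function(v)
        dist_to_centerline(matrix(ctr, 1L), v$centerline) - v$radius_um, 0))
      if (dsurf <= spec$exclusion_margin_um) next
      placed <- placed + 1L
      idx <- idx + 1L
      a <- stats::runif(1, nuc_rng[1], nuc_rng[2])
      u <- random_unit_vector()
      rows[[idx]] <- data.frame(
        id = idx, class = "fibroblast",
        cz = ctr[1], cy = ctr[2], cx = ctr[3],
        nuc_along = a, nuc_perp = a,
        uz = u[1], uy = u[2], ux = u[3],
        soma_along = soma[2], soma_perp = soma[2],
        dist_surface_um = dsurf)
    }
    if (placed < n_fib)
      stop("could not place fibroblasts outside the exclusion margin; ",
           "scene too crowded for the requested density", call. = FALSE)
  }

  cells <- if (idx > 0L) do.call(rbind, rows) else
    data.frame(id = integer(), class = character(), cz = numeric(), cy = numeric(),
               cx = numeric(), nuc_along = numeric(), nuc_perp = numeric(),
               uz = numeric(), uy = numeric(), ux = numeric(),
               soma_along = numeric(), soma_perp = numeric(),
               dist_surface_um = numeric())
  rownames(cells) <- NULL
  structure(list(
    cells = cells,
    vessels = spec$vessels,
    extent_um = ext,
    condition = spec$condition,
    region = spec$region,
    exclusion_margin_um = spec$exclusion_margin_um,
    totals = c(mural = sum(cells$class == "mural"),
               fibroblast = sum(cells$class == "fibroblast")),
    seed = spec$seed
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth %s/%s: %d mural + %d fibroblast cells, %d vessel(s)\n",
              x$condition, x$region, x$totals[["mural"]], x$totals[["fibroblast"]],
              length(x$vessels)))
  invisible(x)
}

# voxel-centre coordinate vectors (um) for an acquisition
voxel_centers <- function(acq) {
  vs <- acq$voxel_size_zyx
  sh <- acq$shape_zyx
  list(z = (seq_len(sh[1]) - 0.5) * vs[1],
       y = (seq_len(sh[2]) - 0.5) * vs[2],
       x = (seq_len(sh[3]) - 0.5) * vs[3])
}

# indices (iy, ix) of voxel centres inside a cell's spheroid on one z-plane;
# `which_axes` selects nucleus or soma semi-axes
spheroid_plane_pixels <- function(cell, acq, plane, what = c("nucleus", "soma")) {
  what <- match.arg(what)
  a_along <- if (what == "nucleus") cell$nuc_along else cell$soma_along
  a_perp <- if (what == "nucleus") cell$nuc_perp else cell$soma_perp
  vc <- voxel_centers(acq)
  zc <- vc$z[plane]
  rmax <- max(a_along, a_perp)
  if (abs(zc - cell$cz) > rmax) return(cbind(iy = integer(), ix = integer()))
  iy <- which(abs(vc$y - cell$cy) <= rmax)
  ix <- which(abs(vc$x - cell$cx) <= rmax)
  if (!length(iy) || !length(ix)) return(cbind(iy = integer(), ix = integer()))
  g <- expand.grid(iy = iy, ix = ix)
  dz <- zc - cell$cz
  dy <- vc$y[g$iy] - cell$cy
  dx <- vc$x[g$ix] - cell$cx
  proj <- dz * cell$uz + dy * cell$uy + dx * cell$ux
  r2 <- dz^2 + dy^2 + dx^2
  inside <- proj^2 / a_along^2 + (r2 - proj^2) / a_perp^2 <= 1
  cbind(iy = g$iy[inside], ix = g$ix[inside])
}

# paint value into a (ny, nx, nz) array at spheroid voxels, keeping the max
paint_spheroid <- function(arr, cell, acq, value, what) {
  for (plane in seq_len(acq$shape_zyx[1])) {
    px <- spheroid_plane_pixels(cell, acq, plane, what)
    if (nrow(px)) {
      lin <- px[, "iy"] + (px[, "ix"] - 1L) * dim(arr)[1] +
        (plane - 1L) * dim(arr)[1] * dim(arr)[2]
      arr[lin] <- pmax(arr[lin], value)
    }
  }
  arr
}

# rasterize vessel lumens into a (ny, nx, nz) array
rasterize_vessels <- function(vessels, acq, value = 1) {
  sh <- acq$shape_zyx
  arr <- array(0, dim = c(sh[2], sh[3], sh[1]))
  vc <- voxel_centers(acq)
  grid <- expand.grid(y = vc$y, x = vc$x, z = vc$z) # matches array linear order
  pts <- cbind(grid$z, grid$y, grid$x)
  inside <- rep(FALSE, nrow(pts))
  for (v in vessels)
    inside <- inside | (dist_to_centerline(pts, v$centerline) <= v$radius_um)
  arr[inside] <- value
  arr
}

# 1D normalized Gaussian kernel; NULL when sigma is negligible
gauss_kernel <- function(sigma_px) {
  if (sigma_px < 1e-3) return(NULL)
  k <- ceiling(3 * sigma_px)
  w <- exp(-(-k:k)^2 / (2 * sigma_px^2))
  w / sum(w)
}

# separable zero-padded Gaussian blur of a (ny, nx, nz) array
blur_volume <- function(arr, sigma_y_px, sigma_x_px, sigma_z_px) {
  for (axis in 1:3) {
    w <- gauss_kernel(c(sigma_y_px, sigma_x_px, sigma_z_px)[axis])
    if (is.null(w)) next
    k <- (length(w) - 1L) / 2L
    n <- dim(arr)[axis]
    out <- array(0, dim = dim(arr))
    for (j in seq_along(w)) {
      off <- j - k - 1L
      src <- seq_len(n) + off
      keep <- src >= 1L & src <= n
      if (!any(keep)) next
      dst <- which(keep)
      src <- src[keep]
      if (axis == 1L) out[dst, , ] <- out[dst, , ] + w[j] * arr[src, , ]
      else if (axis == 2L) out[, dst, ] <- out[, dst, ] + w[j] * arr[, src, ]
      else out[, , dst] <- out[, , dst] + w[j] * arr[, , src]
    }
    arr <- out
  }
  arr
}

#' Render a ground-truth scene into a noisy multi-channel volume
#'
#' FITC receives the rasterized vessel lumens (the intravascular FITC-albumin
#' fill), tdTomato the somata of all Pdgfrb-lineage cells, DAPI the nuclear
#' spheroids. Per-channel background is added, then (optionally) a separable
#' Gaussian PSF blur, Poisson shot noise at `photon_gain`, and additive
#' Gaussian read noise. Deterministic given (truth, acq, seed).
#'
#' @param truth a [build_scene()] result.
#' @param acq an [acquisition_spec()]; the truth extent must fit inside it.
#' @param seed integer seed for the noise draws.
#' @param blur,noise logical switches for PSF blur and for the
#'   Poisson-Gaussian noise.
#' @param amplitudes named per-channel signal amplitude (intensity units).
#' @return An object of class `multichannel_volume`: named channel arrays of
#'   dimension (ny, nx, nz) plus the acquisition metadata.
#' @export
render_volume <- function(truth, acq, seed = 1L, blur = TRUE, noise = TRUE,
                          amplitudes = c(FITC = 1, tdTomato = 1, DAPI = 1)) {
  stopifnot(inherits(truth, "ground_truth"), inherits(acq, "acquisition_spec"))
  if (any(truth$extent_um > acq_extent_um(acq) + 1e-6))
    stop("ground truth extent exceeds the acquisition volume", call. = FALSE)
  if (noise && acq$photon_gain <= 0)
    stop("'photon_gain' must be positive when shot noise is enabled", call. = FALSE)
  sh <- acq$shape_zyx
  dims <- c(sh[2], sh[3], sh[1])

  fitc <- rasterize_vessels(truth$vessels, acq, value = amplitudes[["FITC"]])
  tdt <- array(0, dim = dims)
  dapi <- array(0, dim = dims)
  for (i in seq_len(nrow(truth$cells))) {
    cell <- truth$cells[i, ]
    tdt <- paint_spheroid(tdt, cell, acq, amplitudes[["tdTomato"]], "soma")
    dapi <- paint_spheroid(dapi, cell, acq, amplitudes[["DAPI"]], "nucleus")
  }
  ch <- list(FITC = fitc + acq$background[["FITC"]],
             tdTomato = tdt + acq$background[["tdTomato"]],
             DAPI = dapi + acq$background[["DAPI"]])

  if (blur) {
    sxy <- acq$psf_sigma_xy / acq$voxel_size_zyx[2]
    sz <- acq$psf_sigma_z / acq$voxel_size_zyx[1]
    ch <- lapply(ch, blur_volume, sigma_y_px = sxy, sigma_x_px = sxy,
                 sigma_z_px = sz)
  }
  if (noise) {
    set.seed(seed)
    ch <- lapply(ch, function(x) {
      v <- stats::rpois(length(x), acq$photon_gain * as.numeric(x)) / acq$photon_gain
      v <- v + stats::rnorm(length(x), 0, acq$read_noise_sd)
      array(pmax(0, v), dim = dim(x))
    })
  }
  structure(list(channels = ch, acquisition = acq, amplitudes = amplitudes,
                 condition = truth$condition, region = truth$region,
                 render_seed = as.integer(seed), blur = blur, noise = noise),
            class = "multichannel_volume")
}

#' @export
print.multichannel_volume <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Multi-channel volume %s/%s: %d x %d x %d (y x z), channels %s\n",
              x$condition, x$region, d[1], d[2], d[3],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Simulate a labelled group design
#'
#' Emits `n` independent (volume, truth) pairs per (condition, region) group,
#' with per-sample seeds derived from the master seed by counter-based
#' splitting, so any sample can be regenerated independently.
#'
#' @param design data.frame with columns `condition`, `region`, `n`.
#' @param base_spec a [scene_spec()] providing geometry and densities; its
#'   condition/region are overridden per group (effect multipliers then apply).
#' @param acq an [acquisition_spec()].
#' @param seed master integer seed.
#' @param ... passed to [render_volume()] (e.g. `blur`, `noise`).
#' @return list of samples, each a list with `volume`, `truth`, `condition`,
#'   `region`, `sample` (index within group).
#' @export
simulate_group <- function(design, base_spec, acq, seed = 1L, ...) {
  stopifnot(is.data.frame(design), all(c("condition", "region", "n") %in% names(design)))
  bad <- setdiff(design$condition, .conditions)
  if (length(bad)) stop("unknown condition: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(design$region, .regions)
  if (length(bad)) stop("unknown region: ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(design$n < 1)) stop("each group needs n >= 1", call. = FALSE)
  out <- list()
  counter <- 0L
  for (g in seq_len(nrow(design))) {
    for (i in seq_len(design$n[g])) {
      counter <- counter + 1L
      sp <- base_spec
      sp$condition <- design$condition[g]
      sp$region <- design$region[g]
      sp$seed <- derive_seed(seed, 2L * counter - 1L)
      truth <- build_scene(sp)
      vol <- render_volume(truth, acq, seed = derive_seed(seed, 2L * counter), ...)
      out[[length(out) + 1L]] <- list(volume = vol, truth = truth,
                                      condition = design$condition[g],
                                      region = design$region[g], sample = i)
    }
  }
  out
}
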