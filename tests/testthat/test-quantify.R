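acq_px <- acquisition_spec(shape_zyx = c(1L, 64L, 64L), voxel_size_yx = 1,
                           z_step = 8, psf_sigma_xy = 0, psf_sigma_z = 0,
                           background = 0)

test_that("IsoData threshold separates bimodal data and matches its fixed point", {
  x <- c(rep(0, 400), rep(100, 100))
  t <- isodata_threshold(x)
  expect_gt(t, 0)
  expect_lt(t, 100)

  set.seed(4)
  y <- c(rnorm(4000, 20, 3), rnorm(1000, 80, 6))
  t2 <- isodata_threshold(y, n_bins = 512L)
  # independent fixed-point oracle on the raw values
  expect_lt(abs(t2 - isodata_oracle(y)), diff(range(y)) / 512 * 2)

  expect_error(isodata_threshold(rep(5, 100)), "degenerate")
})

test_that("cross-channel thresholding copies the FITC value onto tdTomato", {
  vol <- make_vol(list(FITC = array(runif(64), c(4, 4, 4)),
                       tdTomato = array(runif(64), c(4, 4, 4))),
                  acq_px)
  fitc <- compute_threshold(vol, "FITC", "manual", manual_value = 40)
  td <- compute_threshold(vol, "tdTomato", "cross", source_threshold = fitc)
  expect_s3_class(td, "channel_threshold")
  expect_equal(td$channel, "tdTomato")
  expect_equal(td$value, 40)
  expect_equal(td$source_channel, "FITC")
  expect_error(compute_threshold(vol, "tdTomato", "cross"), "source_threshold")
  expect_error(compute_threshold(vol, "FITC", "manual"), "manual_value")
})

test_that("vessel mask is the strict FITC superlevel set with correct areas", {
  acq <- acquisition_spec(background = 0)
  sp <- default_scene_spec(acq, mural_density = 0, fibroblast_density = 0,
                           radius_um = 10)
  tr <- build_scene(sp)
  vol <- render_volume(tr, acq, blur = FALSE, noise = FALSE)
  vm <- make_vessel_mask(vol, 0.5)
  expect_identical(vm$mask, vol$channels$FITC > 0.5)
  # mid-vessel plane area vs the rasterization oracle (brute-force count)
  vs <- acq$voxel_size_zyx
  p <- 3L
  zc <- (p - 0.5) * vs[1]
  n_oracle <- 0L
  for (iy in 1:acq$shape_zyx[2]) {
    dy2 <- ((iy - 0.5) * vs[2] - 49.6)^2
    if (dy2 + (zc - 20)^2 <= 100) n_oracle <- n_oracle + acq$shape_zyx[3]
  }
  expect_lt(abs(vm$area_per_plane_um2[p] - n_oracle * vs[2] * vs[3]),
            0.1 * n_oracle * vs[2] * vs[3])
  # threshold above the channel max: empty mask, zero areas
  vm0 <- make_vessel_mask(vol, max(vol$channels$FITC) + 1)
  expect_false(any(vm0$mask))
  expect_true(all(vm0$area_per_plane_um2 == 0))
})

test_that("mask broadening is an exact-disk dilation: identity, cardinality, extensivity", {
  one <- array(0, c(31, 31, 1)); one[16, 16, 1] <- 1
  vm <- structure(list(mask = one > 0, area_per_plane_um2 = 1, threshold = 0,
                       broadened = FALSE, broaden_radius_um = 0,
                       voxel_size_zyx = c(8, 1, 1)), class = "vessel_mask")
  expect_identical(broaden_mask(vm, 0)$mask, vm$mask)
  for (r in c(1, 2, 3, 5)) {
    b <- broaden_mask(vm, r)
    expect_equal(sum(b$mask), disk_count_oracle(r))
    expect_true(b$broadened)
  }
  expect_error(broaden_mask(vm, -1), "non-negative")
  set.seed(8)
  for (i in 1:5) {
    m <- array(runif(31 * 31) < 0.05, c(31, 31, 1))
    vm$mask <- m
    b <- broaden_mask(vm, sample(1:4, 1))
    expect_true(all(b$mask[m]))  # dilation is extensive
  }
})

test_that("nucleus segmentation finds, sizes and splits disk-shaped nuclei", {
  blank <- make_vol(list(DAPI = array(0, c(64, 64, 1))), acq_px)
  expect_length(segment_nuclei(blank, 1, blur_sigma_um = 0), 0L)

  two <- matrix(0, 64, 64)
  two <- paint_disk(two, 20, 20, 4)
  two <- paint_disk(two, 20, 44, 4)
  vol <- make_vol(list(DAPI = array(two, c(64, 64, 1))), acq_px)
  rois <- segment_nuclei(vol, 1, blur_sigma_um = 0, threshold = 0.5)
  expect_length(rois, 2L)
  target <- sum(paint_disk(matrix(0, 64, 64), 20, 20, 4))
  for (r in rois) expect_lt(abs(r$area_um2 - target), 0.15 * target)
  cys <- sort(vapply(rois, function(r) r$centroid_um[["x"]], 0))
  expect_lt(abs(cys[1] - 19.5), 1)
  expect_lt(abs(cys[2] - 43.5), 1)

  # overlapping disks are split by the watershed
  ov <- matrix(0, 64, 64)
  ov <- paint_disk(ov, 30, 28, 4)
  ov <- paint_disk(ov, 30, 34, 4)   # centres 6 px apart, overlap ~2 px
  vol2 <- make_vol(list(DAPI = array(ov, c(64, 64, 1))), acq_px)
  rois2 <- segment_nuclei(vol2, 1, blur_sigma_um = 0, threshold = 0.5)
  expect_length(rois2, 2L)
})

test_that("counting rules: area filter, overlap classes, empty masks", {
  mk_roi <- function(id, pixels, area) {
    structure(list(id = id, plane = 1L, pixels = pixels, area_um2 = area,
                   centroid_um = c(y = 1, x = 1)), class = "nucleus_roi")
  }
  dimp <- c(20, 20)
  td <- matrix(FALSE, 20, 20); td[1:10, 1:20] <- TRUE
  vb <- matrix(FALSE, 20, 20); vb[1:20, 1:10] <- TRUE
  # r1 in td & vessel; r2 in td only; r3 outside both; r4 below min area
  r1 <- mk_roi(1L, which(matrix(seq_len(400), 20, 20) %in% (0:3 * 20 + 5)), 12)
  r1$pixels <- c(5L, 25L, 45L)                      # rows 5, col 1..3 -> td & vb
  r2 <- mk_roi(2L, c(5L + 15L * 20L, 6L + 15L * 20L), 12)  # td, not vb
  r3 <- mk_roi(3L, c(15L + 15L * 20L), 12)          # neither
  r4 <- mk_roi(4L, c(7L), 9)                        # under the 10 um^2 filter
  cc <- classify_and_count(list(r1, r2, r3, r4), td, vb)
  expect_equal(unname(cc$counts), c(3L, 1L, 2L))
  expect_equal(cc$counts[["n_mural"]], 1L)
  expect_false(4L %in% cc$rois$id)

  cc0 <- classify_and_count(list(r1, r2, r3), matrix(FALSE, 20, 20), vb)
  expect_equal(unname(cc0$counts), c(3L, 0L, 0L))
  expect_error(classify_and_count(list(r1), td, matrix(FALSE, 10, 10)), "shape")
})

test_that("plane selection: five planes 8 um apart by default, errors otherwise", {
  acq <- acquisition_spec()  # z_step 8, 5 planes
  vol <- make_vol(list(FITC = array(0, c(8, 8, 5)),
                       tdTomato = array(0, c(8, 8, 5)),
                       DAPI = array(0, c(8, 8, 5))), acq)
  rq <- quantify_region(vol, list(fitc = 1, tdtomato = 1))
  expect_equal(rq$params$planes, 1:5)
  expect_equal(nrow(rq$per_plane), 5L)
  expect_error(
    quantify_region(vol, list(fitc = 1, tdtomato = 1),
                    planes_spec = list(n_planes = 5L, spacing_um = 5)),
    "not a multiple")
  expect_error(
    quantify_region(vol, list(fitc = 1, tdtomato = 1),
                    planes_spec = list(n_planes = 7L, spacing_um = 8)),
    "do not fit")
  # averaged counts are the arithmetic means of per-plane counts
  expect_equal(rq$means[["n_nuclei"]], mean(rq$per_plane$n_nuclei))
})

test_that("region averaging is mean-over-planes then mean-over-images", {
  stub <- function(mural) {
    structure(list(region = "distal", condition = "psnl-ipsi",
                   means = c(n_nuclei = 10, n_mural = mural, n_tdtomato = 8,
                             vessel_area_um2 = 100)),
              class = "region_quant")
  }
  agg <- aggregate_region(list(stub(4), stub(6)))
  expect_equal(agg[["n_mural"]], 5)
  bad <- stub(4); bad$region <- "lesion"
  expect_error(aggregate_region(list(stub(4), bad)), "one region id")
})

test_that("counts are ordered and area-filtered on randomized volumes", {
  acq <- acquisition_spec(shape_zyx = c(5L, 128L, 128L))
  for (s in 1:6) {
    set.seed(s)
    sp <- default_scene_spec(acq, radius_um = sample(c(12, 24), 1),
                             mural_density = runif(1, 5, 30),
                             fibroblast_density = runif(1, 2, 12),
                             seed = 400L + s)
    tr <- build_scene(sp)
    vol <- render_volume(tr, acq, seed = 500L + s)
    fitc <- compute_threshold(vol, "FITC", "auto")
    td <- compute_threshold(vol, "tdTomato", "cross", source_threshold = fitc)
    rq <- quantify_region(vol, list(fitc = fitc, tdtomato = td),
                          broaden_radius_um = runif(1, 2, 8))
    expect_true(all(rq$per_plane$n_mural <= rq$per_plane$n_tdtomato))
    expect_true(all(rq$per_plane$n_tdtomato <= rq$per_plane$n_nuclei))
    expect_true(all(rq$rois$area_um2 >= 10))
  }
})

test_that("mural counts are non-decreasing in the broadening radius", {
  acq <- acquisition_spec()
  sp <- default_scene_spec(acq, seed = 21L)
  tr <- build_scene(sp)
  vol <- render_volume(tr, acq, seed = 22L)
  fitc <- compute_threshold(vol, "FITC", "auto")
  td <- compute_threshold(vol, "tdTomato", "cross", source_threshold = fitc)
  murals <- vapply(c(0, 2, 5, 10), function(r) {
    quantify_region(vol, list(fitc = fitc, tdtomato = td),
                    broaden_radius_um = r)$means[["n_mural"]]
  }, 0)
  expect_true(all(diff(murals) >= 0))
})

test_that("noise-free volumes are recovered exactly against rasterized truth", {
  acq <- acquisition_spec()
  tr <- find_separated_scene(acq)  # precondition: non-overlapping nuclei
  vol <- render_volume(tr, acq, blur = FALSE, noise = FALSE)
  fitc <- compute_threshold(vol, "FITC", "manual", manual_value = 0.5)
  td <- compute_threshold(vol, "tdTomato", "cross", source_threshold = fitc)
  rq <- quantify_region(vol, list(fitc = fitc, tdtomato = td),
                        segment_args = list(blur_sigma_um = 0, threshold = 0.5))
  tc <- truth_plane_counts(tr, acq, rq$params$planes)
  expect_identical(rq$per_plane$n_nuclei, tc$n_nuclei)
  expect_identical(rq$per_plane$n_mural, tc$n_mural)
  expect_identical(rq$per_plane$n_tdtomato, tc$n_tdtomato)
})

test_that("evaluation against truth counts matches a constructed confusion", {
  acq <- acquisition_spec()
  mk_cell <- function(id, y, x) data.frame(
    id = id, class = "mural", cz = 20, cy = y, cx = x, nuc_along = 3,
    nuc_perp = 3, uz = 0, uy = 0, ux = 1, soma_along = 5, soma_perp = 5,
    dist_surface_um = 2)
  truth <- structure(list(cells = do.call(rbind, list(
    mk_cell(1, 20, 20), mk_cell(2, 40, 40), mk_cell(3, 60, 60),
    mk_cell(4, 80, 80)))), class = "ground_truth")
  pred <- data.frame(id = 1:4, plane = 3L, area_um2 = 20,
                     y_um = c(20, 40, 60, 5), x_um = c(21, 41, 61, 5),
                     is_tdtomato = TRUE, is_mural = TRUE, z_um = 20)
  rq <- structure(list(rois = pred,
                       params = list(planes = 3L, min_area_um2 = 10)),
                  class = "region_quant")
  ev <- evaluate_against_truth(rq, truth, acq)
  mur <- ev[ev$class == "mural", ]
  expect_equal(mur$tp, 3L)
  expect_equal(mur$fp, 1L)
  expect_equal(mur$fn, 1L)
  expect_equal(mur$precision, 0.75)
  expect_equal(mur$recall, 0.75)
  # zero predictions -> recall 0
  rq0 <- rq; rq0$rois <- pred[0, ]
  ev0 <- evaluate_against_truth(rq0, truth, acq)
  expect_equal(ev0[ev0$class == "mural", "recall"], 0)
})
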