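test_that("empty scene has vessels only and renders to background", {
  acq <- acquisition_spec()
  sp <- default_scene_spec(acq, mural_density = 0, fibroblast_density = 0,
                           seed = 1L)
  tr <- build_scene(sp)
  expect_equal(nrow(tr$cells), 0L)
  expect_equal(unname(tr$totals), c(0L, 0L))
  expect_length(tr$vessels, 1L)

  # fully empty truth (no vessels either), zero background, no noise -> zeros
  tr0 <- tr
  tr0$vessels <- list()
  acq0 <- acquisition_spec(background = 0)
  vol <- render_volume(tr0, acq0, blur = FALSE, noise = FALSE)
  expect_true(all(vapply(vol$channels, function(x) all(x == 0), TRUE)))
})

test_that("mural counts follow the Poisson law of density x length", {
  # one straight 200 um vessel at 5 cells / 100 um -> Poisson mean 10
  v <- vessel_spec(rbind(c(20, 30, 0), c(20, 30, 200)), radius_um = 6)
  sp <- scene_spec(extent_um = c(40, 60, 200), vessels = list(v),
                   mural_density = 5, fibroblast_density = 0)
  counts <- vapply(1:1000, function(s) {
    sp$seed <- s
    build_scene(sp)$totals[["mural"]]
  }, 0)
  se <- sqrt(10 / 1000)
  expect_lt(abs(mean(counts) - 10), 3 * se)
  expect_gt(stats::var(counts), 5)  # genuinely dispersed, not degenerate
})

test_that("scenes and renders are deterministic under a fixed seed", {
  acq <- acquisition_spec()
  sp <- default_scene_spec(acq, seed = 99L)
  t1 <- build_scene(sp)
  t2 <- build_scene(sp)
  expect_identical(t1, t2)
  v1 <- render_volume(t1, acq, seed = 7L)
  v2 <- render_volume(t2, acq, seed = 7L)
  expect_identical(v1$channels, v2$channels)
  v3 <- render_volume(t1, acq, seed = 8L)
  expect_false(identical(v1$channels, v3$channels))
})

test_that("mural cells sit on the vessel wall, fibroblasts outside the margin", {
  acq <- acquisition_spec()
  for (s in 1:5) {
    sp <- default_scene_spec(acq, seed = 300L + s)
    tr <- build_scene(sp)
    v <- tr$vessels[[1]]
    # straight vessel along x: radial distance in the (z, y) plane
    ax <- v$centerline[1, c("z", "y")]
    mural <- tr$cells[tr$cells$class == "mural", ]
    if (nrow(mural)) {
      d_axis <- sqrt((mural$cz - ax[1])^2 + (mural$cy - ax[2])^2)
      expect_true(all(abs(d_axis - v$radius_um) <= v$wall_offset_um + 1e-9))
      expect_true(all(mural$dist_surface_um <= v$wall_offset_um + 1e-9))
    }
    fib <- tr$cells[tr$cells$class == "fibroblast", ]
    if (nrow(fib)) {
      d_axis <- sqrt((fib$cz - ax[1])^2 + (fib$cy - ax[2])^2)
      expect_true(all(d_axis - v$radius_um > sp$exclusion_margin_um))
    }
  }
})

test_that("rendered nucleus intensity equals amplitude times voxel count", {
  acq <- acquisition_spec(background = 0)
  sp <- default_scene_spec(acq, mural_density = 0, fibroblast_density = 0)
  tr <- build_scene(sp)
  tr$vessels <- list()
  tr$cells <- data.frame(id = 1L, class = "fibroblast", cz = 20, cy = 50,
                         cx = 50, nuc_along = 3, nuc_perp = 3,
                         uz = 0, uy = 0, ux = 1, soma_along = 5, soma_perp = 5,
                         dist_surface_um = 99)
  vol <- render_volume(tr, acq, blur = FALSE, noise = FALSE,
                       amplitudes = c(FITC = 1, tdTomato = 1, DAPI = 2.5))
  # brute-force voxel-count oracle over the whole grid
  vs <- acq$voxel_size_zyx
  n_inside <- 0L
  for (iz in 1:acq$shape_zyx[1]) for (iy in 1:acq$shape_zyx[2])
    for (ix in 1:acq$shape_zyx[3]) {
      d2 <- ((iz - 0.5) * vs[1] - 20)^2 + ((iy - 0.5) * vs[2] - 50)^2 +
        ((ix - 0.5) * vs[3] - 50)^2
      if (d2 <= 9) n_inside <- n_inside + 1L
    }
  expect_equal(sum(vol$channels$DAPI), 2.5 * n_inside)
})

test_that("PSF blur conserves intensity and rendering is linear in amplitude", {
  acq <- acquisition_spec(background = 0)
  sp <- default_scene_spec(acq, seed = 12L)
  tr <- build_scene(sp)
  tr$vessels <- list()  # keep the object interior so zero-padding loses nothing
  v1 <- render_volume(tr, acq, blur = FALSE, noise = FALSE)
  v2 <- render_volume(tr, acq, blur = TRUE, noise = FALSE)
  for (ch in c("tdTomato", "DAPI")) {
    tot <- sum(v1$channels[[ch]])
    expect_lt(abs(sum(v2$channels[[ch]]) - tot), 0.001 * tot)
  }
  v3 <- render_volume(tr, acq, blur = FALSE, noise = FALSE,
                      amplitudes = c(FITC = 2, tdTomato = 2, DAPI = 2))
  for (ch in names(v1$channels))
    expect_equal(sum(v3$channels[[ch]]), 2 * sum(v1$channels[[ch]]))
})

test_that("group simulation emits labelled pairs with derived seeds", {
  acq <- acquisition_spec(shape_zyx = c(5L, 96L, 96L))
  sp <- default_scene_spec(acq, radius_um = 10, fibroblast_density = 2)
  design <- data.frame(condition = c("sham-ipsi", "psnl-ipsi"),
                       region = c("away", "distal"), n = c(5L, 6L))
  out <- simulate_group(design, sp, acq, seed = 1L, blur = FALSE, noise = FALSE)
  expect_length(out, 11L)
  expect_equal(sum(vapply(out, function(s) s$condition == "psnl-ipsi", TRUE)), 6L)
  expect_equal(out[[1]]$truth$condition, "sham-ipsi")
  expect_equal(out[[11]]$region, "distal")
  # unknown labels rejected
  bad <- data.frame(condition = "psnl-ipsi", region = "nowhere", n = 2L)
  expect_error(simulate_group(bad, sp, acq, 1L), "unknown region")
})

test_that("effect multipliers scale mean ground-truth mural counts", {
  em <- data.frame(condition = "psnl-ipsi", region = "distal",
                   mural = 2, fibroblast = 1)
  acq <- acquisition_spec()
  base <- default_scene_spec(acq, fibroblast_density = 0,
                             effect_multipliers = em)
  count_for <- function(cond, region, s) {
    sp <- base
    sp$condition <- cond; sp$region <- region; sp$seed <- s
    build_scene(sp)$totals[["mural"]]
  }
  c_ctrl <- vapply(1:200, function(s) count_for("psnl-contra", "distal", s), 0)
  c_inj <- vapply(1:200, function(s) count_for("psnl-ipsi", "distal", 5000 + s), 0)
  ratio <- mean(c_inj) / mean(c_ctrl)
  # Poisson-mean ratio oracle: lambda and 2*lambda, 200 seeds each
  expect_lt(abs(ratio - 2), 0.25)
  # sham/contralateral default to multiplier 1.0
  c_sham <- vapply(1:50, function(s) count_for("sham-ipsi", "away", s), 0)
  expect_lt(abs(mean(c_sham) / mean(c_ctrl[1:50]) - 1), 0.35)
})

test_that("derived seeds are deterministic, distinct and within integer range", {
  s <- vapply(0:999, function(k) derive_seed(123L, k), 0L)
  expect_identical(s, vapply(0:999, function(k) derive_seed(123L, k), 0L))
  expect_equal(length(unique(s)), 1000L)
  expect_true(all(s >= 1 & s <= .Machine$integer.max))
})
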