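# Build a volume directly with a chosen voxel field.
field_volume <- function(f, nx = 4, ny = 4, nz = 5, zsp = 2.5) {
  data <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) data[, , k] <- f((k - 1) * zsp)
  ctcurate:::new_ct_volume(data, spacing = c(0.7, 0.7, zsp))
}

test_that("volumes assemble from sorted slices with inferred z spacing", {
  dir <- withr::local_tempdir()
  make_series(series_spec(series_id = "VOL", n_slices = 4, rows = 16, cols = 16,
                          phantom = "z_ramp", slice_thickness = 2.5), dir)
  s <- read_series(dir)
  vol <- assemble_volume(s)
  expect_equal(dim(vol$data), c(16, 16, 4))
  expect_equal(vol$spacing, c(0.703125, 0.703125, 2.5))
  # z-ramp phantom: every voxel of slice k holds 10 * z_k after HU rescale
  for (k in 1:4) expect_true(all(vol$data[, , k] == 10 * (k - 1) * 2.5))

  # shuffled input assembles identically (sorted first)
  sh <- s
  sh$instances <- s$instances[c(3, 1, 4, 2)]
  expect_identical(assemble_volume(sh)$data, vol$data)
})

test_that("assembly refuses heterogeneous geometry and gapped stacks", {
  dir <- withr::local_tempdir()
  make_series(series_spec(series_id = "HET", n_slices = 3, rows = 8, cols = 8), dir)
  s <- read_series(dir)
  s$instances[[2]]$elements[[tag_for("Rows")]]$value <- 16L
  expect_error(assemble_volume(s), class = "ctcurate_geometry_error")

  dir2 <- withr::local_tempdir()
  make_series(series_spec(series_id = "GAPV", n_slices = 6, rows = 8, cols = 8,
                          defects = list(defect("remove_slice", index = 3))), dir2)
  expect_error(assemble_volume(read_series(dir2)),
               class = "ctcurate_missing_slice_error")
})

test_that("z-linear resampling is exact on fields affine in z", {
  vol <- field_volume(function(z) 3.7 * z - 12, nz = 5, zsp = 2.5)
  out <- resample_z_linear(vol, 0.7)
  zs <- (seq_len(dim(out$data)[3]) - 1) * 0.7
  for (k in seq_along(zs)) {
    expect_lt(max(abs(out$data[, , k] - (3.7 * zs[k] - 12))),
              1e-9 * max(1, abs(3.7 * zs[k] - 12)))
  }
  # endpoints reproduced exactly, no extrapolation beyond the extent
  expect_identical(out$data[, , 1], vol$data[, , 1])
  expect_lte(max(zs), (5 - 1) * 2.5 + 1e-9)

  # two slices 0 and 10, midway sample is 5
  two <- field_volume(function(z) z, nz = 2, zsp = 10)
  mid <- resample_z_linear(two, 5)
  expect_equal(unique(as.vector(mid$data[, , 2])), 5)

  # constant field stays constant at any target
  cvol <- field_volume(function(z) 42, nz = 4)
  expect_true(all(resample_z_linear(cvol, 0.31)$data == 42))
})

test_that("resampling never overshoots and is the identity on the same grid", {
  set.seed(5)
  data <- array(stats::rnorm(6 * 6 * 7, sd = 300), dim = c(6, 6, 7))
  vol <- ctcurate:::new_ct_volume(data, spacing = c(0.7, 0.7, 2.5))
  for (tz in c(0.33, 0.7, 1.9, 3.3)) {
    out <- resample_z_linear(vol, tz)
    expect_gte(min(out$data), min(data))
    expect_lte(max(out$data), max(data))
  }
  same <- resample_z_linear(vol, 2.5)
  expect_identical(same$data, data)

  single <- ctcurate:::new_ct_volume(array(0, dim = c(2, 2, 1)), c(1, 1, 1))
  expect_error(resample_z_linear(single, 0.5), class = "ctcurate_geometry_error")
})

test_that("the display window maps the abdomen window edges and center as derived", {
  # W=400, L=40: lower edge -160 -> 0, center 40 -> 128 (round half up), upper 240 -> 255
  expect_equal(apply_window(c(-160, 40, 240), width = 400, level = 40, gamma = 1),
               c(0L, 128L, 255L))
  expect_equal(apply_window(-1000), 0L)
  expect_equal(apply_window(3000), 255L)
})

test_that("windowing is monotone for any gamma and gamma=1 is the identity map", {
  v <- sort(c(-500, -160, -40, 0, 39.9, 40, 123, 240, 500))
  for (g in c(0.4, 1, 2.2)) {
    out <- apply_window(v, gamma = g)
    expect_true(all(diff(out) >= 0))
    expect_true(all(out >= 0 & out <= 255))
  }
  norm <- (v - (40 - 200)) / 400
  norm <- pmin(pmax(norm, 0), 1)
  expect_equal(apply_window(v, gamma = 1), as.integer(floor(norm * 255 + 0.5)))
  # gamma darkens or brightens midtones monotonically in gamma
  expect_lt(apply_window(40, gamma = 2.2), apply_window(40, gamma = 1))
  expect_error(apply_window(0, width = -1), class = "ctcurate_config_error")
  expect_error(apply_window(0, gamma = 0), class = "ctcurate_config_error")
})

test_that("DRR mean projection behaves linearly", {
  cvol <- field_volume(function(z) 40, nz = 3)  # window center -> mid gray
  img <- drr_project(cvol)
  expect_true(all(img == 128L))
  expect_equal(dim(img), c(4, 4))

  dir <- withr::local_tempdir()
  make_series(series_spec(series_id = "DRR1", n_slices = 2, rows = 8, cols = 8,
                          phantom = "cylinder"), dir)
  vol <- assemble_volume(read_series(dir))
  single <- ctcurate:::new_ct_volume(vol$data[, , 1, drop = FALSE], vol$spacing)
  expect_identical(drr_project(single, axis = "z"),
                   apply_window(vol$data[, , 1]))
})

test_that("volumes round-trip through raw + sidecar export", {
  vol <- field_volume(function(z) z * 2, nz = 3)
  prefix <- file.path(withr::local_tempdir(), "vol")
  write_volume_raw(vol, prefix)
  back <- read_volume_raw(prefix)
  expect_equal(back$data, vol$data, tolerance = 1e-6)  # float32 payload
  expect_equal(back$spacing, vol$spacing)
  sidecar <- jsonlite::fromJSON(paste0(prefix, ".json"))
  expect_equal(sidecar$dtype, "float32")
  expect_equal(sidecar$dim, dim(vol$data))
})
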