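test_that("denoising objective is non-increasing and improves a speckled disk", {
  set.seed(3)
  H <- 48; W <- 48
  r <- sqrt((row(matrix(0, H, W)) - 24.5)^2 + (col(matrix(0, H, W)) - 24.5)^2)
  clean <- 0.2 + 0.6 * (r < 14)
  noisy <- clean * matrix(rgamma(H * W, shape = 4, scale = 0.25), H, W)
  dn <- denoise_frame(noisy, alpha_d = 0.2)
  expect_true(all(diff(dn$objective) <= 1e-9))
  lo <- min(noisy); hi <- max(noisy)
  cl <- (clean - lo) / (hi - lo)
  rmse_before <- sqrt(mean((normalize_intensity(noisy) - cl)^2))
  rmse_after <- sqrt(mean((dn$image - cl)^2))
  expect_lt(rmse_after, rmse_before)
})

test_that("strong TV regularization drives the image toward a constant", {
  set.seed(4)
  noisy <- matrix(runif(32 * 32), 32, 32)
  dn <- suppressWarnings(denoise_frame(noisy, alpha_d = 50, max_iter = 400))
  expect_lt(sd(dn$image), 0.6 * sd(normalize_intensity(noisy)))
})

test_that("optical flow is zero for identical frames", {
  I <- speckle_frame()
  fl <- optical_flow(I, I)
  expect_lt(max(abs(c(fl$u, fl$v))), 1e-6)
})

test_that("optical flow recovers planted rigid translations within 0.5 px", {
  I <- speckle_frame()
  H <- nrow(I)
  mask <- which(sqrt((row(I) - (H + 1) / 2)^2 + (col(I) - (H + 1) / 2)^2) < 0.4 * H)
  for (shift in list(c(2, 1), c(5, 0), c(-3, 4))) {
    Is <- apply_rigid(I, rigid_transform(-shift[1], -shift[2], 0), fill = 0.12)
    fl <- optical_flow(I, Is)
    epe <- sqrt((fl$u[mask] - shift[1])^2 + (fl$v[mask] - shift[2])^2)
    expect_lt(mean(epe), 0.5)
  }
})

test_that("a single pyramid level equals the non-pyramidal solve", {
  I <- speckle_frame()
  Is <- apply_rigid(I, rigid_transform(-0.8, 0.4, 0), fill = 0.12)
  p1 <- flow_params(levels = 1)
  fl <- optical_flow(I, Is, p1)
  H <- nrow(I)
  mask <- which(sqrt((row(I) - (H + 1) / 2)^2 + (col(I) - (H + 1) / 2)^2) < 0.4 * H)
  epe <- sqrt((fl$u[mask] - 0.8)^2 + (fl$v[mask] + 0.4)^2)
  expect_lt(mean(epe), 0.5)
})

test_that("flow units convert to mm through the pixel spacing", {
  I <- speckle_frame()
  Is <- apply_rigid(I, rigid_transform(-2, 0, 0), fill = 0.12)
  fl <- optical_flow(I, Is, pixel_spacing = 0.016)
  f <- tempfile(fileext = ".tif")
  write_displacement_field(fl, f)
  fl2 <- read_displacement_field(f, pixel_spacing = 0.016)
  expect_equal(fl2$u, fl$u, tolerance = 1e-5)
})

test_that("observation interpolation reproduces affine fields exactly", {
  mesh <- tiny_ring()
  H <- 96; sp <- 0.08               # 96 px x 0.08 mm = 7.7 mm footprint
  cx <- (H + 1) / 2
  # affine flow in pixel units: u = a + b x + c y
  gx <- matrix(rep(1:H, each = H), H, H) - cx
  gy <- matrix(rep(1:H, H), H, H) - cx
  u <- 0.5 + 0.01 * gx - 0.02 * gy
  v <- -0.2 + 0.005 * gx + 0.015 * gy
  fl <- displacement_field(u, v, pixel_spacing = sp)
  obs <- interpolate_observations(list(fl), mesh)
  xy <- mesh$nodes
  px <- xy[, 1] / sp; py <- -xy[, 2] / sp     # node offsets from centre (px)
  expected_x <- (0.5 + 0.01 * px - 0.02 * py) * sp
  expected_y <- -(-0.2 + 0.005 * px + 0.015 * py) * sp
  expect_equal(obs$fields[[1]][, 1], expected_x, tolerance = 1e-9)
  expect_equal(obs$fields[[1]][, 2], expected_y, tolerance = 1e-9)
  # spatially constant field samples to the constant everywhere
  flc <- displacement_field(matrix(1.5, H, H), matrix(-0.7, H, H), sp)
  obsc <- interpolate_observations(list(flc), mesh)
  expect_true(all(abs(obsc$fields[[1]][, 1] - 1.5 * sp) < 1e-12))
  # two phases double the observation length (phase-major stacking)
  obs2 <- interpolate_observations(list(fl, fl), mesh)
  expect_length(obs2$Z, 2 * length(obs$Z))
  expect_equal(obs2$Z[seq_along(obs$Z)], obs$Z)
})

test_that("nodes outside the footprint fall back to the nearest pixel", {
  mesh <- tiny_ring()                        # radius up to 2.71 mm
  H <- 32; sp <- 0.08                        # footprint only +-1.24 mm
  fl <- displacement_field(matrix(2, H, H), matrix(0, H, H), sp)
  expect_warning(obs <- interpolate_observations(list(fl), mesh),
                 "outside the image footprint")
  expect_true(all(is.finite(obs$Z)))
})
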