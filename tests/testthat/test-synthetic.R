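test_that("in-silico observations are self-consistent and reproducible", {
  mesh <- tiny_ring()
  pre <- load_case(80, 0.1, role = "preload")
  fwd <- list(load_case(120, 0.1, role = "forward"))
  o1 <- gen_insilico_observations(mesh, 5e5, pre, fwd)
  o2 <- gen_insilico_observations(mesh, 5e5, pre, fwd)
  expect_identical(o1$Z, o2$Z)
  expect_equal(o1$Z, o1$Z_clean)
  expect_length(o1$Z, 2 * nrow(mesh$nodes))
  # noisy variant: seeded and reproducible, zero-noise limit intact
  n1 <- gen_insilico_observations(mesh, 5e5, pre, fwd, sigma_noise = 1e-3, seed = 4)
  n2 <- gen_insilico_observations(mesh, 5e5, pre, fwd, sigma_noise = 1e-3, seed = 4)
  expect_identical(n1$Z, n2$Z)
  expect_false(identical(n1$Z, n1$Z_clean))
  expect_equal(sd(n1$Z - n1$Z_clean), 1e-3, tolerance = 0.2)
})

test_that("assimilating exact observations reaches zero innovation at the truth", {
  mesh <- tiny_ring()
  pre <- load_case(80, 0.1, role = "preload")
  fwd <- list(load_case(120, 0.1, role = "forward"))
  obs <- gen_insilico_observations(mesh, 5e5, pre, fwd)
  op <- mechanics_operator(mesh, pre, fwd)
  Zhat <- op(matrix(log2(5e5), 1, 1))[, 1]
  expect_lt(max(abs(Zhat - obs$Z)), 1e-10)
})

test_that("observation magnitude decreases with stiffness", {
  mesh <- tiny_ring()
  pre <- load_case(80, 0.1, role = "preload")
  fwd <- list(load_case(120, 0.1, role = "forward"))
  mags <- vapply(c(1e5, 5e5, 4e6), function(ct)
    mean(abs(gen_insilico_observations(mesh, ct, pre, fwd)$Z)), numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("IVUS sequence generator is deterministic and respects limits", {
  g1 <- gen_ivus_sequence(n_frames = 5, size = 48, seed = 2, frame_noise = 10)
  g2 <- gen_ivus_sequence(n_frames = 5, size = 48, seed = 2, frame_noise = 10)
  expect_identical(g1$seq$frames, g2$seq$frames)
  g3 <- gen_ivus_sequence(n_frames = 5, size = 48, seed = 3, frame_noise = 10)
  expect_false(identical(g1$seq$frames, g3$seq$frames))
  expect_error(gen_ivus_sequence(size = 48, pulse_amp = 30), "image bounds")
  # zero motion, zero noise: all frames identical
  g0 <- gen_ivus_sequence(n_frames = 4, size = 48, pulse_amp = 0,
                          rigid_amp = 0, frame_noise = 0, seed = 1)
  expect_equal(g0$seq$frames[[1]], g0$seq$frames[[4]], tolerance = 1e-12)
})

test_that("optical flow on noiseless generated frames matches the planted field", {
  g <- gen_ivus_sequence(n_frames = 12, size = 64, heart_rate = 1.2,
                         rigid_amp = 0, pulse_amp = 1.2, frame_noise = 0,
                         seed = 6)
  n <- 7                                 # mid-cycle frame, largest motion
  fl <- optical_flow(g$seq$frames[[1]], g$seq$frames[[n]])
  tr <- g$true_flows[[n]]
  H <- 64
  r <- sqrt((row(tr$u) - 32.5)^2 + (col(tr$u) - 32.5)^2)
  mask <- which(r > 0.22 * H & r < 0.38 * H)   # the textured wall
  epe <- sqrt((fl$u[mask] - tr$u[mask])^2 + (fl$v[mask] - tr$v[mask])^2)
  expect_lt(mean(epe), 0.5)
})
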