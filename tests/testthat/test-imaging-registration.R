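test_that("frame likelihood takes its exact maximum at identity", {
  I <- speckle_frame()
  HW <- length(I)
  expect_equal(frame_likelihood(I, I), -HW * log(2), tolerance = 1e-12)
  expect_error(frame_likelihood(I, I[1:10, 1:10]), "differ")
})

test_that("frame likelihood matches the hand-evaluated formula on a 2x2 case", {
  In <- matrix(c(1, 0, 0, 0), 2, 2)
  Im <- matrix(0, 2, 2)
  # d = (1,0,0,0): three terms -log 2, one term 1 - log(e^2 + 1)
  expected <- -3 * log(2) + 1 - log(exp(2) + 1)
  expect_equal(frame_likelihood(In, Im), expected, tolerance = 1e-12)
})

test_that("zero shift maximizes the likelihood over integer shifts", {
  I <- speckle_frame()
  shifts <- expand.grid(dx = -3:3, dy = -3:3)
  vals <- mapply(function(dx, dy) {
    J <- apply_rigid(I, rigid_transform(dx, dy, 0), fill = 0)
    frame_likelihood(I, J)
  }, shifts$dx, shifts$dy)
  expect_equal(which.max(vals), which(shifts$dx == 0 & shifts$dy == 0))
})

test_that("transversal registration recovers identity and planted motions", {
  I <- speckle_frame()
  tf0 <- register_transversal(I, I, max_shift = 4, max_angle = 3 * pi / 180)
  expect_equal(abs(tf0$tx) + abs(tf0$ty) + abs(tf0$angle), 0, tolerance = 1e-9)

  # pure translation: recovered transform is the inverse of the planted one
  tf_t <- rigid_transform(3, -2, 0)
  Is <- apply_rigid(I, tf_t, fill = 0.12)
  rec <- register_transversal(Is, I, max_shift = 6, max_angle = 2 * pi / 180)
  expect_lt(abs(rec$tx - (-3)), 0.26)
  expect_lt(abs(rec$ty - 2), 0.26)

  # pure rotation about the centre
  tf_r <- rigid_transform(0, 0, 5 * pi / 180)
  Ir <- apply_rigid(I, tf_r, fill = 0.12)
  rec_r <- register_transversal(Ir, I, max_shift = 3)
  expect_lt(abs(rec_r$angle - (-5 * pi / 180)), 0.15 * pi / 180)
})

test_that("axial registration finds the matching frame and handles w = 0", {
  g <- gen_ivus_sequence(n_frames = 40, size = 48, heart_rate = 1.2,
                         frame_noise = 0, seed = 9)
  stack <- g$seq
  # identical stacks: every frame matches itself
  expect_equal(register_axial(stack, stack, 15), 15)
  # axially shifted stack: frame n of the shifted stack is frame n + 2
  shifted <- image_sequence(stack$frames[3:40], frame_rate = 30)
  m <- register_axial(shifted, stack, 15)
  expect_equal(m, 17)
  # w = 0 reduces to the single-pair likelihood
  m0 <- register_axial(shifted, stack, 15, w = 0)
  ks <- 8:22
  direct <- ks[which.max(vapply(ks, function(k)
    frame_likelihood(shifted$frames[[15]], stack$frames[[k]]), numeric(1)))]
  expect_equal(m0, direct)
})
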