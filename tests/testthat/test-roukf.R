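test_that("spherical simplex sigma points have zero mean and identity covariance", {
  for (M in 1:8) {
    sp <- spherical_simplex_points(M)
    expect_equal(dim(sp$points), c(M, M + 1))
    expect_equal(sp$weights, rep(1 / (M + 1), M + 1))
    expect_lt(max(abs(sp$points %*% sp$weights)), 1e-12)
    cov <- sp$points %*% diag(sp$weights) %*% t(sp$points)
    expect_equal(cov, diag(M), tolerance = 1e-12)
  }
  # M = 1: two points symmetric about 0 with weights 1/2
  sp1 <- spherical_simplex_points(1)
  expect_equal(sort(as.numeric(sp1$points)), c(-1, 1), tolerance = 1e-12)
})

test_that("filter initialization has the prescribed block structure", {
  fs <- roukf_init(c(0, 0, 0), sigma_theta = 2, sigma_z = 0.5)
  expect_equal(fs$Uinv, diag(2, 3))
  expect_equal(fs$L, diag(3))
  expect_equal(fs$r_inv_diag, 1 / 0.25)          # variance convention
  fs2 <- roukf_init(0, sigma_theta = 2, sigma_z = 0.5, r_convention = "sigma")
  expect_equal(fs2$r_inv_diag, 2)
  expect_error(roukf_init(0, sigma_theta = -1), "positive")
  # theta = 0 corresponds to c = 1 Pa (why theta0 must be set physiologically)
  expect_equal(2^fs$theta, c(1, 1, 1))
})

test_that("one ROUKF step equals the closed-form Kalman update (scalar)", {
  a <- 3; theta0 <- 1; s0 <- 2; sz <- 0.5; Zobs <- 7.3
  pf <- function(th) matrix(a * th[1, ], nrow = 1)
  fs <- roukf_init(theta0, sigma_theta = s0, sigma_z = sz)
  pred <- roukf_predict(fs, pf)
  fs2 <- roukf_correct(fs, Zobs, pred)
  r <- sz^2
  K <- s0 * a / (a^2 * s0 + r)
  expect_lt(abs(fs2$theta - (theta0 + K * (Zobs - a * theta0))) /
              abs(theta0 + K * (Zobs - a * theta0)), 1e-8)
  pcov <- as.numeric(roukf_uncertainty(fs2)$cov)
  expect_lt(abs(pcov - 1 / (1 / s0 + a^2 / r)) * (1 / s0 + a^2 / r), 1e-8)
})

test_that("one ROUKF step equals the closed-form Kalman update (3 parameters)", {
  set.seed(2)
  H <- matrix(rnorm(15), 5, 3)
  th0 <- c(0.5, -1, 2); P0d <- c(1, 2, 0.5); sz <- 0.3
  Z <- as.numeric(H %*% c(1, 1, 1)) + rnorm(5, sd = 0.1)
  fs <- roukf_init(th0, sigma_theta = P0d, sigma_z = sz)
  pred <- roukf_predict(fs, function(th) H %*% th)
  fs2 <- roukf_correct(fs, Z, pred)
  P0 <- diag(P0d); R <- diag(sz^2, 5)
  K <- P0 %*% t(H) %*% solve(H %*% P0 %*% t(H) + R)
  th_k <- as.numeric(th0 + K %*% (Z - H %*% th0))
  expect_lt(max(abs(fs2$theta - th_k)) / max(abs(th_k)), 1e-8)
  Pk <- P0 - K %*% H %*% P0
  expect_lt(max(abs(roukf_uncertainty(fs2)$cov - Pk)) / max(abs(Pk)), 1e-8)
})

test_that("repeated iterations on a linear toy approach the least-squares fit", {
  set.seed(5)
  H <- matrix(rnorm(12), 4, 3)
  Z <- as.numeric(H %*% c(2, -1, 0.5)) + rnorm(4, sd = 0.05)
  res <- roukf_estimate(c(0, 0, 0), Z, function(th) H %*% th,
                        iterations = 400, sigma_theta = 1, sigma_z = 0.05)
  ls <- qr.solve(H, Z)
  expect_lt(max(abs(res$state$theta - ls)), 1e-3)
})

test_that("zero innovation leaves the estimate unchanged", {
  pf <- function(th) matrix(2 * th[1, ] + 1, nrow = 1)
  fs <- roukf_init(0.7, sigma_theta = 1, sigma_z = 0.1)
  pred <- roukf_predict(fs, pf)
  fs2 <- roukf_correct(fs, pred$Z_mean, pred)
  expect_equal(fs2$theta, 0.7, tolerance = 1e-12)
})

test_that("prediction of a linear map equals the map of the mean", {
  pf <- function(th) rbind(3 * th[1, ] - 2, -th[1, ])
  fs <- roukf_init(1.3, sigma_theta = 2, sigma_z = 0.1)
  pred <- roukf_predict(fs, pf)
  expect_equal(pred$Z_mean, c(3 * 1.3 - 2, -1.3), tolerance = 1e-12)
  expect_equal(pred$theta_mean, 1.3, tolerance = 1e-12)
  # sigma count is M + 1 regardless of the observation size
  expect_equal(ncol(pred$Z_sigma), 2)
})

test_that("estimate is equivariant under parameter relabeling", {
  set.seed(8)
  H <- matrix(rnorm(18), 6, 3)
  Z <- as.numeric(H %*% c(1.5, 0.2, -0.7))
  perm <- c(3, 1, 2)
  r1 <- roukf_estimate(c(0.1, 0.2, 0.3), Z, function(th) H %*% th,
                       iterations = 20, sigma_theta = 1, sigma_z = 0.1)
  r2 <- roukf_estimate(c(0.1, 0.2, 0.3)[perm], Z,
                       function(th) H[, perm] %*% th,
                       iterations = 20, sigma_theta = 1, sigma_z = 0.1)
  expect_equal(r2$state$theta, r1$state$theta[perm], tolerance = 1e-8)
})

test_that("stiffness stays positive along any trajectory", {
  set.seed(9)
  H <- matrix(rnorm(8), 4, 2)
  Z <- as.numeric(H %*% c(-30, 25))       # extreme targets in log2 space
  res <- roukf_estimate(c(0, 0), Z, function(th) H %*% th,
                        iterations = 50, sigma_theta = 4, sigma_z = 0.1)
  expect_true(all(res$trajectory$c > 0))
})

test_that("U losing positive definiteness is reported", {
  fs <- roukf_init(c(0, 0), sigma_theta = 1, sigma_z = 1)
  pred <- roukf_predict(fs, function(th) matrix(0, 1, ncol(th)))
  fs$Uinv <- matrix(c(1, 2, 2, 1), 2)      # indefinite
  expect_error(roukf_predict(fs, function(th) matrix(0, 1, ncol(th))))
})
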