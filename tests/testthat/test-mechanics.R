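test_that("Neo-Hookean stress vanishes at identity and is frame-indifferent", {
  expect_equal(neo_hookean_pk2(diag(3), 1e5), matrix(0, 3, 3), tolerance = 1e-12)
  expect_equal(neo_hookean_psi(diag(3), 1e5), 0, tolerance = 1e-12)
  F <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  th <- 0.3
  Q <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(neo_hookean_psi(Q %*% F, 1e5), neo_hookean_psi(F, 1e5),
               tolerance = 1e-12)
  expect_error(neo_hookean_pk2(diag(c(-1, 1, 1)), 1e5), "inverted")
})

test_that("Neo-Hookean stress matches the energy derivative oracle", {
  # isochoric uniaxial stretch and a general strained state
  F1 <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  F2 <- diag(3) + matrix(c(0.05, 0.02, 0, -0.01, 0.03, 0.01, 0, 0.02, -0.04), 3, 3)
  for (F in list(F1, F2)) {
    S <- neo_hookean_pk2(F, 1e5)
    S0 <- pk2_complex_step(F, 1e5)
    expect_lt(max(abs(S - S0)) / max(abs(S0)), 1e-10)
  }
})

test_that("push-forward to Cauchy stress is consistent and symmetric", {
  S <- neo_hookean_pk2(diag(3), 2e5)
  expect_equal(push_forward_cauchy(diag(3), S, 0), S)
  # hydrostatic state: S = 0, lambda = p gives sigma = -p I
  expect_equal(push_forward_cauchy(diag(3), matrix(0, 3, 3), 1000),
               -1000 * diag(3))
  set.seed(4)
  A <- matrix(rnorm(9, sd = 0.1), 3, 3)
  F <- diag(3) + A
  sig <- push_forward_cauchy(F, neo_hookean_pk2(F, 1e5), 500)
  expect_equal(sig, t(sig), tolerance = 1e-12)
})

test_that("unloaded equilibrium is the trivial state", {
  mesh <- tiny_ring()
  st <- solve_forward(mesh, 5e5, load_case(0, 0, role = "forward"))
  expect_true(st$converged)
  expect_lt(max(abs(st$u)), 1e-10)
  expect_lt(max(abs(st$lambda)), 1e-6)
  stp <- solve_preload(mesh, 5e5, load_case(0, 0, role = "preload"))
  expect_lt(max(abs(stp$u)), 1e-10)
})

test_that("ring inflation is axisymmetric and matches the tube closed form", {
  mesh <- small_ring()
  c0 <- 5e5
  st <- solve_forward(mesh, c0, load_case(40, 0, role = "forward"))
  wn <- unique(as.vector(mesh$edges_w))
  ur <- sqrt(rowSums(st$u[wn, ]^2))
  expect_lt(diff(range(ur)), 1e-6)            # axisymmetry
  ri <- inner_radius(mesh, st)
  p_cf <- tube_pressure_closed_form(ri, 2, 2.71, c0, 1)
  expect_lt(abs(p_cf - mmhg_to_pa(40)) / mmhg_to_pa(40), 0.01)
})

test_that("softer material gives larger inner-wall displacement", {
  mesh <- tiny_ring()
  disp <- vapply(c(1e5, 5e5, 4e6), function(c0) {
    st <- solve_forward(mesh, c0, load_case(40, 0, role = "forward"))
    inner_radius(mesh, st) - 2
  }, numeric(1))
  expect_true(all(disp > 0))
  expect_true(all(diff(disp) < 0))
})

test_that("solution rotates with the mesh (frame indifference)", {
  mesh <- tiny_ring()
  st <- solve_forward(mesh, 5e5, load_case(40, 0.1, role = "forward"))
  R <- rbind(c(0, -1), c(1, 0))               # 90 degrees
  mesh_r <- mesh
  mesh_r$nodes <- mesh$nodes %*% t(R)
  st_r <- solve_forward(mesh_r, 5e5, load_case(40, 0.1, role = "forward"))
  expect_equal(st_r$u, st$u %*% t(R), tolerance = 1e-6)
})

test_that("preload followed by forward at the same pressure round-trips", {
  mesh <- small_ring()
  for (c0 in c(1e5, 5e5)) {
    pre <- solve_preload(mesh, c0, load_case(80, 0.1, role = "preload"))
    mm <- material_mesh(mesh, pre)
    expect_gt(min(mesh_areas(mm)), 0)
    fwd <- solve_forward(mm, c0, load_case(80, 0.1, role = "forward"))
    expect_lt(max(abs(mm$nodes + fwd$u - mesh$nodes)), 2e-4)
  }
})

test_that("incompressibility holds elementwise at convergence", {
  mesh <- small_ring()
  st <- solve_forward(mesh, 1e5, load_case(80, 0.1, role = "forward"))
  detF2 <- element_detF_cpp(mesh$nodes, mesh$tri, st$u, 0L)
  lamz <- 1.1
  expect_lt(max(abs(lamz * detF2 - 1)), 0.02)  # within stabilization tolerance
})

test_that("assembled tangent matches finite differences of the residual", {
  mesh <- tiny_ring()
  N <- nrow(mesh$nodes)
  set.seed(7)
  st <- list(u = matrix(rnorm(2 * N, sd = 1e-3), N, 2),
             lambda = rnorm(N, sd = 100))
  for (prob in c("forward", "preload")) {
    ld <- load_case(40, 0.1, role = if (prob == "forward") "forward" else "preload")
    sys <- assemble_system(mesh, 5e5, ld, st, problem = prob)
    d <- rnorm(3 * N)
    d <- d / sqrt(sum(d^2))
    h <- 1e-6
    perturb <- function(s) {
      list(u = st$u + s * matrix(d[1:(2 * N)], N, 2, byrow = TRUE),
           lambda = st$lambda + s * d[2 * N + 1:N])
    }
    rp <- assemble_system(mesh, 5e5, ld, perturb(h), problem = prob)$residual
    rm <- assemble_system(mesh, 5e5, ld, perturb(-h), problem = prob)$residual
    fd <- (rp - rm) / (2 * h)
    Kd <- as.numeric(sys$tangent %*% d)
    expect_lt(max(abs(Kd - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("residual at a converged state is at solver tolerance", {
  mesh <- tiny_ring()
  ld <- load_case(40, 0.1, role = "forward")
  st <- solve_forward(mesh, 5e5, ld)
  sys <- assemble_system(mesh, 5e5, ld, st, problem = "forward")
  # residual scale: boundary load magnitude per node
  scale <- mmhg_to_pa(40) * 0.3
  expect_lt(max(abs(sys$residual)) / scale, 1e-3)
})

test_that("pressure stabilization scales as h^2", {
  q_of <- function(n_theta, n_r) {
    mesh <- gen_ring_mesh(n_theta = n_theta, n_r = n_r)
    N <- nrow(mesh$nodes)
    lam <- mesh$nodes[, 1] * 1000                 # smooth field (Pa)
    st <- list(u = matrix(0, N, 2), lambda = lam)
    ld <- load_case(0, 0, role = "forward")
    sys <- assemble_system(mesh, 5e5, ld, st, problem = "forward")
    lam_idx <- 2 * N + seq_len(N)
    # with u = 0 and lambda_z = 1 the pressure-row residual is pure
    # stabilization; its quadratic form scales as h^2
    abs(sum(lam * sys$residual[lam_idx]))
  }
  q1 <- q_of(32, 3)
  q2 <- q_of(64, 6)
  expect_equal(q1 / q2, 4, tolerance = 0.35)
})

test_that("material and load validation reject bad input", {
  mesh <- tiny_ring()
  expect_error(solve_forward(mesh, c(1e5, 1e5), load_case(10, 0, role = "forward")),
               "regions")
  expect_error(solve_forward(mesh, -5, load_case(10, 0, role = "forward")),
               "positive")
  expect_error(load_case(-10, 0, role = "forward"))
  expect_error(load_case(80, 0, tau = 100, role = "preload"), "preload")
})
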