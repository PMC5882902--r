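test_that("ring mesh has the prescribed annular geometry and tags", {
  mesh <- tiny_ring()
  r <- sqrt(rowSums(mesh$nodes^2))
  expect_true(all(r >= 2 - 1e-9) && all(r <= 2.71 + 1e-9))
  expect_gt(min(mesh_areas(mesh)), 0)
  expect_gt(min(mesh_quality(mesh)), 20)           # degrees
  # boundary edges partition into lumen and external rings
  expect_equal(nrow(mesh$edges_w), 48)
  expect_equal(nrow(mesh$edges_e), 48)
  rw <- sqrt(rowSums(mesh$nodes[unique(as.vector(mesh$edges_w)), ]^2))
  re <- sqrt(rowSums(mesh$nodes[unique(as.vector(mesh$edges_e)), ]^2))
  expect_true(all(abs(rw - 2) < 1e-9))
  expect_true(all(abs(re - 2.71) < 1e-9))
  # 4 equidistant lumen nodes flagged for radial-only control
  expect_length(mesh$radial_nodes, 4)
  ang <- sort(atan2(mesh$nodes[mesh$radial_nodes, 2],
                    mesh$nodes[mesh$radial_nodes, 1]))
  expect_equal(diff(ang), rep(pi / 2, 3), tolerance = 1e-6)
})

test_that("too coarse a ring (under 2 elements through-wall) is rejected", {
  expect_error(gen_ring_mesh(element_size = 0.5), "too coarse")
})

test_that("partitioned slice produces the requested region partition", {
  m12 <- gen_partitioned_slice(n_sectors = 6, n_layers = 2, n_theta = 48, n_r = 4)
  expect_equal(m12$n_regions, 12)
  expect_true(all(tabulate(m12$region, 12) > 0))
  m6 <- gen_partitioned_slice(n_sectors = 6, n_layers = 1, n_theta = 48, n_r = 4)
  expect_equal(m6$n_regions, 6)
  # region areas sum to the slice area
  a <- mesh_areas(m12)
  per_region <- vapply(1:12, function(k) sum(a[m12$region == k]), numeric(1))
  expect_equal(sum(per_region), sum(a))
  expect_error(gen_partitioned_slice(eccentricity = 0.9), "degenerate")
})

test_that("untrusted external arc is tagged", {
  m <- gen_partitioned_slice(n_theta = 48, n_r = 4,
                             untrusted_arc = c(0.5, 1.2))
  expect_gt(length(m$untrusted), 0)
  ang <- atan2(m$nodes[m$untrusted, 2], m$nodes[m$untrusted, 1])
  expect_true(all(ang >= 0.4 & ang <= 1.3))
})

test_that("vtu and msh round trips preserve the mesh", {
  mesh <- gen_partitioned_slice(n_sectors = 3, n_layers = 2,
                                n_theta = 24, n_r = 4, eccentricity = 0.1)
  f1 <- tempfile(fileext = ".vtu")
  write_mesh_vtu(mesh, f1)
  m1 <- read_mesh_vtu(f1)
  expect_equal(m1$nodes, mesh$nodes, tolerance = 1e-8)
  expect_equal(m1$tri, mesh$tri)
  expect_equal(m1$region, mesh$region)
  expect_equal(m1$edges_w, mesh$edges_w)

  f2 <- tempfile(fileext = ".msh")
  write_mesh_msh(mesh, f2)
  m2 <- read_mesh_msh(f2)
  expect_equal(m2$nodes, mesh$nodes, tolerance = 1e-8)
  expect_equal(m2$region, mesh$region)
  expect_equal(m2$edges_e, mesh$edges_e)
})

test_that("solution export writes displacement, pressure and stress", {
  mesh <- tiny_ring()
  ld <- load_case(20, 0, role = "forward")
  st <- solve_forward(mesh, 5e5, ld)
  f <- tempfile(fileext = ".vtu")
  write_mesh_vtu(mesh, f, state = st, mat = 5e5, load = ld)
  txt <- readLines(f)
  expect_true(any(grepl("displacement", txt)))
  expect_true(any(grepl("cauchy_stress", txt)))
  m <- read_mesh_vtu(f)
  expect_equal(nrow(m$nodes), nrow(mesh$nodes))
})
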