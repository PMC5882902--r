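# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

tiny_ring <- function() memo("tiny_ring", function()
  gen_ring_mesh(n_theta = 48, n_r = 4))

small_ring <- function() memo("small_ring", function()
  gen_ring_mesh(n_theta = 64, n_r = 6))

speckle_frame <- function() memo("speckle_frame", function() {
  g <- gen_ivus_sequence(n_frames = 1, size = 64, frame_noise = 0, seed = 11)
  g$seq$frames[[1]]
})

# independent oracle for the Neo-Hookean stress: complex-step derivative of
# the strain energy with respect to the Green-Lagrange strain components
pk2_complex_step <- function(F, c) {
  E <- (t(F) %*% F - diag(3)) / 2
  det3 <- function(M)
    M[1, 1] * (M[2, 2] * M[3, 3] - M[2, 3] * M[3, 2]) -
    M[1, 2] * (M[2, 1] * M[3, 3] - M[2, 3] * M[3, 1]) +
    M[1, 3] * (M[2, 1] * M[3, 2] - M[2, 2] * M[3, 1])
  psi_of_E <- function(Ec) {
    C <- 2 * Ec + diag(3)
    I1 <- sum(diag(C))
    c / 2 * (I1 * det3(C)^(-1 / 3) - 3)
  }
  h <- 1e-30
  S <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Ec <- E * (1 + 0i)
    Ec[i, j] <- Ec[i, j] + 1i * h
    S[i, j] <- Im(psi_of_E(Ec)) / h
  }
  S
}

# deformed mean inner radius of a forward solution on a ring mesh
inner_radius <- function(mesh, state) {
  wn <- unique(as.vector(mesh$edges_w))
  mean(sqrt(rowSums((mesh$nodes[wn, ] + state$u[wn, ])^2)))
}
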