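#' Generate in-silico displacement observations Z = h(f(X^t))
#'
#' Runs the forward operator at the true parameters and samples the
#' predicted end-diastole-to-phase displacements at the observation nodes,
#' optionally perturbed by seeded Gaussian noise.  This is the ground-truth
#' generator of the ring and slice recovery experiments: assimilating the
#' sigma_noise = 0 observations with the same model reaches zero innovation
#' at the true parameters.
#'
#' @param mesh imaged-configuration `vessel_mesh`
#' @param c_true per-region true stiffness (Pa)
#' @param preload_case,forward_cases load cases as in [mechanics_operator()]
#' @param obs_nodes observed node indices (default all)
#' @param uof_list optional per-phase Robin anchor flows (see
#'   [mechanics_operator()])
#' @param sigma_noise additive Gaussian noise scale (mm), default 0
#' @param seed RNG seed for the noise
#' @return list with `Z` (stacked observation vector), `Z_clean`, `truth`
#'   (the per-phase displacement fields as N x 2 matrices) and `c_true`
#' @export
gen_insilico_observations <- function(mesh, c_true, preload_case,
                                      forward_cases, obs_nodes = NULL,
                                      uof_list = NULL,
                                      sigma_noise = 0, seed = 1) {
  M <- mesh$n_regions
  stopifnot(length(c_true) == M, all(c_true > 0))
  if (is.null(obs_nodes)) obs_nodes <- seq_len(nrow(mesh$nodes))
  op <- mechanics_operator(mesh, preload_case, forward_cases,
                           obs_nodes = obs_nodes, uof_list = uof_list)
  th <- matrix(log2(c_true), ncol = 1)[, rep(1, M + 1), drop = FALSE]
  Zc <- as.numeric(op(th)[, 1])
  Z <- Zc
  if (sigma_noise > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    Z <- Zc + rnorm(length(Zc), sd = sigma_noise)
    .Random.seed_restore(old)
  }
  S <- length(forward_cases)
  per_phase <- split(Zc, rep(seq_len(S), each = length(Zc) / S))
  truth <- lapply(per_phase, function(z) matrix(z, ncol = 2, byrow = TRUE))
  list(Z = Z, Z_clean = Zc, truth = truth, c_true = c_true,
       obs_nodes = obs_nodes)
}

#' Generate a speckled IVUS-like image sequence with known motion
#'
#' Emulates a transversal IVUS acquisition of a ring-shaped vessel: a
#' smooth echogenicity map (dark lumen, bright media, intermediate
#' surroundings) carries a static multiplicative gamma speckle pattern that
#' moves with the tissue.  Frames are produced by warping this reference
#' pattern with a prescribed cardiac-frequency wall pulsation plus optional
#' rigid motion, and (optionally) corrupting each frame with independent
#' multiplicative gamma noise.  The generator returns the per-frame
#' ground-truth displacement fields (end-diastole to frame) and the true
#' end-diastolic indices, so gating, registration and optical flow can each
#' be validated against a known answer.
#'
#' @param n_frames number of frames
#' @param size image size (pixels, square)
#' @param pixel_spacing mm per pixel
#' @param frame_rate Hz
#' @param heart_rate cardiac frequency (Hz); keep within the physiological
#'   band 0.75-1.66 Hz for gateable sequences
#' @param pulse_amp peak radial wall displacement (pixels)
#' @param rigid_amp rigid translation amplitude (pixels)
#' @param frame_noise shape parameter of per-frame gamma noise (larger =
#'   less noise); 0 disables it
#' @param speckle_shape gamma shape of the static speckle pattern
#' @param r_in,r_out wall radii (pixels); defaults scale with the image
#' @param seed RNG seed (the generator is deterministic given the seed)
#' @return list: `seq` (an [image_sequence()]), `true_flows` (list of
#'   [displacement_field()], ED -> frame, pixels), `ed_indices`,
#'   `heart_rate`
#' @export
gen_ivus_sequence <- function(n_frames = 300, size = 96,
                              pixel_spacing = 0.016, frame_rate = 30,
                              heart_rate = 1.2, pulse_amp = 1.5,
                              rigid_amp = 0.5, frame_noise = 0,
                              speckle_shape = 4,
                              r_in = 0.22 * size, r_out = 0.38 * size,
                              seed = 1) {
  stopifnot(r_out > r_in, r_in > 2)
  if (pulse_amp + rigid_amp > size / 2 - r_out)
    stop("requested motion exceeds the image bounds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  H <- size; W <- size
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  gx <- matrix(rep(seq_len(W), each = H), H, W) - cx
  gy <- matrix(rep(seq_len(H), W), H, W) - cy
  r <- sqrt(gx^2 + gy^2)
  edge <- function(x, w = 1.2) 1 / (1 + exp(-x / w))
  echo <- 0.12 + 0.55 * edge(r - r_in) * edge(r_out - r) +
    0.12 * edge(r - r_out)
  speckle <- matrix(rgamma(H * W, shape = speckle_shape,
                           scale = 1 / speckle_shape), H, W)
  speckle <- gauss_blur(speckle, 0.6)
  ref <- echo * speckle

  # radial pulsation profile: ~1/r decay through and outside the wall
  prof <- r_in / pmax(r, r_in / 2)
  frames <- vector("list", n_frames)
  flows <- vector("list", n_frames)
  tset <- (seq_len(n_frames) - 1) / frame_rate
  # cardiac-like asymmetric waveform: rapid systolic rise, slow diastolic
  # decay, zero at the end-diastolic phase (phi = 0 mod 2 pi); asymmetry
  # keeps the fundamental of the frame-to-frame motion at the heart rate
  pulse <- function(ph) {
    phi <- ph %% (2 * pi)
    exp(-(phi - 1.9)^2 / (2 * 0.85^2)) + 0.25 * exp(-(phi - 3.6)^2 / (2 * 1.1^2))
  }
  for (n in seq_len(n_frames)) {
    t <- tset[n]
    ph <- 2 * pi * heart_rate * t
    A <- pulse_amp * pulse(ph)
    tx <- rigid_amp * pulse(ph + 0.9)
    ty <- rigid_amp * pulse(ph + 2.1)
    ux <- A * prof * gx / pmax(r, 1e-6) + tx
    uy <- A * prof * gy / pmax(r, 1e-6) + ty
    # first-order inverse warp: sample the reference at p - u(p)
    sx <- as.vector(matrix(rep(seq_len(W), each = H), H, W) - ux)
    sy <- as.vector(matrix(rep(seq_len(H), W), H, W) - uy)
    val <- bilinear_sample_cpp(ref, sx, sy)
    val[is.na(val)] <- 0.12
    img <- matrix(val, H, W)
    if (frame_noise > 0)
      img <- img * matrix(rgamma(H * W, shape = frame_noise,
                                 scale = 1 / frame_noise), H, W)
    frames[[n]] <- img
    flows[[n]] <- displacement_field(ux, uy, pixel_spacing,
                                     source_phase = 1, target_phase = n)
  }
  # ground-truth end-diastolic frames: per-cycle minima of the actual
  # frame-to-frame motion (the operational definition gating relies on)
  if (n_frames >= 2) {
    speed <- vapply(2:n_frames, function(n)
      mean(abs(flows[[n]]$u - flows[[n - 1]]$u) +
             abs(flows[[n]]$v - flows[[n - 1]]$v)), numeric(1))
    period <- frame_rate / heart_rate
    n_cyc <- max(1L, floor((n_frames - 1) / period))
    ed <- vapply(seq_len(n_cyc), function(k) {
      win <- max(1, round((k - 1) * period)):min(length(speed), round(k * period))
      win[which.min(speed[win])]
    }, integer(1))
    ed <- sort(unique(ed))
  } else ed <- 1L
  list(seq = image_sequence(frames, pixel_spacing, frame_rate),
       true_flows = flows, ed_indices = ed, heart_rate = heart_rate)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
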