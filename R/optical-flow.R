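#' Optical-flow parameters
#'
#' Defaults follow standard coarse-to-fine warping practice on normalized
#' intensities: 4 pyramid levels with factor 0.5, robust scale kappa = 0.01,
#' structure-tensor width rho = 1.5 px, flow regularization alpha_o = 0.02.
#' Denoising parameters are carried alongside so one object configures the
#' whole displacement-extraction stage.
#'
#' @param levels pyramid levels R (>= 1)
#' @param downsample per-level size factor (0 < f < 1)
#' @param kappa robust-penalty scale of psi(x) = 2 kappa^2 sqrt(1 + x/kappa^2)
#' @param rho structure-tensor Gaussian width (px)
#' @param alpha_o flow regularization weight
#' @param fp_iters fixed-point (warping) iterations per level
#' @param gamma_d,nu_d,delta_d,alpha_d denoising parameters (see
#'   [denoise_frame()])
#' @param w,sigma_g axial-registration neighborhood parameters
#' @return a `flow_params` list
#' @export
flow_params <- function(levels = 4, downsample = 0.5, kappa = 0.01,
                        rho = 1.5, alpha_o = 0.02, fp_iters = 3,
                        gamma_d = 1, nu_d = 1, delta_d = 0, alpha_d = 0.1,
                        w = 2, sigma_g = 1) {
  stopifnot(levels >= 1, downsample > 0, downsample < 1,
            kappa > 0, rho > 0, alpha_o > 0)
  structure(list(levels = levels, downsample = downsample, kappa = kappa,
                 rho = rho, alpha_o = alpha_o, fp_iters = fp_iters,
                 gamma_d = gamma_d, nu_d = nu_d, delta_d = delta_d,
                 alpha_d = alpha_d, w = w, sigma_g = sigma_g),
            class = "flow_params")
}

gauss_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  rad <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  rmax <- min(dim(img)) - 1L
  if (rmax %% 2L == 0L) rmax <- rmax - 1L
  rad <- min(rad, rmax)
  if (rad < 3L) return(img)
  m <- EBImage::gblur(img, sigma = sigma, radius = rad)
  matrix(as.numeric(m), nrow(img), ncol(img))
}

resize_bilinear <- function(img, H2, W2) {
  m <- EBImage::resize(img, w = H2, h = W2)
  matrix(as.numeric(m), H2, W2)
}

warp_image <- function(img, u, v, fallback) {
  H <- nrow(img); W <- ncol(img)
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  sx <- g$x + as.vector(u)
  sy <- g$y + as.vector(v)
  val <- bilinear_sample_cpp(img, sx, sy)
  out <- matrix(val, H, W)
  bad <- is.na(out)
  out[bad] <- fallback[bad]
  out
}

# one incremental flow solve at a fixed resolution; returns the increment
flow_increment <- function(I1, I2w, u, v, p) {
  H <- nrow(I1); W <- ncol(I1); n <- H * W
  Iavg <- (I1 + I2w) / 2
  Ix <- (Iavg[, c(2:W, W)] - Iavg[, c(1, 1:(W - 1))]) / 2
  Iy <- (Iavg[c(2:H, H), ] - Iavg[c(1, 1:(H - 1)), ]) / 2
  It <- I2w - I1
  J11 <- gauss_blur(Ix * Ix, p$rho); J22 <- gauss_blur(Iy * Iy, p$rho)
  J12 <- gauss_blur(Ix * Iy, p$rho); J13 <- gauss_blur(Ix * It, p$rho)
  J23 <- gauss_blur(Iy * It, p$rho); J33 <- gauss_blur(It * It, p$rho)

  # neighbor (5-point) edges, column-major pixel ids
  id <- matrix(seq_len(n), H, W)
  ev <- cbind(as.vector(id[1:(H - 1), ]), as.vector(id[2:H, ]))
  eh <- cbind(as.vector(id[, 1:(W - 1)]), as.vector(id[, 2:W]))
  edges <- rbind(ev, eh)

  du <- matrix(0, H, W); dv <- matrix(0, H, W)
  k2 <- p$kappa^2
  for (it in 1:2) {   # lagged-diffusivity updates of the robust weights
    q <- J11 * du^2 + J22 * dv^2 + J33 +
      2 * (J12 * du * dv + J13 * du + J23 * dv)
    wd <- 1 / sqrt(1 + pmax(q, 0) / k2)
    ut <- u + du; vt <- v + dv
    gxu <- ut[, c(2:W, W)] - ut; gyu <- ut[c(2:H, H), ] - ut
    gxv <- vt[, c(2:W, W)] - vt; gyv <- vt[c(2:H, H), ] - vt
    ws <- 1 / sqrt(1 + (gxu^2 + gyu^2 + gxv^2 + gyv^2) / k2)
    wsv <- as.vector(ws)
    we <- p$alpha_o * (wsv[edges[, 1]] + wsv[edges[, 2]]) / 2
    li <- c(edges[, 1], edges[, 2], edges[, 1], edges[, 2])
    lj <- c(edges[, 1], edges[, 2], edges[, 2], edges[, 1])
    lx <- c(we, we, -we, -we)
    L <- Matrix::sparseMatrix(i = li, j = lj, x = lx, dims = c(n, n))
    wdv <- as.vector(wd)
    A11 <- L + Matrix::Diagonal(n, wdv * as.vector(J11) + 1e-12)
    A22 <- L + Matrix::Diagonal(n, wdv * as.vector(J22) + 1e-12)
    A12 <- Matrix::Diagonal(n, wdv * as.vector(J12))
    rhs_u <- -wdv * as.vector(J13) - as.numeric(L %*% as.vector(u))
    rhs_v <- -wdv * as.vector(J23) - as.numeric(L %*% as.vector(v))
    A <- rbind(cbind(A11, A12), cbind(A12, A22))
    sol <- as.numeric(Matrix::solve(A, c(rhs_u, rhs_v)))
    du <- matrix(sol[1:n], H, W)
    dv <- matrix(sol[n + 1:n], H, W)
  }
  list(du = du, dv = dv)
}

#' Variational multiresolution optical flow
#'
#' Coarse-to-fine estimation of the dense displacement field between the
#' end-diastolic frame `ID` and a phase frame `Is`: at each pyramid level
#' the robust data term (structure-tensor form, Gaussian-smoothed products
#' of spatial/temporal derivatives) plus a robust smoothness penalty on the
#' accumulated flow is minimized by lagged-diffusivity fixed-point
#' iterations, each solving one sparse linear system; the total flow is the
#' sum of the per-level increments.  Frames are expected denoised (see
#' [denoise_frame()]); intensities are normalized internally.
#'
#' In regions without texture the data term vanishes and the flow is
#' determined by the regularization alone (this is by construction, not an
#' error).
#'
#' @param ID reference (end-diastolic) frame, matrix
#' @param Is target (phase) frame, matrix
#' @param params a [flow_params()]
#' @param pixel_spacing mm per pixel, attached to the result
#' @return a [displacement_field()] mapping ID to Is (pixels; convert to mm
#'   with the carried pixel spacing)
#' @export
optical_flow <- function(ID, Is, params = flow_params(),
                         pixel_spacing = 0.016) {
  stopifnot(all(dim(ID) == dim(Is)))
  I1f <- normalize_intensity(ID)
  I2f <- normalize_intensity(Is)
  H <- nrow(I1f); W <- ncol(I1f)
  R <- params$levels
  facs <- params$downsample^((R - 1):0)
  facs <- facs[pmin(round(H * facs), round(W * facs)) >= 8]
  if (!length(facs)) facs <- 1
  u <- NULL; v <- NULL
  for (f in facs) {
    H2 <- max(8L, round(H * f)); W2 <- max(8L, round(W * f))
    I1 <- if (f == 1) I1f else resize_bilinear(I1f, H2, W2)
    I2 <- if (f == 1) I2f else resize_bilinear(I2f, H2, W2)
    if (is.null(u)) {
      u <- matrix(0, H2, W2); v <- matrix(0, H2, W2)
    } else {
      su <- W2 / ncol(u); sv <- H2 / nrow(u)
      u <- resize_bilinear(u, H2, W2) * su
      v <- resize_bilinear(v, H2, W2) * sv
    }
    for (fp in seq_len(params$fp_iters)) {
      I2w <- warp_image(I2, u, v, fallback = I1)
      inc <- flow_increment(I1, I2w, u, v, params)
      u <- u + inc$du
      v <- v + inc$dv
    }
  }
  displacement_field(u, v, pixel_spacing = pixel_spacing)
}

#' Sample displacement fields at mesh nodes as an observation vector
#'
#' Converts per-pixel optical-flow fields (pixel units, image convention:
#' x along columns, y along rows growing downward) into the stacked
#' observation vector of the assimilation: for each phase, the flow is
#' sampled by bilinear interpolation at the node positions of the imaged
#' mesh and converted to physical displacements in mm (y axis flipped to
#' the mesh convention, origin at the image centre).  Stacking is
#' phase-major, node-major within a phase, (x, y) per node — identical to
#' the predicted-observation stacking of [mechanics_operator()].
#'
#' @param flows list of `displacement_field`s, one per cardiac phase
#' @param mesh imaged-configuration `vessel_mesh` (mm, origin at the image
#'   centre)
#' @param obs_nodes node indices observed (default all)
#' @return list: `Z` (stacked vector, mm), `fields` (per-phase N x 2
#'   matrices, mm, mesh convention)
#' @export
interpolate_observations <- function(flows, mesh, obs_nodes = NULL) {
  if (inherits(flows, "displacement_field")) flows <- list(flows)
  if (is.null(obs_nodes)) obs_nodes <- seq_len(nrow(mesh$nodes))
  xy <- mesh$nodes[obs_nodes, , drop = FALSE]
  fields <- lapply(flows, function(fl) {
    H <- nrow(fl$u); W <- ncol(fl$u)
    sp <- fl$pixel_spacing
    cx <- (W + 1) / 2; cy <- (H + 1) / 2
    px <- xy[, 1] / sp + cx
    py <- cy - xy[, 2] / sp
    out_x <- bilinear_sample_cpp(fl$u, px, py)
    out_y <- bilinear_sample_cpp(fl$v, px, py)
    bad <- is.na(out_x) | is.na(out_y)
    if (any(bad)) {
      warning(sprintf("%d node(s) outside the image footprint; using nearest pixel",
                      sum(bad)))
      pxc <- pmin(pmax(px[bad], 1), W); pyc <- pmin(pmax(py[bad], 1), H)
      out_x[bad] <- fl$u[cbind(round(pyc), round(pxc))]
      out_y[bad] <- fl$v[cbind(round(pyc), round(pxc))]
    }
    cbind(out_x * sp, -out_y * sp)   # image y grows downward
  })
  Z <- unlist(lapply(fields, function(f) as.numeric(t(f))))
  list(Z = Z, fields = fields)
}
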