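#' Frame-matching log-likelihood
#'
#' Similarity of two equally-sized frames under the speckle noise model:
#' \deqn{c(I_n, I_m) = \sum_{ij} [d - \log(e^{2d} + 1)], \quad d = I_n - I_m,}
#' evaluated in a numerically stable symmetric form.  Each term is at most
#' `-log 2` (attained at d = 0), so `c(I, I) = -H W log 2` exactly and
#' identity is the global maximizer over intensity perturbations.
#'
#' @param In,Im numeric matrices of identical shape
#' @return scalar log-likelihood (higher = better match)
#' @export
frame_likelihood <- function(In, Im) {
  if (!all(dim(In) == dim(Im))) stop("frame shapes differ")
  d <- abs(In - Im)
  sum(-d - log1p(exp(-2 * d)))
}

#' Rigid in-plane transform (translation + rotation about the image centre)
#'
#' @param tx,ty translation in pixels (x = columns, y = rows, y growing
#'   downward)
#' @param angle rotation in radians about the geometric image centre
#' @return a `rigid_transform`
#' @export
rigid_transform <- function(tx = 0, ty = 0, angle = 0) {
  structure(list(tx = tx, ty = ty, angle = angle), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: t = (%.3f, %.3f) px, angle = %.3f deg\n",
              x$tx, x$ty, x$angle * 180 / pi))
  invisible(x)
}

#' Apply a rigid transform to an image
#'
#' Resampling convention: the output at pixel p takes the value of the
#' input at `R_angle (p - centre) + centre + (tx, ty)` (bilinear
#' interpolation; out-of-frame samples become `fill`).  Consequently the
#' transform *recovered* by [register_transversal()] is the one that warps
#' the moving frame onto the reference, i.e. the inverse of the motion that
#' displaced the content.
#'
#' @param img numeric matrix
#' @param tf a `rigid_transform`
#' @param fill value for out-of-frame samples
#' @return transformed matrix
#' @export
apply_rigid <- function(img, tf, fill = NA_real_) {
  H <- nrow(img); W <- ncol(img)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  g <- expand.grid(y = seq_len(H), x = seq_len(W))
  rx <- g$x - cx; ry <- g$y - cy
  sx <- cos(tf$angle) * rx - sin(tf$angle) * ry + cx + tf$tx
  sy <- sin(tf$angle) * rx + cos(tf$angle) * ry + cy + tf$ty
  v <- bilinear_sample_cpp(img, sx, sy)
  v[is.na(v)] <- fill
  matrix(v, H, W)
}

#' Transversal rigid registration of a frame against the end-diastolic frame
#'
#' Maximizes the mean per-pixel [frame_likelihood()] of the transformed
#' moving frame against the reference over an exhaustive coarse grid
#' (translation and rotation about the image centre), followed by two local
#' refinement passes at quarter resolution.  Out-of-frame pixels are
#' excluded; the mean (rather than the sum) avoids rewarding transforms
#' that shrink the overlap.
#'
#' @param Is moving frame (phase s)
#' @param ID reference frame (end-diastole)
#' @param max_shift translation search range (+- pixels)
#' @param shift_step coarse translation step (pixels)
#' @param max_angle rotation search range (+- radians)
#' @param angle_step coarse rotation step (radians)
#' @return a `rigid_transform` `tf` maximizing the match of
#'   `apply_rigid(Is, tf)` to `ID`, with attribute `value` (the mean
#'   log-likelihood)
#' @export
register_transversal <- function(Is, ID, max_shift = 15, shift_step = 1,
                                 max_angle = 10 * pi / 180,
                                 angle_step = 0.5 * pi / 180) {
  if (!all(dim(Is) == dim(ID))) stop("frame shapes differ")
  Isn <- normalize_intensity(Is)
  IDn <- normalize_intensity(ID)
  txs <- seq(-max_shift, max_shift, by = shift_step)
  angs <- seq(-max_angle, max_angle, by = angle_step)
  best <- likelihood_search_cpp(Isn, IDn, txs, txs, angs)
  # staged local refinement
  st <- shift_step; sa <- angle_step
  for (pass in 1:2) {
    st <- st / 4; sa <- sa / 4
    txs <- best$tx + st * (-3:3)
    tys <- best$ty + st * (-3:3)
    angs <- best$angle + sa * (-3:3)
    best <- likelihood_search_cpp(Isn, IDn, txs, tys, angs)
  }
  tf <- rigid_transform(best$tx, best$ty, best$angle)
  attr(tf, "value") <- best$value
  tf
}

#' Axial registration: best-matching end-diastolic frame for a site
#'
#' Finds, within the 14 adjacent frames (k in n-7..n+7, clamped to the
#' stack), the end-diastolic frame maximizing the Gaussian-weighted
#' neighborhood likelihood
#' \deqn{c_w(I_n^s, I_m^D) = \sum_{d=-w}^{w} \phi_{\sigma_G}(d)
#'   c(I_{n+d}^s, I_{m+d}^D) / \sum_d \phi_{\sigma_G}(d),}
#' with weights renormalized when the neighborhood is truncated at the
#' stack ends.  With `w = 0` this reduces to the single-pair likelihood.
#'
#' @param stack_s,stack_d transversally registered `image_sequence`s (phase
#'   s and end-diastolic)
#' @param n frame index in `stack_s`
#' @param w neighborhood half-width (frames)
#' @param sigma_g Gaussian weight width (frames)
#' @param search half-width of the search window (7 frames each side)
#' @return best-matching index m in `stack_d`
#' @export
register_axial <- function(stack_s, stack_d, n, w = 2, sigma_g = 1,
                           search = 7) {
  Ns <- length(stack_s$frames); Nd <- length(stack_d$frames)
  stopifnot(n >= 1, n <= Ns)
  ks <- max(1, n - search):min(Nd, n + search)
  cw <- vapply(ks, function(m) {
    ds <- (-w):w
    ok <- (n + ds >= 1) & (n + ds <= Ns) & (m + ds >= 1) & (m + ds <= Nd)
    ds <- ds[ok]
    wt <- exp(-ds^2 / (2 * sigma_g^2))
    wt <- wt / sum(wt)
    sum(wt * vapply(ds, function(d)
      frame_likelihood(stack_s$frames[[n + d]], stack_d$frames[[m + d]]),
      numeric(1)))
  }, numeric(1))
  ks[which.max(cw)]
}
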