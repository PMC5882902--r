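#' Spherical simplex sigma points
#'
#' Deterministic set of M+1 unit sigma points in R^M with equal weights
#' 1/(M+1): the vertices of a regular simplex centred at the origin, scaled
#' so that the weighted mean is zero and the weighted covariance is the
#' identity.
#'
#' @param M dimension (number of parameters)
#' @return list with `points` (M x (M+1) matrix, one sigma point per column)
#'   and `weights` (length M+1)
#' @export
spherical_simplex_points <- function(M) {
  stopifnot(M >= 1)
  # orthonormal basis of the hyperplane orthogonal to 1 in R^(M+1)
  Q <- qr.Q(qr(cbind(rep(1, M + 1), diag(M + 1)[, 1:M])))
  P <- Q[, 2:(M + 1), drop = FALSE]            # (M+1) x M, columns _|_ 1
  pts <- sqrt(M + 1) * t(P)                    # M x (M+1)
  list(points = pts, weights = rep(1 / (M + 1), M + 1))
}

#' Initialize a reduced-order unscented Kalman filter state
#'
#' The initial covariance is P0 = L0 U0^-1 L0^T with L0 = [0_u; 0_lambda;
#' I_theta]: zero blocks on the mechanical state, `sigma_theta` on the
#' diagonal of the parameter block.  The observation covariance R is built
#' from `sigma_z`; with the default convention `"sigma_squared"` its diagonal
#' entries are sigma_z^2 (variances in mm^2), with `"sigma"` they are sigma_z
#' as printed.
#'
#' @param theta0 initial parameter estimate (log2 of stiffness in Pa)
#' @param sigma_theta per-parameter initial uncertainty (scalar or length M)
#' @param sigma_z observation uncertainty (mm)
#' @param r_convention `"sigma_squared"` (default) or `"sigma"`
#' @return a `roukf_state`
#' @export
roukf_init <- function(theta0, sigma_theta = 2, sigma_z = 1e-3,
                       r_convention = c("sigma_squared", "sigma")) {
  r_convention <- match.arg(r_convention)
  M <- length(theta0)
  if (any(sigma_theta <= 0) || sigma_z <= 0) stop("uncertainty scales must be positive")
  sp <- spherical_simplex_points(M)
  structure(list(
    theta = as.numeric(theta0),
    L = diag(M),
    Uinv = diag(rep(sigma_theta, length.out = M), M),
    sigma_points = sp$points,
    weights = sp$weights,
    sigma_z = sigma_z,
    r_inv_diag = if (r_convention == "sigma_squared") 1 / sigma_z^2 else 1 / sigma_z,
    r_convention = r_convention,
    iteration = 0L
  ), class = "roukf_state")
}

#' @export
print.roukf_state <- function(x, ...) {
  cat(sprintf("roukf_state: M=%d, iteration %d, theta = (%s)\n",
              length(x$theta), x$iteration,
              paste(sprintf("%.3f", x$theta), collapse = ", ")))
  invisible(x)
}

#' ROUKF prediction: generate and propagate sigma points
#'
#' Generates the M+1 parameter sigma points `theta_i = theta + L C^T s_i`
#' where `C^T C = U^-1` (Cholesky square root), propagates each through the
#' forward operator, and forms the weighted means.
#'
#' @param fs a `roukf_state`
#' @param predict_fn function taking an M x (M+1) matrix of parameter sigma
#'   points (one per column) and returning the predicted observation matrix
#'   (n_obs x (M+1))
#' @return list with `theta_sigma`, `Z_sigma`, `theta_mean`, `Z_mean`
#' @export
roukf_predict <- function(fs, predict_fn) {
  M <- length(fs$theta)
  Cu <- chol((fs$Uinv + t(fs$Uinv)) / 2)       # upper: Uinv = Cu' Cu
  spread <- fs$L %*% t(Cu) %*% fs$sigma_points  # M x (M+1)
  th_sig <- fs$theta + spread
  Z_sig <- predict_fn(th_sig)
  if (!is.matrix(Z_sig) || ncol(Z_sig) != M + 1)
    stop("predict_fn must return one observation column per sigma point")
  w <- fs$weights
  list(theta_sigma = th_sig,
       Z_sigma = Z_sig,
       theta_mean = as.numeric(th_sig %*% w),
       Z_mean = as.numeric(Z_sig %*% w))
}

#' ROUKF correction step
#'
#' Updates the factors L and U and the estimate from the innovation
#' `Z - Zhat`:
#' `L = theta* Dw sigma*'`, `{HL} = Z* Dw sigma*'`,
#' `U = Pw + {HL}' R^-1 {HL}`,
#' `theta+ = theta- + L U^-1 {HL}' R^-1 (Z - Zhat)`.
#' The sigma-point matrices are used uncentred; because the simplex weighted
#' mean is zero this equals the centred form (asserted numerically).
#'
#' @param fs a `roukf_state`
#' @param Z observation vector
#' @param pred the list returned by [roukf_predict()]
#' @return the updated `roukf_state`, with fields `theta`, `L`, `Uinv`,
#'   `U`, and the innovation stored as `innovation`
#' @export
roukf_correct <- function(fs, Z, pred) {
  M <- length(fs$theta)
  w <- fs$weights
  sig <- fs$sigma_points
  stopifnot(max(abs(sig %*% w)) < 1e-12)   # spherical simplex zero mean
  Dw_sig_t <- t(sig * rep(w, each = M))    # (M+1) x M,  Dw sigma*'
  Ltheta <- pred$theta_sigma %*% Dw_sig_t  # M x M
  HL <- pred$Z_sigma %*% Dw_sig_t          # n x M
  Pw <- sig %*% Dw_sig_t                   # = I by construction
  rHL <- fs$r_inv_diag * HL
  U <- Pw + crossprod(HL, rHL)
  U <- (U + t(U)) / 2
  Uinv <- tryCatch(chol2inv(chol(U)), error = function(e)
    stop("U lost positive definiteness: filter diverged (conditioning)"))
  innov <- as.numeric(Z) - pred$Z_mean
  gain_rhs <- crossprod(rHL, innov)        # {HL}' R^-1 (Z - Zhat)
  theta_new <- pred$theta_mean + as.numeric(Ltheta %*% (Uinv %*% gain_rhs))
  fs$theta <- theta_new
  fs$L <- Ltheta
  fs$U <- U
  fs$Uinv <- Uinv
  fs$innovation <- innov
  fs$iteration <- fs$iteration + 1L
  fs
}

#' Parameter covariance and uncertainty interval of a ROUKF state
#'
#' The parameter covariance is L U^-1 L^T; the reported uncertainty interval
#' on the stiffness scale is `[2^(theta - sqrt(diag(U^-1))), 2^(theta +
#' sqrt(diag(U^-1)))]`.
#'
#' @param fs a `roukf_state`
#' @return list with `cov`, `lower`, `upper` (Pa)
#' @export
roukf_uncertainty <- function(fs) {
  hw <- sqrt(pmax(diag(fs$Uinv), 0))
  list(cov = fs$L %*% fs$Uinv %*% t(fs$L),
       lower = 2^(fs$theta - hw),
       upper = 2^(fs$theta + hw))
}

#' Run a ROUKF estimation to convergence
#'
#' Iterates prediction/correction against a fixed observation vector for a
#' fixed number of iterations (the mechanical problems are static, so filter
#' "time" is just the iteration index).  Parameters are estimated on the
#' log2 scale: `c = 2^theta` stays positive for any real theta.
#'
#' @param theta0 initial estimate, log2(c in Pa)
#' @param Z observation vector
#' @param predict_fn see [roukf_predict()]
#' @param iterations fixed iteration count (the stop criterion)
#' @param sigma_theta,sigma_z,r_convention see [roukf_init()]
#' @param callback optional function(iter, fs) called after each correction
#' @return list with the final `state`, and `trajectory`: a data.frame with
#'   one row per iteration (theta, c = 2^theta and interval bounds per
#'   parameter)
#' @export
roukf_estimate <- function(theta0, Z, predict_fn, iterations = 50,
                           sigma_theta = 2, sigma_z = 1e-3,
                           r_convention = c("sigma_squared", "sigma"),
                           callback = NULL) {
  fs <- roukf_init(theta0, sigma_theta, sigma_z, match.arg(r_convention))
  M <- length(theta0)
  traj <- vector("list", iterations)
  for (k in seq_len(iterations)) {
    pred <- roukf_predict(fs, predict_fn)
    fs <- roukf_correct(fs, Z, pred)
    un <- roukf_uncertainty(fs)
    traj[[k]] <- data.frame(iteration = k,
                            parameter = seq_len(M),
                            theta = fs$theta,
                            c = 2^fs$theta,
                            lower = un$lower,
                            upper = un$upper,
                            innovation_rms = sqrt(mean(fs$innovation^2)))
    if (!is.null(callback)) callback(k, fs)
  }
  list(state = fs, trajectory = do.call(rbind, traj))
}

#' Mechanical forward operator for the assimilation
#'
#' Builds the operator f of the filter: for one set of regional stiffness
#' parameters it solves the preload problem once on the imaged mesh and then
#' one forward problem per cardiac phase, and returns the predicted
#' end-diastole-to-phase displacement `u_m - u_d` stacked over phases
#' (phase-major) at the observation nodes.
#'
#' Sigma-point solves are independent and dispatched through
#' [parallel_map()]; each sigma-point slot keeps its previous converged
#' states as warm starts across filter iterations.
#'
#' @param mesh imaged-configuration `vessel_mesh`
#' @param preload_case a [load_case()] with role `"preload"` (diastolic
#'   pressure)
#' @param forward_cases list of [load_case()]s, one per cardiac phase
#' @param obs_nodes integer node indices observed (default: all nodes)
#' @param uof_list optional list (one per phase) of N x 2 observed flow
#'   fields used as the Robin anchor u_d + u_OF when `tau > 0`
#' @param jobs parallel workers for sigma-point solves
#' @param control Newton controls
#' @return a function mapping an M x (M+1) sigma-point matrix to an
#'   observation matrix, suitable for [roukf_estimate()]
#' @export
mechanics_operator <- function(mesh, preload_case, forward_cases,
                               obs_nodes = NULL, uof_list = NULL,
                               jobs = 1, control = newton_control()) {
  if (is.null(obs_nodes)) obs_nodes <- seq_len(nrow(mesh$nodes))
  S <- length(forward_cases)
  cache <- new.env(parent = emptyenv())
  function(th_sig) {
    ncol_s <- ncol(th_sig)
    run_one <- function(i) {
      c_reg <- 2^th_sig[, i]
      key <- paste0("s", i)
      warm <- if (exists(key, envir = cache)) get(key, envir = cache) else NULL
      pre <- solve_preload(mesh, c_reg, preload_case,
                           state0 = warm$pre, control = control)
      mm <- material_mesh(mesh, pre)
      zcols <- vector("list", S)
      fwds <- vector("list", S)
      for (s in seq_len(S)) {
        lc <- forward_cases[[s]]
        if (lc$tau > 0) {
          uof <- if (!is.null(uof_list)) uof_list[[s]] else matrix(0, nrow(mesh$nodes), 2)
          lc$robin_ref <- pre$u + uof     # u_d + u_OF at the material nodes
        }
        st0 <- if (!is.null(warm$fwd[[s]])) warm$fwd[[s]] else pre
        fwd <- solve_forward(mm, c_reg, lc, state0 = st0, control = control)
        fwds[[s]] <- fwd
        d <- fwd$u - pre$u
        zcols[[s]] <- as.numeric(t(d[obs_nodes, , drop = FALSE]))
      }
      list(z = unlist(zcols), warm = list(pre = pre, fwd = fwds))
    }
    out <- parallel_map(seq_len(ncol_s), run_one, jobs = jobs)
    for (i in seq_len(ncol_s)) assign(paste0("s", i), out[[i]]$warm, envir = cache)
    do.call(cbind, lapply(out, `[[`, "z"))
  }
}

#' Run the full ROUKF stiffness estimation on a mesh
#'
#' Convenience wrapper tying [mechanics_operator()] and [roukf_estimate()]
#' together.
#'
#' @inheritParams mechanics_operator
#' @param Z stacked observation vector (see [gen_insilico_observations()] or
#'   [interpolate_observations()])
#' @param theta0 initial log2-stiffness (scalar recycled to M)
#' @param iterations fixed filter iteration count
#' @param sigma_theta,sigma_z,r_convention see [roukf_init()]
#' @param M number of regions (defaults to `mesh$n_regions`)
#' @param restarts number of additional filter sweeps: because the static
#'   observation is replayed at every iteration, the covariance contracts
#'   and the gain decays like 1/k, which can stall multi-parameter estimates
#'   far from the truth.  With `restarts > 0` the filter is re-initialized
#'   (covariance reset to `sigma_theta`) at the current estimate after each
#'   sweep of `iterations`, recovering full Gauss-Newton-sized steps (an
#'   iterated-filter strategy).  The returned trajectory concatenates all
#'   sweeps.
#' @param restart_decay multiplier applied to `sigma_theta` at each restart
#'   (< 1 anneals the sigma-point spread so late sweeps use an accurate
#'   local linearization; useful for ill-conditioned multi-parameter cases)
#' @return as [roukf_estimate()], plus `c` (final stiffness per region, Pa)
#'   and the final uncertainty interval
#' @export
run_roukf <- function(mesh, Z, preload_case, forward_cases,
                      theta0 = NULL, iterations = 50,
                      sigma_theta = 2, sigma_z = 1e-3,
                      r_convention = "sigma_squared",
                      obs_nodes = NULL, uof_list = NULL, jobs = 1,
                      restarts = 0, restart_decay = 1,
                      control = newton_control(), callback = NULL) {
  M <- mesh$n_regions
  if (is.null(theta0))
    theta0 <- roukf_initial_guess(mesh, Z, preload_case, forward_cases,
                                  uof_list = uof_list, control = control)
  theta0 <- rep(theta0, length.out = M)
  op <- mechanics_operator(mesh, preload_case, forward_cases,
                           obs_nodes = obs_nodes, uof_list = uof_list,
                           jobs = jobs, control = control)
  th <- theta0
  trajs <- list()
  for (sweep in seq_len(restarts + 1)) {
    res <- roukf_estimate(th, Z, op, iterations = iterations,
                          sigma_theta = sigma_theta * restart_decay^(sweep - 1),
                          sigma_z = sigma_z,
                          r_convention = r_convention, callback = callback)
    th <- res$state$theta
    tr <- res$trajectory
    tr$sweep <- sweep
    tr$iteration <- tr$iteration + (sweep - 1) * iterations
    trajs[[sweep]] <- tr
  }
  res$trajectory <- do.call(rbind, trajs)
  un <- roukf_uncertainty(res$state)
  res$c <- 2^res$state$theta
  res$lower <- un$lower
  res$upper <- un$upper
  res
}
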