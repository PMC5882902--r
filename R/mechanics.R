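#' Neo-Hookean second Piola-Kirchhoff stress
#'
#' Isochoric part of the incompressible Neo-Hookean stress,
#' \eqn{S = c J^{-2/3} (I - \bar I_1 \dots)}{S = dpsi/dE} with strain energy
#' \eqn{\psi = c/2(\bar I_1 - 3)}, \eqn{\bar I_1 = tr(C) (\det F)^{-2/3}}.
#' The incompressibility pressure is carried separately by the multiplier
#' field and is not part of this stress (see [push_forward_cauchy()]).
#'
#' @param F 3x3 deformation gradient, `det F > 0`
#' @param c stiffness parameter (Pa)
#' @return 3x3 second Piola-Kirchhoff stress (Pa)
#' @export
neo_hookean_pk2 <- function(F, c) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)), c > 0)
  J <- det(F)
  if (J <= 0) stop("inverted element: det F <= 0")
  C <- crossprod(F)
  I1 <- sum(diag(C))
  c * J^(-2 / 3) * (diag(3) - (I1 / 3) * solve(C))
}

#' Neo-Hookean strain energy density
#' @inheritParams neo_hookean_pk2
#' @return energy density (Pa)
#' @export
neo_hookean_psi <- function(F, c) {
  J <- det(F)
  if (J <= 0) stop("inverted element: det F <= 0")
  I1bar <- sum(diag(crossprod(F))) * J^(-2 / 3)
  c / 2 * (I1bar - 3)
}

#' Push a second Piola-Kirchhoff stress forward to Cauchy stress
#'
#' \eqn{\sigma = (1/\det F) F S F^T - \lambda I}; the multiplier
#' \eqn{\lambda} is the solid pressure of the mixed formulation (sign
#' convention: total stress = deviatoric push-forward minus spherical
#' \eqn{\lambda I}).
#'
#' @param F 3x3 deformation gradient
#' @param S 3x3 second Piola-Kirchhoff stress (Pa)
#' @param lambda pressure multiplier (Pa)
#' @return 3x3 Cauchy stress (Pa), symmetric
#' @export
push_forward_cauchy <- function(F, S, lambda = 0) {
  J <- det(F)
  if (J <= 0) stop("inverted element: det F <= 0")
  F %*% S %*% t(F) / J - lambda * diag(3)
}

#' Load case for the equilibrium problems
#'
#' @param pressure_mmhg lumen pressure (mmHg); converted internally to Pa
#' @param axial_stretch prescribed axial stretch fraction (0.10 = 10%);
#'   imposed as the out-of-plane stretch of the generalized plane-strain
#'   kinematics
#' @param tau Robin stiffness of the surrounding-tissue support on the
#'   external boundary (traction per displacement, Pa/mm); 0 disables it
#' @param robin_ref optional N x 2 matrix: the displacement (mm) the external
#'   support is anchored to (the u_d + u_OF field), sampled at all mesh nodes
#' @param role "forward" or "preload" (the preload problem omits the Robin
#'   support by construction)
#' @return a `load_case` object
#' @export
load_case <- function(pressure_mmhg, axial_stretch = 0.10, tau = 0,
                      robin_ref = NULL, role = c("forward", "preload")) {
  role <- match.arg(role)
  stopifnot(pressure_mmhg >= 0, tau >= 0)
  if (role == "preload" && tau != 0)
    stop("the preload problem omits the surrounding-media support (tau must be 0)")
  structure(list(pressure = mmhg_to_pa(pressure_mmhg),
                 pressure_mmhg = pressure_mmhg,
                 lambda_z = 1 + axial_stretch,
                 axial_stretch = axial_stretch,
                 tau = tau, robin_ref = robin_ref, role = role),
            class = "load_case")
}

#' Newton solver controls
#'
#' @param tol_u,tol_lambda convergence thresholds on the last Newton update:
#'   `max|du| < tol_u` (mm) and `max|dlambda| < tol_lambda` (Pa)
#' @param max_iter Newton iterations per load increment
#' @param max_increments load stepping: start at 1 increment, double on
#'   failure up to this many
#' @param beta_stab pressure-diffusion stabilization coefficient
#' @return list of controls
#' @export
newton_control <- function(tol_u = 1e-4, tol_lambda = 1, max_iter = 30,
                           max_increments = 32, beta_stab = 0.1) {
  list(tol_u = tol_u, tol_lambda = tol_lambda, max_iter = max_iter,
       max_increments = max_increments, beta_stab = beta_stab)
}

# rigid-motion control: returns list(T = sparse ndof x ndof basis transform,
# fixed = dof indices (in transformed basis) to pin)
rigid_control_transform <- function(mesh, role, tau) {
  N <- nrow(mesh$nodes)
  ndof <- 3L * N
  fixed <- integer()
  diagx <- rep(1, ndof)
  ei <- integer(); ej <- integer(); ex <- numeric()
  if (length(mesh$radial_nodes) > 0) {
    ctr <- colMeans(mesh$nodes[unique(as.vector(mesh$edges_w)), , drop = FALSE])
    for (k in mesh$radial_nodes) {
      er <- mesh$nodes[k, ] - ctr
      er <- er / sqrt(sum(er^2))
      et <- c(-er[2], er[1])
      d <- c(2L * k - 1L, 2L * k)
      # replace the identity block by the (radial, tangential) basis
      diagx[d] <- 0
      ei <- c(ei, d[1], d[2], d[1], d[2])
      ej <- c(ej, d[1], d[1], d[2], d[2])
      ex <- c(ex, er[1], er[2], et[1], et[2])
      fixed <- c(fixed, d[2])   # tangential component pinned
    }
  } else if (role == "preload" || tau == 0) {
    # pin the small external arc to remove rigid motions
    for (k in mesh$fixed_arc) fixed <- c(fixed, 2L * k - 1L, 2L * k)
  }
  T <- Matrix::sparseMatrix(i = c(seq_len(ndof), ei), j = c(seq_len(ndof), ej),
                            x = c(diagx, ex), dims = c(ndof, ndof))
  list(T = T, fixed = fixed)
}

# shared Newton driver for the forward (mode 0) and preload (mode 1) problems
newton_solve <- function(mesh, c_region, load, mode, state0 = NULL,
                         control = newton_control()) {
  N <- nrow(mesh$nodes)
  ndof <- 3L * N
  u <- if (!is.null(state0)) state0$u else matrix(0, N, 2)
  lam <- if (!is.null(state0)) state0$lambda else numeric(N)
  uref <- load$robin_ref
  if (is.null(uref)) uref <- matrix(0, N, 2)
  tau <- if (mode == 0) load$tau else 0
  tc <- rigid_control_transform(mesh, if (mode == 0) "forward" else "preload", tau)
  free <- setdiff(seq_len(ndof), tc$fixed)
  if (length(tc$fixed) == 0 && tau == 0 && length(mesh$radial_nodes) == 0)
    stop("no rigid-motion control available: singular system")

  n_inc <- 1L
  repeat {
    ok <- TRUE
    u_try <- u; lam_try <- lam
    iters_total <- 0L
    for (inc in seq_len(n_inc)) {
      frac <- inc / n_inc
      p_inc <- load$pressure * frac
      uref_inc <- uref * frac
      converged <- FALSE
      for (it in seq_len(control$max_iter)) {
        sys <- assemble_system_cpp(mesh$nodes, mesh$tri, mesh$region,
                                   c_region, load$lambda_z,
                                   control$beta_stab, u_try, lam_try,
                                   mode, p_inc, mesh$edges_w,
                                   tau, mesh$edges_e, uref_inc, TRUE)
        K <- Matrix::sparseMatrix(i = sys$i + 1L, j = sys$j + 1L, x = sys$x,
                                  dims = c(ndof, ndof))
        Kt <- Matrix::t(tc$T) %*% K %*% tc$T
        rt <- as.numeric(Matrix::t(tc$T) %*% sys$res)
        du_t <- numeric(ndof)
        Kff <- Kt[free, free, drop = FALSE]
        # symmetric diagonal equilibration: the multiplier block scales as
        # h^2/c and would otherwise trip condition bounds for stiff tissue
        dsc <- 1 / sqrt(pmax(abs(Matrix::diag(Kff)), 1e-30))
        Ds <- Matrix::Diagonal(x = dsc)
        sol <- tryCatch(
          Matrix::solve(Ds %*% Kff %*% Ds, -(dsc * rt[free])),
          error = function(e) NULL)
        if (is.null(sol) || any(!is.finite(as.numeric(sol)))) { ok <- FALSE; break }
        du_t[free] <- dsc * as.numeric(sol)
        du <- as.numeric(tc$T %*% du_t)
        # damped update: keep all elements non-inverted
        alpha <- 1
        for (ls in 1:10) {
          u_new <- u_try + alpha * matrix(du[seq_len(2 * N)], N, 2, byrow = TRUE)
          detF <- element_detF_cpp(mesh$nodes, mesh$tri, u_new, mode)
          if (all(is.finite(detF)) && all(detF > 1e-6)) break
          alpha <- alpha / 2
          if (ls == 10) { ok <- FALSE }
        }
        if (!ok) break
        lam_new <- lam_try + alpha * du[2 * N + seq_len(N)]
        step_u <- max(abs(u_new - u_try))
        step_l <- max(abs(lam_new - lam_try))
        u_try <- u_new; lam_try <- lam_new
        iters_total <- iters_total + 1L
        if (alpha == 1 && step_u < control$tol_u && step_l < control$tol_lambda) {
          converged <- TRUE
          break
        }
      }
      if (!ok || !converged) { ok <- FALSE; break }
    }
    if (ok) {
      return(structure(list(u = u_try, lambda = lam_try, converged = TRUE,
                            newton_iters = iters_total, increments = n_inc,
                            mode = if (mode == 0) "forward" else "preload"),
                       class = "mechanical_state"))
    }
    n_inc <- n_inc * 2L
    if (n_inc > control$max_increments)
      stop(sprintf("Newton divergence after %d load increments", n_inc / 2L))
    u <- matrix(0, N, 2); lam <- numeric(N)
  }
}

#' @export
print.mechanical_state <- function(x, ...) {
  cat(sprintf("mechanical_state (%s): converged=%s, %d Newton iterations, max|u| = %.4g mm\n",
              x$mode, x$converged, x$newton_iters, max(abs(x$u))))
  invisible(x)
}

#' Solve the forward equilibrium problem
#'
#' Finds the deformed configuration of the vessel slice given its stress-free
#' material configuration, a lumen pressure (follower load), a prescribed
#' axial stretch and, optionally, a Robin support on the external boundary
#' anchored at `load$robin_ref`.
#'
#' @param mesh a `vessel_mesh` holding the *material* configuration (e.g. the
#'   output of [material_mesh()] after a preload solve)
#' @param mat numeric vector of per-region stiffness parameters c (Pa)
#' @param load a [load_case()] with `role = "forward"`
#' @param state0 optional previous `mechanical_state` used as initial guess
#' @param control see [newton_control()]
#' @return a `mechanical_state` with nodal displacement `u` (mm, material ->
#'   deformed) and pressure multiplier `lambda` (Pa)
#' @export
solve_forward <- function(mesh, mat, load, state0 = NULL,
                          control = newton_control()) {
  stopifnot(inherits(load, "load_case"), load$role == "forward")
  check_material(mat, mesh)
  newton_solve(mesh, mat, load, mode = 0L, state0 = state0, control = control)
}

#' Solve the preload (inverse) equilibrium problem
#'
#' Given the *imaged* configuration (the geometry seen at end-diastole, which
#' is at equilibrium under the diastolic pressure), finds the displacement
#' `u` such that the material, stress-free configuration is
#' `x_material = x_imaged - u`.  The surrounding-media support is omitted in
#' this problem.
#'
#' @param mesh a `vessel_mesh` holding the imaged (spatial) configuration
#' @param mat per-region stiffness parameters c (Pa)
#' @param load a [load_case()] with `role = "preload"`
#' @inheritParams solve_forward
#' @return a `mechanical_state`; `u` maps spatial -> material
#' @export
solve_preload <- function(mesh, mat, load, state0 = NULL,
                          control = newton_control()) {
  stopifnot(inherits(load, "load_case"), load$role == "preload")
  check_material(mat, mesh)
  st <- newton_solve(mesh, mat, load, mode = 1L, state0 = state0,
                     control = control)
  st
}

check_material <- function(mat, mesh) {
  if (length(mat) != mesh$n_regions)
    stop(sprintf("material has %d parameters but mesh has %d regions",
                 length(mat), mesh$n_regions))
  if (any(mat <= 0)) stop("stiffness parameters must be positive")
  invisible(TRUE)
}

#' Material configuration recovered by a preload solve
#'
#' @param mesh the imaged-configuration `vessel_mesh` used for the preload
#' @param preload_state the `mechanical_state` returned by [solve_preload()]
#' @return a `vessel_mesh` whose nodes are the stress-free material
#'   coordinates `x - u`; connectivity and tags are preserved.  The
#'   displacement `u` doubles as the field u_d (material -> imaged) sampled
#'   at the material nodes.
#' @export
material_mesh <- function(mesh, preload_state) {
  m <- mesh
  m$nodes <- mesh$nodes - preload_state$u
  a <- mesh_areas(m)
  if (any(a <= 0)) stop("preload produced a non-positive-volume material configuration")
  m
}

#' Assemble residual and consistent tangent of an equilibrium problem
#'
#' Exposes the discrete system (P1/P1 triangles, one-point quadrature,
#' pressure-diffusion stabilization) for a given state, mainly for
#' verification: the tangent is the consistent linearization of the residual.
#'
#' @inheritParams solve_forward
#' @param state a `mechanical_state` (or list with `u`, `lambda`)
#' @param problem "forward" or "preload"
#' @return list with `residual` (length 3N) and sparse `tangent`
#' @export
assemble_system <- function(mesh, mat, load, state,
                            problem = c("forward", "preload"),
                            control = newton_control()) {
  problem <- match.arg(problem)
  mode <- if (problem == "forward") 0L else 1L
  N <- nrow(mesh$nodes)
  uref <- load$robin_ref
  if (is.null(uref)) uref <- matrix(0, N, 2)
  tau <- if (mode == 0L) load$tau else 0
  sys <- assemble_system_cpp(mesh$nodes, mesh$tri, mesh$region, mat,
                             load$lambda_z, control$beta_stab,
                             state$u, state$lambda, mode, load$pressure,
                             mesh$edges_w, tau, mesh$edges_e, uref, TRUE)
  list(residual = sys$res,
       tangent = Matrix::sparseMatrix(i = sys$i + 1L, j = sys$j + 1L,
                                      x = sys$x, dims = c(3L * N, 3L * N)))
}

#' Closed-form inflation of an incompressible Neo-Hookean tube
#'
#' Semi-analytic pressure-radius relation for a homogeneous, incompressible
#' Neo-Hookean thick-walled cylinder in (generalized) plane strain: the
#' internal pressure carrying an inner radius `ri` in the deformed state is
#' \deqn{p(r_i) = \int_{r_i}^{r_o} c (\lambda_\theta^2 - \lambda_r^2) / r \, dr}
#' with \eqn{\lambda_\theta = r / R(r)}, \eqn{\lambda_r = 1/(\lambda_z
#' \lambda_\theta)}, and the incompressible map \eqn{R(r) = \sqrt{R_i^2 +
#' \lambda_z (r^2 - r_i^2)}}.  Used as an independent benchmark for the
#' finite-element forward solver.
#'
#' @param ri deformed inner radius (mm)
#' @param Ri,Ro material inner/outer radius (mm)
#' @param c stiffness (Pa)
#' @param lambda_z out-of-plane stretch
#' @return internal pressure (Pa)
#' @export
tube_pressure_closed_form <- function(ri, Ri, Ro, c, lambda_z = 1) {
  ro <- sqrt(ri^2 + (Ro^2 - Ri^2) / lambda_z)
  f <- function(r) {
    R <- sqrt(Ri^2 + lambda_z * (r^2 - ri^2))
    lt <- r / R
    lr <- 1 / (lambda_z * lt)
    c * (lt^2 - lr^2) / r
  }
  stats::integrate(f, ri, ro, rel.tol = 1e-10)$value
}
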