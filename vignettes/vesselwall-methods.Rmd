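---
title: "Estimating arterial-wall stiffness from IVUS displacement data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating arterial-wall stiffness from IVUS displacement data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intravascular ultrasound (IVUS) images a coronary cross-section from inside
the lumen at high frame rates while the wall deforms under the cardiac
pressure cycle. If the wall displacement field between end-diastole and other
cardiac phases can be extracted from the images, and a mechanical model of
the wall can predict that displacement as a function of tissue stiffness,
then regional stiffness becomes an estimable parameter — an in-vivo,
patient-specific material characterization. `vesselwall` implements the
three stages of that pipeline:

1. **imaging** — cardiac gating, rigid registration, speckle denoising and
   variational optical flow, turning a frame sequence into displacement
   fields;
2. **mechanics** — a finite-strain, incompressible Neo-Hookean
   mixed finite-element model of the vessel slice, including the *preload*
   (inverse) problem that recovers the stress-free configuration from the
   imaged, pressurized geometry;
3. **assimilation** — a reduced-order unscented Kalman filter (ROUKF) that
   iterates the mechanical model against the observed displacements to
   estimate one stiffness parameter per tissue region, with an uncertainty
   interval.

Because no patient data ship with the package, a fourth component generates
everything synthetically: ring and partitioned-slice meshes, in-silico
displacement observations produced by the forward model itself, and speckled
IVUS-like sequences with known motion.

## Imaging

**Gating.** The per-frame motion signal mixes frame-to-frame intensity
decorrelation with a (negative) gradient-magnitude sharpness term,
`s(n) = alpha_g [1 - corr(I_n, I_{n+1})] + (1 - alpha_g) sum(-|grad I_n|)`.
The mixture weight defaults to `alpha_g = 0.5`; intensities are normalized
to [0, 1] first because the two terms otherwise live on incomparable scales.
The mean cardiac frequency `f_m` is the dominant spectral mode of `s` inside
the physiological band 0.75–1.66 Hz; minima of the low-pass-filtered signal
(zero-phase hard FFT cutoff at `1.4 f_m`, so minima are not phase-shifted)
mark end-diastole. Minima are refined by raising the cutoff as
`(k + 0.4) f_m` and snapping to the nearest local minimum until stable (at
most 10 passes), merging minima that collapse. Frames of a constant image
(zero variance) are degenerate: their correlation term is defined as 0.

**Registration.** Matching uses the speckle-model log-likelihood
`c(I_n, I_m) = sum d - log(e^{2d} + 1)`, `d = I_n - I_m`, evaluated in a
symmetric, overflow-safe form. Each pixel term is maximal (`-log 2`) at
`d = 0`, so `c(I, I) = -HW log 2` exactly. The transversal (in-plane) rigid
transform is found by exhaustive search on a coarse grid (translation ±15 px
step 1, rotation ±10° step 0.5°) followed by two staged local refinements at
quarter resolution; the objective is non-smooth, so derivative-free search
is deliberate. Out-of-frame pixels are excluded and the *mean* per-pixel
likelihood is maximized — a plain sum would reward transforms that shrink
the overlap, since every term is negative. Axial registration maximizes a
Gaussian-weighted neighborhood likelihood over the 14 adjacent frames
(defaults `w = 2`, `sigma_G = 1` frame), renormalizing the weights when the
stack truncates the neighborhood.

**Denoising.** Ultrasound speckle is multiplicative; the data term is the
negative log-likelihood of a (log-)gamma residual `r = J - I`,
`-gamma nu r + delta + gamma e^{gamma r}`, which is convex with an interior
minimum, plus a total-variation penalty `alpha_d |grad I|`. Defaults
`gamma = nu = 1, delta = 0, alpha_d = 0.1` give the pure shape `e^r - r`.
TV is smoothed with `eps = 1e-3` and minimized by gradient descent with an
adaptive backtracking step, which guarantees a non-increasing objective at
every iteration (this property is asserted in the tests on every run); the
budget is 300 iterations, with a warning (not an error) if it is exhausted.

**Optical flow.** A coarse-to-fine variational estimator: at each of `R = 4`
pyramid levels (factor 0.5) the increment minimizes a robust data term in
structure-tensor form — Gaussian-smoothed (width `rho = 1.5` px) products of
spatial/temporal derivatives, penalized by
`psi(x) = 2 kappa^2 sqrt(1 + x/kappa^2)` with `kappa = 0.01` on normalized
intensities — plus `alpha_o = 0.02` times the same robust penalty on the
gradient of the accumulated flow. Two lagged-diffusivity updates per
fixed-point iteration linearize the robust weights; each update solves one
sparse symmetric system (coupled u/v blocks) with a direct solver. Three
warping iterations per level. The total flow is the sum over levels,
converted to mm via the pixel spacing (16 µm default). In textureless
regions the data term vanishes and the flow is determined by the
regularization; that is the intended behavior, not a failure. These
parameter values are conventional for this family of estimators; the
sequences the pipeline targets do not pin them down more precisely, and all
of them are exposed in `flow_params()`.

Image convention: matrices are row = y (downward), column = x; transforms
rotate about the geometric centre pixel. When flow fields are sampled at
mesh nodes (`interpolate_observations()`), the y axis is flipped to the
physical convention (y up, origin at the image centre) and values scaled to
mm.

## Mechanics

**Kinematics and constitutive model.** The wall is incompressible and
isotropic Neo-Hookean per region: strain energy `psi = c/2 (I1bar - 3)` with
`I1bar = tr(C) (det F)^{-2/3}`; `c` (Pa) is the single stiffness parameter
per region. Incompressibility `det F = 1` is enforced by a pressure
multiplier `lambda`, with the sign convention `sigma = sigma_iso - lambda I`
(so `lambda` is the mechanical pressure). Residual stresses are neglected:
the material configuration is stress-free.

**Two equilibrium problems.** The *forward* problem is posed on the known
material configuration: find the deformed state under a lumen pressure
(a follower load, normal to the deformed surface), a prescribed axial
stretch, and optionally a Robin support `tau (u - u_ref)` on the external
boundary modelling surrounding tissue, anchored at the end-diastolic
configuration plus the observed flow (`u_ref = u_d + u_OF`). The *preload*
problem is inverse: the imaged end-diastolic geometry is the equilibrium
(spatial) configuration under the diastolic pressure, and the unknown is
the displacement `u` such that `x_material = x_imaged - u`; it is posed on
the spatial domain with `F = (I - grad u)^{-1}`, and the pressure becomes a
dead load on the known boundary. The surrounding-media support is omitted
in the preload problem (the external tissue is taken relaxed at
end-diastole). Solving preload once and then one forward problem per
cardiac phase yields the predicted end-diastole-to-phase displacement
`u_m - u_d` at every node — the quantity the filter compares with the
optical flow.

**Geometry mode.** The package implements the cross-section as a 2D
triangle mesh in *generalized plane strain*: the out-of-plane stretch is
prescribed (`F_33 = 1 + axial_stretch`, 10% by default), so in-plane
incompressibility reads `lambda_z det F_2d = 1`. This represents the axial
stretch datum exactly while keeping desk-scale runtimes; a thin 3D
extrusion of the same cross-section would add degrees of freedom without
changing the estimation problem, because the slice is kinematically
homogeneous through its 0.05 mm thickness. The axial stretch is imposed as
a kinematic datum rather than identifying the tethering traction that would
produce it, since the stretch is what is physiologically known.

**Discretization and solver.** Linear triangles for displacement and
pressure (P1/P1), one-point quadrature, with a Brezzi–Pitkäranta
pressure-diffusion stabilization `beta h^2 / c` (`beta = 0.1`, `h^2 = 2A`
per element, `c` the element's stiffness) to satisfy inf-sup. The element
residual is written once, templated over the scalar type; the consistent
tangent is obtained per element by complex-step differentiation (step
1e-30), which is exact to machine precision — the finite-difference check
in the tests (central differences on the assembled residual, 1e-6 relative)
is an independent verification, not the construction. Newton iterations
stop when the last update satisfies `max|du| < 1e-4 mm` and
`max|dlambda| < 1 Pa`; an update that would invert an element is damped by
halving, and on failure the load is applied in 2, 4, … up to 32 increments.
The sparse saddle-point systems are solved by direct LU (Matrix package)
after symmetric diagonal equilibration — the multiplier block scales as
`h^2/c`, so for calcified stiffness the unequilibrated matrix is
numerically singular to condition estimators.

Rigid motions are controlled as in the idealized experiments: four
equidistant lumen nodes restricted to radial motion (their degrees of
freedom are rotated into a radial/tangential basis and the tangential
component pinned), which removes both translations and the rotation without
disturbing axisymmetry. Meshes also tag a 0.1 mm external arc that is
pinned in preload solves when no radial control is present. Units are mm,
Pa, and mmHg at the interfaces (1 mmHg = 133.322 Pa). The Robin term is
assembled on the nominal (material) edge measure rather than the deformed
area: `tau` is a surrogate stiffness whose value is what matters, and the
external-boundary strains are small.

**Benchmark.** The forward solver is verified against the semi-analytic
inflation of an incompressible Neo-Hookean thick-walled cylinder
(`tube_pressure_closed_form()`), with agreement within 1% at the coarse
resolutions used in the tests, and the preload/forward pair is verified to
round-trip the imaged geometry to within 2e-4 mm.

## Assimilation

**Filter.** The augmented state stacks the per-phase mechanical states and
the parameters `theta = log2(c)`; the `2^theta` reparametrization keeps
`c > 0` for any real `theta`. The covariance is factored `L U^{-1} L^T`
with reduced dimension M (the number of regions); M+1 spherical-simplex
sigma points with equal weights `1/(M+1)`, zero weighted mean and identity
weighted covariance, are generated from an orthonormal basis of the
hyperplane orthogonal to 1. The prediction step spreads parameters as
`theta_i = theta + L C^T s_i` where `C^T C = U^{-1}` is the Cholesky
square root — using `U^{-1}` itself, as a literal reading of the update
equations would suggest, mis-scales the spread; the square-root form is the
one consistent with the reduced-order square-root filter family this
algorithm belongs to. The correction step forms `L = theta* Dw sigma*'`,
`{HL} = Z* Dw sigma*'`, `U = Pw + {HL}' R^{-1} {HL}` and updates the
estimate with gain `L U^{-1} {HL}' R^{-1}`; sigma-point matrices are used
uncentred, which equals the centred form because the simplex mean is zero
(asserted numerically every iteration). On linear-Gaussian problems one
iteration reproduces the closed-form Kalman update to 1e-8 relative; this
is a test oracle, not a tuning.

**Observation covariance conventions.** The observation covariance is
diagonal with scale `sigma_Z` (mm). Two conventions are implemented:
`"sigma_squared"` (default; entries are variances `sigma_Z^2`, dimensionally
consistent) and `"sigma"` (entries are `sigma_Z` as written). The
distinction matters for convergence *dynamics*: with variances and small
`sigma_Z` the data term saturates the gain and convergence speed becomes
insensitive to `sigma_Z`, whereas the literal convention leaves the gain
partially damped across the 1e-1…1e-3 mm range, which is the regime in
which "smaller observation uncertainty converges faster" is observable.
The convergence-ordering study therefore uses `"sigma"`; the recovery
studies are insensitive to the choice.

**Uncertainty interval.** Reported as
`[2^(theta - sqrt(diag(U^-1))), 2^(theta + sqrt(diag(U^-1)))]`; the square
root makes the half-width a standard deviation on the log2 scale.

**The filter is a local estimator; initialization and restarts.** Because
the observation vector is *static* and replayed at every iteration, the
filter accumulates information as if each replay were new data: the
covariance contracts like 1/k and the sigma spread collapses after the
first few iterations. Two practical consequences, both visible in the
package's studies and handled by protocol design rather than by altering
the filter equations:

* From an initial guess several octaves from the truth the estimate stalls
  — early large-signal linearizations dominate the accumulated information.
  `roukf_initial_guess()` therefore scans a small logarithmic grid of
  homogeneous stiffness values (one forward-operator evaluation each) and
  starts the filter at the best fit, which lands within half a grid step of
  the best homogeneous model. The grid's lower end (1.2e5 Pa) is chosen so
  that the first-iteration sigma points stay above the static-equilibrium
  limit discussed below.
* For many parameters (the 12-region slice) even a well-initialized single
  sweep crawls along ill-conditioned directions. `run_roukf(restarts = k)`
  re-initializes the covariance at the current estimate between sweeps
  (an iterated-filter / Gauss–Newton strategy), optionally annealing the
  sigma spread (`restart_decay`) so late sweeps use an accurate local
  linearization. The 12-region support-sensitivity study uses 6 sweeps of 8
  iterations with decay 0.5.

**Feasibility limit.** An incompressible Neo-Hookean ring can carry only a
bounded internal pressure (of order `c ln(r_out/r_in)`): below roughly
4e4 Pa no static equilibrium exists for the coronary ring at 120 mmHg, and
the preload problem loses its solution slightly below that. A sigma point
softer than the limit makes the forward operator fail, which aborts the
filter iteration with a diagnostic — by design, since silently repairing a
sigma point would bias the statistics. Initial guesses (and the
initialization grid) must therefore keep `2^(theta0 - spread)` above the
limit; this is also why `theta0 = log2` of a very soft prior (e.g. 5e4 Pa)
is not a usable default for pressurized-ring protocols.

**Parallelism.** Sigma-point solves are independent tasks, as are the
per-phase forward solves after the shared preload solve; both are
dispatched through `parallel_map()`, which returns results in task order so
reductions are deterministic for any worker count. The third level of the
original design — mesh-partition parallelism inside one solve — is replaced
by a single-process sparse direct solve, which is the right tool at the
mesh sizes this package targets.

## Synthetic data

The generators define the study conditions. The ring is the idealized
coronary: inner radius 2 mm, outer 2.71 mm, preload 80 mmHg, forward
120 mmHg, 10% axial stretch, free external boundary, three tissue truths
(lipidic 1e5, cellular-fibrotic 5e5, calcified 4e6 Pa), observation
uncertainty 1e-3 mm and parameter uncertainty 2. In-silico observations are
the forward operator's own predictions at the true parameters — exact by
construction (optional seeded Gaussian noise is available but the reference
studies assume the uncertainty lives in the filter's `sigma_Z`, not in the
data). The 12-region slice plants a two-tissue contrast (fibrotic
background, calcified sextant blocks) on a sextants-by-two-layers partition
with the layer boundary at mid-thickness; the support study generates its
ground truth with a near-Dirichlet Robin support (`tau = 1e6`) anchored at
the free-boundary response, then assimilates with decreasing `tau`.

The IVUS-like sequences are a warped static speckle pattern (gamma
multiplicative texture on a smooth echogenicity map: dark lumen, bright
media) under a cardiac-frequency wall pulsation with an *asymmetric*
waveform — rapid systolic rise, slow diastolic decay, quiescent
end-diastole. The asymmetry is deliberate: frame-to-frame decorrelation
tracks motion *speed*, and a symmetric waveform would put its fundamental
at twice the heart rate, outside the physiological band. Ground-truth
end-diastolic frames are defined as the per-cycle minima of the actual
frame-to-frame motion, which is the operational definition gating can
recover. What the generator does **not** emulate: beam physics and
polar-domain reconstruction, guidewire and ringdown artifacts, through-plane
motion, and tissue-dependent speckle statistics. Passing the imaging tests
therefore shows the estimators are correct on their model class, not that
they are robust to every artifact of a real pullback; the registration and
gating stages exist precisely because real sequences violate the clean
model.

Problem sizes in the shipped studies are chosen for interactive runtimes on
one core: the ring mesh has ~1k nodes (112 x 8), the benchmark and
round-trip checks use 96 x 8, the convergence-ordering study 96 x 8, and
the 12-region slice ~0.6k nodes; filter budgets are 50 iterations (ring),
150 (ordering study), and 6 x 8 sweeps (slice). All are arguments, not
constants.

## Known limitations

* Isotropic Neo-Hookean tissue only; no fibers, no residual stress, no
  shear traction from blood flow, no fluid–structure interaction.
* The Robin stiffness `tau` is assumed known; estimating it alongside the
  material parameters is not implemented.
* The preload problem assumes the imaged configuration is a true
  equilibrium of the model class; segmentation error and out-of-model
  motion bias the recovered material configuration.
* The filter's covariance is a replay artifact rather than a calibrated
  posterior: the reported interval is a convergence diagnostic, tight when
  the observations are informative, and should not be read as a Bayesian
  credible interval for real data.
* Very soft tissue near the static-equilibrium pressure limit cannot be
  estimated at these loads — not a numerical shortcoming but a property of
  the physics; the paper trail for this is the feasibility discussion
  above.
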