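#' Vessel cross-section mesh
#'
#' A triangulated annular cross-section of a vessel wall with boundary tags
#' and per-element region labels.  Boundary edges on the lumen (`edges_w`)
#' are stored oriented counter-clockwise around the lumen so that the
#' follower-pressure assembly can determine the outward wall normal; edges on
#' the external surface are stored in `edges_e`.  `radial_nodes` lists lumen
#' nodes constrained to move radially only (rigid-motion control of the ring
#' experiments); `fixed_arc` lists external-boundary nodes pinned during the
#' preload problem when no radial control is present.
#'
#' @param nodes N x 2 numeric matrix of coordinates (mm)
#' @param tri E x 3 integer matrix of triangle connectivity (1-based, CCW)
#' @param region integer vector, one region id (1..M) per element
#' @param edges_w,edges_e boundary edges (2-column integer matrices)
#' @param radial_nodes,fixed_arc,untrusted integer node sets (may be empty)
#' @return an object of class `vessel_mesh`
#' @export
vessel_mesh <- function(nodes, tri, region, edges_w, edges_e,
                        radial_nodes = integer(), fixed_arc = integer(),
                        untrusted = integer()) {
  stopifnot(ncol(nodes) == 2, ncol(tri) == 3, length(region) == nrow(tri))
  stopifnot(all(tri >= 1), all(tri <= nrow(nodes)))
  if (any(region < 1)) stop("region labels must be >= 1")
  m <- structure(list(
    nodes = unname(as.matrix(nodes)),
    tri = unname(as.matrix(tri)),
    region = as.integer(region),
    n_regions = max(region),
    edges_w = unname(as.matrix(edges_w)),
    edges_e = unname(as.matrix(edges_e)),
    radial_nodes = as.integer(radial_nodes),
    fixed_arc = as.integer(fixed_arc),
    untrusted = as.integer(untrusted)
  ), class = "vessel_mesh")
  a <- mesh_areas(m)
  if (any(a <= 0)) stop("mesh contains inverted or degenerate elements")
  m
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf(
    "vessel_mesh: %d nodes, %d triangles, %d region(s), %d lumen / %d external edges\n",
    nrow(x$nodes), nrow(x$tri), x$n_regions, nrow(x$edges_w), nrow(x$edges_e)))
  invisible(x)
}

#' Signed element areas of a vessel mesh (mm^2)
#' @param mesh a `vessel_mesh`
#' @return numeric vector of length `nrow(mesh$tri)`
#' @export
mesh_areas <- function(mesh) {
  p <- mesh$nodes
  t <- mesh$tri
  x1 <- p[t[, 1], ]; x2 <- p[t[, 2], ]; x3 <- p[t[, 3], ]
  0.5 * ((x2[, 1] - x1[, 1]) * (x3[, 2] - x1[, 2]) -
         (x3[, 1] - x1[, 1]) * (x2[, 2] - x1[, 2]))
}

#' Minimum interior angle per element (degrees), a simple quality measure
#' @param mesh a `vessel_mesh`
#' @return numeric vector
#' @export
mesh_quality <- function(mesh) {
  p <- mesh$nodes
  t <- mesh$tri
  ang <- function(a, b, c) {
    u <- b - a; v <- c - a
    acos(pmin(1, pmax(-1, rowSums(u * v) / sqrt(rowSums(u^2) * rowSums(v^2)))))
  }
  a1 <- ang(p[t[, 1], , drop = FALSE], p[t[, 2], , drop = FALSE], p[t[, 3], , drop = FALSE])
  a2 <- ang(p[t[, 2], , drop = FALSE], p[t[, 3], , drop = FALSE], p[t[, 1], , drop = FALSE])
  a3 <- pi - a1 - a2
  pmin(a1, a2, a3) * 180 / pi
}

# structured annular mesh shared by the ring and slice generators.
# r_in_fun / r_out_fun map angle -> radius (mm).
annular_mesh <- function(r_in_fun, r_out_fun, n_theta, n_r,
                         n_sectors = 1L, n_layers = 1L, layer_split = 0.5,
                         sector_offset = 0, untrusted_arc = NULL) {
  stopifnot(n_r >= 2, n_theta >= 8)
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  nodes <- matrix(0, (n_r + 1) * n_theta, 2)
  for (i in 0:n_r) {
    s <- i / n_r
    r <- (1 - s) * r_in_fun(th) + s * r_out_fun(th)
    idx <- i * n_theta + seq_len(n_theta)
    nodes[idx, 1] <- r * cos(th)
    nodes[idx, 2] <- r * sin(th)
  }
  nid <- function(i, j) i * n_theta + ((j - 1L) %% n_theta) + 1L
  ntri <- 2L * n_r * n_theta
  tri <- matrix(0L, ntri, 3)
  region <- integer(ntri)
  k <- 0L
  for (i in 0:(n_r - 1)) {
    layer <- if (i / n_r < layer_split) 1L else 2L
    if (n_layers == 1L) layer <- 1L
    for (j in seq_len(n_theta)) {
      a <- nid(i, j); b <- nid(i, j + 1L)
      c <- nid(i + 1L, j + 1L); d <- nid(i + 1L, j)
      tri[k + 1L, ] <- c(a, d, c)
      tri[k + 2L, ] <- c(a, c, b)
      thm <- (th[j] + pi / n_theta - sector_offset) %% (2 * pi)
      sec <- 1L + (as.integer(floor(thm / (2 * pi / n_sectors))) %% n_sectors)
      region[k + 1:2] <- (layer - 1L) * n_sectors + sec
      k <- k + 2L
    }
  }
  edges_w <- cbind(nid(0, seq_len(n_theta)), nid(0, seq_len(n_theta) + 1L))
  edges_e <- cbind(nid(n_r, seq_len(n_theta)), nid(n_r, seq_len(n_theta) + 1L))
  # 4 equidistant lumen nodes for radial-only rigid-motion control
  jq <- 1L + round((0:3) * n_theta / 4)
  radial_nodes <- nid(0, jq)
  # external-boundary nodes within an arc of length 0.1 mm around theta = 0
  r_out0 <- r_out_fun(0)
  dth_arc <- 0.1 / r_out0
  on_arc <- which(abs(((th + pi) %% (2 * pi)) - pi) <= pmax(dth_arc / 2, 1.01 * 2 * pi / n_theta))
  fixed_arc <- nid(n_r, on_arc)[seq_len(max(2L, sum(abs(((th + pi) %% (2 * pi)) - pi) <= dth_arc / 2)))]
  fixed_arc <- fixed_arc[!is.na(fixed_arc)]
  untrusted <- integer()
  if (!is.null(untrusted_arc)) {
    inarc <- th >= untrusted_arc[1] & th <= untrusted_arc[2]
    untrusted <- nid(n_r, which(inarc))
  }
  vessel_mesh(nodes, tri, region, edges_w, edges_e,
              radial_nodes = radial_nodes, fixed_arc = fixed_arc,
              untrusted = untrusted)
}

#' Generate an idealized ring (annulus) mesh
#'
#' Builds the idealized coronary ring used in the in-silico experiments:
#' a homogeneous annulus with inner radius 2 mm and outer radius 2.71 mm,
#' tagged with lumen/external boundary edges and 4 equidistant lumen nodes
#' flagged for radial-only motion (rigid-motion control).
#'
#' @param r_in,r_out inner and outer radius (mm)
#' @param element_size target element size (mm); determines the resolution
#' @param n_theta,n_r optional explicit resolution (override `element_size`)
#' @return a `vessel_mesh` with a single region
#' @export
gen_ring_mesh <- function(r_in = 2, r_out = 2.71, element_size = 0.1,
                          n_theta = NULL, n_r = NULL) {
  stopifnot(r_out > r_in, r_in > 0)
  thick <- r_out - r_in
  if (is.null(n_r)) n_r <- round(thick / element_size)
  if (n_r < 2) stop("element size too coarse: fewer than 2 elements through the wall")
  if (is.null(n_theta)) n_theta <- max(16L, 4L * round(pi * (r_in + r_out) / 2 / element_size / 2))
  annular_mesh(function(th) rep(r_in, length(th)),
               function(th) rep(r_out, length(th)),
               n_theta = n_theta, n_r = n_r)
}

#' Generate a partitioned vessel-slice mesh
#'
#' Builds an annular (optionally eccentric) cross-section partitioned into
#' `n_sectors x n_layers` material regions, emulating the sextant partitions
#' used for regional stiffness estimation.  An optional external-boundary arc
#' can be tagged as "untrusted" (e.g., shadowed by the guidewire).
#'
#' @param n_sectors,n_layers partition of the annulus (regions = sectors x layers)
#' @param r_in,r_out mean inner/outer radius (mm)
#' @param eccentricity relative first-harmonic modulation of the lumen contour
#' @param layer_split relative through-wall position of the layer boundary
#' @param element_size target element size (mm)
#' @param n_theta,n_r optional explicit resolution
#' @param untrusted_arc optional angular interval (radians, length 2) of the
#'   external boundary to tag as untrusted
#' @return a `vessel_mesh` with `n_sectors * n_layers` regions
#' @export
gen_partitioned_slice <- function(n_sectors = 6, n_layers = 2,
                                  r_in = 2, r_out = 2.71,
                                  eccentricity = 0, layer_split = 0.5,
                                  element_size = 0.1,
                                  n_theta = NULL, n_r = NULL,
                                  untrusted_arc = NULL) {
  stopifnot(r_out > r_in, n_sectors >= 1, n_layers %in% c(1L, 2L))
  if (abs(eccentricity) * r_in >= (r_out - r_in))
    stop("degenerate contour: lumen eccentricity exceeds wall thickness")
  thick <- r_out - r_in
  if (is.null(n_r)) n_r <- max(2L, round(thick / element_size))
  if (is.null(n_theta)) {
    n_theta <- max(16L, 4L * round(pi * (r_in + r_out) / 2 / element_size / 2))
    # keep sector boundaries aligned with the grid
    n_theta <- as.integer(n_sectors * ceiling(n_theta / n_sectors))
    n_theta <- as.integer(4L * ceiling(n_theta / 4L))
  }
  m <- annular_mesh(function(th) r_in * (1 + eccentricity * cos(th)),
                    function(th) rep(r_out, length(th)),
                    n_theta = n_theta, n_r = n_r,
                    n_sectors = n_sectors, n_layers = n_layers,
                    layer_split = layer_split, untrusted_arc = untrusted_arc)
  stopifnot(m$n_regions == n_sectors * n_layers)
  m
}
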