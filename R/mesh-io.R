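#' Write a vessel mesh (optionally with a solution) as ASCII VTK .vtu
#'
#' Triangles carry cell data `region`; boundary edges are written as VTK
#' line cells with cell data `boundary` (W = 1, E = 2).  When a
#' `mechanical_state` is supplied, nodal `displacement` (mm) and `pressure`
#' (Pa) point data and per-element `cauchy_stress` components (Pa) are
#' included.
#'
#' @param mesh a `vessel_mesh`
#' @param path output file (.vtu)
#' @param state optional `mechanical_state`
#' @param mat,load required with `state` to evaluate the Cauchy stress
#' @export
write_mesh_vtu <- function(mesh, path, state = NULL, mat = NULL, load = NULL) {
  np <- nrow(mesh$nodes)
  tri <- mesh$tri; nt <- nrow(tri)
  edges <- rbind(mesh$edges_w, mesh$edges_e)
  bnd <- c(rep(1L, nrow(mesh$edges_w)), rep(2L, nrow(mesh$edges_e)))
  nc <- nt + nrow(edges)
  con <- c(t(tri) - 1L)
  cone <- c(t(edges) - 1L)
  offs <- c(seq_len(nt) * 3L, nt * 3L + seq_len(nrow(edges)) * 2L)
  types <- c(rep(5L, nt), rep(3L, nrow(edges)))
  num <- function(x, fmt = "%.10g") paste(sprintf(fmt, x), collapse = " ")
  lines <- c(
    '<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '<UnstructuredGrid>',
    sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', np, nc),
    '<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">',
    num(as.vector(t(cbind(mesh$nodes, 0)))),
    '</DataArray></Points>',
    '<Cells>',
    '<DataArray type="Int32" Name="connectivity" format="ascii">',
    num(c(con, cone), "%d"),
    '</DataArray>',
    '<DataArray type="Int32" Name="offsets" format="ascii">', num(offs, "%d"),
    '</DataArray>',
    '<DataArray type="Int32" Name="types" format="ascii">', num(types, "%d"),
    '</DataArray>',
    '</Cells>')
  cd <- c('<CellData>',
          '<DataArray type="Int32" Name="region" format="ascii">',
          num(c(mesh$region, rep(0L, nrow(edges))), "%d"),
          '</DataArray>',
          '<DataArray type="Int32" Name="boundary" format="ascii">',
          num(c(rep(0L, nt), bnd), "%d"),
          '</DataArray>')
  pd <- character()
  if (!is.null(state)) {
    pd <- c('<PointData>',
            '<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">',
            num(as.vector(t(cbind(state$u, 0)))),
            '</DataArray>',
            '<DataArray type="Float64" Name="pressure" format="ascii">',
            num(state$lambda),
            '</DataArray>',
            '</PointData>')
    if (!is.null(mat) && !is.null(load)) {
      sig <- element_cauchy(mesh, state, mat, load)
      cd <- c(cd,
              '<DataArray type="Float64" Name="cauchy_stress" NumberOfComponents="4" format="ascii">',
              num(as.vector(t(rbind(sig, matrix(0, nrow(edges), 4))))),
              '</DataArray>')
    }
  }
  lines <- c(lines, pd, cd, '</CellData>', '</Piece>',
             '</UnstructuredGrid>', '</VTKFile>')
  writeLines(lines, path)
  invisible(path)
}

#' Read a vessel mesh from an ASCII .vtu written by [write_mesh_vtu()]
#' @param path input file
#' @return a `vessel_mesh`
#' @export
read_mesh_vtu <- function(path) {
  doc <- xml2::read_xml(path)
  getarr <- function(name) {
    nd <- xml2::xml_find_first(doc, sprintf(".//DataArray[@Name='%s']", name))
    as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
  }
  pts <- xml2::xml_find_first(doc, ".//Points/DataArray")
  xyz <- matrix(as.numeric(strsplit(trimws(xml2::xml_text(pts)), "\\s+")[[1]]),
                ncol = 3, byrow = TRUE)
  con <- as.integer(getarr("connectivity"))
  types <- as.integer(getarr("types"))
  region <- as.integer(getarr("region"))
  boundary <- as.integer(getarr("boundary"))
  nt <- sum(types == 5L)
  tri <- matrix(con[1:(3 * nt)] + 1L, ncol = 3, byrow = TRUE)
  econ <- matrix(con[(3 * nt + 1):length(con)] + 1L, ncol = 2, byrow = TRUE)
  ebnd <- boundary[types == 3L]
  vessel_mesh(xyz[, 1:2], tri, region[types == 5L],
              edges_w = econ[ebnd == 1L, , drop = FALSE],
              edges_e = econ[ebnd == 2L, , drop = FALSE])
}

#' Write a vessel mesh in Gmsh v2.2 ASCII format
#'
#' Triangles get their region id as physical tag; boundary edges get
#' physical tags 101 (lumen, W) and 102 (external, E).
#'
#' @param mesh a `vessel_mesh`
#' @param path output file (.msh)
#' @export
write_mesh_msh <- function(mesh, path) {
  np <- nrow(mesh$nodes)
  ew <- mesh$edges_w; ee <- mesh$edges_e; tri <- mesh$tri
  ne <- nrow(ew) + nrow(ee) + nrow(tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(np)), con)
  writeLines(sprintf("%d %.10g %.10g 0", seq_len(np),
                     mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(ne)), con)
  k <- 0L
  out <- character(0)
  if (nrow(ew)) out <- c(out, sprintf("%d 1 2 101 101 %d %d",
                                      k + seq_len(nrow(ew)), ew[, 1], ew[, 2]))
  k <- k + nrow(ew)
  if (nrow(ee)) out <- c(out, sprintf("%d 1 2 102 102 %d %d",
                                      k + seq_len(nrow(ee)), ee[, 1], ee[, 2]))
  k <- k + nrow(ee)
  out <- c(out, sprintf("%d 2 2 %d %d %d %d %d", k + seq_len(nrow(tri)),
                        mesh$region, mesh$region,
                        tri[, 1], tri[, 2], tri[, 3]))
  writeLines(out, con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh v2.2 ASCII mesh
#'
#' Expects 2-node line elements tagged 101 (lumen) / 102 (external) and
#' 3-node triangles whose first physical tag is the region id.
#'
#' @param path input .msh file
#' @return a `vessel_mesh`
#' @export
read_mesh_msh <- function(path) {
  ln <- readLines(path)
  i_n <- which(ln == "$Nodes")
  nn <- as.integer(ln[i_n + 1])
  nd <- read.table(text = ln[(i_n + 2):(i_n + 1 + nn)])
  i_e <- which(ln == "$Elements")
  ne <- as.integer(ln[i_e + 1])
  tri <- list(); region <- integer(); ew <- list(); ee <- list()
  for (l in ln[(i_e + 2):(i_e + 1 + ne)]) {
    v <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    type <- v[2]; ntags <- v[3]
    tags <- v[4:(3 + ntags)]
    conn <- v[(4 + ntags):length(v)]
    if (type == 2L) { tri[[length(tri) + 1]] <- conn; region <- c(region, tags[1]) }
    else if (type == 1L && tags[1] == 101L) ew[[length(ew) + 1]] <- conn
    else if (type == 1L && tags[1] == 102L) ee[[length(ee) + 1]] <- conn
  }
  vessel_mesh(as.matrix(nd[order(nd[, 1]), 2:3]),
              do.call(rbind, tri), region,
              edges_w = do.call(rbind, ew), edges_e = do.call(rbind, ee))
}

#' Write the final assimilation state as a .vtu with per-node discrepancy
#'
#' Exports the imaged mesh with point data `predicted_displacement` (the
#' filter's final prediction for the first cardiac phase, mm) and `eps_z`
#' (the per-node discrepancy vector Z - Zhat, mm).
#'
#' @param mesh imaged-configuration `vessel_mesh`
#' @param Z,Zhat observed and predicted observation vectors (first phase,
#'   node-major x/y stacking)
#' @param path output .vtu file
#' @export
write_assimilation_vtu <- function(mesh, Z, Zhat, path) {
  N <- nrow(mesh$nodes)
  pred <- matrix(Zhat[seq_len(2 * N)], N, 2, byrow = TRUE)
  eps <- matrix((Z - Zhat)[seq_len(2 * N)], N, 2, byrow = TRUE)
  write_mesh_vtu(mesh, path,
                 state = list(u = pred, lambda = rowSums(eps^2)^0.5,
                              mode = "forward"))
  # rename the scalar field to its meaning
  txt <- readLines(path)
  txt <- sub('Name="pressure"', 'Name="eps_z_norm"', txt, fixed = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' Per-element Cauchy stress of a converged state
#'
#' Evaluates, at each element centroid, the total Cauchy stress of the
#' mixed formulation (isochoric push-forward minus the spherical multiplier
#' part), returning the in-plane components and the out-of-plane normal
#' stress.
#'
#' @param mesh the mesh the state was solved on
#' @param state a `mechanical_state`
#' @param mat per-region stiffness (Pa)
#' @param load the `load_case` used (provides the out-of-plane stretch)
#' @return matrix with columns sxx, syy, sxy, szz (Pa)
#' @export
element_cauchy <- function(mesh, state, mat, load) {
  mode <- if (state$mode == "forward") 0L else 1L
  lamz <- load$lambda_z
  nt <- nrow(mesh$tri)
  out <- matrix(0, nt, 4)
  colnames(out) <- c("sxx", "syy", "sxy", "szz")
  for (e in seq_len(nt)) {
    nd <- mesh$tri[e, ]
    X <- mesh$nodes[nd, ]
    Jx <- cbind(X[2, ] - X[1, ], X[3, ] - X[1, ])
    dN <- t(solve(Jx)) %*% t(matrix(c(-1, -1, 1, 0, 0, 1), 3, 2, byrow = TRUE))
    Gu <- state$u[nd, ]
    G <- t(Gu) %*% t(dN)
    F2 <- if (mode == 0L) diag(2) + G else solve(diag(2) - G)
    F <- rbind(cbind(F2, 0), c(0, 0, lamz))
    c_e <- mat[mesh$region[e]]
    S <- neo_hookean_pk2(F, c_e)
    lam_c <- mean(state$lambda[nd])
    sig <- push_forward_cauchy(F, S, lam_c)
    out[e, ] <- c(sig[1, 1], sig[2, 2], sig[1, 2], sig[3, 3])
  }
  out
}
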