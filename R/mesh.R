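# Triangulated unit sphere and its Laplace-Beltrami operators.

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

subdivide_once <- function(vertices, faces) {
  nv <- nrow(vertices)
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  uk <- unique(key)
  idx <- match(key, uk)
  ue <- e[!duplicated(key), , drop = FALSE]
  mid <- (vertices[ue[, 1], ] + vertices[ue[, 2], ]) / 2
  mid <- mid / sqrt(rowSums(mid^2))
  mids <- nv + idx  # midpoint vertex index per (face, edge) entry
  nf <- nrow(faces)
  m12 <- mids[seq_len(nf)]
  m23 <- mids[nf + seq_len(nf)]
  m31 <- mids[2 * nf + seq_len(nf)]
  new_faces <- rbind(
    cbind(faces[, 1], m12, m31),
    cbind(faces[, 2], m23, m12),
    cbind(faces[, 3], m31, m23),
    cbind(m12, m23, m31))
  list(vertices = rbind(vertices, mid), faces = new_faces)
}

#' Build a triangulated unit sphere (icosphere)
#'
#' Starts from the regular icosahedron and applies `subdivisions` rounds of
#' edge-midpoint subdivision, projecting every new vertex back onto the
#' unit sphere, giving `10 * 4^level + 2` vertices. The mesh carries the
#' assembled finite-element operators: the cotangent-weight stiffness
#' matrix (weak Laplace-Beltrami) and the barycentrically lumped mass
#' matrix, plus an edge list for adjacency queries.
#'
#' @param subdivisions refinement level (0 = icosahedron; at most 8).
#' @return An object of class `cdc42_mesh`: list with `vertices` (n x 3,
#'   unit norm), `faces` (m x 3 indices), `areas` (lumped vertex areas,
#'   summing to the discrete surface area), `K` (sparse symmetric stiffness,
#'   rows summing to zero), `M` (diagonal mass), `edges` (2-column matrix),
#'   `n_vertices`, `surface_area`, and `volume = 4 * pi / 3` (the exact
#'   unit-ball volume used by the nonlocal functional).
#' @examples
#' mesh <- build_icosphere(2)
#' mesh$n_vertices  # 10 * 4^2 + 2 = 162
#' @export
build_icosphere <- function(subdivisions) {
  stopifnot(length(subdivisions) == 1, subdivisions >= 0)
  if (subdivisions > 8) {
    stop("subdivision level > 8 refused (over 650k vertices)", call. = FALSE)
  }
  geo <- icosahedron()
  for (i in seq_len(subdivisions)) {
    geo <- subdivide_once(geo$vertices, geo$faces)
  }
  ops <- assemble_laplace_beltrami(geo$vertices, geo$faces)
  e <- rbind(geo$faces[, c(1, 2)], geo$faces[, c(2, 3)], geo$faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(e), , drop = FALSE]
  structure(
    list(vertices = geo$vertices, faces = geo$faces, areas = ops$areas,
         K = ops$K, M = ops$M, edges = e,
         n_vertices = nrow(geo$vertices),
         surface_area = sum(ops$areas), volume = 4 * pi / 3,
         subdivisions = subdivisions),
    class = "cdc42_mesh")
}

#' @export
print.cdc42_mesh <- function(x, ...) {
  cat(sprintf(
    "Icosphere mesh, level %d: %d vertices, %d faces, area %.5f (4*pi = %.5f)\n",
    x$subdivisions, x$n_vertices, nrow(x$faces), x$surface_area, 4 * pi))
  invisible(x)
}

#' Assemble Laplace-Beltrami stiffness and lumped mass operators
#'
#' Standard linear-FEM cotangent discretisation on a triangle mesh: for the
#' triangle corner opposite edge (i, j) with angle `alpha`, the edge weight
#' `cot(alpha) / 2` accumulates into `-K[i, j]`, and the diagonal is set to
#' minus the off-diagonal row sum, so constants are exactly in the kernel.
#' The mass matrix is lumped barycentrically (one third of each incident
#' triangle area per vertex).
#'
#' @param vertices n x 3 coordinates.
#' @param faces m x 3 vertex indices.
#' @return List with sparse symmetric `K` (positive semi-definite), diagonal
#'   `M`, and the lumped `areas` vector.
#' @export
assemble_laplace_beltrami <- function(vertices, faces) {
  p1 <- vertices[faces[, 1], , drop = FALSE]
  p2 <- vertices[faces[, 2], , drop = FALSE]
  p3 <- vertices[faces[, 3], , drop = FALSE]
  cross3 <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  }
  nrm <- cross3(p2 - p1, p3 - p1)
  area2 <- sqrt(rowSums(nrm^2))  # twice the triangle area
  if (any(area2 < 1e-14)) {
    stop("degenerate triangle(s) in mesh: ",
         paste(which(area2 < 1e-14), collapse = ", "), call. = FALSE)
  }
  # cot of the angle at corner c between edges (a - c) and (b - c)
  cot_at <- function(a, b, c) {
    e1 <- a - c
    e2 <- b - c
    rowSums(e1 * e2) / sqrt(rowSums(cross3(e1, e2)^2))
  }
  cot1 <- cot_at(p2, p3, p1)  # opposite edge (2,3)
  cot2 <- cot_at(p3, p1, p2)  # opposite edge (3,1)
  cot3 <- cot_at(p1, p2, p3)  # opposite edge (1,2)
  ii <- c(faces[, 2], faces[, 3], faces[, 1])
  jj <- c(faces[, 3], faces[, 1], faces[, 2])
  ww <- c(cot1, cot2, cot3) / 2
  n <- nrow(vertices)
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(ww, ww),
                            dims = c(n, n))
  K <- Matrix::Diagonal(n, Matrix::rowSums(W)) - W
  areas <- as.vector(Matrix::sparseMatrix(
    i = as.vector(faces), j = rep(1L, 3 * nrow(faces)),
    x = rep(area2 / 2 / 3, 3), dims = c(n, 1)))
  list(K = Matrix::forceSymmetric(K), M = Matrix::Diagonal(n, areas),
       areas = areas)
}
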