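#' Triangulated surface meshes
#'
#' Minimal triangle-mesh container used for semilandmark projection and for
#' synthetic fixtures: vertices (V x 3), faces (F x 3, 1-based vertex indices)
#' and optional per-vertex unit normals.
#'
#' @param vertices V x 3 numeric matrix.
#' @param faces F x 3 integer matrix of vertex indices.
#' @param normals optional V x 3 matrix of vertex normals (computed from the
#'   faces when absent and needed).
#' @return object of class \code{"tri_mesh"}.
#' @export
tri_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (any(faces < 1L) || any(faces > nrow(vertices))) stop("face index out of range")
  a <- triangle_areas(vertices, faces)
  if (any(a <= 0)) stop("degenerate (zero-area) faces")
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

triangle_areas <- function(vertices, faces) {
  e1 <- vertices[faces[, 2L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  e2 <- vertices[faces[, 3L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mesh_area <- function(mesh) sum(triangle_areas(mesh$vertices, mesh$faces))

#' Per-vertex outward normals (area-weighted face-normal average)
#' @param mesh a \code{tri_mesh}.
#' @return V x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  if (!is.null(mesh$normals)) return(mesh$normals)
  V <- mesh$vertices; Fc <- mesh$faces
  e1 <- V[Fc[, 2L], , drop = FALSE] - V[Fc[, 1L], , drop = FALSE]
  e2 <- V[Fc[, 3L], , drop = FALSE] - V[Fc[, 1L], , drop = FALSE]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  N <- matrix(0, nrow(V), 3L)
  for (j in 1:3) {
    N[, 1] <- N[, 1] + tabulate2(Fc[, j], fn[, 1], nrow(V))
    N[, 2] <- N[, 2] + tabulate2(Fc[, j], fn[, 2], nrow(V))
    N[, 3] <- N[, 3] + tabulate2(Fc[, j], fn[, 3], nrow(V))
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

## sum w into nbins accumulator bins indexed by idx (empty bins stay 0)
tabulate2 <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(w, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  unique(t(apply(e, 1L, sort)))
}

## icosahedron + edge-midpoint subdivision, vertices on the unit sphere
icosphere <- function(subdivisions = 2L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    midcache <- new.env(hash = TRUE)
    nv <- nrow(v)
    vlist <- list(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- midcache[[key]]
      if (!is.null(hit)) return(hit)
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      vlist[[length(vlist) + 1L]] <<- m
      midcache[[key]] <- nv
      nv
    }
    newf <- matrix(0L, 0L, 3L)
    fl <- vector("list", nrow(f))
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      fl[[t]] <- rbind(c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- do.call(rbind, fl)
  }
  list(vertices = v, faces = f)
}

#' Synthetic fixture meshes
#'
#' Watertight genus-0 meshes built by subdividing an icosahedron and mapping
#' the sphere to an ellipsoid or superellipsoid; stand-ins for bone surfaces
#' in tests and simulations.
#'
#' @param kind "ellipsoid" or "superellipsoid".
#' @param semi_axes positive length-3 vector (a, b, c).
#' @param subdivisions icosphere subdivision level (vertex count grows ~4x per
#'   level; level 3 gives 642 vertices).
#' @param exponent superellipsoid shape exponent (2 = ellipsoid, larger =
#'   boxier); ignored for kind = "ellipsoid".
#' @return a \code{tri_mesh}.
#' @export
make_mesh <- function(kind = c("ellipsoid", "superellipsoid"),
                      semi_axes = c(1, 1, 1), subdivisions = 3L, exponent = 4) {
  kind <- match.arg(kind)
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) stop("semi_axes must be 3 positive values")
  ico <- icosphere(subdivisions)
  v <- ico$vertices
  if (kind == "superellipsoid") {
    ## radial rescale of the unit sphere so |x/a|^e + |y/b|^e + |z/c|^e = 1
    p <- sweep(v, 2L, semi_axes, "/")
    rad <- rowSums(abs(p)^exponent)^(1 / exponent)
    v <- v / rad
  } else {
    v <- sweep(v, 2L, semi_axes, "*")
  }
  tri_mesh(v, ico$faces)
}
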