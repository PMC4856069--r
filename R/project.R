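#' Project points onto a triangle mesh
#'
#' Exact nearest point on the triangle set for each query point, handling the
#' vertex / edge / face-interior cases of every triangle (Ericson's
#' closest-point-on-triangle construction), evaluated over all triangles.
#'
#' @param points m x 3 matrix of query points.
#' @param mesh a \code{tri_mesh}.
#' @return list with \code{points} (m x 3 nearest surface points),
#'   \code{distance} (m Euclidean distances) and \code{face} (index of the
#'   nearest triangle).
#' @export
project_to_mesh <- function(points, mesh) {
  points <- rbind(points)
  stopifnot(ncol(points) == 3L, nrow(mesh$faces) >= 1L)
  V <- mesh$vertices; Fc <- mesh$faces
  A <- V[Fc[, 1L], , drop = FALSE]
  B <- V[Fc[, 2L], , drop = FALSE]
  C <- V[Fc[, 3L], , drop = FALSE]
  ab <- B - A; ac <- C - A; bc <- C - B
  m <- nrow(points)
  out_p <- matrix(0, m, 3L); out_d <- numeric(m); out_f <- integer(m)
  dot3 <- function(x, y) x[, 1] * y[, 1] + x[, 2] * y[, 2] + x[, 3] * y[, 3]
  nf <- nrow(Fc)
  for (i in seq_len(m)) {
    p <- matrix(points[i, ], nf, 3L, byrow = TRUE)
    ap <- p - A; bp <- p - B; cp <- p - C
    d1 <- dot3(ab, ap); d2 <- dot3(ac, ap)
    d3 <- dot3(ab, bp); d4 <- dot3(ac, bp)
    d5 <- dot3(ab, cp); d6 <- dot3(ac, cp)
    vc <- d1 * d4 - d3 * d2
    vb <- d5 * d2 - d1 * d6
    va <- d3 * d6 - d5 * d4
    denom <- va + vb + vc
    v <- vb / denom; w <- vc / denom
    cand <- A + v * ab + w * ac            # face interior (default)
    done <- rep(FALSE, nf)
    set <- function(mask, value) {
      mask <- mask & !done
      cand[mask, ] <<- value[mask, , drop = FALSE]
      done[mask] <<- TRUE
    }
    set(d1 <= 0 & d2 <= 0, A)              # vertex A
    set(d3 >= 0 & d4 <= d3, B)             # vertex B
    set(d6 >= 0 & d5 <= d6, C)             # vertex C
    t_ab <- d1 / (d1 - d3)
    set(vc <= 0 & d1 >= 0 & d3 <= 0, A + ifelse(is.finite(t_ab), t_ab, 0) * ab)
    t_ac <- d2 / (d2 - d6)
    set(vb <= 0 & d2 >= 0 & d6 <= 0, A + ifelse(is.finite(t_ac), t_ac, 0) * ac)
    t_bc <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    set(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0,
        B + ifelse(is.finite(t_bc), t_bc, 0) * bc)
    dist2 <- rowSums((cand - p)^2)
    j <- which.min(dist2)
    out_p[i, ] <- cand[j, ]
    out_d[i] <- sqrt(dist2[j])
    out_f[i] <- j
  }
  list(points = out_p, distance = out_d, face = out_f)
}

## area-weighted random points on a mesh surface
sample_surface <- function(mesh, n) {
  areas <- triangle_areas(mesh$vertices, mesh$faces)
  tri <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
  u <- stats::runif(n); v <- stats::runif(n)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  A <- mesh$vertices[mesh$faces[tri, 1L], , drop = FALSE]
  B <- mesh$vertices[mesh$faces[tri, 2L], , drop = FALSE]
  C <- mesh$vertices[mesh$faces[tri, 3L], , drop = FALSE]
  A + u * (B - A) + v * (C - A)
}

#' Poisson-disk semilandmark template on a mesh surface
#'
#' Draws uniformly distributed surface points with a minimum pairwise distance
#' (dart throwing over area-weighted candidates), removes points falling in
#' exclusion regions (e.g. tooth areas), and attaches the fixed landmarks to
#' form a semilandmark template. When \code{target_count} is given, the radius
#' is adjusted iteratively until the retained count is within ~15% of it.
#'
#' @param mesh a watertight \code{tri_mesh}.
#' @param fixed k0 x 3 matrix of fixed (expert) landmarks, back-projected onto
#'   the mesh.
#' @param target_count desired number of semilandmarks (used to pick a radius).
#' @param radius minimum pairwise distance; exactly one of
#'   \code{target_count}/\code{radius} is required.
#' @param exclusion_regions optional list of functions; a candidate point (as a
#'   length-3 vector) is dropped if any returns TRUE.
#' @param seed integer seed for the candidate stream.
#' @param oversample candidate points drawn per requested semilandmark.
#' @return object of class \code{"slm_template"}: list with
#'   \code{reference_config} (a \code{landmark_sample} of fixed + sliding
#'   points), \code{reference_mesh}, \code{radius}.
#' @export
poisson_disk_template <- function(mesh, fixed, target_count = NULL, radius = NULL,
                                  exclusion_regions = NULL, seed = 1L,
                                  oversample = 40L) {
  if (is.null(target_count) == is.null(radius))
    stop("give exactly one of target_count or radius")
  fixed <- as.matrix(fixed)
  fixed_on <- project_to_mesh(fixed, mesh)$points
  area <- mesh_area(mesh)
  if (!is.null(target_count)) {
    ## hexagonal-packing heuristic, then adjust by the realized count
    r <- sqrt(area / (target_count * pi)) * 1.25
  } else r <- radius
  pts <- NULL
  for (iter in 1:8) {
    n_cand <- max(200L, oversample * if (!is.null(target_count)) target_count else
      ceiling(area / (pi * (r / 2)^2)))
    set.seed(seed + iter - 1L)
    cand <- sample_surface(mesh, n_cand)
    if (!is.null(exclusion_regions)) {
      keep <- rep(TRUE, nrow(cand))
      for (f in exclusion_regions)
        keep <- keep & !apply(cand, 1L, function(p) isTRUE(f(p)))
      cand <- cand[keep, , drop = FALSE]
    }
    pts <- dart_throw(cand, r)
    if (is.null(target_count)) break
    ratio <- nrow(pts) / target_count
    if (abs(ratio - 1) <= 0.1) break
    r <- r * sqrt(ratio)
  }
  if (!is.null(target_count) && abs(nrow(pts) / target_count - 1) > 0.15)
    warning(sprintf("poisson-disk sampling reached %d points for target %d",
                    nrow(pts), target_count))
  k0 <- nrow(fixed_on); ks <- nrow(pts)
  config <- landmark_sample(rbind(fixed_on, pts),
                            labels = c(paste0("LM", seq_len(k0)), paste0("SL", seq_len(ks))),
                            fixed = c(rep(TRUE, k0), rep(FALSE, ks)))
  structure(list(reference_config = config, reference_mesh = mesh, radius = r),
            class = "slm_template")
}

## greedy dart throwing: accept candidates in order if >= r from all accepted
dart_throw <- function(cand, r) {
  n <- nrow(cand)
  acc <- matrix(NA_real_, n, 3L)
  na <- 0L
  r2 <- r * r
  for (i in seq_len(n)) {
    p <- cand[i, ]
    if (na > 0L) {
      d2 <- (acc[seq_len(na), 1L] - p[1L])^2 + (acc[seq_len(na), 2L] - p[2L])^2 +
        (acc[seq_len(na), 3L] - p[3L])^2
      if (any(d2 < r2)) next
    }
    na <- na + 1L
    acc[na, ] <- p
  }
  acc[seq_len(na), , drop = FALSE]
}
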