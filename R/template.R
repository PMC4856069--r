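#' Transfer a semilandmark template onto a new specimen
#'
#' Warps the template semilandmarks by the thin-plate spline taking the
#' template's fixed landmarks onto the target's fixed landmarks, then projects
#' every warped semilandmark onto the target mesh (shortest Euclidean
#' distance). The fixed landmarks themselves are also back-projected onto the
#' mesh so the whole configuration lives on the surface.
#'
#' @param template an \code{slm_template} from \code{\link{poisson_disk_template}}.
#' @param target_fixed k0 x 3 matrix of the target specimen's fixed landmarks,
#'   in the template's fixed-landmark order.
#' @param target_mesh the target specimen's \code{tri_mesh}.
#' @return a \code{landmark_sample} (single specimen) with the template's
#'   labels and fixed mask.
#' @export
transfer_template <- function(template, target_fixed, target_mesh) {
  ref <- template$reference_config
  fixed_mask <- attr(ref, "fixed")
  ref_cfg <- ref[, , 1L]
  target_fixed <- as.matrix(target_fixed)
  if (nrow(target_fixed) != sum(fixed_mask))
    stop("target_fixed must match the template's fixed landmarks 1:1")
  warp <- tps_fit(ref_cfg[fixed_mask, , drop = FALSE], target_fixed)
  semis <- tps_deform(warp, ref_cfg[!fixed_mask, , drop = FALSE])
  semis_on <- project_to_mesh(semis, target_mesh)$points
  fixed_on <- project_to_mesh(target_fixed, target_mesh)$points
  out <- matrix(0, nrow(ref_cfg), 3L)
  out[fixed_mask, ] <- fixed_on
  out[!fixed_mask, ] <- semis_on
  landmark_sample(out, labels = attr(ref, "labels"), fixed = fixed_mask)
}

## tangent plane basis (two orthonormal 3-vectors) from a unit normal
tangent_basis <- function(n) {
  a <- if (abs(n[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- a - sum(a * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3], n[1] * u[2] - n[2] * u[1])
  cbind(u, v)
}

#' Slide semilandmarks to minimize bending energy
#'
#' Relaxes the semilandmarks of a target configuration against a reference by
#' minimizing the thin-plate-spline bending energy of the reference-to-target
#' deformation, with each semilandmark constrained to the tangent plane of the
#' target surface at its current position (fixed landmarks never move). Each
#' iteration solves the constrained generalized least-squares problem in
#' closed form, then re-projects the slid points onto the mesh. The bending
#' energy before re-projection is non-increasing across iterations.
#'
#' @param reference \code{landmark_sample} (or k x 3 matrix) reference
#'   configuration, usually the template / mean shape; supplies the bending
#'   energy form.
#' @param target single-specimen \code{landmark_sample} sharing labels and
#'   fixed mask with the reference.
#' @param target_mesh \code{tri_mesh} carrying the target surface.
#' @param iters sliding iterations (slide, re-project).
#' @param ridge small diagonal stabilizer for the tangent normal equations.
#' @return list with \code{config} (slid \code{landmark_sample}),
#'   \code{energy} (bending energy per iteration, after sliding but before
#'   re-projection), \code{energy_in} (energy entering each iteration) and
#'   \code{energy0} (energy before any sliding).
#' @export
slide_semilandmarks <- function(reference, target, target_mesh, iters = 3L,
                                ridge = 1e-10) {
  ref_cfg <- if (inherits(reference, "landmark_sample")) reference[, , 1L] else as.matrix(reference)
  fixed_mask <- if (inherits(target, "landmark_sample")) attr(target, "fixed")
  else rep(TRUE, nrow(ref_cfg))
  tgt <- if (inherits(target, "landmark_sample")) target[, , 1L] else as.matrix(target)
  k <- nrow(ref_cfg)
  slide_idx <- which(!fixed_mask)
  Lb <- bending_energy_matrix(ref_cfg)
  e0 <- bending_energy(Lb, tgt)
  if (length(slide_idx) == 0L)
    return(list(config = target, energy = numeric(0), energy0 = e0))
  vnorm <- vertex_normals(target_mesh)
  energies <- numeric(0); energies_in <- numeric(0)
  for (it in seq_len(iters)) {
    energies_in <- c(energies_in, bending_energy(Lb, tgt))
    ## tangent directions from the mesh normal at the nearest surface point
    pr <- project_to_mesh(tgt[slide_idx, , drop = FALSE], target_mesh)
    nearest_vertex <- apply(pr$points, 1L, function(p) {
      which.min(colSums((t(target_mesh$vertices) - p)^2))
    })
    ## build U: columns are tangent directions of each sliding landmark,
    ## stacked coordinate-major to match vec(Y) = c(Y[,1], Y[,2], Y[,3])
    nslide <- length(slide_idx)
    U <- matrix(0, 3L * k, 2L * nslide)
    for (s in seq_len(nslide)) {
      tb <- tangent_basis(vnorm[nearest_vertex[s], ])
      i <- slide_idx[s]
      U[c(i, i + k, i + 2L * k), 2L * s - 1L] <- tb[, 1L]
      U[c(i, i + k, i + 2L * k), 2L * s] <- tb[, 2L]
    }
    y0 <- as.numeric(tgt)                 # coordinate-major vectorization
    Ey0 <- as.numeric(Lb %*% matrix(y0, k, 3L))     # (I3 (x) Lb) y0
    EU <- matrix(0, 3L * k, ncol(U))
    for (j in seq_len(ncol(U)))
      EU[, j] <- as.numeric(Lb %*% matrix(U[, j], k, 3L))
    A <- crossprod(U, EU)
    A <- A + diag(ridge * max(diag(A), 1), ncol(A))
    tpar <- -solve(A, crossprod(U, Ey0))
    tgt_new <- matrix(y0 + U %*% tpar, k, 3L)
    energies <- c(energies, bending_energy(Lb, tgt_new))
    ## re-project slid points onto the actual surface
    tgt_new[slide_idx, ] <- project_to_mesh(tgt_new[slide_idx, , drop = FALSE],
                                            target_mesh)$points
    tgt <- tgt_new
  }
  cfg <- landmark_sample(tgt, labels = if (inherits(target, "landmark_sample"))
    attr(target, "labels") else NULL, fixed = fixed_mask)
  list(config = cfg, energy = energies, energy_in = energies_in, energy0 = e0)
}

#' Signed distance from one mesh to another
#'
#' For every vertex of \code{mesh_a}, the Euclidean distance to the nearest
#' point of \code{mesh_b}, signed positive when the nearest point lies along
#' the outward vertex normal of \code{mesh_a} (i.e. \code{mesh_b} is outside
#' the surface of \code{mesh_a} at that vertex) and negative when inside.
#'
#' @param mesh_a,mesh_b \code{tri_mesh} objects; normals are computed from the
#'   faces when absent.
#' @return numeric vector, one signed distance per vertex of \code{mesh_a}.
#' @export
signed_surface_distance <- function(mesh_a, mesh_b) {
  pr <- project_to_mesh(mesh_a$vertices, mesh_b)
  n <- vertex_normals(mesh_a)
  dirs <- pr$points - mesh_a$vertices
  sgn <- sign(rowSums(dirs * n))
  sgn[sgn == 0] <- 1
  out <- sgn * pr$distance
  out[pr$distance == 0] <- 0
  out
}
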