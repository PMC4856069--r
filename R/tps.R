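#' Thin-plate splines and bending energy
#'
#' Interpolating thin-plate (2D) / volume (3D) splines between landmark
#' configurations. Radial kernel: U(r) = r^2 log r in 2D and U(r) = -r in 3D.
#' The 3D sign is chosen so that the bending-energy quadratic form is positive
#' semidefinite; with this convention bending energies are always >= 0 and
#' vanish exactly on affine deformations.
#'
#' @name tps
NULL

tps_kernel <- function(r, d) {
  if (d == 2L) {
    out <- ifelse(r > 0, r^2 * log(r), 0)
  } else {
    out <- -r
  }
  out
}

tps_system <- function(source) {
  source <- as.matrix(source)
  k <- nrow(source); d <- ncol(source)
  r <- as.matrix(stats::dist(source))
  K <- tps_kernel(r, d)
  Q <- cbind(1, source)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, d + 1L, d + 1L)))
  list(L = L, K = K, Q = Q, k = k, d = d)
}

#' Fit an interpolating thin-plate spline
#'
#' Solves the TPS system mapping \code{source} control points exactly onto
#' \code{target}. The kernel weights are orthogonal to the affine subspace
#' (Q'w = 0) and the bending energy is the kernel quadratic form summed over
#' coordinates; it is zero (to numerical precision) iff the map is affine.
#'
#' @param source,target k x d matrices of corresponding control points.
#' @return object of class \code{"tps"}: source, target, \code{affine}
#'   ((d+1) x d matrix, first row the translation), \code{weights} (k x d),
#'   \code{bending_energy}.
#' @export
tps_fit <- function(source, target) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target))) stop("source and target must share (k, d)")
  k <- nrow(source); d <- ncol(source)
  if (k < d + 1L) stop("need at least d + 1 control points")
  sys <- tps_system(source)
  rhs <- rbind(target, matrix(0, d + 1L, d))
  coefs <- tryCatch(solve(sys$L, rhs),
                    error = function(e) stop("singular TPS system: control points collinear/coplanar?"))
  W <- coefs[seq_len(k), , drop = FALSE]
  A <- coefs[(k + 1L):(k + d + 1L), , drop = FALSE]
  be <- sum(diag(crossprod(W, sys$K %*% W)))
  structure(list(source = source, target = target, affine = A, weights = W,
                 bending_energy = max(be, 0)),
            class = "tps")
}

#' Evaluate a thin-plate spline at new points
#'
#' @param model a \code{tps_fit()} result.
#' @param points m x d matrix of query points.
#' @return m x d matrix of warped points; at the source control points the
#'   result equals the target exactly.
#' @export
tps_deform <- function(model, points) {
  points <- as.matrix(points)
  d <- ncol(model$source)
  stopifnot(ncol(points) == d)
  ## pairwise distances query -> control
  d2 <- outer(rowSums(points^2), rep(1, nrow(model$source))) +
    outer(rep(1, nrow(points)), rowSums(model$source^2)) -
    2 * tcrossprod(points, model$source)
  r <- sqrt(pmax(d2, 0))
  U <- tps_kernel(r, d)
  cbind(1, points) %*% model$affine + U %*% model$weights
}

#' Bending-energy matrix of a reference configuration
#'
#' Upper-left k x k block of the inverse TPS system for the reference: the
#' matrix L_b such that the bending energy of a displacement field with
#' coordinate columns y is sum over columns of y' L_b y. Symmetric PSD, rows
#' and columns sum to zero, and it annihilates affine displacements of the
#' reference.
#'
#' @param reference k x d control-point matrix.
#' @return k x k matrix.
#' @export
bending_energy_matrix <- function(reference) {
  reference <- as.matrix(reference)
  sys <- tps_system(reference)
  Linv <- tryCatch(solve(sys$L),
                   error = function(e) stop("singular TPS system: reference degenerate"))
  Lb <- Linv[seq_len(sys$k), seq_len(sys$k), drop = FALSE]
  (Lb + t(Lb)) / 2
}

## bending energy of deformation reference -> target via the L_b form
bending_energy <- function(Lb, target) {
  target <- as.matrix(target)
  max(sum(vapply(seq_len(ncol(target)),
                 function(j) c(crossprod(target[, j], Lb %*% target[, j])), 0)), 0)
}
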