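#' Landmark sample arrays
#'
#' Landmark data are carried as a \code{k x d x n} numeric array (k landmarks,
#' d = 2 or 3 coordinates, n specimens), the layout used throughout geometric
#' morphometrics. \code{landmark_sample()} validates and labels such an array.
#'
#' @param coords k x d x n numeric array (a k x d matrix is promoted to n = 1).
#' @param labels optional character vector of k landmark names.
#' @param fixed optional logical vector of length k; \code{TRUE} marks an
#'   expert (anatomical) landmark, \code{FALSE} a surface semilandmark.
#'   Defaults to all fixed.
#' @param ids optional character vector of n specimen identifiers.
#' @return the array with class \code{"landmark_sample"} and attributes
#'   \code{labels}, \code{fixed}, \code{ids}.
#' @export
landmark_sample <- function(coords, labels = NULL, fixed = NULL, ids = NULL) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), ncol(coords), 1L))
  stopifnot(is.array(coords), length(dim(coords)) == 3L)
  k <- dim(coords)[1L]; d <- dim(coords)[2L]; n <- dim(coords)[3L]
  if (!d %in% c(2L, 3L)) stop("landmark dimension must be 2 or 3")
  if (k < 3L) stop("need at least 3 landmarks")
  if (any(!is.finite(coords))) stop("non-finite landmark coordinates")
  if (is.null(labels)) labels <- paste0("L", seq_len(k))
  if (is.null(fixed)) fixed <- rep(TRUE, k)
  if (is.null(ids)) ids <- paste0("spec", seq_len(n))
  stopifnot(length(labels) == k, length(fixed) == k, length(ids) == n)
  structure(coords, labels = labels, fixed = as.logical(fixed), ids = ids,
            class = "landmark_sample")
}

#' @export
print.landmark_sample <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("landmark_sample: %d landmarks x %d dims x %d specimens (%d fixed, %d sliding)\n",
              d[1], d[2], d[3], sum(attr(x, "fixed")), sum(!attr(x, "fixed"))))
  invisible(x)
}

n_specimens <- function(x) dim(x)[3L]

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the size measure removed by Procrustes scaling. Homogeneous of
#' degree one: scaling the configuration by c scales the result by c.
#'
#' @param config k x d coordinate matrix.
#' @return a non-negative scalar; 0 (with a warning) for a fully degenerate
#'   configuration in which all landmarks coincide.
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  ctr <- colMeans(config)
  cs <- sqrt(sum(sweep(config, 2L, ctr)^2))
  if (cs == 0) warning("degenerate configuration: all landmarks coincide")
  cs
}

## center a config and scale to unit centroid size (preshape)
preshape <- function(config) {
  config <- sweep(config, 2L, colMeans(config))
  cs <- sqrt(sum(config^2))
  if (cs == 0) stop("degenerate configuration: zero centroid size")
  config / cs
}

## optimal rotation (no reflection) taking B onto A: minimizes ||A - B R||_F
rotation_onto <- function(B, A) {
  sv <- svd(crossprod(B, A))
  R <- tcrossprod(sv$u, sv$v)
  if (det(R) < 0) {
    u <- sv$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- tcrossprod(u, sv$v)
  }
  R
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centered, scaled to unit centroid size and one is
#' rotated (rotation only, no reflection) onto the other; the distance is the
#' square root of the summed squared coordinate differences of the
#' superimposed preshapes. Symmetric, zero iff the two have the same shape.
#'
#' @param a,b k x d coordinate matrices with matching dimensions.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("configurations must share (k, d)")
  pa <- preshape(a); pb <- preshape(b)
  R <- rotation_onto(pb, pa)
  sqrt(sum((pa - pb %*% R)^2))
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a landmark sample: every configuration is
#' centered and scaled to unit centroid size, then repeatedly rotated onto the
#' current mean shape by orthogonal (non-reflecting) Procrustes fits; the mean
#' is re-estimated and renormalized to unit centroid size until it stops
#' moving. Shape distances between the aligned specimens are invariant to the
#' translation, rotation and scaling of the raw input. The converged solution
#' is rotated so the mean shape sits on its principal axes (flattest
#' direction on the last coordinate), giving the common frame a deterministic
#' orientation in which per-axis effect decompositions are meaningful.
#'
#' @param sample a \code{landmark_sample} (or k x d x n array), n >= 2.
#' @param scale scale configurations to unit centroid size (the default; kept
#'   as an argument so size-retaining superimpositions can be requested).
#' @param max_iter,tol iteration control on the movement of the mean shape.
#' @return an object of class \code{"gpa"}: list with \code{aligned}
#'   (landmark_sample), \code{mean_shape} (k x d), \code{centroid_sizes},
#'   \code{converged}, \code{iterations}.
#' @export
gpa <- function(sample, scale = TRUE, max_iter = 100L, tol = 1e-10) {
  if (!inherits(sample, "landmark_sample")) sample <- landmark_sample(sample)
  k <- dim(sample)[1L]; d <- dim(sample)[2L]; n <- dim(sample)[3L]
  if (n < 2L) stop("GPA needs at least two specimens")
  cs <- apply(sample, 3L, centroid_size)
  X <- array(0, dim(sample))
  for (i in seq_len(n)) {
    Xi <- sweep(sample[, , i], 2L, colMeans(sample[, , i]))
    X[, , i] <- if (scale) Xi / cs[i] else Xi
  }
  mean_shape <- X[, , 1L]
  mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n)) X[, , i] <- X[, , i] %*% rotation_onto(X[, , i], mean_shape)
    new_mean <- apply(X, c(1L, 2L), mean)
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("GPA did not converge in %d iterations; returning best fit", max_iter))
  ## orient the common frame on the mean shape's principal axes (flattest
  ## direction last) so coordinate-axis decompositions are well defined
  Ror <- principal_axes(mean_shape)
  mean_shape <- mean_shape %*% Ror
  for (i in seq_len(n)) X[, , i] <- X[, , i] %*% Ror
  aligned <- landmark_sample(X, labels = attr(sample, "labels"),
                             fixed = attr(sample, "fixed"), ids = attr(sample, "ids"))
  structure(list(aligned = aligned, mean_shape = mean_shape,
                 centroid_sizes = cs, converged = converged, iterations = it),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf("GPA of %d specimens (%d landmarks, %dD): %s after %d iterations\n",
              d[3], d[1], d[2],
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

## vectorize aligned coords: n x (k*d), coordinate-major (x1..xk, y1..yk, ...)
## so that column blocks correspond to coordinate axes
vec_coords <- function(arr) {
  k <- dim(arr)[1L]; d <- dim(arr)[2L]; n <- dim(arr)[3L]
  t(matrix(arr, k * d, n))
}

## inverse of vec_coords for a single specimen row
unvec_config <- function(v, k, d) matrix(v, k, d)
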