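## axis sign choice that is intrinsic to the shape and smooth in the
## coordinates (so small noise cannot flip it): positive third moment of the
## landmark coordinates along the axis; the largest-|coordinate| landmark
## breaks near-symmetric ties
axis_sign <- function(x) {
  m3 <- sum(x^3)
  if (abs(m3) > 1e-6 * sum(x^2)^1.5) sign(m3) else sign(x[which.max(abs(x))])
}

## rotation onto the eigenvectors of the landmark covariance. Sign fixing is
## intrinsic to the shape (hence invariant to the input orientation) on each
## axis but the last; the last axis sign preserves orientation (det = +1).
principal_axes <- function(config) {
  config <- sweep(config, 2L, colMeans(config))
  ev <- eigen(stats::cov(config), symmetric = TRUE)
  R <- ev$vectors
  X <- config %*% R
  d <- ncol(R)
  for (j in seq_len(d - 1L)) {
    if (axis_sign(X[, j]) < 0) { R[, j] <- -R[, j]; X[, j] <- -X[, j] }
  }
  if (det(R) < 0) R[, d] <- -R[, d]
  R
}

## principal-axis alignment of one configuration
principal_align <- function(config) {
  config <- sweep(config, 2L, colMeans(config))
  config %*% principal_axes(config)
}

#' Simulated 2D flattening of a 3D configuration
#'
#' Emulates 2D photographic phenotyping of a nearly flat 3D structure. The
#' configuration is first aligned to its principal axes; three anchor
#' landmarks define the resting plane; when a mesh is supplied the first two
#' anchors are refined iteratively to the innermost mesh vertex along the
#' current plane normal (the points on which the bone would rest), until the
#' anchors stop moving. All landmarks are then projected orthogonally onto the
#' plane and expressed in a deterministic in-plane 2D basis (principal axes of
#' the projected configuration with largest-coordinate-positive sign fixing).
#'
#' @param config k x 3 matrix or single-specimen \code{landmark_sample}.
#' @param anchors integer vector of 3 distinct landmark indices defining the
#'   plane.
#' @param mesh optional \code{tri_mesh} (already principal-axis aligned with
#'   the landmarks) used for anchor refinement.
#' @param max_iter,tol anchor-refinement control.
#' @param align apply principal-axis pre-alignment (disable when the input is
#'   already in the desired frame).
#' @return list with \code{config2d} (k x 2 matrix), \code{plane} (point +
#'   unit normal), \code{offsets} (signed out-of-plane coordinate removed per
#'   landmark), \code{converged}.
#' @export
flatten_to_2d <- function(config, anchors, mesh = NULL, max_iter = 20L,
                          tol = 1e-8, align = TRUE) {
  if (inherits(config, "landmark_sample")) config <- config[, , 1L]
  config <- as.matrix(config)
  stopifnot(ncol(config) == 3L)
  anchors <- as.integer(anchors)
  if (length(anchors) != 3L || anyDuplicated(anchors)) stop("need 3 distinct anchors")
  if (align) config <- principal_align(config)
  a <- config[anchors, , drop = FALSE]
  plane_normal <- function(a) {
    n <- crossprod3(a[2L, ] - a[1L, ], a[3L, ] - a[1L, ])
    nn <- sqrt(sum(n^2))
    if (nn < .Machine$double.eps^0.5) stop("collinear anchors")
    n / nn
  }
  n <- plane_normal(a)
  converged <- TRUE
  if (!is.null(mesh)) {
    converged <- FALSE
    bbox <- max(apply(mesh$vertices, 2L, function(v) diff(range(v))))
    ctr <- colMeans(mesh$vertices)
    ## keep the normal pointing into the body so "innermost along the
    ## normal" consistently means the resting side of the surface
    orient <- function(n, a) if (sum((ctr - a[1L, ]) * n) < 0) -n else n
    n <- orient(n, a)
    seen <- character(0)
    for (it in seq_len(max_iter)) {
      moved <- 0
      for (j in 1:2) {
        ## innermost vertex along the normal, searched near the current
        ## anchor, keeping clear of the other anchors so the plane stays
        ## well defined
        d2 <- colSums((t(mesh$vertices) - a[j, ])^2)
        nearby <- which(d2 <= (0.25 * bbox)^2)
        if (length(nearby) == 0L) nearby <- seq_len(nrow(mesh$vertices))
        other <- a[setdiff(1:3, j), , drop = FALSE]
        clear <- vapply(nearby, function(vi)
          min(sqrt(rowSums(sweep(other, 2L, mesh$vertices[vi, ])^2))) > 0.05 * bbox,
          TRUE)
        if (any(clear)) nearby <- nearby[clear]
        proj <- mesh$vertices[nearby, , drop = FALSE] %*% n
        cand <- mesh$vertices[nearby[which.min(proj)], ]
        moved <- max(moved, sqrt(sum((cand - a[j, ])^2)))
        a[j, ] <- cand
      }
      n <- orient(plane_normal(a), a)
      if (moved < tol) { converged <- TRUE; break }
      ## discrete vertex choices can cycle; a revisited state is settled
      state <- paste(signif(a[1:2, ], 12), collapse = ",")
      if (state %in% seen) { converged <- TRUE; break }
      seen <- c(seen, state)
    }
    if (!converged) warning("anchor refinement did not settle; using last plane")
  }
  ## orient normal consistently (positive third principal axis)
  if (n[3L] < 0) n <- -n
  offsets <- as.numeric((config - matrix(a[1L, ], nrow(config), 3L, byrow = TRUE)) %*% n)
  flat3 <- config - outer(offsets, n)
  ## in-plane basis: principal axes of the projected configuration
  ctr <- colMeans(flat3)
  fc <- sweep(flat3, 2L, ctr)
  ev <- eigen(stats::cov(fc), symmetric = TRUE)
  B <- ev$vectors[, 1:2, drop = FALSE]
  ## first axis sign from the coordinate third moment (stable under noise);
  ## second axis right-handed about the plane normal, so every specimen
  ## flattens with the same chirality and GPA (which never reflects) can
  ## align them
  if (axis_sign(as.numeric(fc %*% B[, 1L])) < 0) B[, 1L] <- -B[, 1L]
  B[, 2L] <- crossprod3(n, B[, 1L])
  config2d <- fc %*% B
  list(config2d = config2d, plane = list(point = a[1L, ], normal = n),
       offsets = offsets, converged = converged)
}

crossprod3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Flatten every specimen of a sample
#'
#' @param sample a \code{landmark_sample} with d = 3.
#' @param anchors 3 landmark indices (see \code{\link{flatten_to_2d}}).
#' @param ... passed to \code{\link{flatten_to_2d}}.
#' @return a 2D \code{landmark_sample}.
#' @export
flatten_sample <- function(sample, anchors, ...) {
  k <- dim(sample)[1L]; n <- dim(sample)[3L]
  out <- array(0, c(k, 2L, n))
  for (i in seq_len(n)) out[, , i] <- flatten_to_2d(sample[, , i], anchors, ...)$config2d
  ## per-specimen basis choices can land individual specimens on the mirror
  ## image (digitizing from the other side of the plane); harmonize the
  ## chirality across the sample against the first specimen, since the
  ## downstream GPA never reflects
  for (i in seq_len(n)[-1L]) {
    mir <- out[, , i] %*% diag(c(1, -1))
    if (procrustes_distance(mir, out[, , 1L]) <
        procrustes_distance(out[, , i], out[, , 1L]))
      out[, , i] <- mir
  }
  landmark_sample(out, labels = attr(sample, "labels"),
                  fixed = attr(sample, "fixed"), ids = attr(sample, "ids"))
}
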