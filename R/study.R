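#' Projector onto the shape tangent subspace
#'
#' Orthogonal projector of vectorized (coordinate-major) k x d configurations
#' onto the complement of the similarity group at a reference shape:
#' translations (d), rotations (d(d-1)/2) and scaling (1) are removed. Effect
#' vectors built with this projector are pure shape effects, so generalized
#' Procrustes superimposition neither shrinks nor rotates them (to the
#' small-variation tangent approximation).
#'
#' @param mean_shape k x d reference configuration (centered internally).
#' @return (k*d) x (k*d) symmetric idempotent matrix.
#' @export
shape_tangent_projector <- function(mean_shape) {
  mean_shape <- sweep(as.matrix(mean_shape), 2L, colMeans(as.matrix(mean_shape)))
  k <- nrow(mean_shape); d <- ncol(mean_shape); kd <- k * d
  basis <- matrix(0, kd, 0)
  for (j in seq_len(d)) {                      # translations
    v <- numeric(kd); v[(j - 1L) * k + seq_len(k)] <- 1
    basis <- cbind(basis, v)
  }
  basis <- cbind(basis, as.numeric(mean_shape))  # scaling
  if (d >= 2) {
    gens <- utils::combn(d, 2L, simplify = FALSE)
    for (g in gens) {                          # infinitesimal rotations
      A <- matrix(0, d, d)
      A[g[1L], g[2L]] <- 1; A[g[2L], g[1L]] <- -1
      basis <- cbind(basis, as.numeric(mean_shape %*% A))
    }
  }
  Q <- qr.Q(qr(basis))
  diag(kd) - tcrossprod(Q)
}

## 13 fixed landmarks of a flat, elongated, mandible-like reference shape:
## mostly in the xy plane with modest z relief, unit centroid size
mandible_reference <- function() {
  xy <- rbind(
    c(-0.50, -0.10), c(-0.45, 0.12), c(-0.20, 0.25), c(0.05, 0.33),
    c(0.30, 0.28), c(0.50, 0.15), c(0.55, -0.05), c(0.40, -0.22),
    c(0.15, -0.30), c(-0.10, -0.28), c(-0.30, -0.22), c(0.10, 0.05),
    c(-0.05, -0.05))
  z <- c(0.02, -0.03, 0.05, 0.02, -0.04, 0.03, -0.02, 0.04, -0.05, 0.02,
         -0.02, 0.08, -0.06)
  cfg <- cbind(xy, z)
  ## principal-axis aligned so the simulation frame coincides with the
  ## orientation GPA reports, making planted per-axis decompositions exact
  cfg <- principal_align(cfg)
  cfg / centroid_size(cfg)
}

#' Simulate the full backcross shape-mapping study
#'
#' One call builds a synthetic dataset shaped like the mapping study the
#' package targets: an N2 backcross of \code{n} individuals genotyped on 19
#' autosomes (~120 markers at 15 cM spacing on mouse-like chromosome
#' lengths), 13 3D landmarks per specimen, additive covariate effects (log
#' centroid size, sex, direction of cross), a configurable number of planted
#' QTL with Procrustes-norm effects in the 1e-3 to 1e-2 range, and isotropic
#' individual error. All effect vectors are projected into the shape tangent
#' space so superimposition recovers them cleanly. Defaults put the planted
#' QTL variance near 10%, and the covariates near 5%, of the total Procrustes
#' variance, matching the magnitudes typical of mouse mandible data.
#'
#' @param n individuals (default 427).
#' @param n_qtl planted QTL (default 15, spread over distinct chromosomes).
#' @param seed integer seed controlling map draw, genotypes and shapes.
#' @param beta_norm_range range of planted effect norms (Procrustes units).
#' @param error_trace total error variance (trace of the isotropic error
#'   covariance over all k*d coordinates).
#' @param error_structure "isotropic", "diagonal" or "factor"; the latter two
#'   perturb the error variances to break sphericity.
#' @param spacing marker spacing in cM.
#' @param geno_error,missing_rate observation noise on genotypes.
#' @return a phenotyped \code{bc_cross} (see \code{\link{simulate_shapes}})
#'   with the \code{sim_truth} attached.
#' @export
sim_mandible_study <- function(n = 427L, n_qtl = 15L, seed = 1L,
                               beta_norm_range = c(0.004, 0.012),
                               error_trace = 0.002,
                               error_structure = c("isotropic", "diagonal", "factor"),
                               spacing = 15, geno_error = 0.002,
                               missing_rate = 0.02) {
  error_structure <- match.arg(error_structure)
  ## mouse-like autosome lengths (cM)
  chr_len <- c(98, 103, 82, 88, 90, 79, 89, 76, 75, 77,
               87, 73, 67, 66, 59, 57, 61, 59, 57)
  names(chr_len) <- as.character(1:19)
  map <- sim_map(chr_len, spacing = spacing)
  cross <- simulate_backcross(map, n, seed = seed, geno_error = geno_error,
                              missing_rate = missing_rate)
  mshape <- mandible_reference()
  k <- nrow(mshape); d <- ncol(mshape); kd <- k * d
  P <- shape_tangent_projector(mshape)
  set.seed(seed + 1000L)
  ## QTL positions: cycle over chromosomes, interior positions
  chrs <- rep(names(chr_len), length.out = n_qtl)
  pos <- vapply(chrs, function(ch) {
    p <- stats::runif(1, 0.15, 0.85) * chr_len[[ch]]
    round(p, 1)
  }, 0)
  norms <- seq(beta_norm_range[1L], beta_norm_range[2L], length.out = n_qtl)
  beta <- matrix(0, n_qtl, kd)
  for (j in seq_len(n_qtl)) {
    v <- stats::rnorm(kd)
    v[2L * k + seq_len(k)] <- 0.4 * v[2L * k + seq_len(k)]  # flat-plane bias
    v <- as.numeric(P %*% v)
    beta[j, ] <- v / sqrt(sum(v^2)) * norms[j]
  }
  mk_effect <- function(nrm, zscale = 0.4) {
    v <- stats::rnorm(kd)
    v[2L * k + seq_len(k)] <- zscale * v[2L * k + seq_len(k)]
    v <- as.numeric(P %*% v)
    v / sqrt(sum(v^2)) * nrm
  }
  covariate_effects <- list(
    size = mk_effect(0.047),            # allometry, ~1% of total variance
    sex = mk_effect(0.009),
    cross_direction = mk_effect(0.0155) # largest covariate, ~2.5%
  )
  base_var <- error_trace / kd
  error_cov <- switch(error_structure,
    isotropic = base_var,
    diagonal = {
      set.seed(seed + 2000L)
      v <- stats::runif(kd, 0.5, 1.5)
      v * (error_trace / sum(v))
    },
    factor = {
      set.seed(seed + 2000L)
      f1 <- as.numeric(P %*% stats::rnorm(kd)); f1 <- f1 / sqrt(sum(f1^2))
      f2 <- as.numeric(P %*% stats::rnorm(kd)); f2 <- f2 / sqrt(sum(f2^2))
      S <- 0.5 * error_trace / kd * diag(kd) +
        0.25 * error_trace * tcrossprod(f1) + 0.25 * error_trace * tcrossprod(f2)
      S * (error_trace / sum(diag(S)))
    })
  truth <- sim_truth(mshape, qtl = data.frame(chr = chrs, pos = pos,
                                              stringsAsFactors = FALSE),
                     beta = beta, covariate_effects = covariate_effects,
                     error_cov = error_cov)
  simulate_shapes(cross, truth, seed = seed + 1L)
}
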