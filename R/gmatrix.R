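#' QTL-based genetic covariance matrix
#'
#' Assembles the additive genetic covariance implied by a fitted multiple-QTL
#' model: G = B' C B, where the rows of B are the coordinate-space QTL effect
#' vectors and C is the covariance matrix of the QTL dosages. C is estimated
#' empirically from the expected dosages (capturing linkage between
#' same-chromosome QTL) or taken as the unlinked backcross closed form I/4.
#'
#' @param fit a \code{qtl_fit} with at least one QTL.
#' @param pca optional \code{\link{pca_reduce}} result to rotate effects back
#'   to coordinate space.
#' @param dosage_cov "empirical" or "unlinked".
#' @param subset optional integer/logical index over coordinate columns (e.g.
#'   the xy(z) block of the fixed landmarks) applied to the effect columns.
#' @param labels optional coordinate labels.
#' @return a \code{cov_matrix} (symmetric PSD, kind "G").
#' @export
qtl_G <- function(fit, pca = NULL, dosage_cov = c("empirical", "unlinked"),
                  subset = NULL, labels = NULL) {
  dosage_cov <- match.arg(dosage_cov)
  if (nrow(fit$qtl) == 0L) stop("model has no QTL")
  B <- if (!is.null(pca)) fit$B %*% t(pca$rotation) else fit$B
  if (!is.null(subset)) B <- B[, subset, drop = FALSE]
  C <- if (dosage_cov == "empirical") stats::cov(fit$dosages) else
    diag(1 / 4, nrow(B))
  if (dosage_cov == "empirical") C <- (C + t(C)) / 2
  G <- t(B) %*% C %*% B
  cov_matrix((G + t(G)) / 2, kind = "G", labels = labels)
}

#' Covariance matrix container
#'
#' @param m symmetric matrix (genetic or phenotypic covariance of landmark
#'   coordinates).
#' @param kind "G" or "P".
#' @param labels optional coordinate labels.
#' @return matrix of class \code{"cov_matrix"}.
#' @export
cov_matrix <- function(m, kind = c("G", "P"), labels = NULL) {
  kind <- match.arg(kind)
  m <- as.matrix(m)
  if (max(abs(m - t(m))) > 1e-10 * max(abs(m), 1)) stop("matrix not symmetric")
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(sum(pmax(ev, 0)), .Machine$double.eps))
    warning("matrix has non-trivial negative eigenvalues; treated as PSD noise")
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  structure(m, kind = kind, class = c("cov_matrix", "matrix"))
}

#' Phenotypic covariance of aligned coordinates
#'
#' Covariance of the vectorized Procrustes coordinates, by default after
#' adjusting for the study covariates (residuals of the multivariate
#' covariate fit), consistent with the covariance structure the mapping model
#' assumes; set \code{adjust = FALSE} for the raw phenotypic covariance.
#'
#' @param gpa_result a \code{\link{gpa}} result or landmark array.
#' @param covariates covariate data.frame (required when \code{adjust}).
#' @param adjust remove covariate effects first (default TRUE).
#' @param subset optional coordinate-column subset.
#' @return a \code{cov_matrix} of kind "P".
#' @export
phenotypic_cov <- function(gpa_result, covariates = NULL, adjust = TRUE,
                           subset = NULL) {
  arr <- if (inherits(gpa_result, "gpa")) unclass(gpa_result$aligned) else unclass(gpa_result)
  Y <- vec_coords(arr)
  if (adjust) {
    if (is.null(covariates)) stop("covariates needed for adjusted P")
    Y <- qr.resid(qr(covariate_design(covariates)), Y)
    P <- crossprod(Y) / (nrow(Y) - qr(covariate_design(covariates))$rank)
  } else {
    P <- stats::cov(Y)
  }
  if (!is.null(subset)) P <- P[subset, subset, drop = FALSE]
  cov_matrix((P + t(P)) / 2, kind = "P")
}

#' Symmetric PSD matrix square root
#'
#' Spectral square root U L^{1/2} U'; eigenvalues below zero (PSD noise) are
#' clipped to zero.
#'
#' @param A symmetric PSD matrix.
#' @return symmetric matrix with \code{(A^{1/2})^2 = A} up to clipping.
#' @export
matrix_sqrt_psd <- function(A) {
  A <- as.matrix(A)
  if (max(abs(A - t(A))) > 1e-8 * max(abs(A), 1)) stop("matrix not symmetric")
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Root Euclidean distance between covariance matrices
#'
#' d_H(G1, G2) = Frobenius norm of the difference of the symmetric matrix
#' square roots; a metric on PSD matrices.
#'
#' @param G1,G2 same-dimension symmetric PSD matrices.
#' @return non-negative scalar.
#' @export
root_euclidean_distance <- function(G1, G2) {
  G1 <- as.matrix(G1); G2 <- as.matrix(G2)
  if (!all(dim(G1) == dim(G2))) stop("dimension mismatch")
  if (!is.null(dimnames(G1)[[1]]) && !is.null(dimnames(G2)[[1]]) &&
      !identical(dimnames(G1)[[1]], dimnames(G2)[[1]]))
    stop("coordinate label mismatch")
  sqrt(sum((matrix_sqrt_psd(G1) - matrix_sqrt_psd(G2))^2))
}

## angle in degrees between two axes (sign-free), folded to [0, 90]
axis_angle <- function(u, v) {
  cth <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(min(cth, 1)) * 180 / pi
}

#' Angle test between leading eigenvectors of two covariance matrices
#'
#' Measures the angle between the g_max axes (leading eigenvectors, folded to
#' [0, 90] degrees since axes are sign-free) and compares it to the angles of
#' random axis pairs drawn uniformly on the sphere of the same dimension:
#' p = fraction of random pairs at least as aligned as the observed pair.
#'
#' @param G1,G2 symmetric matrices.
#' @param n_random random pairs for the null (100000 in the canonical
#'   protocol).
#' @param seed integer seed.
#' @param which pair of eigenvector indices to compare (default c(1, 1);
#'   useful when leading eigenvalues are nearly tied and a PC permutation
#'   must be examined).
#' @return list with \code{angle} (degrees), \code{p}, \code{null_mean},
#'   and \code{eigen_gap} (relative gap of each matrix's two leading
#'   eigenvalues; near-zero gaps flag effectively tied leading axes).
#' @export
gmax_angle_test <- function(G1, G2, n_random = 100000L, seed = 1L,
                            which = c(1L, 1L)) {
  e1 <- eigen(as.matrix(G1), symmetric = TRUE)
  e2 <- eigen(as.matrix(G2), symmetric = TRUE)
  if (max(abs(e1$values)) == 0 || max(abs(e2$values)) == 0)
    stop("zero matrix has no leading axis")
  ang <- axis_angle(e1$vectors[, which[1L]], e2$vectors[, which[2L]])
  m <- nrow(as.matrix(G1))
  gap <- c(g1 = (e1$values[1] - e1$values[2]) / max(e1$values[1], .Machine$double.eps),
           g2 = (e2$values[1] - e2$values[2]) / max(e2$values[1], .Machine$double.eps))
  if (any(gap < 1e-6))
    warning("leading eigenvalues effectively tied; compare alternative pairings via `which`")
  set.seed(seed)
  a <- matrix(stats::rnorm(n_random * m), n_random, m)
  b <- matrix(stats::rnorm(n_random * m), n_random, m)
  cth <- abs(rowSums(a * b)) / sqrt(rowSums(a^2) * rowSums(b^2))
  null_ang <- acos(pmin(cth, 1)) * 180 / pi
  p <- mean(null_ang <= ang)
  list(angle = ang, p = p, null_mean = mean(null_ang), eigen_gap = gap)
}

#' Krzanowski common-subspace analysis
#'
#' For each covariance matrix, takes the smallest leading set of eigenvectors
#' reaching \code{var_fraction} of its variance (the subspace A_i), forms
#' H = sum_i A_i A_i', and eigen-decomposes it. Each H eigenvalue equals
#' sum_i cos^2(delta_i), where delta_i is the angle between the eigenvector
#' and subspace A_i; eigenvalues near the number of matrices flag directions
#' shared by all subspaces.
#'
#' @param matrices list of >= 2 same-dimension symmetric matrices.
#' @param var_fraction cumulative variance used to pick each q_i, in (0, 1].
#' @return list with \code{H}, \code{eigenvalues}, \code{eigenvectors},
#'   \code{angles} (degrees; one row per H eigenvector, one column per
#'   matrix), \code{q} (per-matrix subspace dimensions).
#' @export
krzanowski_subspace <- function(matrices, var_fraction = 0.90) {
  if (length(matrices) < 2L) stop("need at least two matrices")
  if (var_fraction <= 0 || var_fraction > 1) stop("var_fraction must be in (0, 1]")
  m <- nrow(as.matrix(matrices[[1L]]))
  As <- lapply(matrices, function(G) {
    G <- as.matrix(G)
    if (nrow(G) != m) stop("dimension mismatch")
    ev <- eigen(G, symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    qi <- which(cumsum(lam) / sum(lam) >= var_fraction - 1e-12)[1L]
    ev$vectors[, seq_len(qi), drop = FALSE]
  })
  H <- matrix(0, m, m)
  for (A in As) H <- H + tcrossprod(A)
  eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
  angles <- sapply(As, function(A) {
    cosd <- sqrt(pmin(colSums(crossprod(A, eh$vectors)^2), 1))
    acos(cosd) * 180 / pi
  })
  list(H = H, eigenvalues = eh$values, eigenvectors = eh$vectors,
       angles = angles, q = vapply(As, ncol, 0L))
}

#' Multivariate heritability: spectral decomposition of G P^-
#'
#' Eigen-decomposition of G times the Moore-Penrose inverse of P. The
#' eigenvalues are heritabilities of shape directions (clipped into [0, 1],
#' with clipping recorded) and the eigenvectors are the associated shape
#' directions.
#'
#' @param G,P same-dimension symmetric matrices, P PSD.
#' @param rank_tol relative eigenvalue tolerance of the pseudo-inverse.
#' @return list with \code{h2} (eigenvalues, decreasing), \code{directions}
#'   (columns), \code{clipped} (count of eigenvalues clipped into [0, 1]),
#'   \code{rank_P}.
#' @export
multivariate_heritability <- function(G, P, rank_tol = 1e-10) {
  G <- as.matrix(G); P <- as.matrix(P)
  if (!all(dim(G) == dim(P))) stop("dimension mismatch")
  if (max(abs(P)) == 0) stop("zero P matrix")
  ep <- eigen((P + t(P)) / 2, symmetric = TRUE)
  keep <- ep$values > rank_tol * max(ep$values)
  Pinv <- ep$vectors[, keep, drop = FALSE] %*%
    (1 / ep$values[keep] * t(ep$vectors[, keep, drop = FALSE]))
  M <- G %*% Pinv
  ev <- eigen(M)
  lam <- Re(ev$values)
  vec <- Re(ev$vectors)
  o <- order(lam, decreasing = TRUE)
  lam <- lam[o]; vec <- vec[, o, drop = FALSE]
  clipped <- sum(lam < -1e-10 | lam > 1 + 1e-10)
  lam <- pmin(pmax(lam, 0), 1)
  list(h2 = lam, directions = vec, clipped = clipped, rank_P = sum(keep))
}
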