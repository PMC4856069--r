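#' Decompose a shape effect over coordinate axes
#'
#' Fraction of a shape-effect vector lying along each coordinate dimension:
#' fraction_m = sum_i beta[i, m]^2 / ||beta||^2 over the k landmarks. With
#' configurations oriented so the third axis is the flattening-plane normal,
#' the third fraction is the part of the effect leaving the natural 2D plane.
#'
#' @param beta effect vector of length k*d (coordinate-major) or k x d matrix.
#' @param k,d landmark count and dimension (ignored when beta is a matrix).
#' @return length-d vector of fractions summing to 1.
#' @export
plane_decomposition <- function(beta, k = NULL, d = NULL) {
  if (!is.matrix(beta)) {
    if (is.null(k) || is.null(d)) stop("supply k and d for a vectorized beta")
    beta <- matrix(beta, k, d)
  }
  nrm2 <- sum(beta^2)
  if (nrm2 == 0) stop("zero effect vector")
  colSums(beta^2) / nrm2
}

#' Expected fraction of projection-score variance explained by one QTL
#'
#' Closed-form expectation, for a backcross with unlinked QTL, of the
#' proportion of variance of the projection scores v = Y beta_j' / ||beta_j||
#' explained by QTL j: ||beta_j||^4 / (beta_j (B'B + 4 Sigma_e) beta_j').
#' For a single QTL with isotropic error variance sigma^2 per coordinate this
#' reduces to ||beta||^2 / (||beta||^2 + 4 sigma^2).
#'
#' @param beta_j effect vector (length q).
#' @param B all QTL effect rows (m x q), including beta_j.
#' @param sigma_e q x q error covariance (or scalar isotropic variance).
#' @return scalar expectation in [0, 1].
#' @export
expected_h2 <- function(beta_j, B, sigma_e) {
  beta_j <- as.numeric(beta_j)
  B <- rbind(B)
  q <- length(beta_j)
  S <- if (is.matrix(sigma_e)) sigma_e else diag(sigma_e, q)
  num <- sum(beta_j^2)^2
  den <- as.numeric(beta_j %*% (crossprod(B) + 4 * S) %*% beta_j)
  num / den
}

#' Per-QTL effect summaries in shape space
#'
#' For each QTL of a fitted model: the Procrustes-norm of its additive
#' effect; the percentage of total Procrustes variance it explains given all
#' other terms (%SST, type-III trace); the projection scores
#' v = Y beta' / ||beta|| (the shape variable most associated with the QTL's
#' shape change, containing effect plus residual in that direction) and the
#' percentage of their variance explained by the QTL (%SS_proj); the
#' closed-form expectation of that percentage for unlinked backcross QTL; and
#' the fraction of the effect along each coordinate axis.
#'
#' When the model was fit in a PC basis (\code{pca} given), effects are
#' rotated back to coordinate space for the norms and plane decomposition,
#' and %SST is taken against the full total Procrustes variance, retained
#' plus discarded dimensions.
#'
#' @param fit a \code{qtl_fit}.
#' @param Y the n x q phenotype matrix the model was fit on.
#' @param covariates the covariate data.frame used in the fit (NULL if none).
#' @param pca optional \code{\link{pca_reduce}} result behind \code{Y}.
#' @param k,d landmark count and dimension when \code{pca} is not given.
#' @return data.frame with one row per QTL: chr, pos, norm, pct_sst,
#'   pct_ss_proj, expected_h2 and frac_1..frac_d; attributes \code{v}
#'   (n x #QTL projection scores) and \code{B_coord} (coordinate-space effect
#'   rows).
#' @export
effect_summaries <- function(fit, Y, covariates = NULL, pca = NULL,
                             k = NULL, d = NULL) {
  nq <- nrow(fit$qtl)
  if (nq == 0L) stop("model has no QTL")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (!is.null(pca)) {
    B_coord <- fit$B %*% t(pca$rotation)
    k <- pca$k; d <- pca$d
    total_ss <- pca$total_variance * (n - 1)
  } else {
    B_coord <- fit$B
    if (is.null(d)) d <- ncol(B_coord) %/% if (is.null(k)) 1L else k
    total_ss <- sum(sweep(Y, 2L, colMeans(Y))^2)
  }
  norms <- sqrt(rowSums(B_coord^2))
  if (any(norms == 0)) stop("zero-norm QTL effect")
  X0 <- if (is.null(covariates)) matrix(1, n, 1L) else covariate_design(covariates)
  X <- cbind(X0, fit$dosages)
  pct_sst <- pct_proj <- exp_h2 <- numeric(nq)
  v <- matrix(0, n, nq)
  fracs <- matrix(0, nq, d)
  for (j in seq_len(nq)) {
    jq <- ncol(X0) + j
    ## type-III SS trace of QTL j: squared norm of Y residualized on the
    ## other columns, projected on the residualized dosage direction
    qx_ <- qr(X[, -jq, drop = FALSE])
    rj <- qr.resid(qx_, X[, jq])
    nr <- sqrt(sum(rj^2))
    hj <- crossprod(qr.resid(qx_, Y), rj / nr)
    pct_sst[j] <- 100 * sum(hj^2) / total_ss
    ## projection scores in the beta_j direction, on the covariate-adjusted
    ## phenotype (QTL + residual components), matching the h2 expectation
    bdir_pc <- fit$B[j, ] / norms[j]
    vj <- as.numeric((fit$dosages %*% fit$B + fit$resid) %*% bdir_pc)
    v[, j] <- vj
    ## variance of E(v | p_j): fitted dosage component of the full model
    fitted_j <- fit$dosages[, j] * norms[j]
    pct_proj[j] <- 100 * stats::var(fitted_j) / stats::var(vj)
    exp_h2[j] <- expected_h2(fit$B[j, ], fit$B, fit$S)
    fracs[j, ] <- plane_decomposition(B_coord[j, ], k = k, d = d)
  }
  out <- data.frame(chr = fit$qtl$chr, pos = fit$qtl$pos, norm = norms,
                    pct_sst = pct_sst, pct_ss_proj = pct_proj,
                    expected_h2 = exp_h2, stringsAsFactors = FALSE)
  colnames(fracs) <- paste0("frac_", seq_len(d))
  out <- cbind(out, fracs)
  attr(out, "v") <- v
  attr(out, "B_coord") <- B_coord
  out
}
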