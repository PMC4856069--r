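#' Single-QTL genome scan with Pillai's trace LOD scores
#'
#' At every grid position the expected AB dosage (Haley-Knott regression
#' column) is added to the design holding the covariates and any already-fit
#' QTL fixed. Two LOD scales are reported for the added term: \code{lod},
#' the -log10 p-value of its Pillai's trace (the inference scale; at q = 1 it
#' reduces exactly to the univariate F-scan), and \code{lod_lr}, the
#' multivariate likelihood-ratio LOD (n/2) log10(|E_red| / |E_full|) =
#' -(n/2) log10(1 - V), the scale on which model-selection penalties add (at
#' q = 1 it is the classic Haley-Knott LOD). The two are monotone transforms
#' of each other at fixed residual df, so peak positions and permutation
#' exceedances agree. Grid positions within \code{skip_window} cM of a fixed
#' QTL on the same chromosome are skipped (NA).
#'
#' @param Y n x q phenotype scores (e.g. from \code{\link{pca_reduce}}).
#' @param covariates covariate data.frame (NULL for none).
#' @param probs \code{genoprob} object.
#' @param fixed_qtl optional data.frame(chr, pos) of QTL kept in the model.
#' @param skip_window cM exclusion radius around fixed QTL.
#' @return \code{scan_profile}: data.frame with chr, pos, lod (attributes
#'   \code{df}: q, df_h, df_e).
#' @export
qtl_scan <- function(Y, covariates, probs, fixed_qtl = NULL, skip_window = 10) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X0 <- if (is.null(covariates)) matrix(1, n, 1L) else covariate_design(covariates)
  if (!is.null(fixed_qtl) && nrow(fixed_qtl) > 0L)
    for (j in seq_len(nrow(fixed_qtl)))
      X0 <- cbind(X0, dosage(probs, fixed_qtl$chr[j], fixed_qtl$pos[j]))
  q <- ncol(Y)
  qx <- qr(X0)
  Yr <- qr.resid(qx, Y)
  Ered <- crossprod(Yr)
  Rch <- chol(Ered)
  df_e <- n - qx$rank - 1L
  if (df_e <= q) stop("too few residual df for ", q, " dimensions; reduce Y first")
  out <- list()
  for (ch in names(probs)) {
    pr <- probs[[ch]]
    D <- qr.resid(qx, pr$prob)
    nrm <- sqrt(colSums(D^2))
    ok <- nrm > 1e-8
    Dn <- D
    Dn[, ok] <- sweep(D[, ok, drop = FALSE], 2L, nrm[ok], "/")
    h <- crossprod(Yr, Dn)                        # q x npos
    Z <- forwardsolve(t(Rch), h)
    V <- colSums(Z^2)
    lod <- rep(0, length(V)); lod_lr <- rep(0, length(V))
    pf_ <- pillai_f_vec(V[ok], q, df_e)
    lod[ok] <- -log10(pf_$p)
    lod_lr[ok] <- -(n / 2) * log10(pmax(1 - V[ok], .Machine$double.eps))
    if (!is.null(fixed_qtl) && nrow(fixed_qtl) > 0L) {
      same <- fixed_qtl$chr == ch
      if (any(same))
        for (p0 in fixed_qtl$pos[same]) {
          lod[abs(pr$pos - p0) < skip_window] <- NA_real_
          lod_lr[abs(pr$pos - p0) < skip_window] <- NA_real_
        }
    }
    out[[ch]] <- data.frame(chr = ch, pos = unname(pr$pos), lod = lod,
                            lod_lr = lod_lr, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, df = c(q = q, df_h = 1, df_e = df_e), class = c("scan_profile", "data.frame"))
}

## vectorized single-df Pillai F approximation
pillai_f_vec <- function(V, q, df_e) {
  s <- 1
  m <- (q - 2) / 2
  nn <- (df_e - q - 1) / 2
  V <- pmin(pmax(V, 0), 1 - 1e-12)
  Fstat <- (2 * nn + 2) / (2 * m + 2) * V / (1 - V)
  df1 <- 2 * m + 2
  df2 <- 2 * nn + 2
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Genome-wide maximum LOD of a scan
#' @param profile a \code{scan_profile}.
#' @param stat which LOD column to maximize ("pillai" = -log10 p, "lr" =
#'   likelihood-ratio LOD); the argmax position is the same for both.
#' @return list with \code{lod}, \code{chr}, \code{pos} of the maximum
#'   (deterministic tie-break: first chromosome, then lowest position).
#' @export
scan_max <- function(profile, stat = c("pillai", "lr")) {
  stat <- match.arg(stat)
  v <- if (stat == "lr") profile$lod_lr else profile$lod
  i <- which.max(v)
  list(lod = v[i], chr = profile$chr[i], pos = profile$pos[i])
}

#' Permutation threshold for the genome-wide scan
#'
#' Estimates the per-QTL penalty T: rows of the covariate-adjusted phenotype
#' residuals are permuted against the genotype block \code{n_perm} times, a
#' single-QTL genome scan is run for each permutation, and T is the
#' (1 - alpha) quantile of the genome-wide maximum LODs.
#'
#' @param Y n x q phenotype scores.
#' @param covariates covariate data.frame (NULL for none).
#' @param probs \code{genoprob} object.
#' @param n_perm number of permutations (1000 in the canonical protocol).
#' @param alpha genome-wide type-I error target.
#' @param seed integer seed.
#' @param stat LOD scale of the threshold: "lr" (likelihood-ratio LOD, the
#'   scale the model-search penalty needs) or "pillai" (-log10 Pillai p).
#'   Both are monotone in the scan statistic, so exceedance events agree.
#' @return numeric T, with attribute \code{max_lods} (the permutation draws).
#' @export
perm_threshold <- function(Y, covariates, probs, n_perm = 1000L, alpha = 0.05,
                           seed = 1L, stat = c("lr", "pillai")) {
  stat <- match.arg(stat)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X0 <- if (is.null(covariates)) matrix(1, n, 1L) else covariate_design(covariates)
  Yr <- qr.resid(qr(X0), Y)
  q <- ncol(Y)
  E0 <- crossprod(Yr)
  W <- Yr %*% solve(chol(E0))      # n x q; V = || t(W[perm,]) %*% r ||^2
  ## centered unit-norm dosage columns, all chromosomes
  Rmat <- do.call(cbind, lapply(probs, function(pr) {
    D <- sweep(pr$prob, 2L, colMeans(pr$prob))
    nrm <- sqrt(colSums(D^2))
    keep <- nrm > 1e-8
    sweep(D[, keep, drop = FALSE], 2L, nrm[keep], "/")
  }))
  df_e <- n - 2L
  if (df_e <= q) stop("too few residual df for ", q, " dimensions")
  set.seed(seed)
  maxlod <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    V <- colSums(crossprod(W[perm, , drop = FALSE], Rmat)^2)
    maxlod[b] <- if (stat == "lr")
      max(-(n / 2) * log10(pmax(1 - V, .Machine$double.eps)))
    else max(-log10(pillai_f_vec(V, q, df_e)$p))
  }
  T_ <- unname(stats::quantile(maxlod, 1 - alpha, type = 7))
  attr(T_, "max_lods") <- maxlod
  T_
}
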