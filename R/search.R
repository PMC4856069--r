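#' Fit a multiple-QTL model at fixed positions
#'
#' Multivariate least squares of the phenotype scores on intercept,
#' covariates and the expected dosage at each QTL. The model LOD is the
#' multivariate likelihood-ratio LOD against the covariate-only model,
#' (n/2) log10(|E_cov| / |E_full|); it decomposes exactly over nested
#' additions, so pLOD = LOD - T |model| rises under an addition precisely
#' when the added QTL's conditional LOD exceeds the permutation penalty T.
#' Per QTL, both the conditional (drop-one) likelihood-ratio LOD
#' (\code{lod}) and the Pillai's trace with its -log10 p
#' (\code{pillai}, \code{lod_p}) are reported; the joint Pillai test of the
#' whole QTL block is \code{lod_joint}.
#'
#' @param Y n x q phenotype scores.
#' @param covariates covariate data.frame (NULL for none).
#' @param probs \code{genoprob}.
#' @param qtl data.frame(chr, pos) of QTL positions (0 rows for the
#'   covariate-only model).
#' @param T_penalty permutation penalty per QTL (see
#'   \code{\link{perm_threshold}}).
#' @return object of class \code{"qtl_fit"}: list with \code{qtl} (data.frame
#'   chr, pos, lod, pillai), \code{B} (#QTL x q effect rows), \code{coef_cov},
#'   \code{S} (q x q residual covariance), \code{E}, \code{df_e},
#'   \code{lod}, \code{plod}, \code{dosages} (n x #QTL), \code{n}.
#' @export
fit_qtl_model <- function(Y, covariates, probs, qtl, T_penalty = 0) {
  Y <- as.matrix(Y)
  n <- nrow(Y); q <- ncol(Y)
  X0 <- if (is.null(covariates)) matrix(1, n, 1L) else covariate_design(covariates)
  nq <- if (is.null(qtl)) 0L else nrow(qtl)
  D <- matrix(0, n, nq)
  if (nq > 0L) {
    for (j in seq_len(nq)) {
      dj <- dosage(probs, qtl$chr[j], qtl$pos[j])
      qtl$pos[j] <- attr(dj, "pos")          # snap to grid
      D[, j] <- dj
    }
    colnames(D) <- sprintf("q%s@%.1f", qtl$chr, qtl$pos)
  }
  X <- cbind(X0, D)
  full <- fit_mlm(Y, X)
  if (full$df_e <= q) stop("too few residual df for ", q, " dimensions")
  ldet <- function(E) 2 * sum(log(diag(chol(E))))
  lod <- 0; lod_joint <- 0
  qlod <- numeric(0); qlod_p <- numeric(0); qpillai <- numeric(0)
  if (nq > 0L) {
    ld_full <- ldet(full$E)
    red0 <- fit_mlm(Y, X0)
    lod <- (n / 2) * (ldet(red0$E) - ld_full) / log(10)
    Hb <- red0$E - full$E
    Vb <- sum(diag(Hb %*% solve(red0$E)))
    lod_joint <- -log10(pillai_f(Vb, q, nq, full$df_e)$p)
    for (j in seq_len(nq)) {
      redj <- fit_mlm(Y, X[, -(ncol(X0) + j), drop = FALSE])
      qlod[j] <- (n / 2) * (ldet(redj$E) - ld_full) / log(10)
      Hj <- redj$E - full$E
      Vj <- sum(diag(Hj %*% solve(redj$E)))
      pfj <- pillai_f(Vj, q, 1L, full$df_e)
      qlod_p[j] <- -log10(pfj$p)
      qpillai[j] <- pfj$pillai
    }
  }
  B <- if (nq > 0L) full$coef[ncol(X0) + seq_len(nq), , drop = FALSE] else
    matrix(0, 0L, q)
  qtl_out <- if (nq > 0L)
    data.frame(chr = qtl$chr, pos = qtl$pos, lod = qlod, lod_p = qlod_p,
               pillai = qpillai, stringsAsFactors = FALSE)
  else data.frame(chr = character(0), pos = numeric(0), lod = numeric(0),
                  lod_p = numeric(0), pillai = numeric(0))
  structure(list(qtl = qtl_out, B = B,
                 coef_cov = full$coef[seq_len(ncol(X0)), , drop = FALSE],
                 S = full$E / full$df_e, E = full$E, df_e = full$df_e,
                 lod = lod, lod_joint = lod_joint,
                 plod = lod - T_penalty * nq, T_penalty = T_penalty,
                 dosages = D, n = n, resid = full$resid),
            class = "qtl_fit")
}

#' @export
print.qtl_fit <- function(x, ...) {
  cat(sprintf("multiple-QTL fit: %d QTL, LOD %.2f, pLOD %.2f (T = %.2f)\n",
              nrow(x$qtl), x$lod, x$plod, x$T_penalty))
  if (nrow(x$qtl)) print(x$qtl, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bayes credible interval from a LOD profile
#'
#' Normalizes 10^LOD over the grid positions of one chromosome into a
#' discrete density and returns the span of the smallest highest-density set
#' of positions reaching the requested coverage, together with the peak.
#'
#' @param profile data.frame with \code{pos} and \code{lod} (one chromosome).
#' @param coverage target probability mass (default 0.95).
#' @return list with \code{left}, \code{peak}, \code{right} (cM) and
#'   \code{flat} (TRUE when the profile carried no information and the whole
#'   chromosome is returned).
#' @export
bayes_interval <- function(profile, coverage = 0.95) {
  pos <- profile$pos; lod <- profile$lod
  keep <- !is.na(lod)
  pos <- pos[keep]; lod <- lod[keep]
  if (length(pos) == 0L) stop("empty profile")
  w <- 10^(lod - max(lod))
  p <- w / sum(w)
  flat <- diff(range(lod)) < 1e-9
  if (flat)
    return(list(left = min(pos), peak = pos[which.max(lod)], right = max(pos),
                flat = TRUE))
  o <- order(p, decreasing = TRUE)
  ncov <- which(cumsum(p[o]) >= coverage - 1e-12)[1L]
  sel <- o[seq_len(ncov)]
  list(left = min(pos[sel]), peak = pos[which.max(lod)],
       right = max(pos[sel]), flat = FALSE)
}

## profile one QTL's chromosome holding the others fixed; returns profile +
## argmax (positions near other same-chromosome QTL excluded)
profile_qtl <- function(Y, covariates, probs, qtl, j, skip_window = 10) {
  others <- qtl[-j, , drop = FALSE]
  prof <- qtl_scan(Y, covariates, probs, fixed_qtl = others,
                   skip_window = skip_window)
  prof[prof$chr == qtl$chr[j], , drop = FALSE]
}

#' Forward/backward multiple-QTL model search
#'
#' Builds a multiple-QTL model by penalized-LOD search: repeatedly add the
#' genome-wide best QTL given the current model, refine each QTL position by
#' profile scans holding the others fixed (iterated to stability), and drop
#' any QTL whose removal raises the penalized LOD pLOD = LOD - T|model|;
#' every visited model is recorded and the best visited model is returned.
#' LOD here is the multivariate likelihood-ratio model LOD (see
#' \code{\link{fit_qtl_model}}), so a QTL survives exactly when its
#' conditional LOD exceeds T; supply a T from \code{\link{perm_threshold}}
#' with \code{stat = "lr"}. Additive QTL only; two QTL on one chromosome are
#' kept at least \code{min_sep} cM apart. Ties are broken toward the lower
#' chromosome index, then the lower position, so the search is
#' deterministic.
#'
#' @param Y n x q phenotype scores.
#' @param covariates covariate data.frame (NULL for none).
#' @param probs \code{genoprob}.
#' @param T_penalty permutation penalty per QTL.
#' @param max_qtl forward-search cap on model size.
#' @param min_sep minimum same-chromosome QTL separation (cM).
#' @param patience stop after this many consecutive additions without
#'   improving the best pLOD.
#' @param refine_iter maximum position-refinement sweeps per step.
#' @param coverage Bayes interval coverage for the returned QTL.
#' @return the best \code{qtl_fit}, augmented with \code{ci} (data.frame
#'   chr, pos, left, right), \code{profiles} (per-QTL LOD profiles) and
#'   \code{visited} (data.frame n_qtl, lod, plod of every visited model).
#' @export
forward_backward_search <- function(Y, covariates, probs, T_penalty,
                                    max_qtl = 50L, min_sep = 10,
                                    patience = 6L, refine_iter = 3L,
                                    coverage = 0.95) {
  qtl <- data.frame(chr = character(0), pos = numeric(0), stringsAsFactors = FALSE)
  fit0 <- fit_qtl_model(Y, covariates, probs, qtl, T_penalty)
  visited <- list(list(qtl = qtl, lod = fit0$lod, plod = fit0$plod))
  best_plod <- fit0$plod; best_qtl <- qtl
  no_improve <- 0L
  refine <- function(qtl) {
    if (nrow(qtl) < 2L) return(qtl)
    for (sweep_i in seq_len(refine_iter)) {
      moved <- FALSE
      for (j in seq_len(nrow(qtl))) {
        prof <- profile_qtl(Y, covariates, probs, qtl, j, min_sep)
        if (all(is.na(prof$lod_lr))) next
        i <- which.max(prof$lod_lr)
        if (abs(prof$pos[i] - qtl$pos[j]) > 1e-9) {
          qtl$pos[j] <- prof$pos[i]
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    qtl
  }
  record <- function(qtl) {
    fit <- fit_qtl_model(Y, covariates, probs, qtl, T_penalty)
    visited[[length(visited) + 1L]] <<- list(qtl = qtl, lod = fit$lod, plod = fit$plod)
    if (fit$plod > best_plod + 1e-12) {
      best_plod <<- fit$plod; best_qtl <<- qtl
      TRUE
    } else FALSE
  }
  while (nrow(qtl) < max_qtl) {
    qtl_before <- qtl
    prof <- qtl_scan(Y, covariates, probs, fixed_qtl = qtl, skip_window = min_sep)
    if (all(is.na(prof$lod_lr) | prof$lod_lr <= 0)) break
    mx <- scan_max(prof, stat = "lr")
    qtl <- rbind(qtl, data.frame(chr = mx$chr, pos = mx$pos, stringsAsFactors = FALSE))
    qtl <- refine(qtl)
    improved <- record(qtl)
    ## backward drops while they help
    repeat {
      if (nrow(qtl) < 1L) break
      drop_plods <- vapply(seq_len(nrow(qtl)), function(j)
        fit_qtl_model(Y, covariates, probs, qtl[-j, , drop = FALSE], T_penalty)$plod,
        0)
      cur <- fit_qtl_model(Y, covariates, probs, qtl, T_penalty)$plod
      jbest <- which.max(drop_plods)
      if (drop_plods[jbest] > cur + 1e-12) {
        qtl <- refine(qtl[-jbest, , drop = FALSE])
        improved <- record(qtl) || improved
      } else break
    }
    no_improve <- if (improved) 0L else no_improve + 1L
    if (no_improve >= patience) break
    ## add+drop cycle: the drop phase undid the addition and nothing improved
    if (!improved && identical(qtl, qtl_before)) break
  }
  final <- fit_qtl_model(Y, covariates, probs, best_qtl, T_penalty)
  ## per-QTL profiles and Bayes intervals on the final model
  profiles <- list(); ci <- NULL
  if (nrow(final$qtl) > 0L) {
    ci <- final$qtl[, c("chr", "pos")]
    ci$left <- NA_real_; ci$right <- NA_real_
    for (j in seq_len(nrow(final$qtl))) {
      prof <- profile_qtl(Y, covariates, probs, final$qtl, j, min_sep)
      profiles[[j]] <- prof
      ## interval from the 10^LOD profile on the likelihood-ratio scale
      bi <- bayes_interval(data.frame(pos = prof$pos, lod = prof$lod_lr),
                           coverage)
      ci$left[j] <- bi$left; ci$right[j] <- bi$right
    }
  }
  final$ci <- ci
  final$profiles <- profiles
  final$visited <- data.frame(
    n_qtl = vapply(visited, function(v) nrow(v$qtl), 0L),
    lod = vapply(visited, function(v) v$lod, 0),
    plod = vapply(visited, function(v) v$plod, 0))
  final
}
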