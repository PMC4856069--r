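## Pillai's trace F approximation: V = tr(H (H + E)^-1), with
## s = min(q, df_h), m = (|q - df_h| - 1)/2, n* = (df_e - q - 1)/2,
## F = (2n* + s + 1)/(2m + s + 1) * V/(s - V),
## df = (s(2m + s + 1), s(2n* + s + 1))
pillai_f <- function(V, q, df_h, df_e) {
  s <- min(q, df_h)
  m <- (abs(q - df_h) - 1) / 2
  nn <- (df_e - q - 1) / 2
  V <- min(max(V, 0), s - 1e-12)
  Fstat <- (2 * nn + s + 1) / (2 * m + s + 1) * V / (s - V)
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  list(pillai = V, F = Fstat, df1 = df1, df2 = df2, p = p)
}

## multivariate least squares via QR; errors on rank deficiency
fit_mlm <- function(Y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased columns: ", paste(aliased, collapse = ", "))
  }
  coef <- qr.coef(qx, Y)
  resid <- qr.resid(qx, Y)
  E <- crossprod(resid)
  list(qr = qx, coef = coef, resid = resid, E = E, df_e = nrow(Y) - qx$rank)
}

#' Multivariate covariate model with Pillai's trace tests
#'
#' Fits shape scores on the study covariates by multivariate least squares
#' and reports, for every model term, a type-III Pillai's trace (the SSCP of
#' the term given all others), its F approximation and p-value, and the
#' percentage of the total sum of squares attributable to the term
#' (tr(H_term) / tr(total SSCP) x 100).
#'
#' @param Y n x q score or coordinate matrix.
#' @param covariates data.frame of covariates (columns other than \code{id}
#'   are used).
#' @param formula optional model formula over \code{covariates} (default: all
#'   main effects).
#' @param interactions when TRUE and no formula is given, adds all pairwise
#'   interactions.
#' @return object of class \code{"covariate_fit"}: list with \code{terms}
#'   (data.frame: term, df, pillai, F, df1, df2, p, pct_ss), \code{coef},
#'   \code{E}, \code{S} (residual covariance), \code{df_e}, \code{design}.
#' @export
fit_covariates <- function(Y, covariates, formula = NULL, interactions = FALSE) {
  Y <- as.matrix(Y)
  cv <- covariates[, setdiff(names(covariates), "id"), drop = FALSE]
  if (is.null(formula))
    formula <- if (interactions) ~ .^2 else ~ .
  X <- stats::model.matrix(formula, data = cv)
  if (nrow(X) != nrow(Y)) stop("covariates and Y row counts differ")
  asgn <- attr(X, "assign")
  full <- fit_mlm(Y, X)
  q <- ncol(Y)
  if (full$df_e <= q) stop("too few residual df for ", q,
                           " phenotype dimensions; reduce with pca_reduce()")
  Tss <- crossprod(sweep(Y, 2L, colMeans(Y)))
  trT <- sum(diag(Tss))
  labs <- attr(stats::terms(formula, data = cv), "term.labels")
  rows <- lapply(seq_along(labs), function(ti) {
    cols <- which(asgn == ti)
    Xr <- X[, asgn != ti, drop = FALSE]
    red <- fit_mlm(Y, Xr)
    H <- red$E - full$E
    V <- sum(diag(H %*% solve(red$E)))
    pf_ <- pillai_f(V, q, length(cols), full$df_e)
    data.frame(term = labs[ti], df = length(cols), pillai = pf_$pillai,
               F = pf_$F, df1 = pf_$df1, df2 = pf_$df2, p = pf_$p,
               pct_ss = 100 * sum(diag(H)) / trT, stringsAsFactors = FALSE)
  })
  structure(list(terms = do.call(rbind, rows), coef = full$coef, E = full$E,
                 S = full$E / full$df_e, df_e = full$df_e, design = X,
                 resid = full$resid, total_ss = trT),
            class = "covariate_fit")
}

#' @export
print.covariate_fit <- function(x, ...) {
  cat("Multivariate covariate fit (Pillai's trace, type III):\n")
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}

## covariate design matrix used throughout mapping (main effects, intercept)
covariate_design <- function(covariates) {
  cv <- covariates[, setdiff(names(covariates), "id"), drop = FALSE]
  stats::model.matrix(~ ., data = cv)
}
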