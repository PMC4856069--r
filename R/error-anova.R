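#' Procrustes ANOVA for digitization (measurement) error
#'
#' Two digitization sessions of the same specimens are superimposed jointly,
#' then a two-way Procrustes ANOVA (specimen as random factor, session as
#' fixed factor) is run on the aligned coordinates, with degrees of freedom
#' multiplied by the shape-space dimension (2k - 4 in 2D, 3k - 7 in 3D). The
#' session F statistic tests for systematic inter-session differences; the
#' percentage of measurement error is the within-specimen variance component
#' over the total (within + among) variance, overall and per landmark.
#'
#' @param session1,session2 \code{landmark_sample}s of the same specimens and
#'   landmarks (matched by specimen id).
#' @return list with \code{F}, \code{df}, \code{p} for the session effect,
#'   \code{pct_me} (overall percentage of measurement error), and
#'   \code{pct_me_landmark} (per landmark).
#' @export
measurement_error_anova <- function(session1, session2) {
  if (!identical(dim(session1), dim(session2)))
    stop("sessions must have identical landmark and specimen structure")
  ids1 <- attr(session1, "ids"); ids2 <- attr(session2, "ids")
  if (!setequal(ids1, ids2)) stop("mismatched specimen ids between sessions")
  session2 <- session2[, , match(ids1, ids2), drop = FALSE]
  k <- dim(session1)[1L]; d <- dim(session1)[2L]; n <- dim(session1)[3L]
  both <- array(c(session1, session2), c(k, d, 2L * n))
  g <- gpa(landmark_sample(both))
  Y <- vec_coords(unclass(g$aligned))           # 2n x kd
  q <- k * d - d - d * (d - 1) / 2 - 1          # shape-space dimension
  y1 <- Y[seq_len(n), , drop = FALSE]
  y2 <- Y[n + seq_len(n), , drop = FALSE]
  spec_mean <- (y1 + y2) / 2
  sess_mean <- rbind(colMeans(y1), colMeans(y2))
  grand <- colMeans(Y)
  s <- 2L                                        # number of sessions
  ss_spec <- s * sum(sweep(spec_mean, 2L, grand)^2)
  ss_sess <- n * sum(sweep(sess_mean, 2L, grand)^2)
  resid1 <- y1 - spec_mean - matrix(sess_mean[1L, ], n, ncol(Y), byrow = TRUE) +
    matrix(grand, n, ncol(Y), byrow = TRUE)
  resid2 <- y2 - spec_mean - matrix(sess_mean[2L, ], n, ncol(Y), byrow = TRUE) +
    matrix(grand, n, ncol(Y), byrow = TRUE)
  ss_int <- sum(resid1^2) + sum(resid2^2)
  df_sess <- (s - 1L) * q
  df_int <- (n - 1L) * (s - 1L) * q
  ms_sess <- ss_sess / df_sess
  ms_int <- ss_int / df_int
  Fstat <- ms_sess / ms_int
  p <- stats::pf(Fstat, df_sess, df_int, lower.tail = FALSE)
  ## variance components: within = deviation from specimen means (session +
  ## interaction pooled), among = specimen component
  ss_within <- sum((y1 - spec_mean)^2) + sum((y2 - spec_mean)^2)
  df_within <- n * (s - 1L) * q
  df_among <- (n - 1L) * q
  ms_within <- ss_within / df_within
  ms_among <- ss_spec / df_among
  s2_within <- ms_within
  s2_among <- max((ms_among - ms_within) / s, 0)
  pct_me <- if (s2_within + s2_among == 0) 0 else
    100 * s2_within / (s2_within + s2_among)
  ## per landmark: same decomposition on each landmark's d coordinates
  pct_lm <- numeric(k)
  for (l in seq_len(k)) {
    cols <- l + (seq_len(d) - 1L) * k            # coordinate-major layout
    w <- (sum((y1[, cols] - spec_mean[, cols])^2) +
            sum((y2[, cols] - spec_mean[, cols])^2)) / (n * (s - 1L) * d)
    amg <- s * sum(sweep(spec_mean[, cols, drop = FALSE], 2L,
                         grand[cols])^2) / ((n - 1L) * d)
    s2w <- w; s2a <- max((amg - w) / s, 0)
    pct_lm[l] <- if (s2w + s2a == 0) 0 else 100 * s2w / (s2w + s2a)
  }
  names(pct_lm) <- attr(session1, "labels")
  list(F = Fstat, df = c(df_sess, df_int), p = p,
       pct_me = pct_me, pct_me_landmark = pct_lm)
}

#' Principal-component reduction of aligned shapes
#'
#' Eigendecomposition of the covariance of the vectorized Procrustes-aligned
#' coordinates, retaining the smallest leading set of components reaching a
#' requested fraction of the total variance. Mapping is performed in this
#' reduced orthonormal basis; effects can be rotated back to coordinate space
#' with the returned rotation.
#'
#' @param gpa_result a \code{\link{gpa}} result (or a \code{landmark_sample}
#'   of aligned shapes).
#' @param variance_fraction fraction of total variance to retain, in (0, 1].
#' @return list with \code{scores} (n x q), \code{rotation} (kd x q,
#'   orthonormal columns), \code{eigenvalues} (all nonzero), \code{center}
#'   (mean vector), \code{total_variance}, \code{retained} (q), \code{k},
#'   \code{d}.
#' @export
pca_reduce <- function(gpa_result, variance_fraction = 0.95) {
  if (variance_fraction <= 0 || variance_fraction > 1)
    stop("variance_fraction must be in (0, 1]")
  arr <- if (inherits(gpa_result, "gpa")) unclass(gpa_result$aligned) else unclass(gpa_result)
  k <- dim(arr)[1L]; d <- dim(arr)[2L]
  Y <- vec_coords(arr)
  n <- nrow(Y)
  pc <- stats::prcomp(Y, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  nz <- ev > max(ev) * 1e-12
  ev <- ev[nz]
  cum <- cumsum(ev) / sum(ev)
  q <- which(cum >= variance_fraction - 1e-12)[1L]
  list(scores = pc$x[, seq_len(q), drop = FALSE],
       rotation = pc$rotation[, seq_len(q), drop = FALSE],
       eigenvalues = ev, center = pc$center,
       total_variance = sum(ev), retained = q, k = k, d = d)
}
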