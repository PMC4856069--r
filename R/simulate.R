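#' Genetic map specification
#'
#' A map is a named list of chromosomes, each a named numeric vector of
#' strictly increasing marker positions in centimorgans.
#'
#' @param chromosomes named numeric vector of chromosome lengths (cM).
#' @param spacing marker spacing in cM (first marker at 0, last at the
#'   chromosome end).
#' @return a map: list of named position vectors, class \code{"genetic_map"}.
#' @export
sim_map <- function(chromosomes, spacing = 10) {
  if (length(chromosomes) == 0L || any(chromosomes <= 0))
    stop("chromosome lengths must be positive")
  if (is.null(names(chromosomes))) names(chromosomes) <- as.character(seq_along(chromosomes))
  out <- lapply(seq_along(chromosomes), function(i) {
    len <- chromosomes[[i]]
    pos <- unique(c(seq(0, len, by = spacing), len))
    names(pos) <- sprintf("c%s_m%d", names(chromosomes)[i], seq_along(pos))
    pos
  })
  names(out) <- names(chromosomes)
  structure(out, class = "genetic_map")
}

#' Haldane map function
#'
#' Recombination fraction for a map distance of d centimorgans under no
#' interference: r = (1 - exp(-2d/100)) / 2.
#'
#' @param d map distance in cM (non-negative, vectorized).
#' @return recombination fraction in [0, 0.5).
#' @export
haldane <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

## inverse Haldane: cM for a recombination fraction
haldane_inv <- function(r) -50 * log(1 - 2 * r)

#' Simulate backcross genotypes
#'
#' Generates N2 backcross genotypes (classes AA and AB, dosage coding
#' AA = 0 / AB = 1) along each chromosome by a two-state Markov chain with
#' Haldane recombination fractions between adjacent markers and no
#' interference; the marginal P(AB) is 0.5 at every locus. Observed genotypes
#' are then flipped with probability \code{geno_error} and masked (set
#' missing) with probability \code{missing_rate}.
#'
#' @param map a \code{genetic_map} (see \code{\link{sim_map}}).
#' @param n number of individuals (>= 1).
#' @param seed integer seed.
#' @param geno_error per-genotype error (flip) probability in [0, 1).
#' @param missing_rate per-genotype missingness probability in [0, 1).
#' @return a cross object (class \code{"bc_cross"}): list with \code{map},
#'   \code{geno} (list per chromosome of n x m integer matrices, 0 = AA,
#'   1 = AB, NA = missing), \code{truth} (the error-free genotypes) and
#'   \code{pheno} (NULL until \code{\link{simulate_shapes}} fills it).
#' @export
simulate_backcross <- function(map, n, seed = 1L, geno_error = 0,
                               missing_rate = 0) {
  if (length(map) == 0L) stop("empty map")
  if (n < 1L) stop("n must be >= 1")
  if (geno_error < 0 || geno_error >= 1 || missing_rate < 0 || missing_rate >= 1)
    stop("rates must be in [0, 1)")
  set.seed(seed)
  truth <- list(); obs <- list()
  for (ch in names(map)) {
    pos <- map[[ch]]
    m <- length(pos)
    g <- matrix(0L, n, m, dimnames = list(NULL, names(pos)))
    g[, 1L] <- stats::rbinom(n, 1L, 0.5)
    if (m > 1L) {
      r <- haldane(diff(pos))
      for (j in 2:m) {
        swap <- stats::rbinom(n, 1L, r[j - 1L])
        g[, j] <- ifelse(swap == 1L, 1L - g[, j - 1L], g[, j - 1L])
      }
    }
    truth[[ch]] <- g
    go <- g
    if (geno_error > 0) {
      flip <- matrix(stats::rbinom(n * m, 1L, geno_error), n, m) == 1L
      go[flip] <- 1L - go[flip]
    }
    if (missing_rate > 0) {
      miss <- matrix(stats::rbinom(n * m, 1L, missing_rate), n, m) == 1L
      go[miss] <- NA_integer_
    }
    obs[[ch]] <- go
  }
  structure(list(map = map, geno = obs, truth = truth, pheno = NULL),
            class = "bc_cross")
}

#' @export
print.bc_cross <- function(x, ...) {
  nm <- sum(vapply(x$map, length, 0L))
  n <- nrow(x$geno[[1L]])
  cat(sprintf("backcross: %d individuals, %d chromosomes, %d markers%s\n",
              n, length(x$map), nm,
              if (is.null(x$pheno)) "" else ", phenotyped"))
  invisible(x)
}

#' Simulation truth for shape phenotypes
#'
#' Bundles the generative model for \code{\link{simulate_shapes}}: a mean
#' shape, additive QTL effect vectors (the heterozygote-minus-homozygote mean
#' shape difference, in Procrustes units), covariate effect vectors, and the
#' individual error covariance of the vectorized coordinates.
#'
#' @param mean_shape k x d matrix (unit centroid size recommended).
#' @param qtl data.frame with columns \code{chr}, \code{pos}; one row per QTL.
#' @param beta (#QTL) x (k*d) matrix of additive effects (coordinate-major
#'   vectorization), or NULL for no QTL.
#' @param covariate_effects list with optional (k*d)-vectors \code{size},
#'   \code{sex}, \code{cross_direction}.
#' @param error_cov either a (k*d) x (k*d) PSD matrix, a single variance (for
#'   isotropic error), or a (k*d)-vector of variances (diagonal error).
#' @param error_structure one of "isotropic", "diagonal", "matrix" (inferred
#'   from \code{error_cov} when not given).
#' @return list of class \code{"sim_truth"}.
#' @export
sim_truth <- function(mean_shape, qtl = NULL, beta = NULL,
                      covariate_effects = list(), error_cov = 0) {
  mean_shape <- as.matrix(mean_shape)
  kd <- length(mean_shape)
  if (!is.null(beta)) {
    beta <- rbind(beta)
    if (ncol(beta) != kd) stop("beta columns must equal k*d")
    if (is.null(qtl) || nrow(qtl) != nrow(beta)) stop("qtl rows must match beta rows")
    if (any(sqrt(rowSums(beta^2)) == 0)) stop("QTL effects must have positive norm")
  }
  if (is.matrix(error_cov)) {
    if (!isTRUE(all.equal(error_cov, t(error_cov), tolerance = 1e-8)))
      stop("error_cov must be symmetric")
    ev <- eigen(error_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) stop("error_cov must be PSD")
  } else if (length(error_cov) == 1L) {
    if (error_cov < 0) stop("error variance must be >= 0")
  } else if (length(error_cov) == kd) {
    if (any(error_cov < 0)) stop("error variances must be >= 0")
  } else stop("error_cov must be scalar, length k*d, or (k*d) x (k*d)")
  for (nm in names(covariate_effects))
    if (length(covariate_effects[[nm]]) != kd)
      stop("covariate effect vectors must have length k*d")
  structure(list(mean_shape = mean_shape, qtl = qtl, beta = beta,
                 covariate_effects = covariate_effects, error_cov = error_cov),
            class = "sim_truth")
}

## error draw: n x kd matrix from the truth's error model
draw_error <- function(truth, n, kd) {
  ec <- truth$error_cov
  if (is.matrix(ec)) {
    ev <- eigen(ec, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), kd)
    matrix(stats::rnorm(n * kd), n, kd) %*% t(L)
  } else if (length(ec) == 1L) {
    matrix(stats::rnorm(n * kd, sd = sqrt(ec)), n, kd)
  } else {
    sweep(matrix(stats::rnorm(n * kd), n, kd), 2L, sqrt(ec), "*")
  }
}

## true genotype at an arbitrary cM position, simulated conditionally on the
## flanking true marker genotypes (exact bridge of the Markov chain)
true_genotype_at <- function(cross, chr, pos) {
  mp <- cross$map[[chr]]
  g <- cross$truth[[chr]]
  if (pos < min(mp) || pos > max(mp)) stop("QTL position off the map")
  j <- findInterval(pos, mp)
  if (mp[j] == pos) return(g[, j])
  gl <- g[, j]; gr <- g[, j + 1L]
  rl <- haldane(pos - mp[j]); rr <- haldane(mp[j + 1L] - pos)
  ## P(g = gl | flanks): bridge probabilities of the no-interference chain
  p_same <- ifelse(gl == gr,
                   (1 - rl) * (1 - rr) / ((1 - rl) * (1 - rr) + rl * rr),
                   (1 - rl) * rr / ((1 - rl) * rr + rl * (1 - rr)))
  u <- stats::runif(length(gl))
  ifelse(u < p_same, gl, 1L - gl)
}

#' Simulate landmark shapes on top of backcross genotypes
#'
#' Each specimen's vectorized coordinates are mean shape + covariate effects
#' (log centroid size, sex, direction of cross) + genotype dosage times the
#' QTL effect vectors + a draw from the error covariance. Optionally each
#' configuration is then de-superimposed by a random similarity transform
#' (rotation, bounded translation, scale in [0.8, 1.2]) so that GPA is
#' genuinely exercised downstream.
#'
#' @param cross a \code{bc_cross} from \code{\link{simulate_backcross}}.
#' @param truth a \code{\link{sim_truth}}.
#' @param seed integer seed.
#' @param desuperimpose apply random similarity transforms (default TRUE).
#' @return the cross with \code{pheno} filled in: list with \code{shapes}
#'   (raw \code{landmark_sample}), \code{covariates} (data.frame: id, logCS,
#'   sex, cross_direction), \code{qtl_genotypes} (n x #QTL dosage matrix of
#'   the true simulated genotypes at the QTL positions).
#' @export
simulate_shapes <- function(cross, truth, seed = 1L, desuperimpose = TRUE) {
  set.seed(seed)
  k <- nrow(truth$mean_shape); d <- ncol(truth$mean_shape); kd <- k * d
  n <- nrow(cross$geno[[1L]])
  mu <- as.numeric(truth$mean_shape)
  Y <- matrix(mu, n, kd, byrow = TRUE)
  sex <- stats::rbinom(n, 1L, 0.5)
  direction <- stats::rbinom(n, 1L, 0.5)
  ## size covariate doubles as the de-superimposition scale, so the measured
  ## log centroid size downstream recovers it (allometry is then estimable)
  logcs <- stats::runif(n, log(0.8), log(1.2))
  ce <- truth$covariate_effects
  if (!is.null(ce$size)) Y <- Y + outer(logcs, ce$size)
  if (!is.null(ce$sex)) Y <- Y + outer(sex, ce$sex)
  if (!is.null(ce$cross_direction)) Y <- Y + outer(direction, ce$cross_direction)
  qg <- NULL
  if (!is.null(truth$beta)) {
    qg <- matrix(0L, n, nrow(truth$beta))
    for (j in seq_len(nrow(truth$beta))) {
      gj <- true_genotype_at(cross, as.character(truth$qtl$chr[j]), truth$qtl$pos[j])
      qg[, j] <- gj
      Y <- Y + outer(gj, truth$beta[j, ])
    }
  }
  Y <- Y + draw_error(truth, n, kd)
  arr <- array(0, c(k, d, n))
  for (i in seq_len(n)) {
    cfg <- unvec_config(Y[i, ], k, d)
    if (desuperimpose) {
      R <- random_rotation(d)
      tr <- stats::runif(d, -0.5, 0.5)
      cfg <- exp(logcs[i]) * cfg %*% R + matrix(tr, k, d, byrow = TRUE)
    }
    arr[, , i] <- cfg
  }
  ids <- sprintf("ind%04d", seq_len(n))
  cross$pheno <- list(
    shapes = landmark_sample(arr, ids = ids),
    covariates = data.frame(id = ids, logCS = logcs, sex = sex,
                            cross_direction = direction,
                            stringsAsFactors = FALSE),
    qtl_genotypes = qg)
  cross$sim_truth <- truth
  cross
}

## uniform random rotation in SO(d) via QR of a Gaussian matrix
random_rotation <- function(d) {
  qr_ <- qr(matrix(stats::rnorm(d * d), d, d))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), d)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
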