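test_that("matrix_sqrt_psd reconstructs PSD matrices", {
  expect_equal(matrix_sqrt_psd(diag(3)), diag(3))
  expect_equal(matrix_sqrt_psd(diag(c(4, 9))), diag(c(2, 3)))
  set.seed(7)
  for (s in 1:5) {
    A <- crossprod(matrix(rnorm(36), 6, 6))
    R <- matrix_sqrt_psd(A)
    expect_lt(norm(R %*% R - A, "F"), 1e-8 * norm(A, "F"))
    expect_lt(max(abs(R - t(R))), 1e-10)
  }
  expect_error(matrix_sqrt_psd(matrix(rnorm(16), 4, 4)), "symmetric")
})

test_that("root Euclidean distance is a metric with the right hand values", {
  G <- crossprod(matrix(rnorm(25), 5, 5))
  expect_equal(root_euclidean_distance(G, G), 0)
  expect_equal(root_euclidean_distance(diag(2), 4 * diag(2)), sqrt(2))
  set.seed(13)
  for (s in 1:100) {
    A <- crossprod(matrix(rnorm(16), 4, 4))
    B <- crossprod(matrix(rnorm(16), 4, 4))
    C <- crossprod(matrix(rnorm(16), 4, 4))
    dab <- root_euclidean_distance(A, B)
    expect_equal(dab, root_euclidean_distance(B, A))
    expect_lte(dab, root_euclidean_distance(A, C) + root_euclidean_distance(C, B) + 1e-12)
  }
})

test_that("qtl_G: unlinked closed form, empirical trace recovery, and
           subsetting commutes", {
  study <- small_study(n = 2000, n_qtl = 3, seed = 101, qtl_norm = 0.009)
  pm <- prep_mapping(study, vf = 0.999, step = 5)
  fit <- fit_qtl_model(pm$pca$scores, pm$cov, pm$probs, study$sim_truth$qtl)
  ## one QTL, unlinked coding: G = beta' beta / 4, rank 1
  fit1 <- fit_qtl_model(pm$pca$scores, pm$cov, pm$probs, study$sim_truth$qtl[1, ])
  G1 <- qtl_G(fit1, pca = pm$pca, dosage_cov = "unlinked")
  b1 <- fit1$B %*% t(pm$pca$rotation)
  expect_equal(unclass(G1), crossprod(b1) / 4, tolerance = 1e-12, ignore_attr = TRUE)
  ev <- eigen(G1, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[2] / ev[1], 1e-10)
  ## trace(G)/trace(P) near the planted genetic fraction
  G <- qtl_G(fit, pca = pm$pca)
  P <- phenotypic_cov(pm$g, pm$cov)
  planted <- sum(rowSums(study$sim_truth$beta^2)) / 4
  kd <- ncol(study$sim_truth$beta)
  ## P is covariate-adjusted; GPA removes 7 of the kd isotropic error dims
  want_frac <- planted / (planted + 0.002 * (kd - 7) / kd)
  expect_equal(sum(diag(G)) / sum(diag(P)), want_frac, tolerance = 0.15)
  ## subsetting commutes with construction
  sub <- 1:10
  Gs <- qtl_G(fit, pca = pm$pca, subset = sub)
  expect_equal(unclass(Gs), unclass(G)[sub, sub], ignore_attr = TRUE)
  expect_error(qtl_G(fit_qtl_model(pm$pca$scores, pm$cov, pm$probs,
                                   data.frame(chr = character(0), pos = numeric(0)))),
               "no QTL")
})

test_that("gmax angle test: identical and orthogonal leading axes, folded
           null", {
  set.seed(3)
  b <- rnorm(8)
  G1 <- tcrossprod(b) + 0.01 * diag(8)
  ga <- gmax_angle_test(G1, 2 * G1, n_random = 5000, seed = 2)
  expect_equal(ga$angle, 0, tolerance = 1e-8)
  expect_lte(ga$p, 1 / 5000 + 1e-12)
  b2 <- rnorm(8); b2 <- b2 - b * sum(b * b2) / sum(b^2)
  G2 <- tcrossprod(b2) + 0.01 * diag(8)
  ga2 <- gmax_angle_test(G1, G2, n_random = 5000, seed = 2)
  expect_equal(ga2$angle, 90, tolerance = 1e-6)
  expect_gt(ga2$p, 0.99)
  ## null mean against an independent Monte-Carlo with a different generator
  m <- 26
  set.seed(77)
  u <- matrix(runif(4000 * m) - 0.5, 4000, m)  # non-Gaussian directions
  v <- matrix(runif(4000 * m) - 0.5, 4000, m)
  ang <- acos(pmin(abs(rowSums(u * v)) / sqrt(rowSums(u^2) * rowSums(v^2)), 1)) * 180 / pi
  G26 <- crossprod(matrix(rnorm(m * m), m, m))
  ga3 <- gmax_angle_test(G26, G26, n_random = 50000, seed = 5)
  expect_equal(ga3$null_mean, mean(ang), tolerance = 1.5)
})

test_that("Krzanowski subspace: shared subspaces, orthogonal bounds, and the
           eigenvalue identity", {
  set.seed(21)
  ## identical matrices: leading eigenvalues = number of matrices, angles 0
  A <- crossprod(matrix(rnorm(49), 7, 7))
  kz <- krzanowski_subspace(list(A, A, A), var_fraction = 0.9)
  qmin <- min(kz$q)
  expect_equal(kz$eigenvalues[seq_len(qmin)], rep(3, qmin), tolerance = 1e-8)
  expect_equal(max(kz$angles[seq_len(qmin), ]), 0, tolerance = 1e-5)
  ## mutually orthogonal rank-1 matrices: eigenvalues bounded by 1
  E <- diag(6)
  kz2 <- krzanowski_subspace(list(tcrossprod(E[, 1]), tcrossprod(E[, 2]),
                                  tcrossprod(E[, 3])))
  expect_lte(max(kz2$eigenvalues), 1 + 1e-10)
  ## eigenvalue = sum of cos^2(delta) identity on random matrices
  mats <- lapply(1:3, function(i) crossprod(matrix(rnorm(64), 8, 8)))
  kz3 <- krzanowski_subspace(mats, var_fraction = 0.85)
  delta <- rowSums(cos(kz3$angles * pi / 180)^2)
  expect_equal(kz3$eigenvalues, delta, tolerance = 1e-8)
  expect_lte(max(kz3$eigenvalues), 3 + 1e-10)
  expect_error(krzanowski_subspace(list(A)), "at least two")
  expect_error(krzanowski_subspace(mats, var_fraction = 0), "var_fraction")
})

test_that("multivariate heritability: proportional matrices, zero G, and
           recovery of a planted heritable direction", {
  set.seed(31)
  P <- crossprod(matrix(rnorm(36), 6, 6))
  mh <- multivariate_heritability(0.25 * P, P)
  expect_equal(mh$h2, rep(0.25, 6), tolerance = 1e-8)
  mh0 <- multivariate_heritability(matrix(0, 6, 6), P)
  expect_equal(mh0$h2, rep(0, 6))
  expect_error(multivariate_heritability(P, matrix(0, 6, 6)), "zero P")
  ## planted direction with h2 = 0.5 and orthogonal noise, n = 2000
  n <- 2000; q <- 10
  beta <- rnorm(q); beta <- beta / sqrt(sum(beta^2)) * 0.4
  s2 <- sum(beta^2) / 4            # genetic variance = error variance in the beta direction
  g <- rbinom(n, 1, 0.5)
  Y <- outer(g, beta) + matrix(rnorm(n * q, sd = sqrt(s2)), n, q)
  Ghat <- tcrossprod(cov(cbind(g), Y)) / var(g)  # beta_hat' beta_hat scaled
  bhat <- as.numeric(cov(cbind(g), Y)) / var(g)
  Ghat <- tcrossprod(bhat) * var(g)
  Phat <- cov(Y)
  mh2 <- multivariate_heritability(Ghat, Phat)
  expect_equal(mh2$h2[1], 0.5, tolerance = 0.05)
  ang <- acos(min(abs(sum(mh2$directions[, 1] * beta)) /
                    sqrt(sum(mh2$directions[, 1]^2) * sum(beta^2)), 1)) * 180 / pi
  expect_lt(ang, 10)
  expect_lt(mh2$h2[2], 0.15)
})

test_that("comparison statistics are invariant to a common rotation", {
  set.seed(41)
  G1 <- crossprod(matrix(rnorm(36), 6, 6))
  G2 <- crossprod(matrix(rnorm(36), 6, 6))
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  rot <- function(M) t(Q) %*% M %*% Q
  expect_equal(root_euclidean_distance(G1, G2),
               root_euclidean_distance(rot(G1), rot(G2)), tolerance = 1e-8)
  expect_equal(gmax_angle_test(G1, G2, n_random = 1000, seed = 1)$angle,
               gmax_angle_test(rot(G1), rot(G2), n_random = 1000, seed = 1)$angle,
               tolerance = 1e-6)
  kza <- krzanowski_subspace(list(G1, G2))
  kzb <- krzanowski_subspace(list(rot(G1), rot(G2)))
  expect_equal(kza$eigenvalues, kzb$eigenvalues, tolerance = 1e-8)
  expect_equal(sort(multivariate_heritability(G1, G2)$h2),
               sort(multivariate_heritability(rot(G1), rot(G2))$h2),
               tolerance = 1e-8)
})
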