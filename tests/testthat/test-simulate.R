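test_that("backcross genotypes follow the Haldane map function", {
  ## zero distance: identical genotypes
  map0 <- structure(list("1" = c(m1 = 5, m2 = 5)), class = "genetic_map")
  cr0 <- simulate_backcross(map0, 500, seed = 2)
  expect_identical(cr0$geno[["1"]][, 1], cr0$geno[["1"]][, 2])
  ## empirical recombination across a spread of distances
  n <- 10000
  for (d in c(1, 5, 10, 20, 50)) {
    mp <- structure(list("1" = c(m1 = 0, m2 = d)), class = "genetic_map")
    cr <- simulate_backcross(mp, n, seed = 10 + d)
    g <- cr$geno[["1"]]
    rhat <- mean(g[, 1] != g[, 2])
    r <- haldane(d)
    se <- sqrt(r * (1 - r) / n)
    expect_lt(abs(rhat - r), 3 * se + 1e-12)
  }
  ## distant markers: r -> 1/2
  mpfar <- structure(list("1" = c(m1 = 0, m2 = 1000)), class = "genetic_map")
  crf <- simulate_backcross(mpfar, n, seed = 3)
  rhat <- mean(crf$geno[["1"]][, 1] != crf$geno[["1"]][, 2])
  expect_lt(abs(rhat - 0.5), 3 * sqrt(0.25 / n))
  ## marginal AB frequency 1/2
  ab <- mean(crf$geno[["1"]])
  expect_lt(abs(ab - 0.5), 3 * sqrt(0.25 / n))
  expect_error(simulate_backcross(structure(list(), class = "genetic_map"), 5), "empty")
  expect_error(simulate_backcross(mpfar, 0), "n must")
})

test_that("genotyping error and missingness hit the observed matrix at the
           requested rates, truth untouched", {
  map <- sim_map(c("1" = 50), spacing = 10)
  cr <- simulate_backcross(map, 4000, seed = 5, geno_error = 0.1, missing_rate = 0.2)
  g <- cr$geno[["1"]]; tg <- cr$truth[["1"]]
  nobs <- length(g)
  expect_lt(abs(mean(is.na(g)) - 0.2), 3 * sqrt(0.2 * 0.8 / nobs))
  expect_lt(abs(mean(g != tg, na.rm = TRUE) - 0.1), 3 * sqrt(0.1 * 0.9 / (0.8 * nobs)))
  ## reproducible under seed
  cr2 <- simulate_backcross(map, 4000, seed = 5, geno_error = 0.1, missing_rate = 0.2)
  expect_identical(cr$geno, cr2$geno)
})

test_that("zero-noise shapes reproduce the mean shape exactly up to similarity", {
  study <- small_study(n = 6, n_qtl = 0, seed = 21, error_trace = 0)
  truth <- study$sim_truth
  shp <- study$pheno$shapes
  ## covariate effects exist; remove them by regenerating with none
  map <- sim_map(c("1" = 50), spacing = 10)
  cr <- simulate_backcross(map, 6, seed = 1)
  t0 <- sim_truth(truth$mean_shape, error_cov = 0)
  st <- simulate_shapes(cr, t0, seed = 2)
  for (i in 1:6)
    expect_lt(procrustes_distance(st$pheno$shapes[, , i], truth$mean_shape), 1e-7)
})

test_that("a single planted QTL with zero error yields exactly two shapes
           separated by the planted effect norm", {
  mshape <- morphoqtl:::mandible_reference()
  kd <- length(mshape)
  P <- shape_tangent_projector(mshape)
  set.seed(3)
  v <- as.numeric(P %*% rnorm(kd)); v <- v / sqrt(sum(v^2)) * 0.05
  map <- sim_map(c("1" = 50), spacing = 10)
  cr <- simulate_backcross(map, 40, seed = 7)
  tr <- sim_truth(mshape, qtl = data.frame(chr = "1", pos = 20), beta = rbind(v),
                  error_cov = 0)
  st <- simulate_shapes(cr, tr, seed = 8)
  g <- gpa(st$pheno$shapes)
  Y <- morphoqtl:::vec_coords(unclass(g$aligned))
  qg <- st$pheno$qtl_genotypes[, 1]
  expect_gt(min(table(qg)), 0)
  gap <- colMeans(Y[qg == 1, , drop = FALSE]) - colMeans(Y[qg == 0, , drop = FALSE])
  ## recovered difference matches the planted beta in norm and direction
  expect_equal(sqrt(sum(gap^2)), 0.05, tolerance = 0.01)
  expect_gt(abs(sum(gap * v)) / (sqrt(sum(gap^2)) * 0.05), 0.99)
  ## exactly two distinct shapes after GPA
  pd <- procrustes_distance(st$pheno$shapes[, , which(qg == 1)[1]],
                            st$pheno$shapes[, , which(qg == 1)[2]])
  expect_lt(pd, 1e-7)
})

test_that("least-squares effect recovery error shrinks as the error
           covariance shrinks", {
  errs <- c(2e-4, 2e-6)
  rel <- numeric(2)
  for (ei in 1:2) {
    study <- small_study(n = 300, n_qtl = 3, seed = 31, error_trace = errs[ei])
    pm <- prep_mapping(study, vf = 0.999, step = 5)
    fit <- fit_qtl_model(pm$pca$scores, pm$cov, pm$probs, study$sim_truth$qtl)
    B <- fit$B %*% t(pm$pca$rotation)
    rel[ei] <- mean(sqrt(rowSums((B - study$sim_truth$beta)^2)) /
                      sqrt(rowSums(study$sim_truth$beta^2)))
  }
  expect_lt(rel[2], rel[1])
  expect_lt(rel[2], 0.05)
})

test_that("sim_truth validates its inputs", {
  m <- rand_config(5, 2, seed = 1)
  expect_error(sim_truth(m, error_cov = matrix(rnorm(100), 10, 10)), "symmetric")
  expect_error(sim_truth(m, error_cov = -1), ">= 0")
  bad <- diag(10); bad[1, 1] <- -1
  expect_error(sim_truth(m, error_cov = bad), "PSD")
  expect_error(sim_truth(m, qtl = data.frame(chr = "1", pos = 5),
                         beta = rbind(rep(0, 10))), "positive norm")
})
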