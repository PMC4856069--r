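test_that("Pillai covariate tests reduce to the univariate F test at q = 1 and
           match the reference MANOVA implementation", {
  set.seed(17)
  n <- 60
  cv <- data.frame(logCS = rnorm(n), sex = rbinom(n, 1, 0.5),
                   cross_direction = rbinom(n, 1, 0.5))
  Y1 <- matrix(rnorm(n), n, 1)
  f1 <- fit_covariates(Y1, cv)
  ref <- drop1(lm(Y1 ~ logCS + sex + cross_direction, data = cv), test = "F")
  expect_equal(f1$terms$p, ref[["Pr(>F)"]][2:4], tolerance = 1e-10)
  ## q > 1: the last sequential term of stats::manova equals the type-III test
  Y <- matrix(rnorm(n * 5), n, 5)
  f <- fit_covariates(Y, cv)
  mv <- summary(stats::manova(Y ~ logCS + sex + cross_direction, data = cv),
                test = "Pillai")
  expect_equal(f$terms$pillai[3], unname(mv$stats["cross_direction", "Pillai"]),
               tolerance = 1e-10)
  expect_equal(f$terms$p[3], unname(mv$stats["cross_direction", "Pr(>F)"]),
               tolerance = 1e-10)
  ## aliased design reported by name
  cv2 <- cv; cv2$dup <- cv2$logCS
  expect_error(fit_covariates(Y, cv2), "aliased")
})

test_that("null covariates: type-I error near alpha and %SS near its
           expectation", {
  set.seed(23)
  n <- 50; q <- 3; nsim <- 2000
  rej <- 0; pct <- numeric(nsim)
  for (b in seq_len(nsim)) {
    Y <- matrix(rnorm(n * q), n, q)
    cv <- data.frame(logCS = rnorm(n))
    f <- fit_covariates(Y, cv)
    rej <- rej + (f$terms$p[1] < 0.05)
    pct[b] <- f$terms$pct_ss[1]
  }
  ## binomial 95% band around 5%
  expect_lt(abs(rej / nsim - 0.05), 3 * sqrt(0.05 * 0.95 / nsim) + 0.005)
  expect_equal(mean(pct), 100 / (n - 1), tolerance = 0.1 * 100 / (n - 1))
})

test_that("a planted size effect is recovered in %SS", {
  set.seed(29)
  n <- 800; q <- 6
  x <- rnorm(n)
  b <- rnorm(q); b <- b / sqrt(sum(b^2))
  ## size explains ~5% of total variance
  s2 <- 0.05 / 0.95
  Y <- outer(x, b) * sqrt(s2) + matrix(rnorm(n * q), n, q) / sqrt(q)
  f <- fit_covariates(Y, data.frame(logCS = x))
  expect_equal(f$terms$pct_ss[1], 5, tolerance = 1.2)
  expect_lt(f$terms$p[1], 1e-10)
})

test_that("the Pillai scan at q = 1 equals a univariate Haley-Knott F scan", {
  study <- small_study(n = 120, n_qtl = 1, seed = 3)
  pm <- prep_mapping(study, vf = 0.9, step = 5)
  y <- pm$pca$scores[, 1, drop = FALSE]
  sc <- qtl_scan(y, pm$cov, pm$probs)
  X0 <- model.matrix(~ logCS + sex + cross_direction, pm$cov)
  for (i in sample(nrow(sc), 12)) {
    d <- dosage(pm$probs, sc$chr[i], sc$pos[i])
    fit_f <- lm(y ~ X0 - 1 + d)
    fit_0 <- lm(y ~ X0 - 1)
    a <- anova(fit_0, fit_f)
    lod_uni <- -log10(a[["Pr(>F)"]][2])
    expect_equal(sc$lod[i], lod_uni, tolerance = 1e-8)
  }
})

test_that("scan LODs are nonnegative, the null term scores zero, and fixed
           QTL positions are masked", {
  study <- small_study(n = 100, n_qtl = 1, seed = 41)
  pm <- prep_mapping(study, vf = 0.9, step = 5)
  sc <- qtl_scan(pm$pca$scores, pm$cov, pm$probs)
  expect_true(all(sc$lod >= 0, na.rm = TRUE))
  fx <- data.frame(chr = "2", pos = 50)
  sc2 <- qtl_scan(pm$pca$scores, pm$cov, pm$probs, fixed_qtl = fx)
  masked <- sc2$chr == "2" & abs(sc2$pos - 50) < 10
  expect_true(all(is.na(sc2$lod[masked])))
  expect_true(all(!is.na(sc2$lod[!masked])))
})

test_that("a planted QTL is localized by the scan", {
  hits <- 0
  for (s in 1:10) {
    study <- small_study(n = 400, n_qtl = 1, seed = 100 + s,
                         qtl_norm = 0.0083)   # h2_dir ~ 0.25
    pm <- prep_mapping(study, vf = 0.9, step = 2.5)
    mx <- scan_max(qtl_scan(pm$pca$scores, pm$cov, pm$probs))
    if (mx$chr == "1" && abs(mx$pos - 25) <= 5) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("permutation threshold: quantile edge case, determinism, null
           calibration at the scan level", {
  study <- small_study(n = 150, n_qtl = 0, seed = 51)
  pm <- prep_mapping(study, vf = 0.8, step = 5)
  T1 <- perm_threshold(pm$pca$scores, pm$cov, pm$probs, n_perm = 50, seed = 5)
  T1b <- perm_threshold(pm$pca$scores, pm$cov, pm$probs, n_perm = 50, seed = 5)
  expect_identical(as.numeric(T1), as.numeric(T1b))
  ## alpha = 1 gives the minimum of the permutation draws
  Tmin <- perm_threshold(pm$pca$scores, pm$cov, pm$probs, n_perm = 50,
                         alpha = 1, seed = 5)
  expect_equal(as.numeric(Tmin), min(attr(T1, "max_lods")))
  expect_gt(as.numeric(T1), as.numeric(Tmin))
})

test_that("Bayes credible intervals match brute-force HPD enumeration", {
  pos <- seq(0, 60, by = 2)
  ## delta-like profile
  lod <- rep(0, length(pos)); lod[12] <- 8
  bi <- bayes_interval(data.frame(pos = pos, lod = lod))
  expect_equal(c(bi$left, bi$right), rep(pos[12], 2))
  ## flat profile spans the chromosome and is flagged
  bf <- bayes_interval(data.frame(pos = pos, lod = rep(1.3, length(pos))))
  expect_true(bf$flat)
  expect_equal(c(bf$left, bf$right), range(pos))
  ## Gaussian-shaped profiles vs enumeration oracle
  for (s in 1:5) {
    set.seed(s)
    mu <- runif(1, 10, 50); sd_ <- runif(1, 3, 12)
    lod <- 6 * exp(-(pos - mu)^2 / (2 * sd_^2)) + runif(length(pos), 0, 0.3)
    bi <- bayes_interval(data.frame(pos = pos, lod = lod), coverage = 0.9)
    want <- oracle_hpd(pos, lod, 0.9)
    expect_equal(c(bi$left, bi$right), want)
  }
})

test_that("plane decomposition fractions behave and sum to one", {
  k <- 13
  bz <- cbind(matrix(0, k, 2), rnorm(k))
  expect_equal(plane_decomposition(bz), c(0, 0, 1))
  be <- matrix(1, k, 3)
  expect_equal(plane_decomposition(be), rep(1 / 3, 3))
  set.seed(2)
  br <- rnorm(3 * k)
  expect_equal(sum(plane_decomposition(br, k = k, d = 3)), 1, tolerance = 1e-12)
  expect_error(plane_decomposition(rep(0, 3 * k), k = k, d = 3), "zero")
})

test_that("expected_h2: algebraic reduction and agreement with the empirical
           projection-score variance ratio", {
  ## single QTL, isotropic error: ||b||^2 / (||b||^2 + 4 s2)
  b <- c(1, 0, 0, 0)
  expect_equal(expected_h2(b, rbind(b), diag(0.25, 4)), 0.5)
  b2 <- rnorm(6); b2 <- b2 / sqrt(sum(b2^2)) * 0.3
  s2 <- 0.01
  expect_equal(expected_h2(b2, rbind(b2), diag(s2, 6)),
               sum(b2^2) / (sum(b2^2) + 4 * s2))
  ## large-n empirical check on simulated shapes
  study <- small_study(n = 5000, n_qtl = 1, seed = 61, qtl_norm = 0.009)
  pm <- prep_mapping(study, vf = 0.999, step = 5)
  fit <- fit_qtl_model(pm$pca$scores, pm$cov, pm$probs, study$sim_truth$qtl)
  eff <- effect_summaries(fit, pm$pca$scores, pm$cov, pca = pm$pca)
  expect_equal(eff$pct_ss_proj[1], 100 * eff$expected_h2[1], tolerance = 2)
})

test_that("model fits report per-QTL statistics and a zero-QTL model is the
           null", {
  study <- small_study(n = 200, n_qtl = 2, seed = 71, qtl_norm = 0.01)
  pm <- prep_mapping(study, vf = 0.9, step = 5)
  f0 <- fit_qtl_model(pm$pca$scores, pm$cov, pm$probs,
                      data.frame(chr = character(0), pos = numeric(0)))
  expect_equal(f0$lod, 0)
  expect_equal(nrow(f0$qtl), 0)
  f2 <- fit_qtl_model(pm$pca$scores, pm$cov, pm$probs,
                      study$sim_truth$qtl[1:2, ], T_penalty = 2)
  expect_equal(f2$plod, f2$lod - 4)
  expect_true(all(f2$qtl$lod > 0))
  expect_true(all(eigen(f2$S, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("forward/backward search finds planted QTL, avoids duplicates, and
           returns the covariate-only model on pure noise", {
  study <- small_study(n = 430, n_qtl = 3, seed = 81, qtl_norm = 0.009)
  pm <- prep_mapping(study, vf = 0.9, step = 2.5)
  fit <- forward_backward_search(pm$pca$scores, pm$cov, pm$probs,
                                 T_penalty = 4, max_qtl = 8)
  expect_gte(nrow(fit$qtl), 3)
  truth <- study$sim_truth$qtl
  for (j in 1:3) {
    sel <- fit$ci$chr == truth$chr[j]
    expect_true(any(sel & fit$ci$left - 2.5 <= truth$pos[j] &
                      fit$ci$right + 2.5 >= truth$pos[j]))
  }
  ## same-chromosome QTL respect the separation rule
  for (ch in unique(fit$qtl$chr)) {
    p <- sort(fit$qtl$pos[fit$qtl$chr == ch])
    if (length(p) > 1) expect_true(all(diff(p) >= 10))
  }
  ## specimen order invariance
  perm <- sample(430)
  probs_p <- pm$probs
  for (ch in names(probs_p)) probs_p[[ch]]$prob <- probs_p[[ch]]$prob[perm, ]
  fit_p <- forward_backward_search(pm$pca$scores[perm, ], pm$cov[perm, ],
                                   probs_p, T_penalty = 4, max_qtl = 8)
  expect_equal(fit_p$qtl[, c("chr", "pos")], fit$qtl[, c("chr", "pos")])
  ## pure noise: no QTL at a sane threshold
  noise <- matrix(rnorm(200 * 5), 200, 5)
  study0 <- small_study(n = 200, n_qtl = 0, seed = 91)
  pm0 <- prep_mapping(study0, vf = 0.9, step = 5)
  T0 <- perm_threshold(pm0$pca$scores, pm0$cov, pm0$probs, n_perm = 100, seed = 1)
  fit0 <- forward_backward_search(pm0$pca$scores, pm0$cov, pm0$probs,
                                  T_penalty = as.numeric(T0), max_qtl = 5)
  expect_equal(nrow(fit0$qtl), 0)
})
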