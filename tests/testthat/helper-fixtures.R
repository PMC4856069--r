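## shared fixtures and independent oracles, built in code at test time

rand_config <- function(k = 8, d = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(k * d), k, d)
}

## apply a random similarity transform to a configuration
rand_similarity <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(cfg)
  Q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  s <- runif(1, 0.5, 2)
  tr <- runif(d, -3, 3)
  s * cfg %*% Q + matrix(tr, nrow(cfg), d, byrow = TRUE)
}

## independent two-configuration Procrustes distance: numeric minimization
## over explicit rotation parameterizations (never the SVD route)
oracle_procrustes_distance <- function(a, b) {
  pre <- function(x) {
    x <- sweep(x, 2, colMeans(x))
    x / sqrt(sum(x^2))
  }
  pa <- pre(a); pb <- pre(b)
  d <- ncol(a)
  if (d == 2) {
    obj <- function(th) {
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      sum((pa - pb %*% R)^2)
    }
    sqrt(min(vapply(seq(0, 2 * pi, length.out = 20), function(s)
      optimize(obj, c(s - 0.4, s + 0.4))$objective, 0)))
  } else {
    rotmat <- function(ang) {
      cx <- cos(ang[1]); sx <- sin(ang[1])
      cy <- cos(ang[2]); sy <- sin(ang[2])
      cz <- cos(ang[3]); sz <- sin(ang[3])
      Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
      Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
      Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
      Rx %*% Ry %*% Rz
    }
    obj <- function(ang) sum((pa - pb %*% rotmat(ang))^2)
    best <- Inf
    for (s in 1:12) {
      set.seed(s)
      o <- optim(runif(3, -pi, pi), obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-14))
      best <- min(best, o$value)
    }
    sqrt(best)
  }
}

## independent nearest-point-on-triangle: clamped quadratic minimization over
## the face and explicit 1D minimization over each edge
oracle_closest_on_tri <- function(p, a, b, cc) {
  ab <- b - a; ac <- cc - a
  M <- rbind(c(sum(ab * ab), sum(ab * ac)), c(sum(ab * ac), sum(ac * ac)))
  rhs <- c(sum(ab * (p - a)), sum(ac * (p - a)))
  st <- tryCatch(solve(M, rhs), error = function(e) c(-1, -1))
  cands <- list()
  if (all(st >= 0) && sum(st) <= 1) cands <- c(cands, list(a + st[1] * ab + st[2] * ac))
  edge_min <- function(p0, p1) {
    t <- sum((p - p0) * (p1 - p0)) / sum((p1 - p0)^2)
    p0 + min(max(t, 0), 1) * (p1 - p0)
  }
  cands <- c(cands, list(edge_min(a, b), edge_min(a, cc), edge_min(b, cc)))
  d2 <- vapply(cands, function(x) sum((x - p)^2), 0)
  cands[[which.min(d2)]]
}

oracle_project_to_mesh <- function(points, mesh) {
  points <- rbind(points)
  out <- matrix(0, nrow(points), 3)
  dist <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    best <- Inf; bp <- NULL
    for (f in seq_len(nrow(mesh$faces))) {
      tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
      cp <- oracle_closest_on_tri(points[i, ], tri[1, ], tri[2, ], tri[3, ])
      d2 <- sum((cp - points[i, ])^2)
      if (d2 < best) { best <- d2; bp <- cp }
    }
    out[i, ] <- bp; dist[i] <- sqrt(best)
  }
  list(points = out, distance = dist)
}

## exhaustive-path genotype probabilities on a tiny chromosome
oracle_genoprob <- function(positions, obs, error_prob) {
  M <- length(positions)
  states <- as.matrix(expand.grid(rep(list(0:1), M)))
  w <- apply(states, 1, function(s) {
    pr <- 0.5
    if (M > 1) for (j in 2:M) {
      r <- morphoqtl::haldane(positions[j] - positions[j - 1])
      pr <- pr * if (s[j] == s[j - 1]) 1 - r else r
    }
    for (j in seq_len(M)) if (!is.na(obs[j]))
      pr <- pr * if (s[j] == obs[j]) 1 - error_prob else error_prob
    pr
  })
  vapply(seq_len(M), function(j) sum(w[states[, j] == 1]) / sum(w), 0)
}

## brute-force discrete HPD interval
oracle_hpd <- function(pos, lod, coverage) {
  p <- 10^(lod - max(lod)); p <- p / sum(p)
  o <- order(p, decreasing = TRUE)
  sel <- o[seq_len(which(cumsum(p[o]) >= coverage - 1e-12)[1])]
  c(min(pos[sel]), max(pos[sel]))
}

## small phenotyped backcross for mapping tests: 3 chromosomes, 20 markers
## each, 13 3D landmarks, isotropic error
small_study <- function(n = 430, qtl_norm = 0.00602, n_qtl = 3, seed = 1,
                        error_trace = 0.002, desuperimpose = TRUE) {
  map <- sim_map(c("1" = 95, "2" = 95, "3" = 95), spacing = 5)
  cross <- simulate_backcross(map, n, seed = seed)
  mshape <- morphoqtl:::mandible_reference()
  kd <- length(mshape)
  P <- shape_tangent_projector(mshape)
  set.seed(seed + 5000)
  beta <- NULL; qtl <- NULL
  if (n_qtl > 0) {
    beta <- matrix(0, n_qtl, kd)
    for (j in seq_len(n_qtl)) {
      v <- as.numeric(P %*% rnorm(kd))
      beta[j, ] <- v / sqrt(sum(v^2)) * qtl_norm
    }
    qtl <- data.frame(chr = as.character(seq_len(n_qtl)),
                      pos = c(25, 50, 75)[seq_len(n_qtl)],
                      stringsAsFactors = FALSE)
  }
  truth <- sim_truth(mshape, qtl = qtl, beta = beta,
                     covariate_effects = list(size = as.numeric(P %*% rnorm(kd)) * 0.02),
                     error_cov = error_trace / kd)
  simulate_shapes(cross, truth, seed = seed + 1, desuperimpose = desuperimpose)
}

## mapping inputs from a phenotyped cross
prep_mapping <- function(study, vf = 0.90, step = 2.5) {
  g <- gpa(study$pheno$shapes)
  pca <- pca_reduce(g, vf)
  cov <- study$pheno$covariates
  cov$logCS <- log(g$centroid_sizes)
  probs <- calc_genoprob(study, step = step)
  list(g = g, pca = pca, cov = cov, probs = probs)
}
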