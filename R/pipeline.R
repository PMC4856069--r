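#' Run the full shape-mapping pipeline
#'
#' Chains the stages of the analysis on one dataset: load (or simulate) a
#' phenotyped backcross, superimpose the landmarks by GPA, optionally flatten
#' to 2D, reduce to principal components, fit the covariate model, compute
#' genotype probabilities, obtain the permutation penalty, run the
#' forward/backward multiple-QTL search, summarize effects, and build the
#' QTL-based G and the covariate-adjusted P. Every stage is logged with its
#' parameters; all randomness flows from the seeds in the configuration, so
#' reruns are deterministic.
#'
#' @param config a list, or path to a YAML file, with (all optional unless
#'   noted): \code{geno_csv}/\code{pheno_csv} input paths or \code{simulate}
#'   (a list of \code{\link{sim_mandible_study}} arguments); \code{mode}
#'   ("3d", default, or "2d" for the flattened arm); \code{anchors} (3
#'   landmark indices for flattening, default c(1, 2, 12));
#'   \code{variance_fraction} (PC retention, default 0.95); \code{step} and
#'   \code{error_prob} (genotype probabilities, defaults 1 cM and 0.001);
#'   \code{n_perm} (default 1000), \code{alpha} (0.05), \code{T} (explicit
#'   penalty overriding permutations; required if \code{n_perm} = 0);
#'   \code{max_qtl} (50), \code{min_sep} (10); \code{seed} (1);
#'   \code{out_dir} (when given, tidy CSVs and a JSON model descriptor are
#'   written there).
#' @return list with the pieces of every stage: \code{cross}, \code{gpa},
#'   \code{pca}, \code{covariate_fit}, \code{probs}, \code{T},
#'   \code{fit} (the final model with CIs), \code{effects}, \code{G},
#'   \code{P}, \code{log}.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(name, default) if (is.null(config[[name]])) default else config[[name]]
  seed <- cfg("seed", 1L)
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    log <<- c(log, msg)
    message(msg)
  }
  ## --- load or simulate ------------------------------------------------
  if (!is.null(config$geno_csv)) {
    say("stage load: reading cross from %s", config$geno_csv)
    cross <- read_cross_csv(config$geno_csv, config$pheno_csv)
  } else {
    sim_args <- cfg("simulate", list())
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    say("stage simulate: n=%s seed=%s", cfg("simulate", list(n = 427))$n %||% 427,
        sim_args$seed)
    cross <- do.call(sim_mandible_study, sim_args)
  }
  shapes <- cross$pheno$shapes
  covariates <- cross$pheno$covariates
  ## --- superimposition --------------------------------------------------
  say("stage gpa: %d specimens", dim(shapes)[3L])
  mode <- cfg("mode", "3d")
  if (mode == "2d") {
    anchors <- cfg("anchors", c(1L, 2L, 12L))
    say("stage flatten: anchors %s", paste(anchors, collapse = ","))
    shapes <- flatten_sample(shapes, anchors)
  }
  g <- gpa(shapes)
  ## measured size covariate: log centroid size from the raw configurations
  covariates$logCS <- log(g$centroid_sizes)
  ## --- PC reduction and covariates -------------------------------------
  vf <- cfg("variance_fraction", 0.95)
  pca <- pca_reduce(g, vf)
  say("stage pca: retained %d of %d nonzero PCs (%.0f%% variance)",
      pca$retained, length(pca$eigenvalues), 100 * vf)
  cov_fit <- fit_covariates(pca$scores, covariates)
  say("stage covariates: %s", paste(sprintf("%s %.2f%%", cov_fit$terms$term,
                                            cov_fit$terms$pct_ss), collapse = ", "))
  ## --- genotype probabilities ------------------------------------------
  step <- cfg("step", 1); eprob <- cfg("error_prob", 0.001)
  say("stage genoprob: step %g cM, error_prob %g", step, eprob)
  probs <- calc_genoprob(cross, step = step, error_prob = eprob)
  ## --- permutation penalty ----------------------------------------------
  n_perm <- cfg("n_perm", 1000L)
  if (n_perm > 0L) {
    say("stage permtest: %d permutations, alpha %.2f", n_perm, cfg("alpha", 0.05))
    T_ <- perm_threshold(pca$scores, covariates, probs, n_perm = n_perm,
                         alpha = cfg("alpha", 0.05), seed = seed + 1L)
  } else {
    T_ <- config$T
    if (is.null(T_)) stop("n_perm = 0 requires an explicit T in the config")
    say("stage permtest: skipped, using supplied T")
  }
  say("penalty T = %.3f", as.numeric(T_))
  ## --- model search ------------------------------------------------------
  say("stage search: max_qtl %d", cfg("max_qtl", 50L))
  fit <- forward_backward_search(pca$scores, covariates, probs,
                                 T_penalty = as.numeric(T_),
                                 max_qtl = cfg("max_qtl", 50L),
                                 min_sep = cfg("min_sep", 10))
  say("search found %d QTL (pLOD %.2f)", nrow(fit$qtl), fit$plod)
  ## --- effects and G/P ---------------------------------------------------
  effects <- NULL; G <- NULL
  if (nrow(fit$qtl) > 0L) {
    effects <- effect_summaries(fit, pca$scores, covariates, pca = pca)
    G <- qtl_G(fit, pca = pca)
  }
  P <- phenotypic_cov(g, covariates, adjust = TRUE)
  ## --- outputs -----------------------------------------------------------
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cov_fit$terms, file.path(out_dir, "covariates.csv"),
                     row.names = FALSE)
    if (!is.null(effects)) {
      utils::write.csv(cbind(fit$ci, effects[, setdiff(names(effects), c("chr", "pos"))]),
                       file.path(out_dir, "qtl_effects.csv"), row.names = FALSE)
    }
    model <- list(mode = mode, seed = seed, T = as.numeric(T_),
                  n_qtl = nrow(fit$qtl), lod = fit$lod, plod = fit$plod,
                  qtl = fit$qtl, pcs_retained = pca$retained)
    jsonlite::write_json(model, file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("outputs written to %s", out_dir)
  }
  list(cross = cross, gpa = g, pca = pca, covariate_fit = cov_fit,
       probs = probs, T = as.numeric(T_), fit = fit, effects = effects,
       G = G, P = P, log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
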