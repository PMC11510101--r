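#' Univariate parameter-recovery experiment
#'
#' Simulates replicate phenotype sets on one fixed herd (pedigree,
#' genotypes and microbiome are drawn once; genetic and residual effects
#' are redrawn per replicate) and refits the matching single-trait model,
#' returning the per-replicate variance-ratio estimates and their
#' delta-method standard errors.
#'
#' Under `model = "G"` phenotypes carry an additive effect drawn from the
#' single-step H matrix built from the herd's genotypes, and the fit is
#' model G on all phenotyped animals.  Under `model = "M"` phenotypes carry
#' a microbial effect drawn from O, and the fit is model M on the animals
#' with microbiota profiles.  Fits are unconstrained by default so that
#' truncation at the zero boundary does not bias the replicate mean (the
#' relevant check for estimator unbiasedness, particularly at true
#' variance zero).
#'
#' @param truth a [true_params()]; its `var_a`/`var_m` and `var_e` define
#'   the true ratio.
#' @param model `"G"` (genomic, through H) or `"M"` (microbial, through O).
#' @param n_reps number of replicates.
#' @param design herd design (defaults to the study-shaped herd).
#' @param n_snps,n_asvs,depth marker/ASV panel sizes.
#' @param blend_weight blend of A22 into G (keeps G invertible).
#' @param constrain passed to [fit_aireml()].
#' @param seed integer seed.
#' @return data frame with one row per replicate: `estimate` (h2 or m2),
#'   `se`, `var_component`, `var_e`, `converged`.
#' @export
recovery_univariate <- function(truth, model = c("G", "M"), n_reps = 50,
                                design = herd_design(), n_snps = 2000,
                                n_asvs = 300, depth = 5000,
                                blend_weight = 0.05, constrain = FALSE,
                                seed = 1) {
  model <- match.arg(model)
  ped <- simulate_pedigree(design, seed = seed)
  if (model == "G") {
    gids <- select_genotyped(ped, design$n_genotyped, seed = seed + 1L)
    geno <- simulate_genotypes(ped, n_snps, seed = seed + 2L)[gids, ,
                                                              drop = FALSE]
    K <- suppressWarnings(build_H(ped, geno, blend_weight = blend_weight))$H
  } else {
    off <- ped$id[!ped$founder]
    set.seed(seed + 3L)
    mids <- sort(sample(off, design$n_with_microbiota))
    counts <- simulate_microbiome(mids, n_asvs = n_asvs, depth = depth,
                                  presence_prob = 0.6, seed = seed + 4L)
    K <- microbiome_pipeline(counts, depth = depth, seed = seed + 5L)$O
  }
  kf <- factor_kinship(K, "K")
  # the fitting structure is fixed across replicates: factor it once
  fixed <- intersect(c("gender", "batch", "diet"), names(truth$fixed_effects))
  probe <- simulate_phenotypes(ped, truth,
                               K_genetic = if (model == "G") kf,
                               K_microbial = if (model == "M") kf,
                               seed = seed)
  use <- if (model == "M") probe$microbiota else rep(TRUE, nrow(probe))
  ids_use <- probe$id[use]
  Cstr <- kin_structure(K, ids_use)
  cache <- eigen((Cstr + t(Cstr)) / 2, symmetric = TRUE)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ph <- simulate_phenotypes(ped, truth,
                              K_genetic = if (model == "G") kf,
                              K_microbial = if (model == "M") kf,
                              seed = seed + 100L + r)
    dat <- ph[match(ids_use, ph$id), , drop = FALSE]
    X <- stats::model.matrix(stats::reformulate(fixed), data = dat)
    lab <- if (model == "G") "a" else "m"
    fit <- fit_aireml(dat$y, X = X,
                      random = stats::setNames(list(Cstr), lab),
                      constrain = constrain, spectral_cache = cache)
    fit$model <- model
    ratio <- if (model == "G") heritability(fit) else microbiability(fit)
    out[[r]] <- data.frame(estimate = ratio$value, se = ratio$se,
                           var_component = fit$theta[[lab]],
                           var_e = fit$theta[["e"]],
                           converged = fit$converged)
  }
  do.call(rbind, out)
}

#' Bivariate genetic-correlation recovery experiment
#'
#' Simulates replicate trait pairs with genetic correlation `rg_true` on a
#' fixed pedigree (generative covariance \eqn{A \otimes \Sigma_a}) and
#' refits the bivariate animal model, returning per-replicate \eqn{r_g}
#' estimates.
#'
#' @param rg_true true genetic correlation.
#' @param n_reps number of replicates.
#' @param design herd design (a reduced-scale herd keeps the dense
#'   bivariate fits affordable; see the methods vignette).
#' @param var_a,var_e per-trait genetic and residual variances.
#' @param res_cor residual correlation between the traits.
#' @param seed integer seed.
#' @param tol,max_iter convergence settings for the replicate fits; the
#'   defaults resolve the estimates far below the Monte-Carlo noise the
#'   experiment measures.
#' @return data frame: `rg`, `se`, `converged` per replicate.
#' @export
recovery_bivariate <- function(rg_true, n_reps = 50,
                               design = herd_design(n_dams = 50, n_sires = 25,
                                                    n_offspring = 300,
                                                    n_genotyped = 0,
                                                    n_with_microbiota = 0),
                               var_a = 0.5, var_e = 0.5, res_cor = 0.2,
                               seed = 1, tol = 1e-6, max_iter = 100) {
  ped <- simulate_pedigree(design, seed = seed)
  A <- build_A(ped)
  kf <- factor_kinship(A, "A")
  Sa <- matrix(c(var_a, rg_true * var_a, rg_true * var_a, var_a), 2)
  Se <- matrix(c(var_e, res_cor * var_e, res_cor * var_e, var_e), 2)
  truth <- true_params(Sigma_a = Sa, Sigma_p = diag(0, 2), Sigma_e = Se,
                       fixed_effects = c(gender = 0.3))
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ph <- simulate_phenotypes(ped, truth, K_genetic = kf,
                              seed = seed + 200L + r)
    X <- stats::model.matrix(~ gender, data = ph)
    fit <- fit_bivariate(ph$y1, ph$y2, X1 = X, X2 = X, K = A,
                         ids1 = ph$id, ids2 = ph$id, tol = tol,
                         max_iter = max_iter)
    gc <- genetic_correlation(fit)
    out[[r]] <- data.frame(rg = gc$value, se = gc$se,
                           converged = fit$converged)
  }
  do.call(rbind, out)
}

#' Maternal-effect likelihood-ratio experiment
#'
#' Simulates replicates with a given true dam-level permanent environmental
#' variance, fits the pedigree animal model with and without the maternal
#' term, and records the likelihood-ratio p-value, reproducing the
#' inclusion decision of the per-trait workflow (plain chi-squared with
#' 1 df, conservative at the boundary).
#'
#' @param var_p true maternal permanent environmental variance.
#' @param n_reps number of replicates.
#' @param design herd design.
#' @param var_a,var_e additive and residual variances.
#' @param lrt_alpha inclusion threshold (default 0.01).
#' @param seed integer seed.
#' @return data frame: `p_value`, `included` per replicate.
#' @export
maternal_lrt_experiment <- function(var_p, n_reps = 100,
                                    design = herd_design(n_genotyped = 0,
                                                         n_with_microbiota = 0),
                                    var_a = 0.3, var_e = 0.5,
                                    lrt_alpha = 0.01, seed = 1) {
  ped <- simulate_pedigree(design, seed = seed)
  A <- build_A(ped)
  kf <- factor_kinship(A, "A")
  truth <- true_params(var_a = var_a, var_m = 0, var_p = var_p,
                       var_e = var_e, fixed_effects = c(gender = 0.3))
  probe <- simulate_phenotypes(ped, truth, K_genetic = kf, seed = seed)
  Ca <- kin_structure(A, probe$id)
  Cp <- iid_structure(probe$dam)
  cache <- eigen(Ca, symmetric = TRUE)
  out <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    ph <- simulate_phenotypes(ped, truth, K_genetic = kf,
                              seed = seed + 300L + r)
    X <- stats::model.matrix(~ gender, data = ph)
    no_p <- fit_aireml(ph$y, X = X, random = list(a = Ca),
                       spectral_cache = cache)
    vy <- stats::var(ph$y)
    with_p <- fit_aireml(ph$y, X = X, random = list(a = Ca, p = Cp),
                         tol = 1e-6,
                         start = c(0.9 * no_p$theta[["a"]], 0.1 * vy,
                                   0.9 * no_p$theta[["e"]]))
    test <- lrt(with_p, no_p)
    out[[r]] <- data.frame(p_value = test$p_value,
                           included = test$p_value < lrt_alpha)
  }
  do.call(rbind, out)
}
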