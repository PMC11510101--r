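#' Herd design for the synthetic generator
#'
#' Defaults describe the study population the package is designed around:
#' 739 phenotyped offspring of 101 dams randomly mated with 72 sires, 199
#' genotyped animals (about one male and one female per litter), 707 animals
#' with gut-microbiota profiles, and two birth batches and two diets.
#'
#' @param n_dams,n_sires number of founder dams/sires (must be positive).
#' @param n_offspring number of phenotyped offspring.
#' @param n_genotyped number of offspring with genotypes.
#' @param n_with_microbiota number of offspring with microbiota profiles.
#' @param n_batches,n_diets numbers of levels of the batch and diet factors.
#' @return object of class `herd_design`.
#' @export
herd_design <- function(n_dams = 101, n_sires = 72, n_offspring = 739,
                        n_genotyped = 199, n_with_microbiota = 707,
                        n_batches = 2, n_diets = 2) {
  stopifnot(n_dams >= 1, n_sires >= 1, n_offspring >= 0,
            n_genotyped >= 0, n_with_microbiota >= 0,
            n_batches >= 1, n_diets >= 1)
  if (n_genotyped > n_offspring || n_with_microbiota > n_offspring)
    stop("genotyped/microbiota subsets cannot exceed n_offspring")
  structure(list(n_dams = n_dams, n_sires = n_sires,
                 n_offspring = n_offspring, n_genotyped = n_genotyped,
                 n_with_microbiota = n_with_microbiota,
                 n_batches = n_batches, n_diets = n_diets),
            class = "herd_design")
}

#' True simulation parameters
#'
#' Variance components of the generative animal model
#' \eqn{y = Xb + Wp + Z_1 a + Z_2 m + e}: additive genetic (`var_a`),
#' microbial (`var_m`), maternal permanent environmental (`var_p`, at dam
#' level) and residual (`var_e`).  `fixed_effects` holds the effect of the
#' second level of each two-level factor.  For bivariate simulation supply
#' 2x2 blocks `Sigma_a`, `Sigma_p`, `Sigma_e` instead of the scalars.
#'
#' @param var_a,var_m,var_p,var_e nonnegative variances (trait units^2).
#' @param mu intercept.
#' @param fixed_effects named numeric vector, subset of
#'   `c(gender=, batch=, diet=)`.
#' @param Sigma_a,Sigma_p,Sigma_e optional 2x2 covariance blocks
#'   (positive semidefinite) switching the generator to bivariate mode.
#' @export
true_params <- function(var_a = 0.5, var_m = 0.05, var_p = 0.1, var_e = 0.35,
                        mu = 0,
                        fixed_effects = c(gender = 0.3, batch = 0.5, diet = 0.3),
                        Sigma_a = NULL, Sigma_p = NULL, Sigma_e = NULL) {
  stopifnot(var_a >= 0, var_m >= 0, var_p >= 0, var_e >= 0)
  for (S in list(Sigma_a, Sigma_p, Sigma_e)) {
    if (!is.null(S)) {
      stopifnot(is.matrix(S), dim(S) == c(2, 2))
      if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
        stop("covariance block is not positive semidefinite")
    }
  }
  structure(list(var_a = var_a, var_m = var_m, var_p = var_p, var_e = var_e,
                 mu = mu, fixed_effects = fixed_effects,
                 Sigma_a = Sigma_a, Sigma_p = Sigma_p, Sigma_e = Sigma_e,
                 bivariate = !is.null(Sigma_a)),
            class = "true_params")
}

#' Simulate a pedigree from a herd design
#'
#' Founders (dams `D*`, sires `S*`) have unknown parents.  Each dam is mated
#' to one sire drawn at random and offspring are assigned to dams
#' multinomially (uniform litter probabilities), so litter sizes vary.
#' Offspring sex is Bernoulli(1/2).
#'
#' @param design a [herd_design()].
#' @param seed integer seed; identical seeds give identical pedigrees.
#' @return data frame `id, sire, dam, sex, founder`, parents before
#'   offspring.
#' @export
simulate_pedigree <- function(design = herd_design(), seed = 1) {
  stopifnot(inherits(design, "herd_design"))
  set.seed(seed)
  sires <- paste0("S", seq_len(design$n_sires))
  dams <- paste0("D", seq_len(design$n_dams))
  ped <- data.frame(id = c(sires, dams),
                    sire = NA_character_, dam = NA_character_,
                    sex = c(rep("M", design$n_sires), rep("F", design$n_dams)),
                    stringsAsFactors = FALSE)
  if (design$n_offspring > 0) {
    mate <- stats::setNames(sample(sires, design$n_dams, replace = TRUE), dams)
    od <- sample(dams, design$n_offspring, replace = TRUE)
    off <- data.frame(id = paste0("O", seq_len(design$n_offspring)),
                      sire = unname(mate[od]), dam = od,
                      sex = sample(c("M", "F"), design$n_offspring,
                                   replace = TRUE),
                      stringsAsFactors = FALSE)
    ped <- rbind(ped, off)
  }
  ped$founder <- is.na(ped$sire)
  ped
}

# Drop two haplotypes per animal down a pedigree.  `founder_draw(k)` returns
# the allele vector (length n_loci) for the k-th fresh founder haplotype;
# a missing parent contributes a fresh founder haplotype.
.gene_drop <- function(ped, n_loci, founder_draw) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  H1 <- matrix(0, n, n_loci)
  H2 <- matrix(0, n, n_loci)
  hap_counter <- 0L
  fresh <- function() {
    hap_counter <<- hap_counter + 1L
    founder_draw(hap_counter)
  }
  from_parent <- function(p) {
    if (is.na(p)) return(fresh())
    pick <- stats::runif(n_loci) < 0.5
    h <- H1[p, ]
    h[!pick] <- H2[p, !pick]
    h
  }
  for (i in seq_len(n)) {
    if (is.na(si[i]) && is.na(di[i])) {
      H1[i, ] <- fresh()
      H2[i, ] <- fresh()
    } else {
      H1[i, ] <- from_parent(si[i])
      H2[i, ] <- from_parent(di[i])
    }
  }
  list(H1 = H1, H2 = H2, ids = ped$id)
}

#' Simulate SNP dosages by Mendelian gene dropping
#'
#' Founder allele frequencies are uniform on `maf_range` (mirroring a MAF
#' filter on retained markers); founder haplotypes are Bernoulli draws and
#' descendants inherit one random haplotype from each parent, so allele
#' transmission respects the pedigree exactly.
#'
#' @param ped pedigree (parents before offspring).
#' @param n_snps number of markers (> 0).
#' @param maf_range interval for founder allele frequencies.
#' @param seed integer seed.
#' @return integer dosage matrix (animals x markers, values 0/1/2) with
#'   animal ids as rownames and attribute `allele_freqs` (founder
#'   frequencies).
#' @export
simulate_genotypes <- function(ped, n_snps, maf_range = c(0.05, 0.5),
                               seed = 1) {
  if (n_snps < 1) stop("n_snps must be positive")
  ped <- validate_pedigree(ped)
  set.seed(seed)
  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  drop <- .gene_drop(ped, n_snps,
                     founder_draw = function(k) stats::rbinom(n_snps, 1L, p))
  dos <- drop$H1 + drop$H2
  dimnames(dos) <- list(ped$id, paste0("snp", seq_len(n_snps)))
  attr(dos, "allele_freqs") <- p
  dos
}

#' Empirical relationship matrix by gene dropping (IBD oracle)
#'
#' Drops uniquely labelled founder haplotypes down the pedigree at `n_loci`
#' independent loci and returns twice the realized kinship:
#' \eqn{\hat a_{ij} = 2 \bar\varphi_{ij}} with
#' \eqn{\varphi_{ij}} the probability that random alleles from i and j are
#' identical by descent, and \eqn{\hat a_{ii} = 1 + \hat F_i}.  Serves as an
#' independent Monte-Carlo check of [build_A()].
#'
#' @param ped pedigree.
#' @param n_loci number of independent loci (Monte-Carlo precision).
#' @param seed integer seed.
#' @param return_se also return the per-entry Monte-Carlo standard error
#'   (standard deviation of the per-locus statistic over `sqrt(n_loci)`).
#' @export
gene_drop_relationship <- function(ped, n_loci = 1e5, seed = 1,
                                   return_se = FALSE) {
  ped <- validate_pedigree(ped)
  set.seed(seed)
  drop <- .gene_drop(ped, n_loci,
                     founder_draw = function(k) rep.int(k, n_loci))
  # loci in rows for contiguous column access in the pair loop
  T1 <- t(drop$H1); T2 <- t(drop$H2)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  SE <- if (return_se) A else NULL
  for (i in seq_len(n)) {
    h1 <- T1[, i]; h2 <- T2[, i]
    fi <- h1 == h2
    A[i, i] <- 1 + mean(fi)
    if (return_se) {
      m <- mean(fi)
      SE[i, i] <- sqrt(max(m - m^2, 0) / n_loci)
    }
    for (j in seq_len(i - 1L)) {
      g1 <- T1[, j]; g2 <- T2[, j]
      s <- ((h1 == g1) + (h1 == g2) + (h2 == g1) + (h2 == g2)) / 2
      m1 <- mean(s)
      A[i, j] <- A[j, i] <- m1
      if (return_se)
        SE[i, j] <- SE[j, i] <- sqrt(max(mean(s * s) - m1^2, 0) / n_loci)
    }
  }
  if (return_se) list(A = A, se = SE) else A
}

#' Simulate an ASV count table
#'
#' Counts are multinomial draws of fixed sequencing depth from per-animal
#' relative-abundance profiles: ASV baselines on the log scale plus animal-
#' specific log-normal noise (`log_sd`), optionally thinned by a per-ASV
#' presence probability to create structural zeros that exercise the
#' prevalence filter.
#'
#' @param ids character vector of animal ids (one sample each).
#' @param n_asvs number of ASVs.
#' @param depth sequencing depth per sample (every row sums to `depth`).
#' @param log_mean_sd spread of ASV baseline log-abundances.
#' @param log_sd animal-level overdispersion on the log scale (0 = all
#'   animals share one expected profile).
#' @param presence_prob scalar or per-ASV probability that an ASV is present
#'   in a given animal.
#' @param seed integer seed.
#' @return count matrix (animals x ASVs) with ids as rownames.
#' @export
simulate_microbiome <- function(ids, n_asvs = 400, depth = 17688,
                                log_mean_sd = 1.5, log_sd = 1,
                                presence_prob = 1, seed = 1) {
  stopifnot(n_asvs >= 1, depth >= 1)
  set.seed(seed)
  n <- length(ids)
  base <- stats::rnorm(n_asvs, 0, log_mean_sd)
  lat <- matrix(base, n, n_asvs, byrow = TRUE) +
    matrix(stats::rnorm(n * n_asvs, 0, log_sd), n, n_asvs)
  w <- exp(lat)
  if (any(presence_prob < 1)) {
    pp <- rep_len(presence_prob, n_asvs)
    mask <- matrix(stats::rbinom(n * n_asvs, 1L, rep(pp, each = n)),
                   n, n_asvs)
    w <- w * mask
  }
  counts <- t(vapply(seq_len(n), function(j) {
    wj <- w[j, ]
    if (sum(wj) == 0) wj <- rep(1, n_asvs)
    stats::rmultinom(1L, depth, wj)[, 1L]
  }, integer(n_asvs)))
  dimnames(counts) <- list(as.character(ids), paste0("asv", seq_len(n_asvs)))
  counts
}

#' Pre-factor a relationship matrix for repeated simulation
#'
#' Eigen-decomposes a PSD relationship matrix once so that many replicate
#' draws of correlated random effects are cheap.
#'
#' @param K symmetric PSD matrix with id dimnames.
#' @param label name used in error messages.
#' @export
factor_kinship <- function(K, label = deparse(substitute(K))) {
  ed <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(ed$values) < -1e-6 * max(abs(ed$values)))
    stop("matrix '", label, "' is not positive semidefinite (min eigenvalue ",
         signif(min(ed$values), 3), ")")
  structure(list(vectors = ed$vectors,
                 sqrt_values = sqrt(pmax(ed$values, 0)),
                 ids = rownames(K)),
            class = "kin_factor")
}

# Draw r columns of N(0, var * K); returns ids x r matrix.
.draw_effect <- function(kf, var, r = 1L) {
  n <- length(kf$ids)
  z <- matrix(stats::rnorm(n * r), n, r)
  out <- kf$vectors %*% (kf$sqrt_values * z) * sqrt(var)
  rownames(out) <- kf$ids
  out
}

#' Simulate phenotypes under the generative animal model
#'
#' Draws \eqn{a \sim N(0, K_g \sigma_a^2)}, \eqn{m \sim N(0, K_m
#' \sigma_m^2)} (animals absent from `K_microbial` get no microbial effect
#' and are flagged), dam-level \eqn{p \sim N(0, I\sigma_p^2)}, iid
#' residuals, and assembles \eqn{y = Xb + Wp + Z_1 a + Z_2 m + e} for the
#' non-founder animals.  With 2x2 covariance blocks in `truth` the
#' bivariate model is simulated with Kronecker covariance
#' \eqn{K \otimes \Sigma}.
#'
#' @param ped pedigree; phenotypes are generated for non-founders.
#' @param truth a [true_params()] object.
#' @param K_genetic relationship matrix (or [factor_kinship()] result)
#'   covering at least the phenotyped animals; `NULL` means independent
#'   genetic effects (K = I).
#' @param K_microbial microbial relationship matrix (or factor) whose ids
#'   define which animals carry a microbial effect; `NULL` means none.
#' @param n_batches,n_diets numbers of balanced-random factor levels.
#' @param seed integer seed.
#' @return data frame with id, dam, sire, gender, batch, diet, microbiota
#'   flag and trait column(s) `y` (or `y1`, `y2`), plus attribute
#'   `"effects"` holding the drawn true effects.
#' @export
simulate_phenotypes <- function(ped, truth = true_params(), K_genetic = NULL,
                                K_microbial = NULL, n_batches = 2,
                                n_diets = 2, seed = 1) {
  ped <- validate_pedigree(ped)
  rec <- ped[!ped$founder, , drop = FALSE]
  if (!nrow(rec)) stop("pedigree has no non-founder animals to phenotype")
  set.seed(seed)
  n <- nrow(rec)
  gender <- if ("sex" %in% names(ped)) rec$sex else
    sample(c("F", "M"), n, replace = TRUE)
  batch <- paste0("B", sample(rep_len(seq_len(n_batches), n)))
  diet <- paste0("T", sample(rep_len(seq_len(n_diets), n)))
  fx <- truth$fixed_effects
  if (is.null(fx)) fx <- numeric(0)
  eta <- rep(truth$mu, n)
  if (!is.na(fx["gender"])) eta <- eta + fx[["gender"]] * (gender == "M")
  if (!is.na(fx["batch"])) eta <- eta + fx[["batch"]] * (batch != "B1")
  if (!is.na(fx["diet"])) eta <- eta + fx[["diet"]] * (diet != "T1")

  kf_g <- if (is.null(K_genetic)) NULL else
    if (inherits(K_genetic, "kin_factor")) K_genetic else
      factor_kinship(K_genetic, "K_genetic")
  kf_m <- if (is.null(K_microbial)) NULL else
    if (inherits(K_microbial, "kin_factor")) K_microbial else
      factor_kinship(K_microbial, "K_microbial")
  if (!is.null(kf_g) && !all(rec$id %in% kf_g$ids))
    stop("K_genetic does not cover all phenotyped animals")
  dams <- unique(rec$dam)
  r <- if (truth$bivariate) 2L else 1L

  draw_block <- function(kf, ids, var, Sigma) {
    if (truth$bivariate) {
      L <- chol(Sigma + diag(1e-12, 2))
      raw <- if (is.null(kf)) matrix(stats::rnorm(length(ids) * 2),
                                     ncol = 2, dimnames = list(ids, NULL))
             else .draw_effect(kf, 1, 2)
      raw %*% L
    } else {
      if (var == 0) matrix(0, length(if (is.null(kf)) ids else kf$ids), 1,
                           dimnames = list(if (is.null(kf)) ids else kf$ids))
      else if (is.null(kf)) matrix(stats::rnorm(length(ids), 0, sqrt(var)),
                                   dimnames = list(ids, NULL))
      else .draw_effect(kf, var)
    }
  }
  a <- draw_block(kf_g, rec$id, truth$var_a, truth$Sigma_a)
  if (is.null(rownames(a))) rownames(a) <- if (is.null(kf_g)) rec$id else kf_g$ids
  p <- draw_block(NULL, dams, truth$var_p, truth$Sigma_p)
  e <- draw_block(NULL, rec$id, truth$var_e, truth$Sigma_e)
  m <- NULL
  has_mb <- rep(FALSE, n)
  if (!is.null(kf_m)) {
    m <- if (truth$bivariate) .draw_effect(kf_m, truth$var_m, 2) else
      .draw_effect(kf_m, truth$var_m)
    has_mb <- rec$id %in% kf_m$ids
  }
  y <- matrix(eta, n, r) + a[rec$id, , drop = FALSE] +
    p[rec$dam, , drop = FALSE] + e
  if (!is.null(m)) {
    idxm <- match(rec$id, rownames(m))
    add <- m[idxm[!is.na(idxm)], , drop = FALSE]
    y[!is.na(idxm), ] <- y[!is.na(idxm), ] + add
  }
  out <- data.frame(id = rec$id, dam = rec$dam, sire = rec$sire,
                    gender = gender, batch = batch, diet = diet,
                    microbiota = has_mb, stringsAsFactors = FALSE)
  if (r == 1L) out$y <- y[, 1] else { out$y1 <- y[, 1]; out$y2 <- y[, 2] }
  attr(out, "effects") <- list(a = a, m = m, p = p, e = e)
  out
}

#' Select the genotyped subset: one male and one female per litter
#'
#' Litters are dam groups; within each litter one male and one female
#' offspring are picked at random, then the selection is topped up (or
#' truncated) at random to exactly `n`.
#'
#' @param ped pedigree with `sex` column.
#' @param n target number of genotyped offspring.
#' @param seed integer seed.
#' @export
select_genotyped <- function(ped, n, seed = 1) {
  set.seed(seed)
  off <- ped[!is.na(ped$dam), , drop = FALSE]
  pick <- unlist(lapply(split(off, off$dam), function(litter) {
    c(if (any(litter$sex == "M"))
        sample(litter$id[litter$sex == "M"], 1L),
      if (any(litter$sex == "F"))
        sample(litter$id[litter$sex == "F"], 1L))
  }), use.names = FALSE)
  if (length(pick) > n) pick <- sample(pick, n)
  if (length(pick) < n)
    pick <- c(pick, sample(setdiff(off$id, pick), n - length(pick)))
  sort(pick)
}

#' Simulate a complete herd data set
#'
#' Composes pedigree, gene-dropped genotypes for the genotyped subset,
#' ASV counts for the microbiota subset, the relationship matrices used as
#' generative covariances (pedigree A for genetics, O for microbiota), and
#' phenotypes.  This is the entry point used by the analysis scripts and
#' the validation experiments.
#'
#' @param design a [herd_design()].
#' @param truth a [true_params()].
#' @param n_snps,n_asvs,depth sizes of the marker and ASV panels.
#' @param seed integer seed driving every stage.
#' @return list with `ped`, `geno` (genotyped subset), `counts` (microbiota
#'   subset), `pheno`, `A`, `O`, `truth`, `design`.
#' @export
simulate_herd <- function(design = herd_design(), truth = true_params(),
                          n_snps = 3000, n_asvs = 400, depth = 5000,
                          seed = 1) {
  ped <- simulate_pedigree(design, seed = seed)
  A <- build_A(ped)
  gids <- select_genotyped(ped, design$n_genotyped, seed = seed + 1L)
  geno <- simulate_genotypes(ped, n_snps, seed = seed + 2L)[gids, , drop = FALSE]
  off <- ped$id[!ped$founder]
  set.seed(seed + 3L)
  mids <- sort(sample(off, design$n_with_microbiota))
  counts <- simulate_microbiome(mids, n_asvs = n_asvs, depth = depth,
                                presence_prob = 0.6, seed = seed + 4L)
  O <- microbiome_pipeline(counts, depth = depth, seed = seed + 5L)$O
  pheno <- simulate_phenotypes(ped, truth, K_genetic = A, K_microbial = O,
                               n_batches = design$n_batches,
                               n_diets = design$n_diets, seed = seed + 6L)
  pheno$genotyped <- pheno$id %in% gids
  list(ped = ped, geno = geno, counts = counts, pheno = pheno,
       A = A, O = O, truth = truth, design = design)
}

#' Simulate raw growth and feed-intake records
#'
#' Generates body weights and total feed intake over an interval such that
#' daily feed intake follows the linear model
#' \eqn{FI_i = \mu + \alpha\, midBW_i^{0.75} + \beta\, ADG_i + RFI_i}
#' with known coefficients, for testing the trait-derivation functions.
#'
#' @param n number of animals.
#' @param days interval length in days.
#' @param mu,alpha,beta true regression coefficients (g/day scale).
#' @param sd_rfi standard deviation of the residual feed intake (0 gives an
#'   exact fit).
#' @param seed integer seed.
#' @export
simulate_growth_records <- function(n, days = 35, mu = 10, alpha = 0.1,
                                    beta = 2, sd_rfi = 5, seed = 1) {
  set.seed(seed)
  bw_start <- stats::rnorm(n, 840, 130)
  adg <- stats::rnorm(n, 35, 4.5)
  bw_end <- bw_start + adg * days
  midbw75 <- ((bw_start + bw_end) / 2)^0.75
  fi_daily <- mu + alpha * midbw75 + beta * adg + stats::rnorm(n, 0, sd_rfi)
  data.frame(animal_id = paste0("O", seq_len(n)),
             bw_start = bw_start, bw_end = bw_end, days = days,
             feed_intake_total = fi_daily * days,
             stringsAsFactors = FALSE)
}
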