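# Delta-method SE of f(theta) given gradient g and cov(theta).
.delta_se <- function(grad, ai_inverse, labels) {
  g <- numeric(nrow(ai_inverse))
  names(g) <- rownames(ai_inverse)
  g[labels] <- grad
  sqrt(max(0, c(g %*% ai_inverse %*% g)))
}

# Ratio theta[num] / sum(theta[denom]) with delta-method SE.
.variance_ratio <- function(fit, num, denom, name, model) {
  th <- fit$theta
  denom <- intersect(denom, names(th))
  if (!(num %in% names(th))) stop("component '", num, "' absent from fit")
  den <- sum(th[denom])
  if (den <= 0) stop("zero denominator in ", name)
  val <- th[[num]] / den
  grad <- stats::setNames(rep(-val / den, length(denom)), denom)
  grad[num] <- (if (num %in% denom) -val / den else 0) + 1 / den
  se <- .delta_se(grad, fit$ai_inverse, names(grad))
  data.frame(name = name, value = unname(val), se = se, model = model,
             boundary = any(fit$boundary[c(num, denom)]),
             stringsAsFactors = FALSE)
}

#' Heritability from a model-G (or GM) fit
#'
#' \eqn{h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_p^2 + \sigma_e^2)}; terms
#' absent from the fit contribute zero.  The standard error is the
#' first-order delta method using the inverse average-information matrix.
#'
#' @param fit `reml_fit` containing an `a` component.
#' @return one-row data frame `name, value, se, model, boundary`.
#' @export
heritability <- function(fit) {
  .variance_ratio(fit, "a", c("a", "p", "e"), "h2",
                  fit$model %||% "G")
}

#' Microbiability from a model-M fit
#'
#' \eqn{m^2 = \sigma_m^2 / (\sigma_m^2 + \sigma_p^2 + \sigma_e^2)}.
#'
#' @param fit `reml_fit` containing an `m` component.
#' @export
microbiability <- function(fit) {
  .variance_ratio(fit, "m", c("m", "p", "e"), "m2",
                  fit$model %||% "M")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Direct heritability and microbiability from a model-GM fit
#'
#' Both ratios share the four-component denominator
#' \eqn{\sigma_a^2 + \sigma_m^2 + \sigma_p^2 + \sigma_e^2}:
#' \eqn{h_d^2 = \sigma_a^2 / (\cdot)}, \eqn{m_d^2 = \sigma_m^2 / (\cdot)}.
#'
#' @param fit `reml_fit` with both `a` and `m` components.
#' @return two-row data frame (`hd2`, `md2`).
#' @export
direct_partition <- function(fit) {
  stopifnot(all(c("a", "m") %in% names(fit$theta)))
  rbind(.variance_ratio(fit, "a", c("a", "m", "p", "e"), "hd2", "GM"),
        .variance_ratio(fit, "m", c("a", "m", "p", "e"), "md2", "GM"))
}

#' Genetic correlation from a bivariate fit
#'
#' \eqn{r_g = \sigma_{a_1 a_2} / \sqrt{\sigma_{a_1}^2 \sigma_{a_2}^2}} with
#' a delta-method SE over the three genetic parameters.  When either
#' genetic variance is pinned at the boundary the correlation is undefined
#' and returned as `NA` with `boundary = TRUE`.
#'
#' @param fit `reml_fit` from [fit_bivariate()].
#' @export
genetic_correlation <- function(fit) {
  th <- fit$theta
  stopifnot(all(c("a11", "a12", "a22") %in% names(th)))
  if (any(fit$boundary[c("a11", "a22")]))
    return(data.frame(name = "rg", value = NA_real_, se = NA_real_,
                      model = "bivariate-G", boundary = TRUE,
                      stringsAsFactors = FALSE))
  v1 <- th[["a11"]]; v2 <- th[["a22"]]; cv <- th[["a12"]]
  rg <- cv / sqrt(v1 * v2)
  grad <- c(a11 = -rg / (2 * v1), a12 = 1 / sqrt(v1 * v2),
            a22 = -rg / (2 * v2))
  se <- .delta_se(grad, fit$ai_inverse, names(grad))
  data.frame(name = "rg", value = unname(rg), se = se,
             model = "bivariate-G", boundary = any(fit$boundary),
             stringsAsFactors = FALSE)
}

#' Phenotypic correlation matrix with significance stars
#'
#' Pairwise-complete Pearson correlations with two-sided t-test p-values,
#' starred at `* p < 0.05`, `** p < 0.01`, `*** p < 0.001`.
#'
#' @param traits data frame or matrix of trait columns.
#' @return list with matrices `r`, `p`, `stars`.
#' @export
phenotypic_correlations <- function(traits) {
  traits <- as.data.frame(traits)
  nm <- names(traits)
  k <- length(nm)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  stars <- matrix("", k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    r[i, i] <- 1
    for (j in seq_len(i - 1L)) {
      ok <- stats::complete.cases(traits[[i]], traits[[j]])
      if (sum(ok) < 3) stop("fewer than 3 complete pairs for ",
                            nm[i], " vs ", nm[j])
      ct <- suppressWarnings(
        stats::cor.test(traits[[i]][ok], traits[[j]][ok]))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
      s <- if (is.na(ct$p.value)) "" else if (ct$p.value < 0.001) "***"
           else if (ct$p.value < 0.01) "**" else if (ct$p.value < 0.05) "*"
           else ""
      stars[i, j] <- stars[j, i] <- s
    }
  }
  list(r = r, p = p, stars = stars)
}

#' Per-trait model-comparison workflow
#'
#' For one trait: backward-eliminates the fixed effects; fits each of the
#' models G (genetic), M (microbial) and GM (both) with and without the
#' maternal permanent environmental term; decides inclusion by
#' likelihood-ratio test at `lrt_alpha` (reporting both AICs); and derives
#' heritability, microbiability and the direct partition from the selected
#' fits.  Model G uses all phenotyped animals; models M and GM are
#' restricted to animals with microbiota profiles so that O stays
#' well-defined.
#'
#' @param pheno phenotype data frame (columns `id`, `dam`, factors, trait).
#' @param trait trait column name.
#' @param K_a genetic relationship matrix (H).
#' @param K_m microbial relationship matrix (O).
#' @param candidates candidate fixed effects for backward elimination.
#' @param alpha fixed-effect retention threshold (default 0.05).
#' @param lrt_alpha maternal-term inclusion threshold (default 0.01).
#' @param models subset of `c("G", "M", "GM")` to fit.
#' @param ... passed to [fit_aireml()].
#' @return list with `table` (one row per model: N, fixed effects, AICs,
#'   LRT p, variance components, ratios with SEs, convergence) and `fits`.
#' @export
run_trait_workflow <- function(pheno, trait, K_a, K_m,
                               candidates = c("gender", "batch", "diet"),
                               alpha = 0.05, lrt_alpha = 0.01,
                               models = c("G", "M", "GM"), ...) {
  fixed <- backward_eliminate_fixed(pheno, trait, candidates, alpha)
  fits <- list()
  rows <- list()
  for (mod in models) {
    Ka <- if (mod %in% c("G", "GM")) K_a else NULL
    Km <- if (mod %in% c("M", "GM")) K_m else NULL
    with_p <- try(fit_animal_model(pheno, trait, fixed, Ka, Km,
                                   maternal = TRUE, ...), silent = TRUE)
    no_p <- try(fit_animal_model(pheno, trait, fixed, Ka, Km,
                                 maternal = FALSE, ...), silent = TRUE)
    if (inherits(with_p, "try-error") || inherits(no_p, "try-error")) {
      warning("model ", mod, " failed for ", trait, "; skipping")
      next
    }
    test <- lrt(with_p, no_p)
    include_p <- test$p_value < lrt_alpha
    chosen <- if (include_p) with_p else no_p
    fits[[mod]] <- chosen
    th <- chosen$theta
    getv <- function(lbl) if (lbl %in% names(th)) th[[lbl]] else NA_real_
    h2 <- m2 <- data.frame(value = NA_real_, se = NA_real_)
    if (mod == "G") h2 <- heritability(chosen)
    if (mod == "M") m2 <- microbiability(chosen)
    if (mod == "GM") {
      dp <- direct_partition(chosen)
      h2 <- dp[dp$name == "hd2", ]
      m2 <- dp[dp$name == "md2", ]
    }
    rows[[mod]] <- data.frame(
      trait = trait, model = mod, n = chosen$n,
      fixed = paste(fixed, collapse = "+"),
      aic_with_p = aic(with_p), aic_without_p = aic(no_p),
      lrt_p = test$p_value, maternal_included = include_p,
      var_a = getv("a"), var_m = getv("m"), var_p = getv("p"),
      var_e = getv("e"),
      h2 = h2$value, h2_se = h2$se, m2 = m2$value, m2_se = m2$se,
      converged = chosen$converged, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, fits = fits, fixed = fixed)
}
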