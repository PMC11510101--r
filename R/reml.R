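#' Restricted log-likelihood of a linear mixed model
#'
#' Evaluates \eqn{\ell_R(\theta) = -\tfrac12 [\log|V| + \log|X'V^{-1}X| -
#' \log|X'X| + y'Py]} with \eqn{V = \sum_k \theta_k C_k + \theta_e I} and
#' \eqn{P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}}.  The additive
#' constant \eqn{-\tfrac{n-p}{2}\log 2\pi} is omitted and the
#' \eqn{\log|X'X|} term is subtracted, making the value invariant to any
#' full-rank reparameterization of X; all likelihood comparisons in the
#' package use this same convention.
#'
#' @param y numeric response vector (no missing values).
#' @param X fixed-effect design matrix (default: intercept only); must have
#'   full column rank.
#' @param random named list of record-aligned covariance structures
#'   \eqn{C_k = Z_k K_k Z_k'} (n x n matrices), one per non-residual
#'   variance component.
#' @param theta variance vector in the order `c(names(random), "e")`.
#' @return scalar restricted log-likelihood (`-Inf` if V is not positive
#'   definite).
#' @export
reml_loglik <- function(y, X = NULL, random = list(), theta) {
  X <- .check_X(X, length(y))
  Clist <- c(.check_random(random, length(y)), list(e = diag(length(y))))
  stopifnot(length(theta) == length(Clist))
  ops <- .make_dense_ops(y, X, Clist)
  res <- ops$eval(as.numeric(theta))
  if (is.null(res)) -Inf else res$ll
}

.check_X <- function(X, n) {
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("fixed-effect design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  X
}

.check_random <- function(random, n) {
  if (length(random) == 0) return(list())
  stopifnot(!is.null(names(random)), !anyDuplicated(names(random)))
  lapply(random, function(C) {
    if (is.list(C) && !is.null(C$inverse)) C <- solve_sym(C$inverse)
    C <- unclass(as.matrix(C))
    stopifnot(nrow(C) == n, ncol(C) == n)
    (C + t(C)) / 2
  })
}

# Dense evaluator: returns loglik, gradient, average-information matrix and
# the pieces (y'P C P y, tr(PC)) needed for the EM fallback, or NULL when
# V(theta) or X'V^-1 X is not positive definite.  `full = FALSE` computes
# the likelihood only (triangular solves, no inverse), for line searches.
.make_dense_ops <- function(y, X, Clist) {
  n <- length(y)
  k <- length(Clist)
  ld_xx <- c(determinant(crossprod(X))$modulus)
  eval_fn <- function(theta, full = TRUE) {
    V <- matrix(0, n, n)
    for (p in seq_len(k)) V <- V + theta[p] * Clist[[p]]
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(NULL)
    dr <- diag(R)
    # refuse V so ill-conditioned that the factorization is unreliable
    if ((min(dr) / max(dr))^2 < 1e-10) return(NULL)
    zx <- backsolve(R, X, transpose = TRUE)
    zy <- backsolve(R, y, transpose = TRUE)
    XVX <- crossprod(zx)
    cX <- tryCatch(chol(XVX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    XVXi <- chol2inv(cX)
    xvy <- crossprod(zx, zy)
    yPy <- sum(zy^2) - c(crossprod(xvy, XVXi %*% xvy))
    ll <- -0.5 * (2 * sum(log(dr)) + 2 * sum(log(diag(cX))) - ld_xx + yPy)
    if (!full) return(list(ll = ll))
    Vi <- chol2inv(R)
    B <- backsolve(R, zx)          # V^-1 X
    P <- Vi - B %*% tcrossprod(XVXi, B)
    Py <- c(backsolve(R, zy)) - c(B %*% (XVXi %*% xvy))
    W <- matrix(0, n, k)
    trPC <- ydot <- numeric(k)
    for (p in seq_len(k)) {
      w <- c(Clist[[p]] %*% Py)
      W[, p] <- w
      trPC[p] <- sum(P * Clist[[p]])
      ydot[p] <- sum(Py * w)
    }
    AI <- 0.5 * crossprod(W, P %*% W)
    list(ll = ll, grad = -0.5 * (trPC - ydot), AI = (AI + t(AI)) / 2,
         ydot = ydot, trPC = trPC)
  }
  list(eval = eval_fn, n = n)
}

# Spectral evaluator for the common two-component case V = th1*C + th2*I:
# one eigendecomposition makes every iteration O(n p^2).
.make_spectral_ops <- function(y, X, C, ed = NULL) {
  n <- length(y)
  if (is.null(ed)) ed <- eigen((C + t(C)) / 2, symmetric = TRUE)
  d <- ed$values
  yt <- c(crossprod(ed$vectors, y))
  Xt <- crossprod(ed$vectors, X)
  ld_xx <- c(determinant(crossprod(X))$modulus)
  eval_fn <- function(theta, full = TRUE) {
    v <- theta[1] * d + theta[2]
    if (any(v <= 1e-12) || min(v) / max(v) < 1e-10) return(NULL)
    B <- Xt / v
    XVX <- crossprod(Xt, B)
    cX <- tryCatch(chol(XVX), error = function(e) NULL)
    if (is.null(cX)) return(NULL)
    XVXi <- chol2inv(cX)
    Pvec <- function(u) {
      uu <- u / v
      uu - c(B %*% (XVXi %*% crossprod(Xt, uu)))
    }
    Py <- Pvec(yt)
    ll <- -0.5 * (sum(log(v)) + 2 * sum(log(diag(cX))) - ld_xx +
                    sum(yt * Py))
    tr_d <- function(dd) {
      M <- crossprod(Xt, Xt * (dd / v^2))
      sum(dd / v) - sum(XVXi * M)
    }
    trPC <- c(tr_d(d), tr_d(rep(1, n)))
    W <- cbind(d * Py, Py)
    ydot <- c(sum(Py * W[, 1]), sum(Py * W[, 2]))
    PW <- cbind(Pvec(W[, 1]), Pvec(W[, 2]))
    AI <- 0.5 * crossprod(W, PW)
    list(ll = ll, grad = -0.5 * (trPC - ydot), AI = (AI + t(AI)) / 2,
         ydot = ydot, trPC = trPC)
  }
  list(eval = eval_fn, n = n)
}

# Newton-type AI-REML iteration with step halving, an EM-REML fallback, and
# boundary pinning of variances at `lower`.
.aireml_loop <- function(ops, theta0, lower, is_var, blocks, tol, max_iter,
                         constrain) {
  k <- length(theta0)
  project <- function(th) {
    if (constrain) th[is_var] <- pmax(th[is_var], lower[is_var])
    for (b in blocks) {
      v1 <- max(th[b[1]], lower[b[1]]); v2 <- max(th[b[3]], lower[b[3]])
      cap <- 0.9995 * sqrt(v1 * v2)
      if (abs(th[b[2]]) > cap) th[b[2]] <- sign(th[b[2]]) * cap
    }
    th
  }
  at_cap <- function(th) {
    for (b in blocks) {
      v1 <- max(th[b[1]], lower[b[1]]); v2 <- max(th[b[3]], lower[b[3]])
      if (abs(th[b[2]]) >= 0.9995 * sqrt(v1 * v2) * (1 - 1e-9)) return(TRUE)
    }
    FALSE
  }
  th <- project(theta0)
  cur <- ops$eval(th)
  if (is.null(cur)) stop("starting values give a non-positive-definite V")
  pinned <- rep(FALSE, k)
  converged <- FALSE
  it <- 0L
  rel <- Inf
  stall <- 0L
  ridge_levels <- c(1e-10, 1e-4, 1e-2, 1, 100)
  ridge_from <- 1L
  while (it < max_iter) {
    it <- it + 1L
    pinned[pinned & cur$grad > 0] <- FALSE
    free <- !pinned
    AIf <- cur$AI[free, free, drop = FALSE]
    scale_ai <- max(diag(AIf), 1)
    nxt <- NULL
    cand <- th
    # Levenberg-Marquardt style: escalate the ridge (tilting the AI step
    # toward the gradient) whenever the step overshoots; cap each step at
    # one unit on the working scale and halve within each ridge level.
    # Start from one level below the last successful ridge so boundary
    # iterations do not re-pay the whole ladder.
    for (ri in seq(max(1L, ridge_from - 1L), length(ridge_levels))) {
      ridge <- ridge_levels[ri] * scale_ai
      delta <- numeric(k)
      sol <- tryCatch(solve(AIf + diag(ridge, sum(free)), cur$grad[free]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      delta[free] <- sol
      big <- max(abs(delta))
      if (big > 1) delta <- delta / big
      step <- 1
      for (h in 1:8) {
        cand <- project(th + step * delta)
        nxt <- ops$eval(cand, full = FALSE)
        if (!is.null(nxt) && nxt$ll >= cur$ll - 1e-8) break
        nxt <- NULL
        step <- step / 2
      }
      if (!is.null(nxt)) { ridge_from <- ri; break }
    }
    if (is.null(nxt)) {
      # EM-REML-type step on the variance parameters, halved until the
      # likelihood does not decrease
      em <- numeric(k)
      em[is_var] <- th[is_var]^2 *
        (cur$ydot[is_var] - cur$trPC[is_var]) / ops$n
      step <- 1
      for (h in 1:10) {
        cand <- project(th + step * em)
        nxt <- ops$eval(cand, full = FALSE)
        if (!is.null(nxt) && nxt$ll >= cur$ll - 1e-8) break
        nxt <- NULL
        step <- step / 2
      }
      if (is.null(nxt)) { cand <- th; nxt <- cur; break }
    }
    nxt <- ops$eval(cand)    # full quantities at the accepted point
    rel <- max(abs(cand - th) / (abs(th) + 1e-6))
    improvement <- nxt$ll - cur$ll
    th <- cand
    cur <- nxt
    if (constrain) pinned <- is_var & (th <= lower * (1 + 1e-6))
    if (rel < tol) { converged <- TRUE; break }
    # a covariance sitting at the PSD cap with a near-flat likelihood means
    # the optimum lies on (or beyond) the correlation boundary: stop
    # crawling along the constraint surface
    stall <- if (at_cap(th) && improvement < 1e-5) stall + 1L else 0L
    if (stall >= 3L) break
  }
  gnorm <- sqrt(sum(cur$grad[!pinned]^2))
  list(theta = th, ll = cur$ll, AI = cur$AI, iterations = it,
       converged = converged, boundary = pinned, gradient_norm = gnorm,
       rel_change = rel)
}

#' Fit a variance-component model by AI-REML
#'
#' Estimates \eqn{\theta} in \eqn{V = \sum_k \theta_k C_k + \theta_e I} by
#' Newton-type updates with the average-information matrix, falling back on
#' EM-REML steps (with step halving) whenever an AI update would leave the
#' parameter space or decrease the likelihood.  The response is standardized
#' internally (variances are optimized on the scale of var(y) = 1, the
#' "working scale") and estimates are returned on the original scale.
#' Variances are constrained to a small positive floor (1e-8 of the
#' phenotypic variance) and flagged when pinned there; `constrain = FALSE`
#' removes the floor (useful in unbiasedness experiments where truncation
#' at zero would bias the replicate mean).
#'
#' @inheritParams reml_loglik
#' @param random named list of covariance structures; an element may also
#'   be `list(inverse = M)` to supply the precision matrix (e.g. a
#'   single-step H-inverse), which is inverted once.
#' @param tol convergence tolerance on the maximum relative change in
#'   \eqn{\theta} (default 1e-8).
#' @param max_iter maximum number of iterations (default 200).
#' @param constrain keep variances nonnegative (default `TRUE`).
#' @param start optional starting values on the original scale; the default
#'   splits the phenotypic variance equally across components.
#' @param spectral_cache optional precomputed `eigen()` of the single
#'   covariance structure, a performance aid when refitting many responses
#'   against the same structure (ignored with more than one random term).
#' @return object of class `reml_fit`: list with `theta` (named estimates),
#'   `se`, `ai_inverse` (estimated covariance of `theta`), `loglik`
#'   (restricted, original scale, [reml_loglik()] convention), `n`,
#'   `rank_X`, `n_params`, `converged`, `iterations`, `boundary`,
#'   `gradient_norm`.
#' @export
fit_aireml <- function(y, X = NULL, random = list(), tol = 1e-8,
                       max_iter = 200, constrain = TRUE, start = NULL,
                       spectral_cache = NULL) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("y contains missing values; subset the records first")
  n <- length(y)
  X <- .check_X(X, n)
  random <- .check_random(random, n)
  k <- length(random) + 1L
  labels <- c(names(random), "e")
  s2 <- stats::var(y)
  if (!is.finite(s2) || s2 <= 0) stop("response has zero variance")
  ys <- y / sqrt(s2)
  theta0 <- if (is.null(start)) rep(1 / k, k) else as.numeric(start) / s2
  ops <- if (length(random) == 1L)
    .make_spectral_ops(ys, X, random[[1L]], ed = spectral_cache)
  else .make_dense_ops(ys, X, c(random, list(e = diag(n))))
  res <- .aireml_loop(ops, theta0, lower = rep(1e-8, k),
                      is_var = rep(TRUE, k), blocks = list(), tol = tol,
                      max_iter = max_iter, constrain = constrain)
  ai_inv <- .safe_inverse(res$AI) * s2^2
  dimnames(ai_inv) <- list(labels, labels)
  theta <- stats::setNames(res$theta * s2, labels)
  rank_X <- ncol(X)
  structure(list(theta = theta, se = sqrt(pmax(diag(ai_inv), 0)),
                 ai_inverse = ai_inv,
                 loglik = res$ll - 0.5 * (n - rank_X) * log(s2),
                 n = n, rank_X = rank_X, n_params = k,
                 converged = res$converged, iterations = res$iterations,
                 boundary = stats::setNames(res$boundary, labels),
                 gradient_norm = res$gradient_norm),
            class = "reml_fit")
}

.safe_inverse <- function(M) {
  out <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(out)) {
    ridge <- 1e-8 * max(diag(M), 1)
    out <- solve(M + diag(ridge, nrow(M)))
  }
  (out + t(out)) / 2
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("AI-REML fit:", x$n, "records,", x$n_params, "(co)variance components\n")
  est <- cbind(estimate = x$theta, se = x$se)
  print(round(est, 6))
  cat("logLik(REML):", format(x$loglik), " converged:", x$converged,
      " iterations:", x$iterations, "\n")
  if (any(x$boundary)) cat("boundary:",
                           paste(names(x$boundary)[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

#' Fit a bivariate animal model by AI-REML
#'
#' Stacks two traits and estimates 2x2 (co)variance blocks for the additive
#' genetic term (covariance \eqn{K \otimes \Sigma_a}), optionally a
#' dam-level maternal permanent environmental term, and the residual.
#' Records of the two traits are linked through shared animals (genetic
#' block) and the same-animal residual covariance.
#'
#' @param y1,y2 response vectors.
#' @param X1,X2 fixed-effect design matrices (default intercepts).
#' @param K relationship matrix with id dimnames (A, H or O).
#' @param ids1,ids2 animal ids of the records, matched to `rownames(K)`.
#' @param dams1,dams2 dam ids per record; supply to include the maternal
#'   permanent environmental blocks.
#' @inheritParams fit_aireml
#' @return `reml_fit` with components named `a11, a12, a22, (p11, p12,
#'   p22,) e11, e12, e22`.
#' @export
fit_bivariate <- function(y1, y2, X1 = NULL, X2 = NULL, K, ids1, ids2,
                          dams1 = NULL, dams2 = NULL, tol = 1e-8,
                          max_iter = 200, start = NULL) {
  n1 <- length(y1); n2 <- length(y2)
  X1 <- .check_X(X1, n1); X2 <- .check_X(X2, n2)
  i1 <- match(as.character(ids1), rownames(K))
  i2 <- match(as.character(ids2), rownames(K))
  if (anyNA(i1) || anyNA(i2)) stop("record ids missing from K")
  n <- n1 + n2
  b1 <- seq_len(n1); b2 <- n1 + seq_len(n2)
  zero <- function() matrix(0, n, n)
  blockify <- function(M11, M12, M22) {
    C <- zero()
    if (!is.null(M11)) C[b1, b1] <- M11
    if (!is.null(M22)) C[b2, b2] <- M22
    if (!is.null(M12)) { C[b1, b2] <- M12; C[b2, b1] <- t(M12) }
    C
  }
  Clist <- list(a11 = blockify(K[i1, i1], NULL, NULL),
                a12 = blockify(NULL, K[i1, i2, drop = FALSE], NULL),
                a22 = blockify(NULL, NULL, K[i2, i2]))
  maternal <- !is.null(dams1) && !is.null(dams2)
  if (maternal) {
    D11 <- outer(dams1, dams1, "==") * 1
    D22 <- outer(dams2, dams2, "==") * 1
    D12 <- outer(dams1, dams2, "==") * 1
    Clist <- c(Clist, list(p11 = blockify(D11, NULL, NULL),
                           p12 = blockify(NULL, D12, NULL),
                           p22 = blockify(NULL, NULL, D22)))
  }
  S12 <- outer(as.character(ids1), as.character(ids2), "==") * 1
  Clist <- c(Clist, list(e11 = blockify(diag(n1), NULL, NULL),
                         e12 = blockify(NULL, S12, NULL),
                         e22 = blockify(NULL, NULL, diag(n2))))
  labels <- names(Clist)
  is_var <- !grepl("12$", labels)
  blocks <- lapply(unique(sub("[0-9]+$", "", labels)), function(pre)
    match(paste0(pre, c("11", "12", "22")), labels))
  s1 <- stats::sd(y1); s2 <- stats::sd(y2)
  ys <- c(y1 / s1, y2 / s2)
  X <- rbind(cbind(X1, matrix(0, n1, ncol(X2))),
             cbind(matrix(0, n2, ncol(X1)), X2))
  colnames(X) <- c(paste0("t1:", colnames(X1)), paste0("t2:", colnames(X2)))
  X <- .check_X(X, n)
  nt <- sum(is_var) / 2  # variance components per trait
  theta0 <- if (is.null(start)) {
    # split each trait's variance equally across its components and seed
    # the covariances from the observed cross-trait correlation on shared
    # animals (damped; respects positive definiteness of the blocks)
    th <- numeric(length(labels))
    th[is_var] <- 1 / nt
    shared <- intersect(as.character(ids1), as.character(ids2))
    if (length(shared) >= 10) {
      r_obs <- stats::cor(y1[match(shared, ids1)] / s1,
                          y2[match(shared, ids2)] / s2)
      if (is.finite(r_obs)) th[!is_var] <- 0.8 * r_obs / nt
    }
    th
  } else as.numeric(start) / rep(c(s1^2, s1 * s2, s2^2),
                                 length.out = length(labels))
  ops <- .make_dense_ops(ys, X, Clist)
  res <- .aireml_loop(ops, theta0, lower = rep(1e-8, length(labels)),
                      is_var = is_var, blocks = blocks, tol = tol,
                      max_iter = max_iter, constrain = TRUE)
  sc <- ifelse(grepl("11$", labels), s1^2,
               ifelse(grepl("22$", labels), s2^2, s1 * s2))
  theta <- stats::setNames(res$theta * sc, labels)
  ai_inv <- .safe_inverse(res$AI) * tcrossprod(sc)
  dimnames(ai_inv) <- list(labels, labels)
  # report the likelihood on the original scale via one dense evaluation
  ll <- {
    ops0 <- .make_dense_ops(c(y1, y2), X, Clist)
    r0 <- ops0$eval(as.numeric(theta))
    if (is.null(r0)) -Inf else r0$ll
  }
  structure(list(theta = theta, se = sqrt(pmax(diag(ai_inv), 0)),
                 ai_inverse = ai_inv, loglik = ll, n = n,
                 rank_X = ncol(X), n_params = length(labels),
                 converged = res$converged, iterations = res$iterations,
                 boundary = stats::setNames(res$boundary, labels),
                 gradient_norm = res$gradient_norm, bivariate = TRUE),
            class = "reml_fit")
}

#' Akaike information criterion of a REML fit
#'
#' \eqn{AIC = -2\,\ell_R + 2k} with k the number of estimated (co)variance
#' components.  Comparable only across fits with identical fixed effects
#' and records.
#'
#' @param fit a `reml_fit`.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  if (!fit$converged) warning("AIC from an unconverged fit")
  -2 * fit$loglik + 2 * fit$n_params
}

#' Likelihood-ratio test between nested REML fits
#'
#' Refers \eqn{2(\ell_{full} - \ell_{red})} to a plain chi-squared
#' distribution with df equal to the difference in parameter counts.  For a
#' single variance tested on its boundary the 50:50 mixture
#' \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1} is available via
#' `boundary_mixture = TRUE` (the plain chi-squared is conservative there).
#'
#' @param full,reduced nested `reml_fit`s on the same records and fixed
#'   effects.
#' @param boundary_mixture use the boundary mixture p-value (df must be 1).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lrt <- function(full, reduced, boundary_mixture = FALSE) {
  stopifnot(inherits(full, "reml_fit"), inherits(reduced, "reml_fit"))
  df <- full$n_params - reduced$n_params
  if (df <= 0) stop("'full' must have more parameters than 'reduced'")
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < -1e-6 * max(1, abs(full$loglik)))
    stop("full-model log-likelihood is below the reduced model's; ",
         "refit the reduced model from the full model's estimates")
  stat <- max(stat, 0)
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  if (boundary_mixture) {
    if (df != 1) stop("boundary mixture implemented for df = 1 only")
    p <- if (stat == 0) 1 else 0.5 * p
  }
  list(statistic = stat, df = df, p_value = p)
}

#' Backward elimination of categorical fixed effects
#'
#' Iteratively drops the least significant factor (partial F-test in the
#' fixed-effects-only linear model) while its p-value is at least `alpha`.
#' Ties are broken deterministically by dropping the factor listed last
#' among the candidates.  Factors aliased with others are dropped with a
#' warning.
#'
#' @param data data frame containing the trait and candidate factors.
#' @param trait response column name.
#' @param candidates candidate factor names (each needs >= 2 observed
#'   levels; others are skipped with a warning).
#' @param alpha retention threshold (default 0.05).
#' @return character vector of retained factors (possibly empty).
#' @export
backward_eliminate_fixed <- function(data, trait,
                                     candidates = c("gender", "batch", "diet"),
                                     alpha = 0.05) {
  keep_cand <- candidates[vapply(candidates, function(v) {
    v %in% names(data) && length(unique(stats::na.omit(data[[v]]))) >= 2
  }, logical(1))]
  if (length(keep_cand) < length(candidates))
    warning("skipping candidate(s) without >= 2 observed levels: ",
            paste(setdiff(candidates, keep_cand), collapse = ", "))
  current <- keep_cand
  repeat {
    if (!length(current)) break
    fml <- stats::reformulate(current, response = trait)
    fit <- stats::lm(fml, data = data)
    if (any(is.na(stats::coef(fit)))) {
      al <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      bad <- current[vapply(current, function(v) any(startsWith(al, v)),
                            logical(1))]
      warning("dropping confounded factor(s): ", paste(bad, collapse = ", "))
      current <- setdiff(current, bad)
      next
    }
    d1 <- stats::drop1(fit, test = "F")
    pv <- d1[["Pr(>F)"]][match(current, rownames(d1))]
    removable <- which(pv >= alpha)
    if (!length(removable)) break
    # among the least significant, drop the one listed last
    cand_max <- removable[pv[removable] == max(pv[removable])]
    worst <- cand_max[which.max(match(current[cand_max], candidates))]
    current <- setdiff(current, current[worst])
  }
  candidates[candidates %in% current]
}

#' Covariance structure of an animal-level random effect
#'
#' Expands a relationship matrix to record level: `C = K[ids, ids]`
#' (equivalently \eqn{Z K Z'} with incidence Z).
#'
#' @param K relationship matrix with animal ids as dimnames.
#' @param ids id per record.
#' @export
kin_structure <- function(K, ids) {
  m <- match(as.character(ids), rownames(K))
  if (anyNA(m)) stop("ids not in K: ",
                     paste(utils::head(ids[is.na(m)], 5L), collapse = ", "))
  K[m, m, drop = FALSE]
}

#' Covariance structure of an iid grouped random effect
#'
#' Record-level \eqn{Z Z'} for a grouping factor (e.g. dam for the maternal
#' permanent environmental effect): 1 where two records share a level.
#'
#' @param f grouping vector, one entry per record.
#' @export
iid_structure <- function(f) {
  f <- as.character(f)
  outer(f, f, "==") * 1
}

#' Fit a single-trait animal model (G, M or GM)
#'
#' Convenience wrapper assembling the design and covariance structures:
#' subsets records with a non-missing trait (and, when a microbial term is
#' present, with a microbiota profile in `O`), builds the fixed-effect
#' design from the given factors, and calls [fit_aireml()].
#'
#' @param pheno phenotype data frame with columns `id`, `dam`, the trait and
#'   any fixed-effect factors.
#' @param trait trait column name.
#' @param fixed character vector of fixed-effect factor names (may be
#'   empty: intercept only).
#' @param K_a genetic relationship matrix (H or A) or `NULL` to omit the
#'   additive term.
#' @param K_m microbial relationship matrix O or `NULL` to omit the
#'   microbial term.
#' @param maternal include the dam-level permanent environmental term.
#' @param ... passed to [fit_aireml()].
#' @return `reml_fit` with extra fields `model` ("G", "M" or "GM"),
#'   `trait`, `ids` (records used), `fixed`.
#' @export
fit_animal_model <- function(pheno, trait, fixed = character(), K_a = NULL,
                             K_m = NULL, maternal = FALSE, ...) {
  stopifnot(trait %in% names(pheno))
  use <- !is.na(pheno[[trait]])
  for (v in fixed) use <- use & !is.na(pheno[[v]])
  if (!is.null(K_m)) use <- use & pheno$id %in% rownames(K_m)
  if (!is.null(K_a)) use <- use & pheno$id %in% rownames(K_a)
  dat <- pheno[use, , drop = FALSE]
  if (nrow(dat) < 10) stop("fewer than 10 usable records for ", trait)
  X <- if (length(fixed))
    stats::model.matrix(stats::reformulate(fixed), data = dat)
  else NULL
  random <- list()
  if (!is.null(K_a)) random$a <- kin_structure(K_a, dat$id)
  if (!is.null(K_m)) random$m <- kin_structure(K_m, dat$id)
  if (maternal) random$p <- iid_structure(dat$dam)
  fit <- fit_aireml(dat[[trait]], X = X, random = random, ...)
  fit$model <- paste0(if (!is.null(K_a)) "G", if (!is.null(K_m)) "M")
  fit$trait <- trait
  fit$ids <- dat$id
  fit$fixed <- fixed
  fit$maternal <- maternal
  fit
}
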