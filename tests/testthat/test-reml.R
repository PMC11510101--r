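test_that("with no random terms REML reduces to the OLS residual variance", {
  set.seed(1)
  n <- 60
  X <- cbind(1, rnorm(n))
  y <- X %*% c(2, 1) + rnorm(n, 0, 1.5)
  fit <- fit_aireml(y, X = X)
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  expect_equal(fit$theta[["e"]], rss / (n - 2), tolerance = 1e-6)
  # and the likelihood matches the closed form at that point
  th <- fit$theta[["e"]]
  ll_closed <- -0.5 * ((n - 2) * log(th) + rss / th)
  expect_equal(reml_loglik(c(y), X = X, theta = th), ll_closed,
               tolerance = 1e-8)
})

test_that("balanced one-way design matches the ANOVA estimators", {
  set.seed(2)
  groups <- rep(1:20, each = 10)
  y <- rnorm(20, sd = 1.2)[groups] + rnorm(200)
  fit <- fit_aireml(y, random = list(b = iid_structure(groups)))
  ms <- stats::anova(stats::lm(y ~ factor(groups)))$`Mean Sq`
  expect_equal(fit$theta[["b"]], (ms[1] - ms[2]) / 10, tolerance = 1e-6)
  expect_equal(fit$theta[["e"]], ms[2], tolerance = 1e-6)
  expect_lt(fit$gradient_norm, 1e-4)
})

test_that("AI-REML matches direct maximization of the likelihood", {
  ped <- small_herd_ped(n_off = 60, seed = 3)
  A <- build_A(ped)
  ph <- simulate_phenotypes(ped, true_params(var_a = 0.6, var_m = 0,
                                             var_p = 0, var_e = 0.4),
                            K_genetic = A, seed = 4)
  Ca <- kin_structure(A, ph$id)
  fit <- fit_aireml(ph$y, random = list(a = Ca))
  nm <- stats::optim(log(c(0.5, 0.5)), function(lt)
    -reml_loglik(ph$y, random = list(a = Ca), theta = exp(lt)),
    method = "Nelder-Mead", control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(unname(fit$theta), exp(nm$par), tolerance = 1e-4)
})

test_that("estimates agree with lme4 on an unbalanced grouped design", {
  skip_if_not_installed("lme4")
  set.seed(5)
  g <- rep(1:25, times = sample(3:12, 25, replace = TRUE))
  x <- rnorm(length(g))
  y <- rnorm(25, sd = 0.9)[g] + 0.5 * x + rnorm(length(g))
  fit <- fit_aireml(y, X = cbind(1, x), random = list(b = iid_structure(g)))
  lf <- lme4::lmer(y ~ x + (1 | g), REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$theta[["b"]], vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$theta[["e"]], vc$vcov[2], tolerance = 1e-4)
})

test_that("record order does not change the estimates", {
  set.seed(6)
  g <- rep(1:15, each = 8)
  y <- rnorm(15)[g] + rnorm(120)
  X <- cbind(1, rnorm(120))
  f1 <- fit_aireml(y, X = X, random = list(b = iid_structure(g)))
  p <- sample(120)
  f2 <- fit_aireml(y[p], X = X[p, ], random = list(b = iid_structure(g[p])))
  expect_equal(f1$theta, f2$theta, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("likelihood is invariant to full-rank reparameterization of X", {
  set.seed(7)
  g <- rep(1:10, each = 6)
  y <- rnorm(10)[g] + rnorm(60)
  X <- cbind(1, rnorm(60), rnorm(60))
  Tm <- matrix(c(1, 0.3, -1, 0, 2, 0.5, 0, 0, 1), 3, 3)
  th <- c(0.4, 0.8)
  expect_equal(reml_loglik(y, X, list(b = iid_structure(g)), th),
               reml_loglik(y, X %*% Tm, list(b = iid_structure(g)), th),
               tolerance = 1e-8)
})

test_that("aliased fixed-effect columns raise an informative error", {
  y <- rnorm(20)
  X <- cbind(a = rep(1, 20), b = rep(1, 20))
  expect_error(fit_aireml(y, X = X), "aliased")
})

test_that("a zero true variance is pinned at the boundary", {
  ped <- small_herd_ped(n_off = 80, seed = 8)
  A <- build_A(ped)
  hits <- 0L
  for (s in 1:5) {
    ph <- simulate_phenotypes(ped, true_params(var_a = 0, var_m = 0,
                                               var_p = 0, var_e = 1),
                              K_genetic = A, seed = 20 + s)
    fit <- fit_aireml(ph$y, random = list(a = kin_structure(A, ph$id)))
    if (fit$theta[["a"]] < 0.05 * fit$theta[["e"]]) hits <- hits + 1L
    expect_gte(fit$theta[["a"]], 0)
  }
  expect_gte(hits, 3L)
})

test_that("AIC and LRT arithmetic follow their definitions", {
  f3 <- fake_fit(c(a = 1, p = 1, e = 1), loglik = -100)
  expect_equal(aic(f3), 206)
  f2 <- fake_fit(c(a = 1, e = 1), loglik = -100)
  expect_equal(aic(f3) - aic(f2), 2 * 1 - 2 * 0)
  full <- fake_fit(c(a = 1, p = 1, e = 1), loglik = -96.6825)
  red <- fake_fit(c(a = 1, e = 1), loglik = -100)
  out <- lrt(full, red)
  expect_equal(out$statistic, 6.635, tolerance = 1e-6)
  expect_equal(out$df, 1)
  expect_equal(out$p_value, 0.01, tolerance = 1e-3)
  same <- lrt(fake_fit(c(a = 1, p = 1, e = 1), loglik = -100), f2)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(lrt(f2, f3), "more parameters")
  expect_error(lrt(fake_fit(c(a = 1, p = 1, e = 1), loglik = -150), f2),
               "refit")
  mix <- lrt(full, red, boundary_mixture = TRUE)
  expect_equal(mix$p_value, out$p_value / 2)
})

test_that("backward elimination keeps real effects and drops noise", {
  ped <- small_herd_ped(n_off = 200, n_dams = 20, n_sires = 10, seed = 9)
  keep_batch <- 0L
  all3 <- 0L
  for (s in 1:5) {
    tr <- true_params(var_a = 0, var_m = 0, var_p = 0, var_e = 1,
                      fixed_effects = c(batch = 2))
    ph <- simulate_phenotypes(ped, tr, seed = 30 + s)
    sel <- backward_eliminate_fixed(ph, "y")
    if (identical(sel, "batch")) keep_batch <- keep_batch + 1L
    trs <- true_params(var_a = 0, var_m = 0, var_p = 0, var_e = 1,
                       fixed_effects = c(gender = 3, batch = 3, diet = 3))
    phs <- simulate_phenotypes(ped, trs, seed = 40 + s)
    if (setequal(backward_eliminate_fixed(phs, "y"),
                 c("gender", "batch", "diet"))) all3 <- all3 + 1L
  }
  expect_gte(keep_batch, 4L)
  expect_equal(all3, 5L)
  # single-level factor is skipped with a warning, never an error
  ph1 <- simulate_phenotypes(ped, true_params(), seed = 50)
  ph1$diet <- "T1"
  expect_warning(sel <- backward_eliminate_fixed(ph1, "y"), "levels")
  expect_false("diet" %in% sel)
})

test_that("bivariate fit recovers covariance blocks on simulated data", {
  ped <- small_herd_ped(n_off = 150, n_dams = 25, n_sires = 12, seed = 10)
  A <- build_A(ped)
  Sa <- matrix(c(0.5, 0.3, 0.3, 0.4), 2)
  Se <- matrix(c(0.5, 0.1, 0.1, 0.6), 2)
  tr <- true_params(Sigma_a = Sa, Sigma_p = diag(0, 2), Sigma_e = Se,
                    fixed_effects = c(gender = 0.3))
  ph <- simulate_phenotypes(ped, tr, K_genetic = A, seed = 11)
  X <- stats::model.matrix(~ gender, ph)
  fit <- fit_bivariate(ph$y1, ph$y2, X1 = X, X2 = X, K = A,
                       ids1 = ph$id, ids2 = ph$id)
  expect_true(fit$converged)
  expect_equal(length(fit$theta), 6)
  # loose sanity at this n: estimates in the right region
  expect_lt(abs(fit$theta[["a12"]] - 0.3), 0.35)
  rg <- genetic_correlation(fit)
  expect_true(is.finite(rg$value) || rg$boundary)
})

test_that("duplicating the trait drives the genetic correlation to one", {
  ped <- small_herd_ped(n_off = 80, n_dams = 15, n_sires = 8, seed = 12)
  A <- build_A(ped)
  ph <- simulate_phenotypes(ped, true_params(var_a = 0.5, var_m = 0,
                                             var_p = 0, var_e = 0.5),
                            K_genetic = A, seed = 13)
  fit <- fit_bivariate(ph$y, ph$y, K = A, ids1 = ph$id, ids2 = ph$id,
                       max_iter = 100)
  rg <- fit$theta[["a12"]] / sqrt(fit$theta[["a11"]] * fit$theta[["a22"]])
  expect_gt(rg, 0.999)
})

test_that("structures can be supplied as precision matrices", {
  ped <- small_herd_ped(n_off = 50, seed = 14)
  A <- build_A(ped)
  ph <- simulate_phenotypes(ped, true_params(var_a = 0.5, var_m = 0,
                                             var_p = 0, var_e = 0.5),
                            K_genetic = A, seed = 15)
  Ca <- kin_structure(A, ph$id)
  f1 <- fit_aireml(ph$y, random = list(a = Ca))
  f2 <- fit_aireml(ph$y, random = list(a = list(inverse = solve_sym(Ca))))
  expect_equal(f1$theta, f2$theta, tolerance = 1e-5)
})
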