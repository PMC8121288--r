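test_that("noiseless outcomes are recovered to machine precision", {
  set.seed(9)
  G <- 20
  Z <- matrix(rnorm(G * 2), G, 2, dimnames = list(NULL, c("z1", "z2")))
  Xt <- matrix(rnorm(G * 2), G, 2, dimnames = list(NULL, c("x1", "x2")))
  beta <- c(0.5, 1, -2, 0.3, -0.7)
  y <- beta[1] + Z %*% beta[2:3] + Xt %*% beta[4:5]
  fit <- suppressWarnings(fit_micro_macro(drop(y), Z, Xt))
  expect_equal(unname(fit$beta), beta, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("residuals sum to zero and CIs bracket the estimates", {
  sc <- toy_scenario()
  fit <- fit_one_replicate(simulate_dataset(sc, 3))$adjusted
  expect_lt(abs(sum(fit$residuals)), 1e-8)
  expect_true(all(fit$ci_lower < fit$beta & fit$beta < fit$ci_upper))
  expect_gte(fit$r_squared, 0)
  expect_lte(fit$r_squared, 1)
  # sandwich covariance symmetric PSD
  v <- fit$vcov_corrected
  expect_equal(v, t(v), tolerance = 1e-12)
  expect_gte(min(eigen(v, symmetric = TRUE)$values), -1e-12)
})

test_that("HC0 sandwich matches the hand-written formula", {
  set.seed(12)
  G <- 25
  Z <- matrix(rnorm(G), G, 1, dimnames = list(NULL, "z1"))
  y <- 0.3 + 0.8 * Z[, 1] + rnorm(G, 0, 0.5)
  fit <- fit_micro_macro(y, Z, NULL, hc_type = "HC0")
  X <- cbind(1, Z)
  e <- y - X %*% solve(crossprod(X), crossprod(X, y))
  bread <- solve(crossprod(X))
  meat <- t(X) %*% diag(drop(e)^2) %*% X
  expect_equal(unname(fit$vcov_corrected), unname(bread %*% meat %*% bread),
               tolerance = 1e-10)
})

test_that("corrected and classical SEs converge under homoscedasticity", {
  set.seed(13)
  ratio_at <- function(G) {
    Z <- matrix(rnorm(G), G, 1, dimnames = list(NULL, "z1"))
    y <- 1 + Z[, 1] + rnorm(G)
    f <- fit_micro_macro(y, Z, NULL, hc_type = "HC0")
    abs(f$se_corrected["z1"] / f$se_classical["z1"] - 1)
  }
  r_small <- mean(replicate(20, ratio_at(25)))
  r_big <- mean(replicate(5, ratio_at(1000)))
  expect_lt(r_big, r_small)
  expect_lt(r_big, 0.05)
})

test_that("naive and adjusted fits coincide when within-noise is zero", {
  sc <- simulation_scenario(G = 25, group_size = 6,
                            beta = c(0.2, 0.1, 0.3),
                            z_types = "quantitative",
                            x_types = "quantitative",
                            sigma_xi = 1, sigma_upsilon = 0,
                            sigma_eps = 0.05, seed = 77)
  fits <- fit_one_replicate(simulate_dataset(sc, 1))
  expect_equal(fits$adjusted$beta, fits$naive$beta, tolerance = 1e-6)
  expect_true(is.finite(fits$naive$r_squared))
})

test_that("t and normal references order p-values as expected", {
  sc <- toy_scenario()
  td <- simulate_dataset(sc, 4)
  micro <- td$micro; macro <- td$macro
  specs <- c(attr(micro, "specs"), attr(macro, "specs"))
  menc <- encode(micro, specs); zenc <- encode(macro, specs)
  gs <- group_summaries(menc, micro$group_id, macro$group_id)
  mom <- estimate_moments(gs, menc, micro$group_id, macro_z = zenc)
  adj <- adjust_means(mom, gs, macro_z = zenc)
  ft <- fit_micro_macro(macro$outcome, zenc, adj, reference = "t")
  fn <- fit_micro_macro(macro$outcome, zenc, adj, reference = "normal")
  expect_equal(ft$beta, fn$beta)
  # the t reference with few groups is more conservative
  expect_true(all(ft$p_values >= fn$p_values - 1e-12))
  expect_true(all(ft$ci_upper - ft$ci_lower >=
                    fn$ci_upper - fn$ci_lower - 1e-12))
})

test_that("rank-deficient designs fail with the collinear column named", {
  G <- 15
  Z <- matrix(rnorm(G), G, 1, dimnames = list(NULL, "z1"))
  Z2 <- cbind(Z, z1copy = 2 * Z[, 1])
  y <- rnorm(G)
  expect_error(fit_micro_macro(y, Z2, NULL), "z1copy")
  expect_error(fit_micro_macro(y[1:3], Z2[1:3, ], NULL), "more groups")
})

test_that("coefficient table mirrors the reporting layout", {
  sc <- toy_scenario()
  fit <- fit_one_replicate(simulate_dataset(sc, 5))$adjusted
  tab <- coef_table(fit)
  expect_named(tab, c("factor", "level", "beta", "ci_lower", "ci_upper",
                      "p", "se", "se_corr"))
  expect_equal(tab$level,
               c("(intercept)", "group", "group", "individual",
                 "individual"))
})
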