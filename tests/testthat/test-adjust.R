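
# Build moment/summary objects directly so the shrinkage arithmetic can
# be pinned against closed forms.
manual_setup <- function(Sigma_xi, Sigma_w, mu_x, xbar, n_g) {
  p <- length(mu_x)
  gs <- structure(list(group_id = paste0("g", seq_len(nrow(xbar))),
                       n_g = n_g, xbar = xbar),
                  class = "group_summaries")
  mom <- structure(list(mu_x = mu_x, mu_z = NULL,
                        Sigma_within = Sigma_w,
                        Sigma_between_latent = Sigma_xi,
                        Sigma_z = NULL, Sigma_z_xi = NULL,
                        c_anova = NA, G = nrow(xbar), N = sum(n_g),
                        n_g = n_g),
                   class = "moment_estimates")
  list(gs = gs, mom = mom)
}

test_that("scalar shrinkage follows the closed form W = 1/(1 + Sv/(n*Sxi))", {
  # Sigma_xi = 1, Sigma_v = 4, n = 4, mu = 0, xbar = 2 -> xtilde = 1
  s <- manual_setup(matrix(1), matrix(4), 0,
                    matrix(2, 1, 1, dimnames = list("g1", "x")), 4)
  s$mom$G <- 3  # metadata only
  adj <- adjust_means(s$mom, s$gs)
  expect_equal(unname(adj$xtilde[1, 1]), 1, tolerance = 1e-12)
})

test_that("zero within-noise leaves group means unshrunk", {
  set.seed(4)
  xbar <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("g", 1:6),
                                                  c("a", "b")))
  s <- manual_setup(diag(c(1, 2)), matrix(0, 2, 2), colMeans(xbar),
                    xbar, rep(5, 6))
  adj <- adjust_means(s$mom, s$gs)
  expect_equal(adj$xtilde, xbar, tolerance = 1e-10)
})

test_that("zero between-variance shrinks fully to the grand mean", {
  set.seed(5)
  xbar <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("g", 1:5),
                                                  c("a", "b")))
  mu <- c(0.3, -0.2)
  s <- manual_setup(matrix(0, 2, 2), diag(2), mu, xbar, rep(4, 5))
  adj <- adjust_means(s$mom, s$gs)
  for (g in 1:5) expect_equal(unname(adj$xtilde[g, ]), mu,
                              tolerance = 1e-10)
})

test_that("adjusted means stay on the segment between grand and group mean", {
  set.seed(6)
  xbar <- matrix(rnorm(8, 2), 8, 1, dimnames = list(paste0("g", 1:8), "x"))
  mu <- 1.4
  s <- manual_setup(matrix(0.5), matrix(2), mu, xbar, sample(3:20, 8))
  adj <- adjust_means(s$mom, s$gs)
  for (g in 1:8) {
    lo <- min(mu, xbar[g, 1]); hi <- max(mu, xbar[g, 1])
    expect_gte(adj$xtilde[g, 1], lo - 1e-12)
    expect_lte(adj$xtilde[g, 1], hi + 1e-12)
  }
})

test_that("shrinkage toward the group mean increases with group size", {
  mu <- 0; xbar_val <- 2
  gaps <- sapply(c(2, 5, 10, 50, 200), function(n) {
    s <- manual_setup(matrix(1), matrix(4), mu,
                      matrix(xbar_val, 1, 1,
                             dimnames = list("g1", "x")), n)
    abs(adjust_means(s$mom, s$gs)$xtilde[1, 1] - xbar_val)
  })
  expect_true(all(diff(gaps) < 0))
})

test_that("singular joint covariance falls back to a ridge with a warning", {
  xbar <- matrix(c(1, 2, 3, 1, 2, 3), 3, 2,
                 dimnames = list(paste0("g", 1:3), c("a", "b")))
  # identical columns -> exactly singular V_g
  s <- manual_setup(matrix(1, 2, 2), matrix(0, 2, 2), c(2, 2),
                    xbar, rep(4, 3))
  expect_warning(adj <- adjust_means(s$mom, s$gs), "ridge")
  expect_true(all(is.finite(adj$xtilde)))
})

test_that("affine rescaling of a predictor rescales its adjustment and
           inverts its coefficient, leaving fitted values unchanged", {
  sc <- toy_scenario()
  td <- simulate_dataset(sc, 2)
  micro <- td$micro; macro <- td$macro
  specs <- c(attr(micro, "specs"), attr(macro, "specs"))
  fit1 <- fit_one_replicate(td)$adjusted

  a <- 3.5; b <- -1.25   # x1 -> a + b * x1
  micro2 <- micro
  micro2$x1 <- a + b * micro2$x1
  menc2 <- encode(micro2, specs)
  zenc <- encode(macro, specs)
  gs2 <- group_summaries(menc2, micro2$group_id, macro$group_id)
  mom2 <- estimate_moments(gs2, menc2, micro2$group_id, macro_z = zenc)
  adj2 <- adjust_means(mom2, gs2, macro_z = zenc)
  fit2 <- fit_micro_macro(macro$outcome, zenc, adj2)

  expect_equal(unname(fit2$beta["x1"]), unname(fit1$beta["x1"] / b),
               tolerance = 1e-8)
  expect_equal(unname(fitted(fit2$lm_fit)), unname(fitted(fit1$lm_fit)),
               tolerance = 1e-8)
})
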