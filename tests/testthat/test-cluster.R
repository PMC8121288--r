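test_that("identical variables merge first with zero homogeneity loss", {
  set.seed(21)
  x <- rnorm(80)
  df <- data.frame(a = x, b = x, c = rnorm(80))
  tree <- cluster_variables(df, quant_specs(df), level = "individual")
  expect_equal(unname(sort(abs(unlist(tree$merges[1, c("a", "b")])))),
               c(1, 2))  # leaves a and b
  expect_lt(tree$merges$loss[1], 1e-10)
  expect_equal(nrow(tree$merges), 2)  # p - 1 merges
  expect_true(all(tree$merges$loss >= -1e-12))
})

test_that("homogeneity is p at K = p, decreases with coarser partitions,
           and singletons are perfectly represented", {
  df <- blocky_data(n = 100, block_sizes = c(3, 2), noise = 0.5)
  specs <- quant_specs(df)
  tree <- cluster_variables(df, specs, level = "individual")
  p <- length(tree$labels)
  h <- sapply(1:p, function(K) cut_tree(tree, K)$homogeneity)
  expect_equal(h[p], p, tolerance = 1e-10)
  expect_true(all(diff(h) > -1e-10))  # non-decreasing in K
})

test_that("planted variable blocks are recovered at the true K", {
  df <- blocky_data(n = 150, block_sizes = c(3, 3), noise = 0.4, seed = 2)
  tree <- cluster_variables(df, quant_specs(df), level = "individual")
  part <- cut_tree(tree, 2)
  a <- part$assignment
  expect_equal(length(unique(a[c("v1_1", "v1_2", "v1_3")])), 1)
  expect_equal(length(unique(a[c("v2_1", "v2_2", "v2_3")])), 1)
  expect_equal(part$K, 2)
})

test_that("mixed qualitative/quantitative clustering groups a factor with
           its numeric driver", {
  set.seed(23)
  n <- 200
  f <- rnorm(n)
  df <- data.frame(
    num = f + rnorm(n, 0, 0.4),
    cat = ifelse(f > 0, "high", "low"),
    noise = rnorm(n))
  specs <- list(
    variable_spec("num", "individual", "quantitative"),
    variable_spec("cat", "individual", "binary", c("low", "high")),
    variable_spec("noise", "individual", "quantitative"))
  tree <- cluster_variables(df, specs, level = "individual")
  part <- cut_tree(tree, 2)
  expect_equal(part$assignment[["num"]], part$assignment[["cat"]])
  expect_false(part$assignment[["noise"]] == part$assignment[["num"]])
})

test_that("zero-variance variables are excluded with a warning", {
  df <- data.frame(a = rnorm(50), b = rnorm(50), c = rep(1, 50))
  expect_warning(
    tree <- cluster_variables(df, quant_specs(df), level = "individual"),
    "zero-variance")
  expect_equal(sort(tree$labels), c("a", "b"))
})

test_that("representatives are the highest-loading members unless
           overridden", {
  df <- blocky_data(n = 200, block_sizes = c(3, 1), noise = 0.3, seed = 4)
  # v2_1 is a singleton cluster at K = 2
  tree <- cluster_variables(df, quant_specs(df), level = "individual")
  part <- cut_tree(tree, 2)
  reps <- pick_representatives(part)
  expect_length(reps, 2)
  expect_true("v2_1" %in% reps)           # singleton -> its only member
  reps2 <- pick_representatives(part, overrides = "v1_3")
  expect_true("v1_3" %in% reps2)
  expect_error(pick_representatives(part, overrides = c("v1_1", "v1_2")),
               "conflict")
  expect_error(pick_representatives(part, overrides = "nope"),
               "not among")
})

test_that("the highest-loading member wins within a cluster", {
  # in a 2-variable cluster both members load equally on the first
  # component, so 3 members are needed to rank them
  set.seed(25)
  n <- 300
  f <- rnorm(n)
  df <- data.frame(tight1 = f + rnorm(n, 0, 0.2),
                   tight2 = f + rnorm(n, 0, 0.25),
                   loose = f + rnorm(n, 0, 1.5))
  tree <- cluster_variables(df, quant_specs(df), level = "individual")
  part <- cut_tree(tree, 1)
  expect_true(pick_representatives(part) %in% c("tight1", "tight2"))
})

test_that("newick serialization is well formed and covers all leaves", {
  df <- blocky_data(n = 60, block_sizes = c(2, 2), noise = 0.5, seed = 6)
  tree <- cluster_variables(df, quant_specs(df), level = "individual")
  nwk <- to_newick(tree)
  expect_match(nwk, ";$")
  for (lab in tree$labels) expect_match(nwk, lab, fixed = TRUE)
  # parses as a phylo tree with the right tip count
  skip_if_not_installed("ape")
  ph <- ape::read.tree(text = nwk)
  expect_equal(sort(ph$tip.label), sort(tree$labels))
})
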