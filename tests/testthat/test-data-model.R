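test_that("variable specs enforce category invariants", {
  expect_error(variable_spec("a", "individual", "binary",
                             categories = c("x")), "exactly 2")
  expect_error(variable_spec("a", "group", "nominal",
                             categories = "one"), "at least 2")
  expect_error(variable_spec("a", "group", "nominal",
                             categories = c("u", "v"), reference = "w"),
               "not among")
  s <- variable_spec("a", "group", "nominal", c("u", "v", "w"))
  expect_equal(s$reference, "u")
  expect_error(variable_spec("q", "individual", "quantitative",
                             categories = c("u", "v")), "must not declare")
})

test_that("spec YAML dictionary round-trips", {
  specs <- icu_fixture_specs()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_variable_specs(specs, path)
  back <- read_variable_specs(path)
  expect_equal(back, specs)
})

test_that("read_two_level round-trips its own fixture files", {
  dir <- withr::local_tempdir()
  fx <- generate_icu_fixture(seed = 3, out_dir = dir)
  td <- read_two_level(fx$paths["individual"], fx$paths["group"],
                       fx$specs, outcome_col = "outcome")
  expect_s3_class(td, "two_level_data")
  expect_equal(length(unique(td$micro$group_id)), 30)
  expect_equal(nrow(td$macro), 30)
  expect_equal(td$n_g, fx$data$n_g)
  # idempotence: re-reading a re-written table yields an equal object
  utils::write.csv(as.data.frame(td$micro),
                   file.path(dir, "ind2.csv"), row.names = FALSE,
                   quote = FALSE)
  td2 <- read_two_level(file.path(dir, "ind2.csv"), fx$paths["group"],
                        fx$specs, outcome_col = "outcome")
  expect_equal(as.data.frame(td2$micro), as.data.frame(td$micro))
})

test_that("toy counting: two groups of three give n_g = (3,3), N = 6", {
  dir <- withr::local_tempdir()
  ind <- data.frame(group_id = rep(c("a", "b"), each = 3),
                    x = rnorm(6))
  grp <- data.frame(group_id = c("a", "b", "c"),
                    outcome = c(0.1, 0.2, 0.3))
  write.csv(ind, file.path(dir, "i.csv"), row.names = FALSE)
  write.csv(grp, file.path(dir, "g.csv"), row.names = FALSE)
  specs <- list(variable_spec("x", "individual", "quantitative"))
  expect_warning(
    td <- read_two_level(file.path(dir, "i.csv"), file.path(dir, "g.csv"),
                         specs, outcome_col = "outcome"),
    "no individuals")
  expect_equal(unname(td$n_g), c(3L, 3L))
  expect_equal(nrow(td$micro), 6)
})

test_that("ingestion errors name the offending rows and columns", {
  dir <- withr::local_tempdir()
  ind <- data.frame(group_id = c("a", "a", "b", "b"),
                    x = c("1", "oops", "3", "4"))
  grp <- data.frame(group_id = c("a", "b", "b"),
                    outcome = c(0.1, 0.2, 0.3))
  write.csv(ind, file.path(dir, "i.csv"), row.names = FALSE)
  write.csv(grp, file.path(dir, "g.csv"), row.names = FALSE)
  specs <- list(variable_spec("x", "individual", "quantitative"))
  expect_error(
    suppressWarnings(read_two_level(file.path(dir, "i.csv"),
                                    file.path(dir, "g.csv"), specs,
                                    outcome_col = "outcome")),
    "non-numeric value.*'x'")
  grp2 <- data.frame(group_id = c("a", "b"), outcome = c(0.1, 0.2))
  write.csv(grp2, file.path(dir, "g2.csv"), row.names = FALSE)
  specs2 <- list(variable_spec("zz", "individual", "quantitative"))
  expect_error(
    read_two_level(file.path(dir, "i.csv"), file.path(dir, "g2.csv"),
                   specs2, outcome_col = "outcome"),
    "schema error")
  # duplicate group id caught
  expect_error(macro_table(grp, list(), outcome_col = "outcome"),
               "duplicate group identifiers")
})

test_that("missing individual rows are dropped listwise with a count", {
  ind <- data.frame(group_id = rep(c("a", "b"), each = 4),
                    x = c(1, NA, 3, 4, 5, 6, NA, 8))
  specs <- list(variable_spec("x", "individual", "quantitative"))
  expect_warning(mt <- micro_table(ind, specs), "2 individual row")
  expect_equal(nrow(mt), 6)
})

test_that("encode implements reference-omitted dummy coding", {
  specs <- list(
    variable_spec("skip", "individual", "binary", c("no", "yes"),
                  reference = "no"),
    variable_spec("score", "individual", "quantitative"))
  d <- data.frame(group_id = c("a", "a", "b", "b"),
                  skip = c("no", "yes", "yes", "no"),
                  score = c(1.5, 2, -1, 0))
  enc <- encode(micro_table(d, specs))
  expect_equal(unname(enc$values[, "skip"]), c(0, 1, 1, 0))
  expect_equal(unname(enc$values[, "score"]), d$score)

  # 3-modality factor -> 2 columns, reference omitted
  gspecs <- list(variable_spec("icu_type", "group", "nominal",
                               c("medical", "surgical", "polyvalent")))
  g <- data.frame(group_id = c("u1", "u2", "u3"),
                  outcome = c(0.1, 0.2, 0.3),
                  icu_type = c("medical", "surgical", "polyvalent"))
  genc <- encode(macro_table(g, gspecs, outcome_col = "outcome"))
  expect_equal(ncol(genc$values), 2)
  expect_false(any(grepl("medical", colnames(genc$values))))
  expect_true(all(rowSums(genc$values) <= 1))
  expect_error(
    encode(data.frame(icu_type = "cardiac"), gspecs),
    "encoding error")
})

test_that("encoding is invertible and has the expected column count", {
  fx <- generate_icu_fixture(seed = 5)
  enc <- encode(fx$data$micro)
  specs <- attr(fx$data$micro, "specs")
  expected_cols <- sum(vapply(specs, function(s) {
    if (s$type == "quantitative") 1L else length(s$categories) - 1L
  }, integer(1)))
  expect_equal(ncol(enc$values), expected_cols)
  dec <- decode(enc)
  for (s in specs) {
    if (s$type == "quantitative") {
      expect_equal(dec[[s$name]], as.numeric(fx$data$micro[[s$name]]))
    } else {
      expect_equal(dec[[s$name]], as.character(fx$data$micro[[s$name]]))
    }
  }
  # all-quantitative input passes through identically
  qd <- data.frame(group_id = c("a", "b", "c"), q1 = c(1, 2, 3),
                   q2 = c(0.5, -1, 2))
  qs <- list(variable_spec("q1", "individual", "quantitative"),
             variable_spec("q2", "individual", "quantitative"))
  qenc <- encode(suppressWarnings(micro_table(qd, qs)))
  expect_equal(unname(qenc$values), unname(as.matrix(qd[, c("q1", "q2")])))
})
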