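#' Variable dictionary of the synthetic ICU fixture
#'
#' Specs for the 19 individual-level and 7 ICU-level covariates emitted
#' by [generate_icu_fixture()]: continuous scores, counts, 0-3 ordinal
#' items entered through their integer codes, yes/no binaries, and a
#' 3-level unit-type factor.
#'
#' @return List of [variable_spec()]s.
#' @export
icu_fixture_specs <- function() {
  yn <- c("no", "yes")
  c(
    list(
      variable_spec("age", "individual", "quantitative"),
      variable_spec("experience_profession", "individual", "quantitative"),
      variable_spec("experience_position", "individual", "quantitative"),
      variable_spec("commute_minutes", "individual", "quantitative"),
      variable_spec("stress_pss10", "individual", "quantitative"),
      variable_spec("support_colleagues", "individual", "quantitative"),
      variable_spec("support_supervisors", "individual", "quantitative"),
      variable_spec("breaks_mean", "individual", "quantitative"),
      variable_spec("n_children", "individual", "quantitative"),
      variable_spec("schedule_changes", "individual", "quantitative"),
      variable_spec("overtime_hours", "individual", "quantitative"),
      variable_spec("gender_female", "individual", "binary", yn),
      variable_spec("registered_nurse", "individual", "binary", yn),
      variable_spec("night_shift", "individual", "binary", yn),
      variable_spec("skip_break", "individual", "binary", yn),
      variable_spec("nhp_sleep", "individual", "binary", yn),
      variable_spec("nhp_energy", "individual", "binary", yn),
      variable_spec("fatigue_bad", "individual", "binary", yn),
      variable_spec("constant_schedule", "individual", "binary", yn)
    ),
    list(
      variable_spec("n_beds", "group", "quantitative"),
      variable_spec("icu_type", "group", "nominal",
                    c("medical", "surgical", "polyvalent")),
      variable_spec("intermediate_care", "group", "binary", yn),
      variable_spec("shift_12h", "group", "binary", yn),
      variable_spec("ratio_day", "group", "quantitative"),
      variable_spec("ratio_night", "group", "quantitative"),
      variable_spec("ratio_overall", "group", "quantitative")
    )
  )
}

# True generating coefficients of the fixture outcome model. Group-level
# terms act on the observed (encoded) covariate; individual-level terms
# act on the latent group score of the covariate (its group mean /
# success probability). beta0 and sigma_eps are calibrated so the
# outcome has mean ~0.19 and SD ~0.09 across regenerated fixtures.
icu_fixture_truth <- function() {
  data.frame(
    coefficient = c("(Intercept)",
                    "n_beds", "intermediate_care", "ratio_overall",
                    "icu_type.polyvalent",
                    "support_colleagues", "support_supervisors",
                    "experience_profession", "n_children", "skip_break"),
    level = c("(intercept)", rep("group", 4), rep("individual", 5)),
    beta = c(1.077,
             -0.006, 0.06, 0.07, -0.04,
             -0.06, -0.02, -0.012, 0.07, 0.18),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic ICU turnover study fixture
#'
#' Emits a dataset with the shape of a 30-unit nurse-turnover study:
#' 30 ICUs with 7-32 staff each, 19 individual-level covariates with
#' planted correlation blocks (a social-support block, a
#' stress/fatigue/health block, a workload block, a demographic block),
#' 7 ICU-level covariates including a 3-level unit-type factor, and a
#' turnover-rate outcome generated linearly from the latent group
#' scores of five individual covariates and four ICU covariates, with
#' coefficients of the magnitude seen in observational turnover models.
#' The intercept and noise SD are calibrated so the outcome has mean
#' close to 0.19 and SD close to 0.09.
#'
#' All files are plain CSV. The truth sidecar records the generating
#' coefficients so parameter recovery can be checked.
#'
#' @param seed Integer seed; the fixture is deterministic given it.
#' @param out_dir Optional directory; when given, writes
#'   `individual.csv`, `group.csv`, `truth.csv` and `specs.yaml` there.
#' @return (Invisibly when writing) a list with `data` (a
#'   `"two_level_data"`), `specs`, `truth` (data frame of generating
#'   coefficients), and `paths` (when written).
#' @export
generate_icu_fixture <- function(seed = 1, out_dir = NULL) {
  set.seed(replicate_seed(seed, 902013))
  G <- 30
  n_g <- sample(7:32, G, replace = TRUE)
  N <- sum(n_g)
  gid <- sprintf("icu%02d", seq_len(G))
  gi <- rep(seq_len(G), n_g)

  # latent ICU scores: h1 colleague support, h2 supervisor support,
  # h3 strain, h4 workload, h5 demographics, h6 commute, h7 shift
  # culture, h8 size/staffing
  C <- diag(8)
  C[1, 2] <- C[2, 1] <- 0.7
  C[1, 3] <- C[3, 1] <- -0.45
  C[2, 3] <- C[3, 2] <- -0.40
  C[3, 4] <- C[4, 3] <- 0.35
  H <- matrix(stats::rnorm(G * 8), G, 8) %*% chol(C)

  # latent group scores of the outcome-active individual covariates
  xi_support_c <- 11 + 0.6 * H[, 1]
  xi_support_s <- 10 + 0.7 * H[, 2]
  xi_experience <- 10 + 1.8 * H[, 5]
  xi_children <- exp(0.18 + 0.15 * H[, 5])
  xi_skip <- stats::plogis(-0.5 + 0.5 * H[, 4])

  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  ord_item <- function(center) clamp(round(center + stats::rnorm(N)), 0, 3)
  yes_no <- function(p) ifelse(stats::runif(N) < p, "yes", "no")

  stress_c <- 18 + 2.2 * H[gi, 3]
  stress <- clamp(stress_c + stats::rnorm(N, 0, 4.5), 0, 40)
  experience <- clamp(xi_experience[gi] + stats::rnorm(N, 0, 4), 0.5, 40)
  ind <- data.frame(
    group_id = gid[gi],
    age = round(clamp(24 + 0.9 * experience + stats::rnorm(N, 0, 6),
                      21, 64), 1),
    experience_profession = round(experience, 1),
    experience_position = round(clamp(0.55 * experience +
                                        stats::rnorm(N, 0, 2.5), 0.2, 40), 1),
    commute_minutes = round(clamp(42 + 7 * H[gi, 6] +
                                    stats::rnorm(N, 0, 18), 5, 150)),
    stress_pss10 = round(stress),
    support_colleagues = round(clamp(xi_support_c[gi] +
                                       stats::rnorm(N, 0, 1.6), 4, 16)),
    support_supervisors = round(clamp(xi_support_s[gi] +
                                        stats::rnorm(N, 0, 2.0), 4, 16)),
    breaks_mean = round(clamp(2.1 - 0.35 * H[gi, 4] +
                                stats::rnorm(N, 0, 0.7), 0, 5), 1),
    n_children = stats::rpois(N, xi_children[gi]),
    schedule_changes = ord_item(1.1 + 0.45 * H[gi, 4]),
    overtime_hours = ord_item(1.0 + 0.5 * H[gi, 4]),
    gender_female = yes_no(0.8),
    registered_nurse = yes_no(stats::plogis(0.45 + 0.25 * H[gi, 5])),
    night_shift = yes_no(stats::plogis(-0.35 + 0.4 * H[gi, 7])),
    skip_break = yes_no(xi_skip[gi]),
    nhp_sleep = yes_no(stats::plogis(-1.0 + 0.16 * (stress - 18))),
    nhp_energy = yes_no(stats::plogis(-1.2 + 0.18 * (stress - 18))),
    fatigue_bad = yes_no(stats::plogis(-0.8 + 0.14 * (stress - 18) +
                                         0.3 * H[gi, 4])),
    constant_schedule = yes_no(stats::plogis(0.2 + 0.6 * H[gi, 7])),
    stringsAsFactors = FALSE
  )

  n_beds <- clamp(round(18 + 4.5 * H[, 8] + stats::rnorm(G, 0, 1.5)), 8, 35)
  icu_type <- sample(c("medical", "surgical", "polyvalent"), G,
                     replace = TRUE)
  intermediate_care <- ifelse(stats::runif(G) < 0.4, "yes", "no")
  ratio_day <- round(clamp(0.62 + 0.05 * H[, 8] + stats::rnorm(G, 0, 0.05),
                           0.3, 1.1), 3)
  ratio_night <- round(clamp(0.45 + 0.04 * H[, 8] + stats::rnorm(G, 0, 0.04),
                             0.2, 0.9), 3)
  ratio_overall <- round(0.55 * ratio_day + 0.45 * ratio_night +
                           stats::rnorm(G, 0, 0.02), 3)

  truth <- icu_fixture_truth()
  b <- stats::setNames(truth$beta, truth$coefficient)
  y <- b["(Intercept)"] +
    b["n_beds"] * n_beds +
    b["intermediate_care"] * (intermediate_care == "yes") +
    b["ratio_overall"] * ratio_overall +
    b["icu_type.polyvalent"] * (icu_type == "polyvalent") +
    b["support_colleagues"] * xi_support_c +
    b["support_supervisors"] * xi_support_s +
    b["experience_profession"] * xi_experience +
    b["n_children"] * xi_children +
    b["skip_break"] * xi_skip +
    stats::rnorm(G, 0, 0.05)

  grp <- data.frame(
    group_id = gid,
    outcome = round(unname(y), 4),
    n_beds = n_beds,
    icu_type = icu_type,
    intermediate_care = intermediate_care,
    shift_12h = ifelse(stats::runif(G) < 0.5, "yes", "no"),
    ratio_day = ratio_day,
    ratio_night = ratio_night,
    ratio_overall = ratio_overall,
    stringsAsFactors = FALSE
  )

  specs <- icu_fixture_specs()
  td <- suppressWarnings(two_level_data(
    micro_table(ind, specs),
    macro_table(grp, specs, outcome_col = "outcome")
  ))
  out <- list(data = td, specs = specs, truth = truth)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- file.path(out_dir,
                       c("individual.csv", "group.csv", "truth.csv",
                         "specs.yaml"))
    utils::write.csv(ind, paths[1], row.names = FALSE, quote = FALSE)
    utils::write.csv(grp, paths[2], row.names = FALSE, quote = FALSE)
    utils::write.csv(truth, paths[3], row.names = FALSE, quote = FALSE)
    write_variable_specs(specs, paths[4])
    out$paths <- stats::setNames(paths, c("individual", "group", "truth",
                                          "specs"))
    return(invisible(out))
  }
  out
}
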