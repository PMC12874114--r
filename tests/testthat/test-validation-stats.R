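test_that("spearman matches the brute-force ranking oracle", {
  expect_equal(spearman(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman(1:3, c(3, 2, 1)), -1)

  # tied example against the independent pairwise-counting oracle
  x <- c(1, 2, 2, 3, 5, 5)
  y <- c(2, 2, 4, 4, 4, 7)
  expect_equal(spearman(x, y), brute_spearman(x, y), tolerance = 1e-12)
  # and against the reference library implementation
  expect_equal(spearman(x, y), stats::cor(x, y, method = "spearman"),
               tolerance = 1e-12)

  # random vectors with and without ties
  set.seed(4)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- stats::rnorm(n)
    if (length(unique(x)) < 2) next
    expect_equal(spearman(x, y), brute_spearman(x, y), tolerance = 1e-12)
  }

  expect_error(spearman(1:3, 1:4), "equal length")
  expect_error(spearman(1:2, 1:2), "at least 3")
  expect_error(spearman(c(1, 1, 1), 1:3), "constant")
})

test_that("spearman is invariant to strictly increasing transforms", {
  set.seed(8)
  x <- stats::rlnorm(50)
  y <- stats::rlnorm(50)
  r <- spearman(x, y)
  expect_equal(spearman(exp(x), y), r, tolerance = 1e-12)
  expect_equal(spearman(x, y^3), r, tolerance = 1e-12)
  expect_equal(spearman(y, x), r, tolerance = 1e-12)
})

test_that("decile coarsening uses lower-tie cutpoints and preserves ranks", {
  x <- 1:40
  expect_equal(decile_rank(x), rep(0:9, each = 4))
  # rank-preserving pair stays perfectly correlated after coarsening
  y <- exp(x / 5)
  expect_equal(spearman(decile_rank(x), decile_rank(y)), 1)
  expect_error(decile_rank(1:9), "at least 10")
})

test_that("correlation report carries the expected structure and entries", {
  cohort <- generate_cohort(default_spec(300, seed = 19))
  panel <- build_score_panel(cohort)
  prof <- to_density_profile(cohort)
  rep_raw <- correlation_report(panel, prof)

  expect_s3_class(rep_raw, "correlation_report")
  expect_equal(
    rep_raw$construct$r_with_original[
      rep_raw$construct$variant == "mnps_original"], 1)
  expect_true(all(abs(rep_raw$construct$r_with_original) <= 1))
  expect_true(all(abs(rep_raw$convergent$r) <= 1))
  expect_equal(nrow(rep_raw$convergent), 4L * 3L)
  # nutrient panel covers every density column times every score
  expect_equal(nrow(rep_raw$nutrient_panel),
               (ncol(prof) - 3L) * 7L)

  # subgroup filtering restricts n
  rep_m <- correlation_report(panel, prof, subgroup = c(sex = "male"))
  expect_equal(rep_m$meta$n, sum(prof$sex == "male"))
  expect_error(correlation_report(panel, prof, subgroup = c(age = "73")),
               "sex or cohort")
})

test_that("decile-mode correlations track raw-mode correlations closely", {
  cohort <- generate_cohort(default_spec(1000, seed = 29))
  panel <- build_score_panel(cohort)
  prof <- to_density_profile(cohort)
  raw <- correlation_report(panel, prof, mode = "raw")
  dec <- correlation_report(panel, prof, mode = "decile")
  expect_true(all(abs(raw$convergent$r - dec$convergent$r) < 0.05))
  expect_true(all(abs(raw$construct$r_with_original -
                        dec$construct$r_with_original) < 0.05))
})

test_that("scores correlate negatively with the dietary Na/K ratio", {
  cohort <- generate_cohort(default_spec(1000, seed = 37))
  panel <- build_score_panel(cohort)
  prof <- to_density_profile(cohort)
  rep <- correlation_report(panel, prof)
  nak <- dplyr::filter(rep$nutrient_panel, nutrient == "na_k_ratio",
                       grepl("^mnps_", score))
  expect_equal(nrow(nak), 4L)
  expect_true(all(nak$r < 0))
})

test_that("descriptive table reports medians and standard two-group tests", {
  # identical groups: equal summaries, homogeneous tests
  base10 <- make_records(10, energy = seq(1500, 2500, length.out = 10),
                         sex = rep(c("male", "female"), 5))
  base10$age <- 65:74
  half <- dplyr::bind_rows(dplyr::mutate(base10, cohort = "hatoyama"),
                           dplyr::mutate(base10, cohort = "kusatsu"))
  tab <- descriptive_table(half)
  expect_equal(tab$hatoyama, tab$kusatsu)
  expect_true(all(tab$p_value >= 0.05))
  sex_row <- tab[tab$variable == "sex", ]
  expect_equal(sex_row$p_value, 1)

  # separated groups: exact rank-sum p from enumerating all 20 assignments
  recs <- make_records(6, energy = c(1001, 1002, 1003, 2001, 2002, 2003),
                       sex = rep(c("male", "female"), 3))
  recs$cohort <- rep(c("hatoyama", "kusatsu"), each = 3)
  tab2 <- descriptive_table(recs, panels = NULL)
  p_energy <- tab2$p_value[tab2$variable == "energy"]
  # oracle: of the choose(6,3) = 20 equally likely rank-sum values, the
  # observed split is one of the 2 most extreme -> two-sided p = 0.1
  sums <- apply(utils::combn(6, 3), 2, sum)
  obs <- sum(1:3)  # ranks of the three smallest energies
  p_exact <- mean(sums <= obs | sums >= sum(1:6) - obs)
  expect_equal(p_exact, 0.1)
  expect_equal(p_energy, 0.1, tolerance = 1e-12)

  expect_error(descriptive_table(make_records(5)), "two groups")
})

test_that("the pipeline runs end to end, deterministically, with stage labels", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  res1 <- run_pipeline(out1, n = 150, seed = 3,
                       spec = default_spec(150, 3, n_no_consent = 2L,
                                           n_energy_outliers = 2L))
  res2 <- run_pipeline(out2, n = 150, seed = 3,
                       spec = default_spec(150, 3, n_no_consent = 2L,
                                           n_energy_outliers = 2L))
  for (f in c("scores.csv", "descriptives.csv", "construct.csv",
              "convergent.csv", "nutrient_panel.csv", "run_log.txt")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_equal(res1$panel, res2$panel)

  bad <- make_records(20)
  bad$iron[3] <- -2
  expect_error(run_pipeline(withr::local_tempdir(), cohort = bad),
               "stage 'score'")
})
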