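hei_perfect_record <- function() {
  make_records(1, sex = "male", energy = 2000,
               protein = 40, fat = 200 / 3, sfa = 40 / 3,
               fruits = 240, vegetables = 400, legumes = 80,
               whole_grains = 120, dairy = 700, fish = 60, sodium = 2)
}

test_that("HEI-2015 awards 100 to a diet meeting every standard", {
  rec <- hei_perfect_record()
  prof <- to_density_profile(rec)
  hei <- score_hei2015(prof, added_sugar_energy_pct = 5.8)
  expect_equal(hei$total, 100)
  # standards table structure: 13 components, 9 + 4, maxima sum to 100
  st <- hei2015_standards()
  expect_equal(nrow(st), 13L)
  expect_equal(sum(st$type == "adequacy"), 9L)
  expect_equal(sum(st$type == "moderation"), 4L)
  expect_equal(sum(st$max_points), 100)
})

test_that("HEI-2015 whole-grain replication mode zeroes that component", {
  rec <- hei_perfect_record()
  prof <- to_density_profile(rec)
  hei <- score_hei2015(prof, 5.8, whole_grains_zero = TRUE)
  expect_equal(hei$hei_whole_grains, 0)
  expect_equal(hei$total, 90)
})

test_that("HEI-2015 components interpolate linearly between standards", {
  rec <- hei_perfect_record()
  # fruits midway to the 0.8 cup-eq/1000 kcal standard -> half of 5 points
  rec$fruits <- 0.4 * 100 * rec$energy / 1000
  prof <- to_density_profile(rec)
  hei <- score_hei2015(prof, 5.8)
  expect_equal(hei$hei_total_fruits, 2.5)
  expect_equal(hei$hei_whole_fruits, 5)  # 0.4 meets the whole-fruit standard

  # sodium midway between 1.1 and 2.0 g/1000 kcal -> half of 10 points
  rec2 <- hei_perfect_record()
  rec2$sodium <- 1.55 * rec2$energy / 1000
  expect_equal(score_hei2015(to_density_profile(rec2), 5.8)$hei_sodium, 5)

  # totals stay inside [0, 100] across a synthetic cohort
  cohort <- generate_cohort(default_spec(500, seed = 13))
  prof_all <- to_density_profile(cohort)
  added <- impute_sugars(cohort)$added_sugar_g * 4 / cohort$energy * 100
  heis <- score_hei2015(prof_all, added, whole_grains_zero = TRUE)
  expect_true(all(heis$total >= 0 & heis$total <= 100))
})

test_that("NRF9.3 implements capped %DV sums with the documented identities", {
  cfg <- nrf93_config()
  at_dv <- make_records(1, protein = 60, dietary_fiber = 20, vitamin_a = 900,
                        vitamin_c = 100, vitamin_d = 8.5, calcium = 750,
                        iron = 7.5, potassium = 3000, magnesium = 350,
                        sfa = 0, sodium = 0)
  expect_equal(score_nrf93(at_dv, added_sugar_g = 0, cfg), 900)

  # an encourage nutrient at 250 %DV is capped at 100
  rich <- at_dv
  rich$vitamin_c <- 250
  expect_equal(score_nrf93(rich, 0, cfg), 900)

  zero <- make_records(1)
  for (col in c(diet_nutrients(), diet_food_groups())) zero[[col]] <- 0
  expect_equal(score_nrf93(zero, 0, cfg), 0)

  # limit nutrients subtract linearly: sodium at its MRV costs 100
  salted <- at_dv
  salted$sodium <- 7.5
  expect_equal(score_nrf93(salted, 0, cfg), 800)
})

test_that("the %DV cap bounds NRF9.3 and removing it dominates", {
  cohort <- generate_cohort(default_spec(400, seed = 17))
  added <- impute_sugars(cohort)$added_sugar_g
  capped <- score_nrf93(cohort, added, nrf93_config(cap_pct = 100))
  uncapped <- score_nrf93(cohort, added, nrf93_config(cap_pct = Inf))
  expect_true(all(capped <= 900 + 1e-9))
  expect_true(all(uncapped >= capped - 1e-9))

  # per-100kcal basis is invariant to uniform intake+energy scaling
  scaled <- cohort
  for (col in c("energy", diet_nutrients(), diet_food_groups())) {
    scaled[[col]] <- scaled[[col]] * 2
  }
  cfg100 <- nrf93_config(basis = "per_100kcal")
  expect_equal(score_nrf93(scaled, 2 * added, cfg100),
               score_nrf93(cohort, added, cfg100), tolerance = 1e-12)
})

test_that("DQSJ quartile scoring is uniform, bounded and rank-invariant", {
  cohort <- generate_cohort(default_spec(800, seed = 23))
  prof <- to_density_profile(cohort)
  full <- score_dqsj(prof, dqsj_config(character()))
  expect_true(all(full$total >= 0 & full$total <= 30))

  # continuous component with n divisible by 4 per sex: exactly uniform
  n <- 400
  prof_u <- tibble::tibble(
    participant_id = as.character(seq_len(2 * n)),
    sex = rep(c("male", "female"), each = n)
  )
  set.seed(99)
  for (comp in dqsj_config()$components$name) {
    prof_u[[paste0(comp, "_per_1000kcal")]] <- stats::rlnorm(2 * n)
  }
  sc <- score_dqsj(prof_u, dqsj_config(character()))
  for (comp in dqsj_config()$components$name) {
    counts <- table(factor(sc[[paste0("dqsj_", comp)]], levels = 0:3))
    expect_equal(as.integer(counts), rep(n / 2, 4))
  }

  # strictly increasing transform of one component leaves scores unchanged
  prof_t <- prof_u
  prof_t$fruits_per_1000kcal <- exp(prof_t$fruits_per_1000kcal / 10)
  expect_identical(score_dqsj(prof_t, dqsj_config(character())), sc)
})

test_that("DQSJ replication mode caps the attainable total at 24", {
  cohort <- generate_cohort(default_spec(400, seed = 31))
  prof <- to_density_profile(cohort)
  sc <- score_dqsj(prof)  # whole grains and nuts fixed at 0
  expect_true(all(sc$dqsj_whole_grains == 0))
  expect_true(all(sc$dqsj_nuts == 0))
  expect_true(all(sc$total <= 24))

  # an engineered best-stratum participant attains exactly 24
  best <- which.max(sc$total)
  comps <- dqsj_config()$components
  for (i in seq_len(nrow(comps))) {
    col <- paste0(comps$name[i], "_per_1000kcal")
    prof[[col]][best] <- if (comps$type[i] == "adequacy") {
      max(prof[[col]]) * 10
    } else 0
  }
  expect_equal(score_dqsj(prof)$total[best], 24L)
})

test_that("DQSJ tie and small-sample rules behave as declared", {
  prof <- tibble::tibble(
    participant_id = as.character(1:20),
    sex = rep(c("male", "female"), each = 10)
  )
  for (comp in dqsj_config()$components$name) {
    prof[[paste0(comp, "_per_1000kcal")]] <- stats::runif(20)
  }
  # a constant component puts everyone in the lowest intake stratum
  prof$fruits_per_1000kcal <- 5
  sc <- score_dqsj(prof, dqsj_config(character()))
  expect_true(all(sc$dqsj_fruits == 0L))
  prof$sodium_per_1000kcal <- 2                     # moderation: 3 - 0
  sc2 <- score_dqsj(prof, dqsj_config(character()))
  expect_true(all(sc2$dqsj_sodium == 3L))

  expect_error(score_dqsj(prof[1:12, ], dqsj_config(character())),
               "at least 8")
  expect_error(dqsj_config("rice"), "unknown")
})
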