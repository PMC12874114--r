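# in-code fixtures: a minimal valid diet record table with overridable fields

make_records <- function(n = 1, energy = 2000, sex = "male",
                         cohort = "hatoyama", ...) {
  base <- tibble::tibble(
    participant_id = sprintf("F%03d", seq_len(n)),
    cohort = rep_len(cohort, n), sex = rep_len(sex, n),
    age = 73L, energy = rep_len(energy, n),
    consented = TRUE, attended_checkup = TRUE,
    protein = 70, fat = 55, sfa = 15, carbohydrate = 260,
    dietary_fiber = 14, vitamin_a = 650, vitamin_d = 12, vitamin_e = 7,
    vitamin_k = 230, vitamin_b1 = 0.9, vitamin_b2 = 1.3, niacin = 15,
    vitamin_b6 = 1.3, vitamin_b12 = 7, folate = 340, vitamin_c = 110,
    potassium = 2400, calcium = 550, magnesium = 260, phosphorus = 1050,
    iron = 8, zinc = 8.5, copper = 1.1, sodium = 4.5,
    fruits = 120, vegetables = 270, nuts = 2, legumes = 60, dairy = 130,
    whole_grains = 5, fish = 80, red_processed_meat = 55,
    sugar_sweetened_beverages = 50
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- rep_len(overrides[[nm]], n)
  base
}

# independent brute-force Spearman oracle: ranks by pairwise counting
# (average ranks for ties), then the explicit product-moment formula
brute_rank <- function(x) {
  vapply(seq_along(x),
         function(i) sum(x < x[i]) + (sum(x == x[i]) + 1) / 2,
         numeric(1))
}

brute_spearman <- function(x, y) {
  rx <- brute_rank(x)
  ry <- brute_rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
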