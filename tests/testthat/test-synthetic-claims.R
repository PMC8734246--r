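test_that("population generation is seeded, sized and spanned as configured", {
  cfg <- population_config(n_index = 10, control_pool_multiplier = 10)
  p1 <- generate_population(cfg, seed = 1)
  p2 <- generate_population(cfg, seed = 1)
  expect_identical(p1, p2)

  expect_equal(sum(p1$population == "index"), 10)
  expect_equal(sum(p1$population == "control"), 100)
  expect_true(all(p1$birth_year >= 1932 & p1$birth_year <= 1992))
  expect_true(all(p1$sex_at_birth %in% c("M", "F")))

  # zero dropout hazard: every spell covers the full data period
  expect_true(all(p1$registration_start == as.Date("1996-01-01")))
  expect_true(all(p1$registration_end == as.Date("2012-12-31")))

  p3 <- generate_population(cfg, seed = 2)
  expect_false(identical(p1$birth_year, p3$birth_year))
})

test_that("dropout hazard shortens spells but keeps them well-formed", {
  cfg <- population_config(n_index = 200, control_pool_multiplier = 2,
                           dropout_rate = 0.15)
  p <- generate_population(cfg, seed = 7)
  expect_true(all(p$registration_start <= p$registration_end))
  expect_true(all(p$registration_end <= as.Date("2012-12-31")))
  expect_true(any(p$registration_end < as.Date("2012-12-31")))
})

test_that("onset histories follow the constant-hazard exponential model", {
  cfg <- population_config(n_index = 10000, control_pool_multiplier = 1)
  persons <- generate_population(cfg, seed = 11)

  dm0 <- disease_model("null_disease", onset_hazard_per_year = 0)
  expect_equal(nrow(simulate_disease_histories(persons, dm0, seed = 11)), 0)

  # h = 0.05/yr over the 17-year data window: onset fraction 1 - exp(-0.85)
  dm <- disease_model("toy", onset_hazard_per_year = 0.05,
                      encounter_rates = c(physician = 1),
                      code_pool = list(physician = "4019"))
  onsets <- simulate_disease_histories(persons, dm, seed = 11)
  expect_lte(max(table(onsets$person_id)), 1)  # absorbing: one onset max
  p_true <- 1 - exp(-0.05 * 17)
  se <- sqrt(p_true * (1 - p_true) / nrow(persons))
  expect_lt(abs(nrow(onsets) / nrow(persons) - p_true), 3 * se)
  expect_true(all(onsets$onset_date >= as.Date("1996-01-01")))
  expect_true(all(onsets$onset_date <= as.Date("2012-12-31")))
})

test_that("the index-population hazard multiplier raises onset fractions", {
  cfg <- population_config(n_index = 10000, control_pool_multiplier = 1)
  persons <- generate_population(cfg, seed = 3)
  dm <- disease_model("toy", onset_hazard_per_year = 0.05,
                      index_rate_multiplier = 2,
                      encounter_rates = c(physician = 1),
                      code_pool = list(physician = "4019"))
  onsets <- simulate_disease_histories(persons, dm, seed = 3)
  hit <- persons$person_id %in% onsets$person_id
  tab <- table(persons$population, hit)
  tst <- stats::prop.test(tab[, "TRUE"], rowSums(tab),
                          alternative = "less")  # control < index
  expect_lt(tst$p.value, 0.01)
})

test_that("burn-in before the data window produces left-truncated onsets", {
  cfg <- population_config(n_index = 2000, control_pool_multiplier = 1)
  persons <- generate_population(cfg, seed = 5)
  dm <- disease_model("toy", onset_hazard_per_year = 0.2,
                      encounter_rates = c(physician = 1),
                      code_pool = list(physician = "4019"))
  onsets <- simulate_disease_histories(persons, dm, seed = 5,
                                       burn_in_year = 1986)
  expect_gt(sum(onsets$onset_date < as.Date("1996-01-01")), 0)
})

test_that("claim streams recover the Poisson mean and respect onset", {
  n <- 5000
  # 10-year spell, onset at registration start, physician rate 2/yr
  persons <- fx_persons(sprintf("C%05d", seq_len(n)),
                        end = as.Date("2005-12-31"))
  onsets <- tibble::tibble(person_id = persons$person_id,
                           disease_name = "toy",
                           onset_date = persons$registration_start)
  dm <- disease_model("toy", onset_hazard_per_year = 0.1,
                      encounter_rates = c(physician = 2),
                      code_pool = list(physician = "4019"))
  claims <- simulate_claims(persons, onsets, dm, seed = 9)
  counts <- table(factor(claims$person_id, levels = persons$person_id))
  lambda <- 2 * (as.numeric(as.Date("2005-12-31") -
                              as.Date("1996-01-01")) + 1) / 365.25
  se <- sqrt(lambda / n)
  expect_lt(abs(mean(counts) - lambda), 3 * se)

  # zero rates => no claims at all (no background configured either)
  dm0 <- disease_model("toy", onset_hazard_per_year = 0.1)
  expect_equal(nrow(simulate_claims(persons, onsets, dm0, seed = 9)), 0)
})

test_that("claims respect registration spells, onset dates and code pools", {
  cfg <- population_config(n_index = 300, control_pool_multiplier = 2,
                           dropout_rate = 0.1)
  persons <- generate_population(cfg, seed = 21)
  dm <- disease_model("toy", onset_hazard_per_year = 0.15,
                      encounter_rates = c(physician = 1.5,
                                          hospital = 0.3),
                      background_claim_rate = 0.8,
                      code_pool = list(physician = c("4019", "4011"),
                                       hospital = "I10"))
  onsets <- simulate_disease_histories(persons, dm, seed = 21,
                                       burn_in_year = 1986)
  claims <- simulate_claims(persons, onsets, dm, seed = 21)

  d <- dplyr::left_join(claims, persons, by = "person_id")
  expect_true(all(d$service_date >= d$registration_start))
  expect_true(all(d$service_date <= d$registration_end))

  disease_codes <- c("4019", "4011", "I10")
  dc <- dplyr::inner_join(claims[claims$code %in% disease_codes, ],
                          onsets, by = "person_id")
  expect_true(all(dc$service_date >= dc$onset_date))

  # persons without onset emit only background-pool codes
  no_onset <- claims[!claims$person_id %in% onsets$person_id, ]
  expect_true(all(startsWith(no_onset$code, "ZZ9") |
                    startsWith(no_onset$code, "9999999")))

  # pharmacy claims carry DINs, physician ICD-9, hospital ICD-10
  expect_true(all(claims$code_system[claims$source == "pharmacy"] == "DIN"))
  expect_true(all(claims$code_system[claims$source == "physician"] ==
                    "ICD9"))
  expect_true(all(claims$code_system[claims$source == "hospital"] ==
                    "ICD10"))

  # full determinism of the claim stream
  expect_identical(claims, simulate_claims(persons, onsets, dm, seed = 21))
})

test_that("unknown diseases in the onset table are rejected", {
  persons <- fx_persons("A")
  onsets <- tibble::tibble(person_id = "A", disease_name = "mystery",
                           onset_date = as.Date("2000-01-01"))
  dm <- disease_model("toy", onset_hazard_per_year = 0.1)
  expect_error(simulate_claims(persons, onsets, dm, seed = 1), "mystery")
})

test_that("generator tables survive a CSV round trip", {
  cfg <- population_config(n_index = 20, control_pool_multiplier = 2)
  persons <- generate_population(cfg, seed = 2)
  dm <- disease_model("toy", onset_hazard_per_year = 0.2,
                      encounter_rates = c(physician = 1),
                      code_pool = list(physician = "4019"))
  onsets <- simulate_disease_histories(persons, dm, seed = 2)
  claims <- simulate_claims(persons, onsets, dm, seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_tables(persons, onsets, claims, dir)
  expect_identical(as.data.frame(read_persons(paths[["persons"]])),
                   as.data.frame(persons))
  expect_identical(as.data.frame(read_claims(paths[["claims"]])),
                   as.data.frame(claims))
})
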