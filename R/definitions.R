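# Synthetic stand-in DINs for glucose-lowering drugs (insulins, metformin,
# sulfonylureas).  These are NOT real Drug Identification Numbers; they only
# need to be consistent between the generator's pharmacy code pool and the
# diabetes case definition.
SYNTHETIC_DIABETES_DINS <- c("00500100", "00500101", "00500102", "00500103")

#' Default case definitions for eight chronic diseases
#'
#' Ships ready-to-use case definitions for cardiovascular disease, kidney
#' disease, liver disease, COPD, diabetes, osteoarthritis, hypertension and
#' Alzheimer's/dementia, patterned on Canadian Chronic Disease Surveillance
#' System style rules: one hospitalization OR two physician claims within
#' two years, with diabetes additionally identifiable from drug
#' dispensations, and strict age restrictions (> 20, > 35 and > 40 years)
#' for hypertension, COPD and Alzheimer's/dementia respectively.
#'
#' These definitions are illustrative stand-ins built for use with the
#' package's synthetic claims generator.  The ICD prefixes are abbreviated
#' and the diabetes DIN list is synthetic; they are not validated
#' surveillance algorithms and should be replaced (via
#' [read_case_definitions()] or [case_definition()]) before any use on real
#' data.
#'
#' @return A named list of [case_definition()] objects.
#' @export
default_case_definitions <- function() {
  two_yr <- 730L
  defs <- list(
    case_definition("cvd", list(
      clause("hospital", c("I20", "I21", "I22", "I25", "I50", "I60", "I61",
                           "I63", "I64")),
      clause("physician", c("410", "411", "412", "413", "414", "428", "430",
                            "431", "433", "434", "436"),
             min_count = 2, within_days = two_yr))),
    case_definition("kidney_disease", list(
      clause("hospital", c("N17", "N18", "N19")),
      clause("physician", c("580", "581", "582", "583", "585", "586"),
             min_count = 2, within_days = two_yr))),
    case_definition("liver_disease", list(
      clause("hospital", c("K70", "K71", "K72", "K73", "K74", "K75", "K76")),
      clause("physician", c("571", "572", "573"),
             min_count = 2, within_days = two_yr))),
    case_definition("copd", list(
      clause("hospital", c("J41", "J42", "J43", "J44")),
      clause("physician", c("491", "492", "496"),
             min_count = 2, within_days = two_yr)),
      min_age_years = 35),
    case_definition("diabetes", list(
      clause("hospital", c("E10", "E11", "E13", "E14")),
      clause("physician", "250", min_count = 2, within_days = two_yr),
      clause("pharmacy", SYNTHETIC_DIABETES_DINS))),
    case_definition("osteoarthritis", list(
      clause("hospital", c("M15", "M16", "M17", "M18", "M19")),
      clause("physician", "715", min_count = 2, within_days = two_yr))),
    case_definition("hypertension", list(
      clause("hospital", c("I10", "I11", "I12", "I13", "I15")),
      clause("physician", c("401", "402", "403", "404", "405"),
             min_count = 2, within_days = two_yr)),
      min_age_years = 20),
    case_definition("alzheimers_dementia", list(
      clause("hospital", c("F00", "F01", "F02", "F03", "G30")),
      clause("physician", c("290", "3310"),
             min_count = 2, within_days = two_yr)),
      min_age_years = 40)
  )
  setNames(defs, vapply(defs, `[[`, "", "disease_name"))
}

#' Default disease models for the synthetic generator
#'
#' One [disease_model()] per default case definition, with code pools that
#' the matching definition recognises.  Onset hazards and encounter rates
#' are plausible order-of-magnitude choices spanning the spectrum from
#' frequently-encountered conditions (diabetes, with regular dispensations)
#' to sparsely-encountered ones (osteoarthritis, liver disease), which is
#' the contrast that drives lookback-window sensitivity.  Index-population
#' multipliers are largest for kidney and liver disease, where
#' population gaps are widest.
#'
#' @return A named list of [disease_model()] objects.
#' @export
default_disease_models <- function() {
  models <- list(
    disease_model("cvd", onset_hazard_per_year = 0.008,
                  index_rate_multiplier = 1.6,
                  encounter_rates = c(hospital = 0.08, physician = 0.8),
                  background_claim_rate = 0.15,
                  code_pool = list(hospital = c("I21.9", "I50.0"),
                                   physician = c("4139", "4280"))),
    disease_model("kidney_disease", onset_hazard_per_year = 0.004,
                  index_rate_multiplier = 2.5,
                  encounter_rates = c(hospital = 0.04, physician = 0.5),
                  background_claim_rate = 0.15,
                  code_pool = list(hospital = "N18.9",
                                   physician = "5859")),
    disease_model("liver_disease", onset_hazard_per_year = 0.004,
                  index_rate_multiplier = 3,
                  encounter_rates = c(hospital = 0.02, physician = 0.2),
                  background_claim_rate = 0.15,
                  code_pool = list(hospital = "K74.6",
                                   physician = "5715")),
    disease_model("copd", onset_hazard_per_year = 0.005,
                  index_rate_multiplier = 1.8,
                  encounter_rates = c(hospital = 0.05, physician = 0.7),
                  background_claim_rate = 0.15,
                  code_pool = list(hospital = "J44.9",
                                   physician = c("4919", "496"))),
    disease_model("diabetes", onset_hazard_per_year = 0.010,
                  index_rate_multiplier = 1.5,
                  encounter_rates = c(hospital = 0.05, physician = 1.2,
                                      pharmacy = 3),
                  background_claim_rate = 0.15,
                  code_pool = list(hospital = "E11.9",
                                   physician = c("25000", "25001"),
                                   pharmacy = SYNTHETIC_DIABETES_DINS)),
    disease_model("osteoarthritis", onset_hazard_per_year = 0.012,
                  index_rate_multiplier = 1.2,
                  encounter_rates = c(hospital = 0.01, physician = 0.25),
                  background_claim_rate = 0.15,
                  code_pool = list(hospital = "M17.1",
                                   physician = c("7150", "7159"))),
    disease_model("hypertension", onset_hazard_per_year = 0.020,
                  index_rate_multiplier = 1.3,
                  encounter_rates = c(hospital = 0.02, physician = 1.5),
                  background_claim_rate = 0.15,
                  code_pool = list(hospital = "I10",
                                   physician = c("4011", "4019"))),
    disease_model("alzheimers_dementia", onset_hazard_per_year = 0.002,
                  index_rate_multiplier = 1.5,
                  encounter_rates = c(hospital = 0.05, physician = 0.4),
                  background_claim_rate = 0.15,
                  code_pool = list(hospital = c("F03", "G30.9"),
                                   physician = c("2900", "3310")))
  )
  setNames(models, vapply(models, `[[`, "", "disease_name"))
}

#' Read case definitions from a YAML file
#'
#' The file holds one mapping per disease:
#' ```yaml
#' hypertension:
#'   min_age_years: 20
#'   clauses:
#'     - source: physician
#'       code_prefixes: ["401", "402"]
#'       min_count: 2
#'       within_days: 730
#' ```
#'
#' @param path Path to the YAML file.
#' @return A named list of [case_definition()] objects.
#' @export
read_case_definitions <- function(path) {
  raw <- yaml::read_yaml(path)
  defs <- lapply(names(raw), function(dn) {
    spec <- raw[[dn]]
    clauses <- lapply(spec$clauses, function(cl) {
      clause(cl$source, as.character(cl$code_prefixes),
             min_count = cl$min_count %||% 1L,
             within_days = cl$within_days)
    })
    case_definition(dn, clauses, min_age_years = spec$min_age_years)
  })
  setNames(defs, names(raw))
}

#' Write case definitions to a YAML file
#'
#' Inverse of [read_case_definitions()].
#'
#' @param definitions Named list of [case_definition()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_case_definitions <- function(definitions, path) {
  out <- lapply(definitions, function(def) {
    entry <- list(clauses = lapply(def$clauses, function(cl) {
      c(list(source = cl$source,
             code_prefixes = as.list(cl$code_prefixes),
             min_count = cl$min_count),
        if (!is.null(cl$within_days)) list(within_days = cl$within_days))
    }))
    if (!is.null(def$min_age_years)) {
      entry <- c(list(min_age_years = def$min_age_years), entry)
    }
    entry
  })
  names(out) <- vapply(definitions, `[[`, "", "disease_name")
  yaml::write_yaml(out, path)
  invisible(path)
}
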