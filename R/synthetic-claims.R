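#' Configuration for a synthetic two-population cohort
#'
#' Describes the populations that the claims generator emulates: an index
#' population with elevated disease onset / healthcare engagement and a pool
#' of potential controls, all registered with a single-payer health system
#' from `data_start_year` onwards.  Defaults mirror a cohort with complete
#' follow-up over 1996--2012, 82% male, and a birth-year spread giving a
#' median age of about 50 in 2012.
#'
#' @param n_index Number of index persons (>= 1).
#' @param control_pool_multiplier Pool size of potential controls per index
#'   person; must be at least the intended match ratio (it is not validated
#'   against the ratio here -- an undersized pool surfaces as a matching
#'   error downstream).
#' @param birth_year_range Inclusive integer pair; birth years are drawn
#'   uniformly from this range.
#' @param sex_distribution Proportion male, in `[0, 1]`.
#' @param data_start_year First calendar year of data; every registration
#'   spell starts on January 1 of this year.
#' @param data_end_year Last full calendar year of data.
#' @param dropout_rate Per-year hazard of a registration spell ending, in
#'   `[0, 1)`.  The default of 0 reproduces a design requiring complete
#'   follow-up over the whole data period.
#' @return An object of class `lw_population_config`.
#' @export
#' @examples
#' population_config(n_index = 100)
population_config <- function(n_index,
                              control_pool_multiplier = 10L,
                              birth_year_range = c(1932L, 1992L),
                              sex_distribution = 0.82,
                              data_start_year = 1996L,
                              data_end_year = 2012L,
                              dropout_rate = 0) {
  stopifnot(length(n_index) == 1L, n_index >= 1,
            control_pool_multiplier >= 1,
            length(birth_year_range) == 2L,
            birth_year_range[1] <= birth_year_range[2],
            sex_distribution >= 0, sex_distribution <= 1,
            data_start_year < data_end_year,
            dropout_rate >= 0, dropout_rate < 1)
  structure(
    list(n_index = as.integer(n_index),
         control_pool_multiplier = as.integer(control_pool_multiplier),
         birth_year_range = as.integer(birth_year_range),
         sex_distribution = sex_distribution,
         data_start_year = as.integer(data_start_year),
         data_end_year = as.integer(data_end_year),
         dropout_rate = dropout_rate),
    class = "lw_population_config"
  )
}

#' Define a chronic disease for the synthetic generator
#'
#' A disease is modelled as absorbing: once onset occurs there is no
#' remission, and diagnosis-coded healthcare encounters then accrue as
#' independent homogeneous Poisson processes per claim source for as long as
#' the person remains registered.  `encounter_rates` is the knob that
#' controls how quickly a case-finding algorithm can see the disease: a
#' condition managed with frequent dispensations (e.g. diabetes) is visible
#' within a short window, while one with sparse encounters (e.g.
#' osteoarthritis) needs a long lookback.
#'
#' @param disease_name Label used throughout downstream tables.
#' @param onset_hazard_per_year Constant onset hazard (per person-year),
#'   `>= 0`.
#' @param index_rate_multiplier Multiplier applied to the onset hazard for
#'   the index population (> 0).
#' @param encounter_rates Named numeric vector, mean disease-coded claims
#'   per year while diseased, names among `hospital`, `physician`,
#'   `pharmacy`.
#' @param background_claim_rate Mean non-disease claims per year over the
#'   whole registration spell; these carry codes from a reserved background
#'   pool disjoint from every disease code pool.
#' @param code_pool Named list of character vectors: the codes emitted for
#'   this disease per source.  Pharmacy codes must be DIN-style digit
#'   strings.
#' @return An object of class `lw_disease_model`.
#' @export
#' @examples
#' disease_model("hypertension", onset_hazard_per_year = 0.02,
#'               encounter_rates = c(physician = 1.5),
#'               code_pool = list(physician = c("4011", "4019")))
disease_model <- function(disease_name,
                          onset_hazard_per_year,
                          index_rate_multiplier = 1,
                          encounter_rates = c(physician = 0),
                          background_claim_rate = 0,
                          code_pool = list()) {
  stopifnot(is.character(disease_name), nchar(disease_name) > 0,
            onset_hazard_per_year >= 0,
            index_rate_multiplier > 0,
            all(encounter_rates >= 0),
            background_claim_rate >= 0)
  if (!all(names(encounter_rates) %in% CLAIM_SOURCES)) {
    stop("encounter_rates names must be among: ",
         paste(CLAIM_SOURCES, collapse = ", "), call. = FALSE)
  }
  if (!all(names(code_pool) %in% CLAIM_SOURCES)) {
    stop("code_pool sources must be among: ",
         paste(CLAIM_SOURCES, collapse = ", "), call. = FALSE)
  }
  active <- names(encounter_rates)[encounter_rates > 0]
  no_codes <- setdiff(active, names(code_pool))
  if (length(no_codes)) {
    stop("disease '", disease_name, "' has a positive encounter rate but no ",
         "code pool for source(s): ", paste(no_codes, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(disease_name = disease_name,
         onset_hazard_per_year = onset_hazard_per_year,
         index_rate_multiplier = index_rate_multiplier,
         encounter_rates = encounter_rates,
         background_claim_rate = background_claim_rate,
         code_pool = code_pool),
    class = "lw_disease_model"
  )
}

# Reserved background code pools, disjoint by construction from any
# plausible diagnosis/drug pool, so case-finding specificity is perfect.
BACKGROUND_CODES <- list(
  hospital  = sprintf("ZZ9.%d", 0:9),
  physician = sprintf("ZZ9%d", 0:9),
  pharmacy  = sprintf("9999999%d", 0:9)
)

# Fixed mix of sources for background (non-disease) claims.
BACKGROUND_SOURCE_WEIGHTS <- c(hospital = 0.05, physician = 0.70,
                               pharmacy = 0.25)

#' Generate a synthetic two-population person table
#'
#' Draws `n_index` index persons and `n_index * control_pool_multiplier`
#' potential controls.  All registration spells start on January 1 of
#' `data_start_year`; with a positive `dropout_rate` each subsequent year
#' ends the spell with that probability, at a uniform date within the year,
#' otherwise spells run to December 31 of `data_end_year`.
#'
#' @param config An [population_config()] object.
#' @param seed Master integer seed; the population draw uses the stream
#'   `derive_seed(seed, "population")`.
#' @return A tibble with columns `person_id`, `birth_year`, `sex_at_birth`
#'   (`"M"`/`"F"`), `population` (`"index"`/`"control"`),
#'   `registration_start`, `registration_end` (both `Date`).
#' @export
#' @examples
#' generate_population(population_config(n_index = 5), seed = 1)
generate_population <- function(config, seed) {
  stopifnot(inherits(config, "lw_population_config"))
  n_ctrl <- config$n_index * config$control_pool_multiplier
  n <- config$n_index + n_ctrl
  reg_start <- year_start(config$data_start_year)
  data_end <- year_end(config$data_end_year)
  withr::with_seed(derive_seed(seed, "population"), {
    birth_year <- sample(seq(config$birth_year_range[1],
                             config$birth_year_range[2]),
                         n, replace = TRUE)
    sex <- ifelse(runif(n) < config$sex_distribution, "M", "F")
    if (config$dropout_rate > 0) {
      # rgeom counts full years survived before the dropout year
      drop_year <- config$data_start_year + rgeom(n, config$dropout_rate)
      in_range <- drop_year <= config$data_end_year
      reg_end <- rep(data_end, n)
      if (any(in_range)) {
        ys <- drop_year[in_range]
        reg_end[in_range] <- year_start(ys) +
          floor(runif(sum(in_range)) * days_in_year(ys))
      }
    } else {
      reg_end <- rep(data_end, n)
    }
  })
  tibble(
    person_id = sprintf("P%07d", seq_len(n)),
    birth_year = as.integer(birth_year),
    sex_at_birth = sex,
    population = rep(c("index", "control"), c(config$n_index, n_ctrl)),
    registration_start = rep(reg_start, n),
    registration_end = reg_end
  )
}

#' Simulate absorbing chronic-disease onset histories
#'
#' Onset for each person-disease pair follows a constant-hazard
#' (exponential) model over the exposure window from January 1 of
#' `burn_in_year` to the end of the last data year.  Setting `burn_in_year`
#' before the registration start produces left-truncated histories: persons
#' whose onset (and possibly all early claims) predate the data window,
#' which is exactly the situation that makes short lookback windows miss
#' prevalent cases.  The index population's hazard is multiplied by each
#' disease's `index_rate_multiplier`.  Onset is absorbing; at most one onset
#' row is emitted per person-disease.
#'
#' @param persons Person table from [generate_population()].
#' @param diseases List of [disease_model()] objects.
#' @param seed Master integer seed; each disease uses its own stream
#'   `derive_seed(seed, paste0("onset:", disease_name))`.
#' @param burn_in_year First year of onset exposure.  Default: the earliest
#'   registration year in `persons` (no left truncation).
#' @return A tibble with one row per onset: `person_id`, `disease_name`,
#'   `onset_date` (`Date`, uniform within the onset year).  Persons without
#'   onset are absent.
#' @export
simulate_disease_histories <- function(persons, diseases, seed,
                                       burn_in_year = NULL) {
  assert_person_table(persons)
  if (!nrow(persons)) stop("persons table is empty", call. = FALSE)
  if (inherits(diseases, "lw_disease_model")) diseases <- list(diseases)
  data_end_year <- max(calendar_year(persons$registration_end))
  burn_in_year <- as.integer(
    burn_in_year %||% min(calendar_year(persons$registration_start)))
  exposure_years <- (data_end_year + 1L) - burn_in_year
  if (exposure_years <= 0) stop("burn_in_year is after the data period",
                                call. = FALSE)
  out <- lapply(diseases, function(dm) {
    stopifnot(inherits(dm, "lw_disease_model"))
    hazard <- dm$onset_hazard_per_year *
      ifelse(persons$population == "index", dm$index_rate_multiplier, 1)
    if (all(hazard == 0)) return(NULL)
    withr::with_seed(derive_seed(seed, paste0("onset:", dm$disease_name)), {
      t_onset <- rep(Inf, nrow(persons))
      pos <- hazard > 0
      t_onset[pos] <- rexp(sum(pos), rate = hazard[pos])
      hit <- t_onset < exposure_years
      onset_year <- burn_in_year + floor(t_onset[hit])
      onset_date <- year_start(onset_year) +
        floor(runif(sum(hit)) * days_in_year(onset_year))
    })
    if (!any(hit)) return(NULL)
    tibble(person_id = persons$person_id[hit],
           disease_name = dm$disease_name,
           onset_date = onset_date)
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    out <- tibble(person_id = character(), disease_name = character(),
                  onset_date = as.Date(character()))
  }
  dplyr::arrange(out, .data$person_id, .data$disease_name)
}

#' Simulate claim streams from onset histories
#'
#' For every person-disease onset, disease-coded claims arrive per source as
#' a homogeneous Poisson process at the model's `encounter_rates`, from the
#' later of onset and registration start until registration end, with codes
#' sampled uniformly from the model's `code_pool`.  Background (non-disease)
#' claims arrive over the full registration spell at each model's
#' `background_claim_rate` and carry codes from a reserved pool disjoint
#' from all disease pools.  No claim ever precedes onset or falls outside a
#' person's registration spell.
#'
#' @param persons Person table from [generate_population()].
#' @param onsets Onset table from [simulate_disease_histories()] (or built
#'   directly; only `person_id`, `disease_name`, `onset_date` are used).
#' @param diseases List of [disease_model()] objects covering every
#'   `disease_name` in `onsets`.
#' @param seed Master integer seed; claim generation for disease `d` uses
#'   the stream `derive_seed(seed, paste0("claims:", d))` and background
#'   claims use `derive_seed(seed, paste0("background:", d))`.
#' @return A tibble of claims: `person_id`, `service_date` (`Date`),
#'   `source`, `code`, `code_system`, sorted by person and date.
#' @export
simulate_claims <- function(persons, onsets, diseases, seed) {
  assert_person_table(persons)
  if (inherits(diseases, "lw_disease_model")) diseases <- list(diseases)
  names(diseases) <- vapply(diseases, `[[`, "", "disease_name")
  unknown <- setdiff(unique(onsets$disease_name), names(diseases))
  if (length(unknown)) {
    stop("onset table refers to unknown disease(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  person_idx <- persons[, c("person_id", "registration_start",
                            "registration_end")]

  poisson_claims <- function(ids, start, end, rate, codes, source) {
    span_years <- pmax(0, as.numeric(end - start) + 1) / 365.25
    n_claims <- rpois(length(ids), rate * span_years)
    keep <- n_claims > 0
    if (!any(keep)) return(NULL)
    ids <- rep(ids[keep], n_claims[keep])
    start <- rep(start[keep], n_claims[keep])
    end <- rep(end[keep], n_claims[keep])
    tibble(person_id = ids,
           service_date = random_dates_between(start, end),
           source = source,
           code = sample(codes, length(ids), replace = TRUE),
           code_system = unname(SOURCE_CODE_SYSTEM[source]))
  }

  disease_parts <- lapply(diseases, function(dm) {
    dn <- dm$disease_name
    on_d <- onsets[onsets$disease_name == dn, , drop = FALSE]
    if (!nrow(on_d)) return(NULL)
    on_d <- dplyr::inner_join(on_d, person_idx, by = "person_id")
    start <- pmax(on_d$onset_date, on_d$registration_start)
    end <- on_d$registration_end
    live <- start <= end
    if (!any(live)) return(NULL)
    withr::with_seed(derive_seed(seed, paste0("claims:", dn)), {
      parts <- lapply(names(dm$encounter_rates), function(src) {
        rate <- dm$encounter_rates[[src]]
        if (rate <= 0) return(NULL)
        poisson_claims(on_d$person_id[live], start[live], end[live],
                       rate, dm$code_pool[[src]], src)
      })
    })
    dplyr::bind_rows(parts)
  })

  background_parts <- lapply(diseases, function(dm) {
    if (dm$background_claim_rate <= 0) return(NULL)
    withr::with_seed(
      derive_seed(seed, paste0("background:", dm$disease_name)), {
        src <- sample(names(BACKGROUND_SOURCE_WEIGHTS), nrow(person_idx),
                      replace = TRUE, prob = BACKGROUND_SOURCE_WEIGHTS)
        parts <- lapply(CLAIM_SOURCES, function(s) {
          sel <- src == s
          if (!any(sel)) return(NULL)
          poisson_claims(person_idx$person_id[sel],
                         person_idx$registration_start[sel],
                         person_idx$registration_end[sel],
                         dm$background_claim_rate,
                         BACKGROUND_CODES[[s]], s)
        })
      })
    dplyr::bind_rows(parts)
  })

  out <- dplyr::bind_rows(c(disease_parts, background_parts))
  if (!nrow(out)) {
    return(tibble(person_id = character(),
                  service_date = as.Date(character()),
                  source = character(), code = character(),
                  code_system = character()))
  }
  dplyr::arrange(out, .data$person_id, .data$service_date, .data$source,
                 .data$code)
}

#' Write generator outputs to CSV
#'
#' Writes `persons.csv`, `onsets.csv` and `claims.csv` (UTF-8, comma
#' delimited, header row, ISO-8601 dates) into `dir`.
#'
#' @param persons,onsets,claims Tables from the generator.
#' @param dir Output directory, created if absent.
#' @return Invisibly, the named vector of file paths.
#' @export
write_synthetic_tables <- function(persons, onsets, claims, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(persons = file.path(dir, "persons.csv"),
             onsets = file.path(dir, "onsets.csv"),
             claims = file.path(dir, "claims.csv"))
  readr::write_csv(persons, paths[["persons"]])
  readr::write_csv(onsets, paths[["onsets"]])
  readr::write_csv(claims, paths[["claims"]])
  invisible(paths)
}

#' Read a person table written by [write_synthetic_tables()]
#' @param path Path to `persons.csv`.
#' @return A person tibble with typed columns.
#' @export
read_persons <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_character(),
    birth_year = readr::col_integer(),
    sex_at_birth = readr::col_character(),
    population = readr::col_character(),
    registration_start = readr::col_date(),
    registration_end = readr::col_date()
  ))
}

#' Read a claim table written by [write_synthetic_tables()]
#' @param path Path to `claims.csv`.
#' @return A claim tibble with typed columns.
#' @export
read_claims <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    person_id = readr::col_character(),
    service_date = readr::col_date(),
    source = readr::col_character(),
    code = readr::col_character(),
    code_system = readr::col_character()
  ))
}
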