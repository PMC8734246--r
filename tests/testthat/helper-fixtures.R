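# Small in-code fixture builders shared across test files.

fx_persons <- function(ids, birth_year = 1960, sex = "M",
                       population = "control",
                       start = as.Date("1996-01-01"),
                       end = as.Date("2012-12-31")) {
  tibble::tibble(person_id = ids,
                 birth_year = as.integer(birth_year),
                 sex_at_birth = sex,
                 population = population,
                 registration_start = as.Date(start),
                 registration_end = as.Date(end))
}

fx_claims <- function(person_id, dates, source = "physician",
                      code = "4019") {
  sys <- c(hospital = "ICD10", physician = "ICD9", pharmacy = "DIN")
  tibble::tibble(person_id = person_id,
                 service_date = as.Date(dates),
                 source = source,
                 code = code,
                 code_system = unname(sys[source]))
}

# A one-clause physician definition requiring a single claim.
fx_single_claim_def <- function(name = "toy", prefix = "401",
                                source = "physician") {
  case_definition(name, clause(source, prefix))
}

# Random small claim instance for property-style tests: up to `max_claims`
# claims per person across sources/codes drawn from a small pool.
fx_random_instance <- function(n_persons, max_claims = 12) {
  ids <- sprintf("R%03d", seq_len(n_persons))
  codes <- list(physician = c("4019", "4011", "25000", "7150"),
                hospital = c("I10", "E11.9", "K74.6"),
                pharmacy = c("00500100", "00500101"))
  rows <- lapply(ids, function(id) {
    n <- sample.int(max_claims + 1, 1) - 1L
    if (!n) return(NULL)
    src <- sample(names(codes), n, replace = TRUE)
    fx_claims(rep(id, n),
              as.Date("1996-01-01") + sample.int(6210, n, replace = TRUE),
              source = src,
              code = vapply(src, function(s) sample(codes[[s]], 1), ""))
  })
  claims <- dplyr::bind_rows(rows)
  if (is.null(claims) || !nrow(claims)) claims <- fx_claims(ids[1], "2012-06-01")
  list(ids = ids, claims = claims)
}

# Random definition with 1-3 clauses mixing single- and multi-claim rules.
fx_random_definition <- function() {
  pool <- list(
    clause("physician", "401", min_count = 2, within_days = 730),
    clause("physician", "250", min_count = 2, within_days = 365),
    clause("physician", "7150", min_count = 3, within_days = 1095),
    clause("hospital", c("I10", "E11")),
    clause("hospital", "K74"),
    clause("pharmacy", "005001"))
  case_definition("rand", sample(pool, sample(2:3, 1)))
}
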