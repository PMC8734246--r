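`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed for a named random stream
#'
#' Every stochastic operation in the package draws from its own RNG stream,
#' keyed by the master seed and a short operation label.  This keeps stages
#' independent: adding a disease model, for example, does not perturb the
#' population draw.  The derivation is a plain polynomial hash of
#' `"<key>:<seed>"` reduced modulo 2^31 - 1, so it is stable across platforms
#' and sessions.
#'
#' @param seed Master integer seed.
#' @param key Character label naming the stream (e.g. `"population"`).
#' @return An integer in `[0, 2^31 - 1)` suitable for `set.seed()`.
#' @export
#' @examples
#' derive_seed(1, "population")
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- 0
  for (b in utf8ToInt(paste0(key, ":", format(seed, scientific = FALSE)))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

year_start <- function(y) as.Date(sprintf("%d-01-01", y))

year_end <- function(y) as.Date(sprintf("%d-12-31", y))

days_in_year <- function(y) as.integer(year_start(y + 1L) - year_start(y))

calendar_year <- function(d) as.integer(format(d, "%Y"))

# Uniform random dates, one per element, between start and end inclusive.
# start/end are Date vectors of equal length; start <= end assumed.
random_dates_between <- function(start, end) {
  span <- as.numeric(end - start) + 1
  start + floor(runif(length(start)) * span)
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %-10s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, sprintf(fmt, ...)))
}

assert_person_table <- function(persons) {
  need <- c("person_id", "birth_year", "sex_at_birth", "population",
            "registration_start", "registration_end")
  missing <- setdiff(need, names(persons))
  if (length(missing)) {
    stop("person table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(persons)
}

assert_claim_table <- function(claims) {
  need <- c("person_id", "service_date", "source", "code")
  missing <- setdiff(need, names(claims))
  if (length(missing)) {
    stop("claim table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(claims)
}

CLAIM_SOURCES <- c("hospital", "physician", "pharmacy")

# Canonical code system per claim source: hospital discharge abstracts are
# coded in ICD-10-CA (with dots), physician billings in ICD-9 (no dots),
# pharmacy dispensations carry Drug Identification Numbers (digit strings).
SOURCE_CODE_SYSTEM <- c(hospital = "ICD10", physician = "ICD9",
                        pharmacy = "DIN")

title_case <- function(x) {
  paste0(toupper(substring(x, 1, 1)), substring(x, 2))
}
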