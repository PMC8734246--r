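#' Eligibility criteria for an estimation year
#'
#' Mirrors a design requiring adults registered with the health system for
#' the whole data period: age at least `min_age_years` in the estimation
#' year, registration starting no later than January 1 of
#' `require_registered_since`, and at least `require_presence_days` days of
#' registration overlap with the estimation year.
#'
#' @param estimation_year Calendar year the estimates refer to.
#' @param min_age_years Minimum age (in completed years, computed as
#'   `estimation_year - birth_year`) required for inclusion.  Default 19.
#' @param require_registered_since Persons must be registered since January
#'   1 of this year.  Default 1996.
#' @param require_presence_days Minimum days of registration overlap with
#'   the estimation year.  Default 1.
#' @return An object of class `lw_eligibility_criteria`.
#' @export
eligibility_criteria <- function(estimation_year,
                                 min_age_years = 19L,
                                 require_registered_since = 1996L,
                                 require_presence_days = 1L) {
  stopifnot(min_age_years >= 0,
            require_registered_since <= estimation_year,
            require_presence_days >= 1)
  structure(
    list(estimation_year = as.integer(estimation_year),
         min_age_years = as.integer(min_age_years),
         require_registered_since = as.integer(require_registered_since),
         require_presence_days = as.integer(require_presence_days)),
    class = "lw_eligibility_criteria"
  )
}

#' Filter a person table down to the eligible study population
#'
#' Applies the three criteria in sequence (age, registered-since,
#' presence-in-year) and logs the number excluded at each step, mimicking a
#' stepwise cohort selection flow chart.  The per-criterion exclusion counts
#' are attached as the `"exclusions"` attribute of the result.
#'
#' @param persons Person table.
#' @param criteria An [eligibility_criteria()] object.
#' @return The eligible subset of `persons`, with an `"exclusions"`
#'   attribute (a tibble with columns `criterion`, `n_excluded`,
#'   `n_remaining`).
#' @export
filter_eligible <- function(persons, criteria) {
  assert_person_table(persons)
  stopifnot(inherits(criteria, "lw_eligibility_criteria"))
  y <- criteria$estimation_year
  if (nrow(persons) &&
      y > max(calendar_year(persons$registration_end))) {
    stop("estimation_year ", y, " is outside the data range", call. = FALSE)
  }
  age_ok <- (y - persons$birth_year) >= criteria$min_age_years
  reg_ok <- persons$registration_start <=
    year_start(criteria$require_registered_since)
  overlap <- as.numeric(pmin(persons$registration_end, year_end(y)) -
                          pmax(persons$registration_start, year_start(y))) + 1
  pres_ok <- overlap >= criteria$require_presence_days

  s1 <- age_ok
  s2 <- s1 & reg_ok
  s3 <- s2 & pres_ok
  exclusions <- tibble(
    criterion = c(sprintf("age >= %d in %d", criteria$min_age_years, y),
                  sprintf("registered since %d",
                          criteria$require_registered_since),
                  sprintf(">= %d day(s) present in %d",
                          criteria$require_presence_days, y)),
    n_excluded = c(sum(!s1), sum(s1 & !reg_ok), sum(s2 & !pres_ok)),
    n_remaining = c(sum(s1), sum(s2), sum(s3))
  )
  for (i in seq_len(nrow(exclusions))) {
    log_stage("eligibility", "%s: excluded %d, remaining %d",
              exclusions$criterion[i], exclusions$n_excluded[i],
              exclusions$n_remaining[i])
  }
  out <- persons[s3, , drop = FALSE]
  attr(out, "exclusions") <- exclusions
  out
}

#' Matching specification
#'
#' @param ratio Controls per index person (default 5).
#' @param keys Person columns matched exactly (default birth year and sex
#'   at birth).
#' @param seed Integer seed governing the random order in which pool
#'   controls are consumed.
#' @return An object of class `lw_match_spec`.
#' @export
match_spec <- function(ratio = 5L, keys = c("birth_year", "sex_at_birth"),
                       seed = 1L) {
  stopifnot(ratio >= 1, length(keys) >= 1)
  structure(list(ratio = as.integer(ratio), keys = keys,
                 seed = as.integer(seed)),
            class = "lw_match_spec")
}

#' Exact 1:ratio matching of controls to index persons
#'
#' Every index person receives exactly `spec$ratio` controls agreeing on all
#' matching keys, sampled without replacement from the pool in a
#' deterministic shuffled order keyed by `spec$seed`.  A stratum with fewer
#' available controls than required is a hard error naming the stratum.
#'
#' @param index Eligible index person table.
#' @param pool Eligible control pool, disjoint from `index`.
#' @param spec A [match_spec()] object.
#' @return A cohort tibble: all `index` rows plus the selected controls,
#'   with added columns `match_id` (the index person's id) and `role`
#'   (`"index"`/`"control"`).
#' @export
match_controls <- function(index, pool, spec) {
  assert_person_table(index)
  assert_person_table(pool)
  stopifnot(inherits(spec, "lw_match_spec"))
  if (any(index$person_id %in% pool$person_id)) {
    stop("index and pool person tables must be disjoint", call. = FALSE)
  }
  missing_keys <- setdiff(spec$keys, intersect(names(index), names(pool)))
  if (length(missing_keys)) {
    stop("matching keys absent from inputs: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  key_of <- function(df) do.call(paste, c(df[spec$keys], sep = "|"))
  ik <- key_of(index)
  pk <- key_of(pool)
  need <- table(ik) * spec$ratio
  have <- table(factor(pk, levels = names(need)))
  short <- need > have
  if (any(short)) {
    s <- names(need)[which(short)[1]]
    stop(sprintf(
      "insufficient controls in stratum (%s = %s): need %d, available %d",
      paste(spec$keys, collapse = ", "), s, need[[s]], have[[s]]),
      call. = FALSE)
  }
  withr::with_seed(derive_seed(spec$seed, "match_controls"), {
    shuffled <- pool[sample.int(nrow(pool)), , drop = FALSE]
  })
  sk <- key_of(shuffled)
  picked <- lapply(unique(ik), function(s) {
    idx_ids <- index$person_id[ik == s]
    take <- shuffled[which(sk == s)[seq_len(length(idx_ids) * spec$ratio)], ,
                     drop = FALSE]
    take$match_id <- rep(idx_ids, each = spec$ratio)
    take
  })
  controls <- dplyr::bind_rows(picked)
  controls$role <- "control"
  index_out <- index
  index_out$match_id <- index_out$person_id
  index_out$role <- "index"
  out <- dplyr::bind_rows(index_out, controls)
  dplyr::arrange(out, .data$match_id, .data$role, .data$person_id)
}
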