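#' A single case-finding clause
#'
#' A clause is satisfied at date `d` when at least `min_count` claims from
#' `source`, whose codes start with one of `code_prefixes`, lie inside the
#' query window with service dates `<= d` and a maximum date span of
#' `within_days` days.  Clauses with `min_count = 1` take no span.
#'
#' @param source One of `"hospital"`, `"physician"`, `"pharmacy"`.
#' @param code_prefixes Character vector of code prefixes.  Convention:
#'   ICD-9 codes are stored without dots, ICD-10-CA codes with dots, DINs as
#'   digit strings.
#' @param min_count Number of qualifying claims required (>= 1).
#' @param within_days Maximum span in days containing the `min_count`
#'   qualifying claims; required when `min_count > 1`.
#' @return An object of class `lw_clause`.
#' @export
#' @examples
#' clause("physician", c("401", "402"), min_count = 2, within_days = 730)
clause <- function(source, code_prefixes, min_count = 1L,
                   within_days = NULL) {
  stopifnot(source %in% CLAIM_SOURCES,
            is.character(code_prefixes), length(code_prefixes) >= 1,
            min_count >= 1)
  if (min_count > 1 && is.null(within_days)) {
    stop("within_days is required when min_count > 1", call. = FALSE)
  }
  if (!is.null(within_days)) stopifnot(within_days >= 1)
  structure(list(source = source, code_prefixes = code_prefixes,
                 min_count = as.integer(min_count),
                 within_days = if (is.null(within_days)) NULL
                               else as.integer(within_days)),
            class = "lw_clause")
}

#' A disease case definition
#'
#' A case definition combines one or more [clause()]s by OR, optionally with
#' an age restriction on the analysis population (applied when denominators
#' are formed, not inside [ascertain()]).
#'
#' @param disease_name Disease label.
#' @param clauses List of [clause()] objects (at least one).
#' @param min_age_years Strict lower age bound for the analysis population
#'   (persons older than this many years are analysed), or `NULL` for no
#'   restriction.
#' @return An object of class `lw_case_definition`.
#' @export
case_definition <- function(disease_name, clauses, min_age_years = NULL) {
  if (inherits(clauses, "lw_clause")) clauses <- list(clauses)
  stopifnot(is.character(disease_name), length(clauses) >= 1,
            all(vapply(clauses, inherits, TRUE, "lw_clause")))
  if (!is.null(min_age_years)) stopifnot(min_age_years >= 0)
  structure(list(disease_name = disease_name, clauses = clauses,
                 min_age_years = if (is.null(min_age_years)) NULL
                                 else as.integer(min_age_years)),
            class = "lw_case_definition")
}

#' Does each claim match a clause?
#'
#' Vectorised over the rows of `claims`: a claim matches when its source
#' equals the clause's source and its code starts with any listed prefix.
#'
#' @param claims Claim table.
#' @param cl An [clause()] object.
#' @return Logical vector, one element per claim row.
#' @export
#' @examples
#' cls <- clause("hospital", "I21")
#' match_codes(tibble::tibble(person_id = "a",
#'                            service_date = as.Date("2010-01-01"),
#'                            source = "hospital", code = "I21.4"), cls)
match_codes <- function(claims, cl) {
  assert_claim_table(claims)
  stopifnot(inherits(cl, "lw_clause"))
  code_hit <- Reduce(`|`, lapply(cl$code_prefixes,
                                 function(p) startsWith(claims$code, p)),
                     init = rep(FALSE, nrow(claims)))
  claims$source == cl$source & code_hit
}

# Completion candidates for one clause over ALL of a person's qualifying
# claims, independent of any query window.  For min_count = m and span w a
# candidate is any run of m consecutive sorted qualifying dates spanning
# <= w days, recorded as (first_date, completion_date).  Because query
# windows are date intervals, in-window claims form a contiguous slice of
# the sorted claim list, so the candidates valid for window [s, e) are
# exactly those with first_date >= s and completion_date < e.
clause_candidates <- function(claims, cl) {
  q <- claims[match_codes(claims, cl), c("person_id", "service_date")]
  empty <- tibble(person_id = character(),
                  first_date = as.Date(character()),
                  completion_date = as.Date(character()))
  if (!nrow(q)) return(empty)
  if (cl$min_count == 1L) {
    return(tibble(person_id = q$person_id, first_date = q$service_date,
                  completion_date = q$service_date))
  }
  cands <- q |>
    dplyr::arrange(.data$person_id, .data$service_date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::mutate(first_date = dplyr::lag(.data$service_date,
                                          cl$min_count - 1L)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$first_date),
                  as.numeric(.data$service_date - .data$first_date) <=
                    cl$within_days)
  if (!nrow(cands)) return(empty)
  tibble(person_id = cands$person_id, first_date = cands$first_date,
         completion_date = cands$service_date)
}

definition_candidates <- function(claims, definition) {
  dplyr::bind_rows(lapply(definition$clauses, clause_candidates,
                          claims = claims))
}

# Earliest identification date per person for window [ws, we) given
# precomputed candidates.
candidate_id_dates <- function(candidates, window_start, window_end) {
  hit <- candidates[candidates$first_date >= window_start &
                      candidates$completion_date < window_end, ,
                    drop = FALSE]
  if (!nrow(hit)) {
    return(tibble(person_id = character(),
                  identification_date = as.Date(character())))
  }
  hit |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(identification_date = min(.data$completion_date),
                     .groups = "drop")
}

ascertain_candidates <- function(candidates, disease_name, window_start,
                                 window_end, ids) {
  earliest <- candidate_id_dates(candidates, window_start, window_end)
  tibble(person_id = ids) |>
    dplyr::left_join(earliest, by = "person_id") |>
    dplyr::mutate(disease_name = disease_name,
                  identified = !is.na(.data$identification_date)) |>
    dplyr::select("person_id", "disease_name", "identified",
                  "identification_date")
}

#' Ascertain disease cases within a date window
#'
#' Evaluates a case definition over the claims whose service dates fall in
#' the half-open window `[window_start, window_end)`.  A person is
#' identified when any clause is satisfied; the identification date is the
#' earliest date at which any clause's evidence is complete (the date of the
#' claim that completes the rule, not the first qualifying claim).  Only
#' in-window claims contribute, including to `within_days` spans.
#'
#' @param claims Claim table.
#' @param definition A [case_definition()].
#' @param window_start,window_end Window bounds (`Date` or coercible);
#'   `window_start <= window_end`, end exclusive.
#' @param persons Persons to report on: a character vector of ids or a
#'   table with a `person_id` column.  Default: every person appearing in
#'   `claims`.
#' @return A tibble with one row per person, in the order of `persons`:
#'   `person_id`, `disease_name`, `identified` (logical),
#'   `identification_date` (`Date`, `NA` when not identified).
#' @export
ascertain <- function(claims, definition, window_start, window_end,
                      persons = NULL) {
  assert_claim_table(claims)
  stopifnot(inherits(definition, "lw_case_definition"))
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (window_start > window_end) {
    stop("window_start must not be after window_end", call. = FALSE)
  }
  ids <- if (is.null(persons)) unique(claims$person_id)
         else if (is.data.frame(persons)) persons$person_id
         else persons
  ascertain_candidates(definition_candidates(claims, definition),
                       definition$disease_name, window_start, window_end,
                       ids)
}
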