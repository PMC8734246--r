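#' Maximum feasible lookback length for an estimation year
#'
#' With the earliest available data year fixed, the longest lookback window
#' usable for estimation year `Y` is `Y - data_start_year` years: the 2001
#' estimates can look back at most 5 years over data starting in 1996,
#' while 2012 can look back 16.
#'
#' @param estimation_year Calendar year the estimates refer to.
#' @param data_start_year Earliest calendar year with data.
#' @return Integer number of years.
#' @export
#' @examples
#' max_lookback(2001, 1996)  # 5
#' max_lookback(2012, 1996)  # 16
max_lookback <- function(estimation_year, data_start_year = 1996L) {
  if (estimation_year < data_start_year) {
    stop("estimation_year precedes data_start_year", call. = FALSE)
  }
  as.integer(estimation_year - data_start_year)
}

#' Specify an estimation year / lookback length pair
#'
#' @param estimation_year Calendar year the estimates refer to.
#' @param lookback_years Lookback length `k >= 0`, at most
#'   [max_lookback()] for the year.
#' @param data_start_year Earliest calendar year with data.
#' @return An object of class `lw_window_spec`.
#' @export
window_spec <- function(estimation_year, lookback_years,
                        data_start_year = 1996L) {
  k_max <- max_lookback(estimation_year, data_start_year)
  if (lookback_years < 0 || lookback_years > k_max) {
    stop(sprintf("lookback_years must be in [0, %d] for year %d",
                 k_max, estimation_year), call. = FALSE)
  }
  structure(list(estimation_year = as.integer(estimation_year),
                 lookback_years = as.integer(lookback_years),
                 data_start_year = as.integer(data_start_year)),
            class = "lw_window_spec")
}

#' The lookback interval of a window specification
#'
#' Returns the half-open date interval `[Jan 1 (Y - k), Jan 1 Y)` preceding
#' the estimation year.  With `k = 0` the interval is empty (no historical
#' data considered).
#'
#' @param spec A [window_spec()].
#' @return A list with `Date` elements `start` and `end` (end exclusive)
#'   and logical `empty`.
#' @export
#' @examples
#' lookback_interval(window_spec(2012, 16))
lookback_interval <- function(spec) {
  stopifnot(inherits(spec, "lw_window_spec"))
  start <- year_start(spec$estimation_year - spec$lookback_years)
  end <- year_start(spec$estimation_year)
  list(start = start, end = end, empty = spec$lookback_years == 0L)
}

#' Classify persons as prevalent / at-risk / incident for one window
#'
#' Ascertainment for prevalence runs over the union window
#' `[Jan 1 (Y - k), Jan 1 (Y + 1))` -- the lookback interval and the
#' estimation year as one contiguous interval, so multi-claim rules may
#' combine lookback and estimation-year claims.  A person is:
#' * **prevalent** when identified anywhere in the union window;
#' * **at risk** when NOT identified from lookback-interval claims alone
#'   (no prior prevalent case);
#' * **incident** when at risk and the identification date (the
#'   rule-completion date in the union window) falls inside the estimation
#'   year.
#'
#' Callers are expected to have already restricted `persons` to those
#' passing the definition's age restriction for year `Y`;
#' [sweep_lookbacks()] does this automatically.
#'
#' @param claims Claim table.
#' @param definition A [case_definition()].
#' @param spec A [window_spec()].
#' @param persons Persons to classify (character vector of ids or table
#'   with `person_id`).
#' @return A tibble with one row per person: `person_id`, `disease`,
#'   `estimation_year`, `k`, `is_prevalent`, `is_at_risk`, `is_incident`,
#'   `identification_date`.
#' @export
classify <- function(claims, definition, spec, persons) {
  classify_candidates(definition_candidates(claims, definition),
                      definition, spec, persons)
}

# classify() against precomputed completion candidates; lets window sweeps
# scan the claim stream once per definition instead of once per window.
classify_candidates <- function(candidates, definition, spec, persons) {
  stopifnot(inherits(spec, "lw_window_spec"))
  y <- spec$estimation_year
  k <- spec$lookback_years
  ids <- if (is.data.frame(persons)) persons$person_id else persons
  lw <- lookback_interval(spec)
  a_union <- ascertain_candidates(candidates, definition$disease_name,
                                  lw$start, year_start(y + 1L), ids)
  prior_prev <- if (lw$empty) {
    rep(FALSE, nrow(a_union))
  } else {
    ascertain_candidates(candidates, definition$disease_name,
                         lw$start, lw$end, ids)$identified
  }
  in_year <- !is.na(a_union$identification_date) &
    a_union$identification_date >= year_start(y)
  tibble(person_id = a_union$person_id,
         disease = definition$disease_name,
         estimation_year = y,
         k = k,
         is_prevalent = a_union$identified,
         is_at_risk = !prior_prev,
         is_incident = !prior_prev & in_year,
         identification_date = a_union$identification_date)
}

#' Aggregate classifications into prevalence and incidence estimates
#'
#' Prevalence is the proportion of the analysis population with a prevalent
#' case; incidence is the proportion of at-risk persons (those with no
#' prior prevalent case inside the lookback interval) with an incident
#' case.  A zero at-risk denominator yields an explicit undefined sentinel
#' (`incidence_pct = NA` with a reason in `flag`), never a silent zero.
#'
#' @param classifications Output of [classify()] (possibly several stacked
#'   windows/diseases).
#' @param cohort Cohort table carrying `person_id` and `population`.
#' @return A tibble with one row per (population, disease, estimation_year,
#'   k): counts `n_denominator`, `n_prevalent`, `n_at_risk`, `n_incident`,
#'   percentages `prevalence_pct`, `incidence_pct`, and `flag`.
#' @export
compute_estimates <- function(classifications, cohort) {
  if (!nrow(classifications)) {
    stop("no classifications supplied: prevalence denominator is zero",
         call. = FALSE)
  }
  d <- dplyr::inner_join(classifications,
                         dplyr::distinct(cohort[, c("person_id",
                                                    "population")]),
                         by = "person_id")
  if (nrow(d) != nrow(classifications)) {
    stop("some classified persons are missing from the cohort table",
         call. = FALSE)
  }
  d |>
    dplyr::group_by(.data$population, .data$disease, .data$estimation_year,
                    .data$k) |>
    dplyr::summarise(
      n_denominator = dplyr::n(),
      n_prevalent = sum(.data$is_prevalent),
      n_at_risk = sum(.data$is_at_risk),
      n_incident = sum(.data$is_incident),
      .groups = "drop") |>
    dplyr::mutate(
      prevalence_pct = 100 * .data$n_prevalent / .data$n_denominator,
      incidence_pct = ifelse(.data$n_at_risk > 0,
                             100 * .data$n_incident / .data$n_at_risk,
                             NA_real_),
      flag = ifelse(.data$n_at_risk > 0, NA_character_,
                    "incidence_undefined_zero_at_risk")) |>
    dplyr::arrange(.data$population, .data$disease, .data$estimation_year,
                   .data$k)
}

#' Proportion of reference-standard prevalent cases missed by a shorter
#' window
#'
#' Computed on person sets, never on count differences:
#' `|Prev_ref \ Prev_k| / |Prev_ref|`.
#'
#' @param classifications_k Classifications under the shorter window.
#' @param classifications_ref Classifications under the reference window
#'   (same persons, disease and estimation year).
#' @return A list: `proportion` (`NA` when undefined), `numerator`,
#'   `denominator`, `flag`.
#' @export
misclassified_prevalent <- function(classifications_k,
                                    classifications_ref) {
  check_misclass_inputs(classifications_k, classifications_ref)
  prev_ref <- classifications_ref$person_id[classifications_ref$is_prevalent]
  prev_k <- classifications_k$person_id[classifications_k$is_prevalent]
  if (!length(prev_ref)) {
    return(list(proportion = NA_real_, numerator = NA_integer_,
                denominator = 0L,
                flag = "undefined_zero_reference_prevalent"))
  }
  missed <- setdiff(prev_ref, prev_k)
  list(proportion = length(missed) / length(prev_ref),
       numerator = length(missed), denominator = length(prev_ref),
       flag = NA_character_)
}

#' Proportion of shorter-window incident cases that are prevalent under the
#' reference standard
#'
#' `|{p in Inc_k : p has a prior prevalent case under ref}| / |Inc_k|`,
#' computed on person sets.
#'
#' @inheritParams misclassified_prevalent
#' @return A list: `proportion` (`NA` when undefined), `numerator`,
#'   `denominator`, `flag`.
#' @export
misclassified_incident <- function(classifications_k,
                                   classifications_ref) {
  check_misclass_inputs(classifications_k, classifications_ref)
  inc_k <- classifications_k$person_id[classifications_k$is_incident]
  prior_ref <- classifications_ref$person_id[!classifications_ref$is_at_risk]
  if (!length(inc_k)) {
    return(list(proportion = NA_real_, numerator = NA_integer_,
                denominator = 0L, flag = "undefined_zero_incident"))
  }
  hit <- intersect(inc_k, prior_ref)
  list(proportion = length(hit) / length(inc_k),
       numerator = length(hit), denominator = length(inc_k),
       flag = NA_character_)
}

check_misclass_inputs <- function(ck, cref) {
  stopifnot(all(c("person_id", "is_prevalent", "is_at_risk",
                  "is_incident") %in% names(ck)),
            all(c("person_id", "is_prevalent", "is_at_risk",
                  "is_incident") %in% names(cref)))
  if (nrow(ck) && nrow(cref)) {
    if (!setequal(ck$person_id, cref$person_id)) {
      stop("short-window and reference classifications cover different ",
           "persons", call. = FALSE)
    }
    ks <- unique(ck$k)
    if (length(ks) == 1L && length(unique(cref$k)) == 1L &&
        ks > unique(cref$k)) {
      stop("short-window k exceeds the reference k", call. = FALSE)
    }
  }
  invisible(TRUE)
}

restrict_age <- function(cohort, definition, estimation_year) {
  if (is.null(definition$min_age_years)) return(cohort)
  cohort[(estimation_year - cohort$birth_year) > definition$min_age_years, ,
         drop = FALSE]
}

#' Sweep lookback windows for one estimation year
#'
#' For every disease definition and every lookback length in `k_list`,
#' classifies the (age-restricted) cohort, aggregates prevalence and
#' incidence estimates per population, and computes both misclassification
#' proportions against the reference window `ref_k`.  Estimates themselves
#' are reference-free; only the misclassification table depends on `ref_k`.
#'
#' @param claims Claim table.
#' @param cohort Cohort table from [match_controls()] (needs `person_id`,
#'   `birth_year`, `population`).
#' @param definitions List of [case_definition()] objects.
#' @param estimation_year Calendar year the estimates refer to.
#' @param ref_k Reference-standard lookback length; must be in `k_list`.
#' @param k_list Integer vector of lookback lengths, all
#'   `<= max_lookback(estimation_year, data_start_year)`.
#' @param data_start_year Earliest calendar year with data.
#' @param keep_classifications Also return the per-person classifications
#'   (a nested list by disease, then `k`); useful for set-level checks.
#' @return A list with tibbles `estimates` and `misclassification`
#'   (columns `population`, `disease`, `estimation_year`, `k`, `ref_k`,
#'   `prop_misclassified_prevalent`, `prop_misclassified_incident`,
#'   `flag_prevalent`, `flag_incident`), plus `classifications` when
#'   requested.
#' @export
sweep_lookbacks <- function(claims, cohort, definitions, estimation_year,
                            ref_k = 16L, k_list = 0:16,
                            data_start_year = 1996L,
                            keep_classifications = FALSE) {
  if (inherits(definitions, "lw_case_definition")) {
    definitions <- list(definitions)
  }
  k_max <- max_lookback(estimation_year, data_start_year)
  if (any(k_list > k_max)) {
    stop(sprintf("k_list contains lookbacks beyond the maximum %d for %d",
                 k_max, estimation_year), call. = FALSE)
  }
  if (!ref_k %in% k_list) {
    stop("ref_k must be an element of k_list", call. = FALSE)
  }
  k_list <- sort(unique(as.integer(k_list)))
  est <- list()
  mis <- list()
  cls_all <- list()
  for (def in definitions) {
    dn <- def$disease_name
    pop <- restrict_age(cohort, def, estimation_year)
    if (!nrow(pop)) {
      warning("no persons pass the age restriction for ", dn)
      next
    }
    cands <- definition_candidates(claims, def)
    cls <- lapply(k_list, function(k) {
      classify_candidates(cands, def,
                          window_spec(estimation_year, k, data_start_year),
                          pop)
    })
    names(cls) <- as.character(k_list)
    est[[dn]] <- dplyr::bind_rows(lapply(cls, compute_estimates,
                                         cohort = pop))
    ref_cls <- cls[[as.character(ref_k)]]
    pops <- sort(unique(pop$population))
    mis[[dn]] <- dplyr::bind_rows(lapply(pops, function(pl) {
      ids <- pop$person_id[pop$population == pl]
      cref <- ref_cls[ref_cls$person_id %in% ids, , drop = FALSE]
      dplyr::bind_rows(lapply(k_list, function(k) {
        ck <- cls[[as.character(k)]]
        ck <- ck[ck$person_id %in% ids, , drop = FALSE]
        if (k > ref_k) {
          # misclassification is defined against windows at least as long
          # as the one under evaluation
          na <- list(proportion = NA_real_,
                     flag = "not_applicable_k_exceeds_ref")
          mp <- na
          mi <- na
        } else {
          mp <- misclassified_prevalent(ck, cref)
          mi <- misclassified_incident(ck, cref)
        }
        tibble(population = pl, disease = dn,
               estimation_year = as.integer(estimation_year),
               k = k, ref_k = as.integer(ref_k),
               prop_misclassified_prevalent = mp$proportion,
               prop_misclassified_incident = mi$proportion,
               flag_prevalent = mp$flag, flag_incident = mi$flag)
      }))
    }))
    if (keep_classifications) cls_all[[dn]] <- cls
  }
  out <- list(estimates = dplyr::bind_rows(est),
              misclassification = dplyr::bind_rows(mis))
  if (keep_classifications) out$classifications <- cls_all
  out
}

#' Annual prevalence and incidence trends under varying lookbacks
#'
#' Repeats the estimation for each requested year, re-evaluating presence
#' (at least one day of registration in the year) and age restrictions per
#' year.  Because the earliest data year caps the feasible lookback, any
#' requested `k` above `max_lookback(Y, data_start_year)` is skipped for
#' that year with a logged warning.
#'
#' @param claims Claim table.
#' @param cohort Cohort table (all years draw on the same matched cohort).
#' @param definitions List of [case_definition()] objects.
#' @param years Integer vector of estimation years.
#' @param k_list Integer vector of requested lookback lengths.
#' @param data_start_year Earliest calendar year with data.
#' @return An estimates tibble as in [compute_estimates()], keyed by
#'   (population, disease, estimation_year, k).
#' @export
annual_trends <- function(claims, cohort, definitions, years,
                          k_list = 0:16, data_start_year = 1996L) {
  if (!length(years)) stop("years must be non-empty", call. = FALSE)
  if (inherits(definitions, "lw_case_definition")) {
    definitions <- list(definitions)
  }
  rows <- list()
  cands_by_def <- lapply(definitions, definition_candidates,
                         claims = claims)
  for (y in sort(unique(as.integer(years)))) {
    k_max <- max_lookback(y, data_start_year)
    ks <- sort(unique(as.integer(k_list[k_list <= k_max])))
    skipped <- setdiff(k_list, ks)
    if (length(skipped)) {
      warning(sprintf("year %d: skipping lookbacks beyond %d years (%s)",
                      y, k_max, paste(sort(skipped), collapse = ", ")),
              call. = FALSE)
    }
    present <- cohort[cohort$registration_start <= year_end(y) &
                        cohort$registration_end >= year_start(y), ,
                      drop = FALSE]
    if (!nrow(present)) next
    for (di in seq_along(definitions)) {
      def <- definitions[[di]]
      pop <- restrict_age(present, def, y)
      if (!nrow(pop)) next
      cands <- cands_by_def[[di]]
      for (k in ks) {
        cl <- classify_candidates(cands, def,
                                  window_spec(y, k, data_start_year), pop)
        rows[[length(rows) + 1L]] <- compute_estimates(cl, pop)
      }
    }
  }
  dplyr::bind_rows(rows)
}
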