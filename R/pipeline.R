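#' Assemble and validate a pipeline run configuration
#'
#' Collects everything a full run needs: generator settings, matching
#' ratio, estimation year, lookback list and reference, and the output
#' directory.  Validation (in particular `ref_k %in% k_list`) happens here,
#' before any computation.
#'
#' @param seed Master integer seed for every stochastic stage.
#' @param output_dir Directory for all output files.
#' @param n_index Number of index persons to simulate.
#' @param control_pool_multiplier Control pool size per index person.
#'   Exact matching needs headroom in every birth-year/sex stratum; a
#'   multiplier of several times the match ratio is advisable for small
#'   cohorts.
#' @param match_ratio Controls matched per index person.
#' @param birth_year_range,sex_distribution Population shape passed to
#'   [population_config()].
#' @param estimation_year Year the main estimates refer to.
#' @param data_start_year,data_end_year Data period bounds.
#' @param burn_in_year First year of disease-onset exposure; earlier than
#'   `data_start_year` to create left-truncated (pre-data) onsets.
#' @param ref_k Reference-standard lookback length.
#' @param k_list Lookback lengths to sweep.
#' @param trend_years Years for the annual-trend sub-analysis, or `NULL`
#'   to skip it.
#' @param dropout_rate Per-year registration dropout hazard.
#' @param definitions Named list of [case_definition()] objects or a path
#'   to a YAML file readable by [read_case_definitions()].
#' @param disease_models Named list of [disease_model()] objects.
#' @return A validated list of class `lw_run_config`.
#' @export
run_config <- function(seed = 1L,
                       output_dir = tempfile("lookback-run-"),
                       n_index = 500L,
                       control_pool_multiplier = 10L,
                       match_ratio = 5L,
                       birth_year_range = c(1932L, 1992L),
                       sex_distribution = 0.82,
                       estimation_year = 2012L,
                       data_start_year = 1996L,
                       data_end_year = 2012L,
                       burn_in_year = 1986L,
                       ref_k = 16L,
                       k_list = 0:16,
                       trend_years = NULL,
                       dropout_rate = 0,
                       definitions = default_case_definitions(),
                       disease_models = default_disease_models()) {
  if (is.character(definitions)) {
    if (!file.exists(definitions)) {
      stop("definitions file does not exist: ", definitions, call. = FALSE)
    }
    definitions <- read_case_definitions(definitions)
  }
  k_max <- max_lookback(estimation_year, data_start_year)
  if (any(k_list > k_max)) {
    stop(sprintf("k_list exceeds the maximum lookback of %d for %d",
                 k_max, estimation_year), call. = FALSE)
  }
  if (!ref_k %in% k_list) {
    stop("ref_k must be an element of k_list", call. = FALSE)
  }
  if (!all(names(disease_models) %in% names(definitions))) {
    stop("every simulated disease needs a case definition", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), output_dir = output_dir,
         n_index = as.integer(n_index),
         control_pool_multiplier = as.integer(control_pool_multiplier),
         match_ratio = as.integer(match_ratio),
         birth_year_range = as.integer(birth_year_range),
         sex_distribution = sex_distribution,
         estimation_year = as.integer(estimation_year),
         data_start_year = as.integer(data_start_year),
         data_end_year = as.integer(data_end_year),
         burn_in_year = as.integer(burn_in_year),
         ref_k = as.integer(ref_k), k_list = as.integer(k_list),
         trend_years = if (is.null(trend_years)) NULL
                       else as.integer(trend_years),
         dropout_rate = dropout_rate,
         definitions = definitions, disease_models = disease_models),
    class = "lw_run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Scalar fields override the [run_config()] defaults; a `definitions`
#' entry may point to a case-definition YAML file (relative paths resolve
#' against the config file's directory).
#'
#' @param path Path to the YAML config.
#' @return A validated `lw_run_config`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$definitions) && is.character(raw$definitions) &&
      !file.exists(raw$definitions)) {
    raw$definitions <- file.path(dirname(path), raw$definitions)
  }
  do.call(run_config, raw)
}

config_hash <- function(config) {
  plain <- config
  plain$definitions <- lapply(plain$definitions, unclass)
  plain$disease_models <- lapply(plain$disease_models, unclass)
  txt <- paste(deparse(plain), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full lookback-window analysis pipeline
#'
#' Executes simulate -> cohort -> ascertain -> sweep (-> trends) and writes
#' all outputs into `config$output_dir`: `persons.csv`, `onsets.csv`,
#' `claims.csv`, `cohort.csv`, `cases.csv`, `estimates.csv`,
#' `misclassification.csv`, optionally `trends.csv`, and a `manifest.json`
#' recording the seed, a config hash and per-file row counts.  Percentages
#' in the output tables are rounded to one decimal place; the returned
#' in-memory tables keep full precision.  The run is idempotent: identical
#' config and seed reproduce identical files.
#'
#' @param config An [run_config()] object (or a path to a YAML config).
#' @return Invisibly, a list with the in-memory tables (`persons`,
#'   `onsets`, `claims`, `cohort`, `cases`, `estimates`,
#'   `misclassification`, `trends`), the `manifest`, and `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "lw_run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    log_stage(name, "starting")
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  pc <- population_config(
    n_index = config$n_index,
    control_pool_multiplier = config$control_pool_multiplier,
    birth_year_range = config$birth_year_range,
    sex_distribution = config$sex_distribution,
    data_start_year = config$data_start_year,
    data_end_year = config$data_end_year,
    dropout_rate = config$dropout_rate)

  sim <- stage("simulate", {
    persons <- generate_population(pc, config$seed)
    onsets <- simulate_disease_histories(persons, config$disease_models,
                                         config$seed,
                                         burn_in_year = config$burn_in_year)
    claims <- simulate_claims(persons, onsets, config$disease_models,
                              config$seed)
    log_stage("simulate", "%d persons, %d onsets, %d claims",
              nrow(persons), nrow(onsets), nrow(claims))
    list(persons = persons, onsets = onsets, claims = claims)
  })

  cohort <- stage("cohort", {
    crit <- eligibility_criteria(
      estimation_year = config$estimation_year,
      require_registered_since = config$data_start_year)
    eligible <- filter_eligible(sim$persons, crit)
    matched <- match_controls(
      eligible[eligible$population == "index", , drop = FALSE],
      eligible[eligible$population == "control", , drop = FALSE],
      match_spec(ratio = config$match_ratio, seed = config$seed))
    log_stage("cohort", "%d index + %d controls",
              sum(matched$role == "index"), sum(matched$role == "control"))
    matched
  })

  cases <- stage("ascertain", {
    ref_start <- year_start(config$estimation_year - config$ref_k)
    ref_end <- year_start(config$estimation_year + 1L)
    out <- dplyr::bind_rows(lapply(config$definitions, function(def) {
      a <- ascertain(sim$claims, def, ref_start, ref_end,
                     restrict_age(cohort, def, config$estimation_year))
      a[a$identified, c("person_id", "disease_name",
                        "identification_date")]
    }))
    names(out)[names(out) == "disease_name"] <- "disease"
    out
  })

  sweep <- stage("sweep", {
    sweep_lookbacks(sim$claims, cohort, config$definitions,
                    config$estimation_year, ref_k = config$ref_k,
                    k_list = config$k_list,
                    data_start_year = config$data_start_year)
  })

  trends <- if (!is.null(config$trend_years)) {
    stage("trends", {
      annual_trends(sim$claims, cohort, config$definitions,
                    config$trend_years, k_list = config$k_list,
                    data_start_year = config$data_start_year)
    })
  } else NULL

  paths <- stage("write", {
    p <- write_synthetic_tables(sim$persons, sim$onsets, sim$claims,
                                config$output_dir)
    p[["cohort"]] <- file.path(config$output_dir, "cohort.csv")
    readr::write_csv(cohort, p[["cohort"]])
    p[["cases"]] <- file.path(config$output_dir, "cases.csv")
    readr::write_csv(cases, p[["cases"]])
    est_out <- sweep$estimates
    est_out$prevalence_pct <- round(est_out$prevalence_pct, 1)
    est_out$incidence_pct <- round(est_out$incidence_pct, 1)
    p[["estimates"]] <- file.path(config$output_dir, "estimates.csv")
    readr::write_csv(est_out, p[["estimates"]])
    p[["misclassification"]] <- file.path(config$output_dir,
                                          "misclassification.csv")
    readr::write_csv(sweep$misclassification, p[["misclassification"]])
    if (!is.null(trends)) {
      tr_out <- trends
      tr_out$prevalence_pct <- round(tr_out$prevalence_pct, 1)
      tr_out$incidence_pct <- round(tr_out$incidence_pct, 1)
      p[["trends"]] <- file.path(config$output_dir, "trends.csv")
      readr::write_csv(tr_out, p[["trends"]])
    }
    p
  })

  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    estimation_year = config$estimation_year,
    ref_k = config$ref_k,
    files = lapply(paths, function(f) {
      list(path = basename(f),
           rows = length(readr::read_lines(f)) - 1L)
    })
  )
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  paths[["manifest"]] <- manifest_path
  log_stage("done", "outputs in %s", config$output_dir)

  invisible(list(persons = sim$persons, onsets = sim$onsets,
                 claims = sim$claims, cohort = cohort, cases = cases,
                 estimates = sweep$estimates,
                 misclassification = sweep$misclassification,
                 trends = trends, manifest = manifest, paths = paths))
}

#' Threshold band of a misclassification proportion
#'
#' @param p Numeric vector of proportions in `[0, 1]` (`NA` allowed).
#' @param thresholds Increasing band edges as proportions.
#' @return Character vector of band labels such as `"<10%"`, `"<20%"`,
#'   `"<30%"`, `">=30%"`.
#' @export
#' @examples
#' misclass_band(c(0.08, 0.15, 0.45))
misclass_band <- function(p, thresholds = c(0.10, 0.20, 0.30)) {
  thresholds <- sort(thresholds)
  labels <- c(sprintf("<%g%%", 100 * thresholds),
              sprintf(">=%g%%", 100 * max(thresholds)))
  idx <- findInterval(p, thresholds, left.open = FALSE,
                      rightmost.closed = FALSE) + 1L
  out <- labels[idx]
  out[is.na(p)] <- NA_character_
  out
}

#' Render a misclassification grid in publication layout
#'
#' Produces a wide table (rows: population x disease; columns: lookback
#' lengths) with each cell carrying the misclassification percentage and
#' its threshold band, the reference column marked `"Ref"`, and undefined
#' cells left missing.
#'
#' @param misclass Misclassification tibble from [sweep_lookbacks()].
#' @param measure `"prevalent"` or `"incident"`.
#' @param thresholds Band edges as proportions.
#' @return A wide tibble with columns `population`, `disease`, and one
#'   `lw_<k>` column per lookback length.
#' @export
render_misclass_table <- function(misclass,
                                  measure = c("prevalent", "incident"),
                                  thresholds = c(0.10, 0.20, 0.30)) {
  measure <- match.arg(measure)
  if (!nrow(misclass)) stop("misclassification table is empty",
                            call. = FALSE)
  pcol <- paste0("prop_misclassified_", measure)
  fcol <- paste0("flag_", measure)
  d <- misclass
  d$cell <- ifelse(
    !is.na(d[[fcol]]), NA_character_,
    ifelse(d$k == d$ref_k,
           sprintf("%.1f [Ref]", 100 * d[[pcol]]),
           sprintf("%.1f [%s]", 100 * d[[pcol]],
                   misclass_band(d[[pcol]], thresholds))))
  d[, c("population", "disease", "k", "cell")] |>
    tidyr::pivot_wider(names_from = "k", values_from = "cell",
                       names_prefix = "lw_") |>
    dplyr::arrange(.data$population, .data$disease)
}

#' Plot prevalence or incidence against lookback length
#'
#' @param estimates Estimates tibble from [sweep_lookbacks()].
#' @param measure `"prevalence"` or `"incidence"`.
#' @return A ggplot object, faceted by disease with one line per
#'   population.
#' @export
plot_estimates <- function(estimates,
                           measure = c("prevalence", "incidence")) {
  measure <- match.arg(measure)
  ycol <- paste0(measure, "_pct")
  ggplot2::ggplot(estimates,
                  ggplot2::aes(x = .data$k, y = .data[[ycol]],
                               colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~disease, scales = "free_y") +
    ggplot2::labs(x = "Lookback window (years)",
                  y = sprintf("%s (%%)", title_case(measure)),
                  colour = "Population") +
    ggplot2::theme_minimal()
}

#' Plot annual trends for selected lookback lengths
#'
#' @param trends Estimates tibble from [annual_trends()].
#' @param measure `"prevalence"` or `"incidence"`.
#' @param k_show Lookback lengths to draw (default: all present).
#' @return A ggplot object, faceted by disease, lines by lookback length.
#' @export
plot_annual_trends <- function(trends,
                               measure = c("prevalence", "incidence"),
                               k_show = NULL) {
  measure <- match.arg(measure)
  ycol <- paste0(measure, "_pct")
  d <- trends
  if (!is.null(k_show)) d <- d[d$k %in% k_show, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimation_year,
                                  y = .data[[ycol]],
                                  colour = factor(.data$k),
                                  linetype = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~disease, scales = "free_y") +
    ggplot2::labs(x = "Year", y = sprintf("%s (%%)",
                                          title_case(measure)),
                  colour = "Lookback (years)",
                  linetype = "Population") +
    ggplot2::theme_minimal()
}
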