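#' Pipeline configuration
#'
#' Assembles every tunable of the end-to-end analysis in one structured list:
#' the synthetic-cohort generator (or paths to real input tables), the MAP
#' prior, the therapeutic range, the outlier rule and the composite-measure
#' convention. All defaults are materialised into the emitted `report.json`
#' so a report is fully self-describing.
#'
#' @param seed Integer seed driving the whole run. Default 1.
#' @param generator [cohort_config()] for synthetic input. Ignored when
#'   `visits_path` is given.
#' @param visits_path,demographics_path Optional paths to real input tables;
#'   when supplied the generator is bypassed (and no recovery scoring is
#'   possible).
#' @param prior [population_prior()] for MAP fitting.
#' @param m PD slope constant. Default 1.
#' @param inr_range Therapeutic range for TTR. Default c(2, 3).
#' @param max_gap Rosendaal gap limit, days. Default 56.
#' @param z,sided Outlier rule (see [classify_outliers()]). Defaults 1.96,
#'   two-sided for every parameter.
#' @param wcm_convention See [wcm()].
#' @param outlier_parameters Which fitted parameters to classify.
#' @param age_breaks Interior cut points for the age-stratified parameter
#'   summary (see [age_groups()]). Default c(65, 75, 85).
#'
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            generator = cohort_config(),
                            visits_path = NULL, demographics_path = NULL,
                            prior = population_prior(), m = 1,
                            inr_range = c(2, 3), max_gap = 56,
                            z = 1.96, sided = "two",
                            wcm_convention = "higher_worse",
                            outlier_parameters = c("c_max", "k", "cl", "v_d"),
                            age_breaks = c(65, 75, 85)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads a structured config file and merges it over [pipeline_config()]
#' defaults. Recognised top-level keys mirror the `pipeline_config()`
#' arguments; `generator` and `prior` sub-blocks are passed to
#' [cohort_config()] and [population_prior()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw
  if (!is.null(raw$generator)) {
    gen <- raw$generator
    if (!is.null(gen$pk)) gen$pk <- lapply(gen$pk, as.numeric)
    args$generator <- do.call(cohort_config, gen)
  }
  if (!is.null(raw$prior)) {
    args$prior <- do.call(population_prior, lapply(raw$prior, as.numeric))
  }
  do.call(pipeline_config, args)
}

#' Run the full cohort analysis
#'
#' End-to-end driver: obtain the cohort (simulate with the configured seed,
#' or read the configured input tables), MAP-fit every patient, compute the
#' anticoagulation quality indices, summarise the cohort, classify each PK
#' parameter's normal-curve outliers, compare the within/outside groups on
#' demographics and quality indices, and correlate the PK parameters with
#' each other and with predicted liver weight. Deterministic given the seed;
#' any stage failure aborts with a stage-tagged error.
#'
#' @param config [pipeline_config()] or a path readable by [load_config()].
#' @param out_dir If non-`NULL`, the report bundle is written there:
#'   `summary.tsv`, `outliers_<param>.tsv`, `comparisons.tsv`,
#'   `correlations.tsv`, `parameters.tsv`, `indices.tsv`, the cohort tables,
#'   and a machine-readable `report.json` echoing the full configuration.
#'
#' @return An object of class `warfinr_report`: a list with the cohort, the
#'   fitted-parameter table, the index table, the summary, the per-parameter
#'   outlier objects, the comparison and correlation tables, and the
#'   recovery score (synthetic input only).
#' @export
#'
#' @examples
#' \donttest{
#' report <- run_pipeline(pipeline_config(generator = cohort_config(n_patients = 20)))
#' report$summary
#' }
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("[%s] %s", name, conditionMessage(e)),
            class = "warfinr_pipeline_error", parent = e)
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(config$visits_path)) {
      read_cohort(config$visits_path, config$demographics_path)
    } else {
      if (config$generator$n_patients < 1) {
        abort("Generator configured with an empty cohort.")
      }
      simulate_cohort(config$generator, seed = config$seed)
    }
  })

  fits <- stage("fit", fit_cohort(cohort$visits, prior = config$prior, m = config$m))
  ok_fits <- fits[fits$converged, , drop = FALSE]

  indices <- stage("metrics", anticoag_indices(
    cohort$visits, cohort$demographics,
    low = config$inr_range[1], high = config$inr_range[2],
    max_gap = config$max_gap, wcm_convention = config$wcm_convention))

  summary_tbl <- stage("summary", {
    dplyr::bind_rows(
      summarise_block(ok_fits, c("c_max", "k", "cl", "v_d"), "pk_parameter"),
      summarise_block(indices, c("wsi", "ttr", "log_inr_var", "wcm", "liver_weight"),
                      "pd_index"))
  })

  outliers <- stage("outliers", {
    setNames(lapply(config$outlier_parameters, function(p) {
      classify_outliers(ok_fits[[p]], z = config$z, sided = config$sided,
                        parameter = p)
    }), config$outlier_parameters)
  })

  comparisons <- stage("comparisons", {
    purrr::map_dfr(config$outlier_parameters, function(p) {
      grp <- tibble::tibble(patient_id = ok_fits$patient_id,
                            outlier_group = outliers[[p]]$flag)
      if (min(table(grp$outlier_group)) < 2 || length(unique(grp$outlier_group)) < 2) {
        warn(sprintf("Too few patients outside the %s band to compare groups; skipped.", p))
        return(NULL)
      }
      tab <- dplyr::inner_join(grp, indices, by = "patient_id")
      res <- compare_groups(tab, "outlier_group",
                            numeric_vars = c("age_years", "body_weight_kg", "ttr",
                                             "wsi", "log_inr_var", "wcm"),
                            categorical_vars = "interacting_drug")
      dplyr::mutate(res, parameter = p, .before = 1)
    })
  })

  corr_tbl <- stage("correlations", {
    tab <- dplyr::inner_join(ok_fits,
                             indices[c("patient_id", "liver_weight")],
                             by = "patient_id")
    correlations(tab)
  })

  age_strata <- stage("age_strata", {
    tab <- dplyr::inner_join(ok_fits, cohort$demographics, by = "patient_id")
    tab$age_group <- age_groups(tab$age_years, breaks = config$age_breaks)
    strata <- tab |>
      tidyr::pivot_longer(dplyr::all_of(c("c_max", "k", "cl", "v_d")),
                          names_to = "parameter", values_to = "value") |>
      dplyr::group_by(.data$parameter, .data$age_group, .drop = FALSE) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                       sd = sd(.data$value), .groups = "drop")
    kw <- purrr::map_dfr(c("c_max", "k", "cl", "v_d"), function(p) {
      groups <- droplevels(tab$age_group)
      p_val <- if (nlevels(groups) > 1) {
        stats::kruskal.test(tab[[p]], groups)$p.value
      } else NA_real_
      tibble::tibble(parameter = p, kruskal_p = p_val)
    })
    dplyr::left_join(strata, kw, by = "parameter")
  })

  recovery <- NULL
  if (!is.null(cohort$truth)) {
    pop <- vapply(config$generator$pk, `[`, numeric(1), 1)
    recovery <- stage("recovery", score_recovery(cohort$truth, fits, pop_means = pop))
  }

  report <- structure(list(
    config = config, cohort = cohort, parameters = fits, indices = indices,
    summary = summary_tbl, outliers = outliers, comparisons = comparisons,
    correlations = corr_tbl, age_strata = age_strata, recovery = recovery
  ), class = "warfinr_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

summarise_block <- function(tbl, vars, kind) {
  purrr::map_dfr(vars, function(v) {
    x <- tbl[[v]][is.finite(tbl[[v]])]
    tibble::tibble(kind = kind, variable = v, n = length(x),
                   mean = mean(x), sd = sd(x))
  })
}

#' @export
print.warfinr_report <- function(x, ...) {
  cat(sprintf("<warfinr_report> %d patients (%d converged fits)\n",
              nrow(x$cohort$demographics), sum(x$parameters$converged)))
  cat("Parameter and index summary:\n")
  print(as.data.frame(x$summary), digits = 4)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' @param report A `warfinr_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(report$cohort, out_dir)
  readr::write_tsv(report$parameters, file.path(out_dir, "parameters.tsv"))
  readr::write_tsv(report$indices, file.path(out_dir, "indices.tsv"))
  readr::write_tsv(report$summary, file.path(out_dir, "summary.tsv"))
  for (p in names(report$outliers)) {
    readr::write_tsv(tidy(report$outliers[[p]]),
                     file.path(out_dir, sprintf("outliers_%s.tsv", p)))
  }
  readr::write_tsv(report$comparisons, file.path(out_dir, "comparisons.tsv"))
  readr::write_tsv(report$correlations, file.path(out_dir, "correlations.tsv"))
  readr::write_tsv(report$age_strata, file.path(out_dir, "age_strata.tsv"))
  json <- list(
    config = config_as_list(report$config),
    summary = report$summary,
    outliers = lapply(report$outliers, glance),
    comparisons = report$comparisons,
    correlations = report$correlations,
    age_strata = report$age_strata,
    recovery = report$recovery
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

config_as_list <- function(config) {
  strip <- function(x) {
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(config)
}
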