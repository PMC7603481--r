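#' Read a resighting table from CSV
#'
#' Expects the header `individual_id,year,colony,patch_id`, one row per
#' confirmed-breeding observation. Rows with a malformed year or an empty
#' individual id raise a parse error naming the offending line. Under the
#' strict rule (default) an individual recorded in two patches in one year
#' is a data error; `strict = FALSE` keeps the first record with a
#' warning.
#'
#' @param path CSV file path.
#' @param strict Duplicate-handling rule (see [build_sociomatrix()]).
#' @param quiet Suppress the row/individual count message.
#' @return A validated resighting tibble.
#' @export
read_resightings <- function(path, strict = TRUE, quiet = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    individual_id = readr::col_character(),
    year = readr::col_character(),
    colony = readr::col_character(),
    patch_id = readr::col_character()
  ))
  needed <- c("individual_id", "year", "colony", "patch_id")
  if (!identical(names(raw)[seq_along(needed)], needed)) {
    abort(sprintf("header must be %s", paste(needed, collapse = ",")))
  }
  bad_year <- which(is.na(suppressWarnings(as.integer(raw$year))))
  if (length(bad_year) > 0L) {
    abort(sprintf("malformed year at data line %d: '%s'",
                  bad_year[1L], raw$year[bad_year[1L]]))
  }
  bad_id <- which(is.na(raw$individual_id) | raw$individual_id == "")
  if (length(bad_id) > 0L) {
    abort(sprintf("empty individual_id at data line %d", bad_id[1L]))
  }
  raw$year <- as.integer(raw$year)
  out <- validate_resightings(raw, strict = strict)
  if (nrow(out) == 0L) warn("resighting file contains no data rows")
  if (!quiet) {
    inform(sprintf("read %d resightings of %d individuals (%d kept after validation)",
                   nrow(raw), dplyr::n_distinct(out$individual_id), nrow(out)))
  }
  out
}

#' Write a resighting table as CSV
#'
#' @param records Resighting tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_resightings <- function(records, path) {
  readr::write_csv(
    records %>% select("individual_id", "year", "colony", "patch_id"),
    path)
  invisible(path)
}

#' Analysis configuration for the two-phase study driver
#'
#' @param simulation A [sim_config()], or `NULL` when `input_path` is
#'   given.
#' @param input_path Path to a resighting CSV, or `NULL` to simulate.
#' @param stable_period List of two year vectors: the predictor and
#'   outcome sub-periods of the stable phase (defaults 2002-2006 and
#'   2007-2011).
#' @param collapse_period List of two year vectors for the
#'   transition-to-collapse phase (defaults 2007-2011 predictor,
#'   2012-2017 outcome).
#' @param mcmc An [mcmc_config()].
#' @param n_perm Permutations per phase (0 skips the permutation stage).
#' @param perm_stat Statistic for the permutation test (see
#'   [permutation_test()]).
#' @param n_subsample_draws Draws for the power-matched subsampling of the
#'   stable phase.
#' @param alpha Significance level used throughout.
#' @param seed Master seed for the analysis stages.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(simulation = sim_config(years = 2002:2017,
                                                    perturbation_start = 2012),
                            input_path = NULL,
                            stable_period = list(2002:2006, 2007:2011),
                            collapse_period = list(2007:2011, 2012:2017),
                            mcmc = mcmc_config(),
                            n_perm = 200,
                            perm_stat = "chi_square",
                            n_subsample_draws = 1000,
                            alpha = 0.05,
                            seed = 1L) {
  if (is.null(input_path) == is.null(simulation)) {
    abort("exactly one of `input_path` and `simulation` must be supplied.")
  }
  check_phase <- function(p, nm) {
    if (!is.list(p) || length(p) != 2L) {
      abort(sprintf("`%s` must be a list of two year vectors.", nm))
    }
    if (length(intersect(p[[1]], p[[2]])) > 0L) {
      abort(sprintf("`%s` sub-periods must be disjoint.", nm))
    }
    if (max(p[[1]]) >= min(p[[2]])) {
      abort(sprintf("`%s` sub-periods must be ordered in time.", nm))
    }
  }
  check_phase(stable_period, "stable_period")
  check_phase(collapse_period, "collapse_period")
  structure(list(simulation = simulation, input_path = input_path,
                 stable_period = stable_period,
                 collapse_period = collapse_period,
                 mcmc = mcmc, n_perm = n_perm, perm_stat = perm_stat,
                 n_subsample_draws = n_subsample_draws,
                 alpha = alpha, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Run the full dyadic-persistence analysis for one phase
#'
#' Restricts the records to the individuals observed in at least one of
#' the two sub-periods (`individuals = "union"`, default) or in both
#' (`"intersection"`), builds the two sociomatrices over that common
#' ordering, and runs the three analyses: the 3 x 3 transition table with
#' its 2 x 2 chi-square, the probit network regression of the outcome
#' period on the predictor-period together indicator, and (when
#' `n_perm > 0`) the within-year permutation test.
#'
#' @param records Resighting tibble.
#' @param predictor_years,outcome_years Year vectors of the two
#'   sub-periods.
#' @param mcmc An [mcmc_config()].
#' @param n_perm Permutations (0 to skip).
#' @param perm_stat Statistic for [permutation_test()].
#' @param alpha Significance level.
#' @param individuals `"union"` or `"intersection"` rule for the common
#'   individual set.
#' @param seed Optional integer seed for the stochastic stages.
#' @param quiet Suppress progress messages.
#' @return An object of class `phase_report`: list with `sociomatrices`,
#'   `transition`, `chisq`, `ame`, `permutation` (or `NULL`), `counts`
#'   (the filtering funnel) and period metadata.
#' @export
run_phase_analysis <- function(records, predictor_years, outcome_years,
                               mcmc = mcmc_config(), n_perm = 200,
                               perm_stat = "chi_square", alpha = 0.05,
                               individuals = c("union", "intersection"),
                               seed = NULL, quiet = FALSE) {
  individuals <- match.arg(individuals)
  if (length(predictor_years) == 0L || length(outcome_years) == 0L) {
    abort("both sub-periods must be non-empty.")
  }
  records <- validate_resightings(records)
  if (!is.null(seed)) withr::local_seed(seed)

  seen1 <- unique(records$individual_id[records$year %in% predictor_years])
  seen2 <- unique(records$individual_id[records$year %in% outcome_years])
  if (length(seen1) == 0L || length(seen2) == 0L) {
    abort("insufficient data: a sub-period contains no resightings.")
  }
  common <- if (individuals == "union") union(seen1, seen2) else intersect(seen1, seen2)
  common <- sort(common)
  if (length(common) < 3L) {
    abort(sprintf("insufficient data: only %d individuals observed across the two sub-periods.",
                  length(common)))
  }
  say <- function(...) if (!quiet) inform(sprintf(...))
  say("phase %d-%d -> %d-%d: %d records, %d analysable individuals",
      min(predictor_years), max(predictor_years),
      min(outcome_years), max(outcome_years),
      sum(records$year %in% c(predictor_years, outcome_years)),
      length(common))

  s1 <- build_sociomatrix(records, predictor_years, individuals = common)
  s2 <- build_sociomatrix(records, outcome_years, individuals = common)
  trans <- build_transition_table(s1, s2)
  chisq <- chi_square_core(trans)
  say("  complete-case dyads: %d of %d; chi-square(1) = %.3f, P = %.4g",
      chisq$n_dyads_core, sum(trans$counts), chisq$statistic, chisq$p_value)
  fit <- suppressWarnings(fit_ame_probit(ame_data(s2, s1), mcmc))
  perm <- NULL
  if (n_perm > 0) {
    perm <- permutation_test(records, predictor_years, outcome_years,
                             stat = perm_stat, n_perm = n_perm,
                             level = alpha, mcmc = mcmc)
  } else {
    say("  permutation stage skipped (n_perm = 0)")
  }
  structure(list(
    predictor_years = predictor_years, outcome_years = outcome_years,
    sociomatrices = list(predictor = s1, outcome = s2),
    transition = trans, chisq = chisq, ame = fit, permutation = perm,
    counts = tibble::tibble(
      n_records = sum(records$year %in% c(predictor_years, outcome_years)),
      n_individuals = length(common),
      n_dyads = sum(trans$counts),
      n_dyads_core = chisq$n_dyads_core,
      n_together_outcome = sum(sociomatrix_upper(s2) == 1L, na.rm = TRUE))
  ), class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  cat(sprintf("<phase_report> predictor %d-%d, outcome %d-%d\n",
              min(x$predictor_years), max(x$predictor_years),
              min(x$outcome_years), max(x$outcome_years)))
  print(x$chisq)
  print(x$ame)
  if (!is.null(x$permutation)) print(x$permutation)
  invisible(x)
}

#' @rdname run_phase_analysis
#' @param x A `phase_report`.
#' @param ... Unused.
#' @export
tidy.phase_report <- function(x, ...) {
  tidy(x$ame) %>%
    mutate(predictor_years = paste(range(x$predictor_years), collapse = "-"),
           outcome_years = paste(range(x$outcome_years), collapse = "-"))
}

#' Run the full two-phase study
#'
#' Reproduces the study design end to end on one dataset (read from
#' `config$input_path` or simulated from `config$simulation`): the stable
#' phase (predictor sub-period vs outcome sub-period), the
#' transition-to-collapse phase, and the power-matched subsampling that
#' re-tests the stable phase at the collapse phase's complete-case dyad
#' count. Every stage's error is caught and reported with the stage name;
#' independent stages still complete.
#'
#' @param config An [analysis_config()].
#' @param output_dir Optional directory: writes `report.json`, per-phase
#'   edge lists (`edges_stable.csv`, `edges_collapse.csv`, from the
#'   half-weight index over each full phase) and a `manifest.json` with
#'   seeds and package version.
#' @param quiet Suppress progress messages.
#' @return An object of class `study_report`: list with `records`,
#'   `stable`, `collapse`, `subsample`, `errors` (named list of failed
#'   stages) and `config`.
#' @export
run_full_study <- function(config, output_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  records <- if (!is.null(config$input_path)) {
    read_resightings(config$input_path, quiet = quiet)
  } else {
    sim <- config$simulation
    if (is.null(sim$seed)) sim$seed <- config$seed
    simulate_colony(sim)$resightings
  }
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      if (!quiet) inform(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
      NULL
    })
  }
  stable <- stage("stable_phase", run_phase_analysis(
    records, config$stable_period[[1]], config$stable_period[[2]],
    mcmc = config$mcmc, n_perm = config$n_perm, perm_stat = config$perm_stat,
    alpha = config$alpha, seed = config$seed + 101L, quiet = quiet))
  collapse <- stage("collapse_phase", run_phase_analysis(
    records, config$collapse_period[[1]], config$collapse_period[[2]],
    mcmc = config$mcmc, n_perm = config$n_perm, perm_stat = config$perm_stat,
    alpha = config$alpha, seed = config$seed + 202L, quiet = quiet))
  subsample <- NULL
  if (!is.null(stable) && !is.null(collapse)) {
    subsample <- stage("power_matched_subsample", power_matched_subsample(
      stable$transition, n_target = collapse$chisq$n_dyads_core,
      n_draws = config$n_subsample_draws, alpha = config$alpha,
      seed = config$seed + 303L))
  }
  report <- structure(list(records = records, stable = stable,
                           collapse = collapse, subsample = subsample,
                           errors = errors, config = config),
                      class = "study_report")
  if (!is.null(output_dir)) write_study_report(report, output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Stable phase ==\n")
  if (!is.null(x$stable)) print(x$stable) else cat("  (failed)\n")
  cat("== Transition-to-collapse phase ==\n")
  if (!is.null(x$collapse)) print(x$collapse) else cat("  (failed)\n")
  if (!is.null(x$subsample)) {
    cat("== Power-matched subsampling of the stable phase ==\n")
    print(x$subsample)
  }
  if (length(x$errors) > 0) {
    cat(sprintf("failed stages: %s\n", paste(names(x$errors), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname run_full_study
#' @param x A `study_report`.
#' @param ... Unused.
#' @export
tidy.study_report <- function(x, ...) {
  out <- list()
  if (!is.null(x$stable)) out$stable <- tidy(x$stable) %>% mutate(phase = "stable")
  if (!is.null(x$collapse)) out$collapse <- tidy(x$collapse) %>% mutate(phase = "collapse")
  bind_rows(out) %>% select("phase", dplyr::everything())
}

study_report_list <- function(x) {
  phase_list <- function(p) {
    if (is.null(p)) return(NULL)
    list(
      predictor_years = range(p$predictor_years),
      outcome_years = range(p$outcome_years),
      counts = as.list(p$counts),
      transition_table = p$transition$counts,
      chi_square = list(statistic = p$chisq$statistic, df = p$chisq$df,
                        p_value = p$chisq$p_value,
                        n_dyads_core = p$chisq$n_dyads_core),
      ame = list(coefficients = p$ame$summaries,
                 imputation_rate = p$ame$imputation_rate,
                 n_draws = nrow(p$ame$draws)),
      permutation = if (!is.null(p$permutation)) {
        glance(p$permutation)
      }
    )
  }
  list(stable = phase_list(x$stable),
       collapse = phase_list(x$collapse),
       subsample = if (!is.null(x$subsample)) glance(x$subsample),
       errors = x$errors)
}

#' Write a study report to disk
#'
#' @param report A `study_report`.
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_study_report <- function(report, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(study_report_list(report),
                       file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (ph in c("stable", "collapse")) {
    p <- report[[ph]]
    if (is.null(p)) next
    hwi <- half_weight_index(report$records,
                             c(p$predictor_years, p$outcome_years))
    readr::write_csv(export_edges(hwi),
                     file.path(output_dir, sprintf("edges_%s.csv", ph)))
  }
  manifest <- list(
    package = "patchties",
    version = as.character(utils::packageVersion("patchties")),
    created = format(Sys.time(), tz = "UTC"),
    seed = report$config$seed,
    mcmc = report$config$mcmc[c("n_iter", "burn_in", "thin")],
    n_perm = report$config$n_perm,
    n_subsample_draws = report$config$n_subsample_draws)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}
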