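#' Permute individuals among patches within each year
#'
#' For each year independently, reassigns that year's observed individuals
#' to the year's patches uniformly at random while keeping the number of
#' individuals in every patch exactly as observed. Who is seen in which
#' year never changes; only the patch labels move. This is the null model
#' for "no preference for particular individuals": it preserves annual
#' gregariousness (patch sizes) and the observation pattern while
#' destroying any dyad-level preference.
#'
#' @param records Resighting tibble.
#' @param seed Optional integer seed.
#' @return A resighting tibble of the same dimensions with permuted
#'   `patch_id` within each year.
#' @examples
#' recs <- tibble::tibble(individual_id = letters[1:4], year = 2002,
#'                        colony = "SIM", patch_id = c("P1", "P1", "P2", "P2"))
#' sort(permute_within_year(recs, seed = 1)$patch_id)
#' @export
permute_within_year <- function(records, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  records %>%
    group_by(.data$year) %>%
    mutate(patch_id = sample(.data$patch_id)) %>%
    ungroup()
}

#' Permutation test of tie persistence against the patch-size null
#'
#' Computes a persistence statistic on the observed records -- either the
#' chi-square of the period-1 by period-2 dyad table
#' ([chi_square_core()]) or the posterior-mean dyadic regression
#' coefficient from [fit_ame_probit()] -- then recomputes it on `n_perm`
#' datasets in which individuals are randomly rearranged among patches
#' within each year ([permute_within_year()]), holding patch sizes fixed.
#' The observed statistic is located within the null distribution by the
#' add-one extremeness estimator
#' `(1 + #\{|null| >= |observed|\}) / (n_perm + 1)` (two-sided on the
#' magnitude); the test rejects when this proportion is at or below
#' `level`. Replicates on which the statistic cannot be computed (e.g. a
#' degenerate table) are excluded and counted; more than 10% failures
#' aborts the test.
#'
#' @param records Resighting tibble.
#' @param period1,period2 Year vectors for the predictor and outcome
#'   period.
#' @param stat `"chi_square"` (fast, default) or `"ame_beta_dyad"` (the
#'   regression coefficient, refitted on every permuted dataset with
#'   `mcmc`).
#' @param n_perm Number of permutations (>= 19 for a 5% verdict; the
#'   field-scale convention is 200).
#' @param level Significance level of the verdict.
#' @param mcmc [mcmc_config()] used for `stat = "ame_beta_dyad"`
#'   replicates; defaults to a short chain (2000 iterations, burn-in 200)
#'   because the null distribution's location, not its far tail, drives
#'   the verdict.
#' @param permute Permute `"both"` periods (default) or only the
#'   `"outcome"` period before recomputation.
#' @param seed Optional integer seed.
#' @return An object of class `permutation_result`: `observed_stat`,
#'   `null_stats`, `rank_extremeness`, `reject`, `stat_name`, `n_perm`,
#'   `level`, `failures`.
#' @export
permutation_test <- function(records, period1, period2,
                             stat = c("chi_square", "ame_beta_dyad"),
                             n_perm = 200, level = 0.05,
                             mcmc = mcmc_config(n_iter = 2000, burn_in = 200, thin = 2),
                             permute = c("both", "outcome"),
                             seed = NULL) {
  stat <- match.arg(stat)
  permute <- match.arg(permute)
  if (n_perm < 19) abort("`n_perm` must be >= 19 for a 5% verdict.")
  records <- validate_resightings(records)
  if (!is.null(seed)) withr::local_seed(seed)

  compute_stat <- function(recs) {
    inds <- sort(unique(recs$individual_id[recs$year %in% c(period1, period2)]))
    s1 <- build_sociomatrix(recs, period1, individuals = inds)
    s2 <- build_sociomatrix(recs, period2, individuals = inds)
    if (stat == "chi_square") {
      chi_square_core(build_transition_table(s1, s2))$statistic
    } else {
      fit <- suppressWarnings(
        fit_ame_probit(ame_data(s2, s1), mcmc))
      fit$summaries$pmean[fit$summaries$term == ".dyad"]
    }
  }

  observed <- compute_stat(records)
  in_p1 <- records$year %in% period1
  in_p2 <- records$year %in% period2
  null_stats <- rep(NA_real_, n_perm)
  failures <- 0L
  for (b in seq_len(n_perm)) {
    perm <- records
    shuffle <- in_p1 | in_p2
    if (permute == "outcome") shuffle <- in_p2
    perm[shuffle, ] <- permute_within_year(records[shuffle, , drop = FALSE])
    val <- tryCatch(compute_stat(perm), error = function(e) NA_real_)
    if (is.na(val)) failures <- failures + 1L else null_stats[b] <- val
  }
  if (failures > 0.1 * n_perm) {
    abort(sprintf("permutation test aborted: %d of %d replicates failed.",
                  failures, n_perm))
  }
  null_ok <- null_stats[!is.na(null_stats)]
  rank_extremeness <- (1 + sum(abs(null_ok) >= abs(observed))) /
    (length(null_ok) + 1)
  structure(list(observed_stat = observed,
                 null_stats = null_ok,
                 rank_extremeness = rank_extremeness,
                 reject = rank_extremeness <= level,
                 stat_name = stat,
                 n_perm = as.integer(n_perm),
                 level = level,
                 failures = failures),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %s = %.4f vs %d within-year permutations\n",
              x$stat_name, x$observed_stat, length(x$null_stats)))
  cat(sprintf("  extremeness %.4f at level %.2f -> %s non-random association\n",
              x$rank_extremeness, x$level,
              if (x$reject) "evidence of" else "no evidence of"))
  if (x$failures > 0) cat(sprintf("  (%d failed replicates excluded)\n", x$failures))
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(stat_name = x$stat_name,
                 observed_stat = x$observed_stat,
                 n_perm = x$n_perm,
                 rank_extremeness = x$rank_extremeness,
                 reject = x$reject,
                 level = x$level,
                 failures = x$failures)
}

#' @rdname permutation_test
#' @param object A `permutation_result`.
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble::tibble(stat = object$null_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = object$stat_name,
      y = "permutations",
      title = "Observed statistic against the patch-size-preserving null",
      subtitle = sprintf("extremeness = %.4f over %d permutations",
                         object$rank_extremeness, length(object$null_stats))) +
    ggplot2::theme_minimal()
}
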