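#' Cross-classify dyad states across two periods
#'
#' Builds the 3 x 3 table of dyad frequencies indexed by the dyad's state
#' (together / apart / missing) in the first period and in the second. The
#' two sociomatrices must be over an identical individual ordering; every
#' dyad over the common individual set contributes exactly one count, so
#' the table total is `choose(N, 2)`. Dyads with missing data are kept in
#' the table (the missing row/column) but are set aside by the
#' independence test, which uses only the fully observed 2 x 2 core.
#'
#' @param s1,s2 `sociomatrix` objects for the earlier and later period.
#' @return An object of class `transition_table`: list with `counts`
#'   (3 x 3 integer matrix, rows = period-1 state, columns = period-2
#'   state), `periods` (year ranges) and `n_individuals`.
#' @examples
#' recs <- tibble::tibble(
#'   individual_id = rep(c("a", "b", "c"), 2), year = rep(c(2002, 2007), each = 3),
#'   patch_id = c("P1", "P1", "P2", "P3", "P3", "P4"))
#' s1 <- build_sociomatrix(recs, 2002, individuals = c("a", "b", "c"))
#' s2 <- build_sociomatrix(recs, 2007, individuals = c("a", "b", "c"))
#' build_transition_table(s1, s2)
#' @export
build_transition_table <- function(s1, s2) {
  stopifnot(inherits(s1, "sociomatrix"), inherits(s2, "sociomatrix"))
  if (!identical(s1$individuals, s2$individuals)) {
    only1 <- setdiff(s1$individuals, s2$individuals)
    only2 <- setdiff(s2$individuals, s1$individuals)
    abort(paste0(
      "sociomatrices are not over the same individual ordering",
      if (length(only1)) sprintf("; only in period 1: %s",
                                 paste(head(only1, 5L), collapse = ", ")),
      if (length(only2)) sprintf("; only in period 2: %s",
                                 paste(head(only2, 5L), collapse = ", ")),
      ". Rebuild both with a common `individuals` vector."))
  }
  f <- function(v) factor(ifelse(is.na(v), "missing",
                                 ifelse(v == 1L, "together", "apart")),
                          levels = STATE_LEVELS)
  counts <- table(period1 = f(sociomatrix_upper(s1)),
                  period2 = f(sociomatrix_upper(s2)))
  counts <- matrix(as.integer(counts), 3L, 3L,
                   dimnames = list(period1 = STATE_LEVELS,
                                   period2 = STATE_LEVELS))
  structure(list(counts = counts,
                 periods = list(s1$years, s2$years),
                 n_individuals = length(s1$individuals)),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("<transition_table> %d individuals, %d dyads\n",
              x$n_individuals, sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @rdname build_transition_table
#' @param x A `transition_table`.
#' @param ... Unused.
#' @export
tidy.transition_table <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$counts, responseName = "n_dyads"))
}

core_2x2 <- function(x) {
  if (inherits(x, "transition_table")) x$counts[1:2, 1:2, drop = FALSE]
  else matrix(as.numeric(x), 2L, 2L,
              dimnames = list(period1 = STATE_LEVELS[1:2],
                              period2 = STATE_LEVELS[1:2]))
}

#' Chi-square test of dyad-state independence across periods
#'
#' Pearson chi-square test of independence on the fully observed 2 x 2
#' core (together/apart in both periods) of a [build_transition_table()]
#' result, with 1 degree of freedom and no continuity correction. A
#' significant statistic means that breeding together at least once in the
#' second period is not independent of having bred together in the first
#' -- the signature of ties that persist across periods.
#'
#' @param x A `transition_table`, or a 2 x 2 count matrix.
#' @return An object of class `chisq_persistence`: list with `statistic`,
#'   `df` (always 1), `p_value`, `n_dyads_core` and the `core` table.
#' @examples
#' chi_square_core(matrix(c(30, 10, 10, 30), 2))$statistic # 20
#' @export
chi_square_core <- function(x) {
  core <- core_2x2(x)
  if (any(core < 0) || any(!is.finite(core))) {
    abort("core counts must be finite and non-negative.")
  }
  if (any(rowSums(core) == 0) || any(colSums(core) == 0)) {
    abort("degenerate 2x2 core: a row or column margin is zero, the chi-square statistic is undefined.")
  }
  ht <- suppressWarnings(chisq.test(core, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = 1L,
                 p_value = unname(ht$p.value),
                 n_dyads_core = sum(core),
                 core = core),
            class = "chisq_persistence")
}

#' @export
print.chisq_persistence <- function(x, ...) {
  cat(sprintf("chi-square(1) = %.4f, P = %.4g (n = %d complete-case dyads)\n",
              x$statistic, x$p_value, x$n_dyads_core))
  invisible(x)
}

#' @rdname chi_square_core
#' @param ... Unused.
#' @export
glance.chisq_persistence <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n_dyads_core = x$n_dyads_core)
}

#' Power-matched subsampling of the persistence chi-square
#'
#' When two period-pairs differ in sample size (fewer individuals bred
#' during a collapse than during stability), a non-significant result in
#' the smaller analysis could reflect lost power rather than lost
#' cohesion. This procedure equalises power: it repeatedly draws, without
#' replacement, `n_target` complete-case dyads (dyads in the 2 x 2
#' together/apart core) from the richer period-pair, recomputes the
#' chi-square on each draw, and reports the fraction of draws significant
#' at `alpha`. Draws whose reduced table is degenerate (a zero margin)
#' cannot be significant and are counted as non-significant.
#'
#' @param x A `transition_table` (or 2 x 2 core matrix) for the richer
#'   period-pair.
#' @param n_target Complete-case dyad count per draw, typically the number
#'   of complete-case dyads available in the poorer period-pair.
#' @param n_draws Number of draws (the field-scale convention is 1000).
#' @param alpha Significance level per draw.
#' @param seed Optional integer seed.
#' @return An object of class `subsample_result`: list with `n_draws`,
#'   `n_target`, `alpha`, `frac_significant` and the vector of per-draw
#'   p-values.
#' @examples
#' tab <- matrix(c(300, 100, 100, 300), 2)
#' power_matched_subsample(tab, n_target = 200, n_draws = 50, seed = 1)
#' @export
power_matched_subsample <- function(x, n_target, n_draws = 1000, alpha = 0.05,
                                    seed = NULL) {
  core <- core_2x2(x)
  n_avail <- sum(core)
  n_target <- as.integer(n_target)
  if (n_target < 1L) abort("`n_target` must be >= 1.")
  if (n_target > n_avail) {
    abort(sprintf("`n_target` (%d) exceeds the %d available complete-case dyads.",
                  n_target, n_avail))
  }
  if (!is.null(seed)) withr::local_seed(seed)
  cells <- rep.int(1:4, as.vector(core))
  p_values <- vapply(seq_len(n_draws), function(d) {
    drawn <- tabulate(sample(cells, n_target), nbins = 4L)
    sub <- matrix(drawn, 2L, 2L)
    if (any(rowSums(sub) == 0) || any(colSums(sub) == 0)) return(1)
    suppressWarnings(chisq.test(sub, correct = FALSE))$p.value
  }, numeric(1))
  structure(list(n_draws = as.integer(n_draws), n_target = n_target,
                 alpha = alpha,
                 frac_significant = mean(p_values < alpha),
                 p_values = p_values),
            class = "subsample_result")
}

#' @export
print.subsample_result <- function(x, ...) {
  cat(sprintf(
    "<subsample_result> %.1f%% of %d draws of %d dyads significant at alpha = %.2f\n",
    100 * x$frac_significant, x$n_draws, x$n_target, x$alpha))
  invisible(x)
}

#' @rdname power_matched_subsample
#' @param ... Unused.
#' @export
glance.subsample_result <- function(x, ...) {
  tibble::tibble(n_draws = x$n_draws, n_target = x$n_target,
                 alpha = x$alpha, frac_significant = x$frac_significant)
}
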