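#' Assemble dyadic outcome and lagged predictor for the network regression
#'
#' Pairs an outcome-period sociomatrix with a predictor-period sociomatrix
#' over the same individual ordering. The outcome `y` is 1 if the dyad
#' bred together at least once in the outcome period, 0 if recorded apart,
#' and missing otherwise; the predictor `x` is the indicator of having
#' bred together in the earlier period. Missing predictor entries are, by
#' default, coded 0 (no evidence of prior association) with the count
#' reported; `x_missing = "listwise"` drops those dyads instead.
#'
#' @param outcome,predictor `sociomatrix` objects with identical
#'   individual orderings (see [build_sociomatrix()]).
#' @param x_missing How to handle dyads whose predictor state is missing:
#'   `"zero"` (default) or `"listwise"`.
#' @return An object of class `ame_data`: upper-triangle vectors `y`
#'   (integer with `NA`) and `x` (integer), node indices `i`, `j`, node
#'   count `n`, the id vector, and bookkeeping counts `n_x_missing`,
#'   `n_dropped`.
#' @export
ame_data <- function(outcome, predictor, x_missing = c("zero", "listwise")) {
  x_missing <- match.arg(x_missing)
  stopifnot(inherits(outcome, "sociomatrix"), inherits(predictor, "sociomatrix"))
  if (!identical(outcome$individuals, predictor$individuals)) {
    abort("`outcome` and `predictor` must share one individual ordering; rebuild both with a common `individuals` vector.")
  }
  n <- length(outcome$individuals)
  ut <- which(upper.tri(outcome$state), arr.ind = TRUE)
  y <- outcome$state[ut]
  x <- predictor$state[ut]
  i <- ut[, 1L]
  j <- ut[, 2L]
  n_x_missing <- sum(is.na(x))
  n_dropped <- 0L
  if (x_missing == "zero") {
    x[is.na(x)] <- 0L
  } else {
    keep <- !is.na(x)
    n_dropped <- sum(!keep)
    y <- y[keep]; x <- x[keep]; i <- i[keep]; j <- j[keep]
  }
  structure(list(y = y, x = x, i = i, j = j, n = n,
                 individuals = outcome$individuals,
                 n_x_missing = n_x_missing, n_dropped = n_dropped),
            class = "ame_data")
}

# standard normal truncated to (lower, Inf); robust in the far upper tail
rtrunc_std_lower <- function(lower) {
  qnorm(log(runif(length(lower))) +
          pnorm(lower, lower.tail = FALSE, log.p = TRUE),
        lower.tail = FALSE, log.p = TRUE)
}

#' Fit the symmetric probit social-relations network regression
#'
#' Bayesian probit regression for a symmetric binary network with additive
#' individual random effects and a dyadic covariate, fitted by Gibbs
#' sampling with data augmentation. The model for dyad `(i, j)` is
#' \deqn{z_{ij} = \beta_0 + \beta_{dyad} x_{ij} + a_i + a_j + \epsilon_{ij},
#'   \quad y_{ij} = 1(z_{ij} > 0),}
#' with `a_i ~ N(0, sigma2_a)` (one effect per individual, entering both
#' endpoints: the network is undirected) and `epsilon_ij ~ N(0, 1)` (fixed
#' to 1 for probit identification). Priors: independent `N(0,
#' prior_beta_var)` on the coefficients and inverse-gamma on `sigma2_a`.
#'
#' Missing outcome dyads are imputed inside the chain: at each iteration a
#' missing `y_ij` (and its latent `z_ij`) is simulated from its
#' conditional distribution given the current parameters, which is valid
#' when individuals are missing at random. Latent variables for observed
#' dyads are drawn from the correspondingly truncated normal; coefficients,
#' additive effects and the effect variance have conjugate normal /
#' inverse-gamma full conditionals.
#'
#' @param data An `ame_data` object (see [ame_data()]), or any list with
#'   elements `y`, `x`, `i`, `j`, `n` such as [simulate_ame_data()]
#'   returns.
#' @param config An [mcmc_config()].
#' @param include_additive Include the additive individual effects
#'   (default). With `FALSE` the model reduces to an ordinary probit
#'   regression on the dyad list (used for cross-checks against maximum
#'   likelihood).
#' @return An object of class `ame_fit`: list with `draws` (tibble of
#'   retained posterior samples of `beta0`, `beta_dyad`, `sigma2_a`),
#'   `summaries` (tibble with `term`, `pmean`, `psd`, `z`, `p_value` for
#'   the intercept and the dyadic coefficient), `imputation_rate`,
#'   `converged` flag with split-chain `rhat` values, and the config.
#' @examples
#' d <- simulate_ame_data(30, beta0 = -0.5, beta_dyad = 1.5, sigma2_a = 0.3, seed = 2)
#' fit <- fit_ame_probit(d, mcmc_config(n_iter = 600, burn_in = 100, seed = 2))
#' tidy(fit)
#' @export
fit_ame_probit <- function(data, config = mcmc_config(), include_additive = TRUE) {
  stopifnot(inherits(config, "mcmc_config"))
  if (!all(c("y", "x", "i", "j", "n") %in% names(data))) {
    abort("`data` must carry elements y, x, i, j, n (see ame_data()).")
  }
  y <- as.integer(data$y)
  x <- as.numeric(data$x)
  i <- as.integer(data$i)
  j <- as.integer(data$j)
  n <- as.integer(data$n)
  if (n < 3L) abort("at least 3 individuals are required.")
  if (length(y) == 0L) abort("no dyads to fit.")
  obs <- !is.na(y)
  if (!any(obs)) abort("all outcome dyads are missing.")
  if (length(unique(y[obs])) < 2L) {
    abort("non-identifiable outcome: every observed dyad has the same state (need at least one together and one apart dyad).")
  }
  if (anyNA(x)) abort("predictor vector must not contain missing values; build it with ame_data().")
  if (!is.null(config$seed)) withr::local_seed(config$seed)

  d <- length(y)
  idx1 <- which(obs & y == 1L)
  idx0 <- which(obs & y == 0L)
  idxm <- which(!obs)
  ij_all <- c(i, j)
  sx <- sum(x)
  xtx <- matrix(c(d, sx, sx, sum(x * x)), 2L)
  prior_prec <- diag(1 / config$prior_beta_var, 2L)
  x_is1 <- x != 0

  beta <- c(qnorm(pmin(pmax(mean(y[obs]), 0.05), 0.95)), 0)
  a <- numeric(n)
  sigma2 <- 1
  z <- numeric(d)

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  draws <- matrix(NA_real_, n_keep, 3L,
                  dimnames = list(NULL, c("beta0", "beta_dyad", "sigma2_a")))
  k <- 0L

  for (iter in seq_len(config$n_iter)) {
    mu <- beta[1L] + beta[2L] * x + a[i] + a[j]
    # latent scale: truncated for observed dyads, free draw (= imputation
    # of y then z) for missing dyads
    if (length(idx1)) z[idx1] <- mu[idx1] + rtrunc_std_lower(-mu[idx1])
    if (length(idx0)) z[idx0] <- mu[idx0] - rtrunc_std_lower(mu[idx0])
    if (length(idxm)) z[idxm] <- mu[idxm] + rnorm(length(idxm))

    r <- z - a[i] - a[j]
    prec <- xtx + prior_prec
    xtr <- c(sum(r), sum(r[x_is1]))
    u_chol <- chol(prec)
    beta <- drop(backsolve(u_chol, backsolve(u_chol, xtr, transpose = TRUE)) +
                   backsolve(u_chol, rnorm(2L)))

    if (include_additive) {
      r2 <- z - beta[1L] - beta[2L] * x
      b <- numeric(n)
      acc <- rowsum(c(r2, r2), ij_all)
      b[as.integer(rownames(acc))] <- acc
      cc <- (n - 2) + 1 / sigma2
      m <- (b - sum(b) / (cc + n)) / cc
      u <- rnorm(n)
      a <- m + (u - mean(u)) / sqrt(cc) + mean(u) / sqrt(cc + n)
      sigma2 <- 1 / rgamma(1L, shape = config$prior_var_shape + n / 2,
                           rate = config$prior_var_scale + sum(a * a) / 2)
    }

    if (iter > config$burn_in && (iter - config$burn_in) %% config$thin == 0L) {
      k <- k + 1L
      draws[k, ] <- c(beta[1L], beta[2L], if (include_additive) sigma2 else 0)
    }
  }

  draws <- tibble::as_tibble(draws)
  rhat <- vapply(draws[c("beta0", "beta_dyad")], split_rhat, numeric(1))
  converged <- all(is.finite(rhat) & rhat < 1.2)
  if (!converged) {
    warn(sprintf("chain may not have converged (split-Rhat up to %.3f); consider a longer run",
                 max(rhat, na.rm = TRUE)))
  }
  summaries <- dplyr::bind_rows(
    c(term = "intercept", posterior_summary(draws$beta0)),
    c(term = ".dyad", posterior_summary(draws$beta_dyad))
  ) %>%
    mutate(dplyr::across(-"term", as.numeric))
  structure(list(draws = draws, summaries = summaries,
                 imputation_rate = mean(!obs),
                 n_dyads = d, n_individuals = n,
                 include_additive = include_additive,
                 rhat = rhat, converged = converged,
                 config = config),
            class = "ame_fit")
}

# split-half Rhat on one chain: ratio of pooled to within-half variance
split_rhat <- function(v) {
  m <- length(v) %/% 2L
  if (m < 2L) return(NA_real_)
  h1 <- v[seq_len(m)]
  h2 <- v[seq.int(length(v) - m + 1L, length(v))]
  w <- (stats::var(h1) + stats::var(h2)) / 2
  if (w <= 0) return(NA_real_)
  bb <- m * (mean(h1) - mean(h2))^2 / 2
  sqrt(((m - 1) / m * w + bb / m) / w)
}

#' Summarise a vector of posterior draws
#'
#' Computes the posterior mean (`pmean`), posterior standard deviation
#' (`psd`), the nominal z-score `z = pmean / psd`, and the two-sided
#' standard-normal tail probability `p_value = 2 * (1 - pnorm(|z|))`.
#'
#' @param draws Numeric vector of at least 2 retained draws.
#' @return A named list with `pmean`, `psd`, `z`, `p_value`.
#' @examples
#' posterior_summary(c(-0.1, 0.2, 0.05, -0.3))
#' # the z -> p convention:
#' with(posterior_summary(rnorm(100)), 2 * (1 - pnorm(abs(pmean / psd)))) # == p_value
#' @export
posterior_summary <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 2L) abort("need at least 2 draws.")
  psd <- sd(draws)
  if (!is.finite(psd) || psd == 0) {
    abort("degenerate posterior summary: draws have zero variance.")
  }
  pmean <- mean(draws)
  z <- pmean / psd
  list(pmean = pmean, psd = psd, z = z, p_value = 2 * (1 - pnorm(abs(z))))
}

#' Posterior predictive tie probability
#'
#' Posterior mean probability that a dyad with covariate value `x` breeds
#' together, marginal over the additive effects: for each retained draw
#' the pair effect `a_i + a_j` is integrated out as `N(0, 2 sigma2_a)`,
#' giving `pnorm((beta0 + beta_dyad * x) / sqrt(1 + 2 sigma2_a))`, and the
#' result is averaged over draws.
#'
#' @param fit An `ame_fit`.
#' @param x Dyadic covariate value (typically 0 or 1).
#' @return A probability.
#' @examples
#' d <- simulate_ame_data(30, -0.5, 1.5, 0.3, seed = 2)
#' fit <- fit_ame_probit(d, mcmc_config(n_iter = 600, burn_in = 100, seed = 2))
#' predict_tie_probability(fit, x = 1)
#' @export
predict_tie_probability <- function(fit, x) {
  stopifnot(inherits(fit, "ame_fit"))
  dr <- fit$draws
  mean(pnorm((dr$beta0 + dr$beta_dyad * x) / sqrt(1 + 2 * dr$sigma2_a)))
}

#' @export
print.ame_fit <- function(x, ...) {
  cat(sprintf("<ame_fit> %d dyads among %d individuals (%.1f%% of outcomes imputed)\n",
              x$n_dyads, x$n_individuals, 100 * x$imputation_rate))
  s <- x$summaries
  for (r in seq_len(nrow(s))) {
    cat(sprintf("  %-10s pmean %8.3f  psd %7.3f  z %8.3f  P %.3f\n",
                s$term[r], s$pmean[r], s$psd[r], s$z[r], s$p_value[r]))
  }
  if (!x$converged) cat("  (convergence warning: see $rhat)\n")
  invisible(x)
}

#' @rdname fit_ame_probit
#' @param x An `ame_fit`.
#' @param ... Unused.
#' @export
tidy.ame_fit <- function(x, ...) x$summaries

#' @rdname fit_ame_probit
#' @export
glance.ame_fit <- function(x, ...) {
  tibble::tibble(n_individuals = x$n_individuals,
                 n_dyads = x$n_dyads,
                 n_draws = nrow(x$draws),
                 imputation_rate = x$imputation_rate,
                 sigma2_a = mean(x$draws$sigma2_a),
                 max_rhat = max(x$rhat, na.rm = TRUE),
                 converged = x$converged)
}

#' Posterior credible interval for the dyadic coefficient
#'
#' @param fit An `ame_fit`.
#' @param level Credibility level (default 0.95).
#' @return Length-2 numeric vector (lower, upper) of equal-tail quantiles
#'   of the retained `beta_dyad` draws.
#' @export
dyad_credible_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ame_fit"))
  alpha <- (1 - level) / 2
  unname(quantile(fit$draws$beta_dyad, c(alpha, 1 - alpha)))
}
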