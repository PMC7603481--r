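#' Simulation configuration for a synthetic breeding colony
#'
#' Bundles and validates the parameters of the colony simulator. The
#' simulator emulates a colonially breeding, individually marked population
#' in which breeding happens in discrete patches that turn over annually
#' (each patch survives to the next season with probability
#' `patch_survival`, giving a geometric occupancy lifetime of
#' `1 / (1 - patch_survival)` seasons -- 1.5 seasons at the default), while
#' latent social groups of individuals preferentially co-settle. Because
#' patches are ephemeral, any persistent dyadic association must come from
#' the social groups, not from site fidelity.
#'
#' @param n_individuals Number of marked individuals (>= 2).
#' @param years Integer vector of breeding seasons (inclusive, non-empty).
#' @param n_groups Number of latent social groups (>= 1). Individuals are
#'   assigned to groups as evenly as possible (sizes differ by at most 1).
#' @param patch_survival Probability a patch persists to the next season.
#'   The default 1/3 gives a mean patch lifetime of 1.5 seasons.
#' @param mean_patches Expected number of patches available per season
#'   (>= 1).
#' @param tie_strength Probability in `[0, 1]` that an individual settles on
#'   its group's target patch for the season rather than on an
#'   independently drawn patch. `0` removes all social structure; `1` makes
#'   co-settlement within groups deterministic.
#' @param annual_survival Per-season survival probability.
#' @param p_breed Probability an alive, non-emigrated individual breeds in a
#'   season.
#' @param p_detect Probability a breeding individual is resighted that
#'   season (missing completely at random).
#' @param perturbation_start First perturbed season (integer year), or
#'   `NULL` for an unperturbed simulation.
#' @param dispersal_rate Under perturbation, per-season probability that an
#'   individual permanently emigrates from the study site (its records
#'   stop).
#' @param perturbation_mode Either `"emigrate"` (perturbation drives
#'   permanent emigration at `dispersal_rate`) or `"scramble"` (surviving
#'   individuals are reassigned to fresh random groups from
#'   `perturbation_start` onward, eroding group fidelity without removing
#'   individuals).
#' @param colony Colony label written to simulated resighting records.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_individuals = 40, years = 2002:2011, seed = 1)
#' cfg$patch_survival # 1/3 -> mean patch lifetime 1.5 seasons
#' @export
sim_config <- function(n_individuals = 100,
                       years = 2002:2011,
                       n_groups = max(1L, round(n_individuals / 10)),
                       patch_survival = 1 / 3,
                       mean_patches = 8,
                       tie_strength = 0.9,
                       annual_survival = 0.9,
                       p_breed = 0.85,
                       p_detect = 0.5,
                       perturbation_start = NULL,
                       dispersal_rate = 0.3,
                       perturbation_mode = c("emigrate", "scramble"),
                       colony = "SIM",
                       seed = NULL) {
  perturbation_mode <- match.arg(perturbation_mode)
  years <- as.integer(years)
  if (length(years) == 0L) abort("`years` must be non-empty.")
  years <- seq.int(min(years), max(years))
  if (n_individuals < 2) abort("`n_individuals` must be >= 2.")
  if (n_groups < 1) abort("`n_groups` must be >= 1.")
  if (mean_patches < 1) abort("`mean_patches` must be >= 1.")
  for (p in c("patch_survival", "tie_strength", "annual_survival",
              "p_breed", "p_detect", "dispersal_rate")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1].", p))
    }
  }
  if (patch_survival >= 1) abort("`patch_survival` must be < 1 (patches must be ephemeral).")
  if (!is.null(perturbation_start)) {
    perturbation_start <- as.integer(perturbation_start)
    if (!perturbation_start %in% years) {
      abort("`perturbation_start` must fall inside `years`.")
    }
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      years = years,
      n_groups = as.integer(n_groups),
      patch_survival = patch_survival,
      mean_patches = mean_patches,
      tie_strength = tie_strength,
      annual_survival = annual_survival,
      p_breed = p_breed,
      p_detect = p_detect,
      perturbation_start = perturbation_start,
      dispersal_rate = dispersal_rate,
      perturbation_mode = perturbation_mode,
      colony = colony,
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d individuals in %d groups, seasons %d-%d\n",
              x$n_individuals, x$n_groups, min(x$years), max(x$years)))
  cat(sprintf("  patches: ~%.1f per season, survival %.3f (mean lifetime %.2f seasons)\n",
              x$mean_patches, x$patch_survival, 1 / (1 - x$patch_survival)))
  cat(sprintf("  tie_strength %.2f | survival %.2f | p_breed %.2f | p_detect %.2f\n",
              x$tie_strength, x$annual_survival, x$p_breed, x$p_detect))
  if (is.null(x$perturbation_start)) {
    cat("  no perturbation\n")
  } else {
    cat(sprintf("  perturbation from %d, mode '%s', dispersal %.2f\n",
                x$perturbation_start, x$perturbation_mode, x$dispersal_rate))
  }
  invisible(x)
}

#' MCMC configuration for the network probit regression
#'
#' @param n_iter Total Gibbs iterations.
#' @param burn_in Iterations discarded before summarising (must be
#'   `< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw (>= 1).
#' @param seed Integer seed, or `NULL`.
#' @param prior_beta_var Variance of the independent normal prior on each
#'   regression coefficient (weakly informative default 100).
#' @param prior_var_shape,prior_var_scale Shape and scale of the
#'   inverse-gamma prior on the additive-effect variance.
#' @param preset `"test"` (the defaults: 4000 iterations, burn-in 500,
#'   thin 5) or `"field"` (100000 iterations, burn-in 500, thin 10), the
#'   long-chain setting for full field-scale sociomatrices with thousands
#'   of individuals.
#'
#' @return An object of class `mcmc_config`.
#' @examples
#' mcmc_config()
#' mcmc_config(preset = "field")$n_iter
#' @export
mcmc_config <- function(n_iter = 4000,
                        burn_in = 500,
                        thin = 5,
                        seed = NULL,
                        prior_beta_var = 100,
                        prior_var_shape = 2,
                        prior_var_scale = 1,
                        preset = c("test", "field")) {
  preset <- match.arg(preset)
  if (preset == "field") {
    if (missing(n_iter)) n_iter <- 100000
    if (missing(burn_in)) burn_in <- 500
    if (missing(thin)) thin <- 10
  }
  n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) abort("`burn_in` must be smaller than `n_iter`.")
  if (thin < 1) abort("`thin` must be >= 1.")
  if (prior_beta_var <= 0 || prior_var_shape <= 0 || prior_var_scale <= 0) {
    abort("prior hyperparameters must be positive.")
  }
  structure(
    list(n_iter = n_iter, burn_in = burn_in, thin = thin,
         seed = if (!is.null(seed)) as.integer(seed),
         prior_beta_var = prior_beta_var,
         prior_var_shape = prior_var_shape,
         prior_var_scale = prior_var_scale,
         preset = preset),
    class = "mcmc_config"
  )
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf("<mcmc_config> %d iterations, burn-in %d, thin %d (%d retained draws)\n",
              x$n_iter, x$burn_in, x$thin, (x$n_iter - x$burn_in) %/% x$thin))
  invisible(x)
}
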