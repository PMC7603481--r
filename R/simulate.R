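#' Simulate annual patch turnover
#'
#' Each season every extant patch persists to the next season independently
#' with probability `patch_survival`, so patch lifetimes are geometric with
#' mean `1 / (1 - patch_survival)`. Extinct patches are replaced by newly
#' labelled patches (a Poisson number with mean
#' `mean_patches * (1 - patch_survival)`, which keeps the expected patch
#' count stationary at `mean_patches`); at least one patch is always
#' available. Patch ids are never reused: a patch that reappears physically
#' would be a new patch.
#'
#' @param config A [sim_config()].
#' @return A named list (one element per year) of character patch-id
#'   vectors.
#' @examples
#' patches <- simulate_patch_dynamics(sim_config(years = 2002:2005, seed = 1))
#' lengths(patches)
#' @export
simulate_patch_dynamics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) withr::local_seed(config$seed)
  years <- config$years
  counter <- 0L
  new_ids <- function(k) {
    if (k == 0L) return(character(0))
    ids <- sprintf("P%05d", counter + seq_len(k))
    counter <<- counter + k
    ids
  }
  out <- vector("list", length(years))
  names(out) <- as.character(years)
  current <- new_ids(max(1L, rpois(1, config$mean_patches)))
  out[[1L]] <- current
  birth_rate <- config$mean_patches * (1 - config$patch_survival)
  for (t in seq_along(years)[-1L]) {
    survived <- current[runif(length(current)) < config$patch_survival]
    current <- c(survived, new_ids(rpois(1, birth_rate)))
    if (length(current) == 0L) current <- new_ids(1L)
    out[[t]] <- current
  }
  out
}

#' Simulate individual survival, group-led settlement and perturbation
#'
#' Individuals are assigned to latent social groups at initialisation
#' (balanced sizes). Each season every group draws a target patch uniformly
#' from that season's extant patches; each alive, non-emigrated individual
#' breeds with probability `p_breed` and, if it breeds, settles on its
#' group's target with probability `tie_strength`, otherwise on an
#' independently drawn uniform patch. Survival is an annual Bernoulli
#' trial. From `perturbation_start` onward the perturbation acts either as
#' permanent emigration (`"emigrate"` mode, rate `dispersal_rate` per
#' season) or as a one-off reshuffle of surviving individuals into fresh
#' random groups (`"scramble"` mode).
#'
#' @param config A [sim_config()].
#' @param patches Per-year patch ids as returned by
#'   [simulate_patch_dynamics()].
#' @return An object of class `colony_state`: a list with
#'   `breeding` (tibble: `individual_id`, `year`, `patch_id` of every true
#'   breeding event), `group_of` (tibble: `individual_id`, `group` at
#'   initialisation), `status` (tibble: `individual_id`, `year`, `alive`,
#'   `emigrated`) and the `config`.
#' @examples
#' cfg <- sim_config(n_individuals = 20, years = 2002:2004, seed = 1)
#' state <- simulate_individuals(cfg, simulate_patch_dynamics(cfg))
#' head(state$breeding)
#' @export
simulate_individuals <- function(config, patches) {
  stopifnot(inherits(config, "sim_config"))
  if (length(patches) != length(config$years) || any(lengths(patches) == 0L)) {
    abort("`patches` must supply a non-empty patch set for every year.")
  }
  if (!is.null(config$seed)) withr::local_seed(config$seed + 1L)

  n <- config$n_individuals
  years <- config$years
  ids <- sprintf("IND%04d", seq_len(n))
  # balanced assignment: sizes differ by at most one
  group0 <- sample(rep_len(seq_len(config$n_groups), n))
  group_now <- group0

  alive <- rep(TRUE, n)
  emigrated <- rep(FALSE, n)
  perturbed_at <- config$perturbation_start
  scrambled <- FALSE

  rows_id <- rows_year <- rows_patch <- list()
  status <- vector("list", length(years))

  for (t in seq_along(years)) {
    yr <- years[t]
    if (t > 1L) alive <- alive & (runif(n) < config$annual_survival)
    perturbed <- !is.null(perturbed_at) && yr >= perturbed_at
    if (perturbed && config$perturbation_mode == "scramble" && !scrambled) {
      group_now <- sample(rep_len(seq_len(config$n_groups), n))
      scrambled <- TRUE
    }
    if (perturbed && config$perturbation_mode == "emigrate") {
      leaves <- alive & !emigrated & (runif(n) < config$dispersal_rate)
      emigrated <- emigrated | leaves
    }
    pool <- patches[[t]]
    target <- pool[sample.int(length(pool), config$n_groups, replace = TRUE)]
    active <- alive & !emigrated & (runif(n) < config$p_breed)
    if (any(active)) {
      follows <- runif(n) < config$tie_strength
      own <- pool[sample.int(length(pool), n, replace = TRUE)]
      patch <- ifelse(follows, target[group_now], own)
      rows_id[[t]] <- ids[active]
      rows_year[[t]] <- rep(yr, sum(active))
      rows_patch[[t]] <- patch[active]
    }
    status[[t]] <- tibble::tibble(individual_id = ids, year = yr,
                                  alive = alive, emigrated = emigrated)
  }

  structure(
    list(
      breeding = tibble::tibble(
        individual_id = unlist(rows_id, use.names = FALSE) %||% character(0),
        year = as.integer(unlist(rows_year, use.names = FALSE) %||% integer(0)),
        patch_id = unlist(rows_patch, use.names = FALSE) %||% character(0)
      ),
      group_of = tibble::tibble(individual_id = ids, group = group0),
      status = dplyr::bind_rows(status),
      config = config
    ),
    class = "colony_state"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thin true breeding events to resightings (missing at random)
#'
#' Each true breeding event is independently resighted with probability
#' `p_detect`; emitted rows carry the true patch. This is the
#' missing-completely-at-random detection process that the downstream
#' missing-data rules (ternary dyad states, MCMC imputation) assume.
#'
#' @param state A `colony_state` from [simulate_individuals()].
#' @param p_detect Detection probability in `[0, 1]`; defaults to the value
#'   in the state's config.
#' @param seed Optional integer seed.
#' @return A resighting tibble with columns
#'   `individual_id`, `year`, `colony`, `patch_id`, one row per confirmed
#'   breeding observation.
#' @examples
#' cfg <- sim_config(n_individuals = 20, years = 2002:2004, seed = 1)
#' state <- simulate_individuals(cfg, simulate_patch_dynamics(cfg))
#' nrow(apply_detection(state, p_detect = 1))
#' @export
apply_detection <- function(state, p_detect = state$config$p_detect, seed = NULL) {
  stopifnot(inherits(state, "colony_state"))
  if (!is.numeric(p_detect) || p_detect < 0 || p_detect > 1) {
    abort("`p_detect` must be a probability in [0, 1].")
  }
  if (!is.null(seed)) {
    withr::local_seed(seed)
  } else if (!is.null(state$config$seed)) {
    withr::local_seed(state$config$seed + 2L)
  }
  b <- state$breeding
  keep <- runif(nrow(b)) < p_detect
  b[keep, , drop = FALSE] %>%
    mutate(colony = state$config$colony) %>%
    select("individual_id", "year", "colony", "patch_id") %>%
    arrange(.data$year, .data$individual_id)
}

#' Simulate a full synthetic colony dataset
#'
#' Convenience wrapper chaining [simulate_patch_dynamics()],
#' [simulate_individuals()] and [apply_detection()]. The returned object
#' carries both the observable resighting table and the ground truth
#' (group membership, survival/emigration status), so recovery of the
#' social signal can be checked against what was actually simulated.
#'
#' @param config A [sim_config()].
#' @return An object of class `colony_sim`: list with `resightings`
#'   (tibble), `truth` (the `colony_state`) and `patches`.
#' @examples
#' sim <- simulate_colony(sim_config(n_individuals = 30, years = 2002:2006, seed = 7))
#' head(sim$resightings)
#' @export
simulate_colony <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  patches <- simulate_patch_dynamics(config)
  truth <- simulate_individuals(config, patches)
  structure(
    list(resightings = apply_detection(truth),
         truth = truth,
         patches = patches,
         config = config),
    class = "colony_sim"
  )
}

#' @export
print.colony_sim <- function(x, ...) {
  cat("<colony_sim>\n")
  cat(sprintf("  %d resightings of %d individuals over %d seasons\n",
              nrow(x$resightings),
              dplyr::n_distinct(x$resightings$individual_id),
              length(x$config$years)))
  invisible(x)
}

#' Simulate dyadic data directly from the probit social-relations model
#'
#' Draws a symmetric binary network from the generative model fitted by
#' [fit_ame_probit()]: latent
#' `z_ij = beta0 + beta_dyad * x_ij + a_i + a_j + e_ij` with
#' `a_i ~ N(0, sigma2_a)`, `e_ij ~ N(0, 1)`, and `y_ij = 1(z_ij > 0)`.
#' Used for parameter-recovery checks where the fitted model is exactly
#' true.
#'
#' @param n_individuals Number of nodes (>= 3).
#' @param beta0,beta_dyad,sigma2_a True parameter values.
#' @param x_prob Bernoulli probability of the binary dyadic covariate.
#' @param seed Optional integer seed.
#' @return A list with upper-triangle vectors `y`, `x`, index vectors
#'   `i`, `j`, the node count `n`, and the true additive effects `a`.
#' @examples
#' d <- simulate_ame_data(20, beta0 = -1, beta_dyad = 2, sigma2_a = 0.5, seed = 1)
#' mean(d$y)
#' @export
simulate_ame_data <- function(n_individuals, beta0, beta_dyad, sigma2_a,
                              x_prob = 0.2, seed = NULL) {
  if (n_individuals < 3) abort("`n_individuals` must be >= 3.")
  if (sigma2_a < 0) abort("`sigma2_a` must be non-negative.")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- as.integer(n_individuals)
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1L]
  j <- ut[, 2L]
  a <- rnorm(n, 0, sqrt(sigma2_a))
  x <- as.integer(runif(length(i)) < x_prob)
  z <- beta0 + beta_dyad * x + a[i] + a[j] + rnorm(length(i))
  list(y = as.integer(z > 0), x = x, i = i, j = j, n = n, a = a)
}
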