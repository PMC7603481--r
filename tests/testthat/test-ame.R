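fake_fit <- function(beta0, beta_dyad, sigma2_a) {
  structure(list(draws = tibble::tibble(beta0 = beta0, beta_dyad = beta_dyad,
                                        sigma2_a = sigma2_a)),
            class = "ame_fit")
}

test_that("posterior summaries implement the pmean/psd/z/p convention", {
  draws <- c(0.2, -0.1, 0.4, 0.3, -0.2)
  s <- posterior_summary(draws)
  expect_equal(s$pmean, mean(draws))
  expect_equal(s$psd, sd(draws))
  expect_equal(s$z, mean(draws) / sd(draws))
  expect_equal(s$p_value, 2 * (1 - pnorm(abs(s$z))))
  expect_error(posterior_summary(rep(1, 10)), "zero variance")
  expect_error(posterior_summary(1), "at least 2")
})

test_that("posterior predictive tie probability integrates out the pair effects", {
  expect_equal(predict_tie_probability(fake_fit(0, 0, 1e-12), x = 1), 0.5)
  expect_equal(predict_tie_probability(fake_fit(0, 1, 0), x = 1), pnorm(1),
               tolerance = 1e-6)
  expect_lt(predict_tie_probability(fake_fit(-30, 0, 0.5), x = 0), 1e-6)
  # averaging over draws, with additive variance flattening the response
  f <- fake_fit(c(0, 0), c(2, 2), c(0, 1.5))
  expect_equal(predict_tie_probability(f, 1),
               mean(pnorm(2 / sqrt(1 + 2 * c(0, 1.5)))))
})

test_that("fit rejects unusable data and honours the retention schedule", {
  d <- simulate_ame_data(20, -0.5, 1, 0.3, seed = 1)
  cfg <- mcmc_config(n_iter = 730, burn_in = 100, thin = 3, seed = 1)
  fit <- suppressWarnings(fit_ame_probit(d, cfg))
  expect_equal(nrow(fit$draws), (730 - 100) %/% 3)
  expect_true(all(fit$draws$sigma2_a > 0))
  expect_named(fit$summaries, c("term", "pmean", "psd", "z", "p_value"))

  d_const <- d; d_const$y <- rep(1L, length(d$y))
  expect_error(fit_ame_probit(d_const, cfg), "non-identifiable")
  d_tiny <- list(y = c(1L, 0L), x = c(0L, 1L), i = c(1L, 1L), j = c(2L, 2L), n = 2L)
  expect_error(fit_ame_probit(d_tiny, cfg), "3 individuals")
})

test_that("identical data, config and seed replay identical draws", {
  d <- simulate_ame_data(25, -0.5, 1, 0.3, seed = 4)
  cfg <- mcmc_config(n_iter = 500, burn_in = 100, seed = 42)
  f1 <- suppressWarnings(fit_ame_probit(d, cfg))
  f2 <- suppressWarnings(fit_ame_probit(d, cfg))
  expect_identical(f1$draws, f2$draws)
})

test_that("relabelling individuals leaves the coefficient posteriors equivalent", {
  d <- simulate_ame_data(30, -0.8, 1.5, 0.4, seed = 9)
  perm <- sample(d$n)
  d2 <- d
  d2$i <- pmin(perm[d$i], perm[d$j])
  d2$j <- pmax(perm[d$i], perm[d$j])
  cfg <- mcmc_config(n_iter = 2000, burn_in = 400, thin = 2, seed = 5)
  f1 <- suppressWarnings(fit_ame_probit(d, cfg))
  f2 <- suppressWarnings(fit_ame_probit(d2, cfg))
  s1 <- f1$summaries; s2 <- f2$summaries
  for (term in c("intercept", ".dyad")) {
    spread <- sqrt(s1$psd[s1$term == term]^2 + s2$psd[s2$term == term]^2)
    expect_lt(abs(s1$pmean[s1$term == term] - s2$pmean[s2$term == term]),
              2 * spread)
  }
})

test_that("without additive effects the posterior matches maximum-likelihood probit", {
  d <- simulate_ame_data(80, -0.7, 1.4, 0, x_prob = 0.3, seed = 17)
  fit <- suppressWarnings(fit_ame_probit(
    d, mcmc_config(n_iter = 3000, burn_in = 500, thin = 2, seed = 17),
    include_additive = FALSE))
  ml <- stats::glm(d$y ~ d$x, family = binomial("probit"))
  ml_se <- sqrt(diag(stats::vcov(ml)))
  s <- fit$summaries
  for (k in 1:2) {
    combined_se <- sqrt(ml_se[k]^2 + s$psd[k]^2)
    expect_lt(abs(s$pmean[k] - unname(coef(ml)[k])), 3 * combined_se)
  }
})

test_that("a covariate with no variation yields a coefficient centred at zero", {
  withr::local_seed(33)
  means <- replicate(6, {
    d <- simulate_ame_data(30, -0.3, 0, 0.3, x_prob = 0, seed = sample.int(1e6, 1))
    fit <- suppressWarnings(fit_ame_probit(
      d, mcmc_config(n_iter = 800, burn_in = 200, seed = sample.int(1e6, 1))))
    s <- fit$summaries
    c(s$pmean[s$term == ".dyad"], s$psd[s$term == ".dyad"])
  })
  pooled_se <- sqrt(mean(means[2, ]^2) / 6)
  expect_lt(abs(mean(means[1, ])), 2 * pooled_se)
})

test_that("ame_data pairs sociomatrices and accounts for predictor missingness", {
  recs <- dplyr::bind_rows(
    make_records(c("a", "b", "c"), 2002, c("P1", "P1", "P2")),
    make_records(c("a", "b", "c", "d"), 2007, c("Q1", "Q2", "Q1", "Q1")))
  ids <- c("a", "b", "c", "d")
  s1 <- build_sociomatrix(recs, 2002, individuals = ids)
  s2 <- build_sociomatrix(recs, 2007, individuals = ids)
  dz <- ame_data(s2, s1)
  expect_equal(dz$n_x_missing, 3) # d unseen in 2002 -> 3 dyads lack x
  expect_equal(sum(dz$x), 1) # only a-b together in 2002
  expect_equal(length(dz$y), 6)
  dl <- ame_data(s2, s1, x_missing = "listwise")
  expect_equal(dl$n_dropped, 3)
  expect_equal(length(dl$y), 3)
  expect_error(ame_data(s2, build_sociomatrix(recs, 2002, individuals = c("a", "b", "c"))),
               "individual ordering")
})

test_that("credible intervals and tidiers expose the fit", {
  d <- simulate_ame_data(25, -0.5, 1, 0.3, seed = 6)
  fit <- suppressWarnings(fit_ame_probit(d, mcmc_config(n_iter = 600, burn_in = 100, seed = 6)))
  ci <- dyad_credible_interval(fit)
  expect_length(ci, 2)
  expect_lt(ci[1], ci[2])
  expect_equal(tidy(fit), fit$summaries)
  g <- glance(fit)
  expect_equal(g$n_individuals, 25)
  expect_equal(g$n_dyads, choose(25, 2))
})
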