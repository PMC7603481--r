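test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(n_individuals = 1), "n_individuals")
  expect_error(sim_config(years = integer(0)), "years")
  expect_error(sim_config(tie_strength = 1.2), "probability")
  expect_error(sim_config(mean_patches = 0.5), "mean_patches")
  expect_error(sim_config(perturbation_start = 1990, years = 2002:2010),
               "perturbation_start")
})

test_that("patch lifetimes are geometric with the configured mean", {
  # survival 0: every year's patch set disjoint from the previous year's
  cfg0 <- sim_config(years = 2002:2006, patch_survival = 0, seed = 11)
  p0 <- simulate_patch_dynamics(cfg0)
  for (t in 2:5) expect_length(intersect(p0[[t]], p0[[t - 1]]), 0)

  # survival ~1: patch sets essentially identical across years
  cfg1 <- sim_config(years = 2002:2004, patch_survival = 0.999,
                     mean_patches = 20, seed = 12)
  p1 <- simulate_patch_dynamics(cfg1)
  expect_gt(length(intersect(p1[[1]], p1[[3]])) / length(p1[[1]]), 0.9)

  # survival 1/3: mean realized lifetime 1/(1 - 1/3) = 1.5 years
  cfg <- sim_config(years = 1:1600, patch_survival = 1 / 3,
                    mean_patches = 10, seed = 13)
  p <- simulate_patch_dynamics(cfg)
  last_year <- p[[length(p)]]
  lifetimes <- table(unlist(p))
  lifetimes <- lifetimes[!names(lifetimes) %in% last_year] # drop censored
  expect_gt(length(lifetimes), 10000)
  expect_equal(mean(lifetimes), 1.5, tolerance = 0.05 / 1.5)

  # patch ids never reused; yearly count hovers near mean_patches
  expect_true(all(lengths(p) >= 1))
  expect_equal(mean(lengths(p)), 10, tolerance = 0.1)
})

test_that("perfect ties with no mortality put every group in one patch", {
  cfg <- sim_config(n_individuals = 30, years = 2002:2006, n_groups = 3,
                    tie_strength = 1, annual_survival = 1, p_breed = 1,
                    seed = 21)
  st <- simulate_individuals(cfg, simulate_patch_dynamics(cfg))
  joined <- dplyr::inner_join(st$breeding, st$group_of, by = "individual_id")
  per_group_year <- joined %>%
    dplyr::group_by(group, year) %>%
    dplyr::summarise(n_patches = dplyr::n_distinct(patch_id),
                     n = dplyr::n(), .groups = "drop")
  expect_true(all(per_group_year$n_patches == 1))
  expect_true(all(per_group_year$n == 10)) # nobody dies or skips
})

test_that("with tie_strength 0 same-group and different-group dyads co-settle equally", {
  cfg <- sim_config(n_individuals = 50, years = 2002:2011, n_groups = 5,
                    tie_strength = 0, annual_survival = 1, p_breed = 1,
                    mean_patches = 6, seed = 22)
  st <- simulate_individuals(cfg, simulate_patch_dynamics(cfg))
  joined <- dplyr::inner_join(st$breeding, st$group_of, by = "individual_id")
  share_same <- share_diff <- n_same <- n_diff <- 0
  for (yr in cfg$years) {
    ydat <- joined[joined$year == yr, ]
    same_patch <- outer(ydat$patch_id, ydat$patch_id, "==")
    same_group <- outer(ydat$group, ydat$group, "==")
    up <- upper.tri(same_patch)
    share_same <- share_same + sum(same_patch[up & same_group])
    n_same <- n_same + sum(up & same_group)
    share_diff <- share_diff + sum(same_patch[up & !same_group])
    n_diff <- n_diff + sum(up & !same_group)
  }
  p1 <- share_same / n_same
  p2 <- share_diff / n_diff
  se <- sqrt(p2 * (1 - p2) * (1 / n_same + 1 / n_diff))
  expect_lt(abs(p1 - p2), 3 * se)
})

test_that("total dispersal at the perturbation removes later breeding records", {
  cfg <- sim_config(n_individuals = 25, years = 2002:2010,
                    perturbation_start = 2006, dispersal_rate = 1, seed = 23)
  st <- simulate_individuals(cfg, simulate_patch_dynamics(cfg))
  expect_false(any(st$breeding$year > 2006))
})

test_that("group assignment is balanced and fixed at initialization", {
  cfg <- sim_config(n_individuals = 47, years = 2002:2004, n_groups = 5, seed = 24)
  st <- simulate_individuals(cfg, simulate_patch_dynamics(cfg))
  sizes <- table(st$group_of$group)
  expect_length(sizes, 5)
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("detection thinning is binomial and carries the true patch", {
  cfg <- sim_config(n_individuals = 100, years = 1:120, annual_survival = 1,
                    p_breed = 1, seed = 25)
  st <- simulate_individuals(cfg, simulate_patch_dynamics(cfg))
  n_events <- nrow(st$breeding)
  expect_gte(n_events, 10000)

  expect_equal(nrow(apply_detection(st, p_detect = 1)), n_events)
  expect_equal(nrow(apply_detection(st, p_detect = 0)), 0)

  half <- apply_detection(st, p_detect = 0.5, seed = 1)
  expect_lt(abs(nrow(half) - n_events / 2), 3 * sqrt(n_events * 0.25))
  truth_key <- paste(st$breeding$individual_id, st$breeding$year,
                     st$breeding$patch_id)
  expect_true(all(paste(half$individual_id, half$year, half$patch_id)
                  %in% truth_key))
})

test_that("identical config and seed reproduce the resighting table byte for byte", {
  cfg <- sim_config(n_individuals = 40, years = 2002:2008,
                    perturbation_start = 2006, seed = 99)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_resightings(simulate_colony(cfg)$resightings, f1)
  write_resightings(simulate_colony(cfg)$resightings, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("emigration makes the yearly breeder count shrink after the perturbation", {
  counts <- replicate(8, {
    cfg <- sim_config(n_individuals = 80, years = 2002:2011, annual_survival = 1,
                      perturbation_start = 2007, dispersal_rate = 0.4,
                      seed = sample.int(1e6, 1))
    st <- simulate_individuals(cfg, simulate_patch_dynamics(cfg))
    yearly <- st$breeding %>% dplyr::count(year)
    c(before = mean(yearly$n[yearly$year < 2007]),
      after = mean(yearly$n[yearly$year >= 2008]))
  })
  expect_true(all(counts["after", ] < counts["before", ]))
})

test_that("scramble mode erodes cross-period group fidelity without removing birds", {
  cfg <- sim_config(n_individuals = 60, years = 2002:2009, annual_survival = 1,
                    p_breed = 1, tie_strength = 1, n_groups = 6,
                    perturbation_start = 2006, perturbation_mode = "scramble",
                    seed = 31)
  st <- simulate_individuals(cfg, simulate_patch_dynamics(cfg))
  expect_setequal(unique(st$breeding$year), cfg$years) # nobody leaves
  # pre-perturbation partners are no longer systematically co-settled after
  joined <- dplyr::inner_join(st$breeding, st$group_of, by = "individual_id")
  after <- joined[joined$year == 2008, ]
  same_patch <- outer(after$patch_id, after$patch_id, "==")
  same_group0 <- outer(after$group, after$group, "==")
  up <- upper.tri(same_patch)
  frac_old_group <- mean(same_patch[up & same_group0])
  expect_lt(frac_old_group, 0.8) # would be 1.0 without the scramble
})
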