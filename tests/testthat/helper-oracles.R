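# Independent brute-force oracles and small fixture builders.

make_records <- function(individual_id, year, patch_id, colony = "SIM") {
  tibble::tibble(individual_id = individual_id, year = as.integer(year),
                 colony = colony, patch_id = patch_id)
}

# random resighting table: each individual-year observed with prob p_obs,
# assigned a uniform patch label (patch ids distinct across years)
random_records <- function(n_ind, years, n_patches = 3, p_obs = 0.7) {
  rows <- list()
  for (yr in years) {
    seen <- which(runif(n_ind) < p_obs)
    if (length(seen) == 0L) next
    rows[[as.character(yr)]] <- make_records(
      sprintf("i%02d", seen), yr,
      sprintf("Y%d_P%d", yr, sample.int(n_patches, length(seen), replace = TRUE)))
  }
  dplyr::bind_rows(rows)
}

# literal per-dyad, per-year half-weight index recomputation
hwi_oracle <- function(records, years, i, j) {
  x <- y_ab <- y_one <- 0
  for (yr in years) {
    ydat <- records[records$year == yr, ]
    pi <- ydat$patch_id[ydat$individual_id == i]
    pj <- ydat$patch_id[ydat$individual_id == j]
    if (length(pi) == 1L && length(pj) == 1L) {
      if (pi == pj) x <- x + 1 else y_ab <- y_ab + 1
    } else if (length(pi) + length(pj) == 1L) {
      y_one <- y_one + 1
    }
  }
  denom <- x + y_ab + 0.5 * y_one
  if (denom == 0) NA_real_ else x / denom
}

# closed-form Pearson chi-square for a 2x2 table, no correction
chisq_2x2_oracle <- function(m) {
  n <- sum(m)
  num <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2
  den <- prod(rowSums(m)) * prod(colSums(m))
  num / den
}

# expected-counts Pearson chi-square, any table
chisq_expected_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# deterministic grouped colony: members of a group always share a patch,
# groups never share; patches relabelled every year (no site fidelity)
group_records <- function(n_groups, n_per_group, years) {
  ids <- sprintf("g%d_i%d", rep(seq_len(n_groups), each = n_per_group),
                 rep(seq_len(n_per_group), n_groups))
  dplyr::bind_rows(lapply(years, function(yr) {
    make_records(ids, yr,
                 rep(sprintf("Y%d_P%d", yr, seq_len(n_groups)),
                     each = n_per_group))
  }))
}

two_group_records <- function(n_per_group = 5, years = 2002:2006) {
  group_records(2, n_per_group, years)
}
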