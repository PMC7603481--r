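test_that("dyad state for one year follows the together/apart/missing rules", {
  recs <- make_records(c("a", "b", "c"), 2004, c("P7", "P7", "P9"))
  expect_equal(dyad_year_state(recs, "a", "b", 2004), "together")
  expect_equal(dyad_year_state(recs, "a", "c", 2004), "apart")
  expect_equal(dyad_year_state(recs, "a", "d", 2004), "missing") # d missed
  expect_equal(dyad_year_state(recs, "a", "b", 2005), "missing") # no records
  expect_error(dyad_year_state(recs, "a", "a", 2004), "distinct")
})

test_that("period state uses the together > apart > missing precedence", {
  # a-b: apart 2002, together 2003, both unseen 2004 -> together
  # a-c: apart 2002, c unseen after -> apart
  # c-d: never co-observed in any year -> missing
  recs <- dplyr::bind_rows(
    make_records(c("a", "b", "c"), 2002, c("P1", "P2", "P3")),
    make_records(c("a", "b"), 2003, c("P4", "P4")),
    make_records("d", 2004, "P5"))
  s <- build_sociomatrix(recs, 2002:2004)
  expect_s3_class(s, "sociomatrix")
  st <- tidy(s)
  state_of <- function(i, j) as.character(st$state[st$i == i & st$j == j])
  expect_equal(state_of("a", "b"), "together")
  expect_equal(state_of("a", "c"), "apart")
  expect_equal(state_of("c", "d"), "missing")
  expect_equal(state_of("a", "d"), "missing")
  # symmetric storage, undefined diagonal
  expect_true(all(is.na(diag(as.matrix(s)))))
  m <- as.matrix(s)
  expect_identical(m["a", "b"], m["b", "a"])
})

test_that("sociomatrix is invariant under row order and merges over disjoint year sets", {
  withr::local_seed(42)
  recs <- random_records(12, 2002:2009, n_patches = 3, p_obs = 0.6)

  shuffled <- recs[sample(nrow(recs)), ]
  expect_identical(build_sociomatrix(recs, 2002:2009)$state,
                   build_sociomatrix(shuffled, 2002:2009)$state)

  # precedence-merge of two disjoint periods equals the pooled period
  inds <- sort(unique(recs$individual_id))
  sA <- build_sociomatrix(recs, 2002:2005, individuals = inds)
  sB <- build_sociomatrix(recs, 2006:2009, individuals = inds)
  sAB <- build_sociomatrix(recs, 2002:2009, individuals = inds)
  merged <- pmax(sA$state, sB$state, na.rm = TRUE) # together(1) > apart(0) > missing(NA)
  expect_identical(sAB$state, merged)
})

test_that("ambiguous individual-years are rejected (strict) or deduplicated (lenient)", {
  recs <- make_records(c("a", "a", "b"), c(2002, 2002, 2002), c("P1", "P2", "P1"))
  expect_error(build_sociomatrix(recs, 2002), "one patch per year")
  expect_warning(s <- build_sociomatrix(recs, 2002, strict = FALSE), "first patch")
  expect_equal(as.matrix(s)["a", "b"], 1L) # first record (P1) kept
})

test_that("half-weight index matches hand-computed values", {
  # dyad a-b: 3 years together, 1 apart, 2 with only a seen -> 3/(3+1+1) = 0.6
  recs <- dplyr::bind_rows(
    make_records(c("a", "b"), 2001, c("X1", "X1")),
    make_records(c("a", "b"), 2002, c("X2", "X2")),
    make_records(c("a", "b"), 2003, c("X3", "X3")),
    make_records(c("a", "b"), 2004, c("X4", "X5")),
    make_records("a", 2005, "X6"),
    make_records("a", 2006, "X7"))
  h <- half_weight_index(recs, 2001:2006)
  expect_equal(as.matrix(h)["a", "b"], 0.6)

  # always together -> 1; never together -> 0
  always <- dplyr::bind_rows(lapply(1:4, function(y)
    make_records(c("a", "b"), 2000 + y, rep(sprintf("T%d", y), 2))))
  expect_equal(as.matrix(half_weight_index(always, 2001:2004))["a", "b"], 1)
  never <- dplyr::bind_rows(lapply(1:5, function(y)
    make_records(c("a", "b"), 2000 + y, c(sprintf("A%d", y), sprintf("B%d", y)))))
  expect_equal(as.matrix(half_weight_index(never, 2001:2005))["a", "b"], 0)
})

test_that("half-weight index equals the exhaustive per-dyad oracle on random data", {
  withr::local_seed(7)
  for (rep in 1:5) {
    recs <- random_records(10, 2001:2010, n_patches = 3, p_obs = 0.6)
    h <- half_weight_index(recs, 2001:2010)
    ids <- h$individuals
    for (a in seq_along(ids)) {
      for (b in seq_len(a - 1L)) {
        expect_equal(as.matrix(h)[ids[a], ids[b]],
                     hwi_oracle(recs, 2001:2010, ids[a], ids[b]),
                     tolerance = 1e-12)
      }
    }
    expect_true(all(as.matrix(h) >= 0 & as.matrix(h) <= 1, na.rm = TRUE))
  }
})

test_that("edge export keeps exactly the linked dyads", {
  recs <- make_records(c("a", "b", "c"), 2002, c("P1", "P1", "P2"))
  s <- build_sociomatrix(recs, 2002)
  edges <- export_edges(s)
  expect_equal(nrow(edges), 1)
  expect_setequal(c(edges$source, edges$target), c("a", "b"))
  expect_equal(edges$weight, 1)

  # min_weight = 1 on an HWI keeps only never-apart pairs
  recs2 <- dplyr::bind_rows(
    make_records(c("a", "b", "c"), 2002, c("P1", "P1", "P1")),
    make_records(c("a", "b", "c"), 2003, c("P2", "P2", "P3")))
  h <- half_weight_index(recs2, 2002:2003)
  strict <- export_edges(h, min_weight = 1)
  expect_equal(nrow(strict), 1)
  expect_setequal(c(strict$source, strict$target), c("a", "b"))

  # empty record set -> empty matrix (with warning) -> empty edge list
  empty <- suppressWarnings(
    build_sociomatrix(make_records(character(0), integer(0), character(0)), 2002))
  expect_equal(nrow(export_edges(empty)), 0)
})

test_that("graphml export round-trips nodes and weighted edges", {
  recs <- make_records(c("a", "b", "c", "d"), 2002, c("P1", "P1", "P2", "P2"))
  edges <- export_edges(build_sociomatrix(recs, 2002))
  path <- tempfile(fileext = ".graphml")
  write_graphml(edges, path, individuals = c("a", "b", "c", "d", "e"))
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 2)
})
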