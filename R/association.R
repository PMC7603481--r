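#' @noRd
STATE_LEVELS <- c("together", "apart", "missing")

validate_resightings <- function(records, strict = TRUE) {
  needed <- c("individual_id", "year", "patch_id")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    abort(sprintf("resighting table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  records <- tibble::as_tibble(records)
  records$individual_id <- as.character(records$individual_id)
  records$year <- as.integer(records$year)
  records$patch_id <- as.character(records$patch_id)
  dup <- records %>%
    distinct(.data$individual_id, .data$year, .data$patch_id) %>%
    count(.data$individual_id, .data$year) %>%
    filter(n > 1L)
  if (nrow(dup) > 0L) {
    who <- paste(head(paste0(dup$individual_id, "/", dup$year), 5L),
                 collapse = ", ")
    if (strict) {
      abort(sprintf(
        "%d individual-year(s) recorded in more than one patch (e.g. %s); an individual breeds in exactly one patch per year. Use strict = FALSE to keep the first record.",
        nrow(dup), who))
    }
    warn(sprintf("keeping the first patch for %d ambiguous individual-year(s) (e.g. %s)",
                 nrow(dup), who))
  }
  records %>%
    distinct(.data$individual_id, .data$year, .keep_all = TRUE)
}

#' Dyadic association state for one year
#'
#' A dyad is `together` in a year when both individuals were recorded
#' breeding in the same patch that year, `apart` when both were recorded
#' but in different patches, and `missing` when either lacks a confirmed
#' breeding record that year (missed individuals are missing data, not
#' evidence of being apart).
#'
#' @param records Resighting tibble (`individual_id`, `year`, `patch_id`).
#' @param i,j Individual ids (must differ).
#' @param year Breeding season.
#' @return One of `"together"`, `"apart"`, `"missing"`.
#' @examples
#' recs <- tibble::tibble(individual_id = c("a", "b"), year = 2004,
#'                        patch_id = c("P7", "P7"))
#' dyad_year_state(recs, "a", "b", 2004)
#' @export
dyad_year_state <- function(records, i, j, year) {
  if (identical(i, j)) abort("`i` and `j` must be distinct individuals.")
  records <- validate_resightings(records)
  yr <- records[records$year == year, ]
  pi <- yr$patch_id[yr$individual_id == i]
  pj <- yr$patch_id[yr$individual_id == j]
  if (length(pi) == 0L || length(pj) == 0L) return("missing")
  if (pi == pj) "together" else "apart"
}

# Accumulate per-dyad year counts over a period on the full individual set.
# Returns N x N integer matrices: together, both-but-apart, exactly-one-seen.
dyad_year_counts <- function(records, years, individuals) {
  n <- length(individuals)
  X <- Yab <- Yone <- matrix(0L, n, n, dimnames = list(individuals, individuals))
  for (yr in years) {
    ydat <- records[records$year == yr, ]
    if (nrow(ydat) == 0L) next
    idx <- match(ydat$individual_id, individuals)
    keep <- !is.na(idx)
    idx <- idx[keep]
    if (length(idx) == 0L) next
    patch <- ydat$patch_id[keep]
    same <- outer(patch, patch, "==")
    X[idx, idx] <- X[idx, idx] + same
    Yab[idx, idx] <- Yab[idx, idx] + !same
    seen <- integer(n)
    seen[idx] <- 1L
    one <- outer(seen, seen, "+") == 1L
    Yone <- Yone + one
  }
  diag(X) <- diag(Yab) <- diag(Yone) <- 0L
  list(together = X, apart = Yab, one_seen = Yone)
}

#' Build a period-level sociomatrix
#'
#' For a set of years, each dyad's period state is `together` if the pair
#' bred in the same patch in at least one year of the period, otherwise
#' `apart` if the pair was recorded in different patches in at least one
#' year, otherwise `missing` (the pair never co-occurred in an observed
#' year). The precedence together > apart > missing encodes "bred in the
#' same patch at least once in the period". The matrix is symmetric and
#' undirected; the diagonal is undefined.
#'
#' @param records Resighting tibble.
#' @param years Years defining the period (non-empty).
#' @param individuals Optional id vector fixing the node set and order;
#'   defaults to the individuals observed in `years`, sorted. Ids with no
#'   record in the period appear as all-missing rows.
#' @param strict Reject (TRUE, default) or keep-first-with-warning (FALSE)
#'   individual-years recorded in more than one patch.
#' @return An object of class `sociomatrix`: list with `individuals`,
#'   `state` (N x N integer matrix, 1 = together, 0 = apart, NA = missing)
#'   and `years`.
#' @examples
#' recs <- tibble::tibble(
#'   individual_id = c("a", "b", "a", "b"), year = c(2002, 2002, 2003, 2003),
#'   patch_id = c("P1", "P2", "P3", "P3"))
#' build_sociomatrix(recs, 2002:2003)
#' @export
build_sociomatrix <- function(records, years, individuals = NULL, strict = TRUE) {
  if (length(years) == 0L) abort("`years` must be non-empty.")
  records <- validate_resightings(records, strict = strict)
  records <- records[records$year %in% years, , drop = FALSE]
  if (is.null(individuals)) {
    individuals <- sort(unique(records$individual_id))
  } else {
    individuals <- as.character(individuals)
    if (anyDuplicated(individuals)) abort("`individuals` must be unique.")
  }
  if (nrow(records) == 0L) {
    warn("no resightings in the requested years; sociomatrix is empty/all-missing")
  }
  cnt <- dyad_year_counts(records, years, individuals)
  state <- matrix(NA_integer_, length(individuals), length(individuals),
                  dimnames = list(individuals, individuals))
  both <- (cnt$together + cnt$apart) > 0L
  state[both] <- 0L
  state[cnt$together > 0L] <- 1L
  diag(state) <- NA_integer_
  structure(list(individuals = individuals, state = state,
                 years = sort(unique(as.integer(years)))),
            class = "sociomatrix")
}

#' @export
print.sociomatrix <- function(x, ...) {
  st <- x$state[upper.tri(x$state)]
  cat(sprintf("<sociomatrix> %d individuals, years %s\n",
              length(x$individuals),
              paste(range(x$years), collapse = "-")))
  cat(sprintf("  dyads: %d together, %d apart, %d missing\n",
              sum(st == 1L, na.rm = TRUE), sum(st == 0L, na.rm = TRUE),
              sum(is.na(st))))
  invisible(x)
}

#' @export
as.matrix.sociomatrix <- function(x, ...) x$state

#' @rdname build_sociomatrix
#' @param x A `sociomatrix`.
#' @param ... Unused.
#' @export
tidy.sociomatrix <- function(x, ...) {
  ut <- which(upper.tri(x$state), arr.ind = TRUE)
  st <- x$state[ut]
  tibble::tibble(
    i = x$individuals[ut[, 1L]],
    j = x$individuals[ut[, 2L]],
    state = factor(ifelse(is.na(st), "missing",
                          ifelse(st == 1L, "together", "apart")),
                   levels = STATE_LEVELS)
  )
}

sociomatrix_upper <- function(x) x$state[upper.tri(x$state)]

#' Half-weight association index
#'
#' For each dyad, over the years of the period in which at least one of the
#' two was observed, let `x` be the number of years both bred in the same
#' patch, `y_ab` the years both were recorded in different patches, and
#' `y_a`, `y_b` the years in which only one of the two was observed. The
#' half-weight index is `x / (x + y_ab + 0.5 * (y_a + y_b))`, an
#' association measure that down-weights occasions with incomplete
#' identification and is therefore suited to resighting data where not
#' every group member is detected. One breeding season is one sampling
#' occasion. Dyads never observed in any common frame (denominator zero)
#' are undefined (`NA`).
#'
#' @inheritParams build_sociomatrix
#' @return An object of class `hwi_matrix`: list with `individuals`,
#'   `hwi` (symmetric numeric matrix in `[0, 1]`, `NA` where undefined)
#'   and `years`.
#' @examples
#' recs <- tibble::tibble(
#'   individual_id = rep(c("a", "b"), 3), year = rep(2002:2004, each = 2),
#'   patch_id = c("P1", "P1", "P2", "P3", "P4", "P4"))
#' half_weight_index(recs, 2002:2004)
#' @export
half_weight_index <- function(records, years, individuals = NULL, strict = TRUE) {
  if (length(years) == 0L) abort("`years` must be non-empty.")
  records <- validate_resightings(records, strict = strict)
  records <- records[records$year %in% years, , drop = FALSE]
  if (is.null(individuals)) individuals <- sort(unique(records$individual_id))
  cnt <- dyad_year_counts(records, years, as.character(individuals))
  denom <- cnt$together + cnt$apart + 0.5 * cnt$one_seen
  hwi <- ifelse(denom > 0, cnt$together / denom, NA_real_)
  diag(hwi) <- NA_real_
  structure(list(individuals = as.character(individuals), hwi = hwi,
                 years = sort(unique(as.integer(years)))),
            class = "hwi_matrix")
}

#' @export
print.hwi_matrix <- function(x, ...) {
  v <- x$hwi[upper.tri(x$hwi)]
  cat(sprintf("<hwi_matrix> %d individuals, %d defined dyads, mean HWI %.3f\n",
              length(x$individuals), sum(!is.na(v)), mean(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.matrix.hwi_matrix <- function(x, ...) x$hwi

#' @rdname half_weight_index
#' @param x An `hwi_matrix`.
#' @param ... Unused.
#' @export
tidy.hwi_matrix <- function(x, ...) {
  ut <- which(upper.tri(x$hwi), arr.ind = TRUE)
  tibble::tibble(i = x$individuals[ut[, 1L]],
                 j = x$individuals[ut[, 2L]],
                 hwi = x$hwi[ut])
}

#' Export network edges from a sociomatrix or HWI matrix
#'
#' One row per linked dyad: for a [build_sociomatrix()] result every
#' `together` dyad becomes an edge of weight 1; for a
#' [half_weight_index()] result every dyad with a defined index
#' `>= min_weight` becomes an edge weighted by its index.
#'
#' @param x A `sociomatrix` or `hwi_matrix`.
#' @param min_weight Minimum weight for an edge to be exported (HWI
#'   matrices only; must be > 0 so never-together dyads are excluded).
#' @return A tibble with columns `source`, `target`, `weight`.
#' @examples
#' recs <- tibble::tibble(individual_id = c("a", "b"), year = 2002,
#'                        patch_id = c("P1", "P1"))
#' export_edges(build_sociomatrix(recs, 2002))
#' @export
export_edges <- function(x, min_weight = 1e-9) {
  if (min_weight <= 0) abort("`min_weight` must be > 0.")
  if (inherits(x, "sociomatrix")) {
    edges <- tidy(x) %>%
      filter(.data$state == "together") %>%
      mutate(weight = 1) %>%
      select(source = "i", target = "j", "weight")
  } else if (inherits(x, "hwi_matrix")) {
    edges <- tidy(x) %>%
      filter(!is.na(.data$hwi), .data$hwi >= min_weight) %>%
      select(source = "i", target = "j", weight = "hwi")
  } else {
    abort("`x` must be a sociomatrix or hwi_matrix.")
  }
  edges
}

#' Write an edge list as GraphML
#'
#' @param edges Edge tibble from [export_edges()].
#' @param path Output file path.
#' @param individuals Optional full node set, so isolated individuals are
#'   retained as nodes.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(edges, path, individuals = NULL) {
  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = FALSE,
                                     vertices = individuals)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
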