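#' Construct an age-period-cohort design lattice
#'
#' Builds the Lexis-type lattice underlying an APC analysis with unequal
#' interval widths: age groups of width `age_step` (default 5 years),
#' survey periods `period_step` years apart (default 3), and birth cohorts
#' on a 1-year grid. Because cohorts shift by one calendar year while age
#' groups span five, consecutive cohorts overlap; a 12 x 6 lattice of
#' 5-year ages and 3-yearly periods spans `K = 5*11 + 3*5 + 1 = 71`
#' cohorts, only some of which are hit by an observed cell.
#'
#' Indexing convention (used throughout the package): `i = 1` is the
#' youngest age group, `j = 1` the earliest period, and `k = 1` the oldest
#' cohort (the oldest age group in the earliest period). The cohort index
#' of cell `(i, j)` is
#' `k(i, j) = age_step * (I - i) + period_step * (j - 1) + 1`.
#'
#' @param age_starts Integer vector of age-group start years (e.g.
#'   `seq(20, 75, by = 5)`), strictly increasing with a constant step.
#' @param period_years Integer vector of survey calendar years (e.g.
#'   `seq(2004, 2019, by = 3)`), strictly increasing with a constant step.
#' @param cohort_step Width of the cohort grid in years; fixed default 1.
#'
#' @return An object of class `apc_grid`: a list with elements
#'   `age_starts`, `period_years`, `I`, `J`, `K`, `age_step`,
#'   `period_step`, `cohort_step`, `oldest_cohort_start` (calendar year of
#'   the oldest birth cohort's first birth year), `cohort_of_cell` (an
#'   `I x J` integer matrix mapping cell to cohort index) and
#'   `observed_cohorts` (sorted unique cohort indices hit by some cell).
#'
#' @examples
#' g <- apc_grid(seq(20, 75, 5), seq(2004, 2019, 3))
#' g$K                       # 71
#' g$cohort_of_cell[12, 1]   # oldest cohort, index 1
#' cohort_label(g, 1)        # "1925-1929"
#' @export
apc_grid <- function(age_starts, period_years, cohort_step = 1L) {
  age_starts <- as.integer(age_starts)
  period_years <- as.integer(period_years)
  if (length(age_starts) < 1L || length(period_years) < 1L)
    stop("need at least one age group and one period", call. = FALSE)
  age_step <- check_constant_step(age_starts, "age_starts")
  period_step <- check_constant_step(period_years, "period_years")
  I <- length(age_starts)
  J <- length(period_years)
  K <- as.integer(age_step * (I - 1L) + period_step * (J - 1L) + 1L)

  i_idx <- matrix(seq_len(I), I, J)
  j_idx <- matrix(rep(seq_len(J), each = I), I, J)
  cohort_of_cell <- matrix(
    as.integer(age_step * (I - i_idx) + period_step * (j_idx - 1L) + 1L),
    I, J
  )
  # birth year of the oldest member of the oldest cohort:
  # oldest age group in the first period
  oldest_cohort_start <- period_years[1L] - age_starts[I] - (age_step - 1L)

  structure(
    list(
      age_starts = age_starts,
      period_years = period_years,
      I = I, J = J, K = K,
      age_step = as.integer(age_step),
      period_step = as.integer(period_step),
      cohort_step = as.integer(cohort_step),
      oldest_cohort_start = as.integer(oldest_cohort_start),
      cohort_of_cell = cohort_of_cell,
      observed_cohorts = sort(unique(as.vector(cohort_of_cell)))
    ),
    class = "apc_grid"
  )
}

check_constant_step <- function(x, what) {
  if (length(x) == 1L) return(1L)
  d <- diff(x)
  if (any(d <= 0L)) stop(what, " must be strictly increasing", call. = FALSE)
  if (length(unique(d)) != 1L)
    stop(what, " must have a constant step, got steps ",
         paste(unique(d), collapse = ", "), call. = FALSE)
  d[1L]
}

#' Birth-year range label of a cohort
#'
#' Cohort `k` collects people born between
#' `oldest_cohort_start + (k - 1) * cohort_step` and that year plus
#' `age_step - 1`; on the default 1-year cohort grid with 5-year age
#' groups, consecutive cohorts overlap by four birth years.
#'
#' @param grid An [apc_grid].
#' @param k Cohort index (or vector of indices) in `1..K`.
#' @return Character vector of labels such as `"1925-1929"`.
#' @examples
#' g <- apc_grid(seq(20, 75, 5), seq(2004, 2019, 3))
#' cohort_label(g, c(1, 2, 71))
#' @export
cohort_label <- function(grid, k) {
  stopifnot(inherits(grid, "apc_grid"))
  k <- as.integer(k)
  if (any(k < 1L | k > grid$K))
    stop("cohort index out of range 1..", grid$K, call. = FALSE)
  start <- grid$oldest_cohort_start + (k - 1L) * grid$cohort_step
  paste0(start, "-", start + grid$age_step - 1L)
}

#' The 12 x 6 smoking-survey lattice
#'
#' Convenience constructor for the lattice used by the national
#' smoking-prevalence analyses shipped with the package: age groups
#' 20-24 through 75-79 (I = 12) and 3-yearly survey waves 2004 through
#' 2019 (J = 6), giving K = 71 birth cohorts (1925-1929 ... 1995-1999),
#' of which 63 are observed in at least one cell.
#'
#' @return An [apc_grid].
#' @export
smoking_survey_grid <- function() {
  apc_grid(seq(20L, 75L, by = 5L), seq(2004L, 2019L, by = 3L))
}

#' @export
print.apc_grid <- function(x, ...) {
  cat("APC design lattice\n")
  cat(sprintf("  age groups : %d (%d-%d ... %d-%d, step %d)\n",
              x$I, x$age_starts[1], x$age_starts[1] + x$age_step - 1,
              x$age_starts[x$I], x$age_starts[x$I] + x$age_step - 1,
              x$age_step))
  cat(sprintf("  periods    : %d (%d ... %d, step %d)\n",
              x$J, x$period_years[1], x$period_years[x$J], x$period_step))
  cat(sprintf("  cohorts    : %d on a %d-year grid (%s ... %s), %d observed\n",
              x$K, x$cohort_step, cohort_label(x, 1), cohort_label(x, x$K),
              length(x$observed_cohorts)))
  invisible(x)
}

#' Flatten a grid to a per-cell audit table
#'
#' One row per lattice cell with its age-group start, period year, cohort
#' index and cohort birth-year label, suitable for writing to CSV.
#'
#' @param x An [apc_grid].
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return A `data.frame` with columns `cell`, `age_index`,
#'   `period_index`, `age_start`, `period_year`, `cohort_index`,
#'   `cohort_label`, in column-major cell order (age fastest).
#' @export
as.data.frame.apc_grid <- function(x, row.names = NULL, optional = FALSE, ...) {
  i <- rep(seq_len(x$I), times = x$J)
  j <- rep(seq_len(x$J), each = x$I)
  k <- as.vector(x$cohort_of_cell)
  data.frame(
    cell = seq_along(i),
    age_index = i,
    period_index = j,
    age_start = x$age_starts[i],
    period_year = x$period_years[j],
    cohort_index = k,
    cohort_label = cohort_label(x, k),
    stringsAsFactors = FALSE
  )
}

# internal: per-cell index vectors in column-major order (age fastest)
grid_cells <- function(grid) {
  list(
    i = rep(seq_len(grid$I), times = grid$J),
    j = rep(seq_len(grid$J), each = grid$I),
    k = as.vector(grid$cohort_of_cell)
  )
}
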