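#' Stratified prevalence count table
#'
#' Container for the binomial counts an APC model consumes: smoker counts
#' `y[i, j]` and denominators `n[i, j]` on a complete age-group x
#' survey-year lattice for a single stratum (e.g. "men/urban").
#'
#' @param age_groups Integer vector of age-group start years, strictly
#'   increasing with constant step (5-year groups in the shipped data).
#' @param periods Integer vector of survey years, strictly increasing
#'   with constant step (3-yearly waves in the shipped data).
#' @param smokers `I x J` matrix of non-negative integer smoker counts
#'   (rows = age groups, columns = periods).
#' @param denominators `I x J` matrix of positive integer denominators.
#' @param stratum_label Free-text stratum identifier, e.g. `"men/urban"`.
#'
#' @return An object of class `prevalence_table`.
#' @examples
#' tab <- prevalence_table(
#'   age_groups = c(20, 25), periods = c(2004, 2007),
#'   smokers = matrix(c(448, 467, 409, 462), 2, 2),
#'   denominators = matrix(1000, 2, 2),
#'   stratum_label = "men/urban"
#' )
#' observed_prevalence(tab)
#' @export
prevalence_table <- function(age_groups, periods, smokers, denominators,
                             stratum_label = "") {
  age_groups <- as.integer(age_groups)
  periods <- as.integer(periods)
  smokers <- as.matrix(smokers)
  denominators <- as.matrix(denominators)
  I <- length(age_groups)
  J <- length(periods)
  if (!all(dim(smokers) == c(I, J)) || !all(dim(denominators) == c(I, J)))
    stop("smokers and denominators must be ", I, " x ", J, " matrices",
         call. = FALSE)
  check_constant_step(age_groups, "age_groups")
  check_constant_step(periods, "periods")
  if (anyNA(smokers) || anyNA(denominators))
    stop("prevalence table has missing cells", call. = FALSE)
  if (any(denominators <= 0))
    stop("denominators must be positive", call. = FALSE)
  if (any(smokers < 0))
    stop("smoker counts must be non-negative", call. = FALSE)
  if (any(smokers > denominators))
    stop("smoker count exceeds denominator in ",
         sum(smokers > denominators), " cell(s)", call. = FALSE)
  storage.mode(smokers) <- "integer"
  storage.mode(denominators) <- "integer"
  dimnames(smokers) <- dimnames(denominators) <-
    list(age_group_label(age_groups), periods)
  structure(
    list(
      stratum_label = as.character(stratum_label),
      age_groups = age_groups,
      periods = periods,
      smokers = smokers,
      denominators = denominators
    ),
    class = "prevalence_table"
  )
}

age_group_label <- function(starts) {
  step <- if (length(starts) > 1L) diff(starts)[1L] else 5L
  paste0(starts, "-", starts + step - 1L)
}

#' Read a prevalence table from CSV
#'
#' The CSV must have a header and columns `age_group` (either the start
#' year or an `"A-B"` range label), `year`, a denominator column
#' `denominator`, and either a count column `smokers` or a percentage
#' column `prevalence_pct`. When only percentages are given, counts are
#' recovered as `round(prevalence_pct / 100 * denominator)` with
#' half-away-from-zero rounding; survey publications typically print
#' prevalences, while the binomial model needs integer counts.
#' Every (age group, year) combination must be present exactly once.
#'
#' @param path Path to a CSV file (comma-separated, header row, UTF-8).
#' @param stratum_label Stratum identifier stored on the table.
#' @return A [prevalence_table].
#' @export
read_prevalence_table <- function(path, stratum_label = "") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("age_group", "year", "denominator")
  if (!all(need %in% names(df)))
    stop("CSV must have columns age_group, year, denominator and ",
         "either smokers or prevalence_pct", call. = FALSE)
  prevalence_table_from_df(df, stratum_label)
}

prevalence_table_from_df <- function(df, stratum_label = "") {
  age_start <- parse_age_group(df$age_group)
  ages <- sort(unique(age_start))
  years <- sort(unique(as.integer(df$year)))
  I <- length(ages)
  J <- length(years)
  if (nrow(df) != I * J)
    stop("incomplete lattice: expected ", I * J, " rows (", I,
         " age groups x ", J, " years), got ", nrow(df), call. = FALSE)
  key <- paste(age_start, df$year)
  if (anyDuplicated(key))
    stop("duplicate (age_group, year) rows in input", call. = FALSE)

  if ("smokers" %in% names(df)) {
    y <- as.numeric(df$smokers)
  } else if ("prevalence_pct" %in% names(df)) {
    pct <- as.numeric(df$prevalence_pct)
    if (any(!is.finite(pct)) || any(pct < 0 | pct > 100))
      stop("prevalence_pct must lie in [0, 100]", call. = FALSE)
    y <- round_half_away(pct / 100 * as.numeric(df$denominator))
  } else {
    stop("CSV must have a smokers or prevalence_pct column", call. = FALSE)
  }

  ii <- match(age_start, ages)
  jj <- match(as.integer(df$year), years)
  ym <- matrix(NA_real_, I, J)
  nm <- matrix(NA_real_, I, J)
  ym[cbind(ii, jj)] <- y
  nm[cbind(ii, jj)] <- as.numeric(df$denominator)
  if (anyNA(ym) || anyNA(nm))
    stop("incomplete lattice: some (age_group, year) cells are missing",
         call. = FALSE)
  prevalence_table(ages, years, ym, nm, stratum_label)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

parse_age_group <- function(x) {
  x <- as.character(x)
  start <- sub("[-+].*$", "", trimws(x))
  out <- suppressWarnings(as.integer(start))
  if (anyNA(out))
    stop("cannot parse age_group values: ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Write a prevalence table to CSV
#'
#' Inverse of [read_prevalence_table()]: writes one row per cell with
#' columns `age_group`, `year`, `smokers`, `denominator`.
#'
#' @param table A [prevalence_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_prevalence_table <- function(table, path) {
  stopifnot(inherits(table, "prevalence_table"))
  i <- rep(seq_along(table$age_groups), times = length(table$periods))
  j <- rep(seq_along(table$periods), each = length(table$age_groups))
  df <- data.frame(
    age_group = age_group_label(table$age_groups)[i],
    year = table$periods[j],
    smokers = as.vector(table$smokers),
    denominator = as.vector(table$denominators)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive a non-urban table by national-minus-urban subtraction
#'
#' National survey releases often publish totals and an urban stratum
#' only; the complementary stratum is recovered by cell-wise subtraction
#' of both numerators and denominators.
#'
#' @param national,urban [prevalence_table]s on identical lattices, with
#'   national counts at least as large as urban counts in every cell.
#' @param stratum_label Label for the derived table.
#' @return A [prevalence_table] of cell-wise differences.
#' @export
derive_nonurban <- function(national, urban, stratum_label = "non-urban") {
  stopifnot(inherits(national, "prevalence_table"),
            inherits(urban, "prevalence_table"))
  if (!identical(national$age_groups, urban$age_groups) ||
      !identical(national$periods, urban$periods))
    stop("national and urban tables must share the same lattice",
         call. = FALSE)
  y <- national$smokers - urban$smokers
  n <- national$denominators - urban$denominators
  if (any(y < 0) || any(n < 0))
    stop("urban counts exceed national counts in some cell: ",
         "strata are inconsistent", call. = FALSE)
  if (any(n == 0))
    stop("national and urban denominators are equal in some cell: ",
         "derived stratum would be empty", call. = FALSE)
  prevalence_table(national$age_groups, national$periods, y, n,
                   stratum_label)
}

#' Observed cell prevalences
#'
#' @param table A [prevalence_table].
#' @return `I x J` matrix of proportions `y / n` in `[0, 1]`.
#' @export
observed_prevalence <- function(table) {
  stopifnot(inherits(table, "prevalence_table"))
  table$smokers / table$denominators
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat(sprintf("Prevalence table [%s]: %d age groups x %d periods\n",
              if (nzchar(x$stratum_label)) x$stratum_label else "unlabelled",
              length(x$age_groups), length(x$periods)))
  cat("Observed prevalence (%):\n")
  print(round(100 * observed_prevalence(x), 1))
  invisible(x)
}

#' Bundled smoking-prevalence tables
#'
#' Loads one of the four strata of the packaged Japanese
#' smoking-prevalence fixture (men/women x urban/non-urban; 12 age groups
#' 20-24..75-79, survey years 2004..2019). The source publishes
#' percentages, not counts, and does not print the estimated
#' household-member denominators, so counts are reconstructed against a
#' user-chosen constant per-cell denominator (default 10,000); this
#' preserves the printed prevalences while keeping the fixture
#' self-contained.
#'
#' @param gender `"men"` or `"women"`.
#' @param area `"urban"` or `"nonurban"`.
#' @param denominator Constant per-cell denominator.
#' @return A [prevalence_table].
#' @export
smoking_survey_table <- function(gender = c("men", "women"),
                                 area = c("urban", "nonurban"),
                                 denominator = 10000L) {
  gender <- match.arg(gender)
  area <- match.arg(area)
  path <- system.file("extdata",
                      paste0("smoking_", gender, "_", area, ".csv"),
                      package = "prevapc", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$denominator <- as.integer(denominator)
  prevalence_table_from_df(df, paste0(gender, "/", area))
}
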