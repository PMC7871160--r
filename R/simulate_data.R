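#' Generate ground-truth APC parameters for simulation
#'
#' Produces a known parameter point shaped like national smoking-
#' prevalence surfaces: age and period effects decline linearly on the
#' log-odds scale, the cohort effect is a unimodal (quadratic-peak)
#' bump that rises and then falls across birth cohorts, and cell
#' heterogeneity is iid normal noise. All effect curves are centred to
#' sum to zero after scaling, so the truth lives in the same gauge the
#' model reports. Deterministic parametric curves are the default so
#' recovery tests are reproducible and interpretable;
#' `curves = "rw1"` draws the effect vectors from their RW1 prior
#' instead.
#'
#' Default magnitudes are chosen to look like a men's smoking stratum:
#' baseline prevalence 35%, an age decline spanning about 1.5 log-odds
#' units from youngest to oldest, a period decline of about 0.6, a
#' cohort bump of amplitude about 0.6, and cell noise SD 0.05 — all on
#' the log-odds scale, scaled jointly by `effect_scale`.
#'
#' @param grid An [apc_grid].
#' @param scenario Which effects are non-zero: `"null"` (intercept
#'   only), `"age_only"`, `"age_period"`, `"age_cohort"` or `"full"`.
#' @param effect_scale Non-negative multiplier on all effect curves
#'   (default 1).
#' @param heterogeneity_sd SD of the iid cell-level noise `z` (log-odds
#'   scale, default 0.05).
#' @param baseline_prevalence Overall prevalence mapped to the intercept
#'   via `qlogis` (default 0.35).
#' @param denominators Per-cell denominator (scalar or I x J matrix;
#'   default 10,000 per cell).
#' @param curves `"parametric"` (deterministic shapes, default) or
#'   `"rw1"` (random-walk draws scaled to comparable magnitude).
#' @param seed Integer seed (drives `z`, and the walks under
#'   `curves = "rw1"`).
#' @return An object of class `apc_truth`: list with `params`
#'   ([apc_parameters]), `grid`, `denominators` (I x J), `prob`
#'   (true cell prevalences), `scenario` and `seed`.
#' @examples
#' tr <- simulate_truth(smoking_survey_grid(), "full", seed = 42)
#' range(tr$prob)
#' @export
simulate_truth <- function(grid,
                           scenario = c("full", "null", "age_only",
                                        "age_period", "age_cohort"),
                           effect_scale = 1,
                           heterogeneity_sd = 0.05,
                           baseline_prevalence = 0.35,
                           denominators = 10000L,
                           curves = c("parametric", "rw1"),
                           seed = 1) {
  stopifnot(inherits(grid, "apc_grid"))
  scenario <- match.arg(scenario)
  curves <- match.arg(curves)
  if (effect_scale < 0) stop("effect_scale must be >= 0", call. = FALSE)
  if (heterogeneity_sd < 0) stop("heterogeneity_sd must be >= 0", call. = FALSE)
  set.seed(seed)

  ctr <- function(x) x - mean(x)
  lin_decline <- function(len, range) {
    if (len == 1L) return(0)
    ctr(seq(range / 2, -range / 2, length.out = len))
  }
  bump <- function(len, amp) {
    if (len == 1L) return(0)
    t <- seq(0, 1, length.out = len)
    ctr(amp * (1 - (2 * t - 1)^2))  # peak mid-range, falls at both ends
  }
  rw <- function(len, target_sd) {
    if (len == 1L) return(0)
    w <- cumsum(stats::rnorm(len, 0, 1))
    s <- stats::sd(w)
    ctr(if (s > 0) w * target_sd / s else w)
  }

  use_period <- scenario %in% c("age_period", "full")
  use_cohort <- scenario %in% c("age_cohort", "full")
  use_age <- scenario != "null"

  if (curves == "parametric") {
    alpha <- if (use_age) effect_scale * lin_decline(grid$I, 1.5) else
      rep(0, grid$I)
    beta <- if (use_period) effect_scale * lin_decline(grid$J, 0.6) else
      rep(0, grid$J)
    gamma <- if (use_cohort) effect_scale * bump(grid$K, 0.6) else
      rep(0, grid$K)
  } else {
    alpha <- if (use_age) rw(grid$I, 0.45 * effect_scale) else rep(0, grid$I)
    beta <- if (use_period) rw(grid$J, 0.2 * effect_scale) else rep(0, grid$J)
    gamma <- if (use_cohort) rw(grid$K, 0.2 * effect_scale) else rep(0, grid$K)
  }
  z <- matrix(stats::rnorm(grid$I * grid$J, 0, heterogeneity_sd),
              grid$I, grid$J)
  params <- apc_parameters(
    grid,
    delta = stats::qlogis(baseline_prevalence),
    alpha = alpha, beta = beta, gamma = gamma, z = z,
    sigma = c(age = safe_sd(diff(alpha)),
              period = safe_sd(diff(beta)),
              cohort = safe_sd(diff(gamma)),
              z = max(heterogeneity_sd, 1e-3))
  )
  nmat <- matrix(as.integer(denominators), grid$I, grid$J)
  if (any(nmat <= 0)) stop("denominators must be positive", call. = FALSE)
  structure(
    list(params = params, grid = grid, denominators = nmat,
         prob = linear_predictor(params, grid, type = "response"),
         scenario = scenario, seed = as.integer(seed)),
    class = "apc_truth"
  )
}

# SD that stays positive and finite on short (length < 2) inputs
safe_sd <- function(x, floor = 1e-3) {
  s <- stats::sd(x)
  if (!is.finite(s)) floor else max(s, floor)
}

#' @export
print.apc_truth <- function(x, ...) {
  cat(sprintf("Synthetic APC truth [%s]: %d x %d lattice, seed %d\n",
              x$scenario, x$grid$I, x$grid$J, x$seed))
  cat(sprintf("  true prevalence range: %.3f .. %.3f\n",
              min(x$prob), max(x$prob)))
  invisible(x)
}

#' Draw a binomial survey table from a ground truth
#'
#' Cell counts are `y[i,j] ~ Binomial(n[i,j], p[i,j])` at the truth's
#' probabilities and denominators. The truth's stored seed (offset so
#' the counts are independent of the noise used to build the truth)
#' makes repeated generation reproducible.
#'
#' @param truth An [simulate_truth()] result.
#' @param stratum_label Label for the generated table.
#' @return A [prevalence_table].
#' @export
simulate_prevalence_table <- function(truth, stratum_label = "synthetic") {
  stopifnot(inherits(truth, "apc_truth"))
  set.seed(truth$seed + 500000L)
  n <- truth$denominators
  y <- matrix(stats::rbinom(length(n), as.vector(n), as.vector(truth$prob)),
              truth$grid$I, truth$grid$J)
  prevalence_table(truth$grid$age_starts, truth$grid$period_years,
                   y, n, stratum_label)
}

#' Simulate an urban / non-urban stratum pair
#'
#' Two tables on the same lattice whose period-effect slopes differ: the
#' "urban" stratum's period decline is steeper by `period_gap` log-odds
#' units across the study window, emulating a faster urban decline in
#' prevalence, while age and cohort effects are shared.
#'
#' @param grid An [apc_grid].
#' @param period_gap Extra urban period-decline span (log-odds units,
#'   default 0.3).
#' @param ... Passed to [simulate_truth()] (scenario fixed to `"full"`).
#' @param seed Integer seed.
#' @return List with elements `urban` and `nonurban`, each a list of
#'   `truth` and `table`.
#' @export
simulate_strata_pair <- function(grid, period_gap = 0.3, seed = 1, ...) {
  stopifnot(inherits(grid, "apc_grid"))
  nonurban <- simulate_truth(grid, scenario = "full", seed = seed, ...)
  urban <- simulate_truth(grid, scenario = "full", seed = seed + 1L, ...)
  urban$params$beta <- urban$params$beta +
    (if (grid$J > 1L)
       seq(period_gap / 2, -period_gap / 2, length.out = grid$J) else 0)
  urban$params <- center_effects(urban$params)
  urban$prob <- linear_predictor(urban$params, grid, type = "response")
  list(
    urban = list(truth = urban,
                 table = simulate_prevalence_table(urban, "urban")),
    nonurban = list(truth = nonurban,
                    table = simulate_prevalence_table(nonurban, "nonurban"))
  )
}

#' Write a synthetic truth's parameters as CSV
#'
#' Long-format export (component, index, value) of every generating
#' parameter, for audit alongside the generated table.
#'
#' @param truth An [simulate_truth()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "apc_truth"))
  p <- truth$params
  df <- rbind(
    data.frame(component = "delta", index = 1L, value = p$delta),
    data.frame(component = "alpha", index = seq_along(p$alpha),
               value = p$alpha),
    data.frame(component = "beta", index = seq_along(p$beta),
               value = p$beta),
    data.frame(component = "gamma", index = seq_along(p$gamma),
               value = p$gamma),
    data.frame(component = "z", index = seq_along(as.vector(p$z)),
               value = as.vector(p$z)),
    data.frame(component = paste0("sigma_", names(p$sigma)),
               index = 1L, value = unname(p$sigma))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
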