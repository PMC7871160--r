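#' Specify a binomial APC model
#'
#' The model family for a stratified prevalence table: cell counts are
#' `y[i,j] ~ Binomial(n[i,j], p[i,j])` with log odds
#' `eta[i,j] = delta + alpha[i] + beta[j] + gamma[k(i,j)] + z[i,j]`,
#' where `alpha` are age effects, `beta` period effects, `gamma` cohort
#' effects on the 1-year cohort grid, and `z` a cell-level heterogeneity
#' term absorbing extra-binomial variation. Each included effect vector
#' carries a first-order random-walk (RW1) smoothing prior on its
#' increments; on the cohort axis the walk runs over the full `1..K`
#' grid, so cohorts never hit by an observed cell are interpolated by the
#' prior. Each effect vector is constrained to sum to zero, pushing the
#' overall level into the intercept `delta`.
#'
#' The four standard submodels select which effects enter:
#' age (`"a"`), age-period (`"ap"`), age-cohort (`"ac"`) and the full
#' APC model (`"apc"`). Age is always included.
#'
#' Priors the family does not pin down are weakly informative defaults
#' on the log-odds scale: half-normal(0, `prior_scale_effects`) on each
#' RW1 increment SD, half-normal(0, `prior_scale_heterogeneity`) on the
#' heterogeneity SD, and Normal(0, `prior_scale_intercept`^2) on the
#' intercept.
#'
#' @param model One of `"apc"`, `"ap"`, `"ac"`, `"a"`; alternatively set
#'   `include_period` / `include_cohort` directly.
#' @param include_period,include_cohort Logical effect switches
#'   (derived from `model` when that is given).
#' @param include_heterogeneity Include the cell-level `z` term
#'   (default `TRUE`).
#' @param prior_scale_effects Scale of the half-normal hyperprior on the
#'   RW1 increment SDs (log-odds units, default 1).
#' @param prior_scale_heterogeneity Scale of the half-normal hyperprior
#'   on the heterogeneity SD (default 1).
#' @param prior_scale_intercept SD of the normal prior on the intercept
#'   (default 10).
#' @return An object of class `apc_model_spec`.
#' @examples
#' apc_model_spec("ac")
#' @export
apc_model_spec <- function(model = c("apc", "ap", "ac", "a"),
                           include_period = NULL,
                           include_cohort = NULL,
                           include_heterogeneity = TRUE,
                           prior_scale_effects = 1,
                           prior_scale_heterogeneity = 1,
                           prior_scale_intercept = 10) {
  if (is.null(include_period) || is.null(include_cohort)) {
    model <- match.arg(model)
    include_period <- model %in% c("apc", "ap")
    include_cohort <- model %in% c("apc", "ac")
  }
  if (prior_scale_effects <= 0 || prior_scale_heterogeneity <= 0 ||
      prior_scale_intercept <= 0)
    stop("prior scales must be positive", call. = FALSE)
  structure(
    list(
      include_period = isTRUE(include_period),
      include_cohort = isTRUE(include_cohort),
      include_heterogeneity = isTRUE(include_heterogeneity),
      prior_scale_effects = prior_scale_effects,
      prior_scale_heterogeneity = prior_scale_heterogeneity,
      prior_scale_intercept = prior_scale_intercept
    ),
    class = "apc_model_spec"
  )
}

model_code <- function(spec) {
  paste0("a",
         if (spec$include_period) "p" else "",
         if (spec$include_cohort) "c" else "")
}

#' @export
print.apc_model_spec <- function(x, ...) {
  lab <- switch(model_code(x),
                a = "age", ap = "age-period", ac = "age-cohort",
                apc = "age-period-cohort")
  cat(sprintf("Binomial %s model%s\n", lab,
              if (x$include_heterogeneity) " with cell heterogeneity" else ""))
  cat(sprintf(
    "  hyperprior scales: effects %.3g, heterogeneity %.3g, intercept SD %.3g\n",
    x$prior_scale_effects, x$prior_scale_heterogeneity,
    x$prior_scale_intercept))
  invisible(x)
}

#' Serialize / restore a model specification
#'
#' Writes the specification as `key: value` lines (a minimal YAML
#' subset) so a fitted model's configuration can be stored alongside its
#' outputs, and reads it back.
#'
#' @param spec An [apc_model_spec].
#' @param path File path.
#' @return `write_model_spec` returns `path` invisibly;
#'   `read_model_spec` returns an [apc_model_spec].
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "apc_model_spec"))
  lines <- sprintf("%s: %s", names(unclass(spec)),
                   vapply(unclass(spec), format, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  kv <- read.dcf(path)
  g <- function(key, cast) cast(kv[1, key])
  apc_model_spec(
    include_period = g("include_period", as.logical),
    include_cohort = g("include_cohort", as.logical),
    include_heterogeneity = g("include_heterogeneity", as.logical),
    prior_scale_effects = g("prior_scale_effects", as.numeric),
    prior_scale_heterogeneity = g("prior_scale_heterogeneity", as.numeric),
    prior_scale_intercept = g("prior_scale_intercept", as.numeric)
  )
}

#' Bundle APC model parameters
#'
#' A single parameter point of the model: intercept `delta` (log-odds),
#' effect vectors `alpha` (length I), `beta` (length J), `gamma`
#' (length K, on the full 1-year cohort grid), heterogeneity matrix `z`
#' (I x J) and the standard deviations `sigma` (named: `age`, `period`,
#' `cohort`, `z`). Effects excluded from a submodel are identically
#' zero vectors of the right length.
#'
#' @param delta Intercept (log-odds).
#' @param alpha,beta,gamma Effect vectors; recycled from 0 when omitted.
#' @param z `I x J` heterogeneity matrix, or 0.
#' @param sigma Named numeric vector of SDs; defaults to 1 for each of
#'   `age`, `period`, `cohort`, `z`.
#' @param grid An [apc_grid] supplying the dimensions.
#' @return An object of class `apc_parameters`.
#' @export
apc_parameters <- function(grid, delta = 0, alpha = 0, beta = 0, gamma = 0,
                           z = 0,
                           sigma = c(age = 1, period = 1, cohort = 1, z = 1)) {
  stopifnot(inherits(grid, "apc_grid"))
  expand <- function(x, len, what) {
    if (length(x) == 1L) x <- rep(as.numeric(x), len)
    if (length(x) != len)
      stop(what, " must have length ", len, call. = FALSE)
    as.numeric(x)
  }
  if (length(z) == 1L) z <- matrix(as.numeric(z), grid$I, grid$J)
  z <- as.matrix(z)
  if (!all(dim(z) == c(grid$I, grid$J)))
    stop("z must be an I x J matrix", call. = FALSE)
  sig <- c(age = 1, period = 1, cohort = 1, z = 1)
  sig[names(sigma)] <- sigma
  if (any(sig <= 0)) stop("sigmas must be positive", call. = FALSE)
  structure(
    list(
      delta = as.numeric(delta),
      alpha = expand(alpha, grid$I, "alpha"),
      beta = expand(beta, grid$J, "beta"),
      gamma = expand(gamma, grid$K, "gamma"),
      z = z,
      sigma = sig
    ),
    class = "apc_parameters"
  )
}

#' Cell-wise linear predictor and probabilities
#'
#' Evaluates `eta[i,j] = delta + alpha[i] + beta[j] + gamma[k(i,j)] +
#' z[i,j]` over the lattice. Probabilities are `plogis(eta)`.
#'
#' @param params An [apc_parameters].
#' @param grid The matching [apc_grid].
#' @param type `"link"` for the log-odds `eta`, `"response"` for
#'   probabilities.
#' @return `I x J` numeric matrix.
#' @export
linear_predictor <- function(params, grid, type = c("link", "response")) {
  stopifnot(inherits(params, "apc_parameters"), inherits(grid, "apc_grid"))
  type <- match.arg(type)
  if (length(params$alpha) != grid$I || length(params$beta) != grid$J ||
      length(params$gamma) != grid$K || !all(dim(params$z) == c(grid$I, grid$J)))
    stop("parameter dimensions do not match the grid", call. = FALSE)
  eta <- params$delta +
    matrix(params$alpha, grid$I, grid$J) +
    matrix(params$beta, grid$I, grid$J, byrow = TRUE) +
    matrix(params$gamma[grid$cohort_of_cell], grid$I, grid$J) +
    params$z
  if (type == "response") stats::plogis(eta) else eta
}

#' Log prior density of an APC parameter point
#'
#' Sum of (a) the RW1 increment terms
#' `sum(dnorm(diff(effect), 0, sigma_effect, log = TRUE))` for each
#' included effect vector (the cohort walk runs over the full `1..K`
#' grid, so unobserved cohort indices contribute increments too); (b)
#' independent `Normal(0, sigma_z^2)` terms for each cell's `z`; (c)
#' half-normal hyperprior terms on the included SDs and a
#' `Normal(0, prior_scale_intercept^2)` term on the intercept. The RW1
#' density is evaluated on increments only (the level is fixed by the
#' sum-to-zero constraint, not by the prior), so the value is a density
#' in the constrained gauge up to a constant.
#'
#' @param params An [apc_parameters].
#' @param spec An [apc_model_spec].
#' @return Scalar log density. Effects excluded by `spec` contribute 0.
#' @export
log_prior <- function(params, spec) {
  stopifnot(inherits(params, "apc_parameters"),
            inherits(spec, "apc_model_spec"))
  s <- params$sigma
  if (any(s <= 0)) stop("sigmas must be positive", call. = FALSE)
  half_normal <- function(x, scale)
    stats::dnorm(x, 0, scale, log = TRUE) + log(2)
  rw1 <- function(eff, sd) sum(stats::dnorm(diff(eff), 0, sd, log = TRUE))

  lp <- rw1(params$alpha, s["age"]) + half_normal(s["age"], spec$prior_scale_effects)
  if (spec$include_period)
    lp <- lp + rw1(params$beta, s["period"]) +
      half_normal(s["period"], spec$prior_scale_effects)
  if (spec$include_cohort)
    lp <- lp + rw1(params$gamma, s["cohort"]) +
      half_normal(s["cohort"], spec$prior_scale_effects)
  if (spec$include_heterogeneity)
    lp <- lp + sum(stats::dnorm(params$z, 0, s["z"], log = TRUE)) +
      half_normal(s["z"], spec$prior_scale_heterogeneity)
  lp <- lp + stats::dnorm(params$delta, 0, spec$prior_scale_intercept,
                          log = TRUE)
  unname(lp)
}

#' Binomial log likelihood of an APC parameter point
#'
#' `sum(dbinom(y, n, plogis(eta), log = TRUE))` over all cells, binomial
#' coefficients included so that deviances (and hence DIC values) are
#' comparable across submodels.
#'
#' @param params An [apc_parameters].
#' @param table A [prevalence_table].
#' @param grid The matching [apc_grid].
#' @return Scalar log likelihood.
#' @export
log_likelihood <- function(params, table, grid) {
  stopifnot(inherits(table, "prevalence_table"))
  if (length(table$age_groups) != grid$I || length(table$periods) != grid$J)
    stop("table and grid dimensions do not match", call. = FALSE)
  p <- linear_predictor(params, grid, type = "response")
  sum(stats::dbinom(table$smokers, table$denominators, p, log = TRUE))
}

#' Re-centre effect vectors to the sum-to-zero gauge
#'
#' Subtracts each included effect vector's mean and adds the subtracted
#' means to the intercept, leaving the linear predictor `eta` (and hence
#' the likelihood) exactly unchanged. Idempotent.
#'
#' @param params An [apc_parameters].
#' @param spec Optional [apc_model_spec]; effects excluded by it are
#'   left untouched (they are identically zero anyway).
#' @return An [apc_parameters] whose `alpha`, `beta`, `gamma` each sum
#'   to zero.
#' @export
center_effects <- function(params, spec = NULL) {
  stopifnot(inherits(params, "apc_parameters"))
  out <- params
  shift <- 0
  for (eff in c("alpha", "beta", "gamma")) {
    m <- mean(out[[eff]])
    out[[eff]] <- out[[eff]] - m
    shift <- shift + m
  }
  out$delta <- out$delta + shift
  out
}
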