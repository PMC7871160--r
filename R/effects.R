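#' Effect-level prevalence estimates with credible intervals
#'
#' For each level `t` of the chosen axis, the prevalence attributable to
#' the overall level plus that effect alone — `plogis(delta + effect_t)`
#' — is evaluated on every posterior draw; the point estimate is the
#' posterior mean and the interval the equal-tailed 2.5/97.5 percentile
#' range. The cell heterogeneity `z` is deliberately excluded: these are
#' smooth effect-level summaries, not cell fits. On the cohort axis the
#' series covers the full 1-year cohort grid, including cohorts observed
#' in no cell, whose estimates are interpolated by the RW1 prior.
#'
#' @param fit An [apc_fit].
#' @param axis `"age"`, `"period"` or `"cohort"`.
#' @return An object of class `apc_effect` (a `data.frame` with columns
#'   `axis`, `level` (label), `estimate`, `lower95`, `upper95`; cohort
#'   rows also carry `observed`).
#' @export
effect_prevalence <- function(fit, axis = c("age", "period", "cohort")) {
  stopifnot(inherits(fit, "apc_fit"))
  axis <- match.arg(axis)
  grid <- fit$grid
  if (axis == "period" && !fit$spec$include_period)
    stop("period effect is not part of this model (", model_code(fit$spec),
         ")", call. = FALSE)
  if (axis == "cohort" && !fit$spec$include_cohort)
    stop("cohort effect is not part of this model (", model_code(fit$spec),
         ")", call. = FALSE)
  info <- switch(axis,
    age = list(name = "alpha", len = grid$I,
               levels = age_group_label(grid$age_starts)),
    period = list(name = "beta", len = grid$J,
                  levels = as.character(grid$period_years)),
    cohort = list(name = "gamma", len = grid$K,
                  levels = cohort_label(grid, seq_len(grid$K)))
  )
  m <- fit$draws
  cols <- sprintf("%s[%d]", info$name, seq_len(info$len))
  eff <- if (info$len > 1L) m[, cols, drop = FALSE]
         else matrix(0, nrow(m), 1L)
  p <- stats::plogis(m[, "delta"] + eff)
  out <- data.frame(
    axis = axis,
    level = info$levels,
    estimate = colMeans(p),
    lower95 = apply(p, 2, stats::quantile, 0.025),
    upper95 = apply(p, 2, stats::quantile, 0.975),
    stringsAsFactors = FALSE
  )
  if (axis == "cohort")
    out$observed <- seq_len(grid$K) %in% grid$observed_cohorts
  rownames(out) <- NULL
  class(out) <- c("apc_effect", "data.frame")
  out
}

#' Between-stratum prevalence ratio series
#'
#' Divides one stratum's effect-level prevalence estimates by another's
#' (conventionally non-urban / urban), level by level. The two series
#' must come from independently fitted per-stratum models on the same
#' axis and levels. By default the ratio of the posterior-mean
#' prevalences is returned; with two fitted models and
#' `type = "draws"`, the per-draw ratio distribution is summarised
#' instead (posterior mean and 95% interval of the ratio).
#'
#' @param numerator,denominator Either two [effect_prevalence()] series
#'   (`type = "point"` only) or two [apc_fit] objects.
#' @param axis Axis to compare when fits are given.
#' @param type `"point"` (ratio of posterior means, the default) or
#'   `"draws"` (per-draw ratios; fits required).
#' @return An object of class `apc_ratio` (a `data.frame` with columns
#'   `axis`, `level`, `ratio`, plus `lower95`/`upper95` for
#'   `type = "draws"`).
#' @export
prevalence_ratio <- function(numerator, denominator,
                             axis = c("age", "period", "cohort"),
                             type = c("point", "draws")) {
  type <- match.arg(type)
  if (inherits(numerator, "apc_fit") && inherits(denominator, "apc_fit")) {
    axis <- match.arg(axis)
    if (type == "draws")
      return(ratio_from_draws(numerator, denominator, axis))
    numerator <- effect_prevalence(numerator, axis)
    denominator <- effect_prevalence(denominator, axis)
  } else if (type == "draws") {
    stop("type = \"draws\" needs two apc_fit objects, not summaries",
         call. = FALSE)
  }
  stopifnot(inherits(numerator, "apc_effect"),
            inherits(denominator, "apc_effect"))
  if (!identical(numerator$axis[1], denominator$axis[1]) ||
      !identical(numerator$level, denominator$level))
    stop("the two series must share the same axis and levels",
         call. = FALSE)
  if (any(denominator$estimate <= 0))
    stop("denominator series has non-positive estimates", call. = FALSE)
  out <- data.frame(
    axis = numerator$axis,
    level = numerator$level,
    ratio = numerator$estimate / denominator$estimate,
    stringsAsFactors = FALSE
  )
  class(out) <- c("apc_ratio", "data.frame")
  out
}

ratio_from_draws <- function(num, den, axis) {
  a <- effect_draw_probs(num, axis)
  b <- effect_draw_probs(den, axis)
  if (!identical(a$levels, b$levels))
    stop("the two fits must share the same axis levels", call. = FALSE)
  S <- min(nrow(a$p), nrow(b$p))
  r <- a$p[seq_len(S), , drop = FALSE] / b$p[seq_len(S), , drop = FALSE]
  out <- data.frame(
    axis = axis,
    level = a$levels,
    ratio = colMeans(r),
    lower95 = apply(r, 2, stats::quantile, 0.025),
    upper95 = apply(r, 2, stats::quantile, 0.975),
    stringsAsFactors = FALSE
  )
  class(out) <- c("apc_ratio", "data.frame")
  out
}

effect_draw_probs <- function(fit, axis) {
  es <- effect_prevalence(fit, axis)  # validates the axis
  grid <- fit$grid
  info <- switch(axis,
    age = list(name = "alpha", len = grid$I),
    period = list(name = "beta", len = grid$J),
    cohort = list(name = "gamma", len = grid$K))
  m <- fit$draws
  cols <- sprintf("%s[%d]", info$name, seq_len(info$len))
  eff <- if (info$len > 1L) m[, cols, drop = FALSE] else matrix(0, nrow(m), 1L)
  list(levels = es$level, p = stats::plogis(m[, "delta"] + eff))
}

#' Standard population weights for direct age standardization
#'
#' @param weights Non-negative weights, one per age group (any positive
#'   total; normalized to sum to 1).
#' @param age_groups Optional age-group start years used for label
#'   checks against prevalence inputs.
#' @return An object of class `standard_population`.
#' @export
standard_population <- function(weights, age_groups = NULL) {
  weights <- as.numeric(weights)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  if (sum(weights) <= 0)
    stop("weights must have a positive sum", call. = FALSE)
  if (!is.null(age_groups) && length(age_groups) != length(weights))
    stop("one weight per age group required", call. = FALSE)
  structure(list(weights = weights / sum(weights),
                 age_groups = if (is.null(age_groups)) NULL
                              else as.integer(age_groups)),
            class = "standard_population")
}

#' Directly age-standardized prevalence
#'
#' Weighted average `sum(w_i * p_i)` of age-specific prevalences using a
#' fixed standard population's age distribution, making strata and years
#' comparable despite different age structures. Operates equally on
#' observed (`y/n`) and model-fitted prevalences.
#'
#' @param prevalence_by_age Numeric vector of proportions, one per age
#'   group, or a matrix with age groups in rows (one standardized value
#'   per column is returned).
#' @param std A [standard_population()] covering the same age groups
#'   (or a bare weight vector, normalized internally).
#' @return Standardized prevalence(s) in `[0, 1]`.
#' @examples
#' age_standardize(c(0.1, 0.2, 0.4), standard_population(c(0.5, 0.3, 0.2)))
#' @export
age_standardize <- function(prevalence_by_age, std) {
  if (!inherits(std, "standard_population"))
    std <- standard_population(std)
  w <- std$weights
  if (is.matrix(prevalence_by_age)) {
    if (nrow(prevalence_by_age) != length(w))
      stop("weights cover ", length(w), " age groups but prevalences have ",
           nrow(prevalence_by_age), " rows", call. = FALSE)
    return(as.vector(w %*% prevalence_by_age))
  }
  p <- as.numeric(prevalence_by_age)
  if (length(p) != length(w))
    stop("weights cover ", length(w), " age groups but ", length(p),
         " prevalences given", call. = FALSE)
  sum(w * p)
}

#' Posterior heterogeneity diagnostics
#'
#' Summaries of the cell-level heterogeneity term `z[i,j]`: its
#' posterior-mean surface and per-age / per-period means and SDs of
#' those posterior means. When an additive effect is missing from the
#' model, the structure it would have explained is absorbed by `z`, so
#' trends of the per-period (or per-cohort-diagonal) means of `z` across
#' the lattice diagnose misspecification; under a well-specified model
#' the posterior means of `z` show no systematic trend.
#'
#' @param fit An [apc_fit] with heterogeneity included.
#' @return An object of class `apc_heterogeneity`: list with `z_mean`
#'   (`I x J` matrix of posterior means), `by_age` and `by_period`
#'   (data.frames with `level`, `mean`, `sd`), and `overall_sd` (SD of
#'   all posterior-mean `z`).
#' @export
heterogeneity_summary <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  if (!fit$spec$include_heterogeneity)
    stop("model was fitted without a heterogeneity term", call. = FALSE)
  grid <- fit$grid
  cols <- sprintf("z[%d]", seq_len(grid$I * grid$J))
  zm <- matrix(colMeans(fit$draws[, cols, drop = FALSE]), grid$I, grid$J)
  dimnames(zm) <- list(age_group_label(grid$age_starts), grid$period_years)
  structure(
    list(
      z_mean = zm,
      by_age = data.frame(level = age_group_label(grid$age_starts),
                          mean = rowMeans(zm), sd = apply(zm, 1, stats::sd),
                          stringsAsFactors = FALSE),
      by_period = data.frame(level = as.character(grid$period_years),
                             mean = colMeans(zm), sd = apply(zm, 2, stats::sd),
                             stringsAsFactors = FALSE),
      overall_sd = stats::sd(as.vector(zm))
    ),
    class = "apc_heterogeneity"
  )
}

#' @export
print.apc_heterogeneity <- function(x, ...) {
  cat("Heterogeneity term (posterior means of z)\n")
  cat(sprintf("  overall SD: %.4f\n", x$overall_sd))
  cat("  per-period means:\n")
  print(round(stats::setNames(x$by_period$mean, x$by_period$level), 4))
  invisible(x)
}

#' Plot effect-level prevalence series
#'
#' Base-graphics plot of one axis' estimated prevalences with a shaded
#' 95% credible band, in the style of APC effect panels.
#'
#' @param x An [apc_fit].
#' @param axis `"age"`, `"period"` or `"cohort"`.
#' @param ... Passed to [graphics::plot()].
#' @return The plotted `apc_effect` series, invisibly.
#' @export
plot.apc_fit <- function(x, axis = c("age", "period", "cohort"), ...) {
  axis <- match.arg(axis)
  es <- effect_prevalence(x, axis)
  xs <- seq_len(nrow(es))
  graphics::plot(xs, es$estimate, type = "n",
                 ylim = range(es$lower95, es$upper95),
                 xaxt = "n", xlab = axis, ylab = "prevalence", ...)
  graphics::polygon(c(xs, rev(xs)), c(es$lower95, rev(es$upper95)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(xs, es$estimate, lwd = 2, col = "steelblue4")
  keep <- unique(round(seq(1, nrow(es), length.out = min(8, nrow(es)))))
  graphics::axis(1, at = keep, labels = es$level[keep], las = 2,
                 cex.axis = 0.8)
  invisible(es)
}
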