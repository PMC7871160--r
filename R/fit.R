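#' Fit a Bayesian binomial APC model by MCMC
#'
#' Samples the posterior of the binomial age-period-cohort model (see
#' [apc_model_spec()]) for one stratum's [prevalence_table()] using JAGS
#' (Gibbs/slice sampling with the `glm` block-sampler module). During
#' sampling each effect vector is anchored by fixing its first element
#' to zero (a proper corner parameterisation of the RW1 prior); every
#' reported draw is then deterministically re-centred to the sum-to-zero
#' gauge via [center_effects()], which leaves the linear predictor, and
#' hence the likelihood, exactly unchanged. Split potential-scale-
#' reduction factors (R-hat) are computed on the centred draws for every
#' scalar.
#'
#' Note on identification: the three APC axes are linearly dependent, so
#' the linear-trend components of `alpha`, `beta`, `gamma` trade off
#' against each other and are constrained only by the RW1 shrinkage
#' priors, not resolved further. Individual effect coordinates of the
#' full APC model therefore mix slowly and may show elevated R-hat at
#' practical chain lengths, while identified functionals — the
#' intercept, fitted cell probabilities, and second differences of the
#' effects — converge quickly. Judge convergence on the quantities you
#' report; [check_convergence()] accepts a parameter subset.
#'
#' @param table A [prevalence_table].
#' @param grid An [apc_grid]; defaults to the lattice implied by the
#'   table's age groups and periods.
#' @param model Submodel code `"apc"`, `"ap"`, `"ac"` or `"a"`; ignored
#'   when `spec` is given.
#' @param spec An [apc_model_spec]; overrides `model`/`heterogeneity`.
#' @param heterogeneity Include the cell-level `z` term (default `TRUE`).
#' @param chains Number of MCMC chains (default 4; at least 2 are needed
#'   for R-hat).
#' @param iter Kept iterations per chain after warmup (default 2000).
#' @param warmup Burn-in iterations discarded per chain (default =
#'   `iter`).
#' @param adapt JAGS adaptation steps (default 1000).
#' @param thin Thinning interval (default 1).
#' @param seed Integer seed controlling all chains' RNG streams; the
#'   same seed, data and settings reproduce the draws exactly.
#' @param quiet Suppress JAGS progress output.
#'
#' @return An object of class `apc_fit` with components `draws` (an
#'   `S x P` matrix of centred posterior draws, `S = chains * iter /
#'   thin`), `chain` (per-draw chain id), `rhat` (named split-R-hat
#'   vector), and the `table`, `grid`, `spec`, sampler settings and
#'   `seed` used.
#'
#' @examples
#' \donttest{
#' tr <- simulate_truth(smoking_survey_grid(), scenario = "full", seed = 1)
#' tab <- simulate_prevalence_table(tr)
#' fit <- apc_fit(tab, chains = 2, iter = 500, warmup = 500, seed = 1)
#' fit
#' }
#' @export
apc_fit <- function(table, grid = NULL, model = c("apc", "ap", "ac", "a"),
                    spec = NULL, heterogeneity = TRUE,
                    chains = 4, iter = 2000, warmup = iter, adapt = 1000,
                    thin = 1, seed = 1, quiet = TRUE) {
  stopifnot(inherits(table, "prevalence_table"))
  if (is.null(grid))
    grid <- apc_grid(table$age_groups, table$periods)
  stopifnot(inherits(grid, "apc_grid"))
  if (length(table$age_groups) != grid$I || length(table$periods) != grid$J)
    stop("table and grid dimensions do not match", call. = FALSE)
  if (is.null(spec))
    spec <- apc_model_spec(match.arg(model),
                           include_heterogeneity = heterogeneity)
  stopifnot(inherits(spec, "apc_model_spec"))
  if (chains < 1) stop("need at least one chain", call. = FALSE)

  loadNamespace("rjags")
  rjags::load.module("glm", quiet = TRUE)

  cells <- grid_cells(grid)
  dat <- list(
    y = as.vector(table$smokers),
    n = as.vector(table$denominators),
    C = grid$I * grid$J
  )
  if (grid$I > 1L) {
    dat$age <- cells$i
    dat$I <- grid$I
  }
  if (spec$include_period && grid$J > 1L) {
    dat$per <- cells$j
    dat$J <- grid$J
  }
  if (spec$include_cohort && grid$K > 1L) {
    dat$coh <- cells$k
    dat$K <- grid$K
  }

  code <- jags_model_string(spec, grid)

  set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, chains)
  inits <- lapply(chain_seeds, function(s)
    list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = s))

  jm <- tryCatch(
    rjags::jags.model(textConnection(code), data = dat, inits = inits,
                      n.chains = chains, n.adapt = adapt, quiet = quiet),
    error = function(e)
      stop("MCMC initialization failed: ", conditionMessage(e),
           call. = FALSE)
  )
  if (warmup > 0)
    update(jm, warmup, progress.bar = if (quiet) "none" else "text")
  monitors <- jags_monitors(spec, grid)
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter, thin = thin,
                              progress.bar = if (quiet) "none" else "text")

  want <- draw_colnames(spec, grid)
  per_chain <- lapply(samp, function(ch) {
    m <- as.matrix(ch)
    colnames(m) <- rename_jags_cols(colnames(m))
    center_draws(m[, want, drop = FALSE], spec, grid)
  })
  draws <- do.call(rbind, per_chain)
  chain <- rep(seq_along(per_chain), vapply(per_chain, nrow, 0L))

  rhat <- if (chains >= 2) {
    vapply(seq_len(ncol(draws)), function(p)
      split_rhat(lapply(per_chain, function(m) m[, p])), 0)
  } else rep(NA_real_, ncol(draws))
  names(rhat) <- colnames(draws)

  structure(
    list(
      draws = draws, chain = chain, rhat = rhat,
      table = table, grid = grid, spec = spec,
      chains = chains, iter = iter, warmup = warmup, adapt = adapt,
      thin = thin, seed = seed,
      call = match.call()
    ),
    class = "apc_fit"
  )
}

# Build the JAGS model definition for a given spec and grid.
# Corner parameterisation: first element of each included effect is 0,
# remaining elements follow the RW1; draws are re-centred afterwards.
jags_model_string <- function(spec, grid) {
  eta <- "delta"
  if (grid$I > 1L) eta <- paste0(eta, " + alpha[age[c]]")
  if (spec$include_period && grid$J > 1L) eta <- paste0(eta, " + beta[per[c]]")
  if (spec$include_cohort && grid$K > 1L) eta <- paste0(eta, " + gamma[coh[c]]")
  if (spec$include_heterogeneity) eta <- paste0(eta, " + z[c]")

  lines <- c(
    "model {",
    "  for (c in 1:C) {",
    "    y[c] ~ dbin(p[c], n[c])",
    paste0("    logit(p[c]) <- ", eta),
    if (spec$include_heterogeneity) "    z[c] ~ dnorm(0, tau_z)",
    "  }",
    sprintf("  delta ~ dnorm(0, %.17g)", 1 / spec$prior_scale_intercept^2)
  )
  rw1 <- function(name, len, idx, tau, sigma, scale) {
    c(sprintf("  %s[1] <- 0", name),
      if (len > 1L) c(
        sprintf("  for (%s in 2:%s) { %s[%s] ~ dnorm(%s[%s-1], %s) }",
                idx, len_sym(name), name, idx, name, idx, tau),
        sprintf("  %s ~ dnorm(0, %.17g) T(0,)", sigma, 1 / scale^2),
        sprintf("  %s <- 1/(%s*%s)", tau, sigma, sigma)
      ))
  }
  if (grid$I > 1L)
    lines <- c(lines, rw1("alpha", grid$I, "i", "tau_a", "sigma_age",
                          spec$prior_scale_effects))
  if (spec$include_period && grid$J > 1L)
    lines <- c(lines, rw1("beta", grid$J, "j", "tau_b", "sigma_period",
                          spec$prior_scale_effects))
  if (spec$include_cohort && grid$K > 1L)
    lines <- c(lines, rw1("gamma", grid$K, "k", "tau_g", "sigma_cohort",
                          spec$prior_scale_effects))
  if (spec$include_heterogeneity)
    lines <- c(lines,
               sprintf("  sigma_z ~ dnorm(0, %.17g) T(0,)",
                       1 / spec$prior_scale_heterogeneity^2),
               "  tau_z <- 1/(sigma_z*sigma_z)")
  paste(c(lines, "}"), collapse = "\n")
}

len_sym <- function(name)
  switch(name, alpha = "I", beta = "J", gamma = "K")

jags_monitors <- function(spec, grid) {
  m <- "delta"
  if (grid$I > 1L) m <- c(m, "alpha", "sigma_age")
  if (spec$include_period && grid$J > 1L) m <- c(m, "beta", "sigma_period")
  if (spec$include_cohort && grid$K > 1L) m <- c(m, "gamma", "sigma_cohort")
  if (spec$include_heterogeneity) m <- c(m, "z", "sigma_z")
  m
}

# canonical column layout of the draws matrix
draw_colnames <- function(spec, grid) {
  nm <- "delta"
  if (grid$I > 1L) nm <- c(nm, "sigma_age")
  if (spec$include_period && grid$J > 1L) nm <- c(nm, "sigma_period")
  if (spec$include_cohort && grid$K > 1L) nm <- c(nm, "sigma_cohort")
  if (spec$include_heterogeneity) nm <- c(nm, "sigma_z")
  if (grid$I > 1L) nm <- c(nm, sprintf("alpha[%d]", seq_len(grid$I)))
  if (spec$include_period && grid$J > 1L)
    nm <- c(nm, sprintf("beta[%d]", seq_len(grid$J)))
  if (spec$include_cohort && grid$K > 1L)
    nm <- c(nm, sprintf("gamma[%d]", seq_len(grid$K)))
  if (spec$include_heterogeneity)
    nm <- c(nm, sprintf("z[%d]", seq_len(grid$I * grid$J)))
  nm
}

rename_jags_cols <- function(nm) nm  # JAGS names already match the layout

# subtract each effect vector's per-draw mean; add the means to delta
center_draws <- function(m, spec, grid) {
  shift <- 0
  for (eff in list(c("alpha", grid$I),
                   c("beta", grid$J),
                   c("gamma", grid$K))) {
    cols <- sprintf("%s[%d]", eff[1], seq_len(as.integer(eff[2])))
    if (!all(cols %in% colnames(m))) next
    mu <- rowMeans(m[, cols, drop = FALSE])
    m[, cols] <- m[, cols, drop = FALSE] - mu
    shift <- shift + mu
  }
  m[, "delta"] <- m[, "delta"] + shift
  m
}

#' Classical split potential-scale-reduction factor (R-hat)
#'
#' Each chain is split in half and the usual between/within-chain
#' variance ratio is computed over the resulting 2m half-chains.
#' Degenerate cases are resolved conservatively: all draws identical
#' across chains gives 1; zero within-chain variance with between-chain
#' spread gives `Inf`.
#'
#' @param chains A list of numeric vectors, one per chain (equal
#'   lengths; at least 2 chains of at least 4 draws).
#' @return Scalar R-hat.
#' @examples
#' set.seed(1)
#' split_rhat(list(rnorm(500), rnorm(500)))      # ~ 1
#' split_rhat(list(rep(0, 100), rep(10, 100)))   # Inf
#' @export
split_rhat <- function(chains) {
  if (!is.list(chains) || length(chains) < 2L)
    stop("need a list of at least 2 chains", call. = FALSE)
  len <- unique(vapply(chains, length, 0L))
  if (length(len) != 1L || len < 4L)
    stop("chains must have equal length >= 4", call. = FALSE)
  h <- floor(len / 2)
  halves <- unlist(lapply(chains, function(v)
    list(v[seq_len(h)], v[h + seq_len(h)])), recursive = FALSE)
  mns <- vapply(halves, mean, 0)
  vrs <- vapply(halves, stats::var, 0)
  W <- mean(vrs)
  B <- h * stats::var(mns)
  if (B == 0 && W == 0) return(1)
  if (W == 0) return(Inf)
  sqrt(((h - 1) / h * W + B / h) / W)
}

#' Check MCMC convergence by R-hat
#'
#' Passes iff every reported split R-hat is at or below `threshold`
#' (default 1.05). Scalars whose R-hat exceeds the threshold are listed
#' as offenders, worst first, rather than silently dropped.
#'
#' @param fit An [apc_fit] with at least 2 chains.
#' @param threshold R-hat cutoff (default 1.05).
#' @param parameters Optional character vector restricting the check to
#'   a subset of scalar names (e.g. `c("delta", "sigma_z")`); defaults
#'   to all monitored scalars.
#' @return An object of class `apc_convergence`: list with `pass`,
#'   `threshold`, `rhat` (the checked values) and `offenders` (named
#'   vector of failures, decreasing).
#' @export
check_convergence <- function(fit, threshold = 1.05, parameters = NULL) {
  stopifnot(inherits(fit, "apc_fit"))
  if (fit$chains < 2L)
    stop("R-hat requires at least 2 chains; refit with chains >= 2",
         call. = FALSE)
  rhat <- fit$rhat
  if (!is.null(parameters)) {
    miss <- setdiff(parameters, names(rhat))
    if (length(miss))
      stop("unknown parameters: ", paste(miss, collapse = ", "),
           call. = FALSE)
    rhat <- rhat[parameters]
  }
  bad <- rhat[!is.na(rhat) & rhat > threshold]
  structure(
    list(pass = length(bad) == 0L, threshold = threshold, rhat = rhat,
         offenders = sort(bad, decreasing = TRUE)),
    class = "apc_convergence"
  )
}

#' @export
print.apc_convergence <- function(x, ...) {
  cat(sprintf("Convergence check (split R-hat <= %.3g): %s\n",
              x$threshold, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  %d scalars checked, max R-hat %.3f\n",
              length(x$rhat), max(x$rhat, na.rm = TRUE)))
  if (!x$pass) {
    show <- utils::head(x$offenders, 10)
    cat("  worst offenders:\n")
    for (nm in names(show))
      cat(sprintf("    %-14s %.3f\n", nm, show[nm]))
    if (length(x$offenders) > 10)
      cat(sprintf("    ... and %d more\n", length(x$offenders) - 10))
  }
  invisible(x)
}

# S x C matrix of per-draw cell probabilities (column-major cells)
posterior_prob_draws <- function(fit, type = c("response", "link")) {
  type <- match.arg(type)
  grid <- fit$grid
  cells <- grid_cells(grid)
  m <- fit$draws
  eta <- matrix(m[, "delta"], nrow(m), grid$I * grid$J)
  if (grid$I > 1L)
    eta <- eta + m[, sprintf("alpha[%d]", cells$i), drop = FALSE]
  if (fit$spec$include_period && grid$J > 1L)
    eta <- eta + m[, sprintf("beta[%d]", cells$j), drop = FALSE]
  if (fit$spec$include_cohort && grid$K > 1L)
    eta <- eta + m[, sprintf("gamma[%d]", cells$k), drop = FALSE]
  if (fit$spec$include_heterogeneity)
    eta <- eta + m[, sprintf("z[%d]", seq_len(grid$I * grid$J)), drop = FALSE]
  if (type == "response") stats::plogis(eta) else eta
}

# extract one posterior draw as an apc_parameters object
draw_parameters <- function(fit, s) {
  grid <- fit$grid
  m <- fit$draws
  getv <- function(name, len) {
    cols <- sprintf("%s[%d]", name, seq_len(len))
    if (all(cols %in% colnames(m))) unname(m[s, cols]) else rep(0, len)
  }
  sig <- c(age = 1, period = 1, cohort = 1, z = 1)
  for (nm in c("age", "period", "cohort", "z")) {
    col <- paste0("sigma_", nm)
    if (col %in% colnames(m)) sig[nm] <- m[s, col]
  }
  apc_parameters(
    grid,
    delta = m[s, "delta"],
    alpha = getv("alpha", grid$I),
    beta = getv("beta", grid$J),
    gamma = getv("gamma", grid$K),
    z = matrix(getv("z", grid$I * grid$J), grid$I, grid$J),
    sigma = sig
  )
}

#' Deviance information criterion of a fitted APC model
#'
#' Deviance is `D = -2 * log_likelihood` with binomial normalising
#' constants included, so DIC differences between submodels of the same
#' table are meaningful. `dbar` is the posterior mean deviance; `dhat`
#' is the deviance at the plug-in fit, taken as the posterior mean of
#' the cell probabilities `p[i,j]` (well-defined under the sum-to-zero
#' gauge); `pd = dbar - dhat` counts effective parameters and
#' `dic = dbar + pd = dhat + 2 * pd`.
#'
#' @param fit An [apc_fit].
#' @return An object of class `apc_dic`: list with `dic`, `dbar`,
#'   `dhat`, `pd`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "apc_fit"))
  if (nrow(fit$draws) == 0L) stop("fit has no draws", call. = FALSE)
  y <- as.vector(fit$table$smokers)
  n <- as.vector(fit$table$denominators)
  p <- posterior_prob_draws(fit)
  dev <- -2 * vapply(seq_len(nrow(p)), function(s)
    sum(stats::dbinom(y, n, p[s, ], log = TRUE)), 0)
  dbar <- mean(dev)
  phat <- colMeans(p)
  dhat <- -2 * sum(stats::dbinom(y, n, phat, log = TRUE))
  pd <- dbar - dhat
  structure(list(dic = dbar + pd, dbar = dbar, dhat = dhat, pd = pd),
            class = "apc_dic")
}

#' @export
print.apc_dic <- function(x, digits = 1, ...) {
  cat(sprintf("DIC %.*f  (Dbar %.*f, Dhat %.*f, pD %.*f)\n",
              digits, x$dic, digits, x$dbar, digits, x$dhat, digits, x$pd))
  invisible(x)
}

#' Compare submodels by DIC
#'
#' @param ... Named [apc_fit] objects (or a single list of them) fitted
#'   to the same table.
#' @return A `data.frame` with one row per model: `model`, `dic`,
#'   `dbar`, `dhat`, `pd`, `delta_dic` (difference from the smallest
#'   DIC), sorted by DIC.
#' @export
dic_table <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "apc_fit"))
    fits <- fits[[1L]]
  stopifnot(all(vapply(fits, inherits, TRUE, "apc_fit")))
  nm <- names(fits)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(fits, function(f) model_code(f$spec), "")
  rows <- lapply(fits, function(f) {
    d <- dic(f)
    data.frame(dic = d$dic, dbar = d$dbar, dhat = d$dhat, pd = d$pd)
  })
  out <- cbind(data.frame(model = nm, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  out <- out[order(out$dic), ]
  out$delta_dic <- out$dic - min(out$dic)
  rownames(out) <- NULL
  out
}

#' @export
print.apc_fit <- function(x, ...) {
  lab <- switch(model_code(x$spec),
                a = "age", ap = "age-period", ac = "age-cohort",
                apc = "age-period-cohort")
  cat(sprintf("Bayesian binomial %s model%s\n", lab,
              if (x$spec$include_heterogeneity)
                " with cell heterogeneity" else ""))
  if (nzchar(x$table$stratum_label))
    cat(sprintf("  stratum: %s\n", x$table$stratum_label))
  cat(sprintf("  lattice: %d age groups x %d periods (%d cohorts)\n",
              x$grid$I, x$grid$J, x$grid$K))
  cat(sprintf("  draws  : %d chains x %d kept (warmup %d, seed %d)\n",
              x$chains, x$iter, x$warmup, x$seed))
  idn <- intersect(c("delta", "sigma_age", "sigma_period", "sigma_cohort",
                     "sigma_z"), names(x$rhat))
  if (x$chains >= 2)
    cat(sprintf("  split R-hat: %.3f (intercept/SDs), %.3f (all scalars)\n",
                max(x$rhat[idn]), max(x$rhat, na.rm = TRUE)))
  cat(sprintf("  posterior mean intercept: %.3f (prevalence %.1f%%)\n",
              mean(x$draws[, "delta"]),
              100 * mean(stats::plogis(x$draws[, "delta"]))))
  invisible(x)
}

#' @export
summary.apc_fit <- function(object, ...) {
  m <- object$draws
  qs <- t(apply(m, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  tab <- data.frame(
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3],
    rhat = object$rhat
  )
  out <- list(model = model_code(object$spec),
              stratum = object$table$stratum_label,
              scalars = tab,
              dic = dic(object))
  class(out) <- "summary.apc_fit"
  out
}

#' @export
print.summary.apc_fit <- function(x, ...) {
  cat(sprintf("Model: %s   stratum: %s\n", x$model,
              if (nzchar(x$stratum)) x$stratum else "(unlabelled)"))
  print(x$dic)
  keep <- grep("^(delta|sigma_)", rownames(x$scalars))
  cat("Intercept and SDs:\n")
  print(round(x$scalars[keep, ], 3))
  cat(sprintf("(%d effect/heterogeneity scalars omitted; see $scalars)\n",
              nrow(x$scalars) - length(keep)))
  invisible(x)
}

#' @export
coef.apc_fit <- function(object, ...) {
  grid <- object$grid
  m <- object$draws
  mean_of <- function(name, len) {
    cols <- sprintf("%s[%d]", name, seq_len(len))
    if (all(cols %in% colnames(m))) colMeans(m[, cols, drop = FALSE])
    else stats::setNames(rep(0, len), cols)
  }
  c(delta = mean(m[, "delta"]),
    mean_of("alpha", grid$I),
    mean_of("beta", grid$J),
    mean_of("gamma", grid$K))
}

#' @export
fitted.apc_fit <- function(object, ...) {
  p <- colMeans(posterior_prob_draws(object))
  out <- matrix(p, object$grid$I, object$grid$J)
  dimnames(out) <- dimnames(object$table$smokers)
  out
}

#' @export
residuals.apc_fit <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  y <- object$table$smokers
  n <- object$table$denominators
  p <- fitted(object)
  if (type == "pearson") {
    (y - n * p) / sqrt(n * p * (1 - p))
  } else {
    ll <- stats::dbinom(y, n, p, log = TRUE)
    sat <- stats::dbinom(y, n, ifelse(n > 0, y / n, 0), log = TRUE)
    sign(y - n * p) * sqrt(pmax(2 * (sat - ll), 0))
  }
}

#' Posterior-predictive simulation from a fitted APC model
#'
#' For each replicate, one posterior draw of the cell probabilities is
#' selected and a binomial count table is generated with the fitted
#' table's denominators.
#'
#' @param object An [apc_fit].
#' @param nsim Number of replicate tables.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A list of `nsim` [prevalence_table]s.
#' @export
simulate.apc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$table$denominators
  p <- posterior_prob_draws(object)
  idx <- sample.int(nrow(p), nsim, replace = TRUE)
  lapply(idx, function(s) {
    y <- matrix(stats::rbinom(length(n), as.vector(n), p[s, ]),
                object$grid$I, object$grid$J)
    prevalence_table(object$table$age_groups, object$table$periods,
                     y, n, paste0(object$table$stratum_label, "/sim"))
  })
}

#' @export
as.matrix.apc_fit <- function(x, ...) x$draws

#' Export posterior draws as a long CSV
#'
#' One row per (draw, scalar) with the chain id, for external audit.
#'
#' @param fit An [apc_fit].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "apc_fit"))
  m <- fit$draws
  df <- data.frame(
    draw = rep(seq_len(nrow(m)), times = ncol(m)),
    chain = rep(fit$chain, times = ncol(m)),
    parameter = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
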