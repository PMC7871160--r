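# Shared fixtures and shortcuts for the test suite.

# a small 3 x 2 lattice with hand-enterable counts
tiny_table <- function() {
  prevalence_table(
    age_groups = c(20, 25, 30),
    periods = c(2004, 2007),
    smokers = matrix(c(40, 35, 30, 38, 33, 28), 3, 2),
    denominators = matrix(100, 3, 2),
    stratum_label = "tiny"
  )
}

tiny_grid <- function() apc_grid(c(20, 25, 30), c(2004, 2007))

# random parameter point on a given grid, reproducible
random_params <- function(grid, seed = 1) {
  set.seed(seed)
  apc_parameters(
    grid,
    delta = rnorm(1),
    alpha = rnorm(grid$I, 0, 0.5),
    beta = rnorm(grid$J, 0, 0.5),
    gamma = rnorm(grid$K, 0, 0.5),
    z = matrix(rnorm(grid$I * grid$J, 0, 0.1), grid$I, grid$J),
    sigma = c(age = 0.5, period = 0.4, cohort = 0.3, z = 0.1)
  )
}

# short-chain fit for tests that only need a valid posterior object
quick_fit <- function(table, model = "apc", iter = 300, chains = 2,
                      seed = 1, ...) {
  apc_fit(table, model = model, chains = chains, iter = iter,
          warmup = iter, adapt = 300, seed = seed, ...)
}

# assemble an apc_fit-shaped object from externally constructed draws,
# so post-processing can be tested against enumeration oracles
fake_fit <- function(draws, table, grid, spec, chains = 2,
                     chain = NULL) {
  if (is.null(chain))
    chain <- rep(seq_len(chains), each = nrow(draws) / chains)
  structure(
    list(draws = draws, chain = chain,
         rhat = setNames(rep(1, ncol(draws)), colnames(draws)),
         table = table, grid = grid, spec = spec,
         chains = chains, iter = nrow(draws) / chains,
         warmup = 0, adapt = 0, thin = 1, seed = 0, call = NULL),
    class = "apc_fit"
  )
}

# draws matrix layout matching the given spec/grid, filled with zeros
zero_draws <- function(n, spec, grid) {
  nm <- prevapc:::draw_colnames(spec, grid)
  m <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  m[, grep("^sigma_", nm)] <- 1
  m
}
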