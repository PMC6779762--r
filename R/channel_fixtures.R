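#' Fixture specification
#'
#' Synthetic channels and ensembles with known ground truth, so each
#' analysis stage (binning, capacity, MMI, CV) can be tested without
#' simulating the full pathway. Channel kinds have closed-form capacity;
#' ensemble kinds have a known sampling law.
#'
#' @param kind one of `"identity"`, `"bsc"`, `"symmetric"` (channels) or
#'   `"poisson_map"`, `"deterministic_map"`, `"birth_death"` (ensembles).
#' @param n_inputs number of input levels.
#' @param n_samples realizations per input (ensemble kinds).
#' @param seed mandatory integer seed for the sampled kinds.
#' @param crossover crossover probability (`bsc`).
#' @param row first row of a (circularly) symmetric channel.
#' @param lambda per-input Poisson means (`poisson_map`); default `10 * j`.
#' @param levels per-input constant responses (`deterministic_map`);
#'   default `100 * j`.
#' @param birth,death rates of the linear birth-death process.
#' @param t_end,sample_dt birth-death simulation horizon and grid.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, n_inputs = 12, n_samples = 1000, seed = 1L,
                         crossover = 0.25, row = NULL, lambda = NULL,
                         levels = NULL, birth = 20, death = 0.1,
                         t_end = 200, sample_dt = 1) {
  kinds <- c("identity", "bsc", "symmetric",
             "poisson_map", "deterministic_map", "birth_death")
  if (!kind %in% kinds) stop("unknown fixture kind '", kind, "'", call. = FALSE)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  structure(list(kind = kind, n_inputs = n_inputs, n_samples = n_samples,
                 seed = as.integer(seed), crossover = crossover, row = row,
                 lambda = lambda, levels = levels, birth = birth,
                 death = death, t_end = t_end, sample_dt = sample_dt),
            class = "fixture_spec")
}

#' Analytic channel with known capacity
#'
#' * `identity`: noiseless n-ary channel, capacity `log2(n)`.
#' * `bsc`: binary symmetric channel with crossover `p`, capacity
#'   `1 - H2(p)`.
#' * `symmetric`: every row a circular shift of `row`, capacity
#'   `log2(n) - H(row)`.
#'
#' @param spec a [fixture_spec()] of a channel kind.
#' @return List with the `channel` and its closed-form `capacity` (bits).
#' @export
make_channel <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  switch(spec$kind,
    identity = {
      n <- spec$n_inputs
      list(channel = discrete_channel(diag(n)), capacity = log2(n))
    },
    bsc = {
      p <- spec$crossover
      stopifnot(p >= 0, p <= 1)
      W <- matrix(c(1 - p, p, p, 1 - p), 2, 2, byrow = TRUE)
      list(channel = discrete_channel(W),
           capacity = 1 - entropy_bits(c(p, 1 - p)))
    },
    symmetric = {
      row <- spec$row
      stopifnot(!is.null(row), all(row >= 0), abs(sum(row) - 1) < 1e-9)
      n <- length(row)
      W <- t(vapply(seq_len(n) - 1,
                    function(s) row[(seq_len(n) - 1 - s) %% n + 1],
                    numeric(n)))
      list(channel = discrete_channel(W),
           capacity = log2(n) - entropy_bits(row))
    },
    stop("'", spec$kind, "' is not an analytic channel kind", call. = FALSE)
  )
}

#' Sampled ensemble with known law
#'
#' * `poisson_map`: input `j` yields iid `Poisson(lambda_j)` counts -- one
#'   single-time ensemble per input, tagged with its exact law.
#' * `deterministic_map`: zero-variance ensembles at `levels[j]`.
#' * `birth_death`: a linear birth-death process simulated with the exact
#'   SSA engine; its stationary law is `Poisson(birth/death)`.
#'
#' @param spec a [fixture_spec()] of an ensemble kind.
#' @return For the mapped kinds, a named list of `trajectory_ensemble`
#'   (one per input) with the per-input law in `condition$law`; for
#'   `birth_death`, a single ensemble.
#' @export
make_ensemble <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  switch(spec$kind,
    poisson_map = {
      lambda <- spec$lambda %||% (10 * seq_len(spec$n_inputs))
      set.seed(spec$seed)
      ens <- lapply(seq_along(lambda), function(j) {
        x <- stats::rpois(spec$n_samples, lambda[j])
        single_time_ensemble(x, condition = list(
          network = "poisson_map",
          law = list(family = "poisson", lambda = lambda[j])))
      })
      stats::setNames(ens, as.character(lambda))
    },
    deterministic_map = {
      levels <- spec$levels %||% (100 * seq_len(spec$n_inputs))
      ens <- lapply(levels, function(v) {
        single_time_ensemble(rep(v, spec$n_samples), condition = list(
          network = "deterministic_map",
          law = list(family = "constant", value = v)))
      })
      stats::setNames(ens, as.character(levels))
    },
    birth_death = {
      net <- build_birth_death_network(spec$birth, spec$death)
      e <- ssa_simulate(net, t_end = spec$t_end, n_real = spec$n_samples,
                        seed = spec$seed, sample_dt = spec$sample_dt)
      e$condition$law <- list(family = "poisson",
                              lambda = spec$birth / spec$death)
      e
    },
    stop("'", spec$kind, "' is not an ensemble kind", call. = FALSE)
  )
}

single_time_ensemble <- function(x, condition = list()) {
  counts <- array(as.integer(x), dim = c(length(x), 1, 1),
                  dimnames = list(NULL, NULL, "X"))
  trajectory_ensemble(counts, sample_times = 0, condition = condition)
}

#' Linear birth-death network
#'
#' Zero-order production at `birth` events/min, first-order decay at `death`
#' per molecule per min. Stationary law: `Poisson(birth/death)` (mean equals
#' variance), the standard exactness benchmark for an SSA implementation.
#'
#' @param birth,death positive rates.
#' @return A `reaction_network` with single species `X`.
#' @export
build_birth_death_network <- function(birth = 20, death = 0.1) {
  stopifnot(birth > 0, death > 0)
  reaction_network("birth_death", "X",
                   list(rxn("birth", produced = c(X = 1L),
                            prop = prop_const(birth, "birth")),
                        rxn("death", consumed = c(X = 1L),
                            prop = prop_linear(death, "X", "death"))),
                   params = list(birth = birth, death = death))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
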