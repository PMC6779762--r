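#' Extrinsic-noise specification
#'
#' Models cell-to-cell (extrinsic) variability in one kinetic parameter as a
#' piecewise-constant lognormal process: within a realization the parameter
#' is redrawn as `nominal * exp(eps_noise * Z)`, `Z ~ N(0,1)`, at absolute
#' times `0, p_ext, 2 p_ext, ...` and held constant in between. The median of
#' the draws is the nominal value; `eps_noise = 0` recovers the deterministic
#' parameter. The default target is the transcription-factor phosphorylation
#' rate `k11` (nominal 0.11 per molecule per min).
#'
#' @param target_param name of the rate parameter to randomize.
#' @param eps_noise lognormal shape (sigma of the underlying normal), >= 0.
#' @param p_ext update period in minutes, > 0.
#' @param nominal scale (median) of the lognormal.
#' @return An object of class `extrinsic_noise_spec`.
#' @export
extrinsic_noise_spec <- function(target_param = "k11", eps_noise = 0,
                                 p_ext = 10, nominal = 0.11) {
  if (eps_noise < 0) stop("eps_noise must be >= 0", call. = FALSE)
  if (p_ext <= 0) stop("p_ext must be > 0", call. = FALSE)
  if (nominal <= 0) stop("nominal must be > 0", call. = FALSE)
  structure(list(target_param = target_param, eps_noise = eps_noise,
                 p_ext = p_ext, nominal = nominal),
            class = "extrinsic_noise_spec")
}

#' Draw extrinsic parameter values
#'
#' @param noise an [extrinsic_noise_spec()].
#' @param n number of independent draws.
#' @return Numeric vector of parameter values; identically `nominal` when
#'   `eps_noise = 0`.
#' @export
sample_extrinsic <- function(noise, n = 1) {
  stopifnot(inherits(noise, "extrinsic_noise_spec"))
  if (noise$eps_noise == 0) return(rep(noise$nominal, n))
  noise$nominal * exp(noise$eps_noise * stats::rnorm(n))
}

# ---- compilation to the C++ engine -------------------------------------

compile_network <- function(network, spec = network$input_spec, noise = NULL) {
  rx <- network$reactions
  if (!is.null(network$input_species)) {
    if (is.null(spec)) stop("network is input-driven; an input_spec is required",
                            call. = FALSE)
    rx <- c(rx, input_reactions(spec, network$input_species))
  }
  nr <- length(rx)
  idx <- stats::setNames(seq_along(network$species) - 1L, network$species)
  type <- integer(nr); coef <- numeric(nr)
  sidx <- matrix(-1L, nr, 2); aux <- matrix(0, nr, 2)
  for (i in seq_len(nr)) {
    pr <- rx[[i]]$prop
    type[i] <- pr$type
    coef[i] <- pr$coef
    if (length(pr$s)) sidx[i, seq_along(pr$s)] <- idx[pr$s]
    if (pr$type %in% c(3L, 4L)) aux[i, ] <- c(pr$n, pr$K)
    if (pr$type %in% c(5L, 6L)) aux[i, 1] <- pr$Tc
  }
  noisy <- -1L
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "extrinsic_noise_spec"))
    hit <- which(vapply(rx, function(r)
      identical(r$prop$rate_param, noise$target_param), logical(1)))
    if (length(hit) != 1) {
      stop("extrinsic noise target '", noise$target_param,
           "' must match exactly one reaction (matched ", length(hit), ")",
           call. = FALSE)
    }
    if (type[hit] >= 5L) {
      stop("extrinsic noise cannot target an input-hazard reaction", call. = FALSE)
    }
    noisy <- hit - 1L
  }
  list(stoich = stoichiometry(network, spec), type = type, coef = coef,
       sidx = sidx, aux = aux, init = unname(network$initial_state),
       noisy = noisy,
       eps = if (is.null(noise)) 0 else noise$eps_noise,
       p_ext = if (is.null(noise)) Inf else noise$p_ext,
       nominal = if (is.null(noise)) 0 else noise$nominal)
}

#' Simulate a trajectory ensemble (exact SSA)
#'
#' Draws `n_real` statistically exact sample paths of the jump process
#' defined by the network's propensities plus, for input-driven networks,
#' the time-decaying input hazards of `spec`. Waiting times are generated by
#' Ogata thinning: the proposal rate is the total propensity at the current
#' (state, time), which upper-bounds the true total over the waiting interval
#' because input hazards are non-increasing and all other propensities are
#' constant between events; proposals are accepted with probability
#' true/bound. States are recorded on the regular grid
#' `0, sample_dt, ..., t_end`.
#'
#' Seeding: the master `seed` spawns one sub-seed per realization, and each
#' realization is simulated under its own stream, so ensembles are
#' bit-reproducible and sub-ensembles are independent.
#'
#' @param network a `reaction_network`.
#' @param spec the driving [input_spec()] (defaults to the one bound at build
#'   time); ignored for autonomous networks.
#' @param t_end simulation horizon in minutes.
#' @param n_real number of realizations (cells).
#' @param seed master integer seed.
#' @param noise optional [extrinsic_noise_spec()].
#' @param sample_dt sampling interval in minutes.
#' @return A `trajectory_ensemble`: integer count array
#'   `(realization x sample time x species)` with the condition and the seed
#'   record attached.
#' @export
ssa_simulate <- function(network, spec = network$input_spec, t_end = 200,
                         n_real = 1000, seed = 1L, noise = NULL,
                         sample_dt = 1) {
  stopifnot(inherits(network, "reaction_network"), t_end > 0,
            n_real >= 1, sample_dt > 0)
  comp <- compile_network(network, spec, noise)
  sample_times <- seq(0, t_end, by = sample_dt)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_real)
  counts <- array(0L, dim = c(n_real, length(sample_times), length(network$species)),
                  dimnames = list(NULL, NULL, network$species))
  for (i in seq_len(n_real)) {
    set.seed(seeds[i])
    counts[i, , ] <- ssa_run_cpp(comp$stoich, comp$type, comp$coef, comp$sidx,
                                 comp$aux, comp$init, sample_times, t_end,
                                 comp$noisy, comp$eps, comp$p_ext, comp$nominal)
  }
  trajectory_ensemble(counts, sample_times,
                      condition = list(network = network$name,
                                       input = spec, noise = noise),
                      seeds = list(master = seed, realization = seeds))
}

#' Trajectory-ensemble container
#'
#' @param counts integer array `(realization x time x species)` with species
#'   names on the third dimension.
#' @param sample_times numeric vector of sample times (min).
#' @param condition list describing the generating condition.
#' @param seeds seed record.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(counts, sample_times, condition = list(),
                                seeds = list()) {
  stopifnot(length(dim(counts)) == 3, dim(counts)[2] == length(sample_times))
  if (any(counts < 0)) stop("negative counts in ensemble", call. = FALSE)
  structure(list(counts = counts, sample_times = sample_times,
                 species = dimnames(counts)[[3]],
                 condition = condition, seeds = seeds),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %d realizations x %d times x %d species (%s)\n",
              dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
              paste(utils::head(x$species, 6), collapse = ", ")))
  invisible(x)
}

time_index <- function(ens, t) {
  i <- which(abs(ens$sample_times - t) < 1e-9)
  if (!length(i)) stop("t = ", t, " is not on the sample grid", call. = FALSE)
  i[1]
}

#' Responses of one species across realizations
#'
#' @param ens a `trajectory_ensemble`.
#' @param species species name.
#' @return Integer matrix `(realization x time)`.
#' @export
response_matrix <- function(ens, species) {
  stopifnot(species %in% ens$species)
  ens$counts[, , species, drop = TRUE]
}

#' Ensemble mean and standard deviation traces
#'
#' @param ens a `trajectory_ensemble`.
#' @param species species name(s); default all.
#' @return `ensemble_mean()` / `ensemble_sd()`: numeric matrix
#'   `(time x species)`.
#' @export
ensemble_mean <- function(ens, species = ens$species) {
  m <- apply(ens$counts[, , species, drop = FALSE], c(2, 3), mean)
  dimnames(m) <- list(NULL, species)
  m
}

#' @rdname ensemble_mean
#' @export
ensemble_sd <- function(ens, species = ens$species) {
  m <- apply(ens$counts[, , species, drop = FALSE], c(2, 3), stats::sd)
  dimnames(m) <- list(NULL, species)
  m
}

#' Export ensemble summaries
#'
#' Writes a long-format CSV `(time_min, species, mean, sd)` plus a JSON
#' sidecar (`<path>.json`) with the condition and seed record.
#'
#' @param ens a `trajectory_ensemble`.
#' @param path CSV file to write.
#' @param species species to include; default all.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(ens, path, species = ens$species) {
  mu <- ensemble_mean(ens, species)
  sd <- ensemble_sd(ens, species)
  df <- data.frame(
    time_min = rep(ens$sample_times, times = length(species)),
    species = rep(species, each = length(ens$sample_times)),
    mean = as.vector(mu), sd = as.vector(sd))
  utils::write.csv(df, path, row.names = FALSE)
  cond <- ens$condition
  meta <- list(network = cond$network,
               input = if (!is.null(cond$input)) unclass(cond$input),
               noise = if (!is.null(cond$noise)) unclass(cond$noise),
               seeds = ens$seeds,
               n_realizations = dim(ens$counts)[1])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
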