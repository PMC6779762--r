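#' Experiment configuration
#'
#' One object holds every knob of the five in-silico experiments. Two
#' profiles are provided: `"full"` reproduces the reference protocol
#' (1000 realizations, 12 input levels L = 10..120, 200 min, 1 min
#' sampling); `"desk"` is the scaled-down profile used by the test suite
#' (200 realizations, 6 levels L = 10..60) which preserves every ordering
#' and trend conclusion at a fraction of the cost. Explicit arguments
#' override the profile.
#'
#' @param experiment one of `"mapk_cc"`, `"minimal_cc"`, `"linear_vs_ffl"`,
#'   `"affinity_mmi"`, `"extrinsic_noise"`.
#' @param input reference input label (`"I1"`, `"I2"`, `"I3"`); `I2` is the
#'   default condition.
#' @param inputs inputs for the cross-input comparison in `minimal_cc`.
#' @param L input-amplitude sweep (one channel input symbol per level).
#' @param n_real realizations per condition (>= 2).
#' @param t_end,sample_dt simulation horizon and sampling interval (min).
#' @param bins response bins for channel estimation.
#' @param tol_bits Arimoto-Blahut tolerance.
#' @param eps_grid,pext_grid extrinsic-noise intensity and update-period
#'   grids (`extrinsic_noise` experiment).
#' @param mmi_times times at which MMI is evaluated (`affinity_mmi`).
#' @param n_boot bootstrap resamples for trend statistics.
#' @param seed master seed; every random stream derives from it.
#' @param profile `"desk"` or `"full"`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(experiment,
                              input = "I2", inputs = NULL,
                              L = NULL, n_real = NULL,
                              t_end = 200, sample_dt = 1,
                              bins = 64, tol_bits = 1e-6,
                              eps_grid = NULL, pext_grid = NULL,
                              mmi_times = NULL, n_boot = 200,
                              seed = 1L, profile = c("desk", "full")) {
  ids <- c("mapk_cc", "minimal_cc", "linear_vs_ffl", "affinity_mmi",
           "extrinsic_noise")
  if (!experiment %in% ids) {
    stop("unknown experiment '", experiment, "'", call. = FALSE)
  }
  profile <- match.arg(profile)
  if (is.null(L)) {
    # desk subsampling: reporter-based experiments keep the protocol's full
    # amplitude range (the reporter only engages at high L), the minimal-
    # decoder experiments are fully resolved at the lower levels
    L <- if (profile == "full") l_sweep()
         else if (experiment %in% c("minimal_cc", "linear_vs_ffl"))
           l_sweep(10, 60, 10)
         else l_sweep(20, 120, 20)
  }
  if (is.null(n_real)) n_real <- if (profile == "full") 1000 else 200
  if (is.null(eps_grid)) {
    eps_grid <- if (profile == "full") c(0, 0.2, 0.4, 0.6, 0.8, 1.0)
                else c(0, 1.0)
  }
  if (is.null(pext_grid)) {
    pext_grid <- if (profile == "full") c(1, 2, 5, 10, 20, 50, 100, 200)
                 else c(1, 20, 200)
  }
  if (is.null(mmi_times)) mmi_times <- seq(0, t_end, by = 10)
  if (is.null(inputs)) inputs <- input
  if (n_real < 2) stop("n_real must be >= 2", call. = FALSE)
  if (!length(L)) stop("empty L sweep", call. = FALSE)
  if (!input %in% c("I1", "I2", "I3")) {
    stop("input must be one of I1, I2, I3", call. = FALSE)
  }
  structure(list(experiment = experiment, input = input, inputs = inputs,
                 L = L, n_real = n_real, t_end = t_end, sample_dt = sample_dt,
                 bins = bins, tol_bits = tol_bits, eps_grid = eps_grid,
                 pext_grid = pext_grid, mmi_times = mmi_times,
                 n_boot = n_boot, seed = as.integer(seed), profile = profile),
            class = "experiment_config")
}

# deterministic sub-seed for a named condition (kept < 2^31)
key_seed <- function(master, key) {
  s <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((master * 7919 + s * 104729 + 17) %% 2147483629)
}

# simulate one ensemble per L level; builder maps an input_spec to a network
simulate_sweep <- function(builder, config, seed_key, noise = NULL,
                           keep_species = NULL) {
  spec0 <- standard_inputs()[[config$input]]
  ens <- lapply(config$L, function(L) {
    spec <- with_L(spec0, L)
    e <- ssa_simulate(builder(spec), spec, t_end = config$t_end,
                      n_real = config$n_real,
                      seed = key_seed(config$seed, paste0(seed_key, "/L", L)),
                      noise = noise, sample_dt = config$sample_dt)
    if (!is.null(keep_species)) e <- slim_ensemble(e, keep_species)
    e
  })
  stats::setNames(ens, as.character(config$L))
}

slim_ensemble <- function(ens, species) {
  ens$counts <- ens$counts[, , species, drop = FALSE]
  ens$species <- species
  ens
}

cc_table <- function(ens, species_vec, config) {
  do.call(rbind, lapply(species_vec, function(sp) {
    cbind(species = sp,
          cc_timeseries(ens, sp, bins = config$bins,
                        tol_bits = config$tol_bits))
  }))
}

mean_table <- function(ens, species_vec) {
  do.call(rbind, lapply(names(ens), function(L) {
    mu <- ensemble_mean(ens[[L]], species_vec)
    data.frame(L = as.numeric(L),
               time = rep(ens[[L]]$sample_times, times = length(species_vec)),
               species = rep(species_vec, each = length(ens[[L]]$sample_times)),
               mean = as.vector(mu))
  }))
}

cv_table <- function(ens, species_vec, t) {
  do.call(rbind, lapply(names(ens), function(L) {
    data.frame(L = as.numeric(L), time = t, species = species_vec,
               cv = vapply(species_vec, function(sp)
                 coefficient_of_variation(ens[[L]], sp, t), numeric(1)))
  }))
}

#' Reporter genes on the decoding section: CC over time
#'
#' Couples two identical single-copy reporter genes to the MAPK/ERK decoding
#' section -- `Prt_w` reading the pathway output pcFos, `Prt_wo` reading
#' ppERK_nuc directly -- simulates the L sweep, and returns per-minute
#' channel capacities for readouts along the cascade
#' (`ppERK_nuc`, `cFos`, `pcFos`, `Prt_w.P`, `Prt_wo.P`) together with
#' ensemble mean traces.
#'
#' @param config an [experiment_config()].
#' @return List with `cc` (time series per species), `means`, and the
#'   per-level `ensembles`.
#' @export
run_mapk_cc <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  net <- compose(build_mapk_network(),
                 build_gene_network("pcFos", affinity_variant("N"), "Prt_w"),
                 build_gene_network("ppERK_nuc", affinity_variant("N"), "Prt_wo"))
  ens <- simulate_sweep(function(spec) net, config, "mapk_cc")
  sp <- c("ppERK_nuc", "cFos", "pcFos", "Prt_w.P", "Prt_wo.P")
  list(config = config,
       cc = cc_table(ens, sp, config),
       means = mean_table(ens, sp),
       ensembles = ens)
}

#' Minimal decoder: CC over time and CV versus input scale
#'
#' Runs the steady-state-normalized minimal FFL decoder over the L sweep for
#' each requested input, returning the CC time series of proteins B-E, the
#' coefficient of variation versus L at t = 150 min, and the late-time CC
#' per input (the `I3 > I2 > I1` comparison).
#'
#' @param config an [experiment_config()]; `config$inputs` selects the
#'   inputs compared (first one supplies the CC/CV tables).
#' @return List with `cc`, `cv`, `cc_late` and per-input `ensembles`.
#' @export
run_minimal_cc <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  sp <- c("B", "C", "D", "E")
  all_ens <- list()
  cc_late <- NULL
  for (inp in config$inputs) {
    cfg_i <- config
    cfg_i$input <- inp
    ens <- simulate_sweep(build_minimal_network, cfg_i,
                          paste0("minimal_cc/", inp))
    all_ens[[inp]] <- ens
    late <- do.call(rbind, lapply(sp, function(s) {
      ch <- estimate_channel(ens, s, config$t_end, config$bins)
      data.frame(input = inp, species = s,
                 cc = arimoto_blahut(ch, config$tol_bits)$cc_bits)
    }))
    cc_late <- rbind(cc_late, late)
  }
  ens1 <- all_ens[[config$inputs[1]]]
  list(config = config,
       cc = cc_table(ens1, sp, config),
       cv = cv_table(ens1, sp, t = min(150, config$t_end)),
       cc_late = cc_late,
       ensembles = all_ens)
}

#' Feed-forward loop versus linear chain
#'
#' Simulates the minimal FFL decoder and the linear-chain control under the
#' same per-condition seeds and returns paired CC time series and CV-at-150
#' tables for both topologies.
#'
#' @param config an [experiment_config()].
#' @return List with `cc` (column `topology`), `cv`, and `ensembles` (one
#'   sweep per topology).
#' @export
run_linear_vs_ffl <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  sp <- c("B", "C", "D", "E")
  builders <- list(ffl = build_minimal_network,
                   linear = build_linear_chain_network)
  ens <- lapply(builders, function(b)
    simulate_sweep(b, config, "linear_vs_ffl"))  # same key: paired seeds
  cc <- do.call(rbind, lapply(names(ens), function(tp)
    cbind(topology = tp, cc_table(ens[[tp]], sp, config))))
  cv <- do.call(rbind, lapply(names(ens), function(tp)
    cbind(topology = tp, cv_table(ens[[tp]], sp, t = min(150, config$t_end)))))
  list(config = config, cc = cc, cv = cv, ensembles = ens)
}

#' Promoter affinity and the FFL coupled: per-gene CC and set MMI
#'
#' Couples two triplets of reporter genes -- high, nominal and low promoter
#' affinity -- to the decoding section, one triplet reading the pathway
#' output pcFos (`W`), one reading ppERK_nuc (`WO`), and returns the CC time
#' series of each reporter protein plus the multivariate mutual information
#' of each triplet over time.
#'
#' @param config an [experiment_config()].
#' @return List with `cc`, `mmi` (columns `set`, `time`, `mmi`), `genes`
#'   (the six protein species names) and `ensembles`.
#' @export
run_affinity_mmi <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  sets <- list(W = "pcFos", WO = "ppERK_nuc")
  tags <- unlist(lapply(names(sets), function(s)
    paste(s, c("H", "N", "L"), sep = ".")))
  genes <- do.call(c, lapply(names(sets), function(s)
    lapply(c("H", "N", "L"), function(a)
      build_gene_network(sets[[s]], affinity_variant(a),
                         paste(s, a, sep = ".")))))
  net <- do.call(compose, c(list(build_mapk_network()), genes))
  ens <- simulate_sweep(function(spec) net, config, "affinity_mmi")
  proteins <- paste0(tags, ".P")
  mmi_df <- do.call(rbind, lapply(names(sets), function(s) {
    set_proteins <- paste0(s, ".", c("H", "N", "L"), ".P")
    do.call(rbind, lapply(config$mmi_times, function(t) {
      chans <- lapply(set_proteins, function(p)
        estimate_channel(ens, p, t, config$bins))
      data.frame(set = s, time = t,
                 mmi = mmi(chans, tol_bits = max(config$tol_bits, 1e-5)))
    }))
  }))
  list(config = config,
       cc = cc_table(ens, proteins, config),
       mmi = mmi_df, genes = proteins, ensembles = ens)
}

#' Extrinsic noise and information transmission
#'
#' Puts piecewise-constant lognormal extrinsic noise on the pcFos
#' phosphorylation rate `k11` and maps the channel capacity of the coupled
#' reporter `Prt_w` over the `eps_noise` x `P_ext` grid.
#'
#' @param config an [experiment_config()].
#' @return List with `surface` (`eps`, `p_ext`, `time`, `cc`) and the
#'   per-condition slimmed `ensembles` (reporter protein only).
#' @export
run_extrinsic_noise <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  net <- compose(build_mapk_network(),
                 build_gene_network("pcFos", affinity_variant("N"), "Prt_w"))
  conds <- expand.grid(eps = config$eps_grid, p_ext = config$pext_grid)
  surface <- NULL
  keep <- list()
  for (i in seq_len(nrow(conds))) {
    eps <- conds$eps[i]; pe <- conds$p_ext[i]
    noise <- extrinsic_noise_spec("k11", eps_noise = eps, p_ext = pe)
    key <- sprintf("extrinsic/eps%g/pext%g", eps, pe)
    ens <- simulate_sweep(function(spec) net, config, key, noise = noise,
                          keep_species = "Prt_w.P")
    cc <- cc_timeseries(ens, "Prt_w.P", bins = config$bins,
                        tol_bits = config$tol_bits)
    surface <- rbind(surface,
                     data.frame(eps = eps, p_ext = pe,
                                time = cc$time, cc = cc$cc))
    keep[[key]] <- ens
  }
  list(config = config, surface = surface, ensembles = keep)
}

#' Run an experiment by id
#'
#' Dispatches to the matching `run_*` driver; with `out_dir` set, writes the
#' tabular outputs and a JSON run manifest there.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional output directory for CSV tables and manifest.
#' @return The driver's result list (invisibly when writing).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  res <- switch(config$experiment,
                mapk_cc = run_mapk_cc(config),
                minimal_cc = run_minimal_cc(config),
                linear_vs_ffl = run_linear_vs_ffl(config),
                affinity_mmi = run_affinity_mmi(config),
                extrinsic_noise = run_extrinsic_noise(config))
  if (!is.null(out_dir)) {
    write_experiment_csv(res, out_dir)
    return(invisible(res))
  }
  res
}

#' Write an experiment's metric tables
#'
#' Each data-frame component of the result goes to `<out_dir>/<name>.csv`;
#' the configuration is written as `manifest.json`. Re-running the same
#' (config, seed) reproduces these files byte-identically.
#'
#' @param result a `run_*` result list.
#' @param out_dir directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_experiment_csv <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result)) {
    if (is.data.frame(result[[nm]])) {
      utils::write.csv(result[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(unclass(result$config),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
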