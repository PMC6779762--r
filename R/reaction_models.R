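#' @useDynLib decodecap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- propensity descriptors --------------------------------------------
# Shared between the R evaluator, the ODE mean-field right-hand side and the
# compiled SSA core. Type codes must match src/ssa.cpp.

prop_const    <- function(coef, rate_param = NA_character_)
  list(type = 0L, coef = coef, s = character(0), rate_param = rate_param)
prop_linear   <- function(coef, sp, rate_param = NA_character_)
  list(type = 1L, coef = coef, s = sp, rate_param = rate_param)
prop_bilinear <- function(coef, sp2, rate_param = NA_character_)
  list(type = 2L, coef = coef, s = sp2, rate_param = rate_param)
prop_hill_prod <- function(coef, sp2, n, K)
  list(type = 3L, coef = coef, s = sp2, n = n, K = K)
prop_hill_gate <- function(coef, tf, gate, n, K)
  list(type = 4L, coef = coef, s = c(tf, gate), n = n, K = K)
prop_input_prod <- function(coef, Tc)
  list(type = 5L, coef = coef, s = character(0), Tc = Tc)
prop_input_deg <- function(coef, Tc, sp)
  list(type = 6L, coef = coef, s = sp, Tc = Tc)

rxn <- function(name, consumed = NULL, produced = NULL, prop) {
  list(name = name,
       consumed = if (is.null(consumed)) integer(0) else consumed,
       produced = if (is.null(produced)) integer(0) else produced,
       prop = prop)
}

#' Construct a reaction network
#'
#' A network is an ordered species list, a set of reactions (each with a
#' consumed/produced stoichiometry map and a propensity rule), a parameter
#' table and an initial state. Species read catalytically by a propensity do
#' not appear in the stoichiometry maps.
#'
#' @param name network identifier.
#' @param species ordered character vector of species names.
#' @param reactions list of reactions (internal constructors).
#' @param params named list of kinetic parameters (book-keeping; propensity
#'   coefficients are resolved at build time).
#' @param initial_state named integer vector; species not named start at 0.
#' @param input_species name of the species driven by the stochastic input
#'   hazards, or `NULL` for autonomous networks.
#' @param input_spec optional [input_spec()] bound to the network at build
#'   time (used as the default for [ssa_simulate()] and [ode_integrate()]).
#' @return An object of class `reaction_network`.
#' @export
reaction_network <- function(name, species, reactions, params = list(),
                             initial_state = NULL, input_species = NULL,
                             input_spec = NULL) {
  stopifnot(is.character(species))
  if (anyDuplicated(species)) stop("duplicated species names", call. = FALSE)
  init <- stats::setNames(integer(length(species)), species)
  if (!is.null(initial_state)) {
    bad <- setdiff(names(initial_state), species)
    if (length(bad)) stop("initial state names undeclared: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(initial_state < 0)) stop("initial counts must be >= 0", call. = FALSE)
    init[names(initial_state)] <- as.integer(initial_state)
  }
  for (r in reactions) {
    refs <- c(names(r$consumed), names(r$produced), r$prop$s)
    bad <- setdiff(refs, species)
    if (length(bad)) stop("reaction '", r$name, "' references undeclared species: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(input_species) && !input_species %in% species) {
    stop("input_species must be a declared species", call. = FALSE)
  }
  structure(list(name = name, species = species, reactions = reactions,
                 params = params, initial_state = init,
                 input_species = input_species, input_spec = input_spec),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network %s> %d species, %d reactions%s\n",
              x$name, length(x$species), length(x$reactions),
              if (is.null(x$input_species)) ""
              else paste0(", input-driven via ", x$input_species)))
  invisible(x)
}

# the two time-inhomogeneous input reactions (hazards from the input spec)
input_reactions <- function(spec, sp) {
  list(rxn(paste0(sp, "_production"), produced = stats::setNames(1L, sp),
           prop = prop_input_prod(spec$k1 * spec$L / spec$T1, spec$T1)),
       rxn(paste0(sp, "_degradation"), consumed = stats::setNames(1L, sp),
           prop = prop_input_deg(spec$k2 * spec$L / spec$T2, spec$T2, sp)))
}

#' Published kinetic rate constants of the three stochastic models
#'
#' Single source of the published rate constants: the MAPK/ERK decoding
#' block, the minimal decoder block and the reporter-gene block. All builders
#' read from this table, so a single test pins the printed values.
#'
#' @return Nested named list with components `mapk`, `minimal`, `gene`.
#' @export
rate_constants <- function() {
  list(
    mapk = list(k1 = 15.0, k = 1.0, k2 = 50.0, k3 = 14.0, k4 = 0.1,
                k5 = 0.15, n = 1.1, k6 = 0.13, k7 = 0.5, k8 = 0.08,
                k9 = 0.3, k10 = 0.3, k11 = 0.11, k12 = 0.001, k13 = 0.6),
    minimal = list(k = 20, g = 0.1),
    gene = list(kappa_pm = 0.1, n_g = 2.0, K_rp = 100, gamma_pm = 0.2,
                kappa_m = 14.0, gamma_m = 1.0, kappa_p = 20.0, gamma_p = 0.1)
  )
}

#' MAPK/ERK decoding-section network
#'
#' The subnetwork downstream of cytoplasmic ppERK: nuclear import, DUSP
#' negative feedback, RSK activation, Hill-type cFos transcription, and the
#' cFos/pcFos stabilization cycle -- two nested coherent type I feed-forward
#' loops with ppERK_cyt as input and pcFos as output.
#'
#' Stoichiometry follows the deterministic equations: ppERK_cyt is prescribed
#' by the input process and is only read (never consumed) by the import and
#' stabilization reactions; DUSP, pRSK and cFos_pre production are catalytic
#' in their activators; pcFos activation consumes cFos and the inactivation
#' step regenerates it. DUSP has production but no decay.
#'
#' @param input_spec optional [input_spec()] to bind as the network default.
#' @return A `reaction_network` over species `ppERK_cyt`, `ppERK_nuc`,
#'   `DUSP`, `pRSK_nuc`, `cFos_pre`, `cFos_m`, `cFos`, `pcFos`.
#' @export
build_mapk_network <- function(input_spec = NULL) {
  p <- rate_constants()$mapk
  sp <- c("ppERK_cyt", "ppERK_nuc", "DUSP", "pRSK_nuc",
          "cFos_pre", "cFos_m", "cFos", "pcFos")
  rx <- list(
    rxn("erk_import", produced = c(ppERK_nuc = 1L),
        prop = prop_linear(p$k1, "ppERK_cyt", "k1")),
    rxn("dusp_production", produced = c(DUSP = 1L),
        prop = prop_linear(p$k, "ppERK_nuc", "k")),
    rxn("erk_export", consumed = c(ppERK_nuc = 1L),
        prop = prop_linear(p$k2, "ppERK_nuc", "k2")),
    rxn("erk_dephos_dusp", consumed = c(ppERK_nuc = 1L),
        prop = prop_bilinear(p$k3, c("DUSP", "ppERK_nuc"), "k3")),
    rxn("rsk_activation", produced = c(pRSK_nuc = 1L),
        prop = prop_linear(p$k4, "ppERK_nuc", "k4")),
    rxn("rsk_decay", consumed = c(pRSK_nuc = 1L),
        prop = prop_linear(p$k5, "pRSK_nuc", "k5")),
    rxn("cfos_pre_production", produced = c(cFos_pre = 1L),
        prop = prop_hill_prod(1.0, c("ppERK_nuc", "pRSK_nuc"), p$n, p$k6)),
    rxn("cfos_splicing", consumed = c(cFos_pre = 1L), produced = c(cFos_m = 1L),
        prop = prop_linear(p$k7, "cFos_pre", "k7")),
    rxn("cfos_mrna_decay", consumed = c(cFos_m = 1L),
        prop = prop_linear(p$k8, "cFos_m", "k8")),
    rxn("cfos_translation", produced = c(cFos = 1L),
        prop = prop_linear(p$k9, "cFos_m", "k9")),
    rxn("cfos_decay", consumed = c(cFos = 1L),
        prop = prop_linear(p$k10, "cFos", "k10")),
    rxn("cfos_activation", consumed = c(cFos = 1L), produced = c(pcFos = 1L),
        prop = prop_bilinear(p$k11, c("ppERK_cyt", "cFos"), "k11")),
    rxn("pcfos_decay", consumed = c(pcFos = 1L),
        prop = prop_linear(p$k12, "pcFos", "k12")),
    rxn("pcfos_inactivation", consumed = c(pcFos = 1L), produced = c(cFos = 1L),
        prop = prop_linear(p$k13, "pcFos", "k13"))
  )
  reaction_network("mapk", sp, rx, params = p,
                   input_species = "ppERK_cyt", input_spec = input_spec)
}

#' Minimal decoder network (two nested feed-forward loops)
#'
#' Four proteins B, C, D, E driven by the input A, wired as two nested
#' coherent FFLs with all production steps catalytic. Propensities are
#' normalized by `A_N = L (k1 - k2)` (the input plateau) and `G_N = k/g` so
#' that every protein shares the common steady state `SS = A_N * G_N`; the
#' network amplifies nothing by construction, isolating the topology's
#' contribution to information transfer.
#'
#' @param input_spec an [input_spec()]; supplies `A_N` and becomes the
#'   network's default input.
#' @return A `reaction_network` over species `A`, `B`, `C`, `D`, `E` with
#'   `A_N` and `G_N` recorded in `params`.
#' @export
build_minimal_network <- function(input_spec) {
  stopifnot(inherits(input_spec, "input_spec"))
  p <- rate_constants()$minimal
  A_N <- input_spec$L * (input_spec$k1 - input_spec$k2)
  if (A_N <= 0) stop("input plateau A_N = L(k1-k2) must be positive", call. = FALSE)
  G_N <- p$k / p$g
  rx <- c(ffl_backbone(p, A_N, G_N),
          list(
            rxn("d_production", produced = c(D = 1L),
                prop = prop_bilinear(p$k / (A_N * G_N^2), c("B", "C"), "k")),
            rxn("e_production", produced = c(E = 1L),
                prop = prop_bilinear(p$k / (A_N * G_N^2), c("C", "D"), "k"))
          ))
  reaction_network("minimal", c("A", "B", "C", "D", "E"), rx,
                   params = c(p, list(A_N = A_N, G_N = G_N)),
                   input_species = "A", input_spec = input_spec)
}

# shared B/C production and the four decay reactions
ffl_backbone <- function(p, A_N, G_N) {
  list(
    rxn("b_production", produced = c(B = 1L), prop = prop_linear(p$k, "A", "k")),
    rxn("b_decay", consumed = c(B = 1L), prop = prop_linear(p$g, "B", "g")),
    rxn("c_production", produced = c(C = 1L),
        prop = prop_linear(p$k / G_N, "B", "k")),
    rxn("c_decay", consumed = c(C = 1L), prop = prop_linear(p$g, "C", "g")),
    rxn("d_decay", consumed = c(D = 1L), prop = prop_linear(p$g, "D", "g")),
    rxn("e_decay", consumed = c(E = 1L), prop = prop_linear(p$g, "E", "g"))
  )
}

#' Linear-chain control network
#'
#' Identical to [build_minimal_network()] except that D is produced at rate
#' `k C / G_N` and E at `k D / G_N` -- a plain four-protein relay with no
#' joint regulation. Same parameters, same common steady state `A_N * G_N`.
#'
#' @inheritParams build_minimal_network
#' @return A `reaction_network` over `A`, `B`, `C`, `D`, `E`.
#' @export
build_linear_chain_network <- function(input_spec) {
  stopifnot(inherits(input_spec, "input_spec"))
  p <- rate_constants()$minimal
  A_N <- input_spec$L * (input_spec$k1 - input_spec$k2)
  if (A_N <= 0) stop("input plateau A_N = L(k1-k2) must be positive", call. = FALSE)
  G_N <- p$k / p$g
  rx <- c(ffl_backbone(p, A_N, G_N),
          list(
            rxn("d_production", produced = c(D = 1L),
                prop = prop_linear(p$k / G_N, "C", "k")),
            rxn("e_production", produced = c(E = 1L),
                prop = prop_linear(p$k / G_N, "D", "k"))
          ))
  reaction_network("linear_chain", c("A", "B", "C", "D", "E"), rx,
                   params = c(p, list(A_N = A_N, G_N = G_N)),
                   input_species = "A", input_spec = input_spec)
}

#' Promoter-affinity variant
#'
#' Reporter genes come in three promoter-affinity flavours obtained by
#' scaling the half-saturation constant `K_rp` (which is the *inverse* of the
#' affinity): `H` high affinity (`K_rp` x 0.1), `N` nominal (x 1), `L` low
#' (x 10).
#'
#' @param tag one of `"H"`, `"N"`, `"L"`, or a positive numeric scale.
#' @return An object of class `affinity_variant` with fields `tag`, `scale`.
#' @export
affinity_variant <- function(tag = "N") {
  if (is.numeric(tag)) {
    stopifnot(tag > 0)
    return(structure(list(tag = "custom", scale = tag), class = "affinity_variant"))
  }
  scale <- switch(tag, H = 0.1, N = 1.0, L = 10.0,
                  stop("affinity tag must be H, N or L", call. = FALSE))
  structure(list(tag = tag, scale = scale), class = "affinity_variant")
}

#' Single-copy reporter gene network
#'
#' A constitutive gene-expression cassette read out by a transcription
#' factor of a host network: a single promoter copy switching between the
#' inactive (`Pm_star`) and active (`Pm`) state, transcription from the
#' active state, and translation. Promoter activation is Hill-type in the
#' transcription factor with exponent `n_g = 2` and half-saturation
#' `scale * K_rp`; `Pm_star + Pm = 1` is conserved and the promoter starts
#' inactive.
#'
#' The cassette reads `tf_species` catalytically, so attaching it via
#' [compose()] never perturbs the host dynamics.
#'
#' @param tf_species name of the transcription-factor species (a species of
#'   the host network when composed; declared locally so the cassette is
#'   testable standalone).
#' @param variant an [affinity_variant()].
#' @param tag name prefix used when the cassette is composed into a host
#'   (protein species becomes `<tag>.P`).
#' @return A `reaction_network` over `tf_species` plus `Pm_star`, `Pm`, `m`,
#'   `P`.
#' @export
build_gene_network <- function(tf_species, variant = affinity_variant("N"),
                               tag = "gene") {
  stopifnot(inherits(variant, "affinity_variant"), is.character(tf_species))
  p <- rate_constants()$gene
  sp <- c(tf_species, "Pm_star", "Pm", "m", "P")
  rx <- list(
    rxn("promoter_activation", consumed = c(Pm_star = 1L), produced = c(Pm = 1L),
        prop = prop_hill_gate(p$kappa_pm, tf_species, "Pm_star",
                              p$n_g, variant$scale * p$K_rp)),
    rxn("promoter_inactivation", consumed = c(Pm = 1L), produced = c(Pm_star = 1L),
        prop = prop_linear(p$gamma_pm, "Pm", "gamma_pm")),
    rxn("transcription", produced = c(m = 1L),
        prop = prop_linear(p$kappa_m, "Pm", "kappa_m")),
    rxn("mrna_decay", consumed = c(m = 1L),
        prop = prop_linear(p$gamma_m, "m", "gamma_m")),
    rxn("translation", produced = c(P = 1L),
        prop = prop_linear(p$kappa_p, "m", "kappa_p")),
    rxn("protein_decay", consumed = c(P = 1L),
        prop = prop_linear(p$gamma_p, "P", "gamma_p"))
  )
  net <- reaction_network(paste0("gene_", tag), sp, rx,
                          params = c(p, list(K_scale = variant$scale)),
                          initial_state = c(Pm_star = 1L))
  net$gene_tag <- tag
  net$tf_species <- tf_species
  net
}

#' Compose a host network with reporter genes
#'
#' Attaches one or more reporter cassettes to a host. Gene species are
#' renamed `<tag>.<species>`; the transcription factor keeps its host name
#' and is read catalytically, so the host's dynamics are unchanged by
#' construction (no gene reaction touches a host species and no host
#' propensity reads a gene species).
#'
#' @param host a `reaction_network`.
#' @param ... reporter networks from [build_gene_network()], each with a
#'   distinct `tag` and a `tf_species` present in the host.
#' @return The composed `reaction_network`.
#' @export
compose <- function(host, ...) {
  genes <- list(...)
  stopifnot(inherits(host, "reaction_network"), length(genes) >= 1)
  species <- host$species
  reactions <- host$reactions
  params <- host$params
  init <- host$initial_state
  for (g in genes) {
    stopifnot(inherits(g, "reaction_network"), !is.null(g$gene_tag))
    if (!g$tf_species %in% host$species) {
      stop("gene '", g$gene_tag, "': TF species '", g$tf_species,
           "' not in host", call. = FALSE)
    }
    local_sp <- setdiff(g$species, g$tf_species)
    new_sp <- paste(g$gene_tag, local_sp, sep = ".")
    if (any(new_sp %in% species)) {
      stop("species name clash for gene tag '", g$gene_tag, "'", call. = FALSE)
    }
    map <- stats::setNames(new_sp, local_sp)
    map[g$tf_species] <- g$tf_species
    rename <- function(v) if (length(v)) stats::setNames(v, unname(map[names(v)])) else v
    for (r in g$reactions) {
      r$name <- paste(g$gene_tag, r$name, sep = ".")
      r$consumed <- rename(r$consumed)
      r$produced <- rename(r$produced)
      r$prop$s <- unname(map[r$prop$s])
      reactions <- c(reactions, list(r))
    }
    species <- c(species, new_sp)
    gi <- g$initial_state[local_sp]
    init <- c(init, stats::setNames(gi, unname(map[local_sp])))
    params[[g$gene_tag]] <- g$params
  }
  reaction_network(paste0(host$name, "+", length(genes), "genes"),
                   species, reactions, params, initial_state = init,
                   input_species = host$input_species,
                   input_spec = host$input_spec)
}

#' Evaluate all propensities of a network
#'
#' Reference (R-level) propensity evaluator, shared by the mean-field ODE
#' right-hand side and by tests of the compiled simulator. If the network is
#' input-driven and `spec` is supplied, the two input-hazard reactions are
#' appended after the network's own reactions.
#'
#' @param network a `reaction_network`.
#' @param state named numeric vector over `network$species`.
#' @param t time (min).
#' @param spec optional [input_spec()] (defaults to the network's own).
#' @return Named numeric vector of event rates (events/min).
#' @export
propensities <- function(network, state, t = 0,
                         spec = network$input_spec) {
  x <- stats::setNames(numeric(length(network$species)), network$species)
  x[names(state)] <- state
  rx <- network$reactions
  if (!is.null(network$input_species) && !is.null(spec)) {
    rx <- c(rx, input_reactions(spec, network$input_species))
  }
  vapply(rx, function(r) eval_prop(r$prop, x, t), numeric(1)) |>
    stats::setNames(vapply(rx, `[[`, "", "name"))
}

eval_prop <- function(pr, x, t) {
  switch(as.character(pr$type),
    "0" = pr$coef,
    "1" = pr$coef * x[[pr$s[1]]],
    "2" = pr$coef * x[[pr$s[1]]] * x[[pr$s[2]]],
    "3" = {
      v <- x[[pr$s[1]]] * x[[pr$s[2]]]
      if (v <= 0) 0 else pr$coef * v^pr$n / (v^pr$n + pr$K^pr$n)
    },
    "4" = {
      tf <- x[[pr$s[1]]]
      if (tf <= 0) 0 else pr$coef * x[[pr$s[2]]] * tf^pr$n / (tf^pr$n + pr$K^pr$n)
    },
    "5" = pr$coef * exp(-t / pr$Tc),
    "6" = if (x[[pr$s[1]]] > 0) pr$coef * exp(-t / pr$Tc) else 0,
    stop("unknown propensity type")
  )
}

#' Net stoichiometry matrix
#'
#' @param network a `reaction_network`.
#' @param spec optional [input_spec()]; when the network is input-driven the
#'   two input reactions are appended (as in [propensities()]).
#' @return Integer matrix, reactions x species, of net count changes.
#' @export
stoichiometry <- function(network, spec = network$input_spec) {
  rx <- network$reactions
  if (!is.null(network$input_species) && !is.null(spec)) {
    rx <- c(rx, input_reactions(spec, network$input_species))
  }
  S <- matrix(0L, nrow = length(rx), ncol = length(network$species),
              dimnames = list(vapply(rx, `[[`, "", "name"), network$species))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    if (length(r$consumed)) S[i, names(r$consumed)] <- S[i, names(r$consumed)] - r$consumed
    if (length(r$produced)) S[i, names(r$produced)] <- S[i, names(r$produced)] + r$produced
  }
  S
}

#' Write a human-readable model file
#'
#' Plain-text dump of species, initial state, parameters and reactions.
#'
#' @param network a `reaction_network`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  ln <- c(sprintf("network: %s", network$name),
          sprintf("species: %s", paste(network$species, collapse = " ")),
          sprintf("initial: %s",
                  paste(sprintf("%s=%d", network$species, network$initial_state),
                        collapse = " ")),
          if (!is.null(network$input_species))
            sprintf("input_species: %s", network$input_species),
          "reactions:")
  for (r in network$reactions) {
    lhs <- if (length(r$consumed))
      paste(sprintf("%d %s", r$consumed, names(r$consumed)), collapse = " + ") else "0"
    rhs <- if (length(r$produced))
      paste(sprintf("%d %s", r$produced, names(r$produced)), collapse = " + ") else "0"
    ln <- c(ln, sprintf("  %-24s %s -> %s   [type %d, coef %g%s]",
                        r$name, lhs, rhs, r$prop$type, r$prop$coef,
                        if (!is.null(r$prop$K)) sprintf(", n %g, K %g", r$prop$n, r$prop$K)
                        else if (!is.null(r$prop$Tc)) sprintf(", T %g", r$prop$Tc)
                        else ""))
  }
  writeLines(ln, path)
  invisible(path)
}
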