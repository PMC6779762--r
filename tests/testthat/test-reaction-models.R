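test_that("published rate constants are pinned verbatim", {
  p <- rate_constants()
  expect_equal(p$mapk,
               list(k1 = 15.0, k = 1.0, k2 = 50.0, k3 = 14.0, k4 = 0.1,
                    k5 = 0.15, n = 1.1, k6 = 0.13, k7 = 0.5, k8 = 0.08,
                    k9 = 0.3, k10 = 0.3, k11 = 0.11, k12 = 0.001, k13 = 0.6))
  expect_equal(p$minimal, list(k = 20, g = 0.1))
  expect_equal(p$gene,
               list(kappa_pm = 0.1, n_g = 2.0, K_rp = 100, gamma_pm = 0.2,
                    kappa_m = 14.0, gamma_m = 1.0, kappa_p = 20.0, gamma_p = 0.1))
})

test_that("decoding-section propensities at reference states", {
  net <- build_mapk_network()
  expect_length(net$reactions, 14)
  pr <- propensities(net, c(ppERK_cyt = 10), 0, spec = NULL)
  expect_equal(pr[["erk_import"]], 150)
  # Hill term is 1/2 at its half-saturation product, unit prefactor
  pr <- propensities(net, c(ppERK_nuc = 0.13, pRSK_nuc = 1), 0, spec = NULL)
  expect_equal(pr[["cfos_pre_production"]], 0.5)
  pr <- propensities(net, c(ppERK_nuc = 0, pRSK_nuc = 5), 0, spec = NULL)
  expect_equal(pr[["cfos_pre_production"]], 0)
  pr <- propensities(net, c(ppERK_cyt = 5, cFos = 2), 0, spec = NULL)
  expect_equal(pr[["cfos_activation"]], 0.11 * 10)
  expect_true(all(pr >= 0))
})

test_that("minimal decoder normalization constants and zero-state guards", {
  s <- standard_inputs(L = 100)$I2
  net <- build_minimal_network(s)
  expect_equal(net$params$G_N, 200)
  expect_equal(net$params$A_N, 28.1, tolerance = 1e-12)
  expect_equal(net$params$A_N * net$params$G_N, 5620, tolerance = 1e-9)
  pr <- propensities(net, c(A = 3), 0)
  expect_equal(pr[["b_production"]], 60)
  expect_equal(pr[["e_production"]], 0)
  expect_no_error(build_minimal_network(input_spec(1, 0.999, 1, 1, L = 1e-9)))
})

test_that("mean-field right-hand side reconstructs the governing equations", {
  p <- rate_constants()$mapk
  mapk_rhs <- function(x) {
    hill <- if (x[["ppERK_nuc"]] * x[["pRSK_nuc"]] <= 0) 0 else {
      v <- (x[["ppERK_nuc"]] * x[["pRSK_nuc"]])^p$n
      v / (v + p$k6^p$n)
    }
    c(ppERK_cyt = 0,
      ppERK_nuc = p$k1 * x[["ppERK_cyt"]] -
        x[["ppERK_nuc"]] * (p$k2 + p$k3 * x[["DUSP"]]),
      DUSP = p$k * x[["ppERK_nuc"]],
      pRSK_nuc = p$k4 * x[["ppERK_nuc"]] - p$k5 * x[["pRSK_nuc"]],
      cFos_pre = hill - p$k7 * x[["cFos_pre"]],
      cFos_m = p$k7 * x[["cFos_pre"]] - p$k8 * x[["cFos_m"]],
      cFos = p$k9 * x[["cFos_m"]] + p$k13 * x[["pcFos"]] -
        x[["cFos"]] * (p$k10 + p$k11 * x[["ppERK_cyt"]]),
      pcFos = p$k11 * x[["cFos"]] * x[["ppERK_cyt"]] -
        x[["pcFos"]] * (p$k12 + p$k13))
  }
  net <- build_mapk_network()
  S <- stoichiometry(net, spec = NULL)
  set.seed(4)
  for (i in 1:5) {
    x <- stats::setNames(stats::runif(8, 0, 40), net$species)
    got <- as.numeric(crossprod(S, propensities(net, x, 0, spec = NULL)))
    expect_equal(got, unname(mapk_rhs(x)[net$species]), tolerance = 1e-10)
  }

  s <- standard_inputs(L = 50)$I3
  A_N <- 50 * (0.257 - 0.101); G_N <- 200; k <- 20; g <- 0.1
  min_rhs <- function(x) c(
    A = 0,
    B = k * x[["A"]] - g * x[["B"]],
    C = k * x[["B"]] / G_N - g * x[["C"]],
    D = k * x[["B"]] * x[["C"]] / (A_N * G_N^2) - g * x[["D"]],
    E = k * x[["C"]] * x[["D"]] / (A_N * G_N^2) - g * x[["E"]])
  lin_rhs <- function(x) {
    out <- min_rhs(x)
    out[["D"]] <- k * x[["C"]] / G_N - g * x[["D"]]
    out[["E"]] <- k * x[["D"]] / G_N - g * x[["E"]]
    out
  }
  for (builder in list(build_minimal_network, build_linear_chain_network)) {
    net <- builder(s)
    S <- stoichiometry(net, spec = NULL)
    oracle <- if (identical(builder, build_minimal_network)) min_rhs else lin_rhs
    for (i in 1:5) {
      x <- stats::setNames(stats::runif(5, 0, 2000), net$species)
      got <- as.numeric(crossprod(S, propensities(net, x, 0, spec = NULL)))
      expect_equal(got, unname(oracle(x)[net$species]), tolerance = 1e-10)
    }
  }

  pg <- rate_constants()$gene
  gnet <- build_gene_network("TF")
  gene_rhs <- function(x) {
    hill <- if (x[["TF"]] <= 0) 0 else x[["TF"]]^2 / (x[["TF"]]^2 + 100^2)
    act <- pg$kappa_pm * hill * x[["Pm_star"]]
    c(TF = 0,
      Pm_star = pg$gamma_pm * x[["Pm"]] - act,
      Pm = act - pg$gamma_pm * x[["Pm"]],
      m = pg$kappa_m * x[["Pm"]] - pg$gamma_m * x[["m"]],
      P = pg$kappa_p * x[["m"]] - pg$gamma_p * x[["P"]])
  }
  S <- stoichiometry(gnet)
  for (i in 1:5) {
    x <- stats::setNames(stats::runif(5, 0, 150), gnet$species)
    got <- as.numeric(crossprod(S, propensities(gnet, x, 0)))
    expect_equal(got, unname(gene_rhs(x)[gnet$species]), tolerance = 1e-10)
  }
})

test_that("linear-chain topology: D reads only C", {
  s <- tiny_input()
  net <- build_linear_chain_network(s)
  dprod <- Filter(function(r) r$name == "d_production", net$reactions)[[1]]
  expect_identical(dprod$prop$s, "C")
  expect_equal(propensities(net, c(C = 0, B = 500), 0)[["d_production"]], 0)
})

test_that("promoter-affinity variants scale the half-saturation constant", {
  expect_equal(affinity_variant("H")$scale, 0.1)
  expect_equal(affinity_variant("N")$scale, 1.0)
  expect_equal(affinity_variant("L")$scale, 10.0)
  expect_error(affinity_variant("X"), "H, N or L")
  g <- build_gene_network("TF", affinity_variant("N"))
  pr <- propensities(g, c(TF = 100, Pm_star = 1), 0)
  expect_equal(pr[["promoter_activation"]], 0.05)
  expect_equal(propensities(g, c(TF = 0, Pm_star = 1), 0)[["promoter_activation"]], 0)
  gH <- build_gene_network("TF", affinity_variant("H"))
  expect_equal(propensities(gH, c(TF = 10, Pm_star = 1), 0)[["promoter_activation"]],
               0.05)
  # reporter protein gain at full promoter occupancy
  pg <- rate_constants()$gene
  expect_equal(pg$kappa_m * pg$kappa_p / (pg$gamma_m * pg$gamma_p), 2800)
})

test_that("composition renames gene species, keeps the promoter copy, and is catalytic by construction", {
  host <- build_mapk_network()
  net <- compose(host,
                 build_gene_network("pcFos", affinity_variant("N"), "Prt_w"),
                 build_gene_network("ppERK_nuc", affinity_variant("N"), "Prt_wo"))
  expect_length(net$species, 8 + 2 * 4)
  expect_equal(net$initial_state[["Prt_w.Pm_star"]], 1L)
  genes6 <- unlist(lapply(c("W", "WO"), function(s)
    lapply(c("H", "N", "L"), function(a)
      build_gene_network(if (s == "W") "pcFos" else "ppERK_nuc",
                         affinity_variant(a), paste(s, a, sep = ".")))),
    recursive = FALSE)
  six <- do.call(compose, c(list(host), genes6))
  expect_length(six$species, 8 + 6 * 4)
  # structural catalysis: no gene reaction changes a host species, and no
  # host reaction reads a gene species
  S <- stoichiometry(net, spec = NULL)
  gene_rxns <- grepl("^Prt_", rownames(S))
  expect_true(all(S[gene_rxns, host$species] == 0))
  host_rxns <- net$reactions[!grepl("^Prt_", vapply(net$reactions, `[[`, "", "name"))]
  reads <- unlist(lapply(host_rxns, function(r) r$prop$s))
  expect_true(all(reads %in% host$species))
  expect_error(compose(host,
                       build_gene_network("pcFos", tag = "g"),
                       build_gene_network("pcFos", tag = "g")),
               "clash")
  expect_error(compose(host, build_gene_network("nope", tag = "g")), "not in host")
})

test_that("network plumbing validates and serializes", {
  expect_error(reaction_network("x", c("A", "A"), list()), "duplicate")
  expect_error(reaction_network("x", "A", list(), initial_state = c(B = 1L)),
               "undeclared")
  net <- build_birth_death_network()
  f <- tempfile(fileext = ".txt")
  write_network(net, f)
  txt <- readLines(f)
  expect_true(any(grepl("birth_death", txt)))
  expect_true(any(grepl("X", txt)))
})
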