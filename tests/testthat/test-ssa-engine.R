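test_that("identical seed and condition reproduce ensembles bit-exactly", {
  s <- tiny_input()
  net <- build_minimal_network(s)
  e1 <- ssa_simulate(net, s, t_end = 40, n_real = 10, seed = 3)
  e2 <- ssa_simulate(net, s, t_end = 40, n_real = 10, seed = 3)
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$seeds, e2$seeds)
  e3 <- ssa_simulate(net, s, t_end = 40, n_real = 10, seed = 4)
  expect_false(identical(e1$counts, e3$counts))
})

test_that("a network with no active source stays identically zero", {
  g <- build_gene_network("TF")  # TF starts at 0: the promoter can never fire
  e <- ssa_simulate(g, t_end = 50, n_real = 5, seed = 1)
  expect_true(all(e$counts[, , c("TF", "Pm", "m", "P")] == 0))
  expect_true(all(e$counts[, , "Pm_star"] == 1))
})

test_that("linear birth-death stationary law is Poisson (mean = variance)", {
  net <- build_birth_death_network(20, 0.1)
  e <- ssa_simulate(net, t_end = 150, n_real = 300, seed = 1)
  x <- e$counts[, dim(e$counts)[2], "X"]
  se_mean <- sqrt(200 / length(x))
  expect_lt(abs(mean(x) - 200), 3 * se_mean)
  fano <- stats::var(x) / mean(x)
  expect_lt(abs(fano - 1), 3 * sqrt(2 / (length(x) - 1)))
})

test_that("extrinsic parameter sampling follows the lognormal spec", {
  n0 <- extrinsic_noise_spec("k11", eps_noise = 0)
  expect_identical(sample_extrinsic(n0, 10), rep(0.11, 10))
  set.seed(9)
  draws <- sample_extrinsic(extrinsic_noise_spec("k11", eps_noise = 1), 1e5)
  expect_equal(stats::median(draws), 0.11, tolerance = 0.02)
  vars <- vapply(c(0.2, 0.5, 1.0), function(e) {
    set.seed(31)
    stats::var(sample_extrinsic(extrinsic_noise_spec("k11", eps_noise = e), 2e4))
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
  expect_error(extrinsic_noise_spec(eps_noise = -1), "eps_noise")
  expect_error(extrinsic_noise_spec(p_ext = 0), "p_ext")
})

test_that("extrinsic noise in simulation: zero intensity is the nominal model, positive intensity widens the law", {
  net <- build_birth_death_network(20, 0.1)
  base <- ssa_simulate(net, t_end = 100, n_real = 120, seed = 8)
  same <- ssa_simulate(net, t_end = 100, n_real = 120, seed = 8,
                       noise = extrinsic_noise_spec("birth", eps_noise = 0,
                                                    nominal = 20))
  expect_identical(base$counts, same$counts)
  noisy <- ssa_simulate(net, t_end = 100, n_real = 120, seed = 8,
                        noise = extrinsic_noise_spec("birth", eps_noise = 0.6,
                                                     p_ext = 200, nominal = 20))
  x0 <- base$counts[, 101, "X"]; x1 <- noisy$counts[, 101, "X"]
  expect_gt(stats::var(x1), 2 * stats::var(x0))
  # median-preserving: means stay in the right ballpark
  expect_gt(mean(x1), 100)
  expect_error(ssa_simulate(net, t_end = 10, n_real = 2, seed = 1,
                            noise = extrinsic_noise_spec("nope")),
               "exactly one reaction")
})

test_that("single promoter copy is conserved through every sampled state", {
  s <- tiny_input(40)
  net <- compose(build_mapk_network(),
                 build_gene_network("pcFos", affinity_variant("H"), "Prt_w"))
  e <- ssa_simulate(net, s, t_end = 60, n_real = 20, seed = 12)
  tot <- e$counts[, , "Prt_w.Pm_star"] + e$counts[, , "Prt_w.Pm"]
  expect_true(all(tot == 1))
})

test_that("decoding-section ensemble means track the mean-field ODE for abundant species", {
  s <- standard_inputs(L = 100)$I2
  net <- build_mapk_network()
  e <- ssa_simulate(net, s, t_end = 200, n_real = 400, seed = 21)
  sol <- ode_integrate(net, s, t_end = 200)
  mu <- ensemble_mean(e)
  sel <- e$sample_times >= 5
  for (sp in net$species) {
    if (mean(mu[sel, sp]) > 50) {
      rel <- abs(mu[sel, sp] - sol$values[sel, sp]) /
        pmax(sol$values[sel, sp], 1)
      expect_lt(max(rel), 0.10)
    }
  }
  # the prescribed input is one of them wherever it exceeds 5 molecules
  ref <- eval_input(s, e$sample_times)
  big <- ref > 5
  expect_lt(max(abs(mu[big, "ppERK_cyt"] - ref[big]) / ref[big]), 0.10)
})
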