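tiny_cfg <- function(experiment, ...) {
  experiment_config(experiment, L = c(10, 40), n_real = 15, t_end = 30,
                    mmi_times = c(0, 15, 30), n_boot = 20, seed = 7, ...)
}

test_that("configuration profiles and validation", {
  desk <- experiment_config("mapk_cc")
  expect_equal(desk$n_real, 200)
  expect_equal(desk$L, seq(20, 120, by = 20))
  expect_equal(experiment_config("minimal_cc")$L, seq(10, 60, by = 10))
  full <- experiment_config("mapk_cc", profile = "full")
  expect_equal(full$n_real, 1000)
  expect_length(full$L, 12)
  expect_equal(full$pext_grid, c(1, 2, 5, 10, 20, 50, 100, 200))
  expect_error(experiment_config("nope"), "unknown experiment")
  expect_error(experiment_config("mapk_cc", n_real = 1), "n_real")
  expect_error(experiment_config("mapk_cc", input = "I9"), "input")
})

test_that("reporter-gene driver returns bounded capacity traces for every readout", {
  res <- run_mapk_cc(tiny_cfg("mapk_cc"))
  expect_setequal(unique(res$cc$species),
                  c("ppERK_nuc", "cFos", "pcFos", "Prt_w.P", "Prt_wo.P"))
  expect_equal(nrow(res$cc), 5 * 31)
  expect_true(all(res$cc$cc >= 0 & res$cc$cc <= log2(2) + 1e-9))
  expect_equal(res$cc$cc[res$cc$time == 0], rep(0, 5))  # all-zero start
  expect_true(all(res$means$mean >= 0))
})

test_that("minimal-decoder driver reports CV and cross-input late capacities", {
  res <- run_minimal_cc(tiny_cfg("minimal_cc", inputs = c("I2", "I3")))
  expect_equal(nrow(res$cc_late), 2 * 4)
  expect_true(all(res$cc_late$cc >= 0 & res$cc_late$cc <= 1 + 1e-9))
  expect_setequal(unique(res$cv$species), c("B", "C", "D", "E"))
  expect_true(all(is.finite(res$cv$cv)))
})

test_that("paired-topology driver uses identical seeds per condition", {
  res <- run_linear_vs_ffl(tiny_cfg("linear_vs_ffl"))
  expect_setequal(unique(res$cc$topology), c("ffl", "linear"))
  # same seed record for the paired sweeps
  expect_identical(res$ensembles$ffl[["10"]]$seeds,
                   res$ensembles$linear[["10"]]$seeds)
})

test_that("experiment outputs are reproducible byte-for-byte", {
  cfg <- tiny_cfg("minimal_cc")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_experiment(cfg, out_dir = d1)
  run_experiment(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = paste("file", f))
  }
  cfg2 <- tiny_cfg("minimal_cc")
  cfg2$seed <- 8L
  d3 <- withr::local_tempdir()
  run_experiment(cfg2, out_dir = d3)
  expect_false(identical(readBin(file.path(d1, "cc.csv"), "raw", 1e7),
                         readBin(file.path(d3, "cc.csv"), "raw", 1e7)))
})

test_that("bootstrap helpers are deterministic and sane", {
  pois <- make_ensemble(fixture_spec("poisson_map", n_inputs = 4,
                                     n_samples = 200, seed = 13,
                                     lambda = c(10, 30, 90, 270)))
  b1 <- bootstrap_cc(pois, "X", 0, n_boot = 50, seed = 2)
  b2 <- bootstrap_cc(pois, "X", 0, n_boot = 50, seed = 2)
  expect_identical(b1, b2)
  expect_true(all(b1 >= 0 & b1 <= 2 + 1e-9))
  # a separated map beats a flat one with certainty
  flat <- make_ensemble(fixture_spec("poisson_map", n_inputs = 4,
                                     n_samples = 200, seed = 14,
                                     lambda = rep(50, 4)))
  bf <- bootstrap_cc(flat, "X", 0, n_boot = 50, seed = 2)
  expect_lt(p_boot_greater(b1, bf), 0.05)
  expect_true(boot_equivalent(bf, bf))
  bm <- bootstrap_mmi(pois, "X", 0, n_boot = 10, seed = 3)
  expect_true(all(bm >= 0 & bm <= 2 + 1e-9))
})
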