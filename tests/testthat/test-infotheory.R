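test_that("mutual information matches a hand-summed oracle and degenerate cases", {
  W <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  ch <- discrete_channel(W)
  expect_equal(mutual_information(c(0.5, 0.5), ch),
               mi_oracle(c(0.5, 0.5), W), tolerance = 1e-12)
  id <- discrete_channel(diag(12))
  expect_equal(mutual_information(rep(1 / 12, 12), id), log2(12),
               tolerance = 1e-12)
  flat <- discrete_channel(matrix(rep(c(0.3, 0.7), each = 4), 4, 2))
  expect_equal(mutual_information(rep(0.25, 4), flat), 0, tolerance = 1e-12)
  expect_error(mutual_information(c(0.7, 0.7), ch), "probability")
  expect_error(mutual_information(c(1, 0, 0), ch), "match")
})

test_that("capacity maximization: closed forms, brute force, and bounds", {
  ab <- arimoto_blahut(discrete_channel(diag(12)))
  expect_equal(ab$cc_bits, log2(12), tolerance = 1e-6)
  expect_equal(ab$p_star, rep(1 / 12, 12), tolerance = 1e-3)
  expect_true(ab$converged)

  bsc <- discrete_channel(matrix(c(0.75, 0.25, 0.25, 0.75), 2, 2, byrow = TRUE))
  expect_equal(arimoto_blahut(bsc)$cc_bits, 1 - h2(0.25), tolerance = 1e-6)

  flat <- discrete_channel(matrix(rep(c(0.2, 0.5, 0.3), each = 5), 5, 3))
  expect_equal(arimoto_blahut(flat)$cc_bits, 0, tolerance = 1e-6)

  for (seed in 1:5) {
    ch <- random_channel(2, 6, seed)
    expect_equal(arimoto_blahut(ch)$cc_bits, grid_capacity_2(ch$cond),
                 tolerance = 1e-3)
  }
  for (seed in 6:9) {
    ch <- random_channel(5, 16, seed)
    ab <- arimoto_blahut(ch)
    expect_gte(ab$cc_bits + 1e-9, mutual_information(rep(0.2, 5), ch))
    expect_lte(ab$cc_bits, log2(5) + 1e-9)
    expect_equal(sum(ab$p_star), 1, tolerance = 1e-12)
    expect_true(all(ab$p_star >= 0))
  }
})

test_that("histogram channel estimation recovers known laws", {
  det <- make_ensemble(fixture_spec("deterministic_map", n_inputs = 6,
                                    n_samples = 50, seed = 2))
  ch <- estimate_channel(det, "X", 0, bins = 64)
  expect_true(all(rowSums(ch$cond == 1) == 1))       # one-hot rows
  expect_equal(nrow(unique(ch$cond)), 6)             # pairwise distinct
  expect_true(all(abs(rowSums(ch$cond) - 1) < 1e-12))

  same <- make_ensemble(fixture_spec("deterministic_map", n_inputs = 4,
                                     n_samples = 20, seed = 2,
                                     levels = rep(7, 4)))
  ch0 <- estimate_channel(same, "X", 0, bins = 64)
  expect_equal(ncol(ch0$cond), 1)                    # degenerate pooled range
  expect_equal(arimoto_blahut(ch0)$cc_bits, 0, tolerance = 1e-9)

  pois <- make_ensemble(fixture_spec("poisson_map", n_inputs = 4,
                                     n_samples = 1000, seed = 5,
                                     lambda = c(20, 40, 80, 160)))
  chp <- estimate_channel(pois, "X", 0, bins = 32)
  for (j in 1:4) {
    exact <- binned_poisson_row(c(20, 40, 80, 160)[j], chp$bin_edges)
    tv <- 0.5 * sum(abs(chp$cond[j, ] - exact))
    expect_lt(tv, 0.05)
  }
})

test_that("multivariate MI: reduction, deterministic recovery, and inequalities", {
  W <- random_channel(5, 12, 11)
  p_u <- rep(0.2, 5)
  expect_equal(mmi(list(W), p_u), mutual_information(p_u, W), tolerance = 1e-12)

  flat <- discrete_channel(matrix(rep(c(0.4, 0.6), each = 3), 3, 2))
  expect_equal(mmi(list(flat, flat, flat), rep(1 / 3, 3)), 0, tolerance = 1e-9)

  onehot <- discrete_channel(diag(12))
  expect_equal(mmi(list(onehot, onehot, onehot), rep(1 / 12, 12)), log2(12),
               tolerance = 1e-9)

  chans <- lapply(1:3, function(k) random_channel(6, 10, 20 + k))
  ps <- rep(1 / 6, 6)
  m <- mmi(chans, ps)
  singles <- vapply(chans, function(ch) mutual_information(ps, ch), numeric(1))
  expect_gte(m + 1e-9, max(singles))
  expect_lte(m, log2(6) + 1e-9)
  # default input distribution is the joint-channel maximizer: MMI can only grow
  expect_gte(mmi(chans) + 1e-9, m)
})

test_that("post-processing by bin merges never increases capacity", {
  merge_pairs <- function(W) W[, seq(1, ncol(W), by = 2)] +
    W[, seq(2, ncol(W), by = 2)]
  for (seed in 41:45) {
    ch <- random_channel(6, 32, seed)
    cc <- arimoto_blahut(ch)$cc_bits
    cc2 <- arimoto_blahut(discrete_channel(merge_pairs(ch$cond)))$cc_bits
    expect_lte(cc2, cc + 1e-9)
  }
  # collapsing to a single bin kills all information
  one <- discrete_channel(matrix(1, 6, 1))
  expect_equal(arimoto_blahut(one)$cc_bits, 0, tolerance = 1e-12)
})

test_that("coefficient of variation: constants, Poisson scaling, undefined mean", {
  det <- make_ensemble(fixture_spec("deterministic_map", n_inputs = 2,
                                    n_samples = 30, seed = 1))
  expect_equal(coefficient_of_variation(det[[1]], "X", 0), 0)
  pois <- make_ensemble(fixture_spec("poisson_map", n_inputs = 1,
                                     n_samples = 1000, seed = 6,
                                     lambda = 400))
  expect_equal(coefficient_of_variation(pois[[1]], "X", 0), 0.05,
               tolerance = 0.1)
  zero <- make_ensemble(fixture_spec("deterministic_map", n_inputs = 1,
                                     n_samples = 10, seed = 1, levels = 0))
  expect_true(is.na(coefficient_of_variation(zero[[1]], "X", 0)))
})
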