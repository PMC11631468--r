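test_that("incongruence probability under strict isolation follows the closed form", {
  # no divergence: random topology among four exchangeable lineages
  expect_equal(p_incongruence_isolation(0, 1e5, 3e4), 2 / 3)
  # one coalescent time unit of drift in each population
  expect_equal(p_incongruence_isolation(2e5, 1e5, 1e5), (2 / 3) * exp(-2),
               tolerance = 1e-12)
  expect_equal(p_incongruence_isolation(2e5, 1e5, 1e5), 0.09022, tolerance = 1e-4)
  # unequal sizes enter through separate exponents
  expect_equal(p_incongruence_isolation(2e5, 2e5, 1e5),
               (2 / 3) * exp(-0.5) * exp(-1), tolerance = 1e-12)
  # deep divergence drives the probability to zero
  expect_lt(p_incongruence_isolation(1e8, 1e5, 1e5), 1e-200)
  expect_error(p_incongruence_isolation(1e5, -1, 1e5), "population sizes")
  expect_error(p_incongruence_isolation(-1, 1e5, 1e5), "t must be")
})

test_that("incongruence probability under migration has the right limits and value", {
  # panmictic limit T = 0
  expect_equal(p_incongruence(scaled_im_params(0, 0.5)), 2 / 3)
  # M = 0 recovers the strict-isolation result with equal Ne
  expect_equal(p_incongruence(scaled_im_params(1, 0)),
               p_incongruence_isolation(2e5, 1e5, 1e5), tolerance = 1e-12)
  # deep-divergence, rare-migration worked example: 6.7e-5 to 2 s.f.
  expect_equal(signif(p_incongruence(scaled_im_params(10, 1e-4)), 2), 6.7e-5)
  # M -> Inf approaches the panmictic value
  expect_equal(p_incongruence(scaled_im_params(1, 1e8)), 2 / 3, tolerance = 1e-6)
  # strictly increasing in M at fixed T > 0
  for (T in c(0.1, 0.5, 1, 2, 10)) {
    p <- vapply(c(0, 0.1, 1, 3, 10),
                function(M) p_incongruence(scaled_im_params(T, M)), 0)
    expect_true(all(diff(p) > 0), info = paste("T =", T))
  }
})

test_that("conditional branch lengths under isolation are symmetric and correct", {
  e <- expected_tau_incongruent_isolation(0, 1e5)
  expect_equal(e$tau_a_bar, (8 / 3) * 1e5)
  e <- expected_tau_incongruent_isolation(2e5, 1e5)
  expect_equal(e$tau_a_bar, 2 * 2e5 + (8 / 3) * 1e5)
  expect_identical(e$tau_a_bar, e$tau_b_bar)
  expect_error(expected_tau_incongruent_isolation(1e5, 0), "N_ab")
})

test_that("conditional branch lengths under the IM model match known values", {
  # M = 0 reduces to the isolation result in scaled units: 2T + 4/3
  e0 <- expected_tau_incongruent(scaled_im_params(1, 0))
  expect_equal(e0$tau_a_bar, 2 + 4 / 3, tolerance = 1e-9)
  expect_equal(e0$tau_b_bar, 2 + 4 / 3, tolerance = 1e-9)
  # with migration into A, the a branches are the longer ones
  for (M in c(0.1, 1, 3, 10)) {
    e <- expected_tau_incongruent(scaled_im_params(1, M))
    expect_gt(e$tau_a_bar, e$tau_b_bar)
  }
  # degenerate regime: essentially no incongruent genealogies
  expect_error(expected_tau_incongruent(scaled_im_params(800, 0)), "degenerate")
})

test_that("analytic Ai reproduces the reference values", {
  expect_equal(ai_expected(scaled_im_params(1, 0)), 0, tolerance = 1e-9)
  expect_equal(ai_expected(scaled_im_params(0, 3)), 0, tolerance = 1e-9)
  expect_equal(round(ai_expected(scaled_im_params(1, 1)), 5), 0.12016)
  expect_equal(round(ai_expected(scaled_im_params(1, 3)), 5), 0.07494)
  expect_equal(round(ai_expected(scaled_im_params(10, 1e-4)), 3), 0.775)
  # bounded statistic, positive whenever there is gene flow and divergence
  for (M in c(1e-3, 0.5, 2, 20)) {
    a <- ai_expected(scaled_im_params(0.5, M))
    expect_gt(a, 0)
    expect_lte(a, 1)
  }
})

test_that("analytic Am reproduces the reference values and its limits", {
  bm <- table1_model()
  expect_equal(am_expected(scaled_im_params(1, 0), bm), 0, tolerance = 1e-9)
  expect_equal(round(am_expected(scaled_im_params(1, 1), bm), 5), 0.04394)
  expect_equal(round(am_expected(scaled_im_params(1, 3), bm), 5), 0.02432)
  # conditioning on a hetAB mutation reweights towards long-ab genealogies:
  # the vanishing-block limit exists but differs from Ai
  sp <- scaled_im_params(1, 1)
  a1 <- am_expected(sp, block_model(1e-12, 1, 1e5))
  a2 <- am_expected(sp, block_model(1e-13, 1, 1e5))
  expect_equal(a1, a2, tolerance = 1e-4)          # converged
  expect_gt(abs(a1 - ai_expected(sp)), 0.005)     # distinct from Ai
  expect_error(am_expected(scaled_im_params(800, 0), bm), "degenerate")
})

test_that("mutation-rate bias formula matches its worked examples", {
  expect_equal(ai_mutation_bias(2e5, 1e5, 1e-8, 1e-8, 1e-8), 0)
  # t = 2*N_ab, mu_a = 2*mu_b, mu_ab = mu_b
  expect_equal(round(ai_mutation_bias(2e5, 1e5, 2e-8, 1e-8, 1e-8), 3), 0.231)
  # mu_a = 3*mu_b: 12/32 by direct substitution
  expect_equal(ai_mutation_bias(2e5, 1e5, 3e-8, 1e-8, 1e-8), 12 / 32,
               tolerance = 1e-12)
  # swapping the population rates flips the sign
  expect_equal(ai_mutation_bias(2e5, 1e5, 1e-8, 2e-8, 1e-8),
               -ai_mutation_bias(2e5, 1e5, 2e-8, 1e-8, 1e-8))
  expect_error(ai_mutation_bias(2e5, 1e5, 0, 1e-8, 1e-8), "mutation rates")
})
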