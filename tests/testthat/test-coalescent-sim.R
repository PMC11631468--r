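test_that("the sampler is deterministic given a seed and demands one", {
  p <- table1_params()
  g1 <- sim_genealogies(p, 500, seed = 11)
  g2 <- sim_genealogies(p, 500, seed = 11)
  expect_identical(g1, g2)
  g3 <- sim_genealogies(p, 500, seed = 12)
  expect_false(identical(g1, g3))
  expect_error(sim_genealogies(p, 10), "seed")
})

test_that("genealogy summaries respect their structural invariants", {
  g <- sim_genealogies(table1_params(), 2000, seed = 21)
  expect_true(all(g[, c("tau_a", "tau_b", "tau_aa", "tau_ab")] >= 0))
  # an ab internal branch exists exactly on incongruent genealogies
  expect_true(all((g$tau_ab > 0) == (g$incongruent == 1)))
  expect_true(all((g$tau_aa > 0) == (g$incongruent == 0)))
  # occupancy splits add up to the external totals
  expect_equal(g$a_in_A + g$a_in_B + g$a_in_AB, g$tau_a, tolerance = 1e-9)
  expect_equal(g$b_in_A + g$b_in_B + g$b_in_AB, g$tau_b, tolerance = 1e-9)
})

test_that("topology frequencies match the analytic probabilities", {
  n <- 100000
  # panmictic limit
  g <- sim_genealogies(im_params(1e5, 1e5, 1e5, t = 0), n, seed = 31)
  expect_lt(abs(mean(g$incongruent) - 2 / 3), 3 * binom_se(2 / 3, n))
  # strict isolation with unequal sizes
  p_iso <- p_incongruence_isolation(2e5, 2e5, 1e5)
  g <- sim_genealogies(im_params(2e5, 1e5, 1e5, t = 2e5), n, seed = 32)
  expect_lt(abs(mean(g$incongruent) - p_iso), 3 * binom_se(p_iso, n))
  # external branches stay symmetric under isolation even with N_a = 2*N_b
  inc <- g$incongruent == 1
  d <- g$tau_a[inc] - g$tau_b[inc]
  expect_lt(abs(mean(d)), 3 * mean_se(d))
})

test_that("oracle agrees with path-based analytics at several (T, M) points", {
  n <- 100000
  pts <- list(c(1, 0), c(1, 1), c(1, 3), c(0.5, 1))
  for (i in seq_along(pts)) {
    T <- pts[[i]][1]; M <- pts[[i]][2]
    sp <- scaled_im_params(T, M)
    pars <- as_im_params(sp, Ne = 1e5)
    g <- sim_genealogies(pars, n, seed = 40 + i)
    p_hat <- mean(g$incongruent)
    expect_lt(abs(p_hat - p_incongruence(sp)),
              3 * binom_se(p_incongruence(sp), n))
    e <- expected_tau_incongruent(sp)
    inc <- g$incongruent == 1
    ta <- g$tau_a[inc] / (2 * 1e5)  # back to scaled units
    tb <- g$tau_b[inc] / (2 * 1e5)
    expect_lt(abs(mean(ta) - e$tau_a_bar), 3 * mean_se(ta))
    expect_lt(abs(mean(tb) - e$tau_b_bar), 3 * mean_se(tb))
  }
})

test_that("mutation dropping is Poisson with the right means and class rules", {
  bm <- table1_model()
  g <- sim_genealogies(table1_params(), 5000, seed = 51)
  # congruent genealogies can never yield a hetAB polymorphism
  k <- drop_mutations(g, bm, seed = 52)
  expect_true(all(k$k_hetAB[g$incongruent == 0] == 0))
  expect_true(all(as.matrix(k) >= 0))
  # Poisson mean identity on one fixed genealogy, 1e5 droppings
  g1 <- g[rep(which(g$incongruent == 1)[1], 1e5), ]
  k1 <- drop_mutations(g1, bm, seed = 53)
  lam <- bm$mu * bm$block_len * g1$tau_a[1]
  expect_lt(abs(mean(k1$k_hetA) - lam), 3 * sqrt(lam / 1e5))
  lam_ab <- bm$mu * bm$block_len * g1$tau_ab[1]
  expect_lt(abs(mean(k1$k_hetAB) - lam_ab), 3 * sqrt(lam_ab / 1e5))
})

test_that("mc_ai behaves under the null, under migration, and under label swap", {
  n <- 100000
  est0 <- mc_ai(table1_params(M = 0), n, seed = 61)
  expect_lte(est0$ci_low, 0)
  expect_gte(est0$ci_high, 0)
  est1 <- mc_ai(table1_params(M = 1), n, seed = 62)
  expect_gt(est1$ci_low, 0)
  # swapping which population receives migrants flips the sign
  Ne <- 1e5
  swapped <- im_params(Ne, Ne, Ne, 2e5, m_a = 0, m_b = 1 / (2 * Ne))
  est_sw <- mc_ai(swapped, n, seed = 63)
  expect_lt(abs(est_sw$point + est1$point), 3 * (est_sw$se + est1$se))
  # no incongruent genealogies at extreme divergence
  expect_error(mc_ai(im_params(1e5, 1e5, 1e5, t = 1e7), 100, seed = 64),
               "incongruent")
})

test_that("mc_am is null without migration and tracks the dominant direction", {
  bm <- table1_model()
  est0 <- mc_am(table1_params(M = 0), bm, 100000, seed = 71)
  expect_lte(est0$ci_low, 0)
  expect_gte(est0$ci_high, 0)
  # bidirectional gene flow: sign follows the larger rate
  Ne <- 1e5
  fwd <- im_params(Ne, Ne, Ne, 2e5, m_a = 1 / (2 * Ne), m_b = 0.25 / (2 * Ne))
  rev <- im_params(Ne, Ne, Ne, 2e5, m_a = 0.25 / (2 * Ne), m_b = 1 / (2 * Ne))
  est_f <- mc_am(fwd, bm, 500000, seed = 72)
  est_r <- mc_am(rev, bm, 500000, seed = 73)
  expect_gt(est_f$ci_low, 0)
  expect_lt(est_r$ci_high, 0)
  expect_lt(abs(est_f$point + est_r$point), 3 * (est_f$se + est_r$se))
})

test_that("jackknife interval width shrinks like the square root of the data", {
  bm <- table1_model()
  p <- table1_params(M = 1)
  small <- mc_am(p, bm, 25000, seed = 81)
  large <- mc_am(p, bm, 400000, seed = 82)
  ratio <- small$se / large$se  # expect ~ 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})
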