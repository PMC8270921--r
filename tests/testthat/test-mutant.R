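test_that("first-order deviations match hand-evaluated closed forms", {
  s <- slope_set(0, 0.9, 0, 0, 0.9)
  sol <- first_order_epsilons(s, delta1 = 0.02, eta1 = 0)
  expect_equal(sol$eps01, 0.02)
  expect_equal(sol$eps00, 1.81 * 0.02)
  expect_equal(sol$eps10, 0.9 * 0.9 * 0.02)
  expect_equal(sol$eps11, 0)
  zero <- first_order_epsilons(s, 0, 0)
  expect_equal(eps_vec(zero), rep(0, 4))
  # L3 satisfies both non-singularity inequalities
  expect_s3_class(first_order_epsilons(norm_slopes("L3"), 0.02),
                  "perturbation_solution")
})

test_that("singular denominators raise typed errors naming the inequality", {
  expect_error(first_order_epsilons(slope_set(0.5, 1, 0.6, 0, 1), 0.01),
               class = "contrep_singularity")
  expect_error(first_order_epsilons(slope_set(0.5, 1, 0.6, 0, 1), 0.01),
               "Ax - Az")
  expect_error(first_order_epsilons(slope_set(0.3, 1, 0, 0.8, 1), 0.01),
               "Ay\\*Bx")
  # all leading-eight norms violate the finite-p inequality
  for (nm in paste0("L", 1:8)) {
    expect_error(finite_p_epsilons(norm_slopes(nm), 0.02, 0, p = 0.5),
                 class = "contrep_singularity", info = nm)
  }
  expect_error(finite_p_epsilons(norm_slopes("L3"), 0.02, 0, p = 0.5),
               "stationary_numeric")
})

test_that("finite-p closed forms reduce to the rare-mutant limit at p = 0", {
  set.seed(51)
  for (rep in 1:20) {
    s <- random_slopes(constrained = TRUE)
    d1 <- runif(1, 0, 0.05)
    e1 <- runif(1, 0, 0.05)
    expect_equal(eps_vec(finite_p_epsilons(s, d1, e1, p = 0)),
                 eps_vec(first_order_epsilons(s, d1, e1)),
                 tolerance = 1e-12)
  }
  s <- random_slopes(constrained = TRUE)
  expect_equal(eps_vec(finite_p_epsilons(s, 0, 0, p = 0.37)), rep(0, 4))
})

test_that("deviations are non-negative under the preconditions", {
  set.seed(52)
  for (rep in 1:20) {
    s <- random_slopes(constrained = TRUE)
    sol <- finite_p_epsilons(s, runif(1, 0, 0.05), runif(1, 0, 0.05),
                             p = runif(1))
    expect_true(all(eps_vec(sol) >= 0))
  }
})

test_that("the linearized payoff difference is independent of p and equals
           the closed form", {
  set.seed(53)
  game <- game_params(2, 1)
  for (rep in 1:20) {
    s <- random_slopes(constrained = TRUE)
    d1 <- runif(1, 0, 0.05)
    e1 <- runif(1, 0, 0.05)
    target <- payoff_difference_first_order(s, d1, e1, game)
    for (p in c(0, 0.2, 0.5, 0.8, 1)) {
      sol <- finite_p_epsilons(s, d1, e1, p)
      pay <- contrep:::linearized_payoffs(s, sol, e1, game, p)
      expect_lt(abs(unname(pay["pi0"] - pay["pi1"]) - target), 1e-12)
    }
  }
})

test_that("payoff difference: worked example, zero offset, threshold zero", {
  s <- slope_set(0, 0.9, 0, 0, 0.9)
  g21 <- game_params(2, 1)
  expect_equal(payoff_difference_first_order(s, 0.02, 0, g21),
               -(2 * 0.81 - 1) / 1 * (0.9 * 0.02))
  expect_equal(payoff_difference_first_order(s, 0, 0, g21), 0)
  # exactly at the threshold b = c(1-Ax)/(Ay By) the difference vanishes
  bc <- bc_threshold(s)
  g_at <- game_params(b = bc * 1, c = 1)
  expect_equal(payoff_difference_first_order(s, 0.013, 0.007, g_at), 0,
               tolerance = 1e-14)
})

test_that("sign law: mutants lose exactly when b/c exceeds the threshold", {
  set.seed(54)
  for (rep in 1:20) {
    s <- random_slopes(constrained = TRUE)
    thr <- bc_threshold(s)
    if (!is.finite(thr)) next
    d1 <- runif(1, 1e-4, 0.05)
    e1 <- runif(1, 0, 0.05)
    above <- game_params(b = thr * 1.2, c = 1)
    below <- game_params(b = max(thr * 0.8, 1.001), c = 1)
    expect_lt(payoff_difference_first_order(s, d1, e1, above), 0)
    if (below$b < thr) {
      expect_gt(payoff_difference_first_order(s, d1, e1, below), 0)
    }
  }
})

test_that("benefit-cost threshold values and the infinite branch", {
  expect_equal(bc_threshold(norm_slopes("L3")), 1)
  expect_equal(bc_threshold(slope_set(0, 0.9, 0, 0, 0.9)), 1 / 0.81)
  expect_identical(bc_threshold(slope_set(0.2, 0, 0.1, 0, 0.5)), Inf)
  expect_identical(bc_threshold(slope_set(0.2, 0.5, 0.1, 0, 0)), Inf)
})

test_that("expected payoffs: cooperative baseline, p = 0 reduction, symmetry", {
  ss <- interpolate_norm("L3")
  g21 <- game_params(2, 1)
  full <- reduced_state(1, 1, 1, 1, p = 0.5)
  pay <- expected_payoffs(full, ss, ss, g21)
  expect_equal(unname(pay), c(1, 1))  # b - c
  # p = 0: pi0 = b*beta(m11, m10) - c*beta0(m00, m01)
  mut <- offset_norm(ss, mutant_offset(0.02, 0.01))
  st <- reduced_state(0.95, 0.97, 0.96, 1, p = 0)
  pay0 <- expected_payoffs(st, ss, mut, g21)
  expect_equal(unname(pay0["pi0"]),
               2 * ss$beta(1, 0.96) - 1 * mut$beta(0.95, 0.97))
  # identical norms at any stationary state earn equal payoffs
  st2 <- reduced_state(0.9, 0.9, 0.9, 0.9, p = 0.3)
  pay2 <- expected_payoffs(st2, ss, ss, g21)
  expect_equal(unname(pay2["pi0"]), unname(pay2["pi1"]))
})

test_that("the numeric stationary state is exact for an unperturbed norm", {
  ss <- interpolate_norm("L3")
  st <- stationary_numeric(ss, ss, p = 0.5)
  expect_equal(c(st$m00, st$m01, st$m10, st$m11), rep(1, 4))
  expect_lte(attr(st, "iterations"), 2)
})

test_that("numeric oracle agrees with first order to quadratic order", {
  res <- standing_variant(0.9)
  s <- norm_slopes(res)
  errs <- sapply(c(0.02, 0.01, 0.005), function(d1) {
    mut <- offset_norm(res, mutant_offset(delta1 = d1))
    st <- stationary_numeric(res, mut, p = 0)
    max(abs(eps_vec(st) - eps_vec(first_order_epsilons(s, d1))))
  })
  # halving delta1 divides the discrepancy by ~4
  expect_gt(errs[1] / errs[2], 3)
  expect_lt(errs[1] / errs[2], 5)
  expect_gt(errs[2] / errs[3], 3)
  expect_lt(errs[2] / errs[3], 5)
})

test_that("payoff difference from the numeric state is p-independent to
           quadratic order", {
  res <- standing_variant(0.9)
  g21 <- game_params(2, 1)
  spread <- sapply(c(0.02, 0.01), function(d1) {
    mut <- offset_norm(res, mutant_offset(delta1 = d1))
    dpi <- sapply(c(0.1, 0.9), function(p) {
      pay <- expected_payoffs(stationary_numeric(res, mut, p), res, mut, g21)
      unname(pay["pi0"] - pay["pi1"])
    })
    c(spread = abs(dpi[1] - dpi[2]), size = abs(dpi[1]))
  })
  # the p-dependence is second order: it shrinks ~4x when delta1 halves,
  # while the difference itself is first order (shrinks ~2x)
  expect_gt(spread["spread", 1] / spread["spread", 2], 3)
  expect_lt(spread["spread", 1] / spread["spread", 2], 5)
  expect_gt(spread["size", 1], 5 * spread["spread", 1])
})

test_that("second-order residual vanishes at zero and is quadratically small
           at the first-order solution", {
  res <- standing_variant(0.9)
  s <- norm_slopes(res)
  cv <- norm_curvatures(res)
  off0 <- mutant_offset(0, 0)
  expect_equal(second_order_residual(s, cv, off0, rep(0, 4)), rep(0, 4))
  r <- sapply(c(0.02, 0.01), function(d1) {
    off <- mutant_offset(delta1 = d1)
    max(abs(second_order_residual(s, cv, off,
                                  first_order_epsilons(s, d1), p = 0)))
  })
  expect_gt(r[1] / r[2], 3)
  expect_lt(r[1] / r[2], 5)
})

test_that("root-found second-order deviations agree with the numeric oracle
           to cubic order", {
  res <- standing_variant(0.9)
  s <- norm_slopes(res)
  cv <- norm_curvatures(res)
  errs <- sapply(c(0.02, 0.01), function(d1) {
    off <- mutant_offset(delta1 = d1)
    so <- solve_second_order(s, cv, off, p = 0)
    st <- stationary_numeric(res, offset_norm(res, off), p = 0)
    max(abs(eps_vec(so) - eps_vec(st)))
  })
  expect_gt(errs[1] / errs[2], 6)
  expect_lt(errs[1] / errs[2], 11)
})

test_that("the second-order solver handles the leading eight where the
           finite-p closed forms are singular", {
  s <- norm_slopes("L3")
  cv <- norm_curvatures("L3")
  off <- mutant_offset(delta1 = 0.02)
  so <- solve_second_order(s, cv, off, p = 0.5)
  st <- stationary_numeric(interpolate_norm("L3"),
                           offset_norm("L3", off), p = 0.5)
  # near the finite-p singularity the deviations are amplified well beyond
  # delta1, so only moderate (percent-level) agreement is expected
  expect_equal(eps_vec(so), eps_vec(st), tolerance = 0.02)
  expect_gt(min(eps_vec(st)), 0.05)
})

test_that("mutant_report composes the toolkit", {
  rep <- mutant_report("L3", delta1 = 0.02, p = 0.5)
  expect_equal(rep$Q, 0)
  expect_equal(rep$bc_threshold, 1)
  expect_s3_class(rep$first_order, "perturbation_solution")
  expect_match(rep$finite_p, "singular")  # L3 violates the finite-p bound
  expect_lt(rep$dpi0_numeric, 0)
  expect_output(print(rep), "b/c threshold")
})

test_that("game parameters are validated", {
  expect_error(game_params(1, 2), "0 < c <= b")
  expect_error(game_params(2, 0), "0 < c <= b")
  expect_error(reduced_state(1.2, 1, 1, 1, 0.5), "\\[0, 1\\]")
})
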