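test_that("without replication the free-bacteria count is conserved", {
  M <- build_base_matrix(chain_params("base", r = 0, alpha = 1))
  eig <- dominant_eigenpair(M)
  expect_equal(eig$lambda, 0, tolerance = 1e-12)
  expect_equal(eig$distribution[1], 1)
})

test_that("the q = 1 model grows at the replication rate with a geometric
           stationary distribution", {
  p <- chain_params("q_model", r = 1, alpha = 1, q = 1)
  eig <- dominant_eigenpair(build_q_matrix(p, truncation_spec(n_max = 100)),
                            check_convergence = FALSE)
  expect_equal(eig$lambda, 1, tolerance = 1e-10)
  expect_lt(tv_dist(eig$distribution, q1_distribution(1, 1, 1:100)), 1e-10)
})

test_that("eigen growth rate matches the long-time slope of the integrated
           population", {
  p <- chain_params("base", r = 1, alpha = 1)
  op <- build_base_matrix(p, truncation_spec(n_max = 40))
  eig <- dominant_eigenpair(op)
  traj <- integrate_population(op, c(1, rep(0, 39)), c(40, 50))
  slope <- (log(sum(traj[2, ])) - log(sum(traj[1, ]))) / 10
  expect_equal(slope, eig$lambda, tolerance = 1e-6)
  # and the composition converges to the dominant eigenvector
  comp <- traj[2, ] / sum(traj[2, ])
  expect_lt(tv_dist(comp, eig$distribution), 1e-4)
})

test_that("starting on the dominant eigenvector propagates as exp(lambda t)", {
  p <- chain_params("base", r = 0.8, alpha = 1)
  op <- build_base_matrix(p, truncation_spec(n_max = 30))
  eig <- dominant_eigenpair(op, check_convergence = FALSE)
  traj <- integrate_population(op, eig$distribution, c(1, 2))
  expect_equal(traj[1, ], eig$distribution * exp(eig$lambda),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(traj[2, ], eig$distribution * exp(2 * eig$lambda),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("uniform loss rescales escape-model trajectories by exp(-x t)", {
  tr <- truncation_spec(n_max = 25)
  op0 <- build_escape_matrix(chain_params("escape", r = 1, alpha = 1), tr)
  opx <- build_escape_matrix(chain_params("escape", r = 1, alpha = 1,
                                          c = 0.3, c_prime = 0.3), tr)
  init <- c(1, rep(0, 24))
  t0 <- integrate_population(op0, init, c(1, 3))
  tx <- integrate_population(opx, init, c(1, 3))
  expect_equal(tx[1, ], t0[1, ] * exp(-0.3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(tx[2, ], t0[2, ] * exp(-0.9), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("integrate_population validates its inputs", {
  op <- build_base_matrix(chain_params("base"))
  expect_error(integrate_population(op, c(-1, rep(0, 39)), 1),
               "nonnegative")
  expect_error(integrate_population(op, 1, c(2, 1)), "increasing")
  Tm <- build_transfer_matrix(chain_params("fixed_time", tau = 1))
  expect_error(integrate_population(Tm, 1, 1), "rate matrices")
})

test_that("growth curves: identity at q = 1, lambda < r for the base model,
           and a hump near r = 1.09 alpha", {
  rv <- c(0.5, 1.09, 2)
  curve_q1 <- growth_rate_curve(chain_params("q_model", q = 1), rv,
                                truncation_spec(n_max = 150))
  expect_equal(curve_q1$lambda_over_alpha, rv, tolerance = 1e-6)
  curve_base <- growth_rate_curve(chain_params("base"), rv)
  expect_true(all(curve_base$lambda_over_alpha < rv))
  expect_true(all(curve_base$converged))
  expect_gte(curve_base$lambda_over_alpha[2], curve_base$lambda_over_alpha[1])
  expect_gte(curve_base$lambda_over_alpha[2], curve_base$lambda_over_alpha[3])
})

test_that("growth rate is monotone in r for leaky variants but humped for
           sticky ones", {
  rv <- c(0.5, 1, 2, 4, 8)
  lam_q08 <- growth_rate_curve(chain_params("q_model", q = 0.8), rv,
                               truncation_spec(n_max = 150))$lambda_over_alpha
  expect_false(is.unsorted(lam_q08))
  lam_q02 <- growth_rate_curve(chain_params("q_model", q = 0.2), rv,
                               truncation_spec(n_max = 150))$lambda_over_alpha
  expect_gt(max(lam_q02), lam_q02[length(lam_q02)])  # interior maximum
  lam_esc <- growth_rate_curve(
    chain_params("escape", delta = 0.3, delta_prime = 0.3,
                 delta_dprime = 0.3), rv,
    truncation_spec(n_max = 60))$lambda_over_alpha
  expect_false(is.unsorted(lam_esc))
})

test_that("monotone regimes report a boundary argmax instead of erroring", {
  am <- argmax_growth_rate(chain_params("q_model", q = 0.8),
                           bracket = c(0.1, 10), n_scan = 8L,
                           trunc = truncation_spec(n_max = 120))
  expect_true(am$boundary)
  expect_equal(am$r_star_over_alpha, 10)
})

test_that("the fixed-time multiplier approaches 2 for long intervals", {
  eig <- dominant_eigenpair(
    build_transfer_matrix(chain_params("fixed_time", alpha = 1, tau = 8),
                          truncation_spec(n_max = 16)),
    check_convergence = FALSE)
  expect_equal(eig$multiplier_N, 2, tolerance = 1e-3)
  expect_equal(eig$lambda, log(eig$multiplier_N) / 8)
})

test_that("truncation adequacy is flagged by the doubling check", {
  p <- chain_params("base", r = 3, alpha = 1)
  small <- dominant_eigenpair(build_base_matrix(p, truncation_spec(n_max = 6)))
  expect_false(small$converged)
  big <- dominant_eigenpair(build_base_matrix(p, truncation_spec(n_max = 80)))
  expect_true(big$converged)
})

test_that("dominant eigenvectors are nonnegative distributions", {
  ops <- list(
    build_base_matrix(chain_params("base", r = 2, alpha = 1)),
    build_q_matrix(chain_params("q_model", r = 1, alpha = 1, q = 0.5)),
    build_transfer_matrix(chain_params("fixed_time", tau = 0.3)))
  for (op in ops) {
    eig <- dominant_eigenpair(op, check_convergence = FALSE)
    expect_gte(min(eig$distribution), 0)
    expect_equal(sum(eig$distribution), 1)
  }
})
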