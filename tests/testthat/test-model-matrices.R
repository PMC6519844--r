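test_that("base matrix reproduces the coefficient formula at n_max = 3", {
  M <- build_base_matrix(chain_params("base", r = 1, alpha = 1),
                         truncation_spec(n_max = 3))
  expect_equal(strip_op(M),
               matrix(c(-1, 2, 2,
                         1, -3, 2,
                         0, 2, -5), 3, 3, byrow = TRUE))
})

test_that("a free bacterium that never replicates does nothing", {
  M <- build_base_matrix(chain_params("base", r = 0, alpha = 1),
                         truncation_spec(n_max = 4))
  expect_equal(unname(strip_op(M)[, 1]), rep(0, 4))
})

test_that("every variant's matrix action matches the hand-coded equations", {
  set.seed(101)
  cases <- list(
    list(build_base_matrix(chain_params("base", r = 2, alpha = 3),
                           truncation_spec(n_max = 40)),
         function(N) rhs_base_oracle(N, 2, 3)),
    list(build_escape_matrix(
           chain_params("escape", r = 1, alpha = 1, delta = 0.1,
                        delta_prime = 0.1, delta_dprime = 0.1,
                        c = 0.3, c_prime = 0.7),
           truncation_spec(n_max = 40)),
         function(N) rhs_escape_oracle(N, 1, 1, 0.1, 0.1, 0.1, 0.3, 0.7)),
    list(build_q_matrix(chain_params("q_model", r = 2, alpha = 1, q = 0.5),
                        truncation_spec(n_max = 80)),
         function(N) rhs_q_oracle(N, 2, 1, 0.5)),
    list(build_force_matrix(chain_params("force", r = 1, alpha = 1,
                                         beta = 1),
                            truncation_spec(n_max = 15)),
         function(N) rhs_force_oracle(N, 1, 1, 1)))
  for (cs in cases) {
    M <- strip_op(cs[[1]])
    for (rep in 1:25) {
      N <- random_pop(nrow(M))
      expect_equal(as.numeric(M %*% N), cs[[2]](N), tolerance = 1e-12)
    }
  }
})

test_that("rate matrices are Metzler and the transfer matrix nonnegative", {
  ops <- list(
    build_base_matrix(chain_params("base", r = 2, alpha = 1)),
    build_escape_matrix(chain_params("escape", r = 1, alpha = 1,
                                     delta = 0.2, delta_prime = 0.1,
                                     delta_dprime = 0.05, c = 0.1,
                                     c_prime = 0.2)),
    build_q_matrix(chain_params("q_model", r = 1, alpha = 1, q = 0.7)),
    build_force_matrix(chain_params("force", r = 1, alpha = 1, beta = 2),
                       truncation_spec(n_max = 10)))
  for (M in ops) {
    off <- strip_op(M)
    diag(off) <- 0
    expect_gte(min(off), 0)
  }
  Tm <- build_transfer_matrix(chain_params("fixed_time", tau = 0.5))
  expect_gte(min(strip_op(Tm)), 0)
})

test_that("escape, q and force matrices reduce exactly to the base matrix", {
  tr <- truncation_spec(n_max = 30)
  base <- strip_op(build_base_matrix(chain_params("base", r = 1.3,
                                                  alpha = 0.8), tr))
  expect_identical(strip_op(build_escape_matrix(
    chain_params("escape", r = 1.3, alpha = 0.8), tr)), base)
  expect_identical(strip_op(build_q_matrix(
    chain_params("q_model", r = 1.3, alpha = 0.8, q = 0), tr)), base)
  expect_equal(strip_op(build_force_matrix(
    chain_params("force", r = 1.3, alpha = 0.8, beta = 0), tr)), base)
})

test_that("uniform loss shifts the escape matrix diagonal by -x", {
  tr <- truncation_spec(n_max = 20)
  base <- strip_op(build_escape_matrix(chain_params("escape", r = 1,
                                                    alpha = 1), tr))
  shifted <- strip_op(build_escape_matrix(
    chain_params("escape", r = 1, alpha = 1, c = 0.4, c_prime = 0.4), tr))
  expect_equal(shifted, base - diag(0.4, 20))
})

test_that("q = 1 rows carry 2*alpha influx from every longer chain", {
  M <- strip_op(build_q_matrix(chain_params("q_model", r = 1, alpha = 1,
                                            q = 1),
                               truncation_spec(n_max = 12)))
  for (i in 2:11) {
    expect_equal(M[i, i - 1], (i - 1))
    expect_equal(M[i, i], -(i - 1) - i)
    expect_equal(unname(M[i, (i + 1):12]), rep(2, 12 - i))
  }
})

test_that("per-link force rates obey the printed forms and aggregate sums", {
  p <- chain_params("force", r = 1, alpha = 2, beta = 0.7)
  # single central link of a 2-chain
  expect_equal(per_link_breaking_rate(2, 0, p), 2 * exp(0.7 / 2))
  # outermost link of an even chain
  L <- 8
  expect_equal(per_link_breaking_rate(L, L / 2 - 1, p),
               2 * exp(0.7 * (L - 1) / 2))
  # parity and range enforcement
  expect_error(per_link_breaking_rate(4, 0.5, p), "integers")
  expect_error(per_link_breaking_rate(4, 2, p), "outside")
  # per-link sums reproduce the closed aggregate rates
  for (beta in c(0.1, 0.5, 1, 2)) {
    pb <- chain_params("force", r = 1, alpha = 1, beta = beta)
    for (L in 2:20) {
      offs <- seq(-(L / 2 - 1), L / 2 - 1, by = 1)
      expect_equal(sum(per_link_breaking_rate(L, offs, pb)),
                   total_breaking_rate(L, pb), tolerance = 1e-12,
                   label = sprintf("L=%d beta=%g", L, beta))
    }
  }
})

test_that("force construction refuses overflowing truncations", {
  p <- chain_params("force", r = 1, alpha = 1, beta = 3)
  safe <- force_safe_n_max(3)
  expect_error(build_force_matrix(p, truncation_spec(n_max = safe + 2L)),
               as.character(safe))
  expect_silent(build_force_matrix(p, truncation_spec(n_max = 10)))
})

test_that("survival probabilities solve the within-interval loss system", {
  skip_if_not_installed("deSolve")
  # closed form at i = 0 and the initial condition
  expect_equal(survival_prob(5, 0, 0.3, alpha = 2), exp(-2 * 0.3 * 4))
  expect_equal(survival_prob(7, 0:5, 0), c(1, rep(0, 5)))
  # ODE oracle: integrate dl/dt = -a(n-1-i) l + 2a l_{i-1} directly
  n <- 6; a <- 1
  deriv <- function(t, y, parms) {
    i <- 0:(n - 2)
    list(-a * (n - 1 - i) * y + 2 * a * c(0, y[-(n - 1)]))
  }
  sol <- deSolve::ode(c(1, rep(0, n - 2)), c(0, 0.7), deriv, NULL,
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(sol[2, -1]), survival_prob(n, 0:(n - 2), 0.7, a),
               tolerance = 1e-8)
})

test_that("survival probabilities stay in [0, 1] and sum below 1", {
  for (t in c(0.01, 0.1, 0.5, 1, 3, 10)) {
    for (n in c(2, 4, 9)) {
      l <- survival_prob(n, 0:(n - 2), t)
      expect_true(all(l >= 0 & l <= 1))
      expect_lte(sum(l), 1 + 1e-12)
    }
  }
})

test_that("free-bacteria yield matches closed forms and binomial expansion", {
  # n = 2: closed form and the long-interval limit of exactly two bacteria
  expect_equal(free_yield(2, 0.7, 1.3), 2 * (1 - exp(-1.3 * 0.7)))
  expect_equal(free_yield(2, 100), 2)
  # independent evaluation by binomial expansion of (e^{at}-1)^i
  n <- 6; at <- 0.7
  expansion <- 0
  for (i in 0:(n - 2)) {
    ks <- 0:i
    expansion <- expansion + 2^i / factorial(i) *
      sum(choose(i, ks) * (-1)^(i - ks) *
            (1 - exp(-at * (n - 1 - ks))) / (n - 1 - ks))
  }
  expect_equal(free_yield(n, at, 1), 2 * expansion, tolerance = 1e-9)
})

test_that("transfer matrix entries follow the survival/yield layout", {
  tau <- 0.4
  Tm <- strip_op(build_transfer_matrix(
    chain_params("fixed_time", alpha = 1, tau = tau),
    truncation_spec(n_max = 12)))
  expect_equal(Tm[2, 1], exp(-tau))
  expect_equal(Tm[1, 1], 2 * (1 - exp(-tau)))
  expect_equal(Tm[3, 2], 2 * exp(-3 * tau) * (exp(tau) - 1))
  # column j populates only rows 1 and 2..2j
  for (j in 1:5) {
    if (2 * j + 1 <= 12)
      expect_equal(unname(Tm[(2 * j + 1):12, j]), rep(0, 12 - 2 * j))
  }
  # columns with 2j > n_max still count shrinkage products below the cut
  expect_gt(Tm[12, 8], 0)
})

test_that("builders reject mismatched variants", {
  expect_error(build_base_matrix(chain_params("q_model", q = 0.5)),
               "expected a 'base'")
  expect_error(build_transfer_matrix(chain_params("base")),
               "expected a 'fixed_time'")
})
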