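# Natural-log overflow threshold for the force-model guard: exp(x) overflows
# to Inf for x > ~709, and silent infinities corrupt eigensolves.
.FORCE_EXP_MAX <- 700

# Attach bookkeeping so downstream code (convergence checks, eigensolvers)
# can rebuild the operator at a different truncation.
as_chain_operator <- function(M, params, kind) {
  attr(M, "params") <- params
  attr(M, "kind") <- kind
  class(M) <- c("chain_operator", class(M))
  M
}

#' @export
print.chain_operator <- function(x, ...) {
  cat("<chain_operator> kind:", attr(x, "kind"),
      " variant:", attr(x, "params")$variant,
      " n_max:", nrow(x), "\n")
  y <- x
  attributes(y) <- attributes(y)[c("dim")]
  print(utils::head(y[, seq_len(min(ncol(y), 8L)), drop = FALSE], 8L), ...)
  if (nrow(x) > 8L) cat("... (", nrow(x), "x", ncol(x), ")\n")
  invisible(x)
}

check_variant <- function(params, expected) {
  stopifnot(inherits(params, "chain_params"))
  if (params$variant != expected)
    stop(sprintf("expected a '%s' parameter set, got '%s'",
                 expected, params$variant), call. = FALSE)
}

#' Rate matrix of the base model
#'
#' Builds the truncated generator `M` of the base model, in which chains of
#' length `i` replicate with total rate `i*r` (growing to length `i+1`),
#' each of their `i-1` links breaks at rate `alpha`, outermost breaks
#' release a free bacterium, and inner breaks lose the whole chain to a
#' complex cluster. The dynamics of the mean counts `n_i(t)` (with `n_1`
#' the free bacteria) are `dN/dt = M N`, with entries
#'
#' `m[i,j] = r(i-1)[j=i-1] - i r [j=i] - (i-1) alpha [j=i]
#'           + 2 alpha ([j=i+1] + [i=1](1 - [j=1] - [j=2]))`
#'
#' where `[.]` is the indicator. Row 1 collects the `2 alpha` influx of free
#' bacteria from every chain of length >= 2 (a 2-chain break releases two).
#'
#' @param params A `"chain_params"` object with `variant = "base"`.
#' @param trunc A [truncation_spec()], or `NULL` for variant defaults.
#' @return A `"chain_operator"` matrix of size `n_max x n_max` whose
#'   off-diagonal entries are nonnegative (Metzler structure).
#' @examples
#' M <- build_base_matrix(chain_params("base", r = 1, alpha = 1),
#'                        truncation_spec(n_max = 5))
#' @export
build_base_matrix <- function(params, trunc = NULL) {
  check_variant(params, "base")
  trunc <- resolve_trunc(params, trunc)
  M <- base_matrix_entries(params$r, params$alpha, trunc$n_max)
  as_chain_operator(M, params, "rate")
}

# Shared by the base builder and the exact-reduction limits of the others.
base_matrix_entries <- function(r, alpha, n) {
  M <- matrix(0, n, n)
  i <- seq_len(n)
  M[cbind(i, i)] <- -i * r - (i - 1) * alpha
  if (n >= 2) {
    M[cbind(2:n, 1:(n - 1))] <- r * (1:(n - 1))       # growth influx
    M[cbind(1:(n - 1), 2:n)] <- M[cbind(1:(n - 1), 2:n)] + 2 * alpha
    if (n >= 3) M[1, 3:n] <- M[1, 3:n] + 2 * alpha    # frees from i >= 3
  }
  M
}

#' Rate matrix of the escape model
#'
#' Extends the base model with imperfect enchainment upon replication and
#' with loss. A replicating free bacterium yields two free bacteria with
#' probability `delta`; the outer daughter of a replicating tip bacterium
#' escapes with probability `delta_prime`; an interior division fails to
#' bond with probability `delta_dprime`, clipping the chain in two (both
#' parts, having more than one bacterium, are lost to complex clusters).
#' Free bacteria are lost at rate `c` and chains at rate `c_prime`. With
#' all five extra parameters zero the matrix equals the base matrix
#' entrywise, and with `c = c_prime = x` it is the base matrix shifted by
#' `-x` on the diagonal (every population scaled by `exp(-x t)`).
#'
#' @inheritParams build_base_matrix
#' @return A `"chain_operator"` rate matrix.
#' @export
build_escape_matrix <- function(params, trunc = NULL) {
  check_variant(params, "escape")
  trunc <- resolve_trunc(params, trunc)
  n <- trunc$n_max
  r <- params$r; alpha <- params$alpha
  d <- params$delta; dp <- params$delta_prime; dpp <- params$delta_dprime
  M <- matrix(0, n, n)
  # free bacteria: replication (net -1, or +1 when both daughters escape),
  # tip-escape influx 2 r delta' from every chain, break influx 2 alpha,
  # loss c
  M[1, 1] <- r * (-1 + 2 * d) - params$c
  if (n >= 2) M[1, 2:n] <- 2 * r * dp + 2 * alpha
  # chains of length 2
  if (n >= 2) {
    M[2, 1] <- r * (1 - d)
    M[2, 2] <- -2 * r * (1 - dp) - alpha - params$c_prime
    if (n >= 3) M[2, 3] <- 2 * alpha
  }
  # chains of length >= 3
  if (n >= 3) {
    for (i in 3:n) {
      M[i, i] <- r * (2 * dp - i) - (i - 1) * alpha - params$c_prime
      M[i, i - 1] <- r * (i - 1 - 2 * dp + 3 * dpp - i * dpp)
      if (i < n) M[i, i + 1] <- 2 * alpha
    }
  }
  as_chain_operator(M, params, "rate")
}

#' Rate matrix of the subchain-escape (q) model
#'
#' In this variant the two fragments produced by an inner-link break escape
#' as independent linear chains with probability `q` (they are lost to a
#' complex cluster with probability `1 - q`); single bacteria released by
#' outermost breaks always escape. A chain of length `i` therefore receives
#' influx `2 alpha ` from length `i+1` (outermost breaks) plus
#' `2 alpha q` from every length `i + j`, `j >= 2` (escaping fragments).
#' At `q = 0` the matrix equals the base matrix; at `q = 1` every break
#' conserves both fragments and the model is exactly solvable.
#'
#' @inheritParams build_base_matrix
#' @return A `"chain_operator"` rate matrix.
#' @export
build_q_matrix <- function(params, trunc = NULL) {
  check_variant(params, "q_model")
  trunc <- resolve_trunc(params, trunc)
  n <- trunc$n_max
  r <- params$r; alpha <- params$alpha; q <- params$q
  M <- base_matrix_entries(r, alpha, n)
  if (n >= 4) {
    for (i in 2:(n - 2)) M[i, (i + 2):n] <- 2 * alpha * q
  }
  as_chain_operator(M, params, "rate")
}

#' Per-link breaking rate under hydrodynamic load
#'
#' In the force variant, the tension on a link at signed offset `x` from the
#' centre of a chain of length `L` (treated as a string of beads in a
#' shear flow) gives it the breaking rate
#' `alpha * exp(beta * ((L/2)^2 - x^2) / 2)`. Offsets are integers
#' (`0, +/-1, ...`) for even `L` and half-integers (`+/-1/2, +/-3/2, ...`)
#' for odd `L`, with `|x| <= L/2 - 1`; the outermost links (`|x| = L/2 - 1`)
#' break at `alpha * exp(beta (L - 1) / 2)`.
#'
#' @param chain_length Chain length `L >= 2`.
#' @param link_offset Signed offset of the link from the chain centre,
#'   with parity matching `chain_length`.
#' @param params A `"chain_params"` object with `variant = "force"`.
#' @return The breaking rate of that link (per unit time).
#' @seealso [total_breaking_rate()] for the sum over all `L - 1` links.
#' @export
per_link_breaking_rate <- function(chain_length, link_offset, params) {
  check_variant(params, "force")
  L <- chain_length
  stopifnot(L >= 2, L == round(L))
  x <- link_offset
  parity_ok <- if (L %% 2 == 0) all(x == round(x)) else
    all(abs(x * 2 - round(x * 2)) < 1e-12 & round(x * 2) %% 2 != 0)
  if (!parity_ok)
    stop("link offsets must be integers for even lengths, half-integers for odd",
         call. = FALSE)
  if (any(abs(x) > L / 2 - 1 + 1e-12))
    stop("link offset outside the chain: |x| must be <= L/2 - 1",
         call. = FALSE)
  params$alpha * exp(params$beta * ((L / 2)^2 - x^2) / 2)
}

# Offsets of the L-1 links of a chain of length L, from the centre.
link_offsets <- function(L) {
  if (L < 2) return(numeric(0))
  seq(-(L / 2 - 1), L / 2 - 1, by = 1)
}

#' Total breaking rate of a chain in the force model
#'
#' Sum of [per_link_breaking_rate()] over all `L - 1` links:
#' `alpha e^{beta L^2/8} (1 + 2 sum_{j=2}^{L/2} e^{-(j-1)^2 beta/2})` for
#' even `L` and
#' `2 alpha e^{beta L^2/8} sum_{j=1}^{(L-1)/2} e^{-(j-1/2)^2 beta/2}` for
#' odd `L`. At `beta = 0` this reduces to `(L - 1) alpha`.
#'
#' @inheritParams per_link_breaking_rate
#' @return The total breaking rate (per unit time).
#' @export
total_breaking_rate <- function(chain_length, params) {
  check_variant(params, "force")
  L <- chain_length
  if (L < 2) return(0)
  a <- params$alpha; b <- params$beta
  if (L %% 2 == 0) {
    j <- seq_len(L / 2)  # j = 1 is the central link, j >= 2 the pairs
    a * exp(b * L^2 / 8) * (1 + 2 * sum(exp(-(j[-1] - 1)^2 * b / 2)))
  } else {
    j <- seq_len((L - 1) / 2)
    2 * a * exp(b * L^2 / 8) * sum(exp(-(j - 1 / 2)^2 * b / 2))
  }
}

#' Rate matrix of the force-dependent-breaking model
#'
#' Builds the generator in which each link breaks at the position- and
#' length-dependent rate of [per_link_breaking_rate()]. Free bacteria gain
#' `2 alpha e^{beta (j-1)/2}` from each chain of length `j >= 2` (its two
#' outermost links), chains of length `i` lose mass at the total breaking
#' rate of [total_breaking_rate()] plus replication `i r`, and gain
#' `2 alpha e^{beta i / 2}` from length `i + 1`. Inner breaks are lost to
#' complex clusters (`q = 0`), as in the base model, which is recovered
#' exactly at `beta = 0`.
#'
#' Construction refuses truncations with `beta * n_max^2 / 8 > 700`, for
#' which the central-link rate would overflow to infinity, and reports the
#' maximal safe `n_max`.
#'
#' @inheritParams build_base_matrix
#' @return A `"chain_operator"` rate matrix.
#' @export
build_force_matrix <- function(params, trunc = NULL) {
  check_variant(params, "force")
  trunc <- resolve_trunc(params, trunc)
  n <- trunc$n_max
  safe <- force_safe_n_max(params$beta)
  if (n > safe)
    stop(sprintf(paste0("beta * n_max^2 / 8 = %.1f would overflow exp(); ",
                        "maximal safe n_max for beta = %g is %d"),
                 params$beta * n^2 / 8, params$beta, safe), call. = FALSE)
  r <- params$r; a <- params$alpha; b <- params$beta
  M <- matrix(0, n, n)
  M[1, 1] <- -r
  if (n >= 2) M[1, 2:n] <- 2 * a * exp(b * ((2:n) - 1) / 2)
  for (i in 2:n) {
    M[i, i] <- -i * r - total_breaking_rate(i, params)
    M[i, i - 1] <- r * (i - 1)
    if (i < n) M[i, i + 1] <- 2 * a * exp(b * i / 2)
  }
  as_chain_operator(M, params, "rate")
}

#' Maximal truncation length safe from overflow in the force model
#'
#' @param beta Force-coupling constant (>= 0).
#' @return The largest `n_max` with `beta * n_max^2 / 8 <= 700`.
#' @export
force_safe_n_max <- function(beta) {
  if (beta <= 0) return(.Machine$integer.max)
  as.integer(floor(sqrt(8 * .FORCE_EXP_MAX / beta)))
}

#' Survival probability of a shrinking chain between divisions
#'
#' Within one division interval of the fixed-replication-time model
#' (`q = 0`), a chain only shrinks by losing tip bacteria to outermost
#' breaks; an inner break removes it entirely. `survival_prob(n, i, t)` is
#' the probability that a chain that had length `n` right after a division
#' has lost exactly `i` tip bacteria (and no inner break) by time `t`,
#' i.e. is present with length `n - i`:
#'
#' `l(n, i, t) = (2^i / i!) exp(-alpha t (n-1)) (exp(alpha t) - 1)^i`
#'
#' which solves `dl/dt = -alpha (n-1-i) l(n,i,t) + 2 alpha l(n,i-1,t)` with
#' `l(n, 0, 0) = 1`.
#'
#' @param n Initial chain length (>= 2).
#' @param i Number of tip bacteria lost, `0 <= i <= n - 2` (may be a
#'   vector).
#' @param t Elapsed time since the division (>= 0, may be a vector if `i`
#'   is scalar).
#' @param alpha Per-link breaking rate.
#' @return Probabilities in \[0, 1\].
#' @export
survival_prob <- function(n, i, t, alpha = 1) {
  stopifnot(n >= 2, n == round(n), all(t >= 0), alpha > 0)
  if (any(i < 0) || any(i > n - 2) || any(i != round(i)))
    stop("i must be an integer in [0, n - 2]", call. = FALSE)
  # log space; the i = 0 term avoids 0 * log(0)
  at <- alpha * t
  lg <- -at * (n - 1) +
    ifelse(i == 0, 0, i * log(2) - lgamma(i + 1) + i * log(expm1(at)))
  exp(lg)
}

#' Expected free bacteria released by one chain during a division interval
#'
#' Free bacteria are produced at rate `2 alpha` by every surviving chain of
#' length >= 2 (two outermost links for length >= 3; the single link of a
#' 2-chain releases two bacteria at rate `alpha`). Starting from one chain
#' of length `n` right after a division, the expected number released
#' during `tau` is
#'
#' `2 alpha * sum_{i=0}^{n-2} integral_0^tau l(n, i, t) dt`
#'
#' evaluated by adaptive quadrature (closed form `2 (1 - e^{-alpha tau})`
#' for `n = 2`). The integrand is a sum of positive terms, so no
#' cancellation occurs even for long chains.
#'
#' @param n Initial chain length (>= 2).
#' @param tau Division interval (> 0).
#' @param alpha Per-link breaking rate.
#' @return The expected count (a nonnegative number, at most `n`).
#' @export
free_yield <- function(n, tau, alpha = 1) {
  stopifnot(n >= 2, n == round(n), tau > 0, alpha > 0)
  if (n == 2) return(2 * (1 - exp(-alpha * tau)))
  i <- 0:(n - 2)
  ci <- c(0, i[-1] * log(2) - lgamma(i[-1] + 1))
  integrand <- function(t) {
    at <- alpha * t
    res <- numeric(length(t))
    res[at <= 0] <- 1               # l(n, 0, 0) = 1, all other terms vanish
    pos <- at > 0
    if (any(pos)) {
      atp <- at[pos]
      lg <- outer(i, log(expm1(atp))) + ci     # term (i, t): i*le + c_i
      lg <- lg - rep(atp * (n - 1), each = length(i))
      res[pos] <- .colSums(exp(lg), length(i), length(atp))
    }
    res
  }
  2 * alpha * stats::integrate(integrand, 0, tau,
                               rel.tol = 1e-10, abs.tol = 1e-10)$value
}

#' Transfer matrix of the fixed-replication-time model
#'
#' In this variant every bacterium divides synchronously each `tau`; between
#' divisions chains fragment with `q = 0` dynamics. Sampling populations
#' right before each division, a chain of length `j` doubles to `2j` and
#' then contributes [survival_prob()]`(2j, 2j - k, tau)` chains of length
#' `k` (for `2 <= k <= 2j`) and [free_yield()]`(2j, tau)` free bacteria to
#' the next sampling, giving the per-interval map `N(t + tau) = T N(t)`.
#' The matrix is truncated to `n_max x n_max`; columns with `2j > n_max`
#' still count the shrinkage products at lengths `<= n_max`, consistent
#' with truncation-as-loss for the longer products.
#'
#' @param params A `"chain_params"` object with `variant = "fixed_time"`.
#' @inheritParams build_base_matrix
#' @return A nonnegative `"chain_operator"` matrix with
#'   `attr(., "kind") == "transfer"`.
#' @export
build_transfer_matrix <- function(params, trunc = NULL) {
  check_variant(params, "fixed_time")
  trunc <- resolve_trunc(params, trunc)
  n <- trunc$n_max
  tau <- params$tau; alpha <- params$alpha
  Tm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    Tm[1, j] <- free_yield(2 * j, tau, alpha)
    k <- 2:min(2 * j, n)
    Tm[k, j] <- survival_prob(2 * j, 2 * j - k, tau, alpha)
  }
  as_chain_operator(Tm, params, "transfer")
}

#' Build the model operator for any variant
#'
#' Dispatches to the rate-matrix builder of the variant declared in
#' `params`, or to [build_transfer_matrix()] for the fixed-time model.
#'
#' @inheritParams build_base_matrix
#' @param params A `"chain_params"` object.
#' @return A `"chain_operator"` matrix.
#' @export
build_operator <- function(params, trunc = NULL) {
  stopifnot(inherits(params, "chain_params"))
  switch(params$variant,
    base = build_base_matrix(params, trunc),
    escape = build_escape_matrix(params, trunc),
    q_model = build_q_matrix(params, trunc),
    force = build_force_matrix(params, trunc),
    fixed_time = build_transfer_matrix(params, trunc))
}

#' Export an operator as a tab-separated table
#'
#' Writes the entries of a model operator to a TSV file (no row or column
#' names beyond a `length` index column), mainly for debugging.
#'
#' @param operator A `"chain_operator"` matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_operator <- function(operator, path) {
  M <- unclass(operator)
  attr(M, "params") <- NULL; attr(M, "kind") <- NULL
  df <- data.frame(length = seq_len(nrow(M)), M)
  names(df) <- c("length", paste0("from_", seq_len(ncol(M))))
  write_table(df, path)
}
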