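#' Geometric chain-length distribution of the base model
#'
#' In the long-time limit of the base model the balance between replication
#' influx and the dominant loss terms gives, for large lengths, the
#' recursion `p_k ~ (r/(r+alpha)) p_{k-1}`. Applying it at every length
#' yields the normalized geometric form
#'
#' `p_k = (1 - r/(r+alpha)) * (r/(r+alpha))^(k-1)`
#'
#' for the proportion of chains of length `k` among free bacteria and
#' linear chains. The approximation is most accurate for small
#' `r / alpha` and coincides with the exact stationary distribution of the
#' subchain-escape model at `q = 1`.
#'
#' @param r Replication rate (> 0).
#' @param alpha Per-link breaking rate (> 0).
#' @param k Chain length(s), integers >= 1.
#' @return Proportions in \[0, 1\] (they sum to 1 over `k >= 1`).
#' @export
base_distribution <- function(r, alpha, k) {
  stopifnot(r > 0, alpha > 0, all(k >= 1), all(k == round(k)))
  x <- r / (r + alpha)
  (1 - x) * x^(k - 1)
}

#' Geometric chain-length distribution of the escape model
#'
#' As [base_distribution()], but interior-division clipping (probability
#' `delta_dprime`) thins the growth flux, giving the geometric ratio
#' `(1 - delta_dprime) * r / (r + alpha)`. The result depends on neither
#' `delta` nor `delta_prime`, which only matter at small lengths.
#'
#' @inheritParams base_distribution
#' @param delta_dprime Interior clipping probability in \[0, 1\].
#' @return Proportions in \[0, 1\].
#' @export
escape_distribution <- function(r, alpha, delta_dprime, k) {
  stopifnot(r > 0, alpha > 0, delta_dprime >= 0, delta_dprime <= 1,
            all(k >= 1), all(k == round(k)))
  x <- (1 - delta_dprime) * r / (r + alpha)
  (1 - x) * x^(k - 1)
}

#' Exact stationary distribution of the q = 1 model
#'
#' When both fragments of every inner break survive as independent chains
#' (`q = 1`) the model is exactly solvable: the population grows at rate
#' `r` and the number of chains of length `i` is proportional to
#' `(r/(alpha+r))^i`. Normalized over `k >= 1` this is the same geometric
#' law as [base_distribution()] — here exact, not an approximation.
#'
#' @inheritParams base_distribution
#' @return Proportions in \[0, 1\].
#' @export
q1_distribution <- function(r, alpha, k) {
  base_distribution(r, alpha, k)
}

#' Mean chain length of the q = 1 model
#'
#' The exact stationary mean chain length, `1 + r / alpha`: when breaking
#' is fast compared to replication (`r/alpha << 1`) no cluster has time to
#' form and the mean tends to one.
#'
#' @inheritParams base_distribution
#' @return The mean chain length (>= 1).
#' @export
q1_mean_length <- function(r, alpha) {
  stopifnot(r > 0, alpha > 0)
  1 + r / alpha
}

#' Growth-rate approximation for the subchain-escape model
#'
#' Substituting the geometric distribution into the eigenvalue relation of
#' the q-model gives
#'
#' `lambda ~ r (alpha + (2q - 1) r) / (alpha + r)`
#'
#' exact at `q = 1` (where `lambda = r`). The approximation is good for
#' `q` close to 1 and gives the correct large-`r` slope for `q > 0.5`; it
#' does not work for `q < 0.5`, where the true `lambda(r)` has an interior
#' maximum.
#'
#' @inheritParams base_distribution
#' @param q Subchain escape probability in \[0, 1\].
#' @return The approximate growth rate (per unit time).
#' @export
q_growth_rate_approx <- function(r, alpha, q) {
  stopifnot(r >= 0, alpha > 0, q >= 0, q <= 1)
  r * (alpha + (2 * q - 1) * r) / (alpha + r)
}

#' Long-time decay of the free fraction in the q-model
#'
#' The proportion of free bacteria among all bacteria is proportional to
#' `exp(lambda t) / exp(r t)`, which with the growth-rate approximation
#' tends to `exp(-2 r^2 t (1 - q) / (r + alpha))`: even when the number of
#' free bacteria grows, their share decays, the faster the larger `r`.
#'
#' @inheritParams q_growth_rate_approx
#' @param t Elapsed time (>= 0).
#' @return A fraction in (0, 1\].
#' @export
free_fraction_decay <- function(r, alpha, q, t) {
  stopifnot(r >= 0, alpha > 0, q >= 0, q <= 1, all(t >= 0))
  exp(-2 * r^2 * t * (1 - q) / (r + alpha))
}

#' Rough chain-length distribution of the fixed-division-time model
#'
#' Keeping only the leading (no-loss) term of the per-interval recursion
#' and taking the large-`alpha*tau` limit (`N = 2`, the population doubles
#' every interval) gives, for lengths that are powers of two,
#'
#' `p_i / p_1 = i^(alpha*tau/log(2) - 1) * exp(-2 alpha tau i)`
#'
#' anchored here so the ratio is exactly 1 at `i = 1` (the undetermined
#' multiplicative constant of the derivation drops out of ratios). At
#' other lengths the formula interpolates and is an order-of-magnitude
#' guide only; the true distribution is bumpy, with power-of-two lengths
#' overrepresented.
#'
#' @param alpha_tau Product of the breaking rate and the division interval
#'   (> 0); equals `log(2) / (r_eff/alpha)`.
#' @param i Chain length(s) >= 1.
#' @return Relative proportions `p_i / p_1`.
#' @export
fixed_time_distribution <- function(alpha_tau, i) {
  stopifnot(alpha_tau > 0, all(i >= 1), all(i == round(i)))
  expo <- alpha_tau / log(2) - 1
  raw <- function(ii) ii^expo * exp(-2 * alpha_tau * ii)
  raw(i) / raw(1)
}

#' Lattice sums of the force model
#'
#' The constants entering the closed-form distribution of the
#' force-dependent-breaking model:
#' `Y = 1 + 2 sum_{j>=1} exp(-beta j^2 / 2)` (even-length link sums) and
#' `Z = 2 sum_{j>=1} exp(-beta (j - 1/2)^2 / 2)` (odd-length link sums).
#' The series are truncated once a term drops below 1e-16, exact to
#' machine precision for all `beta >= 0.01`.
#'
#' @param beta Force-coupling constant (> 0).
#' @return A list with components `Y` (>= 1) and `Z` (>= 0); both decrease
#'   toward (1, 0) as `beta` grows.
#' @export
force_constants <- function(beta) {
  stopifnot(beta > 0)
  Y <- 1; Z <- 0; j <- 1
  repeat {
    ty <- 2 * exp(-beta * j^2 / 2)
    tz <- 2 * exp(-beta * (j - 1 / 2)^2 / 2)
    Y <- Y + ty; Z <- Z + tz
    if (max(ty, tz) < 1e-16) break
    j <- j + 1
  }
  list(Y = Y, Z = Z)
}

#' Closed-form chain-length distribution of the force model
#'
#' Balancing the dominant terms of the force-model equations gives
#'
#' `p_i ~ (r/alpha)^(i-1) / (i-1)! * Y^floor(i/2) * Z^floor((i-1)/2)
#'        * exp(-(beta/8) * (-1 + (i + 3 i^2 + 2 i^3)/6))`
#'
#' with `Y`, `Z` from [force_constants()]. The cubic term in the exponent
#' makes the distribution decay super-geometrically: long chains are far
#' rarer than in the base model. Computed in log space; the `i = 1`
#' prefactor is exactly 1 before normalization. The approximation works
#' well except for small `beta`.
#'
#' @inheritParams base_distribution
#' @param beta Force-coupling constant (> 0).
#' @param i Chain length(s) >= 1.
#' @param normalize If `TRUE` (default), normalize over the supplied `i`
#'   (the retained range); if `FALSE`, return the raw prefactors.
#' @return Proportions (or raw prefactors).
#' @export
force_distribution <- function(r, alpha, beta, i, normalize = TRUE) {
  stopifnot(r > 0, alpha > 0, beta > 0, all(i >= 1), all(i == round(i)))
  yz <- force_constants(beta)
  lp <- (i - 1) * log(r / alpha) - lgamma(i) +
    floor(i / 2) * log(yz$Y) + floor((i - 1) / 2) * log(yz$Z) -
    (beta / 8) * (-1 + (i + 3 * i^2 + 2 * i^3) / 6)
  p <- exp(lp - max(lp))
  if (normalize) p / sum(p) else exp(lp)
}

#' Back-of-envelope sIgA count per bacterium
#'
#' A gram of digestive content contains at most about `1e11` bacteria and
#' typically 50 micrograms or more of sIgA (molecular mass about 385 kDa),
#' so the number of sIgA molecules per bacterium is
#' `(mass / molecular mass) * N_Avogadro / bacteria`, about 800 — ample
#' for every already-encountered bacterium to be heavily coated.
#'
#' @param siga_mass_per_gram sIgA mass per gram of digestive content, in
#'   grams (default 50 micrograms).
#' @param molecular_mass sIgA molecular mass in Daltons (default 385 kDa).
#' @param bacteria_per_gram Bacterial density per gram (default 1e11).
#' @param rounded If `TRUE`, round to one significant figure for
#'   reporting.
#' @return The sIgA count per bacterium.
#' @examples
#' siga_per_bacterium()                 # ~782
#' siga_per_bacterium(rounded = TRUE)   # 800
#' @export
siga_per_bacterium <- function(siga_mass_per_gram = 50e-6,
                               molecular_mass = 385e3,
                               bacteria_per_gram = 1e11,
                               rounded = FALSE) {
  stopifnot(siga_mass_per_gram > 0, molecular_mass > 0,
            bacteria_per_gram > 0)
  avogadro <- 6.02214076e23
  x <- siga_mass_per_gram / molecular_mass * avogadro / bacteria_per_gram
  if (rounded) signif(x, 1) else x
}
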