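#' Model parameters for enchained-growth chain dynamics
#'
#' Bundles the constants of one model variant of sIgA enchained growth.
#' Free bacteria and linear chains replicate and fragment; the variant
#' determines which mechanisms are active:
#'
#' * `"base"`: fixed replication rate `r`, perfect enchainment upon
#'   replication, fixed per-link breaking rate `alpha`, and subchains from
#'   inner breaks always lost to complex clusters (`q = 0`).
#' * `"escape"`: adds escape probabilities upon replication (`delta` for a
#'   free bacterium, `delta_prime` for the outer daughter at a chain tip,
#'   `delta_dprime` for clipping at an interior division) and loss rates
#'   `c` (free bacteria) and `c_prime` (chains).
#' * `"fixed_time"`: bacteria divide synchronously every `tau` instead of at
#'   rate `r`; the effective growth rate is `r_eff = log(2)/tau`.
#' * `"q_model"`: subchains from an inner break survive as two independent
#'   linear chains with probability `q` (single bacteria released by
#'   outermost breaks always escape).
#' * `"force"`: the per-link breaking rate grows with hydrodynamic load as
#'   `alpha * exp(beta * ((L/2)^2 - x^2) / 2)` for a link at signed offset
#'   `x` from the centre of a chain of length `L`.
#'
#' Only the parameters belonging to the declared variant may differ from
#' their defaults; anything else is rejected, so a parameter set is always
#' interpretable without consulting the variant twice.
#'
#' @param variant One of `"base"`, `"escape"`, `"fixed_time"`, `"q_model"`,
#'   `"force"`.
#' @param r Replication rate per bacterium (per unit time, >= 0). Unused for
#'   `"fixed_time"`, where `tau` sets the pace.
#' @param alpha Per-link breaking rate (per unit time, > 0). In the force
#'   variant this is the unloaded rate.
#' @param tau Division interval (> 0), `"fixed_time"` only.
#' @param delta,delta_prime,delta_dprime Escape probabilities in \[0, 1\],
#'   `"escape"` only.
#' @param c,c_prime Loss rates (>= 0) of free bacteria and of chains,
#'   `"escape"` only.
#' @param q Probability in \[0, 1\] that the two fragments of an inner-link
#'   break persist as independent chains, `"q_model"` only.
#' @param beta Force-coupling constant (>= 0), `"force"` only.
#'
#' @return An object of class `"chain_params"`.
#' @seealso [r_eff()], [build_operator()], [truncation_spec()]
#' @examples
#' chain_params("base", r = 1, alpha = 1)
#' chain_params("fixed_time", alpha = 1, tau = log(2) / 4.1)
#' @export
chain_params <- function(variant = c("base", "escape", "fixed_time",
                                     "q_model", "force"),
                         r = 1, alpha = 1, tau = NULL,
                         delta = 0, delta_prime = 0, delta_dprime = 0,
                         c = 0, c_prime = 0, q = 0, beta = 0) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(r), length(r) == 1, is.finite(r), r >= 0,
            is.numeric(alpha), length(alpha) == 1, is.finite(alpha),
            alpha > 0)
  for (p in list(delta = delta, delta_prime = delta_prime,
                 delta_dprime = delta_dprime, q = q)) {
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
      stop("escape/survival probabilities must be single values in [0, 1]",
           call. = FALSE)
  }
  if (c < 0 || c_prime < 0) stop("loss rates must be >= 0", call. = FALSE)
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)

  if (variant == "fixed_time") {
    if (is.null(tau) || !is.numeric(tau) || length(tau) != 1 || tau <= 0)
      stop("the fixed_time variant requires a division interval tau > 0",
           call. = FALSE)
  } else if (!is.null(tau)) {
    stop("tau is only meaningful for the fixed_time variant", call. = FALSE)
  }
  if (variant != "escape" &&
      (delta != 0 || delta_prime != 0 || delta_dprime != 0 ||
       c != 0 || c_prime != 0))
    stop("escape probabilities and loss rates belong to the escape variant",
         call. = FALSE)
  if (variant != "q_model" && q != 0)
    stop("q is only meaningful for the q_model variant", call. = FALSE)
  if (variant != "force" && beta != 0)
    stop("beta is only meaningful for the force variant", call. = FALSE)

  structure(
    list(variant = variant, r = r, alpha = alpha, tau = tau,
         delta = delta, delta_prime = delta_prime,
         delta_dprime = delta_dprime, c = c, c_prime = c_prime,
         q = q, beta = beta),
    class = "chain_params")
}

#' Effective replication rate of the fixed-division-time model
#'
#' A population dividing synchronously every `tau` doubles each interval, so
#' its exponential growth rate in the absence of any fragmentation is
#' `r_eff = log(2)/tau`. This is the abscissa used when comparing the
#' fixed-time model with the rate-based variants.
#'
#' @param params A `"chain_params"` object with `variant = "fixed_time"`.
#' @return The effective replication rate, per unit time.
#' @export
r_eff <- function(params) {
  stopifnot(inherits(params, "chain_params"))
  if (params$variant != "fixed_time")
    stop("r_eff is defined for the fixed_time variant", call. = FALSE)
  log(2) / params$tau
}

#' @export
print.chain_params <- function(x, ...) {
  cat("<chain_params> variant:", x$variant, "\n")
  shown <- switch(x$variant,
    base = c("r", "alpha"),
    escape = c("r", "alpha", "delta", "delta_prime", "delta_dprime",
               "c", "c_prime"),
    fixed_time = c("alpha", "tau"),
    q_model = c("r", "alpha", "q"),
    force = c("r", "alpha", "beta"))
  for (nm in shown) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  if (x$variant == "fixed_time")
    cat("  r_eff = ", format(r_eff(x)), "\n", sep = "")
  invisible(x)
}

#' Truncation of the chain-length state space
#'
#' The model operators act on populations indexed by chain length
#' `1..n_max`; flux into lengths beyond `n_max` is dropped, i.e. chains
#' growing past the truncation are treated as lost to complex clusters.
#' Adequacy is verified by doubling `n_max` and requiring the dominant
#' eigenvalue to move by less than `convergence_tol` (relative).
#'
#' When `n_max` is `NULL` a variant-appropriate default is chosen by
#' [default_n_max()].
#'
#' @param n_max Maximum chain length retained (integer >= 2), or `NULL`.
#' @param convergence_tol Relative tolerance on the dominant eigenvalue used
#'   by the truncation-adequacy check.
#' @param n_max_cap Upper bound for automatic doubling of `n_max`.
#' @return An object of class `"truncation_spec"`.
#' @export
truncation_spec <- function(n_max = NULL, convergence_tol = 1e-6,
                            n_max_cap = 400L) {
  if (!is.null(n_max)) {
    n_max <- as.integer(n_max)
    if (is.na(n_max) || n_max < 2)
      stop("n_max must be an integer >= 2", call. = FALSE)
  }
  stopifnot(is.numeric(convergence_tol), convergence_tol > 0)
  structure(list(n_max = n_max, convergence_tol = convergence_tol,
                 n_max_cap = as.integer(n_max_cap)),
            class = "truncation_spec")
}

#' Default truncation length per model variant
#'
#' Defaults follow the sizes at which the numerical eigensystems are
#' well converged for moderate parameter values: 40 for the base and escape
#' variants, 32 for the fixed-division-time transfer matrix, 80 for the
#' subchain-escape model (its distributions have heavier tails), and 10-20
#' for the force variant, whose super-exponential per-link rates make long
#' chains vanish quickly (smaller `n_max` for larger `beta`).
#'
#' @param params A `"chain_params"` object.
#' @return An integer truncation length.
#' @export
default_n_max <- function(params) {
  stopifnot(inherits(params, "chain_params"))
  switch(params$variant,
    base = 40L,
    escape = 40L,
    fixed_time = 32L,
    q_model = 80L,
    force = if (params$beta >= 2) 10L else if (params$beta >= 0.1) 15L
            else 20L)
}

# Resolve a truncation spec against a parameter set, filling in n_max.
resolve_trunc <- function(params, trunc = NULL) {
  if (is.null(trunc)) trunc <- truncation_spec()
  stopifnot(inherits(trunc, "truncation_spec"))
  if (is.null(trunc$n_max)) trunc$n_max <- default_n_max(params)
  trunc
}
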