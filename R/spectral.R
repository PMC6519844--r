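#' Dominant eigenpair of a model operator
#'
#' Extracts the long-time growth rate and the stationary chain-length
#' distribution from a model operator. For rate matrices (Metzler
#' structure) the dominant eigenvalue is the one of largest real part and
#' equals the exponential growth rate `lambda` of free bacteria and linear
#' chains; for the nonnegative transfer matrix it is the per-interval
#' multiplier `N` of largest modulus, converted via
#' `lambda = log(N) / tau`. In both cases the dominant eigenvalue is real
#' and its eigenvector can be taken entrywise nonnegative; the returned
#' `distribution` is that eigenvector normalized to sum to 1, so entry `k`
#' is the stationary proportion of chains of length `k` among free
#' bacteria and linear chains.
#'
#' Truncation adequacy is checked by rebuilding the operator with `n_max`
#' doubled and requiring the relative change in `lambda` to stay below
#' `convergence_tol`; the result carries a `converged` flag. Eigenvector
#' entries in `[-1e-10, 0)` (roundoff from the dense solve) are clipped to
#' zero; larger negative entries signal a construction or truncation bug
#' and raise an error.
#'
#' @param operator A `"chain_operator"` matrix from [build_operator()] (or
#'   a plain square matrix, in which case no convergence check is
#'   possible).
#' @param convergence_tol Relative tolerance on `lambda` for the
#'   truncation-adequacy check.
#' @param check_convergence Set to `FALSE` to skip the doubled-`n_max`
#'   rebuild (the flag is then `NA`).
#' @return An object of class `"eigen_result"` with fields `lambda`,
#'   `multiplier_N` (fixed-time only, else `NA`), `distribution`,
#'   `converged`, `n_max`, and `params`.
#' @examples
#' p <- chain_params("base", r = 1, alpha = 1)
#' eig <- dominant_eigenpair(build_base_matrix(p))
#' eig$lambda
#' @export
dominant_eigenpair <- function(operator, convergence_tol = 1e-6,
                               check_convergence = TRUE) {
  if (!is.matrix(operator) || nrow(operator) != ncol(operator))
    stop("operator must be a square matrix", call. = FALSE)
  if (any(!is.finite(operator)))
    stop("operator has non-finite entries", call. = FALSE)
  kind <- attr(operator, "kind")
  params <- attr(operator, "params")
  if (is.null(kind)) kind <- "rate"

  core <- eigen_core(operator, kind)
  converged <- NA
  if (check_convergence && !is.null(params)) {
    n <- nrow(operator)
    n2 <- 2L * n
    if (params$variant == "force")
      n2 <- min(n2, force_safe_n_max(params$beta))
    if (n2 > n) {
      op2 <- build_operator(params, truncation_spec(n_max = n2))
      core2 <- eigen_core(op2, kind)
      converged <- abs(core2$lambda_like - core$lambda_like) <=
        convergence_tol * max(abs(core$lambda_like), .Machine$double.eps)
    }
  }

  lambda <- core$lambda_like
  multiplier <- NA_real_
  if (kind == "transfer") {
    multiplier <- core$raw_value
    lambda <- log(multiplier) / params$tau
  }
  structure(list(lambda = lambda, multiplier_N = multiplier,
                 distribution = core$distribution,
                 converged = converged, n_max = nrow(operator),
                 params = params),
            class = "eigen_result")
}

#' @export
print.eigen_result <- function(x, ...) {
  cat("<eigen_result>\n  lambda =", format(x$lambda))
  if (!is.na(x$multiplier_N))
    cat("  (per-interval multiplier N =", format(x$multiplier_N), ")")
  cat("\n  n_max =", x$n_max, " converged =", x$converged, "\n")
  k <- min(6L, length(x$distribution))
  cat("  distribution[1:", k, "] = ",
      paste(signif(x$distribution[seq_len(k)], 4), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

# Dense solve plus Perron-vector cleanup; lambda_like is the quantity used
# for convergence comparison (log-multiplier per tau for transfer matrices,
# so both kinds compare growth rates).
eigen_core <- function(operator, kind) {
  es <- eigen(unclass(operator))
  if (kind == "transfer") {
    idx <- which(Mod(es$values) >= max(Mod(es$values)) - 1e-12)
  } else {
    idx <- which(Re(es$values) >= max(Re(es$values)) - 1e-12)
  }
  # ties (conjugate pairs at the top would violate Perron structure):
  # prefer the candidate with the most positive eigenvector
  if (length(idx) > 1L) {
    score <- vapply(idx, function(k) {
      v <- Re(es$vectors[, k]); v <- v / v[which.max(abs(v))]
      sum(pmax(v, 0))
    }, numeric(1))
    idx <- idx[which.max(score)]
  }
  value <- es$values[idx]
  if (abs(Im(value)) > 1e-8 * max(1, abs(Re(value))))
    stop("dominant eigenvalue is not real; operator violates the expected ",
         "Metzler/nonnegative structure", call. = FALSE)
  value <- Re(value)
  v <- Re(es$vectors[, idx])
  v <- v / v[which.max(abs(v))]          # largest-magnitude entry -> +1
  if (any(v < -1e-10))
    stop("dominant eigenvector has negative entries beyond roundoff; ",
         "this signals a truncation or construction bug", call. = FALSE)
  v[v < 0] <- 0
  v <- v / sum(v)
  params <- attr(operator, "params")
  lambda_like <- if (kind == "transfer") log(value) / params$tau else value
  list(raw_value = value, lambda_like = lambda_like, distribution = v)
}

# Growth rate with truncation auto-raised (doubling) until converged or
# capped; used by curves and argmax searches.
converged_eigen <- function(params, trunc) {
  trunc <- resolve_trunc(params, trunc)
  n <- trunc$n_max
  cap <- trunc$n_max_cap
  if (params$variant == "force") cap <- min(cap, force_safe_n_max(params$beta))
  repeat {
    op <- build_operator(params, truncation_spec(n_max = n))
    eig <- dominant_eigenpair(op, convergence_tol = trunc$convergence_tol)
    if (isTRUE(eig$converged) || is.na(eig$converged) || 2L * n > cap)
      return(eig)
    n <- 2L * n
  }
}

#' Integrate the mean-field population dynamics
#'
#' Solves `dN/dt = M N` for a rate-matrix operator by matrix-exponential
#' stepping (`expm(M dt)` applied between consecutive output times), which
#' is exact for these linear systems up to the exponential's tolerance.
#' At long times the log-slope of the total population converges to the
#' dominant eigenvalue and the normalized composition to the dominant
#' eigenvector.
#'
#' @param operator A rate-matrix `"chain_operator"`.
#' @param initial Nonnegative initial population vector of length `n_max`
#'   (entry `k` = number of chains of length `k`), or a shorter vector
#'   padded with zeros.
#' @param times Increasing vector of output times starting at values
#'   `>= 0`; time 0 is implicit as the initial condition's time.
#' @return A matrix with one row per output time (rownames are the times)
#'   and one column per chain length.
#' @export
integrate_population <- function(operator, initial, times) {
  kind <- attr(operator, "kind")
  if (!is.null(kind) && kind != "rate")
    stop("integrate_population applies to rate matrices; iterate the ",
         "transfer matrix directly for the fixed-time model", call. = FALSE)
  n <- nrow(operator)
  if (length(initial) < n) initial <- c(initial, rep(0, n - length(initial)))
  if (length(initial) != n || any(initial < 0))
    stop("initial must be a nonnegative vector of length n_max",
         call. = FALSE)
  if (is.unsorted(times, strictly = TRUE) || any(times < 0))
    stop("times must be strictly increasing and nonnegative", call. = FALSE)
  M <- Matrix::Matrix(unclass(operator))
  out <- matrix(NA_real_, length(times), n,
                dimnames = list(format(times), NULL))
  state <- as.numeric(initial)
  t_prev <- 0
  # reuse the propagator when the grid is uniform
  dts <- diff(c(0, times))
  uniform <- length(dts) > 1 && max(abs(dts - dts[1])) < 1e-12 * max(dts)
  E <- if (uniform) Matrix::expm(M * dts[1]) else NULL
  for (k in seq_along(times)) {
    dt <- times[k] - t_prev
    if (dt > 0) {
      Ek <- if (uniform) E else Matrix::expm(M * dt)
      state <- as.numeric(Ek %*% state)
    }
    out[k, ] <- state
    t_prev <- times[k]
  }
  out
}

#' Growth rate as a function of the replication rate
#'
#' Sweeps the long-time growth rate `lambda` over a grid of replication
#' rates. For the rate-based variants the abscissa is `r / alpha`; for the
#' fixed-time variant each grid value is the effective rate
#' `r_eff = log(2) / tau` and the operator is the transfer matrix at the
#' corresponding `tau`. Every point uses a truncation-converged eigenpair
#' (with `n_max` auto-doubled up to the cap in `trunc`); points that fail
#' to converge at the cap are flagged in the `converged` column.
#'
#' @param params A `"chain_params"` template; its `r` (or `tau`) field is
#'   replaced by each grid value.
#' @param r_values Positive, increasing replication rates (absolute units;
#'   divide by `params$alpha` for the conventional abscissa).
#' @param trunc A [truncation_spec()] or `NULL`.
#' @return A data frame of class `"growth_curve"` with columns
#'   `r_over_alpha`, `lambda_over_alpha`, `converged`, and attributes
#'   `argmax_r` / `argmax_lambda` (grid argmax, absolute units).
#' @export
growth_rate_curve <- function(params, r_values, trunc = NULL) {
  stopifnot(inherits(params, "chain_params"))
  if (any(r_values <= 0) || is.unsorted(r_values, strictly = TRUE))
    stop("r_values must be positive and increasing", call. = FALSE)
  eigs <- lapply(r_values, function(r)
    converged_eigen(set_rate(params, r), trunc))
  lam <- vapply(eigs, function(e) e$lambda, numeric(1))
  conv <- vapply(eigs, function(e)
    isTRUE(e$converged) || is.na(e$converged), logical(1))
  df <- data.frame(r_over_alpha = r_values / params$alpha,
                   lambda_over_alpha = lam / params$alpha,
                   converged = conv)
  k <- which.max(df$lambda_over_alpha)
  attr(df, "argmax_r") <- r_values[k]
  attr(df, "argmax_lambda") <- lam[k]
  class(df) <- c("growth_curve", class(df))
  df
}

# Replace the replication rate in a template (tau for fixed_time).
set_rate <- function(params, r) {
  if (params$variant == "fixed_time") params$tau <- log(2) / r
  else params$r <- r
  params
}

eval_lambda <- function(params, r, trunc = NULL) {
  converged_eigen(set_rate(params, r), trunc)$lambda
}

#' Replication rate maximizing the growth rate
#'
#' Locates the replication rate `r*` (or `r_eff*` for the fixed-time
#' variant) that maximizes the long-time growth rate `lambda(r)`, by a
#' coarse log-spaced scan over the bracket followed by golden-section
#' search. Every evaluation uses a truncation-converged eigenpair. If the
#' coarse scan finds the maximum at a bracket boundary (the monotone
#' regimes, e.g. `q > 0.5`), the boundary point is returned with
#' `boundary = TRUE` rather than an error.
#'
#' @param params A `"chain_params"` template.
#' @param bracket Search interval for `r / alpha` (default `c(0.1, 10)`).
#' @param tol Absolute tolerance of the golden-section search, in units of
#'   `r / alpha`.
#' @param n_scan Number of coarse-scan points (log-spaced).
#' @param trunc A [truncation_spec()] or `NULL`.
#' @return A list with `r_star` (absolute units), `r_star_over_alpha`,
#'   `lambda_star`, and `boundary`.
#' @examples
#' \donttest{
#' argmax_growth_rate(chain_params("base", r = 1, alpha = 1))$r_star
#' }
#' @export
argmax_growth_rate <- function(params, bracket = c(0.1, 10), tol = 1e-3,
                               n_scan = 20L, trunc = NULL) {
  stopifnot(inherits(params, "chain_params"),
            length(bracket) == 2, bracket[1] > 0, bracket[2] > bracket[1])
  a <- params$alpha
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = n_scan))
  f <- function(x) eval_lambda(params, x * a, trunc) / a  # x = r/alpha
  ys <- vapply(grid, f, numeric(1))
  k <- which.max(ys)
  if (k == 1L || k == n_scan) {
    return(list(r_star = grid[k] * a, r_star_over_alpha = grid[k],
                lambda_star = ys[k] * a, boundary = TRUE))
  }
  gs <- golden_section_max(f, grid[k - 1], grid[k + 1], tol = tol)
  list(r_star = gs$x * a, r_star_over_alpha = gs$x,
       lambda_star = gs$value * a, boundary = FALSE)
}

# Plain golden-section maximization on [lo, hi] to absolute tolerance tol.
golden_section_max <- function(f, lo, hi, tol = 1e-3) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo)
  x2 <- lo + phi * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo); f1 <- f(x1)
    }
  }
  x <- (lo + hi) / 2
  list(x = x, value = f(x))
}

#' Export a growth curve or a length distribution as TSV
#'
#' @param x A `"growth_curve"` data frame or an `"eigen_result"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(x, path) {
  if (inherits(x, "eigen_result")) {
    df <- data.frame(length = seq_along(x$distribution),
                     proportion = x$distribution)
  } else {
    df <- as.data.frame(x)[, c("r_over_alpha", "lambda_over_alpha")]
  }
  write_table(df, path)
}
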