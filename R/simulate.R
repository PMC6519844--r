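#' Exact stochastic simulation of the rate-based models
#'
#' Event-driven (Gillespie direct-method) realization of the chain
#' dynamics whose mean field is the rate matrix of the same variant. Each
#' chain of length `i` carries replication propensity `i * r` and breaking
#' propensity `(i - 1) * alpha` (or the sum of [per_link_breaking_rate()]
#' for the force variant). On a break, outermost links release the single
#' bacterium, which always escapes; inner breaks release two independent
#' chains with probability `q` and otherwise send both fragments to the
#' complex-cluster pool, an absorbing counter that never releases
#' bacteria. In the escape variant, replication outcomes follow the
#' escape probabilities (`delta` for free bacteria, `delta_prime` at
#' tips, `delta_dprime` for interior clipping, whose two fragments are
#' absorbed into complex clusters), and free bacteria / chains are lost
#' at rates `c` / `c_prime`.
#'
#' Bookkeeping invariant: bacteria in chains + complex clusters + lost
#' equals the initial count plus the number of replications, at every
#' event.
#'
#' @param params A `"chain_params"` object; any variant except
#'   `"fixed_time"` (see [simulate_fixed_tau()]).
#' @param initial Integer vector of initial chain lengths (default one
#'   free bacterium).
#' @param t_end Simulated time horizon.
#' @param seed Optional integer seed.
#' @param population_cap Stop (and flag `truncated = TRUE`) once the
#'   bacteria in chains plus complex clusters reach this count; unchecked
#'   exponential growth would otherwise exhaust memory.
#' @param checkpoints Optional increasing times at which to record the
#'   chain-length counts (lengths `1..record_max_length`).
#' @param record_max_length Number of lengths recorded per checkpoint.
#' @return A list with `state` (fields `chains`, `complex_cluster_bacteria`,
#'   `lost_bacteria`, `time`, `n_replications`, `n_breaks`, `truncated`,
#'   `seed`), `histogram` (a `"chain_histogram"` of the final chains), and
#'   `checkpoint_counts` (matrix, one row per checkpoint) when
#'   `checkpoints` is given.
#' @examples
#' sim <- simulate_rates(chain_params("base", r = 1, alpha = 1),
#'                       initial = 1, t_end = 4, seed = 1)
#' sim$histogram
#' @export
simulate_rates <- function(params, initial = 1L, t_end, seed = NULL,
                           population_cap = 1e6, checkpoints = NULL,
                           record_max_length = 20L) {
  stopifnot(inherits(params, "chain_params"))
  if (params$variant == "fixed_time")
    stop("use simulate_fixed_tau() for the fixed_time variant",
         call. = FALSE)
  stopifnot(all(initial >= 1), all(initial == round(initial)), t_end >= 0)
  if (!is.null(checkpoints))
    stopifnot(!is.unsorted(checkpoints, strictly = TRUE),
              all(checkpoints >= 0), all(checkpoints <= t_end))
  if (!is.null(seed)) set.seed(seed)

  r <- params$r; alpha <- params$alpha; q <- params$q
  d <- params$delta; dp <- params$delta_prime; dpp <- params$delta_dprime
  is_force <- params$variant == "force"
  is_escape <- params$variant == "escape"

  # growing lookup of total breaking rates for the force variant
  brk_table <- if (is_force)
    c(0, vapply(2:64, total_breaking_rate, numeric(1), params = params))
  else numeric(0)
  brk_rate <- function(L) {
    if (!is_force) return((L - 1) * alpha)
    if (any(L > length(brk_table))) {
      new_max <- max(L) * 2L
      brk_table <<- c(brk_table,
                      vapply((length(brk_table) + 1L):new_max,
                             total_breaking_rate, numeric(1),
                             params = params))
    }
    brk_table[L]
  }

  lengths <- as.integer(initial)
  complex <- 0; lost <- 0; n_repl <- 0L; n_brk <- 0L
  time <- 0; truncated <- FALSE
  ckpt <- matrix(0L, length(checkpoints), record_max_length)
  ckpt_complex <- numeric(length(checkpoints))
  next_ck <- 1L
  record_upto <- function(t_now) {
    while (next_ck <= length(checkpoints) &&
           checkpoints[next_ck] <= t_now + 1e-12) {
      ckpt[next_ck, ] <<- utils::head(
        c(tabulate(lengths, nbins = record_max_length)), record_max_length)
      ckpt_complex[next_ck] <<- complex
      next_ck <<- next_ck + 1L
    }
  }

  repeat {
    if (length(lengths) == 0) { record_upto(t_end); time <- t_end; break }
    rp <- lengths * r
    bp <- brk_rate(lengths)
    lp <- if (is_escape)
      ifelse(lengths == 1L, params$c, params$c_prime) else
      numeric(length(lengths))
    total <- sum(rp) + sum(bp) + sum(lp)
    if (total <= 0) { record_upto(t_end); time <- t_end; break }
    dt <- stats::rexp(1, total)
    if (time + dt > t_end) { record_upto(t_end); time <- t_end; break }
    record_upto(time + dt)
    time <- time + dt

    u <- stats::runif(1) * total
    if (u < sum(rp)) {
      # ---- replication ------------------------------------------------
      idx <- sample.int(length(lengths), 1L, prob = rp)
      L <- lengths[idx]
      n_repl <- n_repl + 1L
      if (!is_escape) {
        lengths[idx] <- L + 1L
      } else if (L == 1L) {
        if (stats::runif(1) < d) lengths <- c(lengths, 1L)  # both free
        else lengths[idx] <- 2L
      } else {
        tip <- stats::runif(1) < 2 / L
        if (tip) {
          if (stats::runif(1) < dp) lengths <- c(lengths, 1L)  # outer escapes
          else lengths[idx] <- L + 1L
        } else if (stats::runif(1) < dpp) {
          # interior clip: both fragments (each length >= 2) are absorbed
          complex <- complex + L + 1L
          lengths <- lengths[-idx]
        } else {
          lengths[idx] <- L + 1L
        }
      }
    } else if (u < sum(rp) + sum(bp)) {
      # ---- link breaking ----------------------------------------------
      idx <- sample.int(length(lengths), 1L, prob = bp)
      L <- lengths[idx]
      n_brk <- n_brk + 1L
      if (L == 2L) {
        lengths[idx] <- 1L
        lengths <- c(lengths, 1L)             # two free bacteria
      } else {
        if (is_force) {
          w <- per_link_breaking_rate(L, link_offsets(L), params)
          m <- sample.int(L - 1L, 1L, prob = w)
        } else {
          m <- sample.int(L - 1L, 1L)
        }
        if (m == 1L || m == L - 1L) {         # outermost: free always escapes
          lengths[idx] <- L - 1L
          lengths <- c(lengths, 1L)
        } else if (q > 0 && stats::runif(1) < q) {
          lengths[idx] <- m
          lengths <- c(lengths, L - m)
        } else {
          complex <- complex + L
          lengths <- lengths[-idx]
        }
      }
    } else {
      # ---- loss (escape variant) --------------------------------------
      idx <- sample.int(length(lengths), 1L, prob = lp)
      lost <- lost + lengths[idx]
      lengths <- lengths[-idx]
    }

    if (sum(lengths) + complex >= population_cap) {
      truncated <- TRUE
      record_upto(t_end)
      break
    }
  }

  state <- list(chains = lengths, complex_cluster_bacteria = complex,
                lost_bacteria = lost, time = time,
                n_replications = n_repl, n_breaks = n_brk,
                truncated = truncated, seed = seed)
  hist <- if (length(lengths))
    chain_length_histogram(lengths = lengths,
                           meta = list(variant = params$variant,
                                       params = params, seed = seed,
                                       time = time))
  else NULL
  out <- list(state = state, histogram = hist)
  if (!is.null(checkpoints)) {
    rownames(ckpt) <- format(checkpoints)
    out$checkpoint_counts <- ckpt
    out$checkpoint_complex <- ckpt_complex
  }
  out
}

#' Stochastic simulation of the fixed-division-time model
#'
#' Alternates synchronous doubling of every chain (length `j -> 2j`; free
#' bacteria become 2-chains) with exact continuous-time fragmentation
#' during the interval `tau`: each link carries an exponential clock at
#' rate `alpha`, outermost breaks release a free bacterium (inert until
#' the next division) and a shortened chain, inner breaks absorb the whole
#' chain into the complex-cluster pool (`q = 0`), and a 2-chain break
#' releases two free bacteria. Populations are sampled right before each
#' division, matching the transfer-matrix bookkeeping.
#'
#' @param params A `"chain_params"` object with `variant = "fixed_time"`.
#' @param initial Integer vector of initial chain lengths (sampled right
#'   before a division).
#' @param n_generations Number of division intervals to simulate.
#' @param seed Optional integer seed.
#' @param population_cap As in [simulate_rates()].
#' @return A list with `state` (including `free_history` and
#'   `total_chain_history`, one entry per sampling) and `histogram`.
#' @export
simulate_fixed_tau <- function(params, initial = 1L, n_generations,
                               seed = NULL, population_cap = 1e6) {
  check_variant(params, "fixed_time")
  stopifnot(all(initial >= 1), all(initial == round(initial)),
            n_generations >= 1)
  if (!is.null(seed)) set.seed(seed)
  tau <- params$tau; alpha <- params$alpha
  lengths <- as.integer(initial)
  complex <- 0; n_repl <- 0L; n_brk <- 0L; truncated <- FALSE
  free_hist <- integer(n_generations)
  total_hist <- integer(n_generations)

  for (g in seq_len(n_generations)) {
    n_repl <- n_repl + sum(lengths)
    lengths <- 2L * lengths
    free <- 0L
    survivors <- integer(0)
    for (L in lengths) {
      t <- 0
      repeat {
        if (L < 2L) break
        dt <- stats::rexp(1, (L - 1L) * alpha)
        t <- t + dt
        if (t > tau) break                     # survives the interval
        n_brk <- n_brk + 1L
        if (L == 2L) { free <- free + 2L; L <- 0L; break }
        m <- sample.int(L - 1L, 1L)
        if (m == 1L || m == L - 1L) {
          free <- free + 1L
          L <- L - 1L
        } else {
          complex <- complex + L
          L <- 0L
          break
        }
      }
      if (L >= 2L) survivors <- c(survivors, L)
    }
    lengths <- c(survivors, rep(1L, free))
    free_hist[g] <- free
    total_hist[g] <- length(lengths)
    if (sum(lengths) + complex >= population_cap) {
      truncated <- TRUE
      free_hist <- free_hist[seq_len(g)]
      total_hist <- total_hist[seq_len(g)]
      break
    }
    if (length(lengths) == 0) {
      free_hist <- free_hist[seq_len(g)]
      total_hist <- total_hist[seq_len(g)]
      break
    }
  }

  state <- list(chains = lengths, complex_cluster_bacteria = complex,
                lost_bacteria = 0, time = length(free_hist) * tau,
                n_replications = n_repl, n_breaks = n_brk,
                truncated = truncated, seed = seed,
                free_history = free_hist,
                total_chain_history = total_hist)
  hist <- if (length(lengths))
    chain_length_histogram(lengths = lengths,
                           meta = list(variant = "fixed_time",
                                       params = params, seed = seed,
                                       generations = length(free_hist)))
  else NULL
  list(state = state, histogram = hist)
}
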