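#' Chain-length histogram
#'
#' Integer counts of linear chains by length (length 1 = free bacterium),
#' as produced by the stochastic simulator, by [sample_histogram()], or
#' read from a TSV file of observed counts. Stored as a data frame with
#' columns `length` and `count` (sorted, unique lengths) and a `meta`
#' attribute carrying provenance (variant, parameters, seed, time point).
#'
#' @param lengths Integer vector of observed chain lengths (one entry per
#'   chain), or `NULL` if `counts` is given.
#' @param counts Named integer vector (`names` = lengths) or a two-column
#'   data frame `length`/`count`.
#' @param meta A list of provenance fields.
#' @return An object of class `"chain_histogram"`.
#' @export
chain_length_histogram <- function(lengths = NULL, counts = NULL,
                                   meta = list()) {
  if (!is.null(lengths)) {
    stopifnot(is.null(counts), all(lengths >= 1),
              all(lengths == round(lengths)))
    tab <- table(lengths)
    df <- data.frame(length = as.integer(names(tab)),
                     count = as.integer(tab))
  } else if (is.data.frame(counts)) {
    df <- data.frame(length = as.integer(counts$length),
                     count = as.integer(counts$count))
  } else {
    stopifnot(!is.null(names(counts)))
    df <- data.frame(length = as.integer(names(counts)),
                     count = as.integer(counts))
  }
  if (any(is.na(df$length)) || any(df$length < 1))
    stop("chain lengths must be integers >= 1", call. = FALSE)
  if (any(is.na(df$count)) || any(df$count < 0))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (anyDuplicated(df$length))
    stop("duplicate chain lengths in histogram", call. = FALSE)
  df <- df[order(df$length), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, meta = meta,
            class = c("chain_histogram", "data.frame"))
}

#' @export
print.chain_histogram <- function(x, ...) {
  cat("<chain_histogram> ", sum(x$count), " chains, lengths ",
      min(x$length), "..", max(x$length), "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Total number of chains in a histogram
#'
#' @param h A `"chain_histogram"`.
#' @param min_length Count only chains of at least this length.
#' @return An integer.
#' @export
total_chains <- function(h, min_length = 1L) {
  stopifnot(inherits(h, "chain_histogram"))
  sum(h$count[h$length >= min_length])
}

# Dense count vector over lengths 1..n (zeros filled in).
hist_dense_counts <- function(h, n = max(h$length)) {
  out <- integer(n)
  keep <- h$length <= n
  out[h$length[keep]] <- h$count[keep]
  out
}

#' Multinomial sampling of chain lengths from a distribution
#'
#' Draws `n_chains` chain lengths from a normalized length distribution —
#' the synthetic-data generator used to exercise the fitting machinery.
#'
#' @param distribution Numeric vector of proportions; entry `k` (or the
#'   name, if named) is the probability of length `k`. Must sum to 1.
#' @param n_chains Number of chains to draw (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A `"chain_histogram"` of the drawn lengths.
#' @examples
#' p <- base_distribution(1, 1, 1:30)
#' sample_histogram(p / sum(p), 100, seed = 1)
#' @export
sample_histogram <- function(distribution, n_chains, seed = NULL) {
  stopifnot(is.numeric(distribution), all(distribution >= 0),
            n_chains >= 1, n_chains == round(n_chains))
  if (abs(sum(distribution) - 1) > 1e-8)
    stop("distribution must be normalized (sums to ",
         format(sum(distribution)), ")", call. = FALSE)
  lens <- if (!is.null(names(distribution)))
    as.integer(names(distribution)) else seq_along(distribution)
  if (!is.null(seed)) set.seed(seed)
  draw <- as.integer(stats::rmultinom(1, n_chains, distribution))
  keep <- draw > 0
  chain_length_histogram(
    counts = data.frame(length = lens[keep], count = draw[keep]),
    meta = list(source = "sample_histogram", n_chains = n_chains,
                seed = seed))
}
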