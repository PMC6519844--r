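#' Read a chain-length histogram from a TSV file
#'
#' Strict parser for the tab-separated histogram format: an optional block
#' of `#`-prefixed comment lines, a header line `length<TAB>count`, then
#' one row per occupied length with an integer length >= 1 and an integer
#' count >= 0. Malformed rows are reported with their line number;
#' duplicate lengths are rejected.
#'
#' @param path Path to the TSV file.
#' @return A `"chain_histogram"`; the comment lines are kept in the
#'   `meta` attribute.
#' @export
read_histogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  body_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(body_idx) < 2)
    stop("histogram file needs a header and at least one data row",
         call. = FALSE)
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) != 2 || header[1] != "length" || header[2] != "count")
    stop(sprintf("line %d: expected header 'length<TAB>count'",
                 body_idx[1]), call. = FALSE)
  rows <- lapply(body_idx[-1], function(ln) {
    parts <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("line %d: expected two tab-separated fields", ln),
           call. = FALSE)
    vals <- suppressWarnings(as.numeric(parts))
    if (any(is.na(vals)) || any(vals != round(vals)))
      stop(sprintf("line %d: non-integer length or count", ln),
           call. = FALSE)
    if (vals[1] < 1)
      stop(sprintf("line %d: chain length must be >= 1", ln),
           call. = FALSE)
    if (vals[2] < 0)
      stop(sprintf("line %d: count must be >= 0", ln), call. = FALSE)
    vals
  })
  df <- do.call(rbind, rows)
  if (anyDuplicated(df[, 1]))
    stop("duplicate chain lengths in ", path, call. = FALSE)
  chain_length_histogram(
    counts = data.frame(length = df[, 1], count = df[, 2]),
    meta = list(path = path, comments = lines[is_comment]))
}

#' Write a chain-length histogram to a TSV file
#'
#' Writes `#`-prefixed metadata comment lines, the `length<TAB>count`
#' header, and one row per occupied length, sorted by length, with fixed
#' integer formatting — so identical histograms produce byte-identical
#' files.
#'
#' @param h A `"chain_histogram"`.
#' @param path Output file path.
#' @param comments Character vector of metadata lines (written with a
#'   leading `# `); defaults to a rendering of the histogram's `meta`.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(h, path, comments = NULL) {
  stopifnot(inherits(h, "chain_histogram"))
  if (is.null(comments)) {
    meta <- attr(h, "meta")
    flat <- meta[vapply(meta, function(x)
      is.atomic(x) && length(x) == 1, logical(1))]
    comments <- sprintf("%s=%s", names(flat),
                        vapply(flat, format, character(1)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  writeLines("length\tcount", con)
  o <- order(h$length)
  writeLines(sprintf("%d\t%d", h$length[o], h$count[o]), con)
  invisible(path)
}

#' Write a numeric table as TSV
#'
#' Tab-separated, header from the column names, numbers serialized with 12
#' significant digits (integers as integers), no quoting.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  stopifnot(is.data.frame(df))
  fmt <- vapply(df, function(col) {
    if (is.integer(col) || (is.numeric(col) && all(col == round(col))))
      format(col, scientific = FALSE, trim = TRUE)
    else if (is.numeric(col))
      formatC(col, digits = 12, format = "g")
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  writeLines(apply(fmt, 1L, paste, collapse = "\t"), con)
  invisible(path)
}
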