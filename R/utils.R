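#' Write a data frame as tab-separated text
#'
#' Thin wrapper over [utils::write.table()] with the conventions used by all
#' package outputs (no quoting, no row names, tab delimiter).
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# single point of control for the package's progress/bookkeeping messages
#' @noRd
log_msg <- function(...) message(...)

#' @noRd
assert_cols <- function(df, cols, what = "input") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated. Duplicate members within a set are dropped.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of member ids, with a
#'   `"descriptions"` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stop(sprintf("GMT line(s) %s have fewer than 3 fields",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  ids <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene-set ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  empty <- lengths(sets) == 0L
  if (any(empty)) stop("gene set(s) with no members: ",
                       paste(ids[empty], collapse = ", "), call. = FALSE)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, "", 2L), ids)
  sets
}

#' Write a gene-set collection in GMT format
#'
#' @param sets named list of character vectors of member ids.
#' @param path output file path.
#' @param descriptions optional named character vector of set descriptions;
#'   defaults to the set ids.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all gene sets must be named", call. = FALSE)
  desc <- descriptions %||% attr(sets, "descriptions") %||%
    setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, desc[[id]] %||% id, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
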