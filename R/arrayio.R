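# Two-channel probe-intensity input, background correction and per-gene
# M/A summarization.
#
# Channel semantics throughout: green = Cy3 = polysome (P) pool,
# red = Cy5 = free+monosome (FM) pool, so M = log2(P/FM) is the translation
# efficiency and A = 1/2 log2(R*G) the abundance proxy.

.probe_cols <- c("probe_id", "gene_id", "green_fg", "green_bg", "red_fg", "red_bg")

#' Read a two-channel probe-intensity table
#'
#' Parses a delimiter-separated probe table (one row per probe, replicate
#' probes of the same gene allowed) into the standard probe layout used by
#' the rest of the pipeline. Rows with any negative intensity are dropped
#' with a warning, since fluorescence intensities are non-negative by
#' definition.
#'
#' @param source path to a delimited text file with a header row, or a data
#'   frame already in memory.
#' @param column_map named character vector mapping the required fields
#'   `probe_id`, `gene_id`, `green_fg`, `green_bg`, `red_fg`, `red_bg` to the
#'   column names present in `source`.
#' @param delim field delimiter (default tab).
#' @param condition optional condition label (e.g. `"control"`,
#'   `"stress_3h"`) stored on every row.
#' @return data frame with columns `probe_id`, `gene_id`, `green_fg`,
#'   `green_bg`, `red_fg`, `red_bg` and `condition`, in input row order.
#' @export
read_probe_table <- function(source,
                             column_map = setNames(.probe_cols, .probe_cols),
                             delim = "\t", condition = NA_character_) {
  if (is.character(source)) {
    raw <- read.delim(source, sep = delim, header = TRUE,
                      colClasses = "character", check.names = FALSE)
  } else if (is.data.frame(source)) {
    raw <- source
  } else stop("source must be a file path or a data frame", call. = FALSE)

  miss <- setdiff(.probe_cols, names(column_map))
  if (length(miss) > 0L)
    stop("column_map does not name required field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  absent <- setdiff(unname(column_map[.probe_cols]), names(raw))
  if (length(absent) > 0L)
    stop("probe table is missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  out <- data.frame(
    probe_id = as.character(raw[[column_map[["probe_id"]]]]),
    gene_id  = as.character(raw[[column_map[["gene_id"]]]]),
    stringsAsFactors = FALSE
  )
  for (f in .probe_cols[3:6]) {
    v <- raw[[column_map[[f]]]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad) > 0L)
        stop(sprintf("unparseable numeric value in column '%s' at data line %d",
                     column_map[[f]], bad[1L]), call. = FALSE)
      v <- parsed
    }
    out[[f]] <- as.numeric(v)
  }
  if (any(!nzchar(out$probe_id)))
    stop("empty probe_id encountered", call. = FALSE)

  neg <- rowSums(out[, .probe_cols[3:6]] < 0) > 0
  neg[is.na(neg)] <- FALSE
  if (any(neg)) {
    warning(sprintf("dropped %d probe row(s) with negative intensities", sum(neg)),
            call. = FALSE)
    out <- out[!neg, , drop = FALSE]
  }
  out$condition <- condition
  rownames(out) <- NULL
  out
}

#' Moment-matching fit of the normal + exponential convolution model
#'
#' Fits `X = B + S` with `B ~ Normal(mu, sigma^2)` (background) and
#' `S ~ Exponential(alpha)` (true signal) by matching the first three
#' moments: `E X = mu + alpha`, `Var X = sigma^2 + alpha^2`,
#' `E (X - EX)^3 = 2 alpha^3`.
#'
#' @param x numeric vector of net intensities (foreground minus background).
#' @return list with `mu`, `sigma`, `alpha`, or `NULL` when the moment
#'   system is degenerate (non-positive skew or implied variance).
#' @export
normexp_fit_moments <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L) return(NULL)
  m1 <- mean(x)
  v <- var(x)
  m3 <- mean((x - m1)^3)
  if (!is.finite(m3) || m3 <= 0) return(NULL)
  alpha <- (m3 / 2)^(1 / 3)
  sigma2 <- v - alpha^2
  if (!is.finite(sigma2) || sigma2 <= 0) return(NULL)
  list(mu = m1 - alpha, sigma = sqrt(sigma2), alpha = alpha)
}

#' Expected signal given an observed net intensity under the normexp model
#'
#' The posterior mean `E[S | X = x]` of the exponential signal given the
#' observation, in the usual normal-cdf/pdf closed form.
#'
#' @param par list with `mu`, `sigma`, `alpha` (see [normexp_fit_moments()]).
#' @param x numeric vector of net intensities.
#' @return numeric vector of corrected (strictly positive) signals.
#' @export
normexp_signal <- function(par, x) {
  mu.sf <- x - par$mu - par$sigma^2 / par$alpha
  sig <- mu.sf + par$sigma^2 *
    exp(dnorm(0, mean = mu.sf, sd = par$sigma, log = TRUE) -
        pnorm(0, mean = mu.sf, sd = par$sigma, lower.tail = FALSE, log.p = TRUE))
  pmax(sig, 1e-6)
}

#' Background-correct probe intensities
#'
#' Adds strictly positive corrected intensities (`green`, `red`) to a probe
#' table. `"none"` keeps the foreground; `"half"` takes
#' `max(fg - bg, floor)`; `"normexp"` fits the normal(background) +
#' exponential(signal) convolution to the net intensities of each channel by
#' moment matching and replaces them with the conditional expected signal.
#' A degenerate normexp fit falls back to `"half"` with a warning.
#'
#' @param records probe table as returned by [read_probe_table()].
#' @param method one of `"none"`, `"half"`, `"normexp"`.
#' @param half_floor positivity floor for the `"half"` method, in intensity
#'   units (default 0.5, the conventional choice giving the method its name).
#' @return the probe table with `green` and `red` corrected-intensity
#'   columns appended.
#' @export
background_correct <- function(records, method = c("none", "half", "normexp"),
                               half_floor = 0.5) {
  method <- match.arg(method)
  assert_cols(records, .probe_cols, "probe table")
  half <- function(fg, bg) pmax(fg - bg, half_floor)
  one_channel <- function(fg, bg, label) {
    switch(method,
      none = pmax(fg, half_floor),
      half = half(fg, bg),
      normexp = {
        if (length(fg) < 50L)
          stop("normexp needs at least 50 probes per channel", call. = FALSE)
        par <- normexp_fit_moments(fg - bg)
        if (is.null(par)) {
          warning(sprintf(
            "normexp moment fit degenerate for %s channel; falling back to half",
            label), call. = FALSE)
          half(fg, bg)
        } else normexp_signal(par, fg - bg)
      })
  }
  records$green <- one_channel(records$green_fg, records$green_bg, "green")
  records$red <- one_channel(records$red_fg, records$red_bg, "red")
  stopifnot(all(records$green > 0), all(records$red > 0))
  records
}

#' Summarize corrected probes into per-gene M and A values
#'
#' Per probe, `M = log2(green/red)` and `A = 1/2 log2(green * red)`;
#' replicate probes of a gene are then averaged on the M/A scale.
#'
#' @param records background-corrected probe table (see
#'   [background_correct()]).
#' @return data frame with one row per gene: `gene_id`, `M`, `A`,
#'   `n_probes` (and `condition` when present in the input), ordered by
#'   `gene_id`.
#' @export
summarize_expression <- function(records) {
  assert_cols(records, c("gene_id", "green", "red"), "corrected probe table")
  if (any(records$green <= 0) || any(records$red <= 0))
    stop("non-positive corrected intensity: run background_correct() first",
         call. = FALSE)
  m <- log2(records$green / records$red)
  a <- 0.5 * log2(records$green * records$red)
  g <- factor(records$gene_id)
  out <- data.frame(
    gene_id = levels(g),
    M = as.vector(rowsum(m, g) / tabulate(g)),
    A = as.vector(rowsum(a, g) / tabulate(g)),
    n_probes = tabulate(g),
    stringsAsFactors = FALSE
  )
  if ("condition" %in% names(records)) {
    cond <- unique(records$condition)
    if (length(cond) > 1L)
      stop("probe table mixes conditions; summarize each condition separately",
           call. = FALSE)
    out$condition <- cond
  }
  out
}

#' Filter expression records by abundance
#'
#' Retains genes with `A` strictly greater than the threshold, the
#' reliability filter applied before any comparison.
#'
#' @param expr expression table from [summarize_expression()].
#' @param a_min abundance threshold (records kept when `A > a_min`).
#' @return the retained subset, with the number discarded reported via
#'   [message()].
#' @export
filter_by_abundance <- function(expr, a_min) {
  stopifnot(is.finite(a_min) || a_min == -Inf)
  assert_cols(expr, c("gene_id", "A"), "expression table")
  keep <- expr$A > a_min
  log_msg(sprintf("abundance filter A > %g: kept %d, discarded %d",
                  a_min, sum(keep), sum(!keep)))
  expr[keep, , drop = FALSE]
}
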