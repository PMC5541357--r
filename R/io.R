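#' Read an ASCII scattering data file
#'
#' Parses the whitespace-separated `.dat` dialect used throughout
#' small-angle-scattering pipelines: columns `s`, `I(s)` and optionally
#' `sigma(s)`. Any line whose first two whitespace-separated tokens parse as
#' numbers is treated as data; all other lines are preserved verbatim in
#' `meta$header` (beamline headers vary too much for a stricter grammar).
#'
#' The angular unit is resolved in order of priority: the `unit_hint`
#' argument, a `1/nm`/`nm-1`/`1/A`/`A-1` token in a header line, then the
#' heuristic that biological SAXS rarely exceeds 1 inverse angstrom
#' (`max(s) > 1` implies inverse nanometres). Rows with non-positive sigma
#' are dropped and their count recorded in `meta$dropped_rows`.
#'
#' @param path file to read.
#' @param unit_hint optional `"A-1"` or `"nm-1"`, overrides detection.
#' @return A [scattering_curve()].
#' @export
read_dat <- function(path, unit_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  toks <- strsplit(trimws(lines), "\\s+")
  is_data <- vapply(toks, function(tk) {
    length(tk) >= 2L && !anyNA(suppressWarnings(as.numeric(tk[1:2])))
  }, logical(1))
  header <- lines[!is_data & nzchar(trimws(lines))]
  rows <- toks[is_data]
  if (length(rows) < 2L) {
    stop("fewer than 2 parseable numeric rows in ", path, call. = FALSE)
  }
  ncol <- min(vapply(rows, length, integer(1)), 3L)
  m <- do.call(rbind, lapply(rows, function(tk)
    suppressWarnings(as.numeric(tk[seq_len(ncol)]))))
  keep <- !is.na(m[, 1L]) & !is.na(m[, 2L])
  m <- m[keep, , drop = FALSE]
  has_sigma <- ncol >= 3L && !anyNA(m[, 3L])
  dropped <- 0L
  if (has_sigma) {
    ok <- m[, 3L] > 0
    dropped <- sum(!ok)
    if (dropped > 0L) {
      message("read_dat: dropped ", dropped, " rows with non-positive sigma")
      m <- m[ok, , drop = FALSE]
    }
  }
  if (nrow(m) < 2L) {
    stop("fewer than 2 valid rows in ", path, call. = FALSE)
  }
  if (any(diff(m[, 1L]) <= 0)) {
    stop("non-monotonic grid in ", path, call. = FALSE)
  }
  unit <- unit_hint
  if (is.null(unit)) {
    hdr <- paste(header, collapse = " ")
    if (grepl("(1/nm|nm-1|nm\\^-1)", hdr, ignore.case = TRUE)) {
      unit <- "nm-1"
    } else if (grepl("(1/A|A-1|A\\^-1|angstrom)", hdr, ignore.case = TRUE)) {
      unit <- "A-1"
    } else {
      unit <- if (max(m[, 1L]) > 1.0) "nm-1" else "A-1"
    }
  }
  meta <- list(parent = path)
  if (length(header)) meta$header <- header
  if (dropped > 0L) meta$dropped_rows <- dropped
  scattering_curve(m[, 1L], m[, 2L],
                   sigma = if (has_sigma) m[, 3L],
                   unit = unit, meta = meta)
}

#' Write a scattering curve to an ASCII data file
#'
#' One row per point in fixed-width scientific notation (6 significant
#' digits); the sigma column is present exactly when the curve carries
#' errors. The header records the angular unit and all scalar metadata so
#' that [read_dat()] round-trips the curve.
#'
#' @param curve a [scattering_curve()].
#' @param path destination file.
#' @export
write_dat <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  hdr <- c(sprintf("# Unit: %s", curve$unit))
  for (k in names(curve$meta)) {
    val <- curve$meta[[k]]
    if (is.atomic(val) && length(val) == 1L) {
      hdr <- c(hdr, sprintf("# %s: %s", k, format(val)))
    }
  }
  fmt <- function(x) formatC(x, format = "e", digits = 6, width = 15)
  body <- if (is.null(curve$sigma)) {
    paste0(fmt(curve$s), fmt(curve$i))
  } else {
    paste0(fmt(curve$s), fmt(curve$i), fmt(curve$sigma))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write an indirect-Fourier-transform solution to a text file
#'
#' Self-describing layout with labelled key/value lines (`Dmax`, `Rg`,
#' `I0`, `alpha`, the perceptual criteria scores) followed by two column
#' blocks: the experimental data with the regularized fit, and the p(r)
#' distance distribution with its propagated errors. [read_ift_file()]
#' parses the same layout back.
#'
#' @param solution an `ift_solution` as returned by [ift_solve()].
#' @param path destination file.
#' @export
write_ift_file <- function(solution, path) {
  stopifnot(inherits(solution, "ift_solution"))
  fmt <- function(x) formatC(x, format = "e", digits = 8, width = 17)
  out <- c(
    "# saskit indirect Fourier transform solution",
    sprintf("Dmax: %.8e", solution$pr$dmax),
    sprintf("Rg: %.8e", solution$rg),
    sprintf("I0: %.8e", solution$i0),
    sprintf("alpha: %.8e", solution$alpha),
    sprintf("chi2_reduced: %.8e", solution$chi2_reduced),
    sprintf("total: %.8e", solution$total),
    paste("criteria:", paste(names(solution$criteria),
                             sprintf("%.6f", unlist(solution$criteria)),
                             sep = "=", collapse = " ")),
    sprintf("unit: %s", solution$fit$unit),
    "## DATA_AND_FIT  (s  I  sigma  Ifit)",
    paste0(fmt(solution$data$s), fmt(solution$data$i),
           fmt(solution$data$sigma), fmt(solution$fit$i)),
    "## PR  (r  p  perr)",
    paste0(fmt(solution$pr$r), fmt(solution$pr$p), fmt(solution$pr$perr)))
  writeLines(out, path)
  invisible(path)
}

#' Read an indirect-Fourier-transform solution file
#'
#' @param path file written by [write_ift_file()].
#' @return A list with elements `pr` (list `r`, `p`, `perr`, `dmax`), `data`
#'   and `fit` ([scattering_curve()]s), `rg`, `i0`, `alpha`,
#'   `chi2_reduced`, `total` and `criteria`.
#' @export
read_ift_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  getval <- function(key) {
    ln <- grep(sprintf("^%s:", key), lines, value = TRUE)
    if (!length(ln)) stop("missing key '", key, "' in ", path, call. = FALSE)
    as.numeric(sub(sprintf("^%s:\\s*", key), "", ln[1L]))
  }
  unit_ln <- grep("^unit:", lines, value = TRUE)
  unit <- if (length(unit_ln)) trimws(sub("^unit:", "", unit_ln[1L])) else "A-1"
  blk <- function(tag) {
    i0 <- grep(paste0("^## ", tag), lines)
    if (!length(i0)) stop("missing block ", tag, " in ", path, call. = FALSE)
    out <- list()
    for (ln in lines[seq(i0 + 1L, length(lines))]) {
      if (grepl("^##", ln)) break
      tk <- suppressWarnings(as.numeric(strsplit(trimws(ln), "\\s+")[[1L]]))
      if (anyNA(tk)) break
      out[[length(out) + 1L]] <- tk
    }
    do.call(rbind, out)
  }
  df <- blk("DATA_AND_FIT")
  pr <- blk("PR")
  crit_ln <- grep("^criteria:", lines, value = TRUE)
  criteria <- NULL
  if (length(crit_ln)) {
    kv <- strsplit(strsplit(sub("^criteria:\\s*", "", crit_ln[1L]),
                            "\\s+")[[1L]], "=")
    criteria <- stats::setNames(
      as.list(as.numeric(vapply(kv, `[`, "", 2L))),
      vapply(kv, `[`, "", 1L))
  }
  list(
    pr = list(r = pr[, 1L], p = pr[, 2L], perr = pr[, 3L],
              dmax = getval("Dmax")),
    data = scattering_curve(df[, 1L], df[, 2L], sigma = df[, 3L], unit = unit),
    fit = scattering_curve(df[, 1L], df[, 4L], unit = unit),
    rg = getval("Rg"), i0 = getval("I0"), alpha = getval("alpha"),
    chi2_reduced = getval("chi2_reduced"), total = getval("total"),
    criteria = criteria)
}
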