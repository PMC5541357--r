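#' One-dimensional scattering curve
#'
#' Container for a background-subtracted 1D solution-scattering profile:
#' the momentum-transfer grid `s = 4*pi*sin(theta)/lambda`, intensities
#' `I(s)`, optional 1-sigma point errors and free-form metadata.
#'
#' @param s numeric vector of momentum-transfer values, strictly increasing,
#'   non-negative.
#' @param i numeric vector of intensities, same length as `s`.
#' @param sigma optional numeric vector of 1-sigma errors, strictly positive.
#' @param unit angular unit of `s`: `"A-1"` (inverse angstroms, the internal
#'   canonical unit) or `"nm-1"` (inverse nanometres).
#' @param meta named list of provenance entries (sample name, concentration
#'   in mg/ml, parent files, ...).
#'
#' @return An object of class `scattering_curve` with fields `s`, `i`,
#'   `sigma`, `unit`, `meta`.
#' @examples
#' s <- seq(0.01, 0.5, by = 0.005)
#' crv <- scattering_curve(s, exp(-s^2 * 180), sigma = 0.01 * exp(-s^2 * 180))
#' crv
#' @export
scattering_curve <- function(s, i, sigma = NULL, unit = c("A-1", "nm-1"),
                             meta = list()) {
  unit <- match.arg(unit)
  obj <- structure(
    list(s = as.numeric(s), i = as.numeric(i),
         sigma = if (!is.null(sigma)) as.numeric(sigma),
         unit = unit, meta = meta),
    class = "scattering_curve")
  viol <- validate_curve(obj)
  if (length(viol)) {
    stop("invalid scattering curve: ", paste(viol, collapse = "; "),
         call. = FALSE)
  }
  obj
}

#' Validate a scattering curve
#'
#' Checks every class invariant and reports each violation with the first
#' offending index. Unlike the constructor this never throws, so it can be
#' used to triage questionable input files.
#'
#' @param curve object to check (need not be a valid `scattering_curve`).
#' @return Character vector of violation descriptions; empty if the curve is
#'   valid.
#' @export
validate_curve <- function(curve) {
  v <- character(0)
  s <- curve$s; i <- curve$i; sg <- curve$sigma
  if (!is.numeric(s) || !is.numeric(i)) {
    return("s and i must be numeric vectors")
  }
  if (length(s) < 2L) v <- c(v, "curve length: fewer than 2 points")
  if (length(i) != length(s)) v <- c(v, "length mismatch between s and i")
  if (!is.null(sg) && length(sg) != length(s)) {
    v <- c(v, "length mismatch between s and sigma")
  }
  if (anyNA(s) || anyNA(i)) v <- c(v, "NA values in s or i")
  bad <- which(s < 0)
  if (length(bad)) {
    v <- c(v, sprintf("negative s: first offending index %d", bad[1L]))
  }
  if (length(s) >= 2L) {
    nd <- which(diff(s) <= 0)
    if (length(nd)) {
      v <- c(v, sprintf("strict monotonicity of s violated at index %d",
                        nd[1L] + 1L))
    }
  }
  if (!is.null(sg)) {
    bad <- which(!(sg > 0))
    if (length(bad)) {
      v <- c(v, sprintf("sigma positivity violated at index %d", bad[1L]))
    }
  }
  if (!is.null(curve$unit) && !curve$unit %in% c("A-1", "nm-1")) {
    v <- c(v, "unknown angular unit")
  }
  v
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("scattering curve: %d points, s = [%g, %g] %s, %s errors\n",
              length(x$s), x$s[1L], x$s[length(x$s)], x$unit,
              if (is.null(x$sigma)) "no" else "with"))
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                       sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.scattering_curve <- function(x) length(x$s)

#' Convert the angular unit of a curve
#'
#' Rescales the momentum-transfer grid between inverse angstroms and inverse
#' nanometres using the exact factor 10 (1 nm = 10 A). Intensities are left
#' untouched; conversion is idempotent when the target equals the current
#' unit.
#'
#' @param curve a [scattering_curve()].
#' @param target `"A-1"` or `"nm-1"`.
#' @return The converted curve.
#' @examples
#' crv <- scattering_curve(c(0.1, 0.2), c(1, 0.5))
#' convert_units(crv, "nm-1")$s  # 1, 2
#' @export
convert_units <- function(curve, target = c("A-1", "nm-1")) {
  target <- match.arg(target)
  stopifnot(inherits(curve, "scattering_curve"))
  if (identical(curve$unit, target)) return(curve)
  # exact decimal factor: nm-1 -> A-1 is 0.1
  fac <- if (target == "A-1") 0.1 else 10
  curve$s <- curve$s * fac
  curve$unit <- target
  curve
}

# Internal: coerce a curve to the canonical inverse-angstrom unit.
as_inverse_angstrom <- function(curve) convert_units(curve, "A-1")

# Internal: do two curves share the same grid within relative tolerance?
same_grid <- function(a, b, tol = 1e-6) {
  if (length(a$s) != length(b$s)) return(FALSE)
  scale <- pmax(abs(a$s), abs(b$s), .Machine$double.eps)
  all(abs(a$s - b$s) / scale <= tol)
}

# Internal: stop unless grids match.
check_same_grid <- function(a, b, tol = 1e-6) {
  if (!same_grid(a, b, tol)) stop("grid mismatch between curves", call. = FALSE)
  invisible(TRUE)
}

# Internal: stop unless the curve carries errors.
check_sigma <- function(curve, what = "this operation") {
  if (is.null(curve$sigma)) {
    stop(what, " requires point errors (sigma); none present", call. = FALSE)
  }
  invisible(TRUE)
}
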