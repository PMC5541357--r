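#' Average replicate curves
#'
#' Pointwise inverse-variance weighted mean of replicate measurements on
#' identical grids (gate replicates through [compare_set()] first). The
#' output error is `(sum sigma_k^-2)^(-1/2)`, i.e. `sigma/sqrt(N)` for
#' equal-error replicates.
#'
#' @param curves list of at least 2 [scattering_curve()]s with errors, on
#'   identical grids (1e-6 relative tolerance).
#' @return The averaged [scattering_curve()].
#' @export
average_curves <- function(curves) {
  if (length(curves) < 2L) stop("need at least 2 curves", call. = FALSE)
  ref <- curves[[1L]]
  for (k in seq_along(curves)) {
    check_sigma(curves[[k]], "averaging")
    check_same_grid(ref, curves[[k]])
  }
  w <- vapply(curves, function(cv) 1 / cv$sigma^2, numeric(length(ref$s)))
  iw <- vapply(curves, function(cv) cv$i / cv$sigma^2,
               numeric(length(ref$s)))
  wsum <- rowSums(w)
  scattering_curve(ref$s, rowSums(iw) / wsum, sigma = 1 / sqrt(wsum),
                   unit = ref$unit,
                   meta = list(averaged_from = length(curves)))
}

#' Pointwise curve arithmetic
#'
#' Add, subtract, multiply or divide a curve by another curve (same grid)
#' or by a scalar, with first-order Gaussian error propagation: quadrature
#' for add/subtract, relative-error combination for multiply/divide,
#' plain scaling for scalar multiply/divide.
#'
#' @param a a [scattering_curve()].
#' @param b a [scattering_curve()] on the same grid, or a scalar.
#' @param op one of `"add"`, `"sub"`, `"mul"`, `"div"`.
#' @return The resulting [scattering_curve()].
#' @examples
#' crv <- scattering_curve(c(.1, .2), c(2, 1), sigma = c(.1, .1))
#' arith(crv, 2, "mul")$i
#' @export
arith <- function(a, b, op = c("add", "sub", "mul", "div")) {
  op <- match.arg(op)
  stopifnot(inherits(a, "scattering_curve"))
  if (inherits(b, "scattering_curve")) {
    check_same_grid(a, b)
    if (op == "div" && any(b$i == 0)) {
      stop("division by zero intensity", call. = FALSE)
    }
    i <- switch(op, add = a$i + b$i, sub = a$i - b$i,
                mul = a$i * b$i, div = a$i / b$i)
    sigma <- NULL
    if (!is.null(a$sigma) || !is.null(b$sigma)) {
      va <- if (is.null(a$sigma)) 0 else a$sigma^2
      vb <- if (is.null(b$sigma)) 0 else b$sigma^2
      sigma <- switch(op,
        add = sqrt(va + vb),
        sub = sqrt(va + vb),
        mul = sqrt(vb * a$i^2 + va * b$i^2),
        div = sqrt(va / b$i^2 + vb * a$i^2 / b$i^4))
    }
  } else {
    b <- as.numeric(b)
    stopifnot(length(b) == 1L)
    if (op == "div" && b == 0) stop("division by zero", call. = FALSE)
    i <- switch(op, add = a$i + b, sub = a$i - b, mul = a$i * b, div = a$i / b)
    sigma <- if (!is.null(a$sigma)) {
      switch(op, add = a$sigma, sub = a$sigma,
             mul = a$sigma * abs(b), div = a$sigma / abs(b))
    }
  }
  if (!is.null(sigma)) sigma <- pmax(sigma, .Machine$double.xmin)
  scattering_curve(a$s, i, sigma = sigma, unit = a$unit, meta = a$meta)
}

#' Scale (and optionally shift) one curve onto another
#'
#' Finds `(factor, shift)` minimizing the weighted squared difference
#' `sum w (factor * I_target + shift - I_reference)^2` over a common s
#' range, with `w = 1/sigma_reference^2` when the reference carries errors.
#' Used to match data sets measured under different conditions.
#'
#' @param target curve to be scaled.
#' @param reference curve to match.
#' @param range length-2 numeric `c(smin, smax)` fit interval; default full
#'   overlap.
#' @param allow_shift if `FALSE` (default) the additive constant is fixed
#'   at 0.
#' @return List of class `scale_shift`: `factor`, `shift`, `fit_range`,
#'   `n_points`.
#' @export
scale_shift_match <- function(target, reference, range = NULL,
                              allow_shift = FALSE) {
  check_same_grid(target, reference)
  if (is.null(range)) range <- c(max(min(target$s), min(reference$s)),
                                 min(max(target$s), max(reference$s)))
  sel <- which(target$s >= range[1L] & target$s <= range[2L])
  if (length(sel) < 5L) stop("insufficient overlap: need >= 5 common points",
                             call. = FALSE)
  x <- target$i[sel]; y <- reference$i[sel]
  w <- if (!is.null(reference$sigma)) 1 / reference$sigma[sel]^2 else
    rep(1, length(sel))
  if (allow_shift) {
    sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
    sxx <- sum(w * x^2); sxy <- sum(w * x * y)
    den <- sw * sxx - sx^2
    factor <- (sw * sxy - sx * sy) / den
    shift <- (sy - factor * sx) / sw
  } else {
    factor <- sum(w * x * y) / sum(w * x^2)
    shift <- 0
  }
  if (!is.finite(factor) || factor <= 0) {
    stop("degenerate scaling fit (non-positive factor)", call. = FALSE)
  }
  structure(list(factor = factor, shift = shift, fit_range = range,
                 n_points = length(sel)),
            class = "scale_shift")
}

# Internal: apply a scale_shift to a curve.
apply_scale_shift <- function(curve, ss) {
  out <- arith(curve, ss$factor, "mul")
  if (ss$shift != 0) out <- arith(out, ss$shift, "add")
  out
}

#' Merge low- and high-concentration curves
#'
#' Scales the high-concentration curve onto the low-concentration curve
#' over the overlap of the two keep intervals (shift disabled) and stitches
#' at the overlap midpoint: the merged curve takes the low-concentration
#' points below the midpoint (where interparticle effects are relevant) and
#' the scaled high-concentration points above it. Per-point provenance is
#' returned.
#'
#' @param low low-concentration curve (trusted at low angles).
#' @param high high-concentration curve (better statistics at high angles).
#' @param low_keep,high_keep length-2 `c(smin, smax)` intervals of each
#'   curve to use; they must overlap.
#' @return List of class `merge_result`: `merged` curve, `overlap`
#'   interval, `scale_applied`, and `source_map` (`"low"`/`"high"` per
#'   merged point).
#' @export
merge_ranges <- function(low, high,
                         low_keep = range(low$s), high_keep = range(high$s)) {
  ov <- c(max(low_keep[1L], high_keep[1L], min(low$s), min(high$s)),
          min(low_keep[2L], high_keep[2L], max(low$s), max(high$s)))
  if (ov[1L] >= ov[2L]) stop("no overlap between keep intervals",
                             call. = FALSE)
  # match the high curve to the low curve over the overlap; interpolate the
  # low curve onto the high grid there if the grids differ
  hi_sel <- which(high$s >= ov[1L] & high$s <= ov[2L])
  if (length(hi_sel) < 5L) stop("no overlap: fewer than 5 common points",
                                call. = FALSE)
  low_on_high <- scattering_curve(
    high$s[hi_sel],
    stats::approx(low$s, low$i, xout = high$s[hi_sel])$y,
    sigma = if (!is.null(low$sigma))
      stats::approx(low$s, low$sigma, xout = high$s[hi_sel])$y,
    unit = low$unit)
  hi_piece <- scattering_curve(high$s[hi_sel], high$i[hi_sel],
                               sigma = high$sigma[hi_sel], unit = high$unit)
  ss <- scale_shift_match(hi_piece, low_on_high, allow_shift = FALSE)
  high_scaled <- apply_scale_shift(high, ss)
  mid <- mean(ov)
  keep_lo <- which(low$s >= low_keep[1L] & low$s <= mid)
  keep_hi <- which(high$s > mid & high$s <= high_keep[2L])
  s <- c(low$s[keep_lo], high_scaled$s[keep_hi])
  i <- c(low$i[keep_lo], high_scaled$i[keep_hi])
  sg <- if (!is.null(low$sigma) && !is.null(high$sigma)) {
    c(low$sigma[keep_lo], high_scaled$sigma[keep_hi])
  }
  src <- c(rep("low", length(keep_lo)), rep("high", length(keep_hi)))
  o <- order(s)
  merged <- scattering_curve(s[o], i[o], sigma = sg[o], unit = low$unit,
                             meta = list(merged = TRUE,
                                         scale_applied = ss$factor))
  structure(list(merged = merged, overlap = ov, scale_applied = ss$factor,
                 source_map = src[o]),
            class = "merge_result")
}

#' Extrapolate a concentration series to infinite dilution
#'
#' For every s point, the concentration-normalized intensities `I(s, c)/c`
#' are regressed on `c` by weighted linear least squares and the intercept
#' at `c = 0` is returned with its standard error (from the known-error
#' parameter covariance when sigmas are present). Removes linear
#' interparticle-interference effects from a dilution series.
#'
#' @param curves list of [scattering_curve()]s on a common grid; each must
#'   have `meta$concentration` (mg/ml) unless `concentrations` is given.
#' @param concentrations optional numeric vector overriding the metadata.
#' @return The zero-concentration [scattering_curve()] (on the `I/c`
#'   scale).
#' @export
extrapolate_zero_concentration <- function(curves, concentrations = NULL) {
  k <- length(curves)
  if (k < 2L) stop("need at least 2 concentrations", call. = FALSE)
  if (is.null(concentrations)) {
    concentrations <- vapply(curves, function(cv) {
      cc <- cv$meta$concentration
      if (is.null(cc)) NA_real_ else as.numeric(cc)
    }, numeric(1))
  }
  if (anyNA(concentrations)) stop("missing concentrations", call. = FALSE)
  if (length(unique(concentrations)) < 2L) {
    stop("need at least 2 distinct concentrations", call. = FALSE)
  }
  ref <- curves[[1L]]
  for (j in 2:k) check_same_grid(ref, curves[[j]])
  n <- length(ref$s)
  Y <- vapply(seq_len(k), function(j) curves[[j]]$i / concentrations[j],
              numeric(n))
  has_sigma <- all(!vapply(curves, function(cv) is.null(cv$sigma),
                           logical(1)))
  W <- if (has_sigma) {
    vapply(seq_len(k), function(j)
      (concentrations[j] / curves[[j]]$sigma)^2, numeric(n))
  } else {
    matrix(1, n, k)
  }
  cvec <- concentrations
  sw <- W %*% rep(1, k)
  sc <- W %*% cvec
  scc <- W %*% cvec^2
  sy <- rowSums(W * Y)
  scy <- rowSums(W * sweep(Y, 2L, cvec, `*`))
  den <- sw * scc - sc^2
  intercept <- (scc * sy - sc * scy) / den
  # Var(intercept) = scc / den for known per-point weights 1/sigma_y^2
  sig <- if (has_sigma) sqrt(scc / den) else NULL
  scattering_curve(ref$s, as.numeric(intercept), sigma = as.numeric(sig),
                   unit = ref$unit,
                   meta = list(extrapolated_from = k))
}

#' Crop a curve to an angular interval
#'
#' Retains points with `smin <= s <= smax` (closed interval) and notes the
#' crop in the metadata.
#'
#' @param curve a [scattering_curve()].
#' @param smin,smax interval bounds, `smin < smax`.
#' @return The cropped curve.
#' @export
crop <- function(curve, smin = -Inf, smax = Inf) {
  if (smin >= smax) stop("smin must be below smax", call. = FALSE)
  # closed interval with a relative guard against floating-point grids
  eps <- 1e-9 * max(abs(curve$s))
  sel <- which(curve$s >= smin - eps & curve$s <= smax + eps)
  if (length(sel) < 2L) stop("crop leaves fewer than 2 points",
                             call. = FALSE)
  meta <- curve$meta
  meta$crop <- c(smin = max(smin, curve$s[1L]),
                 smax = min(smax, curve$s[length(curve$s)]))
  scattering_curve(curve$s[sel], curve$i[sel], sigma = curve$sigma[sel],
                   unit = curve$unit, meta = meta)
}

#' Rebin or regrid a curve
#'
#' Two modes: `"bin-by-k"` averages consecutive groups of `k` points
#' (arithmetic mean of s, inverse-variance mean of I, combined sigma);
#' `"template-grid"` linearly interpolates I and sigma onto the s values of
#' a template curve, refusing to extrapolate.
#'
#' @param curve a [scattering_curve()].
#' @param mode `"bin-by-k"` or `"template-grid"`.
#' @param param the bin size `k >= 2`, or the template
#'   [scattering_curve()] (or numeric s vector).
#' @return The regridded curve.
#' @export
regrid <- function(curve, mode = c("bin-by-k", "template-grid"), param) {
  mode <- match.arg(mode)
  if (mode == "bin-by-k") {
    k <- as.integer(param)
    if (k < 2L) stop("bin size must be >= 2", call. = FALSE)
    n <- length(curve$s)
    grp <- (seq_len(n) - 1L) %/% k
    full <- grp < n %/% k  # drop a trailing partial bin
    grp <- grp[full]
    s <- as.numeric(tapply(curve$s[full], grp, mean))
    if (!is.null(curve$sigma)) {
      w <- 1 / curve$sigma[full]^2
      wsum <- as.numeric(tapply(w, grp, sum))
      i <- as.numeric(tapply(w * curve$i[full], grp, sum)) / wsum
      sg <- 1 / sqrt(wsum)
    } else {
      i <- as.numeric(tapply(curve$i[full], grp, mean))
      sg <- NULL
    }
    scattering_curve(s, i, sigma = sg, unit = curve$unit, meta = curve$meta)
  } else {
    s_new <- if (inherits(param, "scattering_curve")) param$s else
      as.numeric(param)
    if (min(s_new) < min(curve$s) || max(s_new) > max(curve$s)) {
      stop("template grid outside curve support", call. = FALSE)
    }
    i <- stats::approx(curve$s, curve$i, xout = s_new)$y
    sg <- if (!is.null(curve$sigma))
      stats::approx(curve$s, curve$sigma, xout = s_new)$y
    scattering_curve(s_new, i, sigma = sg, unit = curve$unit,
                     meta = curve$meta)
  }
}

#' Calibrate a curve to absolute scale using water scattering
#'
#' The flat scattering of pure water has a known absolute level
#' (0.01632 cm^-1 at 20 C); dividing it into the measured
#' water-minus-empty-cell plateau gives the conversion factor to cm^-1.
#'
#' @param sample curve to calibrate.
#' @param water_minus_empty background-subtracted water measurement.
#' @param water_constant absolute water level in cm^-1 (temperature
#'   dependent; default 0.01632 for 20 C).
#' @param plateau_range length-2 s interval over which the water signal is
#'   averaged; must lie within the water curve's support.
#' @return The calibrated curve (intensity unit recorded as cm^-1 in the
#'   metadata).
#' @export
to_absolute_scale <- function(sample, water_minus_empty,
                              water_constant = 0.01632,
                              plateau_range) {
  if (plateau_range[1L] < min(water_minus_empty$s) ||
      plateau_range[2L] > max(water_minus_empty$s)) {
    stop("plateau range outside water curve support", call. = FALSE)
  }
  sel <- water_minus_empty$s >= plateau_range[1L] &
    water_minus_empty$s <= plateau_range[2L]
  plateau <- mean(water_minus_empty$i[sel])
  if (!is.finite(plateau) || plateau <= 0) {
    stop("non-positive water plateau mean", call. = FALSE)
  }
  factor <- water_constant / plateau
  out <- arith(sample, factor, "mul")
  out$meta$intensity_unit <- "cm-1"
  out$meta$absolute_factor <- factor
  out
}
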