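#' Guinier fit over a fixed interval
#'
#' Weighted linear regression in Guinier coordinates. For globular
#' particles `ln I` is regressed on `s^2` and the slope gives
#' `Rg^2 = -3 * slope`; the rod variant regresses `ln(s I)` (cross-section
#' radius, factor 2) and the sheet variant `ln(s^2 I)` (thickness radius,
#' factor 1). Regression weights are `1/sigma_y^2` with
#' `sigma_y = sigma/I` propagated through the log transform.
#'
#' @param curve a [scattering_curve()].
#' @param interval integer index range `c(first, last)` of the fit window
#'   (at least 5 points).
#' @param geometry `"globular"`, `"rod"` or `"sheet"`.
#' @return List of class `guinier_fit`: `i0` (forward intensity, or the
#'   geometry prefactor for rod/sheet), `rg` (Rg, cross-section Rc or
#'   thickness Rt), `rg_stderr`, `i0_stderr`, `interval`, `geometry`,
#'   `srg_min`, `srg_max`, `quality` (weighted R^2 of the regression).
#' @examples
#' crv <- body_intensity(body("sphere", r = 30), seq(0.005, 0.05, 5e-4))
#' crv$sigma <- 0.01 * crv$i
#' guinier_fit(crv, c(1, length(crv$s)))$rg  # ~ sqrt(3/5) * 30
#' @export
guinier_fit <- function(curve, interval,
                        geometry = c("globular", "rod", "sheet")) {
  geometry <- match.arg(geometry)
  curve <- as_inverse_angstrom(curve)
  sel <- seq.int(interval[1L], interval[2L])
  if (length(sel) < 5L) stop("Guinier interval too short (need >= 5 points)",
                             call. = FALSE)
  s <- curve$s[sel]; i <- curve$i[sel]
  pow <- switch(geometry, globular = 0, rod = 1, sheet = 2)
  it <- s^pow * i
  if (any(it <= 0)) {
    stop("non-positive transformed intensities in the Guinier interval",
         call. = FALSE)
  }
  y <- log(it)
  x <- s^2
  w <- if (!is.null(curve$sigma)) (i / curve$sigma[sel])^2 else
    rep(1, length(sel))
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  slope <- fit$coefficients[2L]; icept <- fit$coefficients[1L]
  k <- switch(geometry, globular = 3, rod = 2, sheet = 1)
  if (!is.finite(slope) || slope >= 0) {
    stop("non-negative Guinier slope: no valid Rg", call. = FALSE)
  }
  rg <- sqrt(-k * slope)
  # parameter covariance for known weights (sigma_y built into w)
  XtX <- crossprod(sqrt(w) * cbind(1, x))
  cv <- tryCatch(solve(XtX), error = function(e) matrix(NA, 2, 2))
  slope_se <- sqrt(cv[2L, 2L]); icept_se <- sqrt(cv[1L, 1L])
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * fit$residuals^2) / sum(w * (y - ybar)^2)
  structure(list(
    i0 = exp(icept), rg = rg,
    rg_stderr = k * slope_se / (2 * rg),
    i0_stderr = exp(icept) * icept_se,
    interval = c(interval[1L], interval[2L]),
    geometry = geometry,
    srg_min = s[1L] * rg, srg_max = s[length(s)] * rg,
    quality = max(0, min(1, r2))),
    class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  lbl <- switch(x$geometry, globular = "Rg", rod = "Rc", sheet = "Rt")
  cat(sprintf(
    "Guinier fit (%s): %s = %.3f +/- %.3f A, I0 = %.4g +/- %.2g\n",
    x$geometry, lbl, x$rg, x$rg_stderr, x$i0, x$i0_stderr))
  cat(sprintf("  interval [%d, %d], s*%s in [%.3f, %.3f], quality %.3f\n",
              x$interval[1L], x$interval[2L], lbl, x$srg_min, x$srg_max,
              x$quality))
  invisible(x)
}

#' Automatic Guinier interval selection
#'
#' Scans every candidate window of at least `min_window` points whose
#' self-consistent upper bound satisfies `s_max * Rg <= cap`, scores each
#' window, and returns the fit of the best one. The quality score is a
#' weighted geometric mean of four terms in `[0, 1]`: the weighted
#' regression R^2 (weight 0.4), the window's fraction of the allowed range
#' (0.3), the closeness of its `s * Rg` upper bound to the cap (0.2) and a
#' penalty for discarding low-angle points (0.1). Ties break toward the
#' earliest-starting window, making the selection deterministic.
#'
#' @param curve a [scattering_curve()] with errors and at least 20 points.
#' @param geometry currently only `"globular"` windows are scanned.
#' @param cap maximum allowed `s * Rg` (default 1.3, standard practice for
#'   globular particles).
#' @param min_window minimum window length in points.
#' @return A `guinier_fit` (see [guinier_fit()]) for the selected window,
#'   with the quality score of the window search.
#' @export
autorg <- function(curve, geometry = "globular", cap = 1.3,
                   min_window = 5L) {
  geometry <- match.arg(geometry, "globular")
  curve <- as_inverse_angstrom(curve)
  check_sigma(curve, "autorg")
  n <- length(curve$s)
  if (n < 20L) stop("autorg needs at least 20 points", call. = FALSE)
  # usable leading stretch of positive intensities
  pos <- curve$i > 0
  lead <- if (all(pos)) n else which(!pos)[1L] - 1L
  if (lead < min_window) stop("no valid Guinier region", call. = FALSE)
  # rough Rg from the first points to bound the scan region
  rough_end <- min(lead, 20L)
  rough <- tryCatch(
    guinier_fit(curve, c(1L, rough_end), "globular"),
    error = function(e) NULL)
  s_hi <- if (!is.null(rough)) 2.0 * cap / rough$rg else curve$s[lead]
  idx_max <- max(which(curve$s <= s_hi & seq_len(n) <= lead))
  if (idx_max < min_window) idx_max <- min(lead, 25L)

  s <- curve$s[seq_len(idx_max)]
  y <- log(curve$i[seq_len(idx_max)])
  x <- s^2
  w <- (curve$i[seq_len(idx_max)] / curve$sigma[seq_len(idx_max)])^2
  # cumulative sums for O(1) weighted regression on any window
  c0 <- c(0, cumsum(w)); c1 <- c(0, cumsum(w * x)); c2 <- c(0, cumsum(w * x^2))
  cy <- c(0, cumsum(w * y)); cxy <- c(0, cumsum(w * x * y))
  cyy <- c(0, cumsum(w * y^2))
  starts <- rep(seq_len(idx_max - min_window + 1L),
                times = idx_max - min_window + 2L -
                  seq_len(idx_max - min_window + 1L) - 0L)
  ends <- unlist(lapply(seq_len(idx_max - min_window + 1L),
                        function(a) (a + min_window - 1L):idx_max))
  sw <- c0[ends + 1L] - c0[starts]
  sx <- c1[ends + 1L] - c1[starts]
  sxx <- c2[ends + 1L] - c2[starts]
  sy <- cy[ends + 1L] - cy[starts]
  sxy <- cxy[ends + 1L] - cxy[starts]
  syy <- cyy[ends + 1L] - cyy[starts]
  den <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / den
  ok <- is.finite(slope) & slope < 0
  rg <- sqrt(pmax(-3 * slope, 0))
  srg_hi <- s[ends] * rg
  ok <- ok & srg_hi <= cap
  if (!any(ok)) stop("no valid Guinier region", call. = FALSE)
  icept <- (sy - slope * sx) / sw
  ss_res <- syy - 2 * icept * sy - 2 * slope * sxy + icept^2 * sw +
    2 * icept * slope * sx + slope^2 * sxx
  ss_tot <- syy - sy^2 / sw
  r2 <- pmax(0, pmin(1, 1 - ss_res / pmax(ss_tot, .Machine$double.eps)))
  # allowed range per window: points from the start of the curve up to the
  # last index satisfying the cap for this window's Rg
  n_allowed <- vapply(seq_along(rg), function(j) {
    if (!ok[j]) return(NA_integer_)
    sum(s * rg[j] <= cap)
  }, integer(1))
  frac_len <- (ends - starts + 1L) / pmax(n_allowed, min_window)
  cap_close <- srg_hi / cap
  start_pen <- 1 - (starts - 1L) / pmax(n_allowed, 1L)
  q <- r2^0.4 * pmin(1, frac_len)^0.3 * pmin(1, cap_close)^0.2 *
    pmax(0, pmin(1, start_pen))^0.1
  q[!ok] <- -Inf
  best <- which(q == max(q))
  best <- best[order(starts[best])][1L]
  fit <- guinier_fit(curve, c(starts[best], ends[best]), "globular")
  fit$quality <- max(0, min(1, q[best]))
  fit
}
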