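#' Regularized indirect Fourier transform
#'
#' Recovers the pair-distance distribution `p(r)` on a uniform grid
#' `[0, dmax]` from a noisy intensity curve by minimizing
#' `chi2(fit) + alpha * Omega(p)`, where the fit is the forward transform
#' `I(s) = 4 pi integral p(r) sin(sr)/(sr) dr` (trapezoid quadrature) and
#' `Omega` is the squared-first-difference smoothness functional
#' (squared second differences by option). End constraints
#' `p(0) = p(dmax) = 0` are enforced by default. For `alpha = "auto"` the
#' regularization weight maximizes the perceptual total estimate (see
#' [criteria_scores()]) by golden-section search on `log10(alpha)`.
#'
#' @param curve a [scattering_curve()] with errors.
#' @param dmax assumed maximum particle dimension (angstroms).
#' @param alpha regularization weight, or `"auto"`.
#' @param npts number of r-grid points (default 101).
#' @param force_zero_start,force_zero_end enforce `p(0) = 0` /
#'   `p(dmax) = 0`.
#' @param smoothness `"first"` or `"second"` differences.
#' @param alpha_range log10 search bracket for automatic alpha.
#' @param alpha_tol golden-section tolerance in decades.
#' @return Object of class `ift_solution`: `pr` (list `r`, `p`, `perr`,
#'   `dmax`), `fit` and `data` curves, `alpha`, `chi2_reduced`,
#'   `criteria`, `total`, `rg`, `i0`.
#' @examples
#' crv <- simulate_curve(body("sphere", r = 30), seq(0.008, 0.35, 0.002),
#'                       noise_model(0.01, seed = 2))
#' sol <- ift_solve(crv, dmax = 60)
#' @export
ift_solve <- function(curve, dmax, alpha = "auto", npts = 101L,
                      force_zero_start = TRUE, force_zero_end = TRUE,
                      smoothness = c("first", "second"),
                      alpha_range = c(-8, 4), alpha_tol = 0.01) {
  smoothness <- match.arg(smoothness)
  curve <- as_inverse_angstrom(curve)
  check_sigma(curve, "indirect Fourier transform")
  if (dmax <= 0) stop("dmax must be positive", call. = FALSE)
  npts <- as.integer(npts)
  if (npts < 20L) stop("npts must be at least 20", call. = FALSE)

  ker <- ift_kernel(curve$s, dmax, npts)
  free <- seq_len(npts)
  if (force_zero_start) free <- setdiff(free, 1L)
  if (force_zero_end) free <- setdiff(free, npts)
  prep <- ift_prepare(ker$A, curve, free, smoothness, npts)

  solve_at <- function(a) ift_solve_alpha(prep, ker, curve, a, free, npts)

  if (identical(alpha, "auto")) {
    score <- function(la) {
      sol <- solve_at(10^la)
      cs <- criteria_scores_internal(sol, solve_at)
      cs$total
    }
    # the total estimate need not be unimodal in alpha: locate the global
    # ridge on a coarse log grid first, then refine by golden section
    grid <- seq(alpha_range[1L], alpha_range[2L], by = 0.5)
    vals <- vapply(grid, score, numeric(1))
    k <- which.max(vals)
    lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
    la <- golden_max(score, lo, hi, tol = alpha_tol)
    alpha <- 10^la
  }
  sol <- solve_at(alpha)
  cs <- criteria_scores_internal(sol, solve_at)
  sol$criteria <- cs$criteria
  sol$total <- cs$total
  sol
}

# Forward-transform kernel: A[i, j] = 4 pi w_j sinc(s_i r_j) with trapezoid
# weights w_j on the uniform r grid.
ift_kernel <- function(s, dmax, npts) {
  r <- seq(0, dmax, length.out = npts)
  h <- r[2L] - r[1L]
  w <- rep(h, npts); w[c(1L, npts)] <- h / 2
  A <- 4 * pi * outer(s, r, function(sv, rv) sinc(sv * rv)) *
    rep(w, each = length(s))
  list(A = A, r = r, h = h)
}

# Precompute the normal-equation blocks that do not depend on alpha.
ift_prepare <- function(A, curve, free, smoothness, npts) {
  W <- 1 / curve$sigma^2
  Af <- A[, free, drop = FALSE]
  D <- diff(diag(npts), differences = if (smoothness == "first") 1L else 2L)
  Om <- crossprod(D)[free, free, drop = FALSE]
  AtWA <- crossprod(Af * sqrt(W))
  AtWy <- crossprod(Af, W * curve$i)
  # characteristic scales to make alpha dimensionless-ish across problems
  sc <- mean(diag(AtWA)) / max(mean(diag(Om)), .Machine$double.eps)
  list(AtWA = AtWA, AtWy = AtWy, Om = Om, W = W, alpha_scale = sc)
}

# Solve the regularized linear system at a given alpha and package the
# solution.
ift_solve_alpha <- function(prep, ker, curve, alpha, free, npts) {
  M <- prep$AtWA + alpha * prep$alpha_scale * prep$Om
  p_free <- tryCatch(solve(M, prep$AtWy), error = function(e) {
    stop("singular regularized system (npts too large for data support)",
         call. = FALSE)
  })
  p <- numeric(npts)
  p[free] <- p_free
  fit_i <- as.numeric(ker$A %*% p)
  n <- length(curve$s)
  chi2 <- sum((curve$i - fit_i)^2 * prep$W) / n
  # error propagation through the regularized inverse operator
  Minv <- solve(M)
  cov_free <- Minv %*% prep$AtWA %*% Minv
  perr <- numeric(npts)
  perr[free] <- sqrt(pmax(diag(cov_free), 0))
  pr <- list(r = ker$r, p = p, perr = perr, dmax = ker$r[npts])
  mom <- tryCatch(suppressWarnings(pr_moments(pr)), error = function(e)
    list(rg = NA_real_, i0 = NA_real_))
  structure(list(
    pr = pr,
    fit = scattering_curve(curve$s, fit_i, unit = curve$unit),
    data = curve,
    alpha = alpha, chi2_reduced = chi2,
    criteria = NULL, total = NA_real_,
    rg = mom$rg, i0 = mom$i0),
    class = "ift_solution")
}

#' @export
print.ift_solution <- function(x, ...) {
  cat(sprintf(
    "IFT solution: Dmax = %.2f A, Rg = %.3f A, I0 = %.4g, alpha = %.3g\n",
    x$pr$dmax, x$rg, x$i0, x$alpha))
  cat(sprintf("  chi2_red = %.3f, total estimate = %.3f\n",
              x$chi2_reduced, x$total))
  if (!is.null(x$criteria)) {
    cat("  criteria:", paste(names(x$criteria),
                             sprintf("%.3f", unlist(x$criteria)),
                             sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

# Internal criteria computation; solve_at re-solves at perturbed alpha for
# the stability score.
criteria_scores_internal <- function(sol, solve_at) {
  p <- sol$pr$p; r <- sol$pr$r
  discrp <- exp(-abs(sol$chi2_reduced - 1))
  # oscillation: arc length of the normalized p relative to a single-node
  # half-period sine reference
  pmax_abs <- max(abs(p))
  if (pmax_abs == 0) {
    oscill <- 1
  } else {
    rn <- r / sol$pr$dmax
    pn <- p / pmax_abs
    arclen <- function(y) sum(sqrt(diff(rn)^2 + diff(y)^2))
    osc <- arclen(pn) / arclen(sin(pi * rn))
    oscill <- max(0, min(1, 1 / osc))
  }
  # stability under +/-10% alpha perturbation
  stabil <- tryCatch({
    p_hi <- solve_at(sol$alpha * 1.1)$pr$p
    p_lo <- solve_at(sol$alpha * 0.9)$pr$p
    nrm <- sqrt(sum(p^2))
    if (nrm == 0) 1 else
      max(0, min(1, 1 - sqrt(sum((p_hi - p_lo)^2)) / nrm))
  }, error = function(e) 0)
  # systematic deviations: longest-run probability of the fit residuals
  res <- sol$data$i - sol$fit$i
  n <- length(res)
  runC <- max(rle(ifelse(res >= 0, 1L, -1L))$lengths)
  sysdev <- longest_run_pvalue(n, runC)
  # positivity: positive fraction of the absolute area
  tot_abs <- pracma::trapz(r, abs(p))
  positv <- if (tot_abs == 0) 1 else
    pracma::trapz(r, pmax(p, 0)) / tot_abs
  # centrality: fraction of |p| mass in the central 80% of [0, dmax]
  lo <- 0.1 * sol$pr$dmax; hi <- 0.9 * sol$pr$dmax
  inside <- r >= lo & r <= hi
  valcen <- if (tot_abs == 0) 1 else
    pracma::trapz(r[inside], abs(p[inside])) / tot_abs
  criteria <- list(DISCRP = discrp, OSCILL = oscill, STABIL = stabil,
                   SYSDEV = sysdev, POSITV = positv, VALCEN = valcen)
  list(criteria = criteria, total = mean(unlist(criteria)))
}

#' Perceptual quality criteria of an IFT solution
#'
#' Six named scores in `[0, 1]` assessing a regularized p(r) solution, plus
#' their equal-weight mean (the "total estimate"): DISCRP (closeness of the
#' fit chi2 to 1), OSCILL (smoothness: inverse arc-length ratio of p to a
#' single-node sine), STABIL (insensitivity to a 10% alpha perturbation),
#' SYSDEV (longest-run probability of the residual signs), POSITV (positive
#' fraction of the absolute area) and VALCEN (fraction of mass in the
#' central 80% of `[0, dmax]`). The score definitions are this package's
#' own; the names follow long-standing IFT practice.
#'
#' @param solution an `ift_solution` from [ift_solve()].
#' @return List with `criteria` (named list) and `total`.
#' @export
criteria_scores <- function(solution) {
  stopifnot(inherits(solution, "ift_solution"))
  if (!is.null(solution$criteria)) {
    return(list(criteria = solution$criteria, total = solution$total))
  }
  # rebuild the solver context to evaluate the stability criterion
  curve <- solution$data
  npts <- length(solution$pr$r)
  ker <- ift_kernel(curve$s, solution$pr$dmax, npts)
  free <- which(!(seq_len(npts) %in%
                    c(1L, npts)[c(solution$pr$p[1L] == 0,
                                  solution$pr$p[npts] == 0)]))
  prep <- ift_prepare(ker$A, curve, free, "first", npts)
  solve_at <- function(a) ift_solve_alpha(prep, ker, curve, a, free, npts)
  criteria_scores_internal(solution, solve_at)
}

#' Moments of a distance distribution
#'
#' `I(0) = 4 pi integral p(r) dr` and
#' `Rg^2 = integral r^2 p(r) dr / (2 integral p(r) dr)`, by trapezoidal
#' quadrature.
#'
#' @param pr list with `r` and `p` (e.g. the `pr` element of an
#'   `ift_solution`).
#' @return List with `rg` and `i0`.
#' @examples
#' r <- seq(0, 60, length.out = 301)
#' p <- sphere_pr(r, 30)
#' pr_moments(list(r = r, p = p))$rg  # sqrt(3/5) * 30
#' @export
pr_moments <- function(pr) {
  s0 <- pracma::trapz(pr$r, pr$p)
  if (s0 <= 0) stop("non-positive integral of p(r)", call. = FALSE)
  s2 <- pracma::trapz(pr$r, pr$r^2 * pr$p)
  list(rg = sqrt(s2 / (2 * s0)), i0 = 4 * pi * s0)
}

#' Analytic distance distribution of a uniform sphere
#'
#' `p(r)` proportional to `r^2 (1 - 3r/(4R) + r^3/(16 R^3))` for
#' `0 <= r <= 2R`, normalized here so that the forward transform yields
#' `I(0) = (4/3 pi R^3)^2` (unit contrast).
#'
#' @param r distances (angstroms).
#' @param radius sphere radius R.
#' @return `p(r)` values (0 beyond `2R`).
#' @export
sphere_pr <- function(r, radius) {
  x <- r / (2 * radius)
  p <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
  p[r > 2 * radius | r < 0] <- 0
  # normalize: integral p dr = V^2 (contrast 1) / (4 pi)
  v <- 4 / 3 * pi * radius^3
  p * (v^2 / (4 * pi)) / ((2 * radius)^3 / 24)
}

# Truncation diagnostics of an IFT solution: normalized magnitude of the
# p(r) slope at the outer end, and the fraction of |p| mass beyond
# 0.9 dmax. A solution truncated below the true particle dimension is
# forced to cut its distance distribution off steeply; one solved beyond
# it decays to zero early.
ift_end_slope <- function(sol) {
  p <- sol$pr$p; r <- sol$pr$r; n <- length(r)
  abs(p[n - 1L] - p[n]) / (r[2L] - r[1L]) * sol$pr$dmax / max(abs(p))
}

ift_tail_fraction <- function(sol) {
  p <- abs(sol$pr$p); r <- sol$pr$r
  sum(p[r > 0.9 * sol$pr$dmax]) / sum(p)
}

#' Automatic maximum-dimension search
#'
#' Determines the particle's maximum dimension by scanning
#' `dmax in [2 Rg, 4 Rg]` (Rg from [autorg()]) and applying three
#' truncation diagnostics to the regularized solutions: (a) feasibility --
#' below the true dimension the fit cannot reproduce the data and its chi2
#' rises sharply above the bracket-wide floor; (b) the distance
#' distribution must not be cut off steeply at the end (normalized end
#' slope at most `slope_max`); (c) at most `tail_max` of the |p| mass may
#' sit beyond `0.9 dmax`. The smallest dmax passing all three, sharpened
#' by bisection, is returned; when no candidate passes the shape
#' diagnostics the feasible solution with the best perceptual total
#' estimate is used instead.
#'
#' @param curve a [scattering_curve()] with errors.
#' @param npts r-grid size passed to [ift_solve()].
#' @param n_grid number of dmax candidates in the bracket.
#' @param slope_max end-slope acceptance threshold.
#' @param tail_max outer-tail mass acceptance threshold.
#' @param alpha_tol alpha-search tolerance (decades) used during the scan.
#' @return The `ift_solution` at the selected dmax.
#' @export
auto_dmax <- function(curve, npts = 101L, n_grid = 25L, slope_max = 1,
                      tail_max = 0.01, alpha_tol = 0.05) {
  gf <- autorg(curve)
  lo <- 2 * gf$rg; hi <- 4 * gf$rg
  dgrid <- seq(lo, hi, length.out = n_grid)
  sols <- lapply(dgrid, function(D)
    ift_solve(curve, D, alpha = "auto", npts = npts, alpha_tol = alpha_tol))
  chi2 <- vapply(sols, function(s) s$chi2_reduced, numeric(1))
  thr <- 1.5 * min(chi2) + 0.3
  ok_sol <- function(sol) {
    sol$chi2_reduced <= thr && ift_end_slope(sol) <= slope_max &&
      ift_tail_fraction(sol) <= tail_max
  }
  ok <- vapply(sols, ok_sol, logical(1))
  if (!any(ok)) {
    # no candidate passes the shape diagnostics: fall back to the best
    # total estimate among the feasible fits
    feas <- which(chi2 <= thr)
    if (!length(feas)) feas <- which.min(chi2)
    tot <- vapply(sols[feas], function(s) s$total, numeric(1))
    return(sols[[feas[which.max(tot)]]])
  }
  k <- which(ok)[1L]
  best <- sols[[k]]
  if (k > 1L) {
    dlo <- dgrid[k - 1L]; dhi <- dgrid[k]
    for (it in 1:3) {
      dm <- (dlo + dhi) / 2
      sm <- ift_solve(curve, dm, alpha = "auto", npts = npts,
                      alpha_tol = alpha_tol)
      if (ok_sol(sm)) {
        dhi <- dm; best <- sm
      } else {
        dlo <- dm
      }
    }
  }
  best
}

#' Size distribution of polydisperse spheres
#'
#' Regularized non-negative inversion of
#' `I(s) = sum_j Dv(R_j) V(R_j) Phi^2(s R_j) dR` on a radius grid, with the
#' same first-difference smoothness functional as [ift_solve()] and
#' non-negativity enforced by active-set non-negative least squares.
#' `alpha = "auto"` applies the discrepancy principle: the largest weight
#' whose fit quality stays within a fixed margin of the unregularized
#' optimum.
#'
#' @param curve a [scattering_curve()] with errors.
#' @param rmin,rmax radius range (angstroms), `0 < rmin < rmax`.
#' @param nbins number of radius bins.
#' @param alpha regularization weight or `"auto"`.
#' @return Object of class `size_distribution`: `radii`, `dv`
#'   (volume-weighted distribution), `kernel = "sphere"`, `fit`, `alpha`,
#'   `chi2_reduced`.
#' @export
size_distribution_solve <- function(curve, rmin, rmax, nbins = 50L,
                                    alpha = "auto") {
  curve <- as_inverse_angstrom(curve)
  check_sigma(curve, "size distribution inversion")
  if (!(rmin > 0 && rmax > rmin)) stop("need 0 < rmin < rmax", call. = FALSE)
  radii <- seq(rmin, rmax, length.out = nbins)
  dr <- radii[2L] - radii[1L]
  V <- 4 / 3 * pi * radii^3
  K <- outer(curve$s, seq_len(nbins), function(sv, j)
    sphere_amplitude(sv * radii[j])^2) *
    rep(V * dr, each = length(curve$s))
  W <- 1 / curve$sigma
  Kw <- K * W
  yw <- curve$i * W
  D <- diff(diag(nbins))
  sc <- mean(diag(crossprod(Kw))) / mean(diag(crossprod(D)))
  n <- length(curve$s)
  solve_at <- function(a) {
    Aug <- rbind(Kw, sqrt(a * sc) * D)
    rhs <- c(yw, numeric(nrow(D)))
    x <- nnls_fit(Aug, rhs)$x
    fit_i <- as.numeric(K %*% x)
    chi2 <- sum(((curve$i - fit_i) * W)^2) / n
    list(x = x, fit = fit_i, chi2 = chi2)
  }
  if (identical(alpha, "auto")) {
    # discrepancy principle: the largest alpha whose fit quality stays
    # within a fixed margin of the unregularized optimum, found by
    # bisection on log10(alpha) (chi2 is monotone in alpha)
    chi2_min <- solve_at(10^-8)$chi2
    thr <- 1.3 * chi2_min + 0.2
    llo <- -8; lhi <- 4
    if (solve_at(10^lhi)$chi2 <= thr) {
      llo <- lhi
    } else {
      for (it in 1:20) {
        lm <- (llo + lhi) / 2
        if (solve_at(10^lm)$chi2 <= thr) llo <- lm else lhi <- lm
      }
    }
    alpha <- 10^llo
  }
  solx <- solve_at(alpha)
  structure(list(radii = radii, dv = solx$x, kernel = "sphere",
                 fit = scattering_curve(curve$s, solx$fit,
                                        unit = curve$unit),
                 alpha = alpha, chi2_reduced = solx$chi2),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  mode_r <- x$radii[which.max(x$dv)]
  cat(sprintf(
    "size distribution (sphere kernel): %d bins on [%.1f, %.1f] A, mode %.1f A, chi2_red %.3f\n",
    length(x$radii), min(x$radii), max(x$radii), mode_r, x$chi2_reduced))
  invisible(x)
}

# Golden-section maximization on [a, b] to tolerance tol.
golden_max <- function(f, a, b, tol = 0.01) {
  phi <- (sqrt(5) - 1) / 2
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    }
  }
  (a + b) / 2
}
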