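#' Multicomponent mixture model
#'
#' A linear mixture of up to ten scattering components — geometric
#' [body()]s or tabulated form-factor curves — with non-negative volume
#' fractions, optional per-component size dispersion and an optional
#' hard-sphere structure factor applied to the total (decoupling
#' approximation).
#'
#' @param components list of [body()]s or [scattering_curve()]s.
#' @param fractions non-negative volume fractions, one per component
#'   (normalized to sum 1 when `normalize = TRUE`).
#' @param dispersion optional list (one element per component) of
#'   `list(type = "gaussian"|"lognormal", width = ...)` or `NULL`; the
#'   dispersion applies to the component's designated size parameter (the
#'   first dimension parameter of the body kind). Width is the standard
#'   deviation in angstroms (gaussian) or the log-standard-deviation
#'   (lognormal).
#' @param structure_factor `NULL`, or
#'   `list(type = "hard_sphere", eta = ..., r_hs = ...)`.
#' @param normalize keep fractions on the unit simplex.
#' @return Object of class `mixture_model`.
#' @export
mixture_model <- function(components, fractions = NULL, dispersion = NULL,
                          structure_factor = NULL, normalize = TRUE) {
  k <- length(components)
  if (k < 1L || k > 10L) {
    stop("component limit: between 1 and 10 components", call. = FALSE)
  }
  if (is.null(fractions)) fractions <- rep(1 / k, k)
  if (length(fractions) != k || any(fractions < 0)) {
    stop("fractions must be non-negative, one per component", call. = FALSE)
  }
  if (normalize) {
    tot <- sum(fractions)
    if (tot <= 0) stop("fractions sum to zero", call. = FALSE)
    fractions <- fractions / tot
  }
  if (!is.null(dispersion) && length(dispersion) != k) {
    stop("dispersion must have one entry per component", call. = FALSE)
  }
  if (!is.null(structure_factor)) {
    stopifnot(identical(structure_factor$type, "hard_sphere"))
  }
  structure(list(components = components, fractions = fractions,
                 dispersion = dispersion,
                 structure_factor = structure_factor,
                 normalize = normalize),
            class = "mixture_model")
}

# Size parameter subject to dispersion, per body kind.
dispersion_param <- function(kind) {
  switch(kind, sphere = "r", core_shell_sphere = "r_shell",
         cylinder = "r", core_shell_cylinder = "r_shell",
         ellipsoid_of_revolution = "r", parallelepiped = "a",
         dumbbell = "r1")
}

# Size-dispersed intensity of one body: quadrature average over the
# distribution of its designated size parameter (Gauss-Hermite for
# gaussian, log-spaced trapezoid for lognormal; 15 nodes default).
dispersed_body_intensity <- function(bd, s, disp, n_nodes = 15L) {
  if (is.null(disp) || is.null(disp$type) || disp$width <= 0) {
    return(body_intensity_raw(bd, s))
  }
  pname <- dispersion_param(bd$kind)
  mu <- bd$params[[pname]]
  eval_at <- function(val) {
    b2 <- bd
    if (pname == "r_shell") {
      # scale core with shell to preserve the shell/core ratio
      b2$params$r_core <- bd$params$r_core * val / mu
    }
    b2$params[[pname]] <- val
    body_intensity_raw(b2, s)
  }
  if (disp$type == "gaussian") {
    gh <- pracma::gaussHermite(n_nodes)
    vals <- mu + sqrt(2) * disp$width * gh$x
    wts <- gh$w / sqrt(pi)
    keep <- vals > 0
    vals <- vals[keep]; wts <- wts[keep] / sum(wts[keep])
  } else if (disp$type == "lognormal") {
    lmu <- log(mu)
    lg <- seq(lmu - 4 * disp$width, lmu + 4 * disp$width,
              length.out = max(n_nodes, 15L))
    dens <- stats::dnorm(lg, lmu, disp$width)
    vals <- exp(lg)
    wts <- dens / sum(dens)
  } else {
    stop("unknown dispersion type ", disp$type, call. = FALSE)
  }
  acc <- 0
  for (j in seq_along(vals)) acc <- acc + wts[j] * eval_at(vals[j])
  acc
}

#' Scattering intensity of a mixture model
#'
#' `I(s) = S(s) * sum_k w_k <I_k(s)>`, where `<.>` averages each
#' component's intensity over its size distribution and `S(s)` is the
#' hard-sphere Percus-Yevick structure factor when selected (1 otherwise),
#' applied to the total in the decoupling approximation.
#'
#' @param model a [mixture_model()].
#' @param s_grid momentum-transfer grid (inverse angstroms).
#' @param n_nodes size-distribution quadrature nodes.
#' @return A [scattering_curve()].
#' @export
mixture_intensity <- function(model, s_grid, n_nodes = 15L) {
  stopifnot(inherits(model, "mixture_model"))
  I <- numeric(length(s_grid))
  for (k in seq_along(model$components)) {
    comp <- model$components[[k]]
    disp <- if (!is.null(model$dispersion)) model$dispersion[[k]]
    Ik <- if (inherits(comp, "sas_body")) {
      dispersed_body_intensity(comp, s_grid, disp, n_nodes)
    } else if (inherits(comp, "scattering_curve")) {
      stats::approx(comp$s, comp$i, xout = s_grid)$y
    } else {
      stop("unsupported component type", call. = FALSE)
    }
    I <- I + model$fractions[k] * Ik
  }
  if (!is.null(model$structure_factor)) {
    sf <- model$structure_factor
    I <- I * hard_sphere_sf(s_grid, sf$eta, sf$r_hs)
  }
  scattering_curve(s_grid, I, unit = "A-1", meta = list(model = "mixture"))
}

# Sharp interference minima make body-fit least-squares surfaces locally
# rippled; trust-region steps can stall in a micro-minimum a few percent
# from the optimum. Deterministic coordinate-wise grid-plus-golden
# refinement over a +/-8% (log-space) window recovers the valley floor.
polish_coordinates <- function(par, resid_fn, half_width = 0.08,
                               passes = 3L) {
  rss <- function(p) sum(resid_fn(p)^2)
  for (pass in seq_len(passes)) {
    for (j in seq_along(par)) {
      obj <- function(v) {
        p2 <- par; p2[j] <- v; -rss(p2)
      }
      # the slice can be multimodal at the ripple scale: coarse grid
      # first, then golden section in the best sub-interval
      grid <- seq(par[j] - half_width, par[j] + half_width,
                  length.out = 25L)
      vals <- vapply(grid, obj, numeric(1))
      k <- which.max(vals)
      par[j] <- golden_max(obj, grid[max(1L, k - 1L)],
                           grid[min(length(grid), k + 1L)], tol = 1e-5)
    }
  }
  par
}

# Free parameters of a body kind for fitting, with log-space bounds derived
# from the radius of gyration of the data.
body_param_names <- function(kind) {
  switch(kind,
    sphere = "r",
    core_shell_sphere = c("r_core", "r_shell"),
    cylinder = c("r", "l"),
    core_shell_cylinder = c("r_core", "r_shell", "l_core", "l_shell"),
    ellipsoid_of_revolution = c("r", "ratio"),
    parallelepiped = c("a", "b", "c"),
    dumbbell = c("r1", "r2", "d"))
}

body_from_params <- function(kind, pvec) {
  nm <- body_param_names(kind)
  args <- as.list(pvec)
  names(args) <- nm
  if (kind == "core_shell_sphere") {
    args$r_shell <- args$r_core + args$r_shell  # shell thickness param
    args$rho_core <- 1; args$rho_shell <- 0.5
  }
  if (kind == "core_shell_cylinder") {
    args$r_shell <- args$r_core + args$r_shell
    args$l_shell <- args$l_core + args$l_shell
    args$rho_core <- 1; args$rho_shell <- 0.5
  }
  do.call(body, c(list(kind = kind), args))
}

#' Fit a geometric body to a scattering curve
#'
#' Weighted least squares over the body's free dimensions plus an analytic
#' overall scale, using a Levenberg-Marquardt local optimizer with
#' seeded multi-start initial points spanning bounds derived from the
#' data's radius of gyration. Deterministic for a given seed.
#'
#' @param curve a [scattering_curve()] with errors.
#' @param kind body kind, see [body()].
#' @param init optional named list of initial dimension parameters.
#' @param n_restarts number of multi-start points.
#' @param seed RNG seed for the restart draws.
#' @return List with `body` (fitted [body()]), `scale`, `chi2_reduced`.
#' @examples
#' crv <- simulate_curve(body("sphere", r = 30), seq(0.01, 0.3, 0.002),
#'                       noise_model(0.01, seed = 4))
#' fit_body(crv, "sphere")$body$params$r  # ~30
#' @export
fit_body <- function(curve, kind, init = NULL, n_restarts = 5L, seed = 1L) {
  curve <- as_inverse_angstrom(curve)
  check_sigma(curve, "body fitting")
  nm <- body_param_names(kind)
  rg_data <- tryCatch(autorg(curve)$rg, error = function(e) {
    1 / max(curve$s)
  })
  # generous geometric bounds around the data Rg
  lo <- rep(max(rg_data * 0.05, 1), length(nm))
  hi <- rep(rg_data * 8, length(nm))
  if (kind == "ellipsoid_of_revolution") { lo[2L] <- 0.1; hi[2L] <- 10 }
  resid_fn <- function(logp) {
    bd <- tryCatch(body_from_params(kind, exp(logp)),
                   error = function(e) NULL)
    if (is.null(bd)) return(rep(1e8, length(curve$s)))
    im <- tryCatch(body_intensity_raw(bd, curve$s),
                   error = function(e) NULL)
    if (is.null(im) || any(!is.finite(im))) {
      return(rep(1e8, length(curve$s)))
    }
    w <- 1 / curve$sigma
    sc <- sum(w^2 * im * curve$i) / sum(w^2 * im^2)
    (sc * im - curve$i) * w
  }
  starts <- list()
  if (!is.null(init)) starts[[1L]] <- log(unlist(init[nm]))
  draws <- with_seed(seed, matrix(stats::runif(n_restarts * length(nm)),
                                  ncol = length(nm)))
  for (j in seq_len(n_restarts)) {
    starts[[length(starts) + 1L]] <-
      log(lo) + draws[j, ] * (log(hi) - log(lo))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("optimizer failed on all restarts", call. = FALSE)
  par <- polish_coordinates(best$fit$par, resid_fn)
  refit <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (!is.null(refit) && sum(refit$fvec^2) < sum(resid_fn(par)^2)) {
    par <- refit$par
  }
  pvec <- exp(par)
  bd <- body_from_params(kind, pvec)
  im <- body_intensity_raw(bd, curve$s)
  w <- 1 / curve$sigma
  sc <- sum(w^2 * im * curve$i) / sum(w^2 * im^2)
  n <- length(curve$s)
  nu <- max(1L, n - length(nm) - 1L)
  list(body = bd, scale = sc,
       chi2_reduced = sum(((sc * im - curve$i) * w)^2) / nu)
}

#' Fit a mixture model to a scattering curve
#'
#' Bounded weighted least squares over the masked free parameters of a
#' mixture template: body dimensions (log-reparameterized), volume
#' fractions (softmax-reparameterized onto the unit simplex when the model
#' is normalized) and dispersion widths. When only the fractions are free
#' and no structure factor is present the problem is linear and is solved
#' exactly by non-negative least squares.
#'
#' @param curve a [scattering_curve()] with errors.
#' @param model a [mixture_model()] template holding initial values.
#' @param free named logical/character specification of what to optimize:
#'   `fractions = TRUE` and/or `params = TRUE` (all body dimensions).
#' @param n_restarts multi-start count for the nonlinear case.
#' @param seed RNG seed.
#' @return List with `model` (fitted), `chi2_reduced`.
#' @export
fit_mixture <- function(curve, model,
                        free = list(fractions = TRUE, params = FALSE),
                        n_restarts = 3L, seed = 1L) {
  curve <- as_inverse_angstrom(curve)
  check_sigma(curve, "mixture fitting")
  k <- length(model$components)
  if (k > 10L) stop("component limit: at most 10 components", call. = FALSE)
  free_frac <- isTRUE(free$fractions)
  free_par <- isTRUE(free$params)
  if (free_frac && !free_par && is.null(model$structure_factor)) {
    # linear subproblem: exact non-negative least squares
    FF <- vapply(seq_len(k), function(j) {
      comp <- model$components[[j]]
      disp <- if (!is.null(model$dispersion)) model$dispersion[[j]]
      if (inherits(comp, "sas_body")) {
        dispersed_body_intensity(comp, curve$s, disp)
      } else {
        stats::approx(comp$s, comp$i, xout = curve$s)$y
      }
    }, numeric(length(curve$s)))
    og <- oligomer_fractions(curve, list(s = curve$s, ff = FF),
                             normalize = model$normalize)
    model$fractions <- og$fractions
    return(list(model = model, chi2_reduced = og$chi2_reduced))
  }
  # nonlinear case: log dims + softmax fractions
  kinds <- vapply(model$components, function(cc)
    if (inherits(cc, "sas_body")) cc$kind else "tabulated", "")
  pidx <- list(); p0 <- numeric(0)
  if (free_par) {
    for (j in seq_len(k)) {
      if (kinds[j] == "tabulated") next
      nmj <- body_param_names(kinds[j])
      cur <- log(unlist(model$components[[j]]$params[nmj]))
      pidx[[length(pidx) + 1L]] <- list(comp = j, names = nmj,
                                        at = length(p0) + seq_along(cur))
      p0 <- c(p0, cur)
    }
  }
  f_at <- NULL
  if (free_frac) {
    f_at <- length(p0) + seq_len(k)
    p0 <- c(p0, log(pmax(model$fractions, 1e-6)))
  }
  build <- function(pv) {
    m2 <- model
    for (blk in pidx) {
      vals <- exp(pv[blk$at])
      for (ii in seq_along(blk$names)) {
        m2$components[[blk$comp]]$params[[blk$names[ii]]] <- vals[ii]
      }
    }
    if (!is.null(f_at)) {
      ef <- exp(pv[f_at] - max(pv[f_at]))
      m2$fractions <- if (model$normalize) ef / sum(ef) else exp(pv[f_at])
    }
    m2
  }
  w <- 1 / curve$sigma
  resid_fn <- function(pv) {
    m2 <- tryCatch(build(pv), error = function(e) NULL)
    if (is.null(m2)) return(rep(1e8, length(curve$s)))
    im <- tryCatch(mixture_intensity(m2, curve$s)$i,
                   error = function(e) NULL)
    if (is.null(im) || any(!is.finite(im))) {
      return(rep(1e8, length(curve$s)))
    }
    (im - curve$i) * w
  }
  jitter <- with_seed(seed, matrix(stats::rnorm(n_restarts * length(p0),
                                                0, 0.2),
                                   nrow = n_restarts))
  best <- NULL
  for (j in seq_len(n_restarts)) {
    st <- p0 + if (j == 1L) 0 else jitter[j, ]
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("optimizer failed on all restarts", call. = FALSE)
  par <- polish_coordinates(best$fit$par, resid_fn)
  refit <- tryCatch(
    minpack.lm::nls.lm(par = par, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(refit) && sum(refit$fvec^2) < sum(resid_fn(par)^2)) {
    par <- polish_coordinates(refit$par, resid_fn, passes = 1L)
  }
  m2 <- build(par)
  n <- length(curve$s)
  nu <- max(1L, n - length(p0) - 1L)
  list(model = m2, chi2_reduced = sum(resid_fn(par)^2) / nu)
}

#' Volume fractions of known components
#'
#' Non-negativity-constrained weighted linear least squares for the volume
#' fractions `w` in `I(s) = sum_k w_k F_k(s)`, optionally with the equality
#' constraint `sum w = 1`. Reports the reduced chi-squared and a
#' linearized covariance of the unconstrained (passive) fractions. A
#' rank-deficient component set triggers a warning and the minimum-norm
#' solution is flagged.
#'
#' @param curve a [scattering_curve()] with errors.
#' @param formfactors a form-factor table from [build_formfactor_table()]
#'   (or a list with `s` and matrix `ff`), on the data grid.
#' @param normalize constrain the fractions to sum to 1.
#' @return Object of class `oligomer_result`: `fractions`,
#'   `chi2_reduced`, `covariance`, `rank_deficient`, `fit`.
#' @export
oligomer_fractions <- function(curve, formfactors, normalize = FALSE) {
  curve <- as_inverse_angstrom(curve)
  check_sigma(curve, "volume-fraction decomposition")
  FF <- as.matrix(formfactors$ff)
  if (nrow(FF) != length(curve$s)) {
    stop("component curves must be on the data grid", call. = FALSE)
  }
  k <- ncol(FF)
  w <- 1 / curve$sigma
  A <- FF * w
  bvec <- curve$i * w
  rank_def <- qr(A)$rank < k
  if (rank_def) {
    warning("rank-deficient component set; minimum-norm solution flagged")
  }
  if (normalize) {
    lam <- 1e6 * max(abs(bvec))
    A <- rbind(A, rep(lam, k))
    bvec <- c(bvec, lam)
  }
  nn <- nnls_fit(A, bvec)
  frac <- nn$x
  fit_i <- as.numeric(FF %*% frac)
  n <- length(curve$s)
  nu <- max(1L, n - k)
  chi2 <- sum(((curve$i - fit_i) * w)^2) / nu
  covar <- matrix(NA_real_, k, k)
  P <- nn$passive
  if (length(P)) {
    Ap <- (FF * w)[, P, drop = FALSE]
    cv <- tryCatch(solve(crossprod(Ap)), error = function(e) NULL)
    if (!is.null(cv)) covar[P, P] <- cv
  }
  structure(list(fractions = frac, chi2_reduced = chi2,
                 covariance = covar, rank_deficient = rank_def,
                 fit = scattering_curve(curve$s, fit_i, unit = curve$unit)),
            class = "oligomer_result")
}

#' @export
print.oligomer_result <- function(x, ...) {
  cat("volume fractions:", sprintf("%.4f", x$fractions), "\n")
  cat(sprintf("chi2_red = %.3f%s\n", x$chi2_reduced,
              if (x$rank_deficient) " (rank-deficient set)" else ""))
  invisible(x)
}

#' Assemble a form-factor table
#'
#' Evaluates geometric bodies and/or regrids tabulated curves onto a common
#' s grid, producing the multi-column component table consumed by
#' [oligomer_fractions()]. [write_ff_table()] and [read_ff_table()]
#' round-trip the table as multi-column ASCII (`s F1 F2 ...`).
#'
#' @param components list of [body()]s or [scattering_curve()]s.
#' @param s_grid target momentum-transfer grid.
#' @return List of class `ff_table` with `s` and matrix `ff` (one column
#'   per component).
#' @export
build_formfactor_table <- function(components, s_grid) {
  if (length(components) < 1L) stop("need at least one component",
                                    call. = FALSE)
  ff <- vapply(components, function(comp) {
    if (inherits(comp, "sas_body")) {
      body_intensity_raw(comp, s_grid)
    } else if (inherits(comp, "scattering_curve")) {
      if (min(s_grid) < min(comp$s) || max(s_grid) > max(comp$s)) {
        stop("component support narrower than the target grid",
             call. = FALSE)
      }
      stats::approx(comp$s, comp$i, xout = s_grid)$y
    } else {
      stop("unsupported component type", call. = FALSE)
    }
  }, numeric(length(s_grid)))
  structure(list(s = s_grid, ff = as.matrix(ff)), class = "ff_table")
}

#' @rdname build_formfactor_table
#' @param table an `ff_table`.
#' @param path destination/source file.
#' @export
write_ff_table <- function(table, path) {
  fmt <- function(x) formatC(x, format = "e", digits = 8, width = 17)
  hdr <- sprintf("# form-factor table: %d components", ncol(table$ff))
  rows <- fmt(table$s)
  for (j in seq_len(ncol(table$ff))) rows <- paste0(rows, fmt(table$ff[, j]))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname build_formfactor_table
#' @export
read_ff_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), function(tk)
    suppressWarnings(as.numeric(tk)))
  rows <- rows[!vapply(rows, anyNA, logical(1))]
  rows <- rows[vapply(rows, length, integer(1)) >= 2L]
  m <- do.call(rbind, rows)
  structure(list(s = m[, 1L], ff = m[, -1L, drop = FALSE]),
            class = "ff_table")
}

#' Number of independent scattering components by SVD
#'
#' Decomposes the matrix of curves (optionally error-normalized, making
#' pure noise unit-variance) and counts singular values above a noise
#' floor: 1.5 times the median singular value of 50 seeded pure-noise
#' matrices of the same shape (entries drawn with the curves' sigmas, or
#' unit normal when normalized). Used to detect concentration- or
#' time-dependent structural transitions in series data.
#'
#' @param curves list of at least 2 [scattering_curve()]s on a common
#'   grid.
#' @param normalize_by_sigma divide each curve by its errors first.
#' @param n_noise number of reference noise matrices.
#' @param floor_scale multiplier on the median noise singular value.
#' @param seed RNG seed for the noise reference.
#' @return Object of class `svd_result`: `singular_values`,
#'   `n_significant`, `noise_floor`.
#' @export
svd_rank <- function(curves, normalize_by_sigma = TRUE, n_noise = 50L,
                     floor_scale = 1.5, seed = 1L) {
  k <- length(curves)
  if (k < 2L) stop("need at least 2 curves", call. = FALSE)
  for (j in 2:k) check_same_grid(curves[[1L]], curves[[j]])
  n <- length(curves[[1L]]$s)
  M <- vapply(curves, function(cv) {
    if (normalize_by_sigma) {
      check_sigma(cv, "sigma-normalized SVD")
      cv$i / cv$sigma
    } else {
      cv$i
    }
  }, numeric(n))
  sv <- svd(M, nu = 0, nv = 0)$d
  floor_ref <- with_seed(seed, {
    vapply(seq_len(n_noise), function(b) {
      Z <- if (normalize_by_sigma) {
        matrix(stats::rnorm(n * k), n, k)
      } else {
        vapply(curves, function(cv) {
          if (is.null(cv$sigma)) stats::rnorm(n) else
            stats::rnorm(n, 0, cv$sigma)
        }, numeric(n))
      }
      stats::median(svd(Z, nu = 0, nv = 0)$d)
    }, numeric(1))
  })
  noise_floor <- floor_scale * stats::median(floor_ref)
  structure(list(singular_values = sv,
                 n_significant = sum(sv > noise_floor),
                 noise_floor = noise_floor),
            class = "svd_result")
}

#' @export
print.svd_result <- function(x, ...) {
  cat(sprintf("SVD: %d significant components (noise floor %.3g)\n",
              x$n_significant, x$noise_floor))
  cat("singular values:", sprintf("%.3g", utils::head(x$singular_values, 8)),
      if (length(x$singular_values) > 8) "...", "\n")
  invisible(x)
}
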