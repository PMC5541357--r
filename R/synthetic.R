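#' Noise model for synthetic scattering curves
#'
#' Gaussian noise with intensity-proportional standard deviation,
#' emulating background-subtracted counting statistics at the high count
#' rates of modern solution-scattering detectors:
#' `sigma(s) = relative_level * (I(s) + background) * (1 + (s/s_max)^s_dependence)`,
#' so the relative error grows smoothly toward high angles.
#'
#' @param relative_level sigma/I at the low-angle end (e.g. 0.02 for 2%).
#' @param s_dependence exponent of the high-angle noise growth (default 1:
#'   relative noise doubles by the end of the measured range).
#' @param background additive constant intensity (instrument residual).
#' @param seed integer RNG seed; every simulated curve is bit-reproducible
#'   given the seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(relative_level = 0.02, s_dependence = 1,
                        background = 0, seed = 1L) {
  if (relative_level < 0) stop("negative noise level", call. = FALSE)
  structure(list(relative_level = relative_level,
                 s_dependence = s_dependence,
                 background = background, seed = as.integer(seed)),
            class = "noise_model")
}

# Evaluate any supported model (body, mixture model or tabulated curve) on
# an s grid.
model_intensity <- function(model, s_grid) {
  if (inherits(model, "sas_body")) {
    body_intensity(model, s_grid)$i
  } else if (inherits(model, "mixture_model")) {
    mixture_intensity(model, s_grid)$i
  } else if (inherits(model, "scattering_curve")) {
    if (min(s_grid) < min(model$s) || max(s_grid) > max(model$s)) {
      stop("s grid outside tabulated model support", call. = FALSE)
    }
    stats::approx(model$s, model$i, xout = s_grid)$y
  } else {
    stop("unsupported model type", call. = FALSE)
  }
}

# Run an expression with a locally seeded RNG, restoring the caller's
# stream afterwards so simulation helpers have no hidden global effect.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate a noisy scattering curve from a model
#'
#' `I_obs = scale * I_model + background + eps`, with
#' `eps ~ N(0, sigma(s))` per the [noise_model()]. The sigma column of the
#' returned curve is the exact generating sigma, so downstream tests can
#' compute exact z-scores and chi-squared statistics.
#'
#' @param model a [body()], [mixture_model()] or tabulated
#'   [scattering_curve()].
#' @param s_grid momentum-transfer grid (inverse angstroms).
#' @param noise a [noise_model()]; `relative_level = 0` returns the exact
#'   model curve (with a tiny floor sigma so error-requiring methods work).
#' @param scale overall multiplicative scale.
#' @return A [scattering_curve()] with sigma.
#' @examples
#' crv <- simulate_curve(body("sphere", r = 30), seq(0.005, 0.4, 0.002),
#'                       noise_model(0.02, seed = 7))
#' @export
simulate_curve <- function(model, s_grid, noise = noise_model(),
                           scale = 1) {
  stopifnot(inherits(noise, "noise_model"))
  imod <- scale * model_intensity(model, s_grid) + noise$background
  smax <- max(s_grid)
  sig <- noise$relative_level * pmax(abs(imod), .Machine$double.xmin) *
    (1 + (s_grid / smax)^noise$s_dependence)
  if (noise$relative_level == 0) {
    # exact curve; floor sigma keeps the error column valid
    sig <- rep(max(abs(imod)) * 1e-12, length(s_grid))
    iobs <- imod
  } else {
    iobs <- imod + with_seed(noise$seed, stats::rnorm(length(s_grid), 0, sig))
  }
  scattering_curve(s_grid, iobs, sigma = sig, unit = "A-1",
                   meta = list(seed = noise$seed,
                               noise_level = noise$relative_level))
}

#' Simulate a concentration (dilution) series
#'
#' Each curve is `c * I_body(s) * S_PY(s; eta = interaction * c)` plus
#' noise, where `S_PY` is the hard-sphere Percus-Yevick structure factor
#' with interaction radius equal to the body's effective hard-sphere radius
#' (`sqrt(5/3) * Rg`). This emulates the repulsive low-angle suppression
#' that motivates merging low- and high-concentration measurements and
#' extrapolation to infinite dilution.
#'
#' @param body a [body()].
#' @param concentrations mg/ml values, all positive.
#' @param interaction hard-sphere volume fraction per unit concentration
#'   (`eta = interaction * c`); 0 gives ideal, exactly proportional curves.
#' @param noise a [noise_model()]; seeds are offset per curve for
#'   independent noise realizations.
#' @param s_grid momentum-transfer grid.
#' @return List of [scattering_curve()]s; each `meta$concentration` records
#'   the concentration.
#' @export
dilution_series <- function(body, concentrations, interaction = 0,
                            noise = noise_model(),
                            s_grid = seq(0.005, 0.4, length.out = 200)) {
  if (any(concentrations <= 0)) stop("concentrations must be positive",
                                     call. = FALSE)
  if (interaction < 0) stop("invalid interaction parameter", call. = FALSE)
  r_hs <- sqrt(5 / 3) * body_rg(body)
  ibody <- body_intensity(body, s_grid)$i
  lapply(seq_along(concentrations), function(k) {
    cc <- concentrations[k]
    eta <- interaction * cc
    S <- if (eta > 0) hard_sphere_sf(s_grid, eta, r_hs) else 1
    model <- scattering_curve(s_grid, cc * ibody * S)
    nm <- noise
    nm$seed <- noise$seed + k - 1L
    out <- simulate_curve(model, s_grid, nm)
    out$meta$concentration <- cc
    out
  })
}

#' Bead-filled sphere fixture
#'
#' Cubic-lattice points inside a sphere, jittered by seeded uniform offsets
#' of at most a tenth of the lattice spacing; unit weights. Used as the
#' reference input for [debye_intensity()].
#'
#' @param radius sphere radius (angstroms).
#' @param bead_spacing lattice constant, must be smaller than the radius.
#' @param seed RNG seed for the jitter.
#' @return List with `points` (`n x 3`) and `weights`.
#' @export
bead_sphere <- function(radius, bead_spacing, seed = 1L) {
  if (bead_spacing >= radius) stop("spacing must be below radius",
                                   call. = FALSE)
  g <- seq(-radius, radius, by = bead_spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  jit <- with_seed(seed, matrix(stats::runif(length(pts),
                                             -0.1 * bead_spacing,
                                             0.1 * bead_spacing),
                                ncol = 3L))
  list(points = pts + jit, weights = rep(1, nrow(pts)))
}

#' Random protein sequence fixture
#'
#' Uniformly random sequence over the 20 standard amino-acid letters.
#'
#' @param length sequence length, at least 1.
#' @param seed RNG seed.
#' @return Single character string.
#' @export
random_protein_sequence <- function(length, seed = 1L) {
  if (length < 1) stop("length must be at least 1", call. = FALSE)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  with_seed(seed, paste(sample(aa, length, replace = TRUE), collapse = ""))
}
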