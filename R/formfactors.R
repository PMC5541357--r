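#' Geometric body for form-factor computation
#'
#' Describes a simple homogeneous (or core-shell) geometric body whose
#' orientationally averaged scattering intensity can be evaluated with
#' [body_intensity()]. Dimensions are in angstroms, contrasts are relative
#' excess scattering densities.
#'
#' Supported kinds and their parameters:
#' \describe{
#'   \item{sphere}{`r` radius.}
#'   \item{core_shell_sphere}{`r_core`, `r_shell` (outer, > core),
#'     `rho_core`, `rho_shell` contrasts.}
#'   \item{cylinder}{`r` radius, `l` length.}
#'   \item{core_shell_cylinder}{`r_core`, `r_shell`, `l_core`, `l_shell`,
#'     `rho_core`, `rho_shell`.}
#'   \item{ellipsoid_of_revolution}{`r` equatorial semi-axis, `ratio` axial
#'     ratio (polar = `ratio * r`).}
#'   \item{parallelepiped}{edges `a`, `b`, `c`.}
#'   \item{dumbbell}{two spheres `r1`, `r2` with centre distance `d`
#'     (tangent when `d = r1 + r2`, separated when larger).}
#' }
#'
#' @param kind body kind, see Details.
#' @param ... kind-specific dimension parameters.
#' @param contrast overall relative excess density (scales amplitude).
#' @return Object of class `sas_body`.
#' @examples
#' body("sphere", r = 30)
#' body("cylinder", r = 20, l = 100)
#' @export
body <- function(kind = c("sphere", "core_shell_sphere", "cylinder",
                          "core_shell_cylinder", "ellipsoid_of_revolution",
                          "parallelepiped", "dumbbell"),
                 ..., contrast = 1) {
  kind <- match.arg(kind)
  params <- list(...)
  need <- switch(kind,
    sphere = "r",
    core_shell_sphere = c("r_core", "r_shell", "rho_core", "rho_shell"),
    cylinder = c("r", "l"),
    core_shell_cylinder = c("r_core", "r_shell", "l_core", "l_shell",
                            "rho_core", "rho_shell"),
    ellipsoid_of_revolution = c("r", "ratio"),
    parallelepiped = c("a", "b", "c"),
    dumbbell = c("r1", "r2", "d"))
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    stop("missing parameters for ", kind, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  params <- params[need]
  dims <- setdiff(need, c("rho_core", "rho_shell"))
  if (any(unlist(params[dims]) <= 0)) {
    stop("all dimensions must be positive", call. = FALSE)
  }
  if (kind == "core_shell_sphere" && params$r_shell <= params$r_core) {
    stop("shell radius must exceed core radius", call. = FALSE)
  }
  if (kind == "core_shell_cylinder" &&
      (params$r_shell <= params$r_core || params$l_shell <= params$l_core)) {
    stop("shell dimensions must exceed core dimensions", call. = FALSE)
  }
  structure(list(kind = kind, params = params, contrast = contrast),
            class = "sas_body")
}

#' @export
print.sas_body <- function(x, ...) {
  cat(sprintf("body: %s (%s), contrast %g\n", x$kind,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "), x$contrast))
  invisible(x)
}

# Normalized sphere scattering amplitude phi(x) = 3(sin x - x cos x)/x^3,
# with the exact small-x limit phi(0) = 1 handled by series expansion.
sphere_amplitude <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-3
  out[small] <- 1 - x[small]^2 / 10
  xs <- x[!small]
  out[!small] <- 3 * (sin(xs) - xs * cos(xs)) / xs^3
  out
}

# sin(x)/x with the limit at 0.
sinc <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1
  out[!small] <- sin(x[!small]) / x[!small]
  out
}

# 2 J1(x)/x with the limit at 0 (cylinder cross-section amplitude).
bessel_j1_over <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1
  out[!small] <- 2 * besselJ(x[!small], 1) / x[!small]
  out
}

# Geometric volume of a body (total envelope for core-shell kinds).
#' Volume of a geometric body
#' @param body a [body()].
#' @return Volume in cubic angstroms (outer envelope for core-shell kinds,
#'   sum of both spheres for the dumbbell).
#' @export
body_volume <- function(body) {
  p <- body$params
  switch(body$kind,
    sphere = 4 / 3 * pi * p$r^3,
    core_shell_sphere = 4 / 3 * pi * p$r_shell^3,
    cylinder = pi * p$r^2 * p$l,
    core_shell_cylinder = pi * p$r_shell^2 * p$l_shell,
    ellipsoid_of_revolution = 4 / 3 * pi * p$r^3 * p$ratio,
    parallelepiped = p$a * p$b * p$c,
    dumbbell = 4 / 3 * pi * (p$r1^3 + p$r2^3))
}

#' Radius of gyration of a geometric body
#'
#' Closed-form (uniform-density) radius of gyration; used for sanity checks
#' and to seed fitting bounds. Core-shell kinds use the contrast-weighted
#' second moment.
#' @param body a [body()].
#' @return Rg in angstroms.
#' @export
body_rg <- function(body) {
  p <- body$params
  sq <- switch(body$kind,
    sphere = 3 / 5 * p$r^2,
    core_shell_sphere = {
      vc <- 4 / 3 * pi * p$r_core^3; vs <- 4 / 3 * pi * p$r_shell^3
      m_core <- p$rho_core * vc + p$rho_shell * (vs - vc)
      num <- p$rho_core * vc * 3 / 5 * p$r_core^2 +
        p$rho_shell * (vs * 3 / 5 * p$r_shell^2 - vc * 3 / 5 * p$r_core^2)
      num / m_core
    },
    cylinder = p$r^2 / 2 + p$l^2 / 12,
    core_shell_cylinder = {
      vc <- pi * p$r_core^2 * p$l_core; vs <- pi * p$r_shell^2 * p$l_shell
      gc <- p$r_core^2 / 2 + p$l_core^2 / 12
      gs <- p$r_shell^2 / 2 + p$l_shell^2 / 12
      m <- p$rho_core * vc + p$rho_shell * (vs - vc)
      (p$rho_core * vc * gc + p$rho_shell * (vs * gs - vc * gc)) / m
    },
    ellipsoid_of_revolution = (2 * p$r^2 + (p$ratio * p$r)^2) / 5,
    parallelepiped = (p$a^2 + p$b^2 + p$c^2) / 12,
    dumbbell = {
      v1 <- p$r1^3; v2 <- p$r2^3  # volumes up to 4pi/3
      # centre of mass along the axis, parallel-axis theorem
      z1 <- -p$d * v2 / (v1 + v2); z2 <- p$d + z1
      (v1 * (3 / 5 * p$r1^2 + z1^2) + v2 * (3 / 5 * p$r2^2 + z2^2)) /
        (v1 + v2)
    })
  sqrt(sq)
}

# Orientation-averaged intensity of a body on an s grid, absolute amplitude
# ((contrast * volume)^2 at s = 0). n_quad controls the Gauss-Legendre
# orientation quadrature for the non-closed-form kinds.
body_intensity_raw <- function(body, s, n_quad = 64L) {
  p <- body$params
  rho <- body$contrast
  switch(body$kind,
    sphere = {
      v <- 4 / 3 * pi * p$r^3
      (rho * v * sphere_amplitude(s * p$r))^2
    },
    core_shell_sphere = {
      vc <- 4 / 3 * pi * p$r_core^3; vs <- 4 / 3 * pi * p$r_shell^3
      amp <- p$rho_core * vc * sphere_amplitude(s * p$r_core) +
        p$rho_shell * (vs * sphere_amplitude(s * p$r_shell) -
                         vc * sphere_amplitude(s * p$r_core))
      (rho * amp)^2
    },
    cylinder = {
      v <- pi * p$r^2 * p$l
      gl <- pracma::gaussLegendre(n_quad, 0, pi / 2)
      sa <- sin(gl$x); ca <- cos(gl$x)
      I <- vapply(seq_along(gl$x), function(k) {
        amp <- bessel_j1_over(s * p$r * sa[k]) * sinc(s * p$l * ca[k] / 2)
        amp^2 * sa[k]
      }, numeric(length(s)))
      (rho * v)^2 * as.numeric(I %*% gl$w)
    },
    core_shell_cylinder = {
      vc <- pi * p$r_core^2 * p$l_core; vs <- pi * p$r_shell^2 * p$l_shell
      gl <- pracma::gaussLegendre(n_quad, 0, pi / 2)
      sa <- sin(gl$x); ca <- cos(gl$x)
      I <- vapply(seq_along(gl$x), function(k) {
        ac <- vc * bessel_j1_over(s * p$r_core * sa[k]) *
          sinc(s * p$l_core * ca[k] / 2)
        as <- vs * bessel_j1_over(s * p$r_shell * sa[k]) *
          sinc(s * p$l_shell * ca[k] / 2)
        amp <- p$rho_core * ac + p$rho_shell * (as - ac)
        amp^2 * sa[k]
      }, numeric(length(s)))
      rho^2 * as.numeric(I %*% gl$w)
    },
    ellipsoid_of_revolution = {
      v <- 4 / 3 * pi * p$r^3 * p$ratio
      gl <- pracma::gaussLegendre(n_quad, 0, 1)  # over cos(theta)
      I <- vapply(seq_along(gl$x), function(k) {
        re <- p$r * sqrt(1 + (p$ratio^2 - 1) * gl$x[k]^2)
        sphere_amplitude(s * re)^2
      }, numeric(length(s)))
      (rho * v)^2 * as.numeric(I %*% gl$w)
    },
    parallelepiped = {
      v <- p$a * p$b * p$c
      nq <- max(16L, n_quad %/% 2L)
      glc <- pracma::gaussLegendre(nq, 0, 1)        # cos(theta)
      glp <- pracma::gaussLegendre(nq, 0, pi / 2)   # phi
      acc <- numeric(length(s))
      for (ic in seq_len(nq)) {
        ct <- glc$x[ic]; st <- sqrt(1 - ct^2)
        for (ip in seq_len(nq)) {
          u <- st * cos(glp$x[ip]); w <- st * sin(glp$x[ip])
          amp <- sinc(s * p$a * u / 2) * sinc(s * p$b * w / 2) *
            sinc(s * p$c * ct / 2)
          acc <- acc + amp^2 * glc$w[ic] * glp$w[ip]
        }
      }
      (rho * v)^2 * acc * (2 / pi)
    },
    dumbbell = {
      v1 <- 4 / 3 * pi * p$r1^3; v2 <- 4 / 3 * pi * p$r2^3
      f1 <- v1 * sphere_amplitude(s * p$r1)
      f2 <- v2 * sphere_amplitude(s * p$r2)
      rho^2 * (f1^2 + f2^2 + 2 * f1 * f2 * sinc(s * p$d))
    })
}

#' Orientationally averaged scattering intensity of a body
#'
#' Sphere, core-shell sphere and dumbbell use closed forms; cylinder,
#' core-shell cylinder, ellipsoid of revolution and parallelepiped are
#' averaged over orientations by Gauss-Legendre quadrature (default order
#' 64, converged to better than 1e-6 relative for particle sizes times s
#' up to ~50).
#'
#' @param body a [body()].
#' @param s_grid momentum-transfer grid (inverse angstroms), non-negative.
#' @param normalized if `TRUE`, `I(0) = 1`; otherwise
#'   `I(0) = (contrast * volume)^2`.
#' @param n_quad orientation quadrature order.
#' @return A [scattering_curve()] without errors.
#' @examples
#' crv <- body_intensity(body("sphere", r = 30), seq(0, 0.3, 0.005))
#' @export
body_intensity <- function(body, s_grid, normalized = FALSE, n_quad = 64L) {
  stopifnot(inherits(body, "sas_body"), all(s_grid >= 0))
  I <- body_intensity_raw(body, s_grid, n_quad = n_quad)
  if (normalized) I <- I / body_intensity_raw(body, 0, n_quad = n_quad)
  scattering_curve(s_grid, I, unit = "A-1",
                   meta = list(model = body$kind))
}

#' Debye pairwise-distance intensity of a point (bead) model
#'
#' Evaluates `I(s) = sum_jk w_j w_k sin(s d_jk)/(s d_jk)` over all point
#' pairs. Pair distances are computed exactly (O(n^2)); for speed on large
#' models the pair sum is accumulated on a fine distance histogram
#' (default bin 0.01 A), which perturbs phases by less than `0.005 * s`
#' radians and is far below any practical tolerance.
#'
#' @param points numeric matrix `n x 3` of coordinates (angstroms).
#' @param weights per-point scattering lengths (default all 1).
#' @param s_grid momentum-transfer grid (inverse angstroms).
#' @param bin_width distance histogram resolution in angstroms; set to 0 to
#'   force the exact unbinned pair sum.
#' @return A [scattering_curve()].
#' @export
debye_intensity <- function(points, weights = NULL, s_grid,
                            bin_width = 0.01) {
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("need at least one point", call. = FALSE)
  stopifnot(ncol(points) == 3L)
  n <- nrow(points)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n)
  self_term <- sum(weights^2)
  if (n == 1L) {
    return(scattering_curve(s_grid, rep(self_term, length(s_grid))))
  }
  d <- as.numeric(stats::dist(points))
  # pair weights w_j * w_k in dist() order (j < k, column-major)
  if (all(weights == weights[1L])) {
    wp <- rep(weights[1L]^2, length(d))
  } else {
    idx <- 0L
    wp <- numeric(length(d))
    for (j in seq_len(n - 1L)) {
      k <- (j + 1L):n
      wp[idx + seq_along(k)] <- weights[j] * weights[k]
      idx <- idx + length(k)
    }
  }
  if (bin_width > 0 && length(d) > 2e5) {
    cell <- floor(d / bin_width) + 1L
    agg <- rowsum(wp, cell)
    dmid <- (as.numeric(rownames(agg)) - 0.5) * bin_width
    wsum <- as.numeric(agg)
  } else {
    dmid <- d; wsum <- wp
  }
  I <- vapply(s_grid, function(sv) {
    self_term + 2 * sum(wsum * sinc(sv * dmid))
  }, numeric(1))
  scattering_curve(s_grid, I, unit = "A-1", meta = list(model = "debye"))
}

#' Read a bead model in PDB format
#'
#' Extracts coordinates (angstroms) from the ATOM/HETATM records of a
#' PDB-format file via the `bio3d` reader. Bead-modelling outputs follow
#' the PDB fixed-width convention; beads get unit weight unless occupancy
#' weighting is requested.
#'
#' @param path PDB-format file.
#' @param occupancy_weights use the occupancy column as weights.
#' @return List with `points` (`n x 3` matrix) and `weights`.
#' @export
read_bead_model <- function(path, occupancy_weights = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) {
    stop("no parseable ATOM/HETATM records in ", path, call. = FALSE)
  })
  at <- pdb$atom
  if (is.null(at) || nrow(at) < 1L) {
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  }
  pts <- as.matrix(at[, c("x", "y", "z")])
  w <- if (occupancy_weights && "o" %in% names(at)) {
    as.numeric(at$o)
  } else {
    rep(1, nrow(pts))
  }
  list(points = pts, weights = w)
}

#' Write a bead model in PDB format
#'
#' Companion writer for [read_bead_model()], emitting minimal ATOM records
#' with carbon dummy atoms at PDB coordinate precision (1e-3 A).
#'
#' @param points `n x 3` coordinate matrix (angstroms).
#' @param path destination file.
#' @param weights optional occupancies.
#' @export
write_bead_model <- function(points, path, weights = NULL) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(weights)) weights <- rep(1, n)
  lines <- sprintf(
    "ATOM  %5d  CA  DUM A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n) %% 100000L, seq_len(n) %% 10000L,
    points[, 1L], points[, 2L], points[, 3L], weights, 20)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Hard-sphere Percus-Yevick structure factor
#'
#' Closed-form structure factor of a hard-sphere fluid at volume fraction
#' `eta` and interaction radius `r_hs`, used to model repulsive
#' interparticle interference at finite concentration.
#'
#' @param s momentum-transfer grid (inverse angstroms).
#' @param eta hard-sphere volume fraction in `[0, 0.74]`.
#' @param r_hs interaction (effective hard-sphere) radius, angstroms.
#' @return Numeric vector `S(s)`.
#' @export
hard_sphere_sf <- function(s, eta, r_hs) {
  if (eta < 0 || eta >= 0.74) stop("eta out of range [0, 0.74)", call. = FALSE)
  if (eta == 0) return(rep(1, length(s)))
  A <- 2 * s * r_hs
  al <- (1 + 2 * eta)^2 / (1 - eta)^4
  be <- -6 * eta * (1 + eta / 2)^2 / (1 - eta)^4
  ga <- eta * al / 2
  G <- numeric(length(A))
  big <- A > 0.05
  Ab <- A[big]
  G[big] <- al * (sin(Ab) - Ab * cos(Ab)) / Ab^2 +
    be * (2 * Ab * sin(Ab) + (2 - Ab^2) * cos(Ab) - 2) / Ab^3 +
    ga * (-Ab^4 * cos(Ab) +
            4 * ((3 * Ab^2 - 6) * cos(Ab) + (Ab^3 - 6 * Ab) * sin(Ab) + 6)) /
      Ab^5
  # small-A limit: G/A -> alpha/3 + beta/4 + gamma/6
  g0 <- al / 3 + be / 4 + ga / 6
  S <- numeric(length(A))
  S[big] <- 1 / (1 + 24 * eta * G[big] / A[big])
  S[!big] <- 1 / (1 + 24 * eta * g0)
  S
}
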