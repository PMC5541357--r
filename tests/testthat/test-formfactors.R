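test_that("sphere intensity matches its closed-form amplitude", {
  # normalized sphere at sR = pi: amplitude 3(sin x - x cos x)/x^3 = 3/pi^2
  crv <- body_intensity(body("sphere", r = 30), c(pi / 30, pi / 30 + 1e-5),
                        normalized = TRUE)
  expect_equal(crv$i[1], (3 / pi^2)^2, tolerance = 1e-9)
  # any body is 1 at s = 0 when normalized
  for (bd in list(body("sphere", r = 20),
                  body("cylinder", r = 15, l = 80),
                  body("ellipsoid_of_revolution", r = 20, ratio = 2),
                  body("parallelepiped", a = 20, b = 30, c = 40),
                  body("dumbbell", r1 = 15, r2 = 15, d = 40),
                  body("core_shell_sphere", r_core = 15, r_shell = 25,
                       rho_core = 1, rho_shell = 0.4))) {
    expect_equal(body_intensity(bd, c(0, 0.01), normalized = TRUE)$i[1], 1,
                 tolerance = 1e-9, label = bd$kind)
  }
  # unnormalized I(0) = (contrast * volume)^2
  bd <- body("sphere", r = 25, contrast = 2)
  expect_equal(body_intensity(bd, c(0, 0.01))$i[1],
               (2 * body_volume(bd))^2, tolerance = 1e-9)
})

test_that("the first sphere minimum sits at the root of tan x = x", {
  # root-finding oracle, independent of the intensity code
  x_root <- uniroot(function(x) tan(x) - x, c(pi + 0.1, 1.5 * pi),
                    tol = 1e-12)$root
  f <- function(x) body_intensity(body("sphere", r = 1), c(x, x + 1e-6),
                                  normalized = TRUE)$i[1]
  x_min <- optimize(f, c(3.5, 5.5), tol = 1e-10)$minimum
  expect_equal(x_min, x_root, tolerance = 1e-3)
  expect_equal(x_root, 4.4934, tolerance = 1e-4)
})

test_that("degenerate bodies collapse to simpler ones", {
  s <- seq(0.005, 0.4, 0.005)
  sph <- body_intensity(body("sphere", r = 25), s, normalized = TRUE)
  ell <- body_intensity(body("ellipsoid_of_revolution", r = 25, ratio = 1),
                        s, normalized = TRUE)
  expect_lt(max(abs(ell$i - sph$i)), 1e-6)
  # orientation quadrature converged at the default order
  for (bd in list(body("cylinder", r = 20, l = 100),
                  body("parallelepiped", a = 30, b = 40, c = 50))) {
    i1 <- body_intensity(bd, s)$i
    i2 <- body_intensity(bd, s, n_quad = 128L)$i
    expect_lt(max(abs(i1 - i2) / i2), 1e-6, label = bd$kind)
  }
})

test_that("body construction validates its parameters", {
  expect_error(body("sphere", r = -1), "positive")
  expect_error(body("sphere"), "missing parameters")
  expect_error(body("core_shell_sphere", r_core = 20, r_shell = 10,
                    rho_core = 1, rho_shell = 1), "shell radius")
  expect_equal(body_rg(body("sphere", r = 30)), sqrt(3 / 5) * 30)
  expect_equal(body_rg(body("cylinder", r = 20, l = 100)),
               sqrt(200 + 10000 / 12))
})

test_that("Debye sums honor exact limits and the analytic sphere", {
  sg <- seq(0.005, 4 / 30, length.out = 50)
  one <- debye_intensity(matrix(0, 1, 3), s_grid = sg)
  expect_identical(unique(one$i), 1)
  # two unit points at distance d: I(0) limit 4 (coherent addition)
  two <- debye_intensity(rbind(c(0, 0, 0), c(10, 0, 0)),
                         s_grid = c(1e-8, 0.01))
  expect_equal(two$i[1], 4, tolerance = 1e-9)
  beads <- bead_sphere(30, 3, seed = 1)
  expect_gte(nrow(beads$points), 3000)
  dby <- debye_intensity(beads$points, s_grid = sg)
  ana <- body_intensity(body("sphere", r = 30), sg, normalized = TRUE)
  expect_lt(max(abs(dby$i / max(dby$i) - ana$i)), 0.02)
})

test_that("bead models round-trip through PDB format", {
  beads <- bead_sphere(20, 5, seed = 2)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_bead_model(beads$points, path)
  back <- read_bead_model(path)
  expect_identical(nrow(back$points), nrow(beads$points))
  expect_lt(max(abs(back$points - beads$points)), 1e-3 + 1e-9)
  writeLines(character(0), path)
  expect_error(read_bead_model(path), "records")
})

test_that("body fitting recovers parameters and ranks models correctly", {
  cv <- simulate_curve(body("sphere", r = 30), seq(0.01, 0.3, 0.002),
                       noise_model(0.01, seed = 4))
  fit <- fit_body(cv, "sphere")
  expect_lt(abs(fit$body$params$r - 30) / 30, 0.005)
  # far initial guess with restarts still converges
  far <- fit_body(cv, "sphere", init = list(r = 300), n_restarts = 5,
                  seed = 3)
  expect_lt(abs(far$body$params$r - 30) / 30, 0.01)
  # a cylinder cannot fit sphere data as well
  wrong <- suppressWarnings(fit_body(cv, "cylinder", seed = 2))
  expect_gt(wrong$chi2_reduced, fit$chi2_reduced)
})

test_that("mixture intensities are linear with degenerate limits", {
  s <- seq(0.005, 0.3, 0.003)
  b1 <- body("sphere", r = 20); b2 <- body("sphere", r = 50)
  i1 <- body_intensity(b1, s)$i; i2 <- body_intensity(b2, s)$i
  pure <- mixture_intensity(mixture_model(list(b1, b2), c(1, 0)), s)
  expect_equal(pure$i, i1, tolerance = 1e-12)
  # two identical components give the single-component curve
  same <- mixture_intensity(mixture_model(list(b1, b1), c(0.3, 0.7)), s)
  expect_equal(same$i, i1, tolerance = 1e-12)
  # superposition at fixed S = 1
  for (w in list(c(0.2, 0.8), c(0.5, 0.5))) {
    mi <- mixture_intensity(mixture_model(list(b1, b2), w), s)
    expect_equal(mi$i, w[1] * i1 + w[2] * i2, tolerance = 1e-12)
  }
  # zero dispersion width equals the sharp body
  disp <- mixture_intensity(
    mixture_model(list(b1), 1,
                  dispersion = list(list(type = "gaussian", width = 0))), s)
  expect_equal(disp$i, i1, tolerance = 1e-12)
  expect_error(mixture_model(rep(list(b1), 11)), "component limit")
})

test_that("hard-sphere structure factor behaves physically", {
  s <- seq(0.001, 0.5, 0.001)
  expect_identical(hard_sphere_sf(s, 0, 30), rep(1, length(s)))
  S <- hard_sphere_sf(s, 0.2, 30)
  expect_lt(S[1], 1)       # repulsive suppression at low angles
  expect_lt(max(abs(S[length(S)] - 1)), 0.2)  # tends to 1 at high angles
  expect_error(hard_sphere_sf(s, 0.9, 30), "eta")
})

test_that("mixture fitting recovers fractions and free radii", {
  s <- seq(0.005, 0.25, 0.0015)
  truth <- mixture_model(list(body("sphere", r = 20), body("sphere", r = 50)),
                         c(0.4, 0.6))
  clean <- exact_curve(truth, s, rel_sigma = 0.01)
  # radii fixed: exact linear subproblem
  lin <- fit_mixture(clean,
                     mixture_model(list(body("sphere", r = 20),
                                        body("sphere", r = 50)),
                                   c(0.5, 0.5)))
  expect_equal(lin$model$fractions, c(0.4, 0.6), tolerance = 1e-3)
  # radii free at 1% noise
  noisy <- simulate_curve(truth, s, noise_model(0.01, seed = 5))
  fm <- suppressWarnings(fit_mixture(
    noisy,
    mixture_model(list(body("sphere", r = 23), body("sphere", r = 45)),
                  c(0.5, 0.5)),
    free = list(fractions = TRUE, params = TRUE), seed = 5))
  radii <- vapply(fm$model$components, function(b) b$params$r, numeric(1))
  expect_lt(abs(radii[1] - 20) / 20, 0.03)
  expect_lt(abs(radii[2] - 50) / 50, 0.03)
  expect_lt(max(abs(fm$model$fractions - c(0.4, 0.6))), 0.05)
})

test_that("volume-fraction decomposition solves the linear problem exactly", {
  s <- seq(0.005, 0.3, 0.002)
  FF <- build_formfactor_table(list(body("sphere", r = 20),
                                    body("sphere", r = 50)), s)
  itrue <- 0.3 * FF$ff[, 1] + 0.7 * FF$ff[, 2]
  dat <- scattering_curve(s, itrue, sigma = 0.01 * itrue)
  og <- oligomer_fractions(dat, FF)
  expect_equal(og$fractions, c(0.3, 0.7), tolerance = 1e-6)
  # unphysical data hit the non-negativity boundary
  neg <- scattering_curve(s, -FF$ff[, 1], sigma = 0.01 * FF$ff[, 1])
  ogn <- oligomer_fractions(neg, FF)
  expect_identical(ogn$fractions, c(0, 0))
  # duplicated component triggers the rank-deficiency warning
  FFdup <- build_formfactor_table(list(body("sphere", r = 20),
                                       body("sphere", r = 20)), s)
  expect_warning(oligomer_fractions(dat, FFdup), "rank-deficient")
  # normalized mode returns simplex fractions
  ogs <- oligomer_fractions(dat, FF, normalize = TRUE)
  expect_equal(sum(ogs$fractions), 1, tolerance = 1e-6)
})

test_that("decomposition matches an exhaustive fraction-grid oracle", {
  s <- seq(0.005, 0.3, 0.002)
  FF <- build_formfactor_table(list(body("sphere", r = 20),
                                    body("sphere", r = 50)), s)
  itrue <- 0.45 * FF$ff[, 1] + 0.55 * FF$ff[, 2]
  dat <- simulate_curve(scattering_curve(s, itrue), s,
                        noise_model(0.01, seed = 13))
  og <- oligomer_fractions(dat, FF, normalize = TRUE)
  # 0.01-step grid search over the simplex, weighted residual oracle
  grid <- seq(0, 1, by = 0.01)
  w <- 1 / dat$sigma
  rss <- vapply(grid, function(f)
    sum(((f * FF$ff[, 1] + (1 - f) * FF$ff[, 2] - dat$i) * w)^2),
    numeric(1))
  f_star <- grid[which.min(rss)]
  expect_lte(abs(og$fractions[1] - f_star), 0.01 + 1e-9)
})

test_that("form-factor tables assemble, round-trip and stay consistent", {
  s <- seq(0.005, 0.3, 0.005)
  tb <- build_formfactor_table(list(body("sphere", r = 20),
                                    body("sphere", r = 35),
                                    body("cylinder", r = 10, l = 60)), s)
  expect_identical(ncol(tb$ff), 3L)
  expect_equal(tb$ff[, 1], body_intensity(body("sphere", r = 20), s)$i,
               tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".dat")
  write_ff_table(tb, path)
  expect_identical(ncol(read_ff_table(path)$ff), 3L)
  expect_equal(read_ff_table(path)$ff, tb$ff,
               tolerance = 1e-6, ignore_attr = TRUE)
  # tabulated component narrower than the grid refuses
  narrow <- scattering_curve(s[5:20], tb$ff[5:20, 1])
  expect_error(build_formfactor_table(list(narrow), s), "support")
})

test_that("singular values count scattering components", {
  s <- seq(0.005, 0.3, 0.0015)
  comps <- list(body("sphere", r = 20), body("sphere", r = 50),
                body("cylinder", r = 15, l = 80))
  FF <- vapply(comps, function(b)
    body_intensity(b, s, normalized = TRUE)$i, numeric(length(s)))
  weights <- rbind(1 + cos(1:10), 1 + sin(2 * (1:10)), (1:10) / 5)
  curves <- lapply(1:10, function(k) {
    ii <- as.numeric(FF %*% weights[, k])
    simulate_curve(scattering_curve(s, ii), s, noise_model(0))
  })
  sr <- svd_rank(curves, normalize_by_sigma = FALSE)
  expect_identical(sr$n_significant, 3L)
  expect_lt(sr$singular_values[4] / sr$singular_values[1], 1e-8)
  # seeded pure noise reports zero components
  noise <- lapply(1:8, function(k)
    simulate_curve(scattering_curve(s, rep(1, length(s)),
                                    sigma = rep(1, length(s))),
                   s, noise_model(1, seed = 60 + k)))
  for (k in seq_along(noise)) noise[[k]]$i <- noise[[k]]$i - 1
  expect_identical(svd_rank(noise, seed = 9)$n_significant, 0L)
  # sigma-normalized counting is invariant under rescaling
  sr1 <- svd_rank(curves, normalize_by_sigma = TRUE, seed = 2)
  big <- lapply(curves, function(cv) {
    cv$i <- cv$i * 10; cv$sigma <- cv$sigma * 10; cv
  })
  sr2 <- svd_rank(big, normalize_by_sigma = TRUE, seed = 2)
  expect_identical(sr1$n_significant, sr2$n_significant)
})
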