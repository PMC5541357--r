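test_that("noise-free sphere inversion matches the analytic p(r)", {
  s <- seq(0.008, 0.35, 0.0015)
  crv <- exact_curve(body("sphere", r = 30), s)
  sol <- ift_solve(crv, dmax = 60)
  pan <- sphere_pr(sol$pr$r, 30)
  expect_lt(max(abs(sol$pr$p - pan)) / max(pan), 0.02)
  expect_lt(abs(sol$rg - sphere_rg_true(30)) / sphere_rg_true(30), 0.01)
  expect_equal(sol$pr$r[1], 0)
  expect_equal(sol$pr$r[length(sol$pr$r)], 60)
})

test_that("the stored fit is the exact forward transform of p(r)", {
  s <- seq(0.01, 0.3, 0.002)
  crv <- simulate_curve(body("sphere", r = 30), s, noise_model(0.02, seed = 5))
  sol <- ift_solve(crv, dmax = 60, alpha = 1e-5)
  # independent reconstruction of the forward operator
  r <- sol$pr$r
  h <- r[2] - r[1]
  w <- rep(h, length(r)); w[c(1, length(r))] <- h / 2
  fwd <- vapply(s, function(sv) {
    x <- sv * r
    sn <- ifelse(x == 0, 1, sin(x) / x)
    4 * pi * sum(w * sn * sol$pr$p)
  }, numeric(1))
  expect_lt(max(abs(fwd - sol$fit$i)) / max(abs(sol$fit$i)), 1e-8)
})

test_that("degenerate and noisy inversions behave as specified", {
  s <- seq(0.01, 0.3, 0.002)
  zero <- scattering_curve(s, rep(0, length(s)), sigma = rep(1, length(s)))
  solz <- ift_solve(zero, dmax = 50, alpha = 1e-3)
  expect_identical(max(abs(solz$pr$p)), 0)
  crv <- simulate_curve(body("sphere", r = 30), s, noise_model(0.02, seed = 9))
  sol <- ift_solve(crv, dmax = 60)
  expect_gt(sol$chi2_reduced, 0.7)
  expect_lt(sol$chi2_reduced, 1.3)
  expect_gt(min(sol$pr$p), -0.01 * max(sol$pr$p))
  nos <- crv; nos$sigma <- NULL
  expect_error(ift_solve(nos, dmax = 60), "sigma")
  expect_error(ift_solve(crv, dmax = -1), "dmax")
})

test_that("fit discrepancy is monotone in the regularization weight", {
  s <- seq(0.01, 0.3, 0.002)
  crv <- simulate_curve(body("sphere", r = 30), s, noise_model(0.02, seed = 2))
  chi2 <- vapply(10^seq(-8, 2, by = 1), function(a)
    ift_solve(crv, dmax = 60, alpha = a)$chi2_reduced, numeric(1))
  expect_true(all(diff(chi2) >= -1e-8))
})

test_that("perceptual criteria score the documented trivial cases", {
  s <- seq(0.01, 0.3, 0.002)
  crv <- simulate_curve(body("sphere", r = 30), s, noise_model(0.02, seed = 4))
  sol <- ift_solve(crv, dmax = 60)
  cs <- criteria_scores(sol)
  expect_true(all(unlist(cs$criteria) >= 0 & unlist(cs$criteria) <= 1))
  expect_equal(cs$total, mean(unlist(cs$criteria)))
  # non-negative p implies POSITV = 1
  solp <- sol
  solp$pr$p <- abs(solp$pr$p)
  solp$criteria <- NULL
  csp <- criteria_scores(solp)
  expect_equal(csp$criteria$POSITV, 1)
  # 10% negative absolute area implies POSITV = 0.9
  r <- sol$pr$r
  p <- rep(1, length(r)); p[r > 0.9 * 60] <- -1
  soln <- sol; soln$pr$p <- p; soln$criteria <- NULL
  csn <- criteria_scores(soln)
  expect_equal(csn$criteria$POSITV, 0.9, tolerance = 0.02)
  # alternating residual signs give SYSDEV = 1
  sola <- sol
  sola$criteria <- NULL
  sola$fit$i <- sola$data$i - sola$data$sigma * rep_len(c(1, -1),
                                                        length(s)) * 0.1
  csa <- criteria_scores(sola)
  expect_identical(csa$criteria$SYSDEV, 1.0)
})

test_that("automatic dmax recovers sphere and dumbbell dimensions", {
  s <- seq(0.008, 0.30, 0.0015)
  sph <- exact_curve(body("sphere", r = 30), s, rel_sigma = 0.005)
  sol <- auto_dmax(sph)
  expect_lt(abs(sol$pr$dmax - 60) / 60, 0.05)
  db <- exact_curve(body("dumbbell", r1 = 15, r2 = 15, d = 60), s,
                    rel_sigma = 0.005)
  sol2 <- auto_dmax(db)
  expect_lt(abs(sol2$pr$dmax - 90) / 90, 0.05)
})

test_that("automatic dmax is robust to 2% noise", {
  s <- seq(0.008, 0.30, 0.002)
  errs <- vapply(1:20, function(k) {
    crv <- simulate_curve(body("sphere", r = 30), s,
                          noise_model(0.02, seed = 500 + k))
    abs(auto_dmax(crv)$pr$dmax - 60) / 60
  }, numeric(1))
  expect_lt(stats::median(errs), 0.08)
})

test_that("p(r) moments follow the closed forms and homogeneity", {
  r <- seq(0, 60, length.out = 601)
  pr <- list(r = r, p = sphere_pr(r, 30))
  m <- pr_moments(pr)
  expect_lt(abs(m$rg - sphere_rg_true(30)), 0.1)
  v <- 4 / 3 * pi * 30^3
  expect_lt(abs(m$i0 - v^2) / v^2, 1e-3)
  m2 <- pr_moments(list(r = r, p = 2 * pr$p))
  expect_equal(m2$i0, 2 * m$i0, tolerance = 1e-12)
  expect_equal(m2$rg, m$rg, tolerance = 1e-12)
  expect_error(pr_moments(list(r = r, p = rep(0, length(r)))),
               "non-positive")
})

test_that("sphere-kernel size distributions resolve mono- and bimodal mixtures", {
  s <- seq(0.005, 0.3, 0.0015)
  mono <- simulate_curve(body("sphere", r = 30), s, noise_model(0.01, seed = 3))
  sd1 <- size_distribution_solve(mono, 5, 80, nbins = 40)
  binw <- diff(sd1$radii[1:2])
  expect_lte(abs(sd1$radii[which.max(sd1$dv)] - 30), binw)
  expect_true(all(sd1$dv >= 0))
  # equal-volume 20/50 mixture: intensity weights proportional to volume
  v20 <- 4 / 3 * pi * 20^3; v50 <- 4 / 3 * pi * 50^3
  mx <- mixture_model(list(body("sphere", r = 20), body("sphere", r = 50)),
                      fractions = c(1 / v20, 1 / v50))
  bi <- simulate_curve(mx, s, noise_model(0.01, seed = 4))
  sd2 <- size_distribution_solve(bi, 5, 80, nbins = 40)
  dv <- sd2$dv
  peaks <- which(diff(sign(diff(c(-1, dv, -1)))) == -2)
  top2 <- sort(sd2$radii[peaks[order(dv[peaks], decreasing = TRUE)][1:2]])
  expect_lte(abs(top2[1] - 20), binw)
  expect_lte(abs(top2[2] - 50), binw)
  # zero data give the zero distribution
  zero <- scattering_curve(s, rep(0, length(s)), sigma = rep(1, length(s)))
  expect_identical(max(size_distribution_solve(zero, 5, 80, 30,
                                               alpha = 1)$dv), 0)
})
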