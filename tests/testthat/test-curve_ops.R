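make_replicates <- function(n_rep, seed0 = 20, rel = 0.02) {
  s <- seq(0.01, 0.4, length.out = 120)
  lapply(seq_len(n_rep), function(k)
    simulate_curve(body("sphere", r = 25), s,
                   noise_model(rel, seed = seed0 + k)))
}

test_that("averaging follows inverse-variance statistics", {
  reps <- make_replicates(4)
  # equal sigmas: sigma_out = sigma / 2 for four replicates
  avg <- average_curves(reps)
  expect_equal(avg$sigma, reps[[1]]$sigma / 2, tolerance = 1e-12)
  # two identical curves: same curve back, sigma / sqrt(2)
  two <- average_curves(list(reps[[1]], reps[[1]]))
  expect_equal(two$i, reps[[1]]$i, tolerance = 1e-12)
  expect_equal(two$sigma, reps[[1]]$sigma / sqrt(2), tolerance = 1e-12)
  # grid mismatch and missing sigma refuse
  off <- reps[[2]]; off$s[5] <- off$s[5] * 1.01
  expect_error(average_curves(list(reps[[1]], off)), "grid mismatch")
  nos <- reps[[2]]; nos$sigma <- NULL
  expect_error(average_curves(list(reps[[1]], nos)), "sigma")
})

test_that("averaging many noise realizations converges to the model", {
  s <- seq(0.01, 0.4, length.out = 120)
  model <- body_intensity(body("sphere", r = 25), s)$i
  reps <- make_replicates(40, seed0 = 300)
  avg <- average_curves(reps)
  z <- (avg$i - model) / avg$sigma
  expect_lt(mean(abs(z) > 3), 0.01)  # pointwise 3 sigma, allow rare tails
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
})

test_that("curve arithmetic propagates first-order errors", {
  reps <- make_replicates(2)
  a <- reps[[1]]
  z <- arith(a, a, "sub")
  expect_equal(z$i, rep(0, length(a$s)))
  expect_equal(z$sigma, a$sigma * sqrt(2), tolerance = 1e-12)
  m <- arith(a, 2, "mul")
  expect_equal(m$i, 2 * a$i)
  expect_equal(m$sigma, 2 * a$sigma)
  withzero <- a; withzero$i[3] <- 0
  expect_error(arith(a, withzero, "div"), "zero")
})

test_that("scale and shift matching recovers exact linear relations", {
  a <- make_replicates(1, rel = 0)[[1]]
  dbl <- arith(a, 2, "mul")
  ss <- scale_shift_match(a, dbl)
  expect_equal(ss$factor, 2, tolerance = 1e-12)
  expect_identical(ss$shift, 0)
  shifted <- arith(a, 5, "add")
  ss2 <- scale_shift_match(a, shifted, allow_shift = TRUE)
  expect_equal(ss2$factor, 1, tolerance = 1e-9)
  expect_equal(ss2$shift, 5, tolerance = 1e-6 * max(a$i))
  few <- crop(a, smax = a$s[4])
  expect_error(scale_shift_match(few, few), "overlap")
})

test_that("noisy scale recovery matches the closed-form weighted fit", {
  s <- seq(0.01, 0.4, length.out = 150)
  ref <- simulate_curve(body("sphere", r = 25), s, noise_model(0.01, seed = 1))
  target <- simulate_curve(body("sphere", r = 25), s,
                           noise_model(0.01, seed = 2), scale = 1 / 3)
  ss <- scale_shift_match(target, ref)
  # independent closed-form weighted least-squares oracle
  w <- 1 / ref$sigma^2
  oracle <- sum(w * target$i * ref$i) / sum(w * target$i^2)
  expect_equal(ss$factor, oracle, tolerance = 1e-12)
  expect_lt(abs(ss$factor - 3) / 3, 0.01)
})

test_that("merging scales the high curve onto the low curve", {
  s <- seq(0.01, 0.4, length.out = 200)
  low <- simulate_curve(body("sphere", r = 25), s, noise_model(0))
  high <- arith(low, 0.5, "mul")
  mr <- merge_ranges(low, high)
  expect_equal(mr$scale_applied, 2, tolerance = 1e-9)
  expect_equal(mr$merged$i,
               stats::approx(low$s, low$i, xout = mr$merged$s)$y,
               tolerance = 1e-9 * max(low$i))
  # idempotence on identical inputs
  mi <- merge_ranges(low, low)
  expect_equal(mi$merged$i, stats::approx(low$s, low$i,
                                          xout = mi$merged$s)$y,
               tolerance = 1e-12 * max(low$i))
  expect_setequal(unique(mi$source_map), c("low", "high"))
})

test_that("a structure-factor dip in the high curve is replaced by the low curve", {
  s <- seq(0.01, 0.4, length.out = 200)
  low <- simulate_curve(body("sphere", r = 25), s, noise_model(0))
  dip <- hard_sphere_sf(s, eta = 0.15, r_hs = 32)
  high <- low
  high$i <- 4 * low$i * dip
  high$sigma <- 4 * low$sigma
  mr <- merge_ranges(low, high, low_keep = c(0.01, 0.15),
                     high_keep = c(0.1, 0.4))
  lo_part <- mr$source_map == "low"
  expect_true(all(mr$merged$s[lo_part] <= mean(c(0.1, 0.15)) + 1e-9))
  expect_equal(mr$merged$i[lo_part],
               stats::approx(low$s, low$i, xout = mr$merged$s[lo_part])$y,
               tolerance = 1e-9 * max(low$i))
  expect_error(merge_ranges(low, high, low_keep = c(0.01, 0.05),
                            high_keep = c(0.3, 0.4)), "overlap")
})

test_that("zero-concentration extrapolation is exact for linear models", {
  s <- seq(0.01, 0.3, length.out = 80)
  i0 <- body_intensity(body("sphere", r = 25), s)$i
  kc <- 0.08
  concs <- c(1, 2, 4, 8)
  curves <- lapply(concs, function(cc)
    scattering_curve(s, cc * i0 * (1 - kc * cc), sigma = 1e-3 * cc * i0,
                     meta = list(concentration = cc)))
  ext <- extrapolate_zero_concentration(curves)
  expect_equal(ext$i, i0, tolerance = 5e-3)
  # exactly proportional series: intercept equals I/c of any input
  prop <- lapply(concs, function(cc)
    scattering_curve(s, cc * i0, sigma = 1e-3 * cc * i0,
                     meta = list(concentration = cc)))
  ext2 <- extrapolate_zero_concentration(prop)
  expect_equal(ext2$i, i0, tolerance = 1e-9 * max(i0))
  expect_error(extrapolate_zero_concentration(prop[1]), "at least 2")
  expect_error(extrapolate_zero_concentration(list(prop[[1]], prop[[1]])),
               "distinct")
})

test_that("cropping retains the closed interval", {
  s <- seq(0.01, 0.5, by = 0.01)
  crv <- scattering_curve(s, seq_along(s), sigma = rep(1, length(s)))
  cc <- crop(crv, 0.1, 0.3)
  expect_length(cc$s, 21L)
  expect_equal(crop(crv, 0, 1)$i, crv$i)
  expect_error(crop(crv, 0.6, 0.7), "fewer than 2")
  expect_error(crop(crv, 0.3, 0.1), "smin")
})

test_that("regridding bins and interpolates as specified", {
  s <- seq(0.01, 0.4, length.out = 100)
  crv <- scattering_curve(s, 100 - s * 100, sigma = rep(0.5, 100))
  b2 <- regrid(crv, "bin-by-k", 2)
  expect_length(b2$s, 50L)
  expect_equal(b2$s[1], mean(s[1:2]))
  expect_equal(b2$sigma, rep(0.5 / sqrt(2), 50), tolerance = 1e-12)
  same <- regrid(crv, "template-grid", crv)
  expect_equal(same$i, crv$i, tolerance = 1e-12)
  tpl <- scattering_curve(c(0.1, 0.45), c(1, 1))
  expect_error(regrid(crv, "template-grid", tpl), "support")
})

test_that("absolute-scale calibration uses the water plateau", {
  s <- seq(0.01, 0.4, length.out = 100)
  sample <- scattering_curve(s, exp(-100 * s^2), sigma = rep(1e-3, 100))
  water <- scattering_curve(s, rep(0.01632, 100))
  cal <- to_absolute_scale(sample, water, plateau_range = c(0.1, 0.3))
  expect_equal(cal$i, sample$i, tolerance = 1e-12)
  water2 <- scattering_curve(s, rep(2 * 0.01632, 100))
  cal2 <- to_absolute_scale(sample, water2, plateau_range = c(0.1, 0.3))
  expect_equal(cal2$i, sample$i / 2, tolerance = 1e-12)
  neg <- scattering_curve(s, rep(-1, 100))
  expect_error(to_absolute_scale(sample, neg, plateau_range = c(0.1, 0.3)),
               "plateau")
})
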