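# Shared fixtures and independent oracles for the test suite.

# Exhaustive enumeration oracle for the longest-run null distribution:
# walks all 2^n sign strings and counts those with a run of length >= C.
brute_longest_run_pvalue <- function(n, C) {
  hits <- 0L
  for (x in 0:(2^n - 1L)) {
    bits <- as.integer(intToBits(x))[seq_len(n)]
    if (max(rle(bits)$lengths) >= C) hits <- hits + 1L
  }
  hits / 2^n
}

# Noise-free model curve with a realistic error column: constant relative
# error plus a small additive floor (0.1% of the forward intensity), as on
# a real detector -- without the floor, points at the deep interference
# minima of ideal bodies would carry unphysical near-zero errors.
exact_curve <- function(model, s_grid, rel_sigma = 0.01) {
  crv <- simulate_curve(model, s_grid, noise_model(0))
  crv$sigma <- rel_sigma * (abs(crv$i) + 1e-3 * max(abs(crv$i)))
  crv
}

sphere_rg_true <- function(radius) sqrt(3 / 5) * radius

# Analytic infinite-cylinder cross-section curve (radius R): the rod
# Guinier variant applies to I(s) ~ [2 J1(sR)/(sR)]^2 / s.
rod_cross_section_curve <- function(radius, s_grid, rel_sigma = 0.01) {
  I <- (2 * besselJ(s_grid * radius, 1) / (s_grid * radius))^2 / s_grid
  scattering_curve(s_grid, I, sigma = rel_sigma * I)
}

# Analytic flat-sheet curve (thickness T): the sheet variant applies to
# I(s) ~ sinc^2(s T/2) / s^2.
sheet_curve <- function(thickness, s_grid, rel_sigma = 0.01) {
  y <- s_grid * thickness / 2
  I <- (sin(y) / y)^2 / s_grid^2
  scattering_curve(s_grid, I, sigma = rel_sigma * I)
}
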