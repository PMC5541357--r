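#' Exact longest-run p-value (correlation-map test)
#'
#' Null distribution of the longest same-sign run in `n` independent fair
#' Bernoulli trials. A binary string of length `n` whose maximal runs are
#' all at most `m` is determined by its first symbol (2 choices) and a
#' composition of `n` into parts of size at most `m`; counting compositions
#' by the recurrence `K_m(n) = sum_{j=1..min(m,n)} K_m(n-j)` and dividing by
#' `2^n` gives the exact probability. The recurrence is run directly in
#' probability space (each term carries its `2^-j` weight) with a sliding
#' window sum, so it is O(n), free of integer overflow and stable for
#' `n` up to at least 1e4.
#'
#' @param n number of trials (compared points), `n >= 1`.
#' @param C run length of interest, `1 <= C <= n`.
#' @return `P(longest run >= C)`, exact to double precision.
#' @examples
#' longest_run_pvalue(5, 5)   # 2/32
#' longest_run_pvalue(10, 4)  # 476/1024
#' @export
longest_run_pvalue <- function(n, C) {
  n <- as.integer(n); C <- as.integer(C)
  if (length(n) != 1L || length(C) != 1L || is.na(n) || is.na(C)) {
    stop("n and C must be scalar integers", call. = FALSE)
  }
  if (C < 1L || C > n) stop("C must satisfy 1 <= C <= n", call. = FALSE)
  if (C == 1L) return(1.0)
  m <- C - 1L
  # t[k] = K_m(k) / 2^k; window[j] accumulates t[k-j]/2^j for j = 1..m
  t <- numeric(n + 1L)
  t[1L] <- 1.0  # t[k+1] stores t(k); t(0) = 1
  acc <- 0.0
  half_m <- 0.5^m
  for (k in seq_len(n)) {
    # acc(k) = sum_{j=1..min(m,k)} t(k-j)/2^j
    acc <- 0.5 * (t[k] + acc)
    if (k > m) acc <- acc - t[k - m] * half_m * 0.5
    t[k + 1L] <- acc
  }
  p <- 1 - 2 * t[n + 1L]
  min(max(p, 0), 1)
}

#' Reduced chi-squared comparison of two curves
#'
#' Classical error-weighted discrepancy between two curves on a common
#' grid: `chi2_red = sum((Ia - Ib)^2 / sigma^2) / nu` with
#' `nu = n - 1 - dof_extra`. When both curves carry errors they are
#' combined in quadrature; at least one must have them.
#'
#' @param a,b [scattering_curve()]s on the same grid.
#' @param dof_extra extra degrees of freedom absorbed by any prior fitting
#'   (e.g. a scale factor); default 0.
#' @return List of class `chi2_result`: `chi2_reduced`, `dof`, `n_points`,
#'   `p_value` (upper tail of the chi-squared distribution).
#' @export
reduced_chi2 <- function(a, b, dof_extra = 0L) {
  check_same_grid(a, b)
  if (is.null(a$sigma) && is.null(b$sigma)) {
    stop("reduced chi2 requires sigma on at least one curve", call. = FALSE)
  }
  var_comb <- (if (is.null(a$sigma)) 0 else a$sigma^2) +
    (if (is.null(b$sigma)) 0 else b$sigma^2)
  n <- length(a$s)
  nu <- n - 1L - as.integer(dof_extra)
  if (nu < 1L) stop("fewer than 1 degree of freedom", call. = FALSE)
  stat <- sum((a$i - b$i)^2 / var_comb)
  structure(list(chi2_reduced = stat / nu, dof = nu, n_points = n,
                 p_value = stats::pchisq(stat, df = nu, lower.tail = FALSE)),
            class = "chi2_result")
}

#' Correlation-map (longest-run) test between two curves
#'
#' Error-free comparison: the signs of the pointwise differences
#' `Ia - Ib` are reduced to their longest same-sign run `C`, whose exact
#' null probability under a fair-sign hypothesis is
#' [longest_run_pvalue()]. Exact zero differences are assigned positive
#' sign; this is deterministic and documented because real measurements
#' essentially never tie.
#'
#' @param a,b [scattering_curve()]s on the same grid.
#' @return List of class `cormap_result`: `n`, `C` (longest run),
#'   `p_value`.
#' @export
cormap_test <- function(a, b) {
  check_same_grid(a, b)
  n <- length(a$s)
  if (n < 2L) stop("need at least 2 points", call. = FALSE)
  sgn <- ifelse(a$i - b$i >= 0, 1L, -1L)
  C <- max(rle(sgn)$lengths)
  structure(list(n = n, C = C, p_value = longest_run_pvalue(n, C)),
            class = "cormap_result")
}

# Internal: paired Student t-test on standardized differences, reported for
# reference alongside the chi2 and correlation-map tests.
ttest_curves <- function(a, b) {
  check_same_grid(a, b)
  if (is.null(a$sigma) && is.null(b$sigma)) {
    stop("t-test requires sigma on at least one curve", call. = FALSE)
  }
  var_comb <- (if (is.null(a$sigma)) 0 else a$sigma^2) +
    (if (is.null(b$sigma)) 0 else b$sigma^2)
  z <- (a$i - b$i) / sqrt(var_comb)
  ht <- stats::t.test(z, mu = 0)
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Pairwise statistical comparison of a set of curves
#'
#' Applies the chosen two-curve test to every pair and returns the matrix of
#' (optionally Bonferroni-adjusted) p-values. The Bonferroni factor is the
#' number of distinct pairs `m = k(k-1)/2`; adjusted values are capped at 1.
#'
#' @param curves list of at least 2 [scattering_curve()]s on a common grid.
#' @param method `"cormap"`, `"chi2"` or `"ttest"`.
#' @param adjustment `"bonferroni"` or `"none"`.
#' @return Symmetric `k x k` matrix of adjusted p-values with unit diagonal.
#' @export
compare_set <- function(curves, method = c("cormap", "chi2", "ttest"),
                        adjustment = c("bonferroni", "none")) {
  method <- match.arg(method)
  adjustment <- match.arg(adjustment)
  k <- length(curves)
  if (k < 2L) stop("need at least 2 curves", call. = FALSE)
  for (j in 2:k) check_same_grid(curves[[1L]], curves[[j]])
  m <- k * (k - 1L) / 2
  fac <- if (adjustment == "bonferroni") m else 1
  p <- diag(1, k)
  for (i1 in 1:(k - 1L)) {
    for (i2 in (i1 + 1L):k) {
      pr <- switch(method,
        cormap = cormap_test(curves[[i1]], curves[[i2]])$p_value,
        chi2 = reduced_chi2(curves[[i1]], curves[[i2]])$p_value,
        ttest = ttest_curves(curves[[i1]], curves[[i2]])$p_value)
      p[i1, i2] <- p[i2, i1] <- min(1, pr * fac)
    }
  }
  nm <- names(curves)
  if (!is.null(nm)) dimnames(p) <- list(nm, nm)
  p
}
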