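kBT300 <- 0.0083144621 * 300

test_that("zero and constant mean force integrate to the expected PMF", {
  s <- seq(0, 2, by = 0.01)
  f0 <- mean_force_profile(s, rep(0, length(s)))
  expect_equal(pmf_from_mean_force(f0)$W, rep(0, length(s)))

  fc <- mean_force_profile(s, rep(3, length(s)))
  pmf <- pmf_from_mean_force(fc, s0 = 2)
  # W(s) = -int_{s0}^{s} c ds' = c * (s0 - s) = 3 * (2 - s)
  expect_equal(pmf$W, 3 * (2 - s), tolerance = 1e-12)
  expect_identical(pmf$W[length(s)], 0)
})

test_that("integrated force matches the closed-form antiderivative of an
           analytic well", {
  s <- seq(0, 2, by = 0.002)
  # force of the Gaussian well W(s) = -A exp(-(s-c)^2 / 2sig^2):
  # F = -dW/ds (mean force on the adsorbate)
  A <- 15; ctr <- 0.5; sig <- 0.12
  Wfun <- function(s) -A * exp(-(s - ctr)^2 / (2 * sig^2))
  Ffun <- function(s) -A * exp(-(s - ctr)^2 / (2 * sig^2)) *
    (s - ctr) / sig^2
  pmf <- pmf_from_mean_force(mean_force_profile(s, Ffun(s)), s0 = 2)
  expect_equal(pmf$W, Wfun(s) - Wfun(2), tolerance = 1e-4)
})

test_that("flat and constant-well PMFs give the analytic free energy", {
  s <- seq(0, 2, by = 0.01)
  flat <- pmf_profile(s, rep(0, length(s)))
  expect_identical(adsorption_free_energy(flat), 0)
  for (w in c(2, 7.5, 20)) {
    well <- suppressWarnings(pmf_profile(s, rep(-w, length(s)), tol = Inf))
    for (ls in c(0, 0.3, 1.2))
      expect_equal(adsorption_free_energy(well, layer_start = ls), -w,
                   tolerance = 1e-9)
  }
})

test_that("Gaussian-well free energy matches a fine-grid quadrature oracle", {
  s <- seq(0, 2, by = 0.002)
  A <- 20; sig <- 0.1; ctr <- 0.4
  Wfun <- function(x) -A * exp(-(x - ctr)^2 / (2 * sig^2))
  pmf <- suppressWarnings(pmf_profile(s, Wfun(s), tol = Inf))
  dg <- adsorption_free_energy(pmf, layer_start = 0)
  expect_equal(dg, oracle_dg(Wfun, 0), tolerance = 1e-3)
})

test_that("free energy is monotone in pointwise well depth and converges
           under grid refinement", {
  ctr <- 0.4; sig <- 0.1
  Wfun <- function(x, A) -A * exp(-(x - ctr)^2 / (2 * sig^2))
  s <- seq(0, 2, by = 0.002)
  dgs <- vapply(c(5, 10, 20, 30), function(A)
    adsorption_free_energy(
      suppressWarnings(pmf_profile(s, Wfun(s, A), tol = Inf)),
      layer_start = 0), 0)
  expect_true(all(diff(dgs) < 0))

  coarse <- adsorption_free_energy(
    suppressWarnings(pmf_profile(seq(0, 2, 0.004), Wfun(seq(0, 2, 0.004),
                                                        20), tol = Inf)),
    layer_start = 0)
  fine <- adsorption_free_energy(
    suppressWarnings(pmf_profile(seq(0, 2, 0.002), Wfun(seq(0, 2, 0.002),
                                                        20), tol = Inf)),
    layer_start = 0)
  expect_lt(abs(coarse - fine), 5e-3)
})

test_that("free energy is reference-independent once W(s0) = 0 is enforced", {
  s <- seq(0, 2, by = 0.002)
  Wfun <- function(x) -18 * exp(-(x - 0.4)^2 / 0.02)
  f <- mean_force_profile(s, 18 * exp(-(s - 0.4)^2 / 0.02) *
                            (s - 0.4) / 0.01)
  dg1 <- adsorption_free_energy(pmf_from_mean_force(f, s0 = 2),
                                layer_start = 0)
  dg2 <- adsorption_free_energy(pmf_from_mean_force(f, s0 = 1.8),
                                layer_start = 0)
  expect_equal(dg1, dg2, tolerance = 1e-6)
})

test_that("window envelopes collapse for identical windows and are
           symmetric for mirrored ones", {
  pmf <- generate_pmf(depth = 10, noise_sd = 0)
  wb <- windowed_bounds(list(pmf, pmf, pmf))
  expect_equal(wb$dg_min, wb$dg)
  expect_equal(wb$dg_max, wb$dg)

  s <- seq(0, 2, 0.01)
  W <- sin(s * 4) * 2; W <- W - W[length(W)]
  up <- suppressWarnings(pmf_profile(s, W, tol = Inf))
  dn <- suppressWarnings(pmf_profile(s, -W, tol = Inf))
  wb <- windowed_bounds(list(up, dn), layer_start = 0.2)
  # mean PMF is identically zero, so the central value is the flat-PMF 0
  # and the envelopes are the symmetric curves -/+ |W| * sqrt(2); the
  # reported dg_min/dg_max must equal the free energies of those curves
  expect_equal(wb$dg, 0, tolerance = 1e-12)
  env <- abs(W) * sqrt(2)   # sd of {W, -W} at each grid point
  dg_lo <- adsorption_free_energy(
    suppressWarnings(pmf_profile(s, -env, tol = Inf)), layer_start = 0.2)
  dg_hi <- adsorption_free_energy(
    suppressWarnings(pmf_profile(s, env, tol = Inf)), layer_start = 0.2)
  expect_equal(wb$dg_min, min(dg_lo, dg_hi, 0), tolerance = 1e-9)
  expect_equal(wb$dg_max, max(dg_lo, dg_hi, 0), tolerance = 1e-9)
})

test_that("envelope spread shrinks with window noise", {
  mk <- function(noise, seeds) lapply(seeds, function(sd)
    generate_pmf(depth = 15, noise_sd = noise, seed = sd))
  spread <- function(noise) {
    wb <- windowed_bounds(mk(noise, 1:5), layer_start = 0.1)
    wb$dg_max - wb$dg_min
  }
  expect_gt(spread(2), spread(0.2))
  expect_gt(spread(0.2), 0)
})

test_that("windowed bounds reject mismatched grids and single windows", {
  p1 <- generate_pmf(depth = 5, noise_sd = 0)
  p2 <- generate_pmf(depth = 5, grid = seq(0, 2, 0.01), noise_sd = 0)
  expect_error(windowed_bounds(list(p1)), "at least two")
  expect_error(windowed_bounds(list(p1, p2)), "common grid")
})

test_that("profile text round-trips and comment lines are skipped", {
  p <- withr::local_tempfile(fileext = ".dat")
  s <- seq(0, 1, 0.05); v <- sin(s)
  write_profile(s, v, p, header = "s [nm]  W [kJ/mol]")
  df <- read_profile(p)
  expect_equal(df$s, s, tolerance = 1e-9)
  expect_equal(df$value, v, tolerance = 1e-9)
  writeLines(c("# comment", "0.1 2.0", "0.2 not-a-number"), p)
  expect_error(read_profile(p), "non-numeric")
})

test_that("layer placement and grid violations are reported", {
  s <- seq(0, 0.5, 0.01)
  pmf <- pmf_profile(s, rep(0, length(s)))
  expect_error(adsorption_free_energy(pmf), "shorter than")
  s <- seq(0, 2, 0.01)
  pmf <- pmf_profile(s, rep(0, length(s)))
  expect_error(adsorption_free_energy(pmf, layer_start = 1.5), "exceeds")
  expect_error(pmf_from_mean_force(mean_force_profile(s, rep(0, 201)),
                                   s0 = 3), "outside")
})
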