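# Free-energy extraction from mean-force / PMF profiles.
#
# Profiles live on an ascending grid of surface separation distance (SSD,
# nm). The PMF W(s) is the integral of the negative average force from a
# far reference s0 where the force has decayed; the adsorption free energy
# is a Boltzmann average of exp(-W/kBT) over an adsorption layer of width
# delta (0.8 nm by default).

#' Boltzmann constant in kJ/(mol K)
#' @keywords internal
.KB_KJMOL <- 0.0083144621

#' Thermodynamic parameters for adsorption free-energy evaluation
#'
#' @param delta adsorption layer thickness, nm. Default 0.8.
#' @param temperature absolute temperature, K. Default 300.
#' @return list with `delta`, `temperature` and the derived `kBT` (kJ/mol).
#' @export
fe_params <- function(delta = 0.8, temperature = 300) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0,
            is.numeric(temperature), length(temperature) == 1L,
            temperature > 0)
  list(delta = delta, temperature = temperature,
       kBT = .KB_KJMOL * temperature)
}

.check_grid <- function(s, v, what) {
  if (length(s) < 2L) stop("profile needs at least 2 grid points",
                           call. = FALSE)
  if (length(s) != length(v))
    stop("grid and ", what, " differ in length", call. = FALSE)
  if (any(!is.finite(s)) || any(!is.finite(v)))
    stop("non-finite entries in profile", call. = FALSE)
  if (any(diff(s) <= 0))
    stop("SSD grid must be strictly increasing", call. = FALSE)
}

#' Mean-force profile along the surface separation distance
#'
#' @param s ascending SSD grid, nm.
#' @param force average force on the adsorbate at each `s`, kJ/mol/nm.
#' @return object of class `mean_force_profile`.
#' @export
mean_force_profile <- function(s, force) {
  .check_grid(s, force, "force")
  structure(list(s = as.numeric(s), force = as.numeric(force)),
            class = "mean_force_profile")
}

#' Potential-of-mean-force profile
#'
#' @param s ascending SSD grid, nm.
#' @param W potential of mean force, kJ/mol, with `W(s0) = 0`.
#' @param s0 reference distance (nm) where the PMF is pinned to zero.
#' @param tol tolerance on `|W(s0)|`.
#' @return object of class `pmf_profile`.
#' @export
pmf_profile <- function(s, W, s0 = max(s), tol = 1e-8) {
  .check_grid(s, W, "W")
  if (s0 < min(s) || s0 > max(s))
    stop("s0 outside the SSD grid", call. = FALSE)
  w0 <- stats::approx(s, W, xout = s0)$y
  if (abs(w0) > tol)
    warning(sprintf("W(s0) = %.3g kJ/mol, not zero within tol", w0))
  structure(list(s = as.numeric(s), W = as.numeric(W), s0 = s0),
            class = "pmf_profile")
}

#' Integrate a mean-force profile into a PMF
#'
#' Computes `W(s) = -integral_{s0}^{s} <F(s')> ds'` by trapezoidal
#' quadrature on the supplied grid and pins `W(s0) = 0`.
#'
#' @param f a [mean_force_profile()].
#' @param s0 reference distance, nm; must lie within the grid, in a region
#'   where the average force is negligibly small.
#' @return a [pmf_profile()].
#' @export
pmf_from_mean_force <- function(f, s0 = max(f$s)) {
  stopifnot(inherits(f, "mean_force_profile"))
  if (s0 < min(f$s) || s0 > max(f$s))
    stop("s0 outside the SSD grid", call. = FALSE)
  cw <- -as.numeric(pracma::cumtrapz(f$s, f$force))
  w0 <- stats::approx(f$s, cw, xout = s0)$y
  pmf_profile(f$s, cw - w0, s0 = s0)
}

# Boltzmann layer average of exp(-W/kBT) over [a, b]: trapezoid on the
# grid nodes inside the layer plus linearly interpolated boundary values,
# normalized by the trapezoid of the constant 1 on the same nodes (equal
# to the layer width delta analytically, and float-exact for a flat PMF).
.boltzmann_layer_average <- function(s, W, a, b, kBT) {
  inside <- s > a & s < b
  ss <- c(a, s[inside], b)
  ww <- c(stats::approx(s, W, xout = a)$y, W[inside],
          stats::approx(s, W, xout = b)$y)
  pracma::trapz(ss, exp(-ww / kBT)) / pracma::trapz(ss, rep(1, length(ss)))
}

#' Adsorption free energy from a PMF
#'
#' Evaluates `dG = -kBT * log( (1/delta) * integral exp(-W(s)/kBT) ds )`
#' over the adsorption layer `[layer_start, layer_start + delta]` by
#' trapezoidal quadrature. A flat PMF gives exactly 0; negative values mean
#' favorable binding.
#'
#' @param pmf a [pmf_profile()].
#' @param params a [fe_params()] list.
#' @param layer_start left edge of the adsorption layer, nm. Default: the
#'   grid point of minimum `W` minus `delta/2`, clipped so the layer fits
#'   the grid.
#' @return adsorption free energy, kJ/mol.
#' @export
adsorption_free_energy <- function(pmf, params = fe_params(),
                                   layer_start = NULL) {
  stopifnot(inherits(pmf, "pmf_profile"))
  s <- pmf$s; W <- pmf$W
  if (max(s) - min(s) < params$delta)
    stop("grid shorter than the adsorption layer", call. = FALSE)
  if (is.null(layer_start)) {
    layer_start <- s[which.min(W)] - params$delta / 2
    layer_start <- min(max(layer_start, min(s)), max(s) - params$delta)
  }
  a <- layer_start; b <- layer_start + params$delta
  if (a < min(s) - 1e-12 || b > max(s) + 1e-12)
    stop("adsorption layer exceeds the PMF grid", call. = FALSE)
  -params$kBT * log(.boltzmann_layer_average(s, W, a, b, params$kBT))
}

#' Free energy with window-based uncertainty envelopes
#'
#' Takes PMFs evaluated over independent simulation windows on a common
#' grid, forms the pointwise mean PMF and mean +/- `n_sd` standard
#' deviations envelopes, and evaluates the adsorption free energy for all
#' three. Because the Boltzmann average is nonlinear, the three free
#' energies are re-sorted so `dg_min <= dg_max`.
#'
#' @param window_pmfs list of at least two [pmf_profile()]s on an identical
#'   grid.
#' @param params a [fe_params()] list.
#' @param layer_start as in [adsorption_free_energy()]; when `NULL` the
#'   layer is placed from the mean PMF and reused for the envelopes.
#' @param n_sd envelope half-width in standard deviations (default 1).
#' @return list with `dg` (mean PMF), `dg_min`, `dg_max` (kJ/mol).
#' @export
windowed_bounds <- function(window_pmfs, params = fe_params(),
                            layer_start = NULL, n_sd = 1) {
  if (length(window_pmfs) < 2L)
    stop("need at least two windows", call. = FALSE)
  s <- window_pmfs[[1L]]$s
  for (p in window_pmfs) {
    stopifnot(inherits(p, "pmf_profile"))
    if (!isTRUE(all.equal(p$s, s, tolerance = 1e-12)))
      stop("window PMFs are not on a common grid", call. = FALSE)
  }
  Wm <- do.call(rbind, lapply(window_pmfs, `[[`, "W"))
  mu <- colMeans(Wm)
  sd <- apply(Wm, 2L, stats::sd)
  s0 <- window_pmfs[[1L]]$s0
  mean_pmf <- pmf_profile(s, mu, s0 = s0, tol = Inf)
  if (is.null(layer_start)) {
    layer_start <- s[which.min(mu)] - params$delta / 2
    layer_start <- min(max(layer_start, min(s)), max(s) - params$delta)
  }
  dg <- adsorption_free_energy(mean_pmf, params, layer_start)
  dg_lo <- adsorption_free_energy(
    pmf_profile(s, mu - n_sd * sd, s0 = s0, tol = Inf), params, layer_start)
  dg_hi <- adsorption_free_energy(
    pmf_profile(s, mu + n_sd * sd, s0 = s0, tol = Inf), params, layer_start)
  rng <- range(c(dg, dg_lo, dg_hi))
  list(dg = dg, dg_min = rng[1L], dg_max = rng[2L])
}

#' Read a two-column whitespace profile (distance, value)
#'
#' Lines starting with `#` are ignored (the dialect of free-energy output
#' files produced by common biased-sampling toolchains).
#'
#' @param path file path.
#' @return data.frame with columns `s` and `value`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("line ", bad[1L], " does not have two columns", call. = FALSE)
  s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(s) || anyNA(v)) stop("non-numeric profile entry", call. = FALSE)
  data.frame(s = s, value = v)
}

#' Write a two-column whitespace profile
#'
#' @param s,value numeric vectors of equal length.
#' @param path output path.
#' @param header optional comment written as a leading `#` line.
#' @return `path`, invisibly.
#' @export
write_profile <- function(s, value, path, header = NULL) {
  stopifnot(length(s) == length(value))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste("#", header), con)
  writeLines(sprintf("%.10g %.10g", s, value), con)
  invisible(path)
}
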