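# Synthetic adsorption data with planted group structure.
#
# The generator emulates the qualitative structure of the measured
# fingerprint dataset: a small group of aromatic/cyclic molecules binding
# strongly to hydrophobic carbon surfaces, a small group of anionic
# molecules binding selectively to charged/polar surfaces, a broad
# remainder group, plus additive per-molecule and per-material offsets and
# ~0.5 kJ/mol Gaussian noise.

#' Default group-interaction effects (kJ/mol)
#'
#' Rows: molecule groups (aromatic, remainder, anionic); columns: material
#' groups (hydrophobic carbon, polar, charged). Every between-group
#' contrast is at least 15 kJ/mol.
#' @keywords internal
.default_interaction <- function() {
  matrix(c(-30,  -8,  -4,
           -10,  -7,  -3,
            -5,  -8, -26),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("aromatic", "remainder", "anionic"),
                         c("hydrophobic", "polar", "charged")))
}

#' Configuration of the synthetic fingerprint generator
#'
#' Cell values follow `mu + a_i + b_j + gamma[g(i), h(j)] + eps_ij` with
#' `a`, `b` zero-mean normal offsets, `gamma` the group-interaction matrix
#' and `eps` Gaussian noise. Defaults plant three molecule groups (7/22/3)
#' and three material groups (6/19/8) with contrasts well above the noise.
#'
#' @param n_molecules,n_materials axis sizes.
#' @param molecule_group_sizes,material_group_sizes integer partitions of
#'   the axis sizes.
#' @param mu global mean free energy, kJ/mol.
#' @param molecule_offsets_sd,material_offsets_sd sd of the additive
#'   per-molecule / per-material offsets, kJ/mol.
#' @param interaction_effects group x group matrix of mean shifts, kJ/mol.
#' @param noise_sd sd of cellwise Gaussian noise, kJ/mol (default 0.5, the
#'   typical statistical uncertainty of the simulated free energies).
#' @param seed integer RNG seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_molecules = 32L, n_materials = 33L,
                             molecule_group_sizes = c(7L, 22L, 3L),
                             material_group_sizes = c(6L, 19L, 8L),
                             mu = -8, molecule_offsets_sd = 1.5,
                             material_offsets_sd = 1.5,
                             interaction_effects = .default_interaction(),
                             noise_sd = 0.5, seed = 1L) {
  if (sum(molecule_group_sizes) != n_molecules)
    stop("molecule_group_sizes must sum to n_molecules", call. = FALSE)
  if (sum(material_group_sizes) != n_materials)
    stop("material_group_sizes must sum to n_materials", call. = FALSE)
  if (any(molecule_group_sizes <= 0L) || any(material_group_sizes <= 0L))
    stop("group sizes must be positive", call. = FALSE)
  if (!is.matrix(interaction_effects) ||
      nrow(interaction_effects) != length(molecule_group_sizes) ||
      ncol(interaction_effects) != length(material_group_sizes) ||
      any(!is.finite(interaction_effects)))
    stop("interaction_effects must be a finite group x group matrix",
         call. = FALSE)
  stopifnot(noise_sd >= 0, molecule_offsets_sd >= 0,
            material_offsets_sd >= 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_materials = as.integer(n_materials),
                 molecule_group_sizes = as.integer(molecule_group_sizes),
                 material_group_sizes = as.integer(material_group_sizes),
                 mu = mu, molecule_offsets_sd = molecule_offsets_sd,
                 material_offsets_sd = material_offsets_sd,
                 interaction_effects = interaction_effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic fingerprint matrix with planted labels
#'
#' @param cfg a [synthetic_config()].
#' @return list with `matrix` (an [fe_matrix()] whose bounds are
#'   `value -/+ noise_sd`) and `planted`, a list carrying the ground truth:
#'   `molecule_group` / `material_group` (named integer vectors),
#'   `molecule_offsets`, `material_offsets`, `mu` and the interaction
#'   matrix.
#' @examples
#' sim <- generate_matrix(synthetic_config(seed = 7))
#' dim(sim$matrix)
#' table(sim$planted$molecule_group)
#' @export
generate_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    g <- rep(seq_along(cfg$molecule_group_sizes), cfg$molecule_group_sizes)
    h <- rep(seq_along(cfg$material_group_sizes), cfg$material_group_sizes)
    mol_ids <- sprintf("mol%02d", seq_len(cfg$n_molecules))
    mat_ids <- sprintf("mat%02d", seq_len(cfg$n_materials))
    a <- stats::rnorm(cfg$n_molecules, 0, cfg$molecule_offsets_sd)
    b <- stats::rnorm(cfg$n_materials, 0, cfg$material_offsets_sd)
    eps <- matrix(stats::rnorm(cfg$n_molecules * cfg$n_materials, 0,
                               cfg$noise_sd),
                  cfg$n_molecules, cfg$n_materials)
    vals <- cfg$mu + outer(a, b, `+`) + cfg$interaction_effects[cbind(
      rep(g, times = cfg$n_materials), rep(h, each = cfg$n_molecules))] + eps
    dim(vals) <- c(cfg$n_molecules, cfg$n_materials)
    dimnames(vals) <- list(mol_ids, mat_ids)
    m <- fe_matrix(vals, lower = vals - cfg$noise_sd,
                   upper = vals + cfg$noise_sd)
    planted <- list(
      molecule_group = stats::setNames(g, mol_ids),
      material_group = stats::setNames(h, mat_ids),
      molecule_offsets = stats::setNames(a, mol_ids),
      material_offsets = stats::setNames(b, mat_ids),
      mu = cfg$mu, interaction_effects = cfg$interaction_effects)
    list(matrix = m, planted = planted)
  })
}

#' Generate a toy PMF profile: Gaussian well plus optional noise
#'
#' `W(s) = -depth * exp(-(s - center)^2 / (2 width^2)) + noise`, pinned to
#' zero at the far end of the grid (the reference distance `s0`).
#'
#' @param depth well depth, kJ/mol (>= 0 for a well).
#' @param width Gaussian width sigma, nm.
#' @param center well center, nm.
#' @param grid ascending numeric SSD grid, nm; must extend at least
#'   `center + 4 * width` so the tail is flat.
#' @param noise_sd sd of pointwise Gaussian noise, kJ/mol.
#' @param seed integer RNG seed.
#' @return a [pmf_profile()].
#' @export
generate_pmf <- function(depth, width = 0.1, center = 0.4,
                         grid = seq(0, 2, by = 0.005), noise_sd = 0,
                         seed = 1L) {
  stopifnot(width > 0, noise_sd >= 0)
  if (any(diff(grid) <= 0) || length(grid) < 2L)
    stop("grid must be strictly increasing", call. = FALSE)
  if (max(grid) < center + 4 * width)
    stop("grid too short for a flat tail beyond the well", call. = FALSE)
  withr::with_seed(as.integer(seed), {
    W <- -depth * exp(-(grid - center)^2 / (2 * width^2))
    if (noise_sd > 0) W <- W + stats::rnorm(length(grid), 0, noise_sd)
    W <- W - W[length(W)]
    pmf_profile(grid, W, s0 = max(grid))
  })
}
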