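#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Produces a 32 x 33 adsorption free-energy matrix with three planted
# molecule groups (aromatic-like strong binders to hydrophobic carbon,
# small anionic selective binders, a broad remainder) and three planted
# material groups, plus ten toy PMF "windows" of a Gaussian-well profile
# as would come out of independent stretches of a biased simulation.

suppressMessages(library(bionanofp))

seed <- 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- synthetic_config(seed = seed)
sim <- generate_matrix(cfg)

jsonlite::write_json(unclass(cfg), file.path(out, "synthetic_config.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA,
                     matrix = "rowmajor")
write_fe_matrix(sim$matrix, file.path(out, "synthetic_dg_matrix.csv"))
utils::write.csv(
  data.frame(molecule = names(sim$planted$molecule_group),
             group = unname(sim$planted$molecule_group)),
  file.path(out, "planted_molecule_groups.csv"), row.names = FALSE)
utils::write.csv(
  data.frame(material = names(sim$planted$material_group),
             group = unname(sim$planted$material_group)),
  file.path(out, "planted_material_groups.csv"), row.names = FALSE)

grid <- seq(0, 2, by = 0.002)
for (k in 1:10) {
  pmf <- generate_pmf(depth = 20, width = 0.1, center = 0.4, grid = grid,
                      noise_sd = 0.5, seed = seed * 100 + k)
  write_profile(pmf$s, pmf$W,
                file.path(out, sprintf("pmf_window_%02d.dat", k)),
                header = "s [nm]   W [kJ/mol]  (toy Gaussian well, one window)")
}

cat("synthetic matrix:", nrow(sim$matrix$values), "molecules x",
    ncol(sim$matrix$values), "materials, noise", cfg$noise_sd, "kJ/mol\n")
cat("molecule groups:", paste(cfg$molecule_group_sizes, collapse = "/"),
    " material groups:", paste(cfg$material_group_sizes, collapse = "/"),
    "\n")
cat("wrote matrix, planted labels and 10 PMF windows under", out, "\n")
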