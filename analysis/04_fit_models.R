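#!/usr/bin/env Rscript
# Stage 4: regression models predicting the full fingerprint from probes.
#
# Fits LR, AdaBoost.R2 and the one-hidden-layer NN with the stage-3
# probes as features, over ten random 70/30 splits of the materials, and
# additionally runs the leakage-free protocol where clustering and probe
# selection are redone inside every training split.

suppressMessages(library(bionanofp))

seed <- 1L
out <- "results"
m <- read_fe_matrix(file.path(out, "synthetic_dg_matrix.csv"))
clust <- jsonlite::read_json(file.path(out, "molecule_clustering.json"))
probes <- unlist(clust$representatives, use.names = FALSE)

scheme <- split_scheme(test_fraction = 0.3, n_repeats = 10L, seed = seed)

evals <- list(
  lr = evaluate_features(m, probes, regressor_spec("lr", seed = seed),
                         scheme),
  adaboost = evaluate_features(m, probes,
                               regressor_spec("adaboost", seed = seed),
                               scheme),
  nn = suppressWarnings(
    evaluate_features(m, probes, regressor_spec("nn", seed = seed),
                      scheme)))

overall <- do.call(rbind, lapply(names(evals), function(f) {
  ov <- evals[[f]]$overall
  cbind(family = f, n_features = length(probes), ov)
}))

lf <- evaluate_leakage_free(m, 3, regressor_spec("lr", seed = seed),
                            scheme)
overall <- rbind(overall,
                 cbind(family = "lr_leakage_free",
                       n_features = length(lf$feature_ids), lf$overall))
utils::write.csv(overall, file.path(out, "model_performance.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  list(probes = probes,
       leakage_free_probe_stability = lf$representative_stability,
       overall = overall),
  file.path(out, "model_performance.json"),
  auto_unbox = TRUE, pretty = TRUE, digits = NA, dataframe = "rows")

per_mol <- do.call(rbind, lapply(names(evals), function(f)
  cbind(family = f, evals[[f]]$per_molecule)))
utils::write.csv(per_mol, file.path(out, "per_molecule_performance.csv"),
                 row.names = FALSE)

# coefficients of the LR model refit on all materials (probe -> response)
resp <- setdiff(m$molecule_ids, probes)
full_lr <- fit_regressor(regressor_spec("lr", seed = seed),
                         t(m$values[probes, ]), t(m$values[resp, ]))
utils::write.csv(lr_coefficients(full_lr),
                 file.path(out, "lr_coefficients.csv"), row.names = FALSE)

cat("probes:", paste(probes, collapse = ", "), "\n")
for (i in seq_len(nrow(overall)))
  cat(sprintf("%-16s %-5s R2 = %5.2f +/- %4.2f  MAE = %4.2f +/- %4.2f kJ/mol\n",
              overall$family[i], overall$set[i], overall$r2_mean[i],
              overall$r2_sd[i], overall$mae_mean[i], overall$mae_sd[i]))
cat("leakage-free probe-set stability:",
    lf$representative_stability, "\n")
cat("wrote model_performance.csv, per_molecule_performance.csv,",
    "lr_coefficients.csv under", out, "\n")
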