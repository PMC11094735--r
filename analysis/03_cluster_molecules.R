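#!/usr/bin/env Rscript
# Stage 3: cluster the biomolecules and pick probe molecules.
#
# Uses the fingerprint matrix from stage 1: PCA variance spectrum for the
# expected dimensionality, Ward dendrogram cut at k = 3, k-means elbow
# diagnostic, and one representative ("probe") molecule per cluster by
# closest distance to the cluster centroid. Recovery is scored against
# the planted labels.

suppressMessages(library(bionanofp))

seed <- 1L
out <- "results"
m <- read_fe_matrix(file.path(out, "synthetic_dg_matrix.csv"))
planted <- utils::read.csv(file.path(out, "planted_molecule_groups.csv"))
truth <- stats::setNames(planted$group, planted$molecule)

pv <- pca_variance(m)
utils::write.csv(
  data.frame(component = seq_along(pv$explained_variance_ratio),
             explained_variance_ratio = pv$explained_variance_ratio),
  file.path(out, "pca_variance.csv"), row.names = FALSE)

d <- molecule_distance_matrix(m)
tree <- ward_linkage(d)
as_newick(tree, file.path(out, "molecule_dendrogram.nwk"))
part <- cut_tree(tree, 3)

curve <- inertia_curve(m, ks = 1:8, seed = seed)
utils::write.csv(data.frame(k = curve$k, inertia = curve$inertia),
                 file.path(out, "kmeans_inertia.csv"), row.names = FALSE)
km <- kmeans_partition(m, 3, seed = seed)

reps <- select_representatives(m, part)
report <- list(
  pca_components_estimate = pv$n_components_estimate,
  kmeans_elbow_k = curve$suggested_k,
  ward_k3_ari_vs_planted = adjusted_rand_index(part, truth),
  kmeans_k3_ari_vs_planted = adjusted_rand_index(km$partition, truth),
  ward_vs_kmeans_ari = adjusted_rand_index(part, km$partition),
  representatives = as.list(stats::setNames(as.character(reps),
                                            paste0("cluster", names(reps)))))
jsonlite::write_json(report, file.path(out, "molecule_clustering.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
utils::write.csv(data.frame(molecule = names(part),
                            ward_k3 = unname(part),
                            kmeans_k3 = unname(km$partition[names(part)])),
                 file.path(out, "molecule_partitions.csv"),
                 row.names = FALSE)

cat("PCA suggests", pv$n_components_estimate, "components;",
    "k-means elbow at k =", curve$suggested_k, "\n")
cat("Ward k=3 ARI vs planted:", report$ward_k3_ari_vs_planted,
    "| k-means k=3 ARI:", report$kmeans_k3_ari_vs_planted, "\n")
cat("probe molecules:", paste(as.character(reps), collapse = ", "), "\n")
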