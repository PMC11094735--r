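# Grouping of nanomaterials from measured or model-predicted fingerprints,
# and quantitative agreement between the two groupings.

#' Ward clustering of nanomaterials
#'
#' Ward linkage on Euclidean distances between material columns (each
#' material described by the vector of molecule free energies binding to
#' it). Reuses the molecule-clustering engine on the transposed matrix.
#'
#' @param m an [fe_matrix()].
#' @param normalize passed to [molecule_distance_matrix()].
#' @return a [stats::hclust] tree over materials.
#' @export
cluster_materials <- function(m, normalize = c("euclidean", "rms")) {
  stopifnot(inherits(m, "fe_matrix"))
  ward_linkage(molecule_distance_matrix(t(m$values),
                                        normalize = match.arg(normalize)))
}

#' Replace response rows by model predictions
#'
#' Keeps the probe (feature) molecule rows as measured and replaces every
#' response row by the model's prediction for all materials, yielding the
#' matrix a practitioner would have after measuring only the probes.
#'
#' @param m an [fe_matrix()]; must contain the model's feature ids.
#' @param model a fitted `fe_model` trained on molecules of `m`.
#' @return an [fe_matrix()] (bounds dropped) with a `predicted` attribute:
#'   a named logical vector flagging which rows are model output.
#' @export
build_predicted_matrix <- function(m, model) {
  stopifnot(inherits(m, "fe_matrix"), inherits(model, "fe_model"))
  miss <- setdiff(c(model$feature_ids, model$response_ids),
                  m$molecule_ids)
  if (length(miss))
    stop("model molecule id not in matrix: ", miss[1L], call. = FALSE)
  X <- t(m$values[model$feature_ids, , drop = FALSE])
  P <- predict(model, X)                     # materials x responses
  vals <- m$values
  vals[model$response_ids, ] <- t(P)
  out <- fe_matrix(vals)
  attr(out, "predicted") <- stats::setNames(
    m$molecule_ids %in% model$response_ids, m$molecule_ids)
  out
}

#' Agreement between two linkage trees over the same leaves
#'
#' Cuts both trees at `k` and reports the adjusted Rand index between the
#' partitions, plus the cophenetic correlation between the trees'
#' cophenetic distance matrices.
#'
#' @param t1,t2 [stats::hclust] trees with identical label sets.
#' @param k number of clusters for the partition comparison.
#' @return list with `ari`, `cophenetic_correlation`, and the two
#'   partitions.
#' @export
compare_groupings <- function(t1, t2, k = 3L) {
  stopifnot(inherits(t1, "hclust"), inherits(t2, "hclust"))
  if (!setequal(t1$labels, t2$labels))
    stop("trees have different leaf sets", call. = FALSE)
  p1 <- cut_tree(t1, k)
  p2 <- cut_tree(t2, k)[names(p1)]
  c1 <- as.matrix(stats::cophenetic(t1))
  c2 <- as.matrix(stats::cophenetic(t2))[rownames(c1), colnames(c1)]
  lt <- lower.tri(c1)
  list(ari = adjusted_rand_index(p1, p2),
       cophenetic_correlation = stats::cor(c1[lt], c2[lt]),
       partition1 = p1, partition2 = p2)
}
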