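# Repeated random 70/30 train/test splitting over materials, R^2 / MAE
# metrics, aggregation, and the leakage-free protocol where molecule
# clustering and probe selection see only the training materials.

#' Shuffle-split scheme over materials
#'
#' Repeated independent random train/test partitions (not disjoint
#' cross-validation folds): each repeat draws a fresh random test set.
#'
#' @param test_fraction proportion of materials held out (default 0.3).
#' @param n_repeats number of random splits (default 10).
#' @param seed integer seed; split `i` uses the derived seed `seed + i`.
#' @return list of class `split_scheme`.
#' @export
split_scheme <- function(test_fraction = 0.3, n_repeats = 10L, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_repeats >= 1L)
  structure(list(test_fraction = test_fraction,
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "split_scheme")
}

#' Draw the train/test splits of a scheme
#'
#' Train size is `round((1 - test_fraction) * n)`; with 33 materials and a
#' 0.3 test fraction that is 23 train / 10 test.
#'
#' @param ids character vector of material ids (>= 4).
#' @param scheme a [split_scheme()].
#' @return list of `n_repeats` elements, each `list(train =, test =)`.
#' @export
make_splits <- function(ids, scheme) {
  stopifnot(inherits(scheme, "split_scheme"))
  n <- length(ids)
  if (n < 4L) stop("need at least 4 materials", call. = FALSE)
  n_train <- round((1 - scheme$test_fraction) * n)
  if (n_train < 1L || n_train >= n)
    stop("empty train or test set after rounding", call. = FALSE)
  lapply(seq_len(scheme$n_repeats), function(i) {
    withr::with_seed(scheme$seed + i, {
      tr <- sort(sample.int(n, n_train))
      list(train = ids[tr], test = ids[-tr])
    })
  })
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. Undefined for a
#' constant `y_true`; returned as `NA` with a warning rather than silently
#' zero.
#'
#' @param y_true,y_pred numeric vectors of equal length >= 2.
#' @return dimensionless scalar (<= 1; negative means worse than the mean
#'   predictor).
#' @export
r2_score <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    warning("R^2 undefined: y_true is constant")
    return(NA_real_)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Mean absolute error (kJ/mol)
#'
#' @param y_true,y_pred numeric vectors of equal length.
#' @return non-negative scalar.
#' @export
mae <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 1L)
  mean(abs(y_true - y_pred))
}

.metrics_row <- function(molecule, split, set, yt, yp) {
  data.frame(molecule = molecule, split = split, set = set,
             r2 = suppressWarnings(r2_score(yt, yp)),
             mae = mae(yt, yp), stringsAsFactors = FALSE)
}

.eval_one_split <- function(values, feature_ids, response_ids, spec,
                            split, split_index) {
  sp <- spec
  sp$seed <- spec$seed + split_index        # derived per-split seed
  Xtr <- t(values[feature_ids, split$train, drop = FALSE])
  Ytr <- t(values[response_ids, split$train, drop = FALSE])
  Xte <- t(values[feature_ids, split$test, drop = FALSE])
  Yte <- t(values[response_ids, split$test, drop = FALSE])
  model <- fit_regressor(sp, Xtr, Ytr)
  Ptr <- predict(model, Xtr)
  Pte <- predict(model, Xte)
  rows <- lapply(response_ids, function(mol) {
    rbind(.metrics_row(mol, split_index, "train", Ytr[, mol], Ptr[, mol]),
          .metrics_row(mol, split_index, "test", Yte[, mol], Pte[, mol]))
  })
  list(metrics = do.call(rbind, rows), model = model)
}

.aggregate_metrics <- function(metrics) {
  per_molecule <- do.call(rbind, lapply(
    split(metrics, metrics[c("molecule", "set")], drop = TRUE),
    function(d) data.frame(molecule = d$molecule[1L], set = d$set[1L],
                           r2_mean = mean(d$r2, na.rm = TRUE),
                           r2_sd = stats::sd(d$r2, na.rm = TRUE),
                           mae_mean = mean(d$mae),
                           mae_sd = stats::sd(d$mae))))
  rownames(per_molecule) <- NULL
  # overall: equal weight per molecule within each split, then mean +/- sd
  # over splits
  by_split <- do.call(rbind, lapply(
    split(metrics, metrics[c("split", "set")], drop = TRUE),
    function(d) data.frame(split = d$split[1L], set = d$set[1L],
                           r2 = mean(d$r2, na.rm = TRUE),
                           mae = mean(d$mae))))
  overall <- do.call(rbind, lapply(split(by_split, by_split$set),
    function(d) data.frame(set = d$set[1L],
                           r2_mean = mean(d$r2), r2_sd = stats::sd(d$r2),
                           mae_mean = mean(d$mae),
                           mae_sd = stats::sd(d$mae))))
  rownames(overall) <- NULL
  list(per_molecule = per_molecule, by_split = by_split,
       overall = overall)
}

#' Evaluate a regression family over repeated splits
#'
#' For each shuffle split: fits the model on the training materials,
#' predicts train and test, and computes per-molecule R^2 and MAE across
#' the materials of each set. R^2 is computed per molecule, then averaged
#' with equal weight over molecules within a split, then mean +/- sd over
#' splits (Table-style aggregates over all non-probe molecules).
#'
#' @param m an [fe_matrix()].
#' @param feature_ids probe molecule ids used as features; responses are
#'   all remaining molecules.
#' @param spec a [regressor_spec()].
#' @param scheme a [split_scheme()].
#' @return object of class `fe_eval`: `metrics` (long per-molecule x split
#'   data.frame), `per_molecule`, `by_split`, `overall` aggregates,
#'   `feature_ids`, `models` (one fitted model per split).
#' @export
evaluate_features <- function(m, feature_ids, spec,
                              scheme = split_scheme()) {
  stopifnot(inherits(m, "fe_matrix"))
  miss <- setdiff(feature_ids, m$molecule_ids)
  if (length(miss)) stop("unknown feature id: ", miss[1L], call. = FALSE)
  response_ids <- setdiff(m$molecule_ids, feature_ids)
  if (!length(response_ids)) stop("no response molecules", call. = FALSE)
  splits <- make_splits(m$material_ids, scheme)
  res <- lapply(seq_along(splits), function(i)
    .eval_one_split(m$values, feature_ids, response_ids, spec,
                    splits[[i]], i))
  metrics <- do.call(rbind, lapply(res, `[[`, "metrics"))
  agg <- .aggregate_metrics(metrics)
  structure(c(list(metrics = metrics, feature_ids = feature_ids,
                   response_ids = response_ids, splits = splits,
                   models = lapply(res, `[[`, "model")), agg),
            class = "fe_eval")
}

#' @export
print.fe_eval <- function(x, ...) {
  cat(sprintf("<fe_eval> %d features, %d responses, %d splits\n",
              length(x$feature_ids), length(x$response_ids),
              max(x$metrics$split)))
  ov <- x$overall
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  %-5s R2 = %5.2f +/- %.2f   MAE = %5.2f +/- %.2f kJ/mol\n",
                ov$set[i], ov$r2_mean[i], ov$r2_sd[i], ov$mae_mean[i],
                ov$mae_sd[i]))
  invisible(x)
}

#' Leakage-free evaluation: cluster, select and train on train materials
#'
#' For every split, molecule clustering (Ward, cut at `k`) and probe
#' selection are redone using only the training-material columns, so the
#' held-out materials are never seen at any stage.
#'
#' @param m an [fe_matrix()].
#' @param k number of molecule clusters (default 3).
#' @param spec a [regressor_spec()].
#' @param scheme a [split_scheme()].
#' @param extra_features molecule ids always appended to the selected
#'   representatives (e.g. poorly modeled charged probes).
#' @return an `fe_eval` with an additional `representatives` element (the
#'   per-split probe sets) and `representative_stability` (fraction of
#'   splits whose probe set equals the full-data set).
#' @export
evaluate_leakage_free <- function(m, k = 3L, spec,
                                  scheme = split_scheme(),
                                  extra_features = character(0)) {
  stopifnot(inherits(m, "fe_matrix"))
  splits <- make_splits(m$material_ids, scheme)
  full_reps <- select_representatives(
    m, cut_tree(ward_linkage(molecule_distance_matrix(m)), k))
  full_set <- sort(union(full_reps, extra_features))
  res <- list(); reps_by_split <- list(); metrics <- NULL
  for (i in seq_along(splits)) {
    sub <- fe_subset(m, materials = splits[[i]]$train)
    reps <- select_representatives(
      sub, cut_tree(ward_linkage(molecule_distance_matrix(sub)), k))
    feats <- sort(union(reps, extra_features))
    reps_by_split[[i]] <- feats
    responses <- setdiff(m$molecule_ids, feats)
    out <- .eval_one_split(m$values, feats, responses, spec,
                           splits[[i]], i)
    res[[i]] <- out
    metrics <- rbind(metrics, out$metrics)
  }
  agg <- .aggregate_metrics(metrics)
  stability <- mean(vapply(reps_by_split, function(r)
    setequal(r, full_set), logical(1L)))
  structure(c(list(metrics = metrics,
                   feature_ids = full_set,
                   response_ids = setdiff(m$molecule_ids, full_set),
                   splits = splits,
                   models = lapply(res, `[[`, "model"),
                   representatives = reps_by_split,
                   representative_stability = stability), agg),
            class = "fe_eval")
}
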