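#' Residualize CpG features against a purity proportion
#'
#' For every probe, fits an ordinary least-squares regression of beta on the
#' purity-associated LMC proportion. Where the slope is significant
#' (two-sided p < `alpha`), the feature becomes the residuals re-centered by
#' the fitted intercept (i.e. `beta - slope * purity`), removing
#' normal-cell signal while keeping the beta-scale location; otherwise the
#' raw beta passes through. The per-probe regression records are kept so new
#' samples can be adjusted with the training-time coefficients only.
#'
#' @param beta_sites Probes x samples beta matrix (the selected feature
#'   sites).
#' @param purity_proportion Per-sample purity-LMC proportion.
#' @param alpha Significance threshold for the slope.
#' @return List: `features` (adjusted probes x samples matrix), `records`
#'   (`data.frame(probe_id, slope, intercept, p_value, residualized)`).
#' @export
residualize_features <- function(beta_sites, purity_proportion, alpha = 0.05) {
  n <- ncol(beta_sites)
  if (length(purity_proportion) != n)
    stop2("purity_proportion length must equal the sample count")
  x <- as.numeric(purity_proportion)
  records <- data.frame(probe_id = rownames(beta_sites), slope = 0,
                        intercept = rowMeans(beta_sites), p_value = NA_real_,
                        residualized = FALSE, stringsAsFactors = FALSE)
  if (stats::sd(x) == 0) {
    warning("purity proportion is constant: no probe residualized")
    return(list(features = beta_sites, records = records))
  }
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.numeric(beta_sites %*% xc) / sxx
  intercept <- rowMeans(beta_sites) - slope * mean(x)
  fitted <- outer(slope, x) + intercept
  rss <- rowSums((beta_sites - fitted)^2)
  df <- n - 2
  se <- sqrt(rss / df / sxx)
  t <- slope / se
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0] <- 1
  resid_flag <- p < alpha
  features <- beta_sites
  features[resid_flag, ] <- beta_sites[resid_flag, , drop = FALSE] -
    outer(slope[resid_flag], x)
  records$slope <- ifelse(resid_flag, slope, 0)
  records$intercept <- intercept
  records$p_value <- p
  records$residualized <- resid_flag
  list(features = features, records = records)
}

#' Apply stored residualization records to new samples
#'
#' @param beta_sites Probes x samples beta matrix over the recorded probes.
#' @param records Regression records from [residualize_features()].
#' @param purity_proportion Per-sample purity-LMC proportion of the new
#'   samples.
#' @return Adjusted feature matrix.
#' @export
apply_residualization <- function(beta_sites, records, purity_proportion) {
  missing <- setdiff(records$probe_id, rownames(beta_sites))
  if (length(missing))
    stop2("probes absent from beta: ",
          paste(utils::head(missing, 5), collapse = ", "))
  b <- beta_sites[records$probe_id, , drop = FALSE]
  b - outer(records$slope, as.numeric(purity_proportion))
}

#' Random Forest configuration
#'
#' Defaults mirror a standard high-capacity probability forest for
#' methylation classifiers: 1500 trees, sqrt feature subsampling, Gini
#' splits, depth cap 12, out-of-bag scoring, seed 3.
#'
#' @param num_trees,max_depth,seed Forest size, depth cap, RNG seed.
#' @return List of class `"forest_config"`.
#' @export
forest_config <- function(num_trees = 1500, max_depth = 12, seed = 3L) {
  structure(list(num_trees = num_trees, max_depth = max_depth,
                 mtry = "sqrt", criterion = "gini", oob_score = TRUE,
                 seed = as.integer(seed)), class = "forest_config")
}

#' Train the tissue-of-origin Random Forest
#'
#' Fits a probability forest on the reference samples (the caller is
#' expected to exclude metastases and other query-only samples). Records
#' the out-of-bag accuracy and feature importances. Determinism: the same
#' data and seed give identical predictions.
#'
#' @param features Probes x samples feature matrix (typically
#'   purity-residualized betas).
#' @param labels Per-sample class labels.
#' @param config A [forest_config()].
#' @param records Optional residualization records to store with the model.
#' @param class_list Optional class ordering (default: sorted unique labels).
#' @return List of class `"origin_model"`: `forest` (ranger object),
#'   `class_list`, `feature_probe_ids`, `records`, `config`, `oob_score`,
#'   `importance`.
#' @export
train_origin_model <- function(features, labels, config = forest_config(),
                               records = NULL, class_list = NULL) {
  if (length(labels) != ncol(features))
    stop2("labels length must equal the sample count")
  if (anyNA(features)) stop2("features must be complete")
  tab <- table(labels)
  if (length(tab) < 2) stop2("need >= 2 classes")
  if (any(tab < 3))
    stop2("class below minimum size (3): ",
          paste(names(tab)[tab < 3], collapse = ", "))
  if (is.null(class_list)) class_list <- sort(names(tab))
  df <- as.data.frame(t(features), check.names = FALSE)
  feat_names <- paste0("f", seq_len(ncol(df)))   # ranger-safe column names
  names(df) <- feat_names
  df$.class <- factor(labels, levels = class_list)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = config$num_trees, mtry = floor(sqrt(nrow(features))),
    max.depth = config$max_depth, splitrule = "gini", probability = TRUE,
    importance = "impurity", seed = config$seed, num.threads = 1)
  oob_pred <- fit$predictions
  oob_label <- class_list[max.col(oob_pred, ties.method = "first")]
  importance <- stats::setNames(fit$variable.importance, rownames(features))
  structure(list(forest = fit, class_list = class_list,
                 feature_probe_ids = rownames(features),
                 feature_names = feat_names, records = records,
                 config = config,
                 oob_score = mean(oob_label == labels),
                 importance = importance),
            class = "origin_model")
}

#' Proportional prediction scores and argmax origin call
#'
#' Scores each sample with the forest's class-probability estimates
#' (tree-vote proportions); the highest value determines the predicted
#' organ site. Ties are broken by `class_list` order and flagged.
#'
#' @param model An [train_origin_model()] model.
#' @param features Probes x samples feature matrix over the model's feature
#'   probes (already residualized if the model was trained on residualized
#'   features; see [apply_residualization()]).
#' @return `data.frame` with `sample_id`, one score column per class,
#'   `predicted_label`, `top_score`, `tie`.
#' @export
predict_origin <- function(model, features) {
  stopifnot(inherits(model, "origin_model"))
  requireNamespace("ranger", quietly = TRUE)  # registers predict.ranger
  missing <- setdiff(model$feature_probe_ids, rownames(features))
  if (length(missing))
    stop2("features missing probes: ",
          paste(utils::head(missing, 5), collapse = ", "))
  X <- t(features[model$feature_probe_ids, , drop = FALSE])
  df <- as.data.frame(X, check.names = FALSE)
  names(df) <- model$feature_names
  scores <- stats::predict(model$forest, data = df,
                           num.threads = 1)$predictions
  scores <- scores[, model$class_list, drop = FALSE]
  scores <- scores / rowSums(scores)
  idx <- max.col(scores, ties.method = "first")
  top <- scores[cbind(seq_len(nrow(scores)), idx)]
  tie <- rowSums(abs(scores - top) < 1e-12) > 1
  out <- data.frame(sample_id = colnames(features), scores,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$predicted_label <- model$class_list[idx]
  out$top_score <- top
  out$tie <- tie
  rownames(out) <- NULL
  out
}

# Rank-based one-vs-rest AUC (Mann-Whitney with midranks).
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Stratified cross-validation with per-class one-vs-rest AUC
#'
#' Splits samples into class-stratified folds; for each fold, trains the
#' forest on the remainder and scores the held-out samples. Held-out scores
#' are pooled across folds and a one-vs-rest ROC AUC is computed per class,
#' together with the pooled confusion matrix.
#'
#' @param features Probes x samples feature matrix.
#' @param labels Per-sample class labels.
#' @param folds Number of folds (default 3).
#' @param config A [forest_config()].
#' @param seed Seed for the fold assignment.
#' @return List of class `"cv_report"`: `auc` (per class), `mean_auc`,
#'   `fold_assignments`, `confusion`, `scores` (pooled score matrix),
#'   `accuracy`.
#' @export
cross_validate <- function(features, labels, folds = 3,
                           config = forest_config(), seed = 1L) {
  tab <- table(labels)
  if (any(tab < folds))
    stop2("class smaller than fold count: ",
          paste(names(tab)[tab < folds], collapse = ", "))
  class_list <- sort(names(tab))
  assign <- stratified_folds(labels, folds, seed)
  n <- length(labels)
  scores <- matrix(NA_real_, n, length(class_list),
                   dimnames = list(colnames(features), class_list))
  pred <- character(n)
  for (f in seq_len(folds)) {
    hold <- assign == f
    model <- train_origin_model(features[, !hold, drop = FALSE],
                                labels[!hold], config,
                                class_list = class_list)
    p <- predict_origin(model, features[, hold, drop = FALSE])
    scores[hold, ] <- as.matrix(p[, class_list])
    pred[hold] <- p$predicted_label
  }
  auc <- vapply(class_list, function(cl)
    auc_rank(scores[, cl], labels == cl), numeric(1))
  confusion <- table(truth = factor(labels, class_list),
                     predicted = factor(pred, class_list))
  structure(list(auc = auc, mean_auc = mean(auc),
                 fold_assignments = assign, confusion = confusion,
                 scores = scores, accuracy = mean(pred == labels)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Cross-validation: mean one-vs-rest AUC %.3f, accuracy %.3f\n",
              x$mean_auc, x$accuracy))
  print(round(x$auc, 3))
  invisible(x)
}

#' Gradient-boosting feature funnel
#'
#' Fits a gradient-boosted tree model (softprob objective) on the full
#' feature set, ranks features by gain importance, keeps the `top_n` most
#' informative ones, retrains the Random Forest on that subset and compares
#' cross-validated AUC of the full and funneled pipelines. If the booster
#' uses fewer than `top_n` features, the remainder is filled by descending
#' feature variance.
#'
#' @param features Probes x samples feature matrix.
#' @param labels Per-sample class labels.
#' @param top_n Number of features to keep (default 404).
#' @param config A [forest_config()] for the downstream forests.
#' @param nrounds,max_depth,eta Booster parameters.
#' @param folds,seed Cross-validation settings for the comparison.
#' @return List: `selected` (probe ids), `importance` (named gain vector),
#'   `cv_full`, `cv_subset` (both [cross_validate()] reports),
#'   `mean_auc_difference` (full minus subset).
#' @export
boosting_feature_funnel <- function(features, labels, top_n = 404,
                                    config = forest_config(), nrounds = 50,
                                    max_depth = 6, eta = 0.3, folds = 3,
                                    seed = 1L) {
  if (top_n <= 0) stop2("top_n must be > 0")
  if (top_n > nrow(features)) stop2("top_n exceeds the feature count")
  class_list <- sort(unique(labels))
  y <- factor(labels, class_list)
  X <- t(features)
  colnames(X) <- rownames(features)
  bst <- xgboost::xgboost(
    x = X, y = y, objective = "multi:softprob", nrounds = nrounds,
    max_depth = max_depth, learning_rate = eta, nthreads = 1,
    seed = seed, verbosity = 0)
  imp <- xgboost::xgb.importance(model = bst)
  gain <- stats::setNames(imp$Gain, imp$Feature)
  ranked <- names(gain)
  if (length(ranked) < top_n) {
    rest <- setdiff(rownames(features), ranked)
    rest <- rest[order(-row_sds(features[rest, , drop = FALSE]))]
    ranked <- c(ranked, rest)
  }
  selected <- ranked[seq_len(top_n)]
  cv_full <- cross_validate(features, labels, folds, config, seed)
  cv_subset <- cross_validate(features[selected, , drop = FALSE], labels,
                              folds, config, seed)
  list(selected = selected, importance = gain, cv_full = cv_full,
       cv_subset = cv_subset,
       mean_auc_difference = cv_full$mean_auc - cv_subset$mean_auc)
}
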