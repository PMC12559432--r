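#' Build a tissue-of-origin reference model from a cohort
#'
#' End-to-end reference construction: probe filtering, site selection
#' (per-class differential + most variable), latent-component
#' deconvolution, LUMP purity scoring and purity-component flagging,
#' purity residualization of the top variable feature sites, Random Forest
#' training and stratified cross-validation. Only samples whose sample-sheet
#' `specimen` is `"tumor"` enter training; reference/normal specimens are
#' kept aside (they serve the CNA module).
#'
#' @param cohort A `"nen_cohort"` list (see [simulate_cohort()] /
#'   [read_fixture()]), or any list with `beta`, `manifest`,
#'   `sample_sheet`.
#' @param k Number of latent methylation components.
#' @param lambda Deconvolution regularization weight.
#' @param per_class_n,variable_n Site-selection sizes.
#' @param feature_n Number of most-variable selected sites used as
#'   classifier features.
#' @param alpha Residualization significance threshold.
#' @param deconvolve Set `FALSE` to skip deconvolution; features are then
#'   raw (non-residualized) betas.
#' @param n_restarts Deconvolution restarts.
#' @param folds Cross-validation folds.
#' @param config A [forest_config()].
#' @param seed Master seed; stages use fixed offsets from it.
#' @return List of class `"origin_reference"`: `model`
#'   ([train_origin_model()] result), `fit` (deconvolution), `purity`
#'   (annotation), `cv` (report), `selected_sites`, `feature_sites`,
#'   `filter_report`, `lump`, `seed`.
#' @export
run_build_reference <- function(cohort, k = 9, lambda = 0.01,
                                per_class_n = 500, variable_n = 5000,
                                feature_n = 2000, alpha = 0.05,
                                deconvolve = TRUE, n_restarts = 5,
                                folds = 3, config = forest_config(),
                                seed = 1L) {
  sheet <- cohort$sample_sheet
  man <- cohort$manifest
  cpg <- man$probe_id[man$probe_class == "cpg"]
  filt <- filter_probes(cohort$beta[intersect(rownames(cohort$beta), cpg), ,
                                    drop = FALSE], man)
  tumor <- sheet$sample_id[sheet$specimen == "tumor"]
  beta_t <- filt$beta[, tumor, drop = FALSE]
  labels <- sheet$class_label[match(tumor, sheet$sample_id)]

  sites <- deconvolution_site_selection(
    beta_t, labels, per_class_n = per_class_n,
    variable_n = min(variable_n, nrow(beta_t)))
  feature_sites <- top_variable_sites(beta_t[sites, , drop = FALSE],
                                      min(feature_n, length(sites)))

  fit <- NULL; purity <- NULL; lump <- NULL; records <- NULL
  features <- beta_t[feature_sites, , drop = FALSE]
  if (deconvolve) {
    fit <- fit_deconvolution(beta_t[sites, , drop = FALSE], k = k,
                             lambda = lambda, n_restarts = n_restarts,
                             seed = seed + 10L)
    lump_probes <- intersect(man$probe_id[man$lump_marker],
                             rownames(filt$beta))
    if (length(lump_probes)) {
      lump <- lump_score(filt$beta[, tumor, drop = FALSE], lump_probes)
      purity <- flag_purity_component(fit, lump)
    }
    if (!is.null(purity) && !is.na(purity$purity_lmc_index)) {
      res <- residualize_features(features,
                                  fit$A[purity$purity_lmc_index, ],
                                  alpha = alpha)
      features <- res$features
      records <- res$records
    }
  }
  model <- train_origin_model(features, labels, config, records = records)
  cv <- cross_validate(features, labels, folds = folds, config = config,
                       seed = seed + 20L)
  structure(list(model = model, fit = fit, purity = purity, cv = cv,
                 selected_sites = sites, feature_sites = feature_sites,
                 filter_report = filt$report, lump = lump, seed = seed),
            class = "origin_reference")
}

#' Predict tissue of origin for query samples
#'
#' Computes features for the query betas exactly as at training time — the
#' purity proportion of each query is estimated against the trained
#' component matrix, and the stored residualization coefficients are
#' applied (no training-time information is recomputed) — then scores the
#' forest. Rows are sorted by predicted class and descending top score.
#'
#' @param reference A [run_build_reference()] result.
#' @param beta Probes x query-samples beta matrix covering the model's
#'   feature probes.
#' @return Prediction `data.frame` as from [predict_origin()].
#' @export
run_predict <- function(reference, beta) {
  stopifnot(inherits(reference, "origin_reference"))
  model <- reference$model
  missing <- setdiff(model$feature_probe_ids, rownames(beta))
  if (length(missing))
    stop2("query beta lacks model probes: ",
          paste(utils::head(missing, 5), collapse = ", "))
  features <- beta[model$feature_probe_ids, , drop = FALSE]
  if (!is.null(model$records) && !is.null(reference$fit)) {
    A_new <- project_proportions(reference$fit,
                                 beta[rownames(reference$fit$T), ,
                                      drop = FALSE])
    purity_new <- A_new[reference$purity$purity_lmc_index, ]
    features <- apply_residualization(features, model$records, purity_new)
  }
  pred <- predict_origin(model, features)
  pred[order(pred$predicted_label, -pred$top_score), , drop = FALSE]
}

#' t-SNE embedding of the most variable sites
#'
#' Selects the `n_sites` most variable probes by standard deviation and
#' embeds the samples with t-SNE (defaults: 10,000 sites, 3,000 iterations,
#' perplexity 10). Seeded, hence reproducible.
#'
#' @param beta Probes x samples beta matrix.
#' @param n_sites Number of most-variable sites.
#' @param perplexity t-SNE perplexity; must be below `(samples - 1) / 3`.
#' @param iterations t-SNE iterations.
#' @param seed RNG seed.
#' @return `data.frame(sample_id, tsne1, tsne2)`.
#' @export
run_embedding <- function(beta, n_sites = 10000, perplexity = 10,
                          iterations = 3000, seed = 1L) {
  if (n_sites > nrow(beta))
    stop2("n_sites exceeds the probe count (", nrow(beta), ")")
  n <- ncol(beta)
  if (perplexity >= (n - 1) / 3)
    stop2("perplexity must be < (samples - 1) / 3 = ", (n - 1) / 3)
  sites <- top_variable_sites(beta, n_sites)
  X <- t(beta[sites, , drop = FALSE])
  emb <- with_seed(seed,
                   Rtsne::Rtsne(X, perplexity = perplexity,
                                max_iter = iterations, check_duplicates = FALSE,
                                pca = ncol(X) > 50, num_threads = 1))
  data.frame(sample_id = colnames(beta), tsne1 = emb$Y[, 1],
             tsne2 = emb$Y[, 2], stringsAsFactors = FALSE)
}

#' Scatter plot of an embedding colored by group
#'
#' @param embedding A [run_embedding()] result.
#' @param groups Per-sample group labels.
#' @param ... Passed to [graphics::plot()].
#' @return The embedding, invisibly.
#' @export
plot_embedding <- function(embedding, groups, ...) {
  g <- factor(groups)
  graphics::plot(embedding$tsne1, embedding$tsne2,
                 col = grDevices::rainbow(nlevels(g))[as.integer(g)],
                 pch = 19, xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  graphics::legend("topright", legend = levels(g), cex = 0.6, pch = 19,
                   col = grDevices::rainbow(nlevels(g)))
  invisible(embedding)
}

#' Read a proportional prediction-score table
#'
#' Reads a TSV of per-sample class prediction scores (the format written
#' for query predictions: identifier columns followed by one numeric score
#' column per class). The packaged worked example
#' `system.file("extdata", "hepatic_nen_scores.tsv", package =
#' "methorigin")` holds such a table for 22 hepatic NEN of unknown primary.
#'
#' @param path TSV path.
#' @param class_columns Names of the score columns; defaults to every
#'   numeric column whose values all lie in `[0, 1]` (proportional
#'   probabilities), which skips numeric metadata such as cluster indices.
#' @return List: `table` (the full data.frame), `scores` (samples x classes
#'   matrix), `class_list`.
#' @export
read_prediction_table <- function(path, class_columns = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (is.null(class_columns))
    class_columns <- names(df)[vapply(df, function(x)
      is.numeric(x) && all(x >= 0 & x <= 1, na.rm = TRUE), logical(1))]
  scores <- as.matrix(df[, class_columns, drop = FALSE])
  rownames(scores) <- if ("sample_id" %in% names(df)) df$sample_id
    else as.character(seq_len(nrow(df)))
  list(table = df, scores = scores, class_list = class_columns)
}

#' Summarize a prediction-score table by argmax class
#'
#' Applies the argmax rule (highest proportional score wins, ties to the
#' first class) to each row and tabulates the predicted classes, the
#' maximum single score in the table, and each row's top score.
#'
#' @param scores Samples x classes score matrix (or a
#'   [read_prediction_table()] result).
#' @return List: `predicted` (per-sample class), `counts` (named class
#'   counts, classes ordered as the columns), `top_scores`, `max_score`.
#' @export
summarize_predictions <- function(scores) {
  if (is.list(scores) && !is.null(scores$scores)) scores <- scores$scores
  idx <- max.col(scores, ties.method = "first")
  predicted <- colnames(scores)[idx]
  top <- scores[cbind(seq_len(nrow(scores)), idx)]
  counts <- vapply(colnames(scores), function(cl) sum(predicted == cl),
                   integer(1))
  list(predicted = stats::setNames(predicted, rownames(scores)),
       counts = counts, top_scores = top, max_score = max(scores))
}
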