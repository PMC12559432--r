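make_separable <- function(n_classes = 3, per_class = 12, p = 120, seed = 14,
                           noise = 0.05) {
  set.seed(seed)
  labels <- rep(paste0("C", seq_len(n_classes)), each = per_class)
  X <- matrix(runif(p * length(labels), 0.3, 0.7), p, length(labels),
              dimnames = list(sprintf("cg%04d", seq_len(p)),
                              sprintf("s%03d", seq_along(labels))))
  for (c in seq_len(n_classes)) {
    rows <- ((c - 1) * 10 + 1):(c * 10)
    X[rows, labels == paste0("C", c)] <-
      X[rows, labels == paste0("C", c)] + 0.3
  }
  X <- pmin(X + matrix(rnorm(length(X), 0, noise), nrow(X)), 1)
  list(X = pmax(X, 0), labels = labels)
}

test_that("purity residualization removes the purity association", {
  set.seed(8)
  n <- 60
  purity <- runif(n, 0, 0.6)
  probes <- sprintf("cg%03d", 1:3)
  beta <- rbind(0.5 + 0.4 * purity + rnorm(n, 0, 0.01),  # purity-driven
                runif(n, 0.4, 0.6),                       # independent
                0.3 + 0.4 * purity + rnorm(n, 0, 0.01))
  dimnames(beta) <- list(probes, sprintf("s%d", 1:n))
  res <- residualize_features(beta, purity)
  expect_true(res$records$residualized[1])
  expect_true(res$records$residualized[3])
  expect_false(res$records$residualized[2])
  expect_lt(abs(cor(res$features[1, ], purity)), 0.05)
  expect_identical(res$features[2, ], beta[2, ])
  # slope estimates recover the planted coefficient
  expect_equal(res$records$slope[1], 0.4, tolerance = 0.05)
  # constant purity: no-op with warning
  expect_warning(res0 <- residualize_features(beta, rep(0.3, n)), "constant")
  expect_identical(res0$features, beta)
})

test_that("prediction-time residualization uses stored coefficients only", {
  set.seed(9)
  n <- 40
  purity <- runif(n)
  beta <- matrix(0.4 + 0.3 * purity + rnorm(2 * n, 0, 0.01), 2, n,
                 byrow = TRUE, dimnames = list(c("a", "b"), sprintf("s%d", 1:n)))
  res <- residualize_features(beta, purity)
  newbeta <- matrix(c(0.7, 0.2), 2, 1, dimnames = list(c("a", "b"), "q1"))
  adj <- apply_residualization(newbeta, res$records, 0.5)
  # closed form: feature = beta - slope * purity, from the stored records
  expect_equal(unname(adj[, 1]),
               c(0.7, 0.2) - res$records$slope * 0.5)
})

test_that("forest training separates planted classes and is seeded", {
  d <- make_separable()
  model <- train_origin_model(d$X, d$labels)
  expect_gte(model$oob_score, 0.95)
  p1 <- predict_origin(model, d$X)
  p2 <- predict_origin(train_origin_model(d$X, d$labels), d$X)
  expect_identical(p1, p2)
  # scores live on the simplex
  sc <- as.matrix(p1[, model$class_list])
  expect_true(all(sc >= 0))
  expect_equal(rowSums(sc), rep(1, nrow(sc)), tolerance = 1e-9)
  expect_error(train_origin_model(d$X, rep(c("A", "B"), c(2, 34))),
               "minimum size")
})

test_that("shuffled labels give chance-level out-of-bag accuracy", {
  d <- make_separable(n_classes = 4, per_class = 30)
  set.seed(77)
  shuffled <- sample(d$labels)
  model <- train_origin_model(d$X, shuffled)
  expect_lt(abs(model$oob_score - 0.25), 0.1)
})

test_that("one-vs-rest AUC equals the Mann-Whitney statistic", {
  # 6-sample toy, hand-counted: pos {0.9, 0.8, 0.4} vs neg {0.7, 0.3, 0.2}
  # concordant pairs: 3 + 3 + 2 = 8 of 9
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  labels <- c("P", "P", "P", "N", "N", "N")
  feats <- matrix(0, 1, 6)
  expect_equal(methorigin:::auc_rank(scores, labels == "P"), 8 / 9)
  skip_if_not_installed("pROC")
  set.seed(15)
  s <- runif(40); y <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  expect_equal(methorigin:::auc_rank(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("stratified cross-validation reports per-class AUC and folds", {
  d <- make_separable()
  cv <- cross_validate(d$X, d$labels, folds = 3, seed = 5)
  expect_named(cv$auc, sort(unique(d$labels)))
  expect_true(all(cv$auc > 0.95))
  # stratification: every fold holds every class
  for (f in 1:3)
    expect_setequal(unique(d$labels[cv$fold_assignments == f]),
                    unique(d$labels))
  # label-independent scores give chance AUC
  set.seed(16)
  noise <- matrix(runif(120 * 36), 120, 36,
                  dimnames = dimnames(d$X))
  cvn <- cross_validate(noise, d$labels, folds = 3, seed = 5)
  expect_lt(abs(cvn$mean_auc - 0.5), 0.12)
  expect_error(cross_validate(d$X, rep(c("A", "B"), c(2, 34)), folds = 3),
               "smaller than fold")
})

test_that("argmax prediction semantics match the worked example", {
  classes <- c("Merkel cell carcinoma", "Appendiceal NEN", "Colorectal NEN",
               "Gastric/duodenal NEN", "Ileal NEN", "Pancreatic NEN",
               "Pulmonary NEC", "Pulmonary carcinoid")
  row <- matrix(c(0.022, 0.055, 0.040, 0.065, 0.627, 0.123, 0.015, 0.054),
                1, 8, dimnames = list("Patient #038", classes))
  s <- summarize_predictions(row)
  expect_equal(unname(s$predicted), "Ileal NEN")
  expect_equal(unname(s$top_scores), 0.627)
  # uniform scores: tie resolved to the first class
  u <- matrix(1 / 8, 1, 8, dimnames = list("q", classes))
  expect_equal(unname(summarize_predictions(u)$predicted), classes[1])
})

test_that("boosting funnel recovers planted informative features", {
  # 50 informative features with distinct class-mean patterns among 400
  set.seed(44)
  labels <- rep(paste0("C", 1:4), each = 15)
  X <- matrix(runif(400 * 60, 0.3, 0.7), 400, 60,
              dimnames = list(sprintf("cg%04d", 1:400),
                              sprintf("s%03d", 1:60)))
  planted <- sprintf("cg%04d", 1:50)
  for (r in 1:50) {
    offs <- rnorm(4, 0, 0.25)
    X[r, ] <- X[r, ] + offs[as.integer(factor(labels))]
  }
  X <- pmin(pmax(X, 0), 1)
  d <- list(X = X, labels = labels)
  fun <- boosting_feature_funnel(d$X, d$labels, top_n = 50, nrounds = 60,
                                 folds = 3, seed = 2)
  expect_gte(length(intersect(fun$selected, planted)), 45)
  expect_lt(abs(fun$mean_auc_difference), 0.05)
  # top_n = all features returns everything
  fun_all <- boosting_feature_funnel(d$X, d$labels, top_n = nrow(d$X),
                                     nrounds = 10, folds = 3, seed = 2)
  expect_setequal(fun_all$selected, rownames(d$X))
  expect_error(boosting_feature_funnel(d$X, d$labels, top_n = 0), "top_n")
})
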