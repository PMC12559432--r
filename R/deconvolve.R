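#' Euclidean projection of matrix columns onto the probability simplex
#'
#' Sorting-based projection: each column is mapped to the closest (in
#' Euclidean distance) vector with non-negative entries summing to 1.
#'
#' @param X Numeric matrix; columns are projected independently.
#' @return Matrix of the same shape with simplex columns.
#' @export
project_simplex_columns <- function(X) {
  k <- nrow(X); n <- ncol(X)
  if (k == 1) return(matrix(1, 1, n, dimnames = dimnames(X)))
  # sort each column descending without per-column apply
  U <- matrix(X[order(col(X), -X)], k, n)
  css <- U
  for (i in seq(2, k)) css[i, ] <- css[i - 1, ] + U[i, ]
  # the feasibility condition holds on a prefix of each sorted column,
  # so the largest feasible index is the per-column count
  cond <- U - sweep(css - 1, 1, seq_len(k), `/`) > 0
  rho <- colSums(cond)
  theta <- (css[cbind(rho, seq_len(n))] - 1) / rho
  out <- pmax(sweep(X, 2, theta), 0)
  dimnames(out) <- dimnames(X)
  out
}

# Solve min ||D - T A||_F^2 over A with simplex columns, T fixed, by
# projected gradient with step 1/L (monotone). Warm-started from A0.
update_proportions <- function(D, T, A0, inner = 60, inner_tol = 1e-10) {
  TtT <- crossprod(T)
  TtD <- crossprod(T, D)
  L <- 2 * max(eigen(TtT, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) return(A0)
  A <- A0
  for (i in seq_len(inner)) {
    G <- 2 * (TtT %*% A - TtD)
    A_new <- project_simplex_columns(A - G / L)
    if (max(abs(A_new - A)) < inner_tol) { A <- A_new; break }
    A <- A_new
  }
  A
}

# One full sweep of coordinate descent on T for
# min ||D - T A||_F^2 + lambda * sum T (1 - T), 0 <= T <= 1, A fixed.
# Each column update is the exact coordinate minimizer (boundary point when
# the coordinate problem is concave), so the objective never increases.
update_components <- function(D, T, A, lambda, sweeps = 2) {
  G <- tcrossprod(A)            # k x k
  C <- D %*% t(A)               # p x k
  k <- ncol(T)
  for (s in seq_len(sweeps)) {
    for (j in seq_len(k)) {
      r <- C[, j] - T[, -j, drop = FALSE] %*% G[-j, j] - lambda / 2
      denom <- G[j, j] - lambda
      if (denom > 1e-12) {
        T[, j] <- clip(r / denom)
      } else {
        # concave (or flat) in this coordinate: pick the better endpoint
        # f(t) = denom t^2 - 2 r t (+ const)
        T[, j] <- as.numeric(denom - 2 * r < 0)
      }
    }
  }
  T
}

deconv_objective <- function(D, T, A, lambda) {
  sum((D - T %*% A)^2) + lambda * sum(T * (1 - T))
}

# Furthest-point (kmeans++-style, deterministic) column seeding for T.
furthest_columns <- function(D, k) {
  n <- ncol(D)
  sel <- which.max(colSums(D^2))
  for (i in seq_len(k - 1)) {
    d2 <- vapply(seq_len(n), function(j)
      min(colSums((D[, sel, drop = FALSE] - D[, j])^2)), numeric(1))
    sel <- c(sel, which.max(d2))
  }
  sel
}

#' Deconvolve a beta matrix into latent methylation components
#'
#' Approximately minimizes
#' \deqn{\|D - TA\|_F^2 + \lambda \sum_{ij} T_{ij}(1 - T_{ij})}
#' subject to \eqn{0 \le T \le 1} and columns of \eqn{A} on the probability
#' simplex: \eqn{T} holds k latent methylation component (LMC) profiles and
#' \eqn{A} per-sample mixing proportions. The penalty drives component
#' entries toward 0/1, matching the bimodality of array methylation.
#' Optimization alternates an exact coordinate-descent step on T with
#' simplex-projected gradient steps on A; both steps are monotone, so the
#' recorded objective trace is non-increasing. The best of `n_restarts`
#' initializations is returned (restart 1 seeds T deterministically from
#' furthest-point data columns, the rest from uniform random matrices).
#'
#' @param D Probes x samples beta matrix, complete, values in `[0, 1]`.
#' @param k Number of components (>= 1).
#' @param lambda Bimodality regularization weight (>= 0).
#' @param n_restarts Number of random restarts.
#' @param max_iter Maximum alternating iterations per restart.
#' @param tol Relative objective-change stopping tolerance.
#' @param seed Seed; restart r uses `seed + r`.
#' @return A list of class `"deconvolution_fit"`: `T`, `A`, `k`, `lambda`,
#'   `objective`, `objective_trace` (best restart), `seed`, `n_restarts`.
#' @export
fit_deconvolution <- function(D, k, lambda = 0, n_restarts = 10,
                              max_iter = 200, tol = 1e-8, seed = 1L) {
  check_beta_matrix(D, allow_na = FALSE)
  if (k < 1) stop2("k must be >= 1")
  if (k > min(dim(D))) stop2("k exceeds min(dim(D))")
  if (lambda < 0) stop2("lambda must be >= 0")
  p <- nrow(D); n <- ncol(D)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    T <- if (r == 1) {
      # deterministic furthest-point seeding from data columns
      unname(D[, furthest_columns(D, k), drop = FALSE])
    } else {
      with_seed(seed + r, matrix(stats::runif(p * k), p, k))
    }
    A <- matrix(1 / k, k, n)
    trace <- deconv_objective(D, T, A, lambda)
    for (it in seq_len(max_iter)) {
      A <- update_proportions(D, T, A)
      T <- update_components(D, T, A, lambda)
      obj <- deconv_objective(D, T, A, lambda)
      trace <- c(trace, obj)
      prev <- trace[length(trace) - 1]
      if (prev - obj < tol * max(prev, 1e-300)) break
    }
    if (is.null(best) || obj < best$objective) {
      dimnames(T) <- list(rownames(D), paste0("LMC", seq_len(k)))
      dimnames(A) <- list(paste0("LMC", seq_len(k)), colnames(D))
      best <- list(T = T, A = A, k = k, lambda = lambda, objective = obj,
                   objective_trace = trace, seed = seed,
                   n_restarts = n_restarts, restart = r)
    }
  }
  structure(best, class = "deconvolution_fit")
}

#' @export
print.deconvolution_fit <- function(x, ...) {
  cat(sprintf(
    "Deconvolution fit: k = %d, lambda = %g, objective = %.6g (%d restarts)\n",
    x$k, x$lambda, x$objective, x$n_restarts))
  invisible(x)
}

#' Estimate mixing proportions of new samples against fixed components
#'
#' Solves the simplex-constrained least-squares problem for each new sample
#' given a trained component matrix; used to carry LMC proportions (e.g. the
#' purity component) to prediction-time samples.
#'
#' @param fit A [fit_deconvolution()] result (or a probes x k matrix).
#' @param beta Probes x samples beta matrix over the fit's probes.
#' @return k x samples proportion matrix with simplex columns.
#' @export
project_proportions <- function(fit, beta) {
  T <- if (inherits(fit, "deconvolution_fit")) fit$T else fit
  if (!all(rownames(T) %in% rownames(beta)))
    stop2("beta lacks probes of the component matrix")
  D <- beta[rownames(T), , drop = FALSE]
  A0 <- matrix(1 / ncol(T), ncol(T), ncol(D),
               dimnames = list(colnames(T), colnames(D)))
  update_proportions(D, T, A0, inner = 500)
}

#' LUMP-style purity score
#'
#' Mean beta over designated leukocyte-unmethylated probes, divided by a
#' scale constant and capped at 1. High values mean high tumor purity; the
#' complement `1 - lump` tracks leukocyte/normal-cell content.
#'
#' @param beta Probes x samples beta matrix.
#' @param lump_probes Probe ids of the leukocyte-unmethylated set.
#' @param scale Scale constant (default 0.85).
#' @return Named per-sample purity vector in `[0, 1]`.
#' @export
lump_score <- function(beta, lump_probes, scale = 0.85) {
  if (!length(lump_probes)) stop2("lump_probes must be non-empty")
  missing <- setdiff(lump_probes, rownames(beta))
  if (length(missing))
    stop2("lump probes absent from beta: ",
          paste(utils::head(missing, 5), collapse = ", "))
  pmin(1, colMeans(beta[lump_probes, , drop = FALSE]) / scale)
}

#' Flag the purity-associated latent component
#'
#' Correlates each LMC's proportion row with `1 - lump` (normal-cell
#' content). The component with the largest absolute Pearson correlation is
#' flagged when `|r| >= r_threshold`; a flagged component should be excluded
#' from downstream class-discriminative feature sets.
#'
#' @param fit A [fit_deconvolution()] result.
#' @param lump Per-sample purity scores aligned with the fit's samples.
#' @param r_threshold Minimum `|r|` to flag.
#' @return List of class `"purity_annotation"`: `lump`,
#'   `lmc_lump_correlations` (NA for zero-variance rows),
#'   `purity_lmc_index` (integer or NA).
#' @export
flag_purity_component <- function(fit, lump, r_threshold = 0.7) {
  stopifnot(inherits(fit, "deconvolution_fit"))
  if (length(lump) != ncol(fit$A))
    stop2("lump length must equal the fit's sample count")
  content <- 1 - lump
  rs <- apply(fit$A, 1, function(row) {
    if (stats::sd(row) == 0 || stats::sd(content) == 0) return(NA_real_)
    stats::cor(row, content)
  })
  idx <- NA_integer_
  if (any(!is.na(rs)) && max(abs(rs), na.rm = TRUE) >= r_threshold)
    idx <- unname(which.max(abs(rs)))
  structure(list(lump = lump, lmc_lump_correlations = rs,
                 purity_lmc_index = idx),
            class = "purity_annotation")
}

#' Match estimated components to reference components
#'
#' Finds the one-to-one assignment of estimated to reference components
#' maximizing the summed Pearson correlation (Hungarian assignment), e.g.
#' for recovery checks against known ground truth.
#'
#' @param T_hat,T_true Probes x k matrices with equal dimensions.
#' @return List: `permutation` (index into `T_hat` columns for each `T_true`
#'   column), `correlations` (matched Pearson r per reference component).
#' @export
match_components <- function(T_hat, T_true) {
  if (!identical(dim(T_hat), dim(T_true)))
    stop2("T_hat and T_true must have identical dimensions")
  C <- stats::cor(T_true, T_hat)
  sol <- clue::solve_LSAP(C + 1, maximum = TRUE)
  perm <- as.integer(sol)
  list(permutation = perm,
       correlations = C[cbind(seq_len(ncol(T_true)), perm)])
}

#' Cross-validated reconstruction error over k and lambda grids
#'
#' Holds out a fraction of samples, fits components on the rest, estimates
#' held-out proportions against the fixed components, and reports the mean
#' squared reconstruction error on the held-out samples — a lightweight
#' model-selection aid for `k` and `lambda`.
#'
#' @param D Probes x samples beta matrix.
#' @param ks Component counts to evaluate.
#' @param lambdas Regularization weights to evaluate.
#' @param holdout_frac Fraction of samples held out (default one quarter).
#' @param n_restarts,max_iter,seed Passed to [fit_deconvolution()].
#' @return `data.frame(k, lambda, cv_error)`.
#' @export
deconvolution_cv_error <- function(D, ks, lambdas = c(0, 0.001, 0.01, 0.1),
                                   holdout_frac = 0.25, n_restarts = 3,
                                   max_iter = 100, seed = 1L) {
  n <- ncol(D)
  hold <- with_seed(seed, sample(n, max(1, round(holdout_frac * n))))
  D_tr <- D[, -hold, drop = FALSE]
  D_ho <- D[, hold, drop = FALSE]
  grid <- expand.grid(k = ks, lambda = lambdas)
  grid$cv_error <- vapply(seq_len(nrow(grid)), function(i) {
    fit <- fit_deconvolution(D_tr, grid$k[i], grid$lambda[i],
                             n_restarts = n_restarts, max_iter = max_iter,
                             seed = seed)
    A_ho <- project_proportions(fit, D_ho)
    mean((D_ho - fit$T %*% A_ho)^2)
  }, numeric(1))
  grid
}

#' Serialize / load a deconvolution fit
#'
#' Writes `components.tsv` (T), `proportions.tsv` (A) and `fit.json`
#' (k, lambda, objective, seed, flagged purity index if given).
#'
#' @param fit A [fit_deconvolution()] result.
#' @param dir Output directory.
#' @param purity Optional [flag_purity_component()] annotation.
#' @return `dir`, invisibly.
#' @export
write_deconvolution <- function(fit, dir, purity = NULL) {
  stopifnot(inherits(fit, "deconvolution_fit"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop2("cannot create directory: ", dir)
  write_numeric_tsv(fit$T, file.path(dir, "components.tsv"))
  write_numeric_tsv(fit$A, file.path(dir, "proportions.tsv"), id_col = "lmc")
  meta <- list(k = fit$k, lambda = fit$lambda, objective = fit$objective,
               seed = fit$seed, n_restarts = fit$n_restarts,
               purity_lmc_index = if (is.null(purity)) NULL else
                 purity$purity_lmc_index)
  jsonlite::write_json(meta, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
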