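#' Compute beta values from channel intensities
#'
#' Beta is the methylated-signal fraction `M / (M + U + offset)`; the
#' intensity offset (default 100) shrinks betas of low-intensity probes
#' toward zero and keeps the ratio defined when both channels are empty.
#'
#' @param methylated,unmethylated Non-negative intensity matrices with
#'   matching dimensions and dimnames (probes x samples).
#' @param offset Intensity offset added to the denominator.
#' @return Beta matrix of the same shape.
#' @export
compute_beta <- function(methylated, unmethylated, offset = 100) {
  if (!identical(dim(methylated), dim(unmethylated)))
    stop2("methylated and unmethylated must have identical dimensions")
  neg <- which(methylated < 0 | unmethylated < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop2("negative intensity at probe ", rownames(methylated)[neg[1, 1]],
          ", sample ", colnames(methylated)[neg[1, 2]])
  }
  denom <- methylated + unmethylated + offset
  b <- methylated / denom
  b[denom == 0] <- 0
  dimnames(b) <- dimnames(methylated)
  b
}

FILTER_FLAGS <- c("snp_overlap", "cross_reactive", "low_quality",
                  "sex_chromosome")

manifest_flag_list <- function(manifest) {
  strsplit(ifelse(is.na(manifest$flags), "", manifest$flags), ";", fixed = TRUE)
}

#' Filter flagged probes from a beta matrix
#'
#' Removes probes flagged in the manifest as SNP-overlapping,
#' cross-reactive, low quality, or on a sex chromosome, in that order. The
#' removal report counts each probe once, at the first step that removes it,
#' so the step counts are disjoint and sum to the total removed.
#'
#' @param beta Probes x samples beta matrix.
#' @param manifest Probe manifest with `probe_id` and semicolon-separated
#'   `flags` columns.
#' @return List: `beta` (filtered matrix), `report` (named integer vector of
#'   per-step removal counts plus `kept`).
#' @export
filter_probes <- function(beta, manifest) {
  check_beta_matrix(beta)
  missing <- setdiff(rownames(beta), manifest$probe_id)
  if (length(missing))
    stop2("probes missing from manifest: ",
          paste(utils::head(missing, 5), collapse = ", "))
  flags <- manifest_flag_list(manifest)
  names(flags) <- manifest$probe_id
  flags <- flags[rownames(beta)]
  keep <- rep(TRUE, nrow(beta))
  report <- stats::setNames(integer(length(FILTER_FLAGS)), FILTER_FLAGS)
  for (f in FILTER_FLAGS) {
    hit <- keep & vapply(flags, function(x) f %in% x, logical(1))
    report[f] <- sum(hit)
    keep <- keep & !hit
  }
  list(beta = beta[keep, , drop = FALSE],
       report = c(report, kept = sum(keep)))
}

#' Merge beta matrices on their common probes
#'
#' Restricts each matrix to the probes present in all of them (in the first
#' matrix's row order) and concatenates samples — the standard move when
#' combining platforms with different probe sets (e.g. 450K and EPIC).
#'
#' @param matrices List of >= 2 beta matrices with disjoint sample ids.
#' @return Merged beta matrix.
#' @export
merge_common_probes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2)
    stop2("need a list of at least two beta matrices")
  common <- rownames(matrices[[1]])
  for (m in matrices[-1]) common <- common[common %in% rownames(m)]
  if (!length(common)) stop2("no common probes across matrices")
  samples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(samples))
    stop2("duplicated sample ids across matrices: ",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  do.call(cbind, lapply(matrices, function(m) m[common, , drop = FALSE]))
}

#' Per-probe linear batch correction of log2 intensities
#'
#' Fits, per probe, a univariable linear model of the log2 intensity on the
#' batch factor and subtracts the fitted batch effects, so every batch ends
#' up sharing the reference (first) batch's mean. Apply separately to the
#' methylated and unmethylated channels.
#'
#' @param log2_intensities Probes x samples matrix of log2 intensities.
#' @param batch Per-sample batch factor (length = sample count).
#' @return Adjusted matrix of the same shape.
#' @export
batch_correct <- function(log2_intensities, batch) {
  if (length(batch) != ncol(log2_intensities))
    stop2("batch length must equal the number of samples")
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    warning("single batch: batch correction is a no-op")
    return(log2_intensities)
  }
  sizes <- table(batch)
  if (any(sizes < 2))
    stop2("every batch needs >= 2 samples; too small: ",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  # with a single categorical covariate the least-squares batch effect is
  # the difference of per-batch means from the reference batch mean
  out <- log2_intensities
  ref_mean <- rowMeans(log2_intensities[, batch == levels(batch)[1],
                                        drop = FALSE])
  for (b in levels(batch)[-1]) {
    cols <- batch == b
    eff <- rowMeans(log2_intensities[, cols, drop = FALSE]) - ref_mean
    out[, cols] <- out[, cols] - eff
  }
  out
}

# Per-probe sample SD (denominator n - 1); NA if any entry missing.
row_sds <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1))
}

#' Select the most variable probes
#'
#' Ranks probes by per-probe sample standard deviation (descending, ties
#' broken by probe id) and returns the top `n`. Probes with any missing
#' value are excluded from the ranking.
#'
#' @param beta Probes x samples beta matrix.
#' @param n Number of probes to return.
#' @return Character vector of probe ids.
#' @export
top_variable_sites <- function(beta, n) {
  check_beta_matrix(beta)
  if (n <= 0) stop2("n must be > 0")
  complete <- !apply(is.na(beta), 1, any)
  sds <- row_sds(beta[complete, , drop = FALSE])
  if (n > length(sds)) stop2("n exceeds the number of complete probes")
  ids <- rownames(beta)[complete]
  ord <- order(-sds, ids)
  ids[ord][seq_len(n)]
}

# Vectorized two-sample Welch t-test across rows; returns two-sided p and
# the group-mean difference.
welch_rows <- function(x, grp) {
  x1 <- x[, grp, drop = FALSE]; x2 <- x[, !grp, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- ifelse(m1[se2 == 0] == m2[se2 == 0], 1, 0)
  list(p = p, diff = m1 - m2)
}

#' Select sites for deconvolution: per-class differential plus most variable
#'
#' For each class, a one-vs-rest comparison: probes passing a Welch t test
#' at Benjamini-Hochberg-adjusted p < 0.05 (within the comparison) are
#' ranked by absolute mean beta difference and the top `per_class_n` taken.
#' The union over classes is combined with the `variable_n` most variable
#' probes; unique probe ids are returned.
#'
#' @param beta Probes x samples beta matrix (complete rows are used).
#' @param labels Per-sample class labels.
#' @param per_class_n Differential probes kept per class (0 disables the
#'   differential arm).
#' @param variable_n Size of the most-variable arm.
#' @param fdr Benjamini-Hochberg threshold for the differential screen.
#' @return Character vector of unique selected probe ids.
#' @export
deconvolution_site_selection <- function(beta, labels, per_class_n = 500,
                                         variable_n = 5000, fdr = 0.05) {
  check_beta_matrix(beta)
  if (length(labels) != ncol(beta))
    stop2("labels length must equal the number of samples")
  classes <- unique(labels)
  if (length(classes) < 2) stop2("need >= 2 classes")
  small <- names(which(table(labels) < 2))
  if (length(small))
    stop2("class with < 2 samples: ", paste(small, collapse = ", "))
  complete <- !apply(is.na(beta), 1, any)
  b <- beta[complete, , drop = FALSE]
  selected <- character(0)
  if (per_class_n > 0) {
    if (per_class_n > nrow(b)) stop2("per_class_n exceeds probe count")
    for (cl in classes) {
      w <- welch_rows(b, labels == cl)
      padj <- stats::p.adjust(w$p, method = "BH")
      pass <- which(padj < fdr)
      if (!length(pass)) next
      ord <- pass[order(-abs(w$diff[pass]), rownames(b)[pass])]
      selected <- c(selected, rownames(b)[utils::head(ord, per_class_n)])
    }
  }
  variable <- top_variable_sites(beta, min(variable_n, nrow(b)))
  unique(c(selected, variable))
}
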