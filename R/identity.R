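#' Call genotypes from SNP-probe beta values
#'
#' SNP probes show three beta clusters; thresholds partition them into
#' genotype calls: `beta < low` is 0 (homozygous-reference-like),
#' `low <= beta <= high` is 1 (heterozygous, boundaries inclusive),
#' `beta > high` is 2 (homozygous-alternate-like). Missing betas stay
#' missing.
#'
#' @param snp_betas Loci x samples beta matrix of SNP probes.
#' @param low,high Cluster thresholds, `0 < low < high < 1`.
#' @return Integer matrix of calls in `{0, 1, 2}` (NA preserved).
#' @export
call_genotypes <- function(snp_betas, low = 1 / 3, high = 2 / 3) {
  if (!(low > 0 && low < high && high < 1))
    stop2("thresholds must satisfy 0 < low < high < 1")
  g <- matrix(NA_integer_, nrow(snp_betas), ncol(snp_betas),
              dimnames = dimnames(snp_betas))
  g[snp_betas < low] <- 0L
  g[snp_betas >= low & snp_betas <= high] <- 1L
  g[snp_betas > high] <- 2L
  g
}

#' SNP distance between two genotype vectors
#'
#' The fraction of discordant genotypes over the loci non-missing in both
#' samples: `d = sum(g_i != g_j) / M` with `M` the shared-locus count.
#'
#' @param g_i,g_j Equal-length genotype vectors in `{0, 1, 2, NA}`.
#' @return List: `d` (distance in `[0, 1]`), `M` (shared loci).
#' @export
snp_distance <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) stop2("genotype vectors differ in length")
  ok <- !is.na(g_i) & !is.na(g_j)
  M <- sum(ok)
  if (M == 0) stop2("no shared non-missing loci")
  list(d = sum(g_i[ok] != g_j[ok]) / M, M = M)
}

#' Pairwise SNP distance matrix
#'
#' Computes all pairwise SNP distances. In `strict` mode the comparison is
#' restricted to loci non-missing in every sample (avoiding missing-data
#' bias across the cohort); the default pairwise-complete mode uses, per
#' pair, the loci non-missing in both, and reports the shared-locus counts
#' so the strictness is auditable. Both modes agree exactly on complete
#' data.
#'
#' @param genotypes Loci x samples genotype matrix.
#' @param strict Use only loci shared across all samples.
#' @return List of class `"snp_distance_matrix"`: `d` (samples x samples,
#'   symmetric, zero diagonal), `M` (shared-locus counts).
#' @export
snp_distance_matrix <- function(genotypes, strict = FALSE) {
  if (strict) {
    keep <- !apply(is.na(genotypes), 1, any)
    if (!any(keep)) stop2("no locus shared across all samples")
    genotypes <- genotypes[keep, , drop = FALSE]
  }
  n <- ncol(genotypes)
  ids <- colnames(genotypes)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  M <- matrix(nrow(genotypes), n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    s <- snp_distance(genotypes[, i], genotypes[, j])
    d[i, j] <- d[j, i] <- s$d
    M[i, j] <- M[j, i] <- s$M
  }
  structure(list(d = d, M = M), class = "snp_distance_matrix")
}

#' Hierarchical clustering of SNP distances for sample identity
#'
#' Agglomerative clustering of the SNP distance matrix; sample pairs that
#' merge below the identity cutoff are reported as same-individual
#' candidates (e.g. a primary and its metastasis).
#'
#' @param dist A [snp_distance_matrix()] result or a symmetric numeric
#'   matrix with zero diagonal.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param cutoff Distance below which co-merging samples are called the
#'   same individual.
#' @return List of class `"identity_clustering"`: `hclust`, `pairs`
#'   (`data.frame(sample_a, sample_b, distance)`), `cutoff`.
#' @export
cluster_identity <- function(dist, linkage = "average", cutoff = 0.10) {
  d <- if (inherits(dist, "snp_distance_matrix")) dist$d else dist
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-12)))
    stop2("distance matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  grp <- stats::cutree(hc, h = cutoff)
  pairs <- do.call(rbind, lapply(split(names(grp), grp), function(ids) {
    if (length(ids) < 2) return(NULL)
    cmb <- utils::combn(ids, 2)
    data.frame(sample_a = cmb[1, ], sample_b = cmb[2, ],
               distance = d[cbind(cmb[1, ], cmb[2, ])],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(sample_a = character(0), sample_b = character(0),
                        distance = numeric(0))
  rownames(pairs) <- NULL
  structure(list(hclust = hc, pairs = pairs, cutoff = cutoff),
            class = "identity_clustering")
}

#' Export an identity dendrogram as Newick
#'
#' @param clustering An [cluster_identity()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_identity_newick <- function(clustering, path) {
  phy <- ape::as.phylo(clustering$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
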