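#' Configuration for the synthetic EPIC-like cohort generator
#'
#' Builds the parameter set for [simulate_cohort()]. The generator emulates
#' the structure of a multi-organ-site NEN methylation cohort: bimodal
#' per-probe methylation, class-specific differential CpG blocks, a
#' leukocyte/normal-cell contamination component with variable per-sample
#' proportion, SNP probes with three-cluster beta distributions shared within
#' a patient, chromosome-arm-scale copy-number segments planted per class,
#' and per-batch log2-intensity offsets.
#'
#' @param n_classes Number of tumor origin classes.
#' @param samples_per_class Samples simulated per class.
#' @param n_probes Total number of CpG probes (SNP probes are extra).
#' @param informative_per_class Size of each class's differential CpG block.
#' @param delta_beta Methylation shift (beta scale) of a class's informative
#'   block relative to all other classes.
#' @param n_snp_probes Number of SNP fingerprint probes.
#' @param n_lump_probes Number of designated leukocyte-unmethylated probes
#'   (unmethylated in leukocytes, methylated in tumor) used for LUMP purity.
#' @param n_reference Number of flat-genome normal reference samples.
#' @param paired_patients Number of patients contributing two samples
#'   (identical germline genotype), for sample-identity checks.
#' @param contamination Normal-cell proportion law: a length-2 numeric
#'   `c(min, max)` for a uniform draw, or a single value for a point mass.
#'   Values must lie in `[0, 1)`.
#' @param noise_sd Gaussian noise standard deviation on the beta scale.
#' @param snp_noise_sd Noise standard deviation around the three SNP beta
#'   cluster centers (0.05 / 0.5 / 0.95).
#' @param base_intensity Baseline combined channel intensity per probe.
#' @param probe_factor_sdlog Log-scale SD of the per-probe lognormal
#'   affinity factor shared across samples.
#' @param intensity_noise_sdlog Log-scale SD of independent per-measurement
#'   lognormal intensity noise.
#' @param batch_offsets Per-batch log2-intensity shifts; the number of
#'   batches equals its length and samples are assigned round-robin.
#' @param cna_segments `data.frame(class, chrom, start, end, copy_ratio)`
#'   of copy-number segments planted in every sample of the named class
#'   (`copy_ratio` on the linear scale, 1 = neutral). `NULL` plants the
#'   default one-loss-one-gain design.
#' @param class_labels Class names; defaults to eight NEN organ sites.
#' @param seed Integer master seed; all randomness derives from it.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_classes = 8,
                       samples_per_class = 20,
                       n_probes = 5000,
                       informative_per_class = 50,
                       delta_beta = 0.5,
                       n_snp_probes = 60,
                       n_lump_probes = 50,
                       n_reference = 8,
                       paired_patients = 3,
                       contamination = c(0.05, 0.5),
                       noise_sd = 0.02,
                       snp_noise_sd = 0.02,
                       base_intensity = 4000,
                       probe_factor_sdlog = 0.15,
                       intensity_noise_sdlog = 0.1,
                       batch_offsets = c(0, 0.3),
                       cna_segments = NULL,
                       class_labels = NULL,
                       seed = 1L) {
  if (is.null(class_labels)) {
    class_labels <- c("Merkel cell carcinoma", "Appendiceal NEN",
                      "Colorectal NEN", "Gastric/duodenal NEN", "Ileal NEN",
                      "Pancreatic NEN", "Pulmonary NEC", "Pulmonary carcinoid")
  }
  class_labels <- class_labels[seq_len(min(n_classes, length(class_labels)))]
  if (length(class_labels) < n_classes)
    class_labels <- c(class_labels,
                      paste0("Class", seq(length(class_labels) + 1, n_classes)))
  counts <- c(n_classes = n_classes, samples_per_class = samples_per_class,
              n_probes = n_probes, informative_per_class = informative_per_class,
              n_snp_probes = n_snp_probes, n_lump_probes = n_lump_probes)
  if (any(counts <= 0)) stop2("all counts must be > 0")
  # one informative block per class, one for the leukocyte component, plus
  # the LUMP block, all disjoint
  if ((n_classes + 1) * informative_per_class + n_lump_probes > n_probes)
    stop2("informative blocks and LUMP block exceed n_probes")
  if (any(contamination < 0) || any(contamination >= 1))
    stop2("contamination values must lie in [0, 1)")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  if (base_intensity <= 0) stop2("base_intensity must be > 0")
  if (is.null(cna_segments)) {
    half <- floor(n_probes / 2) * 1000
    cna_segments <- data.frame(
      class = class_labels[c(min(3, n_classes), min(7, n_classes))],
      chrom = c("chr1", "chr2"),
      start = c(floor(half * 0.5), 0L),
      end = c(half, floor(half * 0.4)),
      copy_ratio = c(2^-0.585, 1.5),
      stringsAsFactors = FALSE)
    cna_segments <- cna_segments[!duplicated(cna_segments$class), ]
  }
  structure(list(
    n_classes = n_classes, samples_per_class = samples_per_class,
    n_probes = n_probes, informative_per_class = informative_per_class,
    delta_beta = delta_beta, n_snp_probes = n_snp_probes,
    n_lump_probes = n_lump_probes, n_reference = n_reference,
    paired_patients = paired_patients, contamination = contamination,
    noise_sd = noise_sd, snp_noise_sd = snp_noise_sd,
    base_intensity = base_intensity, probe_factor_sdlog = probe_factor_sdlog,
    intensity_noise_sdlog = intensity_noise_sdlog,
    batch_offsets = batch_offsets, cna_segments = cna_segments,
    class_labels = class_labels, seed = as.integer(seed)),
    class = "sim_config")
}

# Probe layout shared by all generator stages: two synthetic chromosomes,
# evenly spaced probes (1 kb apart, 0-based half-open), informative blocks
# first, then the leukocyte block, then the LUMP block.
probe_layout <- function(config) {
  p <- config$n_probes
  ids <- sprintf("cg%06d", seq_len(p))
  half <- ceiling(p / 2)
  chrom <- rep(c("chr1", "chr2"), c(half, p - half))
  pos <- c(seq_len(half) - 1L, seq_len(p - half) - 1L) * 1000L
  m <- config$informative_per_class
  blocks <- lapply(seq_len(config$n_classes + 1), function(c)
    ids[seq((c - 1) * m + 1, c * m)])
  names(blocks) <- c(config$class_labels, "Leukocyte")
  lump <- ids[seq((config$n_classes + 1) * m + 1,
                  (config$n_classes + 1) * m + config$n_lump_probes)]
  list(probe_ids = ids, chrom = chrom, start = pos, end = pos + 2L,
       blocks = blocks, lump_probes = lump)
}

draw_contamination <- function(config, n) {
  law <- config$contamination
  if (length(law) == 1) rep(law, n)
  else stats::runif(n, law[1], law[2])
}

#' Draw latent component methylation profiles
#'
#' Each probe/component entry comes from a two-mode mixture concentrated near
#' beta 0.05 and 0.95 (array-style bimodality). Every class has a disjoint
#' informative block shifted by `delta_beta` toward the opposite mode
#' relative to all other components; the leukocyte component additionally has
#' its own shifted block and is set unmethylated on the designated LUMP
#' probes, where all tumor components are methylated.
#'
#' @param config A [sim_config()] object.
#' @return Matrix of `n_probes` x `(n_classes + 1)` component profiles in
#'   `[0, 1]`; last column is the leukocyte/normal component.
#' @export
sample_component_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- probe_layout(config)
  p <- config$n_probes
  k <- config$n_classes + 1
  with_seed(config$seed + 1L, {
    mode <- ifelse(stats::runif(p) < 0.5, 0.05, 0.95)
    base <- clip(mode + stats::rnorm(p, 0, 0.02))
    T <- matrix(base, p, k, dimnames = list(layout$probe_ids,
                                            names(layout$blocks)))
    for (c in seq_len(k)) {
      idx <- layout$blocks[[c]]
      shift <- ifelse(T[idx, c] < 0.5, config$delta_beta, -config$delta_beta)
      T[idx, c] <- clip(T[idx, c] + shift)
    }
    # LUMP block: leukocytes unmethylated, all tumor components share one
    # methylated profile there
    nl <- length(layout$lump_probes)
    T[layout$lump_probes, ] <- clip(0.95 + stats::rnorm(nl, 0, 0.01))
    T[layout$lump_probes, k] <- clip(0.05 + stats::rnorm(nl, 0, 0.01))
    T
  })
}

#' Draw per-sample mixing proportions
#'
#' Each sample is a two-component mixture: `(1 - c)` of its own class
#' component and `c` of the leukocyte component, with the normal-cell
#' proportion `c` drawn from the configured contamination law. Columns lie on
#' the probability simplex by construction.
#'
#' @param config A [sim_config()] object.
#' @param labels Per-sample class labels (must be in `config$class_labels`;
#'   the value `"Control"` yields a pure leukocyte column).
#' @return `(n_classes + 1)` x `length(labels)` proportion matrix.
#' @export
sample_proportions <- function(config, labels) {
  stopifnot(inherits(config, "sim_config"))
  comps <- c(config$class_labels, "Leukocyte")
  n <- length(labels)
  bad <- setdiff(unique(labels), c(config$class_labels, "Control"))
  if (length(bad)) stop2("unknown class labels: ", paste(bad, collapse = ", "))
  with_seed(config$seed + 2L, {
    cont <- draw_contamination(config, n)
    A <- matrix(0, length(comps), n,
                dimnames = list(comps, names(labels)))
    for (i in seq_len(n)) {
      if (labels[i] == "Control") {
        A["Leukocyte", i] <- 1
        cont[i] <- 1
      } else {
        A[labels[i], i] <- 1 - cont[i]
        A["Leukocyte", i] <- cont[i]
      }
    }
    attr(A, "contamination") <- cont
    A
  })
}

#' Synthesize a beta matrix from the forward mixture model
#'
#' `D = clip(T A + e, 0, 1)` with i.i.d. Gaussian noise `e`.
#'
#' @param components Probes x components matrix `T` in `[0, 1]`.
#' @param proportions Components x samples matrix `A`, simplex columns.
#' @param noise_sd Gaussian noise SD on the beta scale.
#' @param seed Seed for the noise draw.
#' @return Probes x samples beta matrix.
#' @export
synthesize_beta_matrix <- function(components, proportions, noise_sd = 0.02,
                                   seed = 1L) {
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  if (ncol(components) != nrow(proportions))
    stop2("components and proportions are not conformable")
  D <- components %*% proportions
  if (noise_sd > 0)
    D <- D + with_seed(seed + 3L,
                       matrix(stats::rnorm(length(D), 0, noise_sd), nrow(D)))
  clip(D)
}

#' Synthesize methylated/unmethylated channel intensities
#'
#' Per probe and sample, the combined intensity is
#' `base_intensity * copy_ratio * probe_factor * 2^batch_offset`, where
#' `copy_ratio` comes from the sample's planted copy-number segments and the
#' lognormal probe factor models per-probe affinity (shared across samples).
#' The methylated channel is `beta * total`, the unmethylated channel
#' `(1 - beta) * total`, so beta is recoverable exactly with offset 0.
#'
#' @param beta Probes x samples beta matrix.
#' @param manifest Probe manifest (see [simulate_cohort()]).
#' @param sample_sheet Sample sheet with `sample_id` and `batch` columns.
#' @param cna_truth Per-sample segment `data.frame(sample_id, chrom, start,
#'   end, copy_ratio)`; samples absent from it are copy-neutral.
#' @param base_intensity Baseline combined intensity.
#' @param probe_factor_sdlog Log-scale SD of the per-probe factor (0 disables).
#' @param intensity_noise_sdlog Log-scale SD of independent per-measurement
#'   lognormal noise (default 0: the combined intensity is then an exact
#'   function of copy state, probe factor and batch).
#' @param batch_offsets Named or positional per-batch log2 shifts.
#' @param seed Seed for the probe-factor and noise draws.
#' @return List with matrices `methylated` and `unmethylated`.
#' @export
synthesize_intensities <- function(beta, manifest, sample_sheet, cna_truth,
                                   base_intensity = 4000,
                                   probe_factor_sdlog = 0.15,
                                   intensity_noise_sdlog = 0,
                                   batch_offsets = c(0, 0.3), seed = 1L) {
  if (base_intensity <= 0) stop2("base_intensity must be > 0")
  p <- nrow(beta); n <- ncol(beta)
  stopifnot(identical(rownames(beta), manifest$probe_id),
            identical(colnames(beta), sample_sheet$sample_id))
  factor_p <- if (probe_factor_sdlog > 0)
    with_seed(seed + 5L, stats::rlnorm(p, 0, probe_factor_sdlog)) else rep(1, p)
  ratio <- matrix(1, p, n, dimnames = dimnames(beta))
  if (!is.null(cna_truth) && nrow(cna_truth)) {
    for (r in seq_len(nrow(cna_truth))) {
      seg <- cna_truth[r, ]
      rows <- manifest$chrom == seg$chrom & manifest$start >= seg$start &
        manifest$start < seg$end
      ratio[rows, seg$sample_id] <- seg$copy_ratio
    }
  }
  boff <- batch_offsets[as.integer(factor(sample_sheet$batch))]
  total <- base_intensity * factor_p * ratio *
    matrix(2^boff, p, n, byrow = TRUE)
  if (intensity_noise_sdlog > 0)
    total <- total * with_seed(seed + 7L,
      matrix(stats::rlnorm(p * n, 0, intensity_noise_sdlog), p, n))
  list(methylated = beta * total, unmethylated = (1 - beta) * total)
}

#' Synthesize patient genotypes and SNP-probe beta rows
#'
#' Per-locus minor-allele frequencies are drawn uniformly in `[0.1, 0.5]`;
#' each patient's genotype at a locus is binomial(2, MAF). All samples of a
#' patient share its genotypes exactly. SNP-probe betas sit near the cluster
#' centers 0.05 / 0.5 / 0.95 for genotypes 0 / 1 / 2, with Gaussian noise.
#'
#' @param config A [sim_config()] object.
#' @param patient_ids Per-sample patient identifiers (names = sample ids).
#' @return List: `genotypes` (loci x samples integer matrix in `{0,1,2}`),
#'   `snp_beta` (loci x samples), `mafs`, `patient_genotypes`.
#' @export
synthesize_snp_genotypes <- function(config, patient_ids) {
  stopifnot(inherits(config, "sim_config"))
  loci <- sprintf("rs%06d", seq_len(config$n_snp_probes))
  patients <- unique(patient_ids)
  with_seed(config$seed + 4L, {
    mafs <- stats::runif(config$n_snp_probes, 0.1, 0.5)
    gp <- matrix(stats::rbinom(length(loci) * length(patients), 2,
                               rep(mafs, length(patients))),
                 length(loci), length(patients),
                 dimnames = list(loci, patients))
    g <- gp[, patient_ids, drop = FALSE]
    colnames(g) <- names(patient_ids)
    centers <- c(0.05, 0.5, 0.95)
    b <- matrix(centers[g + 1L], nrow(g), ncol(g), dimnames = dimnames(g))
    if (config$snp_noise_sd > 0)
      b <- clip(b + stats::rnorm(length(b), 0, config$snp_noise_sd))
    list(genotypes = g, snp_beta = b, mafs = mafs, patient_genotypes = gp)
  })
}

#' Simulate a complete synthetic EPIC-like cohort
#'
#' Runs the whole forward model: component profiles, per-sample proportions
#' (tumor classes plus flat-genome leukocyte "Control" references), beta
#' matrix, SNP probes, channel intensities with planted copy-number segments
#' and batch offsets, probe manifest with planted quality flags, and a
#' sample sheet. Identical config and seed give identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"nen_cohort"`: `beta` (CpG + SNP probe rows),
#'   `methylated`/`unmethylated` intensities, `manifest`, `sample_sheet`,
#'   and `truth` (components, proportions, contamination, class labels,
#'   patient ids, genotypes, CNA segments, LUMP probes, informative blocks).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  layout <- probe_layout(config)
  n_tumor <- config$n_classes * config$samples_per_class
  labels <- rep(config$class_labels, each = config$samples_per_class)
  labels <- c(labels, rep("Control", config$n_reference))
  n <- length(labels)
  sample_ids <- sprintf("S%03d", seq_len(n))
  names(labels) <- sample_ids

  # patient structure: the first `paired_patients` classes contribute one
  # patient with two samples (their first two samples); everyone else is
  # their own patient
  patient_ids <- paste0("P", sprintf("%03d", seq_len(n)))
  for (c in seq_len(min(config$paired_patients, config$n_classes))) {
    i1 <- (c - 1) * config$samples_per_class + 1
    patient_ids[i1 + 1] <- patient_ids[i1]
  }
  names(patient_ids) <- sample_ids

  T <- sample_component_profiles(config)
  A <- sample_proportions(config, labels)
  colnames(A) <- sample_ids
  contamination <- attr(A, "contamination")
  names(contamination) <- sample_ids
  attr(A, "contamination") <- NULL
  beta_cpg <- synthesize_beta_matrix(T, A, config$noise_sd, config$seed)
  snp <- synthesize_snp_genotypes(config, patient_ids)

  beta <- rbind(beta_cpg, snp$snp_beta)

  manifest <- data.frame(
    chrom = c(layout$chrom, rep("chr2", config$n_snp_probes)),
    start = c(layout$start,
              max(layout$start) + seq_len(config$n_snp_probes) * 1000L),
    end = NA_integer_,
    probe_id = c(layout$probe_ids, rownames(snp$snp_beta)),
    probe_class = rep(c("cpg", "snp"),
                      c(config$n_probes, config$n_snp_probes)),
    flags = "", lump_marker = FALSE, stringsAsFactors = FALSE)
  manifest$end <- manifest$start + 2L
  manifest$lump_marker <- manifest$probe_id %in% layout$lump_probes

  # planted quality flags, outside informative/LUMP blocks
  flaggable <- with(manifest, probe_class == "cpg" & !lump_marker &
                      !(probe_id %in% unlist(layout$blocks)))
  manifest$flags[flaggable] <- with_seed(config$seed + 6L, {
    f <- character(sum(flaggable))
    u <- stats::runif(length(f))
    f[u < 0.02] <- "snp_overlap"
    f[u >= 0.02 & u < 0.06] <- "cross_reactive"
    f[u >= 0.06 & u < 0.08] <- "low_quality"
    f[u >= 0.08 & u < 0.095] <- "sex_chromosome"
    f
  })
  manifest <- manifest[order(manifest$chrom, manifest$start), ]
  rownames(manifest) <- NULL

  sample_sheet <- data.frame(
    sample_id = sample_ids, patient_id = patient_ids,
    class_label = labels,
    batch = paste0("batch", (seq_len(n) - 1L) %% length(config$batch_offsets) + 1L),
    specimen = ifelse(labels == "Control", "reference", "tumor"),
    stringsAsFactors = FALSE)
  rownames(sample_sheet) <- NULL

  seg <- config$cna_segments
  cna_truth <- do.call(rbind, lapply(seq_len(nrow(seg)), function(r) {
    ids <- sample_ids[labels == seg$class[r]]
    if (!length(ids)) return(NULL)
    data.frame(sample_id = ids, chrom = seg$chrom[r], start = seg$start[r],
               end = seg$end[r], copy_ratio = seg$copy_ratio[r],
               stringsAsFactors = FALSE)
  }))

  # manifest order must match matrix order for intensity synthesis
  beta <- beta[manifest$probe_id, , drop = FALSE]
  intens <- synthesize_intensities(
    beta, manifest, sample_sheet, cna_truth,
    base_intensity = config$base_intensity,
    probe_factor_sdlog = config$probe_factor_sdlog,
    intensity_noise_sdlog = config$intensity_noise_sdlog,
    batch_offsets = config$batch_offsets, seed = config$seed)

  structure(list(
    beta = beta, methylated = intens$methylated,
    unmethylated = intens$unmethylated,
    manifest = manifest, sample_sheet = sample_sheet,
    truth = list(components = T, proportions = A,
                 contamination = contamination, class_labels = labels,
                 patient_ids = patient_ids, genotypes = snp$genotypes,
                 mafs = snp$mafs, cna_truth = cna_truth,
                 lump_probes = layout$lump_probes,
                 informative_blocks = layout$blocks)),
    class = "nen_cohort")
}

#' Simulate metastasis-like query samples
#'
#' Generates held-out samples carrying an existing class's methylation
#' signature plus extra normal-cell (leukocyte) contamination on top of the
#' base contamination law — emulating liver metastases whose biopsies carry
#' abundant non-tumor tissue.
#'
#' @param config The [sim_config()] used for the reference cohort (component
#'   profiles are re-derived from it, so the signature matches).
#' @param n Number of query samples.
#' @param extra_contamination Added normal-cell proportion (scalar or range
#'   `c(min, max)` for a uniform draw); total contamination is capped at 0.9.
#' @param seed Seed for the query draw.
#' @return List: `beta` (probes x queries), `labels` (true classes),
#'   `contamination` (total normal-cell proportion per query).
#' @export
simulate_metastases <- function(config, n = 40,
                                extra_contamination = c(0.1, 0.3),
                                seed = 99L) {
  stopifnot(inherits(config, "sim_config"))
  T <- sample_component_profiles(config)
  comps <- colnames(T)
  with_seed(seed, {
    labels <- sample(config$class_labels, n, replace = TRUE)
    base <- draw_contamination(config, n)
    extra <- if (length(extra_contamination) == 1) rep(extra_contamination, n)
      else stats::runif(n, extra_contamination[1], extra_contamination[2])
    cont <- pmin(base + extra, 0.9)
    A <- matrix(0, length(comps), n, dimnames = list(comps, NULL))
    for (i in seq_len(n)) {
      A[labels[i], i] <- 1 - cont[i]
      A["Leukocyte", i] <- cont[i]
    }
    D <- clip(T %*% A + matrix(stats::rnorm(nrow(T) * n, 0, config$noise_sd),
                               nrow(T)))
    colnames(D) <- sprintf("Q%03d", seq_len(n))
    names(labels) <- colnames(D)
    names(cont) <- colnames(D)
    list(beta = D, labels = labels, contamination = cont)
  })
}

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

write_numeric_tsv <- function(mat, path, id_col = "probe_id") {
  df <- data.frame(rownames(mat), apply(mat, 2, fmt_num),
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c(id_col, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_numeric_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  mat <- vapply(df[-1], as.numeric, numeric(nrow(df)))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = nrow(df),
                                     dimnames = list(NULL, colnames(df)[-1]))
  rownames(mat) <- df[[1]]
  mat
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Writes `beta.tsv`, `methylated.tsv`, `unmethylated.tsv` (first column
#' probe id, header sample ids, 17-significant-digit values so matrices
#' round-trip bit-for-bit), `manifest.tsv` (BED-like, sorted by chromosome
#' and position), `sample_sheet.csv` and `truth.json`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "nen_cohort"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop2("cannot create fixture directory: ", dir)
  write_numeric_tsv(cohort$beta, file.path(dir, "beta.tsv"))
  write_numeric_tsv(cohort$methylated, file.path(dir, "methylated.tsv"))
  write_numeric_tsv(cohort$unmethylated, file.path(dir, "unmethylated.tsv"))
  man <- cohort$manifest[order(cohort$manifest$chrom, cohort$manifest$start), ]
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$sample_sheet, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE)
  tr <- cohort$truth
  # numeric blocks go through 17-significant-digit strings so doubles
  # round-trip exactly
  json <- list(components = array(fmt_num(tr$components),
                                  dim(tr$components)),
               proportions = array(fmt_num(tr$proportions),
                                   dim(tr$proportions)),
               contamination = fmt_num(tr$contamination),
               class_labels = tr$class_labels, patient_ids = tr$patient_ids,
               genotypes = tr$genotypes, mafs = fmt_num(tr$mafs),
               cna_truth = tr$cna_truth, lump_probes = tr$lump_probes,
               informative_blocks = tr$informative_blocks,
               component_names = colnames(tr$components),
               probe_ids = rownames(tr$components),
               sample_ids = colnames(tr$proportions),
               locus_ids = rownames(tr$genotypes))
  jsonlite::write_json(json, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return A `"nen_cohort"` list mirroring [simulate_cohort()] output.
#' @export
read_fixture <- function(dir) {
  need <- c("beta.tsv", "methylated.tsv", "unmethylated.tsv", "manifest.tsv",
            "sample_sheet.csv", "truth.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop2("fixture files missing in ", dir, ": ", paste(missing, collapse = ", "))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  truth <- list(
    components = matrix(as.numeric(unlist(tr$components)),
                        length(tr$probe_ids),
                        dimnames = list(tr$probe_ids, tr$component_names)),
    proportions = matrix(as.numeric(unlist(tr$proportions)),
                         length(tr$component_names),
                         dimnames = list(tr$component_names, tr$sample_ids)),
    contamination = stats::setNames(as.numeric(tr$contamination), tr$sample_ids),
    class_labels = stats::setNames(unlist(tr$class_labels), tr$sample_ids),
    patient_ids = stats::setNames(unlist(tr$patient_ids), tr$sample_ids),
    genotypes = matrix(as.integer(unlist(tr$genotypes)), length(tr$locus_ids),
                       dimnames = list(tr$locus_ids, tr$sample_ids)),
    mafs = as.numeric(tr$mafs),
    cna_truth = as.data.frame(tr$cna_truth),
    lump_probes = unlist(tr$lump_probes),
    informative_blocks = tr$informative_blocks)
  structure(list(
    beta = read_numeric_tsv(file.path(dir, "beta.tsv")),
    methylated = read_numeric_tsv(file.path(dir, "methylated.tsv")),
    unmethylated = read_numeric_tsv(file.path(dir, "unmethylated.tsv")),
    manifest = utils::read.delim(file.path(dir, "manifest.tsv"),
                                 stringsAsFactors = FALSE,
                                 colClasses = c(flags = "character")),
    sample_sheet = utils::read.csv(file.path(dir, "sample_sheet.csv"),
                                   stringsAsFactors = FALSE),
    truth = truth), class = "nen_cohort")
}
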