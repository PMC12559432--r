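mk_mat <- function(values, probes, samples) {
  matrix(values, length(probes), length(samples),
         dimnames = list(probes, samples))
}

test_that("beta computation matches the offset formula", {
  M <- mk_mat(c(0, 900, 100, 250), c("p1", "p2", "p3", "p4"), "s1")
  U <- mk_mat(c(0, 0, 100, 250), c("p1", "p2", "p3", "p4"), "s1")
  b <- compute_beta(M, U, offset = 100)
  expect_equal(unname(b[, 1]), c(0, 900 / 1000, 100 / 300, 250 / 600))
  # offset 0 with both channels empty stays defined
  expect_equal(unname(compute_beta(M, U, offset = 0)[1, 1]), 0)
  Mneg <- M; Mneg["p2", 1] <- -5
  expect_error(compute_beta(Mneg, U), "p2")
})

test_that("beta is monotone in M and bounded in (0,1) for offset > 0", {
  for (seed in 1:3) {
    set.seed(seed)
    U <- mk_mat(runif(20, 0, 5000), sprintf("p%d", 1:20), "s")
    M1 <- mk_mat(runif(20, 0, 5000), sprintf("p%d", 1:20), "s")
    M2 <- M1 + mk_mat(runif(20, 0, 100), sprintf("p%d", 1:20), "s")
    b1 <- compute_beta(M1, U); b2 <- compute_beta(M2, U)
    expect_true(all(b2 >= b1))
    expect_true(all(b1 > 0 & b1 < 1))
  }
})

test_that("probe filtering removes flags in order with disjoint counts", {
  probes <- sprintf("p%03d", 1:100)
  beta <- mk_mat(runif(100 * 2), probes, c("s1", "s2"))
  flags <- rep("", 100)
  flags[1:5] <- "snp_overlap"
  flags[6:8] <- "cross_reactive"
  flags[9:10] <- "low_quality"
  flags[11:14] <- "sex_chromosome"
  man <- data.frame(probe_id = probes, flags = flags)
  f <- filter_probes(beta, man)
  expect_equal(unname(f$report[c("snp_overlap", "cross_reactive",
                                 "low_quality", "sex_chromosome")]),
               c(5L, 3L, 2L, 4L))
  expect_equal(unname(f$report["kept"]), 86L)
  expect_equal(nrow(beta) - nrow(f$beta),
               sum(f$report[c("snp_overlap", "cross_reactive", "low_quality",
                              "sex_chromosome")]))
  # no flags: identity
  f0 <- filter_probes(beta, data.frame(probe_id = probes, flags = ""))
  expect_identical(f0$beta, beta)
  expect_equal(sum(f0$report[1:4]), 0L)
  # double-flagged probe counted once, at the first step
  flags2 <- rep("", 100)
  flags2[1] <- "snp_overlap;sex_chromosome"
  f2 <- filter_probes(beta, data.frame(probe_id = probes, flags = flags2))
  expect_equal(unname(f2$report[c("snp_overlap", "sex_chromosome")]), c(1L, 0L))
  expect_error(filter_probes(beta, man[-1, ]), "missing from manifest")
})

test_that("common-probe merging intersects rows and concatenates samples", {
  m1 <- mk_mat(runif(6), c("a", "b", "c"), c("s1", "s2"))
  m2 <- mk_mat(runif(6), c("b", "c", "d"), c("s3", "s4"))
  mg <- merge_common_probes(list(m1, m2))
  expect_identical(rownames(mg), c("b", "c"))
  expect_identical(colnames(mg), c("s1", "s2", "s3", "s4"))
  expect_equal(mg[, "s3"], m2[c("b", "c"), "s3"])
  # identical probe sets: row count unchanged
  m3 <- mk_mat(runif(6), c("a", "b", "c"), c("s5", "s6"))
  expect_equal(nrow(merge_common_probes(list(m1, m3))), 3)
  # planted three-way intersection, counted by an independent set oracle
  set.seed(10)
  universe <- sprintf("cg%04d", 1:500)
  sets <- lapply(1:3, function(i) sort(sample(universe, 300)))
  mats <- lapply(seq_along(sets), function(i)
    mk_mat(runif(length(sets[[i]])), sets[[i]], paste0("x", i)))
  oracle <- length(Reduce(intersect, sets))
  expect_equal(nrow(merge_common_probes(mats)), oracle)
  expect_error(merge_common_probes(list(m1, mk_mat(1, "z", "s9"))), "common")
  expect_error(merge_common_probes(list(m1, m1)), "duplicated")
})

test_that("batch correction equalizes batch means per probe", {
  probes <- sprintf("p%d", 1:30)
  set.seed(3)
  base <- mk_mat(rnorm(30 * 10, 10), probes, sprintf("s%d", 1:10))
  batch <- rep(c("A", "B"), each = 5)
  shifted <- base
  shifted[, batch == "B"] <- shifted[, batch == "B"] + 0.7
  adj <- batch_correct(shifted, batch)
  mA <- rowMeans(adj[, batch == "A"]); mB <- rowMeans(adj[, batch == "B"])
  expect_lt(max(abs(mA - mB)), 1e-10)
  # all batches share the reference batch mean
  expect_lt(max(abs(mA - rowMeans(base[, batch == "A"]))), 1e-10)
  # zero shift: identity; and idempotence
  expect_equal(batch_correct(base, batch)[, batch == "A"],
               base[, batch == "A"])
  expect_equal(batch_correct(adj, batch), adj)
  # within-batch variance unchanged
  expect_equal(apply(adj[, batch == "B"], 1, var),
               apply(shifted[, batch == "B"], 1, var))
  expect_warning(batch_correct(base, rep("A", 10)), "single batch")
  expect_error(batch_correct(base, c(rep("A", 9), "B")), ">= 2 samples")
})

test_that("batch correction agrees with limma up to a per-probe constant", {
  skip_if_not_installed("limma")
  set.seed(4)
  x <- mk_mat(rnorm(20 * 8, 12), sprintf("p%d", 1:20), sprintf("s%d", 1:8))
  batch <- rep(c("A", "B"), 4)
  x[, batch == "B"] <- x[, batch == "B"] + 1.3
  ours <- batch_correct(x, batch)
  ref <- limma::removeBatchEffect(x, batch = batch)
  delta <- ours - ref
  # same correction up to the centering convention
  expect_lt(max(apply(delta, 1, function(d) diff(range(d)))), 1e-10)
})

test_that("variable-site ranking follows per-probe SD with id tie-break", {
  # two samples: sd = |a - b| / sqrt(2); planted SDs 0.3/0.25/0.1/0/0
  d <- c(0.3, 0.25, 0.1, 0, 0) * sqrt(2)
  beta <- mk_mat(c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2 + d),
                 c("p1", "p2", "p3", "p4", "p5"), c("s1", "s2"))
  expect_identical(top_variable_sites(beta, 2), c("p1", "p2"))
  all5 <- top_variable_sites(beta, 5)
  expect_identical(all5[1:3], c("p1", "p2", "p3"))
  expect_identical(sort(all5[4:5]), c("p4", "p5"))  # constant probes last
  expect_identical(all5[4:5], c("p4", "p5"))        # lexicographic tie-break
  expect_error(top_variable_sites(beta, 0), "n must be")
})

test_that("deconvolution site selection unions differential and variable arms", {
  set.seed(6)
  probes <- sprintf("cg%04d", 1:400)
  labels <- rep(c("X", "Y", "Z"), each = 10)
  beta <- mk_mat(runif(400 * 30, 0.4, 0.6), probes, sprintf("s%d", 1:30))
  planted <- probes[1:50]
  beta[planted, labels == "X"] <- beta[planted, labels == "X"] + 0.4
  beta <- pmin(beta, 1)
  sel <- deconvolution_site_selection(beta, labels, per_class_n = 50,
                                      variable_n = 60)
  expect_true(all(planted %in% sel))
  # per_class_n = 0 reduces to the variable arm
  expect_identical(
    deconvolution_site_selection(beta, labels, per_class_n = 0,
                                 variable_n = 60),
    top_variable_sites(beta, 60))
  # size bound and set-union oracle
  per_class <- lapply(unique(labels), function(cl) {
    w_in <- rowMeans(beta[, labels == cl]); w_out <- rowMeans(beta[, labels != cl])
    p <- sapply(seq_len(nrow(beta)), function(i)
      stats::t.test(beta[i, labels == cl], beta[i, labels != cl])$p.value)
    keep <- which(p.adjust(p, "BH") < 0.05)
    keep <- keep[order(-abs(w_in - w_out)[keep], probes[keep])]
    probes[head(keep, 50)]
  })
  oracle <- unique(c(unlist(per_class), top_variable_sites(beta, 60)))
  expect_setequal(sel, oracle)
  expect_lte(length(sel), 50 * 3 + 60)
  # invariant under sample permutation
  perm <- sample(ncol(beta))
  expect_setequal(sel, deconvolution_site_selection(
    beta[, perm], labels[perm], per_class_n = 50, variable_n = 60))
  expect_error(deconvolution_site_selection(beta, rep("X", 30)), "classes")
})
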