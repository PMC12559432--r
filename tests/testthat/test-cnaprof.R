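flat_manifest <- function(p, per_chrom = p / 2, spacing = 1000) {
  data.frame(chrom = rep(c("chr1", "chr2"), each = per_chrom),
             start = rep(seq_len(per_chrom) - 1, 2) * spacing,
             probe_id = sprintf("cg%05d", seq_len(p)))
}

test_that("combined log2 ratios are zero for reference-like queries", {
  p <- 200
  man <- flat_manifest(p)
  set.seed(20)
  total <- matrix(1000 * rlnorm(p), p, 6,
                  dimnames = list(man$probe_id, sprintf("s%d", 1:6)))
  beta <- matrix(0.5, p, 6, dimnames = dimnames(total))
  M <- beta * total; U <- (1 - beta) * total
  r <- combined_log2_ratio(M, U, reference_samples = c("s1", "s2", "s3"),
                           query_samples = c("s4", "s5", "s6"))
  expect_lt(max(abs(r)), 1e-12)
  # global intensity scaling leaves ratios unchanged
  r2 <- combined_log2_ratio(2 * M, 2 * U, c("s1", "s2", "s3"),
                            c("s4", "s5", "s6"))
  expect_equal(r2, r)
  expect_error(combined_log2_ratio(M, U, character(0)), "non-empty")
  expect_error(combined_log2_ratio(M, U, c("s1"), c("s1", "s2")), "disjoint")
})

test_that("a planted 1.5x segment shows at log2(1.5)", {
  p <- 400
  man <- flat_manifest(p, per_chrom = 200)
  total <- matrix(2000, p, 4, dimnames = list(man$probe_id,
                                              sprintf("s%d", 1:4)))
  seg_rows <- 51:100  # chr1 segment
  total[seg_rows, "s4"] <- total[seg_rows, "s4"] * 1.5
  beta <- matrix(0.4, p, 4, dimnames = dimnames(total))
  r <- combined_log2_ratio(beta * total, (1 - beta) * total,
                           reference_samples = c("s1", "s2"),
                           query_samples = "s4")
  expect_equal(mean(r[seg_rows, 1]), log2(1.5), tolerance = 0.02)
  expect_lt(max(abs(r[-seg_rows, 1])), 0.02)
})

test_that("binning yields sorted, minimum-occupancy bins with median stats", {
  p <- 500
  man <- flat_manifest(p, per_chrom = 250)
  set.seed(21)
  r <- matrix(rnorm(p * 2, 0, 0.1), p, 2,
              dimnames = list(man$probe_id, c("q1", "q2")))
  # span of 25 probes exactly
  tr <- bin_probes(r, man, min_probes = 25, bin_span = 25000)
  expect_true(all(tr$bins$n_probes == 25))
  expect_false(is.unsorted(order(tr$bins$chrom, tr$bins$start)))
  # per-bin statistic is the median of member probes
  rows <- man$chrom == "chr1" & man$start < 25000
  expect_equal(unname(tr$ratio[1, "q1"]), median(r[rows, "q1"]))
  # hand-computed median of five listed ratios
  man5 <- data.frame(chrom = "chr9", start = (0:4) * 100,
                     probe_id = paste0("x", 1:5))
  r5 <- matrix(c(0.1, -0.2, 0.4, 0, 0.05), 5, 1,
               dimnames = list(man5$probe_id, "q"))
  expect_warning(tr5 <- bin_probes(r5, man5, min_probes = 20), "fewer")
  expect_equal(unname(tr5$ratio[1, 1]), 0.05)
  # sample permutation leaves each sample's track unchanged
  tr_perm <- bin_probes(r[, c(2, 1)], man, min_probes = 25, bin_span = 25000)
  expect_equal(tr_perm$ratio[, "q1"], tr$ratio[, "q1"])
})

test_that("baseline correction centers the dominant copy-neutral state", {
  man <- flat_manifest(600, per_chrom = 300)
  set.seed(22)
  r <- matrix(rnorm(600, 0.3, 0.05), 600, 1,
              dimnames = list(man$probe_id, "q"))
  tr <- baseline_correct(bin_probes(r, man, min_probes = 20,
                                    bin_span = 20000))
  expect_lt(abs(median(tr$ratio[, 1])), 0.02)
  expect_equal(unname(attr(tr, "baseline_shift")["q"]), 0.3,
               tolerance = 0.1)
  # already centered: shift below 0.01-ish noise scale
  r0 <- matrix(rnorm(600, 0, 0.02), 600, 1,
               dimnames = list(man$probe_id, "q"))
  tr0 <- baseline_correct(bin_probes(r0, man, min_probes = 20,
                                     bin_span = 20000))
  expect_lt(abs(attr(tr0, "baseline_shift")["q"]), 0.02)
  # 70% neutral at +0.2, 30% gained at +0.8: the mode (not the mean) wins
  rmix <- matrix(c(rnorm(420, 0.2, 0.03), rnorm(180, 0.8, 0.03)), 600, 1,
                 dimnames = list(man$probe_id, "q"))
  trmix <- baseline_correct(bin_probes(rmix, man, min_probes = 20,
                                       bin_span = 20000))
  expect_equal(unname(attr(trmix, "baseline_shift")["q"]), 0.2,
               tolerance = 0.05 / 0.2)
})

test_that("segmentation finds planted breakpoints and calls signs", {
  man <- flat_manifest(1000, per_chrom = 500)
  set.seed(23)
  # flat: one neutral segment per chromosome
  rf <- matrix(rnorm(1000, 0, 0.03), 1000, 1,
               dimnames = list(man$probe_id, "q"))
  trf <- bin_probes(rf, man, min_probes = 20, bin_span = 20000)
  segf <- segment_and_call(trf, penalty = 0.1)
  expect_equal(nrow(segf$segments), 2)
  expect_true(all(segf$segments$call == "neutral"))
  # planted step of 0.6 on chr1 from bin 13 onward
  r <- rf
  step_rows <- man$chrom == "chr1" & man$start >= 240000
  r[step_rows, 1] <- r[step_rows, 1] + 0.6
  tr <- bin_probes(r, man, min_probes = 20, bin_span = 20000)
  seg <- segment_and_call(tr, penalty = 0.1)
  chr1 <- seg$segments[seg$segments$chrom == "chr1", ]
  expect_equal(nrow(chr1), 2)
  # brute-force best single split on the chr1 bin series
  y <- tr$ratio[tr$bins$chrom == "chr1", 1]
  rss <- sapply(1:(length(y) - 1), function(i)
    sum((y[1:i] - mean(y[1:i]))^2) + sum((y[-(1:i)] - mean(y[-(1:i)]))^2))
  oracle_cut <- which.min(rss)
  found_cut <- chr1$n_bins[1]
  expect_lte(abs(found_cut - oracle_cut), 1)
  expect_equal(chr1$call, c("neutral", "gain"))
  expect_error(segment_and_call(tr, penalty = 0), "penalty")
})

test_that("cohort frequencies count gain/loss fractions per bin", {
  man <- flat_manifest(200, per_chrom = 100)
  set.seed(24)
  base <- matrix(rnorm(200 * 4, 0, 0.02), 200, 4,
                 dimnames = list(man$probe_id, sprintf("q%d", 1:4)))
  gain_rows <- man$chrom == "chr2" & man$start < 40000
  base[gain_rows, "q1"] <- base[gain_rows, "q1"] + 0.585
  tr <- bin_probes(base, man, min_probes = 20, bin_span = 20000)
  seg <- segment_and_call(tr, penalty = 0.1)
  cf <- cohort_frequency(seg)
  expect_true(all(cf$gain_frequency + cf$loss_frequency <= 1))
  gained_bins <- cf$chrom == "chr2" & cf$start < 40000
  expect_equal(unique(cf$gain_frequency[gained_bins]), 0.25)
  expect_true(all(cf$gain_frequency[!gained_bins] == 0))
  # single all-gain sample
  one <- matrix(0.6, 200, 1, dimnames = list(man$probe_id, "q"))
  tr1 <- bin_probes(one, man, min_probes = 20, bin_span = 20000)
  cf1 <- cohort_frequency(segment_and_call(tr1, penalty = 0.1))
  expect_true(all(cf1$gain_frequency == 1))
})
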