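#' Combined-intensity log2 copy-number ratios
#'
#' Adds the methylated and unmethylated channel intensities per probe,
#' normalizes each sample so its median combined intensity matches the
#' reference median (library-size normalization), and forms per-probe log2
#' ratios of each query sample against the mean of flat-genome reference
#' samples.
#'
#' @param methylated,unmethylated Probes x samples intensity matrices.
#' @param reference_samples Sample ids of flat-genome (copy-neutral)
#'   references; must be non-empty and disjoint from the queries.
#' @param query_samples Sample ids to profile (default: all non-reference
#'   columns).
#' @return Probes x queries matrix of log2 ratios (probes with
#'   non-positive reference mean are NA-masked).
#' @export
combined_log2_ratio <- function(methylated, unmethylated, reference_samples,
                                query_samples = NULL) {
  total <- methylated + unmethylated
  if (!length(reference_samples)) stop2("reference set must be non-empty")
  if (!all(reference_samples %in% colnames(total)))
    stop2("unknown reference samples")
  if (is.null(query_samples))
    query_samples <- setdiff(colnames(total), reference_samples)
  if (length(intersect(query_samples, reference_samples)))
    stop2("query and reference samples must be disjoint")
  med <- apply(total, 2, stats::median)
  target <- stats::median(med[reference_samples])
  scaled <- sweep(total, 2, target / med, `*`)
  ref_mean <- rowMeans(scaled[, reference_samples, drop = FALSE])
  bad <- ref_mean <= 0
  out <- log2(sweep(scaled[, query_samples, drop = FALSE], 1, ref_mean, `/`))
  out[bad, ] <- NA_real_
  out
}

#' Bin probe-level ratios into genomic bins
#'
#' Lays fixed-span bins (0-based half-open) along each chromosome and
#' merges bins rightward until each holds at least `min_probes` probes; the
#' per-bin statistic is the median ratio. A chromosome with fewer than
#' `min_probes` probes becomes a single whole-chromosome bin, with a
#' warning.
#'
#' @param ratios Probes x samples matrix of log2 ratios.
#' @param manifest Probe manifest (`chrom`, `start`, `probe_id`), sorted by
#'   chromosome and position, covering the ratio probes.
#' @param min_probes Minimum probes per bin.
#' @param bin_span Bin width in bp.
#' @return List of class `"cna_bin_track"`: `bins`
#'   (`data.frame(chrom, start, end, n_probes)`), `ratio` (bins x samples
#'   median matrix).
#' @export
bin_probes <- function(ratios, manifest, min_probes = 20, bin_span = 25000) {
  man <- manifest[match(rownames(ratios), manifest$probe_id), ]
  if (anyNA(man$probe_id)) stop2("ratio probes missing from manifest")
  bins <- NULL
  stats_rows <- list()
  for (ch in unique(man$chrom)) {
    sel <- which(man$chrom == ch)
    sel <- sel[order(man$start[sel])]
    pos <- man$start[sel]
    if (length(sel) < min_probes) {
      warning("chromosome ", ch, " has fewer than ", min_probes,
              " probes: single whole-chromosome bin")
      edges <- c(0, max(pos) + 1)
    } else {
      edges <- seq(0, max(pos) + bin_span, by = bin_span)
    }
    grp <- findInterval(pos, edges, rightmost.closed = FALSE)
    # merge spans rightward until each bin reaches min_probes
    starts <- integer(0); ends <- integer(0); members <- list()
    cur <- integer(0); cur_start <- edges[1]
    for (g in seq_len(length(edges) - 1)) {
      cur <- c(cur, sel[grp == g])
      if (length(cur) >= min_probes || g == length(edges) - 1) {
        if (length(cur)) {
          starts <- c(starts, cur_start); ends <- c(ends, edges[g + 1])
          members <- c(members, list(cur))
        }
        cur <- integer(0); cur_start <- edges[g + 1]
      }
    }
    # fold a trailing short bin into its predecessor
    if (length(members) > 1 &&
        length(members[[length(members)]]) < min_probes) {
      m <- length(members)
      members[[m - 1]] <- c(members[[m - 1]], members[[m]])
      ends[m - 1] <- ends[m]
      members <- members[-m]; starts <- starts[-m]; ends <- ends[-m]
    }
    for (b in seq_along(members)) {
      rows <- ratios[members[[b]], , drop = FALSE]
      stats_rows[[length(stats_rows) + 1]] <-
        apply(rows, 2, stats::median, na.rm = TRUE)
      bins <- rbind(bins, data.frame(chrom = ch, start = starts[b],
                                     end = ends[b],
                                     n_probes = length(members[[b]])))
    }
  }
  ratio <- do.call(rbind, stats_rows)
  colnames(ratio) <- colnames(ratios)
  rownames(bins) <- NULL
  structure(list(bins = bins, ratio = ratio), class = "cna_bin_track")
}

# Kernel-density mode of a numeric vector (fallback: median for short input).
density_mode <- function(x, min_n = 5) {
  x <- x[!is.na(x)]
  if (length(x) < min_n) return(stats::median(x))
  d <- stats::density(x)
  d$x[which.max(d$y)]
}

#' Baseline-correct a bin track
#'
#' Shifts each sample's bin ratios so the dominant copy-neutral state sits
#' at zero, using the kernel-density mode of the bin-ratio distribution
#' (robust to unbalanced gains/losses; falls back to the median for very
#' short tracks).
#'
#' @param track A [bin_probes()] result.
#' @return Corrected `"cna_bin_track"` with a `baseline_shift` attribute
#'   (per-sample shift subtracted).
#' @export
baseline_correct <- function(track) {
  stopifnot(inherits(track, "cna_bin_track"))
  shifts <- apply(track$ratio, 2, density_mode)
  track$ratio <- sweep(track$ratio, 2, shifts)
  attr(track, "baseline_shift") <- shifts
  track
}

# Best single split of y by between-segment sum-of-squares reduction.
best_split <- function(y) {
  n <- length(y)
  if (n < 2) return(list(pos = NA_integer_, gain = 0))
  cs <- cumsum(y); tot <- cs[n]
  i <- seq_len(n - 1)
  gain <- cs[i]^2 / i + (tot - cs[i])^2 / (n - i) - tot^2 / n
  pos <- which.max(gain)
  list(pos = pos, gain = gain[pos])
}

binary_segment <- function(y, penalty) {
  segs <- list(c(1, length(y)))
  repeat {
    gains <- lapply(segs, function(s) best_split(y[s[1]:s[2]]))
    g <- vapply(gains, `[[`, numeric(1), "gain")
    if (!length(g) || max(g) <= penalty) break
    i <- which.max(g)
    s <- segs[[i]]; cut <- s[1] + gains[[i]]$pos - 1
    segs <- c(segs[-i], list(c(s[1], cut)), list(c(cut + 1, s[2])))
  }
  segs <- segs[order(vapply(segs, `[[`, numeric(1), 1))]
  do.call(rbind, segs)
}

#' Segment a bin track and call gains/losses
#'
#' Per chromosome and sample, binary segmentation of the bin ratios with a
#' penalty-controlled stopping rule (a split is accepted while the
#' between-segment sum-of-squares reduction exceeds `penalty`); each
#' segment is called by its mean ratio against the gain/loss thresholds.
#'
#' @param track A baseline-corrected [bin_probes()] track.
#' @param gain_thr,loss_thr Mean-log2-ratio call thresholds.
#' @param penalty Minimum sum-of-squares improvement to accept a split.
#' @return List of class `"cna_segments"`: `segments`
#'   (`data.frame(sample_id, chrom, start, end, n_bins, mean_ratio, call)`),
#'   `bin_calls` (bins x samples character matrix), `bins`.
#' @export
segment_and_call <- function(track, gain_thr = 0.15, loss_thr = -0.15,
                             penalty = 0.1) {
  stopifnot(inherits(track, "cna_bin_track"))
  if (penalty <= 0) stop2("penalty must be > 0")
  bins <- track$bins
  n_s <- ncol(track$ratio)
  seg_rows <- list()
  bin_calls <- matrix("neutral", nrow(bins), n_s,
                      dimnames = list(NULL, colnames(track$ratio)))
  for (s in seq_len(n_s)) {
    for (ch in unique(bins$chrom)) {
      idx <- which(bins$chrom == ch)
      y <- track$ratio[idx, s]
      segs <- binary_segment(y, penalty)
      for (r in seq_len(nrow(segs))) {
        rows <- idx[segs[r, 1]:segs[r, 2]]
        m <- mean(track$ratio[rows, s], na.rm = TRUE)
        call <- if (m >= gain_thr) "gain" else if (m <= loss_thr) "loss"
          else "neutral"
        bin_calls[rows, s] <- call
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          sample_id = colnames(track$ratio)[s], chrom = ch,
          start = bins$start[rows[1]], end = bins$end[rows[length(rows)]],
          n_bins = length(rows), mean_ratio = m, call = call,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(segments = do.call(rbind, seg_rows), bin_calls = bin_calls,
                 bins = bins), class = "cna_segments")
}

#' Cohort gain/loss frequency track
#'
#' Per bin, the fraction of samples whose overlapping segment is called
#' gain, and the fraction called loss (mutually exclusive calls, so the two
#' never sum above 1).
#'
#' @param segments A [segment_and_call()] result (or a list of them on the
#'   identical bin grid, which are column-bound).
#' @return `data.frame(chrom, start, end, gain_frequency, loss_frequency)`.
#' @export
cohort_frequency <- function(segments) {
  if (inherits(segments, "cna_segments")) segments <- list(segments)
  bins <- segments[[1]]$bins
  for (s in segments[-1]) {
    if (!identical(s$bins, bins)) stop2("segment sets use different bin grids")
  }
  calls <- do.call(cbind, lapply(segments, `[[`, "bin_calls"))
  data.frame(bins[, c("chrom", "start", "end")],
             gain_frequency = rowMeans(calls == "gain"),
             loss_frequency = rowMeans(calls == "loss"))
}

#' Export CNA segments as BED
#'
#' 0-based half-open coordinates; name column holds the call, score the
#' mean log2 ratio.
#'
#' @param segments A [segment_and_call()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  s <- segments$segments
  bed <- data.frame(s$chrom, s$start, s$end,
                    paste(s$sample_id, s$call, sep = "|"),
                    round(s$mean_ratio, 4))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
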