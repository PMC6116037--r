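# Shared fixtures and independent brute-force oracles.

# positions whose start-to-start distances are exactly `dists`
positions_from_dists <- function(dists, chrom = "chr1", width = 1, origin = 0) {
  starts <- origin + cumsum(c(0, dists))
  tibble::tibble(chrom = chrom, start = starts, end = starts + width)
}

# hand-built spacing model (viterbi only consumes rates and weight)
toy_model <- function(mean_target = 100, mean_background = 10000, w = 0.3) {
  structure(list(mean_target = mean_target, mean_background = mean_background,
                 rate_target = 1 / mean_target,
                 rate_background = 1 / mean_background,
                 mixing_weight = w, log_likelihood = NA_real_,
                 iterations = 0L, converged = TRUE,
                 mean_ratio = mean_background / mean_target,
                 no_signal = FALSE, n_gaps = NA_integer_),
            class = "spacing_model")
}

# all-pairs interval overlap scan (oracle for intersect_sets)
bf_intersect_count <- function(a, b) {
  hits <- 0
  bp <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
    if (ov >= 1) { hits <- hits + 1; bp <- bp + ov }
  }
  list(n = hits, bp = bp)
}

# O(n^2) overlap/book-end merge (oracle for merge_reads)
bf_merge <- function(reads) {
  reads <- reads[order(reads$chrom, reads$start, reads$end), ]
  out <- NULL
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (!is.null(out) && out$chrom[nrow(out)] == r$chrom &&
        r$start <= out$end[nrow(out)]) {
      out$end[nrow(out)] <- max(out$end[nrow(out)], r$end)
      out$n[nrow(out)] <- out$n[nrow(out)] + 1
    } else {
      out <- rbind(out, data.frame(chrom = r$chrom, start = r$start,
                                   end = r$end, n = 1))
    }
  }
  out
}

# exhaustive enumeration over all 2^n state paths (oracle for the
# two-state most-probable-path segmentation)
bf_best_path <- function(dists, model, p) {
  n <- length(dists)
  lt <- stats::dexp(dists, model$rate_target, log = TRUE)
  lb <- stats::dexp(dists, model$rate_background, log = TRUE)
  best <- -Inf
  best_path <- NULL
  for (k in 0:(2^n - 1)) {
    st <- bitwAnd(bitwShiftR(k, 0:(n - 1)), 1L) == 1L  # TRUE = target
    lp <- if (st[1]) log(model$mixing_weight) + lt[1]
          else log1p(-model$mixing_weight) + lb[1]
    if (n > 1) {
      same <- st[-1] == st[-n]
      lp <- lp + sum(ifelse(same, log1p(-p), log(p))) +
        sum(ifelse(st[-1], lt[-1], lb[-1]))
    }
    if (lp > best) { best <- lp; best_path <- st }
  }
  best_path
}

# a 20 Mb single-chromosome scenario with 5 planted regions (the package's
# standard desk-scale simulation shape)
desk_scenario <- function(seed, extra = c(1, 4, 6, 2, 3),
                          starts = c(2e6, 5e6, 9e6, 13e6, 17e6),
                          ends = c(3.2e6, 5.4e6, 10.8e6, 13.3e6, 18.9e6)) {
  ref <- ref_index("chr1", 20e6)
  simulation_scenario(ref,
                      gintervals("chr1", starts, ends, extra_copies = extra),
                      seed = seed)
}

# windowed depth with exact (noise-free) expected counts for a scenario
noiseless_depth <- function(scenario) {
  ref <- scenario$reference
  w <- scenario$window_size
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    n_win <- ceiling(ref$length[i] / w)
    start <- (seq_len(n_win) - 1) * w
    end <- pmin(start + w, ref$length[i])
    mid <- (start + end) / 2
    cn <- rep(2, n_win)
    reg <- scenario$planted_regions[scenario$planted_regions$chrom == ref$chrom[i], ]
    for (j in seq_len(nrow(reg))) {
      sel <- mid >= reg$start[j] & mid < reg$end[j]
      cn[sel] <- 2 + reg$extra_copies[j]
    }
    del <- scenario$deletions[scenario$deletions$chrom == ref$chrom[i], ]
    for (j in seq_len(nrow(del))) {
      sel <- mid >= del$start[j] & mid < del$end[j]
      cn[sel] <- 0
    }
    tibble::tibble(chrom = ref$chrom[i], start = start, end = end,
                   count = scenario$wgs_baseline_depth * cn / 2)
  })
  depth_track(dplyr::bind_rows(rows), window_size = w)
}
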