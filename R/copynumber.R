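#' Windowed depth track
#'
#' Wraps a table of fixed-width window read counts. Windows must tile each
#' chromosome in order; the last window of a chromosome may be shorter. Window
#' sizes below 500 bp draw a warning: at small windows, uneven cross-species
#' read mapping produces large numbers of false positive deletions.
#'
#' @param x tibble with `chrom`, `start`, `end`, `count` (and optionally a
#'   logical `masked` column).
#' @param window_size window width in bp (default 1000).
#' @return A tibble of class `depth_track` with a `window_size` attribute.
#' @export
depth_track <- function(x, window_size = 1000) {
  check_intervals(x)
  stopifnot("count" %in% names(x))
  if (any(x$count < 0)) rlang::abort("window counts must be >= 0")
  if (window_size < 500) {
    rlang::warn("window sizes below 500 bp are prone to false positive deletions")
  }
  bad <- x$end - x$start > window_size
  if (any(bad)) rlang::abort("window wider than window_size")
  x <- dplyr::as_tibble(x)
  if (!inherits(x, "depth_track")) class(x) <- c("depth_track", class(x))
  attr(x, "window_size") <- window_size
  x
}

#' @rdname depth_track
#' @param track a `depth_track`.
#' @export
window_size <- function(track) attr(track, "window_size")

#' Read and write bedGraph windowed count tracks
#'
#' Four tab-separated columns (chrom, start, end, value), 0-based half-open,
#' no header.
#'
#' @param path file path.
#' @param window_size window width in bp used to build the track.
#' @return `read_bedgraph()`: a [depth_track()].
#' @export
read_bedgraph <- function(path, window_size = 1000) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "start", "end", "count"),
                         colClasses = c("character", "numeric", "numeric",
                                        "numeric"))
  depth_track(dplyr::as_tibble(x), window_size = window_size)
}

#' @rdname read_bedgraph
#' @param track a `depth_track`.
#' @export
write_bedgraph <- function(track, path) {
  out <- data.frame(chrom = track$chrom,
                    start = format(track$start, scientific = FALSE, trim = TRUE),
                    end = format(track$end, scientific = FALSE, trim = TRUE),
                    count = track$count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Normalize a depth track to the diploid baseline
#'
#' Divides each window count by the genome-wide median window count, so 1.0
#' corresponds to the diploid state and copy number is `round(2 * depth)`.
#' The median — robust against the amplified B regions themselves — is
#' computed over unmasked windows only, but masked windows are still
#' normalized.
#'
#' @param track a [depth_track()] with at least 100 windows.
#' @param exclusion optional interval tibble; windows whose midpoint falls
#'   inside it are masked for the median.
#' @return The track with `norm` and `masked` columns and a `genome_median`
#'   attribute.
#' @export
normalize_depth <- function(track, exclusion = NULL) {
  stopifnot(inherits(track, "depth_track"))
  if (nrow(track) < 100) {
    rlang::abort("at least 100 windows are required to normalize")
  }
  masked <- if ("masked" %in% names(track)) track$masked
            else rep(FALSE, nrow(track))
  if (!is.null(exclusion) && nrow(exclusion) > 0) {
    mid <- (track$start + track$end) / 2
    masked <- masked | point_in_intervals(track$chrom, mid, exclusion)
  }
  med <- stats::median(track$count[!masked])
  if (!is.finite(med) || med == 0) {
    rlang::abort("genome median depth is zero; cannot normalize")
  }
  ws <- window_size(track)
  track$masked <- masked
  track$norm <- track$count / med
  track <- depth_track(track, window_size = ws)
  attr(track, "genome_median") <- med
  track
}

#' @rdname normalize_depth
#' @export
genome_median <- function(track) attr(track, "genome_median")

# round half away from zero (copy numbers, per-B reporting)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Segment a normalized depth track into constant-copy-number runs
#'
#' Median-filters the normalized depth with a `smooth_span`-window kernel and
#' rounds `2 * smoothed` to integer copy number; maximal runs of identical
#' copy number seed the segmentation (the median filter localizes copy steps
#' to within a couple of windows). Because per-window rounding flickers under
#' Poisson counting noise, adjacent runs are then agglomeratively merged while
#' their mean depths differ by less than half a copy — a genuine copy-number
#' step shifts the mean by at least one copy — and any remaining run shorter
#' than `min_seg` windows is absorbed into its nearer-depth neighbour. Each
#' final segment's copy number is `round(2 * mean normalized depth)`.
#' Deterministic.
#'
#' @param track a normalized [depth_track()] (see [normalize_depth()]).
#' @param smooth_span median filter span in windows (odd; default 5).
#' @param min_seg minimum reportable run length in windows (default 8).
#' @return Tibble of segments: `chrom`, `start`, `end`, `normalized_depth`
#'   (mean of raw normalized windows), `copy_number`, `extra_copies`.
#' @export
segment_depth <- function(track, smooth_span = 5, min_seg = 8) {
  stopifnot(inherits(track, "depth_track"))
  if (!"norm" %in% names(track)) {
    rlang::abort("track is not normalized; call normalize_depth() first")
  }
  if (smooth_span %% 2 == 0) smooth_span <- smooth_span + 1
  dplyr::as_tibble(track) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(d, key) {
      n <- nrow(d)
      k <- min(smooth_span, if (n %% 2 == 1) n else n - 1)
      sm <- if (k >= 3) as.numeric(stats::runmed(d$norm, k)) else d$norm
      cn <- round_half_away(2 * sm)
      r <- rle(cn)
      runs <- merge_depth_runs(r$lengths, d$norm, min_seg)
      stops <- cumsum(runs$len)
      starts <- stops - runs$len + 1
      nd <- purrr::map2_dbl(starts, stops, ~mean(d$norm[.x:.y]))
      cn_final <- round_half_away(2 * nd)
      # collapse neighbours that round to the same copy number
      grp <- cumsum(c(TRUE, diff(cn_final) != 0))
      tibble::tibble(chrom = key$chrom, start = d$start[starts],
                     end = d$end[stops], nd = nd, cn = cn_final,
                     len = runs$len, .grp = grp) |>
        dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                         end = max(.data$end),
                         normalized_depth = sum(.data$nd * .data$len) /
                           sum(.data$len),
                         copy_number = .data$cn[1], .by = ".grp") |>
        dplyr::select(-".grp") |>
        dplyr::mutate(extra_copies = .data$copy_number - 2)
    }) |> purrr::list_rbind() |> sort_intervals()
}

# agglomerative merge of adjacent runs: while any adjacent pair has mean
# depths within half a copy (|2 * delta nd| < 0.5) or a side shorter than
# min_seg windows, merge the eligible pair with the smallest depth
# difference (leftmost on ties); deterministic
merge_depth_runs <- function(len, norm, min_seg) {
  stops <- cumsum(len)
  starts <- stops - len + 1
  s <- vapply(seq_along(len), function(i) sum(norm[starts[i]:stops[i]]),
              numeric(1))
  len <- as.numeric(len)
  repeat {
    if (length(len) <= 1) break
    m <- 2 * s / len  # mean 2*nd per run
    delta <- abs(diff(m))
    eligible <- delta < 0.5 |
      pmin(len[-length(len)], len[-1]) < min_seg
    if (!any(eligible)) break
    i <- which(eligible)[which.min(delta[eligible])]
    len[i] <- len[i] + len[i + 1]
    s[i] <- s[i] + s[i + 1]
    len <- len[-(i + 1)]
    s <- s[-(i + 1)]
  }
  list(len = as.integer(len))
}

#' Per-B-chromosome copy estimates
#'
#' Divides the extra copies of each segment by the B-chromosome count of the
#' individual: six extra copies on three Bs is two copies per B. The reported
#' integer rounds half away from zero; fractional values below one are
#' reported, not suppressed — they indicate regions lost from some of the Bs.
#'
#' @param segments segment tibble from [segment_depth()] (needs
#'   `extra_copies`).
#' @param n_b number of B chromosomes (>= 1).
#' @return `segments` with `per_b` (real) and `per_b_reported` (integer).
#' @export
per_b_copies <- function(segments, n_b) {
  if (n_b < 1) rlang::abort("n_b must be >= 1")
  dplyr::mutate(segments,
                per_b = .data$extra_copies / n_b,
                per_b_reported = as.integer(round_half_away(.data$per_b)))
}

#' Concordance between distance-based calls and depth-based segments
#'
#' Matches region calls against amplified depth segments (copy number > 2):
#' candidate pairs share at least 1 bp, then pairs are accepted greedily by
#' descending reciprocal overlap subject to `min_overlap`, each call and
#' segment matching at most once. For every matched pair both breakpoint
#' differences (`|start - start|`, `|end - end|`) enter the pooled median.
#'
#' @param regions region call tibble.
#' @param segments depth segment tibble; rows with `copy_number > 2` are the
#'   amplified set (all rows if there is no `copy_number` column).
#' @param min_overlap minimum reciprocal overlap fraction (default 0.5).
#' @return A list of class `concordance`: `matches` (pair tibble with
#'   `d_start`, `d_end`), `median_breakpoint_diff` (bp),
#'   `region_recovery` (fraction of calls matched), `only_regions`,
#'   `only_segments`. Has a [glance()] method.
#' @export
concordance <- function(regions, segments, min_overlap = 0.5) {
  if (min_overlap <= 0 || min_overlap > 1) {
    rlang::abort("min_overlap must be in (0, 1]")
  }
  amp <- if ("copy_number" %in% names(segments)) {
    segments[segments$copy_number > 2, , drop = FALSE]
  } else segments
  a <- dplyr::as_tibble(regions)[c("chrom", "start", "end")]
  b <- dplyr::as_tibble(amp)[c("chrom", "start", "end")]
  pairs <- intersect_sets(a, b)
  pairs$reciprocal <- with(pairs, pmin(
    overlap_bp / (end_a - start_a), overlap_bp / (end_b - start_b)))
  pairs <- pairs[pairs$reciprocal >= min_overlap, , drop = FALSE]
  pairs <- pairs[order(-pairs$reciprocal, pairs$chrom, pairs$start_a,
                       pairs$start_b), , drop = FALSE]
  used_a <- character(0); used_b <- character(0)
  keep <- logical(nrow(pairs))
  key_a <- paste(pairs$chrom, pairs$start_a, pairs$end_a)
  key_b <- paste(pairs$chrom, pairs$start_b, pairs$end_b)
  for (i in seq_len(nrow(pairs))) {
    if (!(key_a[i] %in% used_a) && !(key_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, key_a[i])
      used_b <- c(used_b, key_b[i])
    }
  }
  m <- pairs[keep, , drop = FALSE]
  m$d_start <- abs(m$start_a - m$start_b)
  m$d_end <- abs(m$end_a - m$end_b)
  m <- sort_intervals(dplyr::rename(m, start = "start_a", end = "end_a")) |>
    dplyr::rename(start_a = "start", end_a = "end")
  only_a <- a[!(paste(a$chrom, a$start, a$end) %in% used_a), , drop = FALSE]
  only_b <- b[!(paste(b$chrom, b$start, b$end) %in% used_b), , drop = FALSE]
  structure(list(
    matches = dplyr::as_tibble(m),
    median_breakpoint_diff = if (nrow(m) > 0)
      stats::median(c(m$d_start, m$d_end)) else NA_real_,
    region_recovery = if (nrow(a) > 0) nrow(m) / nrow(a) else NA_real_,
    only_regions = dplyr::as_tibble(only_a),
    only_segments = dplyr::as_tibble(only_b)),
    class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Two-method concordance\n")
  cat(sprintf("  matched pairs: %d | median breakpoint difference: %s bp\n",
              nrow(x$matches),
              format(x$median_breakpoint_diff)))
  cat(sprintf("  region recovery: %s | one-method-only: %d regions, %d segments\n",
              format(x$region_recovery), nrow(x$only_regions),
              nrow(x$only_segments)))
  invisible(x)
}

#' Copy-number spectrum of detected regions
#'
#' Restricts depth segments to those overlapping region calls and tallies them
#' by extra-copy count — region parts with different copy numbers count
#' separately. Values below the B count indicate regions lost from some Bs;
#' values above it, amplification within Bs.
#'
#' @param segments depth segment tibble (needs `extra_copies`).
#' @param regions region call tibble.
#' @return Tibble histogram: `extra_copies`, `n`.
#' @export
copy_spectrum <- function(segments, regions) {
  if (nrow(segments) == 0 || nrow(regions) == 0) {
    return(tibble::tibble(extra_copies = numeric(), n = integer()))
  }
  reg <- merge_intervals(regions[c("chrom", "start", "end")])
  ov <- overlap_with_set(segments, reg)
  hit <- segments[ov > 0, , drop = FALSE]
  if (nrow(hit) == 0) {
    return(tibble::tibble(extra_copies = numeric(), n = integer()))
  }
  dplyr::count(dplyr::as_tibble(hit), .data$extra_copies) |>
    dplyr::arrange(.data$extra_copies)
}
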