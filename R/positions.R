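#' Filter mapped read records
#'
#' Applies the standard isolated-chromosome filters: minimum mapping quality,
#' minimum aligned length (both thresholds inclusive, the conventional reading
#' of a keep-threshold), removal of reads flagged as contaminant by the
#' upstream comparative-alignment step, and removal of reads whose midpoint
#' falls inside a reference exclusion mask (telomeric/centromeric repeat
#' stretches are a known source of false signal).
#'
#' @param reads tibble with `chrom`, `start`, `end` and optionally
#'   `mapq` (default `Inf`), `aligned_length` (default `end - start`),
#'   `contaminant` (default `FALSE`).
#' @param min_mapq,min_len inclusive keep-thresholds (defaults 20 and 20).
#' @param ref optional [ref_index()]; its exclusion set, if any, is applied.
#' @return The kept subset of `reads` (always a subset of the input).
#' @export
filter_reads <- function(reads, min_mapq = 20, min_len = 20, ref = NULL) {
  if (min_mapq < 0 || min_len < 0) rlang::abort("thresholds must be >= 0")
  check_intervals(reads)
  reads <- dplyr::as_tibble(reads)
  if (nrow(reads) == 0) return(reads)
  mapq <- if ("mapq" %in% names(reads)) reads$mapq else rep(Inf, nrow(reads))
  alen <- if ("aligned_length" %in% names(reads)) reads$aligned_length
          else reads$end - reads$start
  if (any(alen > reads$end - reads$start)) {
    rlang::abort("aligned_length may not exceed the mapped interval length")
  }
  contam <- if ("contaminant" %in% names(reads)) reads$contaminant
            else rep(FALSE, nrow(reads))
  keep <- mapq >= min_mapq & alen >= min_len & !contam
  excl <- if (!is.null(ref)) ref_exclusion(ref) else NULL
  if (!is.null(excl) && nrow(excl) > 0) {
    mid <- floor((reads$start + reads$end) / 2)
    keep <- keep & !point_in_intervals(reads$chrom, mid, excl)
  }
  reads[keep, , drop = FALSE]
}

#' Flag contaminant reads from two alignment scores
#'
#' Helper reducing the upstream two-genome comparative alignment to a per-read
#' boolean: a read is a contaminant when its alignment score against the
#' contaminant genome strictly exceeds its score against the reference.
#'
#' @param reads tibble with numeric columns `score_ref` and `score_contam`.
#' @return `reads` with a logical `contaminant` column added/overwritten.
#' @export
flag_contaminants <- function(reads) {
  stopifnot(all(c("score_ref", "score_contam") %in% names(reads)))
  dplyr::mutate(reads, contaminant = .data$score_contam > .data$score_ref)
}

#' Merge filtered reads into positions
#'
#' Collapses maximal runs of overlapping-or-book-ended reads on the same
#' chromosome into merged positions, the unit whose spacing carries the
#' detection signal. `read_count` is the number of reads supporting each
#' position. Coverage-preserving; after this merge all inter-position gaps
#' are strictly positive, so the log-scale rainfall transform is safe.
#'
#' @param reads filtered read tibble.
#' @return Sorted, disjoint tibble `chrom`, `start`, `end`, `read_count`.
#' @export
merge_reads <- function(reads) {
  out <- merge_intervals(reads, join_gap = 0)
  dplyr::rename(out, read_count = "n_merged")
}

#' Inter-position distance track
#'
#' For each chromosome, the distances between successive merged positions.
#' Two statistics are carried per adjacent pair: `dist`, the start-to-start
#' distance (`start[i+1] - start[i]`) on which the spacing model and the
#' segmentation operate — the distance between consecutive merged positions,
#' expected to be much lower inside regions present on the sampled chromosome
#' — and `gap`, the uncovered span between them (`start[i+1] - end[i]`),
#' anchored at the end of the left position, which feeds the rainfall export
#' and gives deletion coordinates their printed (end, start) form. The first
#' position of each chromosome contributes no row, so a chromosome with n
#' positions yields n - 1 rows.
#'
#' @param positions sorted, non-overlapping merged-position tibble.
#' @return Tibble of class `distance_track` with columns `chrom`, `anchor`
#'   (end of left position), `gap`, `dist`, `left_start` (start of left
#'   position) and `right_end` (end of right position).
#' @export
distance_track <- function(positions) {
  check_intervals(positions)
  if (nrow(positions) > 1) {
    unsorted <- any(positions$chrom[-1] == positions$chrom[-nrow(positions)] &
                      positions$start[-1] < positions$end[-nrow(positions)])
    if (is.unsorted(order(positions$chrom, positions$start, method = "radix")) ||
        unsorted) {
      rlang::abort("positions must be sorted and non-overlapping; merge_reads() first")
    }
  }
  out <- dplyr::as_tibble(positions) |>
    dplyr::mutate(.nxt_start = dplyr::lead(.data$start),
                  .nxt_end = dplyr::lead(.data$end),
                  .by = "chrom") |>
    dplyr::filter(!is.na(.data$.nxt_start)) |>
    dplyr::transmute(chrom = .data$chrom, anchor = .data$end,
                     gap = .data$.nxt_start - .data$end,
                     dist = .data$.nxt_start - .data$start,
                     left_start = .data$start, right_end = .data$.nxt_end)
  class(out) <- c("distance_track", class(out))
  out
}

#' Rainfall table export
#'
#' Tabular form of the rainfall plot: one row per inter-position gap with its
#' anchor coordinate and `log10(gap + 1)`. Written as TSV when `path` is
#' given; the exported table carries the raw gap too, so reading it back
#' reproduces the track exactly.
#'
#' @param track a [distance_track()].
#' @param path optional TSV output path.
#' @return Tibble `chrom`, `anchor`, `gap`, `log10_gap`.
#' @export
rainfall_export <- function(track, path = NULL) {
  out <- tibble::tibble(chrom = track$chrom, anchor = track$anchor,
                        gap = track$gap, log10_gap = log10(track$gap + 1))
  if (!is.null(path)) {
    readr::write_tsv(out, path)
  }
  out
}

#' @rdname rainfall_export
#' @export
read_rainfall <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), anchor = readr::col_double(),
    gap = readr::col_double(), log10_gap = readr::col_double()))
}
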