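#' Genomic interval tibbles
#'
#' Every interval set in dopseqr is a plain tibble with at least the columns
#' `chrom` (character), `start` and `end` (numeric base pairs). Coordinates are
#' 0-based half-open, so an interval covers `end - start` bp. Printed region
#' tables from the literature are ingested verbatim as `(start, end)` pairs;
#' with this convention their lengths sum exactly to the published totals.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors of 0-based half-open coordinates.
#' @param ... further equal-length columns to carry along.
#' @return A tibble with columns `chrom`, `start`, `end` (plus `...`).
#' @examples
#' gintervals("chr1", 100, 200)
#' @export
gintervals <- function(chrom, start, end, ...) {
  x <- tibble::tibble(chrom = as.character(chrom),
                      start = as.numeric(start),
                      end = as.numeric(end), ...)
  check_intervals(x)
  x
}

#' Validate an interval tibble
#'
#' Checks the column contract and the coordinate invariant `0 <= start < end`;
#' optionally checks that every chromosome exists in a reference index and that
#' intervals fit inside their chromosome.
#'
#' @param x a data frame with `chrom`, `start`, `end`.
#' @param ref optional reference index (see [ref_index()]).
#' @return `x`, invisibly. Errors on violation.
#' @export
check_intervals <- function(x, ref = NULL) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss) > 0) {
    rlang::abort(paste0("interval table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (any(x$start < 0) || any(x$end <= x$start)) {
      rlang::abort("intervals must satisfy 0 <= start < end")
    }
    if (!is.null(ref)) {
      idx <- match(x$chrom, ref$chrom)
      if (anyNA(idx)) {
        rlang::abort(paste0("chromosome(s) absent from reference: ",
                            paste(unique(x$chrom[is.na(idx)]), collapse = ", ")))
      }
      if (any(x$end > ref$length[idx])) {
        rlang::abort("interval end beyond chromosome length")
      }
    }
  }
  invisible(x)
}

#' Reference index: chromosome names, lengths and exclusion masks
#'
#' The reference index pins down the coordinate universe: an ordered table of
#' chromosome lengths, optionally with an exclusion set of intervals (repeat,
#' telomere or centromere masks) inside which evidence is ignored — isolated
#' chromosome sequencing is prone to false signal at telomeric and centromeric
#' repeat stretches.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length numeric vector of chromosome lengths in bp (> 0).
#' @param exclusion optional interval tibble of masked spans; every exclusion
#'   interval must lie within its chromosome.
#' @return A tibble of class `ref_index` with columns `chrom`, `length` and an
#'   `exclusion` attribute.
#' @examples
#' ref_index(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
ref_index <- function(chrom, length, exclusion = NULL) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) rlang::abort("duplicated chromosome names")
  if (any(length <= 0)) rlang::abort("chromosome lengths must be > 0")
  ref <- tibble::tibble(chrom = chrom, length = length)
  class(ref) <- c("ref_index", class(ref))
  if (!is.null(exclusion)) {
    check_intervals(exclusion, ref = ref)
    exclusion <- dplyr::as_tibble(exclusion[c("chrom", "start", "end")])
  }
  attr(ref, "exclusion") <- exclusion
  ref
}

#' @rdname ref_index
#' @param ref a `ref_index`.
#' @export
ref_exclusion <- function(ref) attr(ref, "exclusion")

# order rows by chromosome then start (stable, locale-independent)
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end, method = "radix"), , drop = FALSE]
}

#' Merge intervals closer than a join gap
#'
#' Collapses an interval set into a sorted, pairwise non-overlapping set. Two
#' intervals on the same chromosome merge when the gap between them is at most
#' `join_gap`; book-ended intervals (gap exactly `join_gap`) merge, consistent
#' with the half-open convention. With `join_gap = 0` this is the plain union.
#'
#' @param x interval tibble.
#' @param join_gap non-negative gap (bp) across which intervals are bridged.
#' @return Tibble `chrom`, `start`, `end`, `n_merged` (inputs per output row),
#'   sorted and disjoint. Idempotent: merging a merged set is a no-op.
#' @examples
#' merge_intervals(gintervals("chr1", c(100, 140, 500), c(150, 200, 550)))
#' @export
merge_intervals <- function(x, join_gap = 0) {
  if (!is.numeric(join_gap) || length(join_gap) != 1 || is.na(join_gap) ||
      join_gap < 0) {
    rlang::abort("join_gap must be a single non-negative number")
  }
  check_intervals(x)
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_merged = integer()))
  }
  x <- sort_intervals(x)
  new_run <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)] |
                 x$start[-1] > cummax_by(x$end, x$chrom) + join_gap)
  grp <- cumsum(new_run)
  dplyr::tibble(chrom = x$chrom, start = x$start, end = x$end, .grp = grp) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                     end = max(.data$end), n_merged = dplyr::n(),
                     .by = ".grp") |>
    dplyr::select(-".grp")
}

# running max of `end` within each chromosome, lagged by one row, aligned so
# element i is the max end among rows 1..i of the same chromosome block
cummax_by <- function(end, chrom) {
  out <- numeric(length(end) - 1)
  cur <- end[1]
  for (i in seq_len(length(end) - 1)) {
    if (chrom[i + 1] != chrom[i]) cur <- -Inf
    out[i] <- cur
    cur <- max(cur, end[i + 1])
  }
  out
}

#' Pairwise overlaps between two disjoint interval sets
#'
#' Finds every pair of intervals (one from each set) sharing at least 1 bp —
#' the operation behind "regions reused on Bs of two species". Both inputs must
#' individually be non-overlapping (apply [merge_intervals()] first). The
#' result is independent of input row order.
#'
#' @param a,b disjoint interval tibbles on the same reference.
#' @return Tibble with one row per overlapping pair: `chrom`, `start_a`,
#'   `end_a`, `start_b`, `end_b`, `overlap_bp`.
#' @export
intersect_sets <- function(a, b) {
  check_disjoint(a, "a")
  check_disjoint(b, "b")
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_pairs())
  pairs <- dplyr::inner_join(
    dplyr::select(a, "chrom", start_a = "start", end_a = "end"),
    dplyr::select(b, "chrom", start_b = "start", end_b = "end"),
    by = "chrom", relationship = "many-to-many")
  pairs <- dplyr::mutate(pairs, overlap_bp = pmin(.data$end_a, .data$end_b) -
                           pmax(.data$start_a, .data$start_b))
  pairs <- dplyr::filter(pairs, .data$overlap_bp >= 1)
  dplyr::arrange(pairs, .data$chrom, .data$start_a, .data$start_b)
}

empty_pairs <- function() {
  tibble::tibble(chrom = character(), start_a = numeric(), end_a = numeric(),
                 start_b = numeric(), end_b = numeric(), overlap_bp = numeric())
}

check_disjoint <- function(x, label = "x") {
  check_intervals(x)
  if (nrow(x) < 2) return(invisible(x))
  s <- sort_intervals(x)
  same <- s$chrom[-1] == s$chrom[-nrow(s)]
  if (any(same & s$start[-1] < s$end[-nrow(s)])) {
    rlang::abort(paste0("interval set '", label,
                        "' contains overlaps; merge_intervals() first"))
  }
  invisible(x)
}

#' Total bases covered by a disjoint interval set
#'
#' @param x disjoint interval tibble.
#' @return Total bp (sum of `end - start`); 0 for an empty set. Errors if the
#'   set overlaps itself, since the sum would double-count.
#' @export
total_size <- function(x) {
  check_disjoint(x)
  if (nrow(x) == 0) return(0)
  sum(x$end - x$start)
}

#' Read and write BED interval files
#'
#' BED is tab-separated, 0-based half-open, no header. Three columns are always
#' read; columns 4–6 (`name`, `score`, `strand`) are kept when present.
#' `write_bed()` emits as many of the six columns as `x` carries.
#'
#' @param path file path.
#' @return `read_bed()`: an interval tibble.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "numeric", "numeric",
                                        "character", "numeric", "character")[1:6],
                         fill = TRUE, stringsAsFactors = FALSE,
                         col.names = cols, na.strings = character())
  keep <- !vapply(x, function(col) all(is.na(col) | col == ""), logical(1))
  keep[1:3] <- TRUE
  x <- dplyr::as_tibble(x[keep])
  check_intervals(x)
  x
}

#' @rdname read_bed
#' @param x interval tibble.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  out <- as.data.frame(x[cols])
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path file path.
#' @param exclusion optional interval tibble of masked spans.
#' @return A [ref_index()].
#' @export
read_chrom_sizes <- function(path, exclusion = NULL) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "numeric"))
  ref_index(x$chrom, x$length, exclusion = exclusion)
}

#' @rdname read_chrom_sizes
#' @param ref a `ref_index`.
#' @export
write_chrom_sizes <- function(ref, path) {
  out <- data.frame(chrom = ref$chrom,
                    length = format(ref$length, scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# TRUE per row of x when the point (chrom, pos) falls inside any interval of set
point_in_intervals <- function(chrom, pos, set) {
  if (is.null(set) || nrow(set) == 0) return(rep(FALSE, length(chrom)))
  out <- rep(FALSE, length(chrom))
  for (cc in unique(set$chrom)) {
    sel <- chrom == cc
    if (!any(sel)) next
    s <- set[set$chrom == cc, ]
    for (j in seq_len(nrow(s))) {
      out[sel] <- out[sel] | (pos[sel] >= s$start[j] & pos[sel] < s$end[j])
    }
  }
  out
}

# overlap bp of each row of x with a disjoint interval set (0 when none)
overlap_with_set <- function(x, set) {
  if (nrow(x) == 0) return(numeric(0))
  if (is.null(set) || nrow(set) == 0) return(rep(0, nrow(x)))
  out <- rep(0, nrow(x))
  for (j in seq_len(nrow(set))) {
    sel <- x$chrom == set$chrom[j]
    if (!any(sel)) next
    ov <- pmin(x$end[sel], set$end[j]) - pmax(x$start[sel], set$start[j])
    out[sel] <- out[sel] + pmax(0, ov)
  }
  out
}
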