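#' Build consensus regions across samples
#'
#' Union-merges the strong calls of all samples into the consensus row set of
#' a presence matrix. Weak calls never create rows: they only ever fill cells
#' of rows established by strong evidence elsewhere (the "recovered manually"
#' tier).
#'
#' @param calls tiered call tibble (one or more samples; needs `tier`).
#' @param join_gap merge gap in bp (default 10 kb).
#' @param ref optional [ref_index()]; calls on chromosomes absent from it —
#'   e.g. from a different reference assembly — are an error.
#' @return Disjoint consensus interval tibble, sorted. Permutation-invariant
#'   over samples.
#' @export
build_consensus <- function(calls, join_gap = 1e4, ref = NULL) {
  if (!"tier" %in% names(calls)) {
    rlang::abort("calls must carry a tier column; run assign_tiers() first")
  }
  if (!is.null(ref)) check_intervals(calls, ref = ref)
  strong <- calls[calls$tier == "strong", c("chrom", "start", "end")]
  out <- merge_intervals(strong, join_gap = join_gap)
  dplyr::select(out, "chrom", "start", "end")
}

#' Fill a strong/weak/absent presence matrix
#'
#' For each consensus region (row) and sample (column): strong (`"+"`) when
#' the sample has a strong call overlapping the row; weak (`"~"`) when it has
#' no strong call there but at least `weak_min` merged positions fall inside
#' the row — presence rescued by cross-sample evidence; absent (`""`)
#' otherwise. `weak_min` defaults to 2 so that a single stray position never
#' counts as presence.
#'
#' @param consensus consensus interval tibble from [build_consensus()].
#' @param calls tiered call tibble with `sample_id`.
#' @param positions merged-position tibble with `sample_id`.
#' @param samples column order; defaults to samples seen in `calls` then
#'   `positions`.
#' @param weak_min minimum positions for a weak cell (default 2).
#' @return A tibble of class `presence_matrix`: `chrom`, `start`, `end`, one
#'   character column per sample; attribute `samples`.
#' @export
fill_matrix <- function(consensus, calls, positions, samples = NULL,
                        weak_min = 2) {
  check_disjoint(consensus, "consensus")
  if (is.null(samples)) {
    samples <- unique(c(calls$sample_id, positions$sample_id))
  }
  out <- dplyr::as_tibble(consensus[c("chrom", "start", "end")])
  strong <- calls[calls$tier == "strong", , drop = FALSE]
  for (s in samples) {
    sc <- strong[strong$sample_id == s, , drop = FALSE]
    sp <- positions[positions$sample_id == s, , drop = FALSE]
    cell <- character(nrow(out))
    for (i in seq_len(nrow(out))) {
      row <- out[i, ]
      has_strong <- nrow(sc) > 0 &&
        any(sc$chrom == row$chrom & sc$start < row$end & sc$end > row$start)
      if (has_strong) {
        cell[i] <- "+"
      } else {
        n_pos <- sum(sp$chrom == row$chrom & sp$start < row$end &
                       sp$end > row$start)
        cell[i] <- if (n_pos >= weak_min) "~" else ""
      }
    }
    out[[s]] <- cell
  }
  as_presence_matrix(out, samples = samples)
}

#' Presence matrix construction and I/O
#'
#' A presence matrix is a tibble with `chrom`, `start`, `end` and one
#' character column per sample holding `"+"` (strong), `"~"` (weak) or `""`
#' (absent); further columns (e.g. external hybridization evidence) are
#' carried along but are not samples. The TSV form writes the region as
#' `chrom:start-end`; reading it back is lossless.
#'
#' @param x a tibble in the shape above.
#' @param samples character vector naming the sample columns.
#' @return A `presence_matrix`.
#' @export
as_presence_matrix <- function(x, samples) {
  check_intervals(x)
  stopifnot(all(samples %in% names(x)))
  x <- sort_intervals(dplyr::as_tibble(x))
  if (!inherits(x, "presence_matrix")) {
    class(x) <- c("presence_matrix", class(x))
  }
  attr(x, "samples") <- samples
  x
}

#' @rdname as_presence_matrix
#' @param m a `presence_matrix`.
#' @export
matrix_samples <- function(m) attr(m, "samples")

#' @rdname as_presence_matrix
#' @param path TSV file path.
#' @export
write_presence_matrix <- function(m, path) {
  samples <- matrix_samples(m)
  extra <- setdiff(names(m), c("chrom", "start", "end", samples))
  out <- tibble::tibble(region = sprintf("%s:%s-%s", m$chrom,
                                         format(m$start, scientific = FALSE, trim = TRUE),
                                         format(m$end, scientific = FALSE, trim = TRUE)))
  for (s in c(samples, extra)) out[[s]] <- m[[s]]
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname as_presence_matrix
#' @export
read_presence_matrix <- function(path, samples = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    region = readr::col_character(), .default = readr::col_character()))
  x[is.na(x)] <- ""
  parsed <- parse_region(x$region)
  out <- dplyr::bind_cols(parsed, dplyr::select(x, -"region"))
  if (is.null(samples)) samples <- setdiff(names(out),
                                           c("chrom", "start", "end"))
  as_presence_matrix(out, samples = samples)
}

#' Parse `chrom:start-end` region strings
#'
#' @param x character vector like `"CFA13:47122582-47327423"`.
#' @return Interval tibble `chrom`, `start`, `end`.
#' @export
parse_region <- function(x) {
  chrom <- sub(":.*$", "", x)
  rng <- sub("^[^:]*:", "", x)
  tibble::tibble(chrom = chrom,
                 start = as.numeric(sub("-.*$", "", rng)),
                 end = as.numeric(sub("^.*-", "", rng)))
}

#' Group samples by identical presence columns
#'
#' Partitions the samples of a presence matrix by exact cell-for-cell column
#' equality (strong and weak are *not* collapsed). Samples in the same group
#' detected exactly the same region set at the same tiers — the "perfect
#' agreement" comparison.
#'
#' @param m a `presence_matrix` with at least 2 samples.
#' @return Tibble `sample`, `group` (numbered by first appearance),
#'   `group_size`.
#' @export
sample_agreement <- function(m) {
  samples <- matrix_samples(m)
  if (length(samples) < 2) rlang::abort("need at least 2 samples to compare")
  sig <- vapply(samples, function(s) paste(m[[s]], collapse = "\r"),
                character(1))
  grp <- match(sig, unique(sig))
  tibble::tibble(sample = samples, group = grp) |>
    dplyr::add_count(.data$group, name = "group_size")
}

#' Shared and proximal regions between two consensus sets
#'
#' Shared pairs overlap by at least 1 bp (the region-reuse signal). Proximal
#' pairs sit on the same chromosome within `prox_max` bp of each other without
#' overlapping — nearby but distinct acquisition events. The two pair sets
#' are disjoint by construction.
#'
#' @param consensus_a,consensus_b disjoint interval tibbles on one reference.
#' @param prox_max maximum proximity gap in bp (default 5 Mb).
#' @return List with `shared` (as [intersect_sets()]) and `proximal` (pair
#'   tibble with a `gap` column).
#' @export
cross_species_overlap <- function(consensus_a, consensus_b, prox_max = 5e6) {
  shared <- intersect_sets(consensus_a, consensus_b)
  a <- dplyr::select(dplyr::as_tibble(consensus_a), "chrom",
                     start_a = "start", end_a = "end")
  b <- dplyr::select(dplyr::as_tibble(consensus_b), "chrom",
                     start_b = "start", end_b = "end")
  prox <- dplyr::inner_join(a, b, by = "chrom",
                            relationship = "many-to-many") |>
    dplyr::mutate(gap = pmax(.data$start_a, .data$start_b) -
                    pmin(.data$end_a, .data$end_b)) |>
    dplyr::filter(.data$gap > 0, .data$gap <= prox_max) |>
    dplyr::arrange(.data$chrom, .data$start_a, .data$start_b)
  list(shared = shared, proximal = prox)
}

#' Check consensus regions against external evidence
#'
#' An evidence interval (e.g. a BAC clone hybridization site) is recovered
#' when it overlaps any consensus region by at least 1 bp.
#'
#' @param consensus consensus interval tibble or a `presence_matrix`.
#' @param evidence interval tibble of external evidence sites.
#' @return List: `recovered` and `missed` evidence tibbles, `n_recovered`,
#'   `n_evidence`.
#' @export
external_evidence_check <- function(consensus, evidence) {
  rows <- merge_intervals(dplyr::as_tibble(consensus)[c("chrom", "start", "end")])
  check_intervals(evidence)
  if (nrow(evidence) == 0) {
    return(list(recovered = dplyr::as_tibble(evidence),
                missed = dplyr::as_tibble(evidence),
                n_recovered = 0L, n_evidence = 0L))
  }
  hit <- overlap_with_set(evidence, rows) > 0
  list(recovered = dplyr::as_tibble(evidence[hit, , drop = FALSE]),
       missed = dplyr::as_tibble(evidence[!hit, , drop = FALSE]),
       n_recovered = sum(hit), n_evidence = nrow(evidence))
}
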