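#' Published B-chromosome region tables shipped as fixtures
#'
#' The region sets identified on red fox (VVUB) and Chinese raccoon dog
#' (NPPB) B chromosomes, with per-sample presence tiers and the BAC-clone
#' mapping evidence column, on dog (CanFam3.1) genome coordinates. These
#' tables are the package's in-literature reference surface: interval
#' arithmetic on them reproduces the published totals (14 fox regions,
#' 7,708,416 bp; 27 raccoon dog regions, 8,510,228 bp).
#'
#' `fox_b_regions()` has samples VVUB2 (flow sorted) and VVUB3/5/6
#' (microdissected from one metaphase plate); `raccoondog_b_regions()` has
#' NPPB1 (flow sorted) and NPPB2–8 (microdissected whole Bs and B portions).
#' Cells are `"+"` (strong, automatically recovered), `"~"` (weak, manually
#' rescued) or `""`. The `BAC` column is external evidence, not a sample.
#'
#' @return A [presence matrix][as_presence_matrix()].
#' @export
fox_b_regions <- function() {
  read_fixture_matrix("fox_b_regions.tsv", c("VVUB2", "VVUB3", "VVUB5", "VVUB6"))
}

#' @rdname fox_b_regions
#' @export
raccoondog_b_regions <- function() {
  read_fixture_matrix("raccoondog_b_regions.tsv", paste0("NPPB", 1:8))
}

read_fixture_matrix <- function(file, samples) {
  path <- system.file("extdata", file, package = "dopseqr", mustWork = TRUE)
  read_presence_matrix(path, samples = samples)
}

#' Internal deletions footnoted on the fox region table
#'
#' The coverage voids recorded inside two fox B regions (two deletions in the
#' CFA13:34 Mbp region, one in CFA22:24–25 Mbp). Subtracting them from the
#' total region size gives the 7.4 Mbp figure quoted for the fox B content.
#'
#' @return Interval tibble with the host `region` string.
#' @export
fox_b_deletions <- function() {
  path <- system.file("extdata", "fox_region_deletions.tsv",
                      package = "dopseqr", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), region = readr::col_character()))
}

#' BAC-clone mapping evidence intervals
#'
#' `fox_bac_evidence()` returns the seven fox regions previously detected by
#' BAC clone mapping (the BAC-flagged rows of the fox table).
#' `raccoondog_bac_evidence()` returns the five raccoon dog BAC evidence
#' sites: three match published region rows; the remaining two (CFA13:34 Mbp
#' and CFA29:41 Mbp, not recovered by sequencing) are shipped as synthetic
#' 1-bp point stand-ins at their printed megabase positions, marked in the
#' `source` column.
#'
#' @return Interval tibble.
#' @export
fox_bac_evidence <- function() {
  m <- fox_b_regions()
  dplyr::as_tibble(m[m$BAC == "+", c("chrom", "start", "end")])
}

#' @rdname fox_bac_evidence
#' @export
raccoondog_bac_evidence <- function() {
  path <- system.file("extdata", "raccoondog_bac_evidence_standins.tsv",
                      package = "dopseqr", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), name = readr::col_character(),
    source = readr::col_character()))
}

#' Consensus region intervals of a presence matrix fixture
#'
#' Convenience accessor: just the `chrom`/`start`/`end` rows.
#'
#' @param m a `presence_matrix`.
#' @return Interval tibble.
#' @export
matrix_regions <- function(m) {
  dplyr::as_tibble(m)[c("chrom", "start", "end")]
}
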