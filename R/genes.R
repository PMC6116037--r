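#' Genes overlapping detected regions
#'
#' Selects annotation records with at least 1 bp of overlap with any region
#' (any-overlap, the conventional "gene predictions overlapping the regions"
#' rule); a stricter minimum overlap fraction of the gene body is available.
#' Each gene is returned once however many regions it touches.
#'
#' @param annotation gene tibble with `gene_id`, `chrom`, `start`, `end` and
#'   optionally `biotype`; `gene_id` must be unique.
#' @param regions interval tibble (merged internally).
#' @param min_overlap_frac minimum overlapped fraction of the gene length
#'   (default 0: any overlap).
#' @return The overlapping subset of `annotation`.
#' @export
genes_in_regions <- function(annotation, regions, min_overlap_frac = 0) {
  check_intervals(annotation)
  stopifnot("gene_id" %in% names(annotation))
  if (anyDuplicated(annotation$gene_id)) {
    rlang::abort("gene_id must be unique within an annotation set")
  }
  reg <- merge_intervals(dplyr::as_tibble(regions)[c("chrom", "start", "end")])
  if (nrow(annotation) == 0) return(dplyr::as_tibble(annotation))
  ov <- overlap_with_set(annotation, reg)
  len <- annotation$end - annotation$start
  keep <- ov >= 1 & ov >= min_overlap_frac * len
  dplyr::as_tibble(annotation[keep, , drop = FALSE])
}

#' Homology counts for a gene set
#'
#' Joins a flat homology table onto a gene set and counts, per the published
#' statistics layout: genes, genes with at least one homolog in the query
#' species, and genes with a one-to-one (single copy) ortholog. By
#' construction `n_one_to_one <= n_hom <= n_genes`; published tables violating
#' that ordering cannot arise from per-gene counting.
#'
#' @param genes gene tibble with unique `gene_id`.
#' @param map homology tibble: `gene_id`, `homolog_species`, `homolog_id`,
#'   `one_to_one` (logical). `(gene_id, homolog_species)` must be unique among
#'   one-to-one rows.
#' @param species homolog species code to count (e.g. `"HSA"`).
#' @return One-row tibble: `species`, `n_genes`, `n_hom`, `n_one_to_one`.
#' @export
homology_summary <- function(genes, map, species) {
  stopifnot("gene_id" %in% names(genes))
  need <- c("gene_id", "homolog_species", "one_to_one")
  if (nrow(map) > 0 && !all(need %in% names(map))) {
    rlang::abort(paste0("homology map needs columns: ",
                        paste(need, collapse = ", ")))
  }
  rel <- if (nrow(map) > 0) {
    map[map$homolog_species == species & map$gene_id %in% genes$gene_id, ,
        drop = FALSE]
  } else map
  if (nrow(rel) > 0) {
    oto <- rel[rel$one_to_one, , drop = FALSE]
    if (anyDuplicated(oto[c("gene_id", "homolog_species")])) {
      rlang::abort("duplicate (gene_id, species) pairs among one-to-one rows")
    }
  }
  tibble::tibble(species = species,
                 n_genes = nrow(genes),
                 n_hom = if (nrow(rel) > 0) length(unique(rel$gene_id)) else 0L,
                 n_one_to_one = if (nrow(rel) > 0)
                   length(unique(rel$gene_id[rel$one_to_one])) else 0L)
}

#' Retrogene pattern: exons present, introns absent
#'
#' A processed retrogene inserted into the sampled chromosome shows exon
#' sequence without intron sequence. Given one gene's exon intervals, the
#' flag is `TRUE` when every exon overlaps the regions while at least one
#' inferred intron (the gap between successive exons) does not. Genes with a
#' single exon have no introns and return `NA` (not applicable).
#'
#' @param exons interval tibble of one gene's exons (same chromosome).
#' @param regions interval tibble of detected regions.
#' @return `TRUE`, `FALSE` or `NA`.
#' @export
retrogene_flag <- function(exons, regions) {
  check_intervals(exons)
  if (length(unique(exons$chrom)) > 1) {
    rlang::abort("exons of one gene must share a chromosome")
  }
  ex <- merge_intervals(exons[c("chrom", "start", "end")])
  if (nrow(ex) < 2) return(NA)
  introns <- tibble::tibble(chrom = ex$chrom[-nrow(ex)],
                            start = ex$end[-nrow(ex)],
                            end = ex$start[-1])
  reg <- merge_intervals(dplyr::as_tibble(regions)[c("chrom", "start", "end")])
  all(overlap_with_set(ex, reg) > 0) && any(overlap_with_set(introns, reg) == 0)
}

#' Read gene records from a GFF3 annotation
#'
#' Imports a GFF3 file (via rtracklayer), keeps features of the requested
#' type and returns them as a gene tibble in 0-based half-open coordinates.
#'
#' @param path GFF3 file path.
#' @param feature_type feature type to keep (default `"gene"`).
#' @return Gene tibble: `gene_id`, `chrom`, `start`, `end`, `biotype`.
#' @export
read_genes_gff3 <- function(path, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    rlang::abort("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  md <- as.data.frame(gr)
  id <- if (!is.null(md$ID)) md$ID else md$gene_id
  bt <- if (!is.null(md$biotype)) md$biotype
        else if (!is.null(md$gene_biotype)) md$gene_biotype
        else NA_character_
  tibble::tibble(gene_id = as.character(id),
                 chrom = as.character(md$seqnames),
                 start = md$start - 1,   # GFF is 1-based inclusive
                 end = as.numeric(md$end),
                 biotype = as.character(bt))
}

#' Read a flat homology table
#'
#' Tab-separated with header: `gene_id`, `homolog_species`, `homolog_id`,
#' `one_to_one` (TRUE/FALSE).
#'
#' @param path TSV file path.
#' @return Homology tibble.
#' @export
read_homology_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    homolog_species = readr::col_character(),
    homolog_id = readr::col_character(),
    one_to_one = readr::col_logical()))
}

#' Per-sample gene content statistics
#'
#' The per-species statistics row: sample, reference, total region size, gene
#' count and homology counts for one query species.
#'
#' @param sample_id,reference labels for the row.
#' @param regions disjoint region tibble.
#' @param annotation gene tibble.
#' @param map homology tibble (may be empty).
#' @param species homolog species code (default `"HSA"`).
#' @return One-row tibble: `sample_id`, `reference`, `region_bp`, `n_genes`,
#'   `n_hom`, `n_one_to_one`.
#' @export
gene_content_report <- function(sample_id, reference, regions, annotation,
                                map, species = "HSA") {
  genes <- genes_in_regions(annotation, regions)
  hs <- homology_summary(genes, map, species)
  tibble::tibble(sample_id = sample_id, reference = reference,
                 region_bp = total_size(merge_intervals(
                   dplyr::as_tibble(regions)[c("chrom", "start", "end")])),
                 n_genes = hs$n_genes, n_hom = hs$n_hom,
                 n_one_to_one = hs$n_one_to_one)
}
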