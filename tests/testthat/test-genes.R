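toy_genes <- function() {
  tibble::tibble(gene_id = paste0("g", 1:5),
                 chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
                 start = c(0, 5000, 20000, 0, 9000),
                 end = c(1000, 6000, 21000, 500, 10000),
                 biotype = c("protein_coding", "lincRNA", "protein_coding",
                             "pseudogene", "protein_coding"))
}

test_that("gene-region overlap uses the any-overlap rule", {
  genes <- toy_genes()
  regions <- tibble::tibble(chrom = c("chr1", "chr2"),
                            start = c(500, 9999), end = c(5500, 20000))
  hit <- genes_in_regions(genes, regions)
  # g1 and g2 overlap the chr1 region; g5 overlaps chr2 by exactly 1 bp
  expect_equal(hit$gene_id, c("g1", "g2", "g5"))
  # region order must not matter; each gene appears once
  expect_equal(genes_in_regions(genes, regions[2:1, ]), hit)
  expect_equal(anyDuplicated(hit$gene_id), 0)
  # a stricter overlap fraction drops the 1 bp touch
  expect_equal(genes_in_regions(genes, regions, min_overlap_frac = 0.5)$gene_id,
               c("g1", "g2"))
  expect_error(genes_in_regions(dplyr::mutate(genes, gene_id = "x"), regions),
               "unique")
})

test_that("gene-region overlap equals a brute-force all-pairs scan", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      genes <- tibble::tibble(gene_id = paste0("g", seq_len(n)),
                              chrom = sample(c("chr1", "chr2"), n, TRUE),
                              start = sample(0:20000, n))
      genes$end <- genes$start + sample(100:3000, n, TRUE)
      k <- sample(1:6, 1)
      st <- sample(0:20000, k)
      regions <- merge_intervals(gintervals(
        sample(c("chr1", "chr2"), k, TRUE), st, st + sample(500:5000, k, TRUE)))
      got <- genes_in_regions(genes, regions)$gene_id
      want <- genes$gene_id[vapply(seq_len(n), function(i) {
        any(regions$chrom == genes$chrom[i] &
              pmin(regions$end, genes$end[i]) -
              pmax(regions$start, genes$start[i]) >= 1)
      }, logical(1))]
      expect_equal(got, want)
    }
  })
})

test_that("homology summary preserves the count ordering", {
  genes <- tibble::tibble(gene_id = paste0("g", 1:10),
                          chrom = "chr1", start = (0:9) * 1000,
                          end = (0:9) * 1000 + 500)
  # 6 genes with a human homolog, 4 of them one-to-one
  map <- tibble::tibble(gene_id = paste0("g", 1:6),
                        homolog_species = "HSA",
                        homolog_id = paste0("h", 1:6),
                        one_to_one = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  hs <- homology_summary(genes, map, "HSA")
  expect_equal(unlist(hs[c("n_genes", "n_hom", "n_one_to_one")],
                      use.names = FALSE), c(10L, 6L, 4L))

  empty <- homology_summary(genes, map[0, ], "HSA")
  expect_equal(unlist(empty[c("n_genes", "n_hom", "n_one_to_one")],
                      use.names = FALSE), c(10L, 0L, 0L))

  all1 <- homology_summary(genes, tibble::tibble(
    gene_id = genes$gene_id, homolog_species = "HSA",
    homolog_id = genes$gene_id, one_to_one = TRUE), "HSA")
  expect_equal(all1$n_genes, all1$n_hom)
  expect_equal(all1$n_hom, all1$n_one_to_one)

  # other species' rows are ignored
  hs2 <- homology_summary(genes, dplyr::mutate(map, homolog_species = "MMU"),
                          "HSA")
  expect_equal(hs2$n_hom, 0L)

  dup <- dplyr::bind_rows(map, map[1, ])
  expect_error(homology_summary(genes, dup, "HSA"), "duplicate")

  withr::with_seed(77, {
    for (rep in 1:10) {
      n <- sample(3:30, 1)
      g <- tibble::tibble(gene_id = paste0("g", seq_len(n)), chrom = "chr1",
                          start = seq_len(n) * 100, end = seq_len(n) * 100 + 50)
      pick <- sample(n, sample(0:n, 1))
      mp <- tibble::tibble(gene_id = paste0("g", pick),
                           homolog_species = "HSA",
                           homolog_id = paste0("h", pick),
                           one_to_one = sample(c(TRUE, FALSE), length(pick),
                                               TRUE))
      s <- homology_summary(g, mp, "HSA")
      expect_lte(s$n_one_to_one, s$n_hom)
      expect_lte(s$n_hom, s$n_genes)
    }
  })
})

test_that("retrogene flag needs exons in and at least one intron out", {
  # regions covering exactly the exon footprint, as for a processed retrogene
  regions <- tibble::tibble(chrom = "chr1", start = c(1100, 3100, 5100),
                            end = c(1300, 3300, 5300))
  exons <- gintervals("chr1", c(1100, 3100, 5100), c(1300, 3300, 5300))
  expect_true(retrogene_flag(exons, regions))

  # whole gene (exons and introns) inside one region: not a retrogene
  whole_region <- tibble::tibble(chrom = "chr1", start = 1000, end = 1500)
  whole <- gintervals("chr1", c(1010, 1200, 1400), c(1100, 1300, 1490))
  expect_false(retrogene_flag(whole, whole_region))

  # one exon outside: not a retrogene
  ex_out <- gintervals("chr1", c(1100, 2600, 5100), c(1300, 2700, 5300))
  expect_false(retrogene_flag(ex_out, regions))

  # single-exon gene: no introns, not applicable
  expect_true(is.na(retrogene_flag(gintervals("chr1", 1100, 1200), regions)))
  expect_error(retrogene_flag(gintervals(c("chr1", "chr2"), c(0, 0),
                                         c(10, 10)), regions), "chromosome")
})

test_that("GFF3 annotations load as 0-based gene tibbles", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=geneA;biotype=protein_coding",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=tA;Parent=geneA",
    "chr2\tsrc\tgene\t501\t900\t.\t-\t.\tID=geneB;biotype=lincRNA"), gff)
  g <- read_genes_gff3(gff)
  expect_equal(g$gene_id, c("geneA", "geneB"))
  expect_equal(g$start, c(1000, 500))   # converted to 0-based half-open
  expect_equal(g$end, c(2000, 900))
  expect_equal(g$biotype, c("protein_coding", "lincRNA"))
})

test_that("gene content report combines region size and homology counts", {
  genes <- toy_genes()
  regions <- tibble::tibble(chrom = "chr1", start = 0, end = 10000)
  map <- tibble::tibble(gene_id = c("g1", "g2"), homolog_species = "HSA",
                        homolog_id = c("h1", "h2"),
                        one_to_one = c(TRUE, FALSE))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(map, tsv)
  homs <- read_homology_tsv(tsv)
  rep <- gene_content_report("VVUB", "CanFam3.1", regions, genes, homs)
  expect_equal(rep$region_bp, 10000)
  expect_equal(rep$n_genes, 2L)
  expect_equal(rep$n_hom, 2L)
  expect_equal(rep$n_one_to_one, 1L)
})
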