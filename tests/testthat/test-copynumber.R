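make_flat_track <- function(n = 300, count = 30, chrom = "chr1", w = 1000) {
  depth_track(tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * w,
                             end = seq_len(n) * w, count = count),
              window_size = w)
}

test_that("depth_track validates windows and warns on small window sizes", {
  expect_warning(make_flat_track(w = 200), "500")
  bad <- tibble::tibble(chrom = "chr1", start = 0, end = 2000, count = 1)
  expect_error(depth_track(bad, window_size = 1000), "wider")
  neg <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, count = -1)
  expect_error(depth_track(neg), ">= 0")
})

test_that("bedGraph round-trips a depth track", {
  tr <- make_flat_track(n = 120, count = 7)
  tmp <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, tmp)
  back <- read_bedgraph(tmp, window_size = 1000)
  expect_equal(back$start, tr$start)
  expect_equal(back$count, tr$count)
})

test_that("normalization divides by the unmasked genome median", {
  tr <- make_flat_track(n = 200, count = 10)
  nd <- normalize_depth(tr)
  expect_true(all(nd$norm == 1))
  expect_equal(genome_median(nd), 10)

  expect_error(normalize_depth(make_flat_track(n = 99)), "100 windows")
  expect_error(normalize_depth(make_flat_track(n = 200, count = 0)), "zero")

  # masked windows are excluded from the median but still normalized
  x <- make_flat_track(n = 300, count = 10)
  x$count[1:160] <- 1000
  nd2 <- normalize_depth(x, exclusion = gintervals("chr1", 0, 1.6e5))
  expect_equal(genome_median(nd2), 10)
  expect_true(all(nd2$norm[1:160] == 100))
  expect_true(all(nd2$masked[1:160]))

  # without the mask the (majority) amplified stretch inflates the median
  nd3 <- normalize_depth(x)
  expect_gt(genome_median(nd3), 10)

  # simulated null genome at baseline 30: median within 5% of the baseline
  sc <- simulation_scenario(ref_index("chr1", 1e7), seed = 2,
                            wgs_baseline_depth = 30)
  nd4 <- normalize_depth(simulate_depth(sc))
  expect_lt(abs(genome_median(nd4) - 30) / 30, 0.05)
})

test_that("noiseless segmentation recovers planted copy numbers exactly", {
  ref <- ref_index(c("chr1", "chr2"), c(2e6, 1e6))
  reg <- gintervals("chr1", c(4e5, 12e5), c(7e5, 14e5), extra_copies = c(6, 1))
  del <- gintervals("chr1", 5e5, 5.5e5)
  sc <- simulation_scenario(ref, reg, deletions = del, seed = 1)
  nd <- normalize_depth(noiseless_depth(sc))
  seg <- segment_depth(nd)

  # chr2 is flat diploid: a single segment
  expect_equal(sum(seg$chrom == "chr2"), 1)
  expect_equal(seg$copy_number[seg$chrom == "chr2"], 2)

  # planted structure on chr1: 2 | 8 | 0 | 8 | 2 | 3 | 2
  s1 <- seg[seg$chrom == "chr1", ]
  expect_equal(s1$copy_number, c(2, 8, 0, 8, 2, 3, 2))
  expect_equal(s1$start[2], 4e5)
  expect_equal(s1$end[4], 7e5)
  expect_equal(s1$start[3], 5e5)
  expect_equal(s1$end[3], 5.5e5)
  # round(2 * normalized depth) equals the planted copy number everywhere
  expect_equal(round(2 * s1$normalized_depth), s1$copy_number)

  # segmentation conserves windows: lengths tile each chromosome
  tiled <- dplyr::summarise(seg, bp = sum(end - start), .by = chrom)
  expect_equal(tiled$bp[tiled$chrom == "chr1"], 2e6)
  expect_equal(tiled$bp[tiled$chrom == "chr2"], 1e6)
  expect_error(segment_depth(noiseless_depth(sc)), "normalize")
})

test_that("noisy segmentation finds a planted amplification near its boundaries", {
  ref <- ref_index("chr1", 15e6)
  reg <- gintervals("chr1", 14e6, 14.3e6, extra_copies = 6)
  sc <- simulation_scenario(ref, reg, seed = 42, wgs_baseline_depth = 30)
  seg <- segment_depth(normalize_depth(simulate_depth(sc)))
  amp <- seg[seg$copy_number > 2, ]
  expect_equal(nrow(amp), 1)
  expect_equal(amp$copy_number, 8)
  expect_lte(abs(amp$start - 14e6), 2000)   # within 2 windows of truth
  expect_lte(abs(amp$end - 14.3e6), 2000)

  # planted homozygous deletion: a copy-number-0 segment
  reg2 <- gintervals("chr1", 2e6, 2.4e6, extra_copies = 0)
  del2 <- gintervals("chr1", 2.1e6, 2.2e6)
  sc2 <- simulation_scenario(ref, reg2, deletions = del2, seed = 6)
  seg2 <- segment_depth(normalize_depth(simulate_depth(sc2)))
  zero <- seg2[seg2$copy_number == 0, ]
  expect_equal(nrow(zero), 1)
  expect_lte(abs(zero$start - 2.1e6), 2000)
  expect_lte(abs(zero$end - 2.2e6), 2000)
})

test_that("per-B copies divide extra copies by the B count", {
  seg <- tibble::tibble(extra_copies = c(6, 20, 0, -2, 1))
  out <- per_b_copies(seg, n_b = 3)
  expect_equal(out$per_b, c(2, 20 / 3, 0, -2 / 3, 1 / 3))
  expect_equal(out$per_b_reported, c(2L, 7L, 0L, -1L, 0L))
  expect_error(per_b_copies(seg, n_b = 0), ">= 1")
})

test_that("concordance matches by reciprocal overlap and pools breakpoints", {
  reg <- tibble::tibble(chrom = "chr1", start = c(1e6, 5e6), end = c(2e6, 5.5e6))
  seg <- dplyr::mutate(reg, copy_number = c(5, 8))
  same <- concordance(reg, seg)
  expect_equal(same$median_breakpoint_diff, 0)
  expect_equal(same$region_recovery, 1)

  shifted <- dplyr::mutate(seg, start = start + 700, end = end + 700)
  sh <- concordance(reg, shifted)
  expect_equal(sh$median_breakpoint_diff, 700)
  expect_equal(nrow(sh$matches), 2)

  # symmetry: swapping the two call sets preserves the median
  rev <- concordance(shifted[c("chrom", "start", "end")],
                     dplyr::mutate(reg, copy_number = 5))
  expect_equal(rev$median_breakpoint_diff, sh$median_breakpoint_diff)

  # diploid segments are never matched; unmatched sides are reported
  dip <- dplyr::mutate(reg, copy_number = 2)
  none <- concordance(reg, dip)
  expect_equal(nrow(none$matches), 0)
  expect_true(is.na(none$median_breakpoint_diff))
  expect_equal(nrow(none$only_regions), 2)

  # reciprocal overlap below min_overlap does not match
  small <- tibble::tibble(chrom = "chr1", start = 1e6, end = 1.1e6,
                          copy_number = 5)
  expect_equal(nrow(concordance(reg, small, min_overlap = 0.5)$matches), 0)

  gl <- glance(sh)
  expect_equal(gl$n_matched, 2L)
  expect_equal(gl$median_breakpoint_diff, 700)
})

test_that("copy spectrum counts region parts by extra copies", {
  expect_equal(nrow(copy_spectrum(
    tibble::tibble(chrom = "chr1", start = 0, end = 1e4, extra_copies = 3),
    tibble::tibble(chrom = "chr2", start = 0, end = 1e4))), 0)

  # one region split 2/8/2: one part at extra 6, two at extra 0
  segs <- tibble::tibble(chrom = "chr1",
                         start = c(0e5, 1e5, 2e5), end = c(1e5, 2e5, 3e5),
                         copy_number = c(2, 8, 2), extra_copies = c(0, 6, 0))
  reg <- tibble::tibble(chrom = "chr1", start = 0, end = 3e5)
  sp <- copy_spectrum(segs, reg)
  expect_equal(sp$extra_copies, c(0, 6))
  expect_equal(sp$n, c(2L, 1L))

  # noiseless heterogeneous scenario: histogram matches the planted multiset
  ref <- ref_index("chr1", 2e7)
  reg2 <- gintervals("chr1", seq(2e6, 18e6, by = 4e6),
                     seq(2e6, 18e6, by = 4e6) + 3e5,
                     extra_copies = c(1, 6, 2, 6, 20))
  sc <- simulation_scenario(ref, reg2, seed = 1)
  nd <- normalize_depth(noiseless_depth(sc))
  seg2 <- segment_depth(nd)
  calls <- dplyr::mutate(reg2, sample_id = "s")
  sp2 <- copy_spectrum(seg2[seg2$extra_copies > 0, ], calls)
  got <- rep(sp2$extra_copies, sp2$n)
  expect_equal(sort(got), sort(reg2$extra_copies))
})
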