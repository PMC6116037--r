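test_that("spacing model fit requires data and flags degenerate input", {
  # 19 distances: below the minimum
  expect_error(fit_spacing_model(distance_track(
    positions_from_dists(rep(100, 19)))), "at least 20")
  # identical distances: one component only, no detection contrast
  m <- fit_spacing_model(distance_track(positions_from_dists(rep(500, 50))))
  expect_true(m$no_signal)
  expect_true(m$converged)
  # a no-signal model yields an empty call set with a warning
  tr <- distance_track(positions_from_dists(rep(500, 50)))
  expect_warning(calls <- segment_chromosome(tr, m), "no target signal")
  expect_equal(nrow(calls), 0)
})

test_that("EM recovers well-separated mixture components", {
  withr::with_seed(7, {
    n <- 10000
    d <- pmax(2, round(ifelse(stats::runif(n) < 0.5,
                              stats::rexp(n, 1 / 100),
                              stats::rexp(n, 1 / 10000))))
    m <- fit_spacing_model(distance_track(positions_from_dists(d)))
    expect_false(m$no_signal)
    expect_lt(abs(m$mean_target - 100) / 100, 0.1)
    expect_lt(abs(m$mean_background - 10000) / 10000, 0.1)
    expect_lt(abs(m$mixing_weight - 0.5), 0.05)
  })
})

test_that("tidy and glance summarize the fitted model", {
  m <- fit_spacing_model(distance_track(positions_from_dists(
    c(rep(100, 30), rep(10000, 30)))))
  td <- tidy(m)
  expect_equal(td$component, c("target", "background"))
  expect_lt(td$mean_gap[1], td$mean_gap[2])
  expect_equal(sum(td$weight), 1)
  gl <- glance(m)
  expect_true(gl$converged)
  expect_equal(gl$n_gaps, 60L)
})

test_that("most-probable state path equals exhaustive enumeration (<= 12 gaps)", {
  model <- toy_model(100, 10000, w = 0.3)
  withr::with_seed(19, {
    for (rep in 1:40) {
      n <- sample(2:12, 1)
      d <- ifelse(stats::runif(n) < 0.5, stats::rexp(n, 1 / 100),
                  stats::rexp(n, 1 / 10000))
      p <- sample(c(1e-3, 1e-2, 0.2), 1)
      expect_equal(dopseqr:::viterbi_two_state(d, model, p),
                   bf_best_path(d, model, p))
    }
  })
})

test_that("segmentation spans flanking positions and respects state runs", {
  model <- toy_model(100, 50000, w = 0.5)
  # all distances strongly target-like: one region spanning all positions
  tr <- distance_track(positions_from_dists(rep(100, 30), width = 40))
  calls <- segment_chromosome(tr, model)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$start, 0)
  expect_equal(calls$end, 30 * 100 + 40)
  expect_equal(calls$n_positions, 31L)

  # a dense run flanked by background distances: call covers only the run
  d <- c(50000, 60000, rep(100, 10), 70000, 55000)
  tr2 <- distance_track(positions_from_dists(d, width = 40))
  calls2 <- segment_chromosome(tr2, model)
  expect_equal(nrow(calls2), 1)
  expect_equal(calls2$n_positions, 11L)
  expect_equal(calls2$start, 110000)
  expect_equal(calls2$end, 110000 + 10 * 100 + 40)

  expect_error(segment_chromosome(tr2, model, switch_penalty = 0), "switch")
})

test_that("threshold mode agrees with the model on clean contrasts", {
  model <- toy_model(100, 50000, w = 0.5)
  d <- c(50000, rep(100, 8), 60000, rep(120, 6), 45000)
  tr <- distance_track(positions_from_dists(d, width = 40))
  a <- segment_chromosome(tr, model)
  b <- segment_threshold(tr, cutoff = 5000)
  expect_equal(a[c("chrom", "start", "end", "n_positions")],
               b[c("chrom", "start", "end", "n_positions")])
})

test_that("detection is scale-equivariant", {
  sc <- desk_scenario(seed = 14)
  p <- simulate_positions(sc)
  tr <- distance_track(p)
  m <- fit_spacing_model(tr)
  calls <- assign_tiers(segment_chromosome(tr, m))

  p10 <- dplyr::mutate(p, start = start * 10, end = end * 10)
  tr10 <- distance_track(p10)
  m10 <- fit_spacing_model(tr10)
  calls10 <- assign_tiers(segment_chromosome(tr10, m10))
  expect_equal(calls10$start, calls$start * 10)
  expect_equal(calls10$end, calls$end * 10)
  expect_equal(calls10$n_positions, calls$n_positions)
  expect_equal(calls10$tier, calls$tier)
})

test_that("tier assignment follows the >5 / 2..5 / <2 position rule", {
  calls <- tibble::tibble(chrom = "chr1",
                          start = c(0, 100, 200, 300), end = c(50, 150, 250, 350),
                          sample_id = "s",
                          n_positions = c(6L, 5L, 3L, 1L),
                          mean_gap = 10)
  t <- assign_tiers(calls, strong_min = 5)
  expect_equal(nrow(t), 3)  # the 1-position call is dropped
  expect_equal(t$tier, c("strong", "weak", "weak"))
  expect_error(assign_tiers(calls, strong_min = 1), ">= 2")
})

test_that("internal coverage voids become deletions at the printed coordinates", {
  model <- toy_model(200, 50000)
  # uniform dense region: no deletions
  tr <- distance_track(positions_from_dists(rep(200, 20), width = 50))
  call <- tibble::tibble(chrom = "chr1", start = 0, end = 19 * 200 + 50,
                         sample_id = "s", n_positions = 21L, mean_gap = 150)
  out <- call_deletions(call, tr, model)
  expect_equal(nrow(out$deletions[[1]]), 0)

  # one 170 kb void inside an otherwise dense region: one deletion
  d <- c(rep(200, 10), 170000, rep(200, 10))
  tr2 <- distance_track(positions_from_dists(d, width = 50))
  call2 <- tibble::tibble(chrom = "chr1", start = 0, end = sum(d) + 50,
                          sample_id = "s", n_positions = 22L, mean_gap = NA)
  out2 <- call_deletions(call2, tr2, model)
  expect_equal(nrow(out2$deletions[[1]]), 1)
  expect_equal(out2$deletions[[1]]$end - out2$deletions[[1]]$start, 170000 - 50)

  # fox CFA13:34 Mbp region rebuilt with position voids at its two printed
  # deletions: both recovered at the exact printed coordinates
  fox <- fox_b_regions()
  host <- fox[fox$chrom == "CFA13" & fox$start == 34034756, ]
  dels <- fox_b_deletions()
  dels <- dels[dels$chrom == "CFA13", ]
  keep_starts <- seq(host$start, host$end - 100, by = 200)
  void <- rep(FALSE, length(keep_starts))
  for (j in seq_len(nrow(dels))) {
    void <- void | (keep_starts + 100 > dels$start[j] &
                      keep_starts < dels$end[j])
  }
  starts <- keep_starts[!void]
  # position widths reach exactly to each deletion's printed start
  ends <- pmin(starts + 100, host$end)
  for (j in seq_len(nrow(dels))) {
    ends[which.max(starts[starts < dels$start[j]])] <- dels$start[j]
    starts[which(starts > dels$end[j])[1]] <- dels$end[j]
  }
  pos <- tibble::tibble(chrom = "CFA13", start = starts, end = ends)
  tr3 <- distance_track(pos)
  call3 <- tibble::tibble(chrom = "CFA13", start = host$start, end = host$end,
                          sample_id = "VVUB", n_positions = nrow(pos),
                          mean_gap = NA)
  out3 <- call_deletions(call3, tr3, model)
  found <- out3$deletions[[1]]
  expect_equal(nrow(found), 2)
  expect_equal(found$start, dels$start)
  expect_equal(found$end, dels$end)
})

test_that("region_report totals are consistent with interval arithmetic", {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), sample_id = character(),
                          n_positions = integer(), mean_gap = numeric())
  expect_equal(nrow(region_report(empty)), 0)

  calls <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                          start = c(0, 1000, 0), end = c(100, 1400, 50),
                          sample_id = c("a", "a", "b"),
                          n_positions = c(10L, 10L, 10L), mean_gap = 1)
  rep <- region_report(calls)
  expect_equal(rep$n_regions, c(2L, 1L))
  expect_equal(rep$total_bp, c(500, 50))
})
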