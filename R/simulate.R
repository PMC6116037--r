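#' Define a simulation scenario with known ground truth
#'
#' A scenario describes an isolated-chromosome sequencing experiment and a
#' matched whole-genome sequencing (WGS) run over the same reference: a set of
#' planted regions (the DNA actually present on the sampled B chromosome),
#' optional internal deletions nested inside them, the B-chromosome count of
#' the individual, and the spacing/depth parameters that drive the generators.
#' The detection signal is the contrast between dense read positions inside
#' planted regions and the sparse contamination background outside them.
#'
#' Defaults reflect the study conditions this package models: three B
#' chromosomes per individual, 1000-bp depth windows, ~30 reads per window of
#' WGS baseline, ~200 bp spacing between read positions inside target regions
#' against ~50 kb background spacing.
#'
#' @param reference a [ref_index()].
#' @param planted_regions interval tibble with an `extra_copies` column
#'   (integer >= 0, copies above the diploid two carried by the Bs); may be
#'   empty for a null genome.
#' @param deletions interval tibble of spans nested strictly inside planted
#'   regions; they yield no read positions and are modeled as homozygous
#'   (copy number 0) in the depth track.
#' @param n_b number of B chromosomes in the individual (>= 1).
#' @param target_spacing_mean,background_spacing_mean mean distance (bp)
#'   between successive read-position starts inside / outside planted regions.
#'   A contrast below 10x draws a warning: the method's signal is this ratio.
#' @param position_width_mean mean of the exponential part of position widths;
#'   widths are 36 bp plus an exponential draw (read-length-like floor).
#' @param wgs_baseline_depth expected reads per window at the diploid state.
#' @param window_size depth window in bp (default 1000).
#' @param dropout_rate probability in `[0, 1)` that a generated position is
#'   lost (whole-chromosome amplification dropout stand-in).
#' @param seed master seed; position and depth tracks use fixed documented
#'   offsets (`seed`, `seed + 1`) so adding one track never perturbs the other.
#' @return A list of class `sim_scenario`.
#' @export
simulation_scenario <- function(reference,
                                planted_regions = NULL,
                                deletions = NULL,
                                n_b = 3,
                                target_spacing_mean = 200,
                                background_spacing_mean = 5e4,
                                position_width_mean = 64,
                                wgs_baseline_depth = 30,
                                window_size = 1000,
                                dropout_rate = 0,
                                seed = 1L) {
  stopifnot(inherits(reference, "ref_index"))
  if (is.null(planted_regions)) {
    planted_regions <- tibble::tibble(chrom = character(), start = numeric(),
                                      end = numeric(), extra_copies = numeric())
  }
  if (!"extra_copies" %in% names(planted_regions)) {
    planted_regions$extra_copies <- 0
  }
  check_intervals(planted_regions, ref = reference)
  check_disjoint(planted_regions, "planted_regions")
  if (any(planted_regions$extra_copies < 0)) {
    rlang::abort("extra_copies must be >= 0")
  }
  if (is.null(deletions)) {
    deletions <- tibble::tibble(chrom = character(), start = numeric(),
                                end = numeric())
  }
  if (nrow(deletions) > 0) {
    check_intervals(deletions, ref = reference)
    check_disjoint(deletions, "deletions")
    host <- purrr::map_lgl(seq_len(nrow(deletions)), function(i) {
      any(planted_regions$chrom == deletions$chrom[i] &
            planted_regions$start < deletions$start[i] &
            planted_regions$end > deletions$end[i])
    })
    if (!all(host)) {
      rlang::abort("every deletion must nest strictly inside a planted region")
    }
  }
  if (target_spacing_mean <= 0 || background_spacing_mean <= 0) {
    rlang::abort("spacing means must be > 0")
  }
  if (position_width_mean <= 0) rlang::abort("position_width_mean must be > 0")
  if (wgs_baseline_depth <= 0) rlang::abort("wgs_baseline_depth must be > 0")
  if (n_b < 1) rlang::abort("n_b must be >= 1")
  if (window_size < 1) rlang::abort("window_size must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    rlang::abort("dropout_rate must be in [0, 1)")
  }
  if (background_spacing_mean / target_spacing_mean < 10) {
    rlang::warn("background/target spacing contrast below 10x: detection signal is weak")
  }
  structure(list(reference = reference,
                 planted_regions = dplyr::as_tibble(planted_regions),
                 deletions = dplyr::as_tibble(deletions),
                 n_b = as.integer(n_b),
                 target_spacing_mean = target_spacing_mean,
                 background_spacing_mean = background_spacing_mean,
                 position_width_mean = position_width_mean,
                 wgs_baseline_depth = wgs_baseline_depth,
                 window_size = as.integer(window_size),
                 dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# evaluate code under a fixed seed, restoring the caller's RNG state after
with_fixed_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# piecewise spacing plan for one chromosome: rows of (start, end, mean) where
# mean NA marks a deletion void (no positions at all)
chrom_spacing_plan <- function(scenario, cc, len) {
  reg <- scenario$planted_regions
  reg <- sort_intervals(reg[reg$chrom == cc, , drop = FALSE])
  del <- scenario$deletions
  del <- sort_intervals(del[del$chrom == cc, , drop = FALSE])
  cuts <- sort(unique(c(0, len, reg$start, reg$end, del$start, del$end)))
  seg <- tibble::tibble(start = cuts[-length(cuts)], end = cuts[-1])
  mid <- (seg$start + seg$end) / 2
  in_reg <- point_in_intervals(rep(cc, nrow(seg)), mid, reg)
  in_del <- point_in_intervals(rep(cc, nrow(seg)), mid, del)
  seg$mean <- ifelse(in_del, NA_real_,
                     ifelse(in_reg, scenario$target_spacing_mean,
                            scenario$background_spacing_mean))
  seg
}

# successive starts spaced Exp(mean) inside [from, to); first start offset by
# one exponential draw from `from`
draw_starts <- function(from, to, mean) {
  if (is.na(mean)) return(numeric(0))
  span <- to - from
  expected <- span / mean
  out <- numeric(0)
  cur <- from
  repeat {
    k <- max(16, ceiling(expected - length(out) + 4 * sqrt(expected + 1)))
    s <- cur + cumsum(stats::rexp(k, rate = 1 / mean))
    out <- c(out, s[s < to])
    cur <- s[length(s)]
    if (cur >= to) break
  }
  out
}

#' Simulate merged read positions for an isolated-chromosome sample
#'
#' Inside planted regions (minus deletions) successive position starts are
#' spaced `Exponential(target_spacing_mean)`; outside them,
#' `Exponential(background_spacing_mean)`; planted deletions emit nothing.
#' Position widths are 36 bp plus an exponential draw, clipped so that
#' positions never overlap (downstream gaps stay strictly positive) and never
#' cross the chromosome end. Each position is independently retained with
#' probability `1 - dropout_rate`; exponential thinning keeps the surviving
#' spacing exponential with mean scaled by `1 / (1 - dropout_rate)`. The
#' output is deterministic for a fixed scenario seed.
#'
#' @param scenario a [simulation_scenario()].
#' @return A tibble of merged positions (`chrom`, `start`, `end`,
#'   `read_count`) with the ground-truth manifest attached as attribute
#'   `"manifest"` (see [sim_manifest()]).
#' @export
simulate_positions <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  ref <- scenario$reference
  pos <- with_fixed_seed(scenario$seed, {
    purrr::map(seq_len(nrow(ref)), function(i) {
      plan <- chrom_spacing_plan(scenario, ref$chrom[i], ref$length[i])
      starts <- purrr::map(seq_len(nrow(plan)), function(j) {
        draw_starts(plan$start[j], plan$end[j], plan$mean[j])
      })
      starts <- floor(sort(unlist(starts)))
      starts <- unique(starts)
      if (scenario$dropout_rate > 0 && length(starts) > 0) {
        starts <- starts[stats::runif(length(starts)) >= scenario$dropout_rate]
      }
      if (length(starts) >= 2) starts <- starts[c(diff(starts) >= 2, TRUE)]
      n <- length(starts)
      if (n == 0) return(NULL)
      widths <- ceiling(36 + stats::rexp(n, rate = 1 / scenario$position_width_mean))
      ends <- starts + widths
      lim <- c(starts[-1] - 1, ref$length[i])
      ends <- pmin(ends, lim)
      keep <- ends > starts
      tibble::tibble(chrom = ref$chrom[i], start = starts[keep],
                     end = ends[keep],
                     read_count = 1 + stats::rpois(sum(keep), 0.5))
    }) |> purrr::list_rbind()
  })
  if (nrow(pos) == 0) {
    pos <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), read_count = integer())
  }
  attr(pos, "manifest") <- build_manifest(scenario, track = "positions")
  pos
}

#' Simulate a windowed WGS depth track
#'
#' Per-window read counts are drawn `Poisson(baseline * CN / 2)` where the
#' copy number CN is `2 + extra_copies` inside planted regions, 0 inside
#' planted (homozygous) deletions, and 2 elsewhere; window membership is by
#' midpoint. Deterministic for a fixed scenario seed (offset +1 from the
#' position track so the two tracks are independent but reproducible).
#'
#' @inheritParams simulate_positions
#' @return A [depth_track()] tibble (`chrom`, `start`, `end`, `count`) with
#'   the ground-truth manifest attached as attribute `"manifest"`.
#' @export
simulate_depth <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  ref <- scenario$reference
  w <- scenario$window_size
  track <- with_fixed_seed(scenario$seed + 1L, {
    purrr::map(seq_len(nrow(ref)), function(i) {
      n_win <- ceiling(ref$length[i] / w)
      start <- (seq_len(n_win) - 1) * w
      end <- pmin(start + w, ref$length[i])
      mid <- (start + end) / 2
      cc <- rep(ref$chrom[i], n_win)
      cn <- rep(2, n_win)
      reg <- scenario$planted_regions[scenario$planted_regions$chrom == ref$chrom[i], ]
      for (j in seq_len(nrow(reg))) {
        sel <- mid >= reg$start[j] & mid < reg$end[j]
        cn[sel] <- 2 + reg$extra_copies[j]
      }
      cn[point_in_intervals(cc, mid, scenario$deletions)] <- 0
      tibble::tibble(chrom = cc, start = start, end = end,
                     count = stats::rpois(n_win, scenario$wgs_baseline_depth * cn / 2))
    }) |> purrr::list_rbind()
  })
  track <- depth_track(track, window_size = w)
  attr(track, "manifest") <- build_manifest(scenario, track = "depth")
  track
}

build_manifest <- function(scenario, track) {
  list(track = track,
       seed = scenario$seed,
       n_b = scenario$n_b,
       target_spacing_mean = scenario$target_spacing_mean,
       background_spacing_mean = scenario$background_spacing_mean,
       position_width_mean = scenario$position_width_mean,
       wgs_baseline_depth = scenario$wgs_baseline_depth,
       window_size = scenario$window_size,
       dropout_rate = scenario$dropout_rate,
       reference = as.data.frame(scenario$reference[c("chrom", "length")]),
       planted_regions = as.data.frame(scenario$planted_regions),
       deletions = as.data.frame(scenario$deletions))
}

#' Ground-truth manifest of a simulated track
#'
#' Every simulated output carries a manifest recording the scenario that
#' produced it: seed, rates, reference, planted regions and deletions. The
#' manifest round-trips losslessly through JSON, so planted truth is always
#' recoverable from files alone.
#'
#' @param x a simulated positions or depth tibble.
#' @return The manifest list.
#' @export
sim_manifest <- function(x) attr(x, "manifest")

#' @rdname sim_manifest
#' @param manifest a manifest list.
#' @param path JSON file path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname sim_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("reference", "planted_regions", "deletions")) {
    m[[f]] <- tibble::as_tibble(lapply(m[[f]], unlist))
    if (nrow(m[[f]]) == 0 && f == "planted_regions") {
      m[[f]] <- tibble::tibble(chrom = character(), start = numeric(),
                               end = numeric(), extra_copies = numeric())
    }
    if (nrow(m[[f]]) == 0 && f != "planted_regions") {
      m[[f]] <- tibble::tibble(chrom = character(), start = numeric(),
                               end = numeric())
    }
  }
  m
}

#' Read and write scenario configuration as YAML
#'
#' The scenario config is a flat YAML mapping of the [simulation_scenario()]
#' arguments, with the reference and planted regions as column maps.
#'
#' @param scenario a `sim_scenario`.
#' @param path YAML file path.
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "sim_scenario"))
  obj <- build_manifest(scenario, track = "scenario")
  obj$track <- NULL
  obj$reference <- as.list(obj$reference)
  obj$planted_regions <- as.list(obj$planted_regions)
  obj$deletions <- as.list(obj$deletions)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scenario_yaml
#' @return `read_scenario_yaml()`: a `sim_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  as_cols <- function(x, template) {
    if (is.null(x) || length(x) == 0 || length(x[[1]]) == 0) return(template)
    tibble::as_tibble(lapply(x, unlist))
  }
  ref <- as_cols(obj$reference, tibble::tibble(chrom = character(),
                                               length = numeric()))
  simulation_scenario(
    reference = ref_index(ref$chrom, ref$length),
    planted_regions = as_cols(obj$planted_regions,
                              tibble::tibble(chrom = character(), start = numeric(),
                                             end = numeric(), extra_copies = numeric())),
    deletions = as_cols(obj$deletions,
                        tibble::tibble(chrom = character(), start = numeric(),
                                       end = numeric())),
    n_b = obj$n_b,
    target_spacing_mean = obj$target_spacing_mean,
    background_spacing_mean = obj$background_spacing_mean,
    position_width_mean = obj$position_width_mean,
    wgs_baseline_depth = obj$wgs_baseline_depth,
    window_size = obj$window_size,
    dropout_rate = obj$dropout_rate,
    seed = obj$seed)
}
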