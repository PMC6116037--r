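#' Pipeline configuration
#'
#' Bundles the tunable parameters of every stage with their conventional
#' defaults: alignment filters `min_mapq = 20` and `min_len = 20`, the
#' 1000-bp depth window, `strong_min = 5` positions for the automatic tier,
#' and an individual with three B chromosomes. Any field can be overridden.
#'
#' @param scenario optional [simulation_scenario()]; when present the
#'   pipeline simulates its own inputs.
#' @param positions optional merged-position tibble (used when no scenario).
#' @param reads optional raw read tibble (filtered and merged when given).
#' @param depth optional [depth_track()].
#' @param ref optional [ref_index()].
#' @param min_mapq,min_len read filters.
#' @param strong_min,switch_penalty,min_del,del_quantile,tol,max_iter
#'   detector parameters (see [fit_spacing_model()], [segment_chromosome()],
#'   [call_deletions()], [assign_tiers()]).
#' @param n_b,window_size,smooth_span,min_seg,min_overlap copy-number
#'   parameters.
#' @param join_gap,prox_max,weak_min comparative parameters.
#' @param sample_id sample label.
#' @param seed seed recorded in provenance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, positions = NULL, reads = NULL,
                            depth = NULL, ref = NULL,
                            min_mapq = 20, min_len = 20,
                            strong_min = 5, switch_penalty = 1e-3,
                            min_del = 1e4, del_quantile = 0.999,
                            tol = 1e-8, max_iter = 200,
                            n_b = 3, window_size = 1000, smooth_span = 5,
                            min_seg = 8, min_overlap = 0.5,
                            join_gap = 1e4, prox_max = 5e6, weak_min = 2,
                            sample_id = "sample", seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

provenance_line <- function(stage, inputs, params) {
  sprintf("%s\tdopseqr %s\tseed=%s\tinputs=%s\tparams=%s",
          stage, as.character(utils::packageVersion("dopseqr")),
          params$seed %||% NA,
          paste(inputs, collapse = ","),
          jsonlite::toJSON(params[setdiff(names(params), "seed")],
                           auto_unbox = TRUE, digits = NA))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate (when a scenario is given), filter,
#' merge, distance track, model fit, segmentation, tiers, deletions, depth
#' normalization and segmentation, per-B copies, concordance, copy spectrum —
#' writing each stage's output as a plain-text table under `outdir` together
#' with a provenance log (stage, package version, seed, inputs, parameters).
#' Stages only consume files/objects produced by earlier stages; re-running
#' with the same configuration reproduces every output byte for byte.
#'
#' An empty position set is not an error: the detect stage emits an empty
#' call set and the pipeline completes.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results (`positions`,
#'   `track`, `model`, `calls`, `report`, `depth_segments`, `concordance`,
#'   `spectrum` — the latter three `NULL` without depth data).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(stage, inputs, params = list(seed = config$seed)) {
    log_lines <<- c(log_lines, provenance_line(stage, inputs, params))
  }

  positions <- config$positions
  depth <- config$depth
  if (!is.null(config$scenario)) {
    positions <- simulate_positions(config$scenario)
    depth <- simulate_depth(config$scenario)
    write_bed(dplyr::mutate(positions, name = config$sample_id,
                            score = .data$read_count),
              file.path(outdir, "positions.bed"))
    write_bedgraph(depth, file.path(outdir, "depth.bedgraph"))
    write_manifest(sim_manifest(positions),
                   file.path(outdir, "truth_manifest.json"))
    note("simulate", "scenario",
         list(seed = config$scenario$seed,
              window_size = config$scenario$window_size))
  } else if (!is.null(config$reads)) {
    kept <- filter_reads(config$reads, config$min_mapq, config$min_len,
                         ref = config$ref)
    positions <- merge_reads(kept)
    note("filter+merge", "reads",
         list(seed = config$seed, min_mapq = config$min_mapq,
              min_len = config$min_len))
  }
  if (is.null(positions)) {
    rlang::abort("pipeline stage 'detect' has no input: supply scenario, reads or positions")
  }

  track <- if (nrow(positions) >= 2) distance_track(positions) else NULL
  calls <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), sample_id = character(),
                          n_positions = integer(), mean_gap = numeric(),
                          tier = character())
  model <- NULL
  if (!is.null(track) && nrow(track) >= 20) {
    rainfall_export(track, file.path(outdir, "rainfall.tsv"))
    model <- fit_spacing_model(track, max_iter = config$max_iter,
                               tol = config$tol)
    if (!model$no_signal) {
      calls <- segment_chromosome(track, model,
                                  switch_penalty = config$switch_penalty,
                                  sample_id = config$sample_id) |>
        assign_tiers(strong_min = config$strong_min) |>
        call_deletions(track, model, min_del = config$min_del,
                       del_quantile = config$del_quantile)
    }
    note("detect", "positions.bed",
         list(seed = config$seed, strong_min = config$strong_min,
              switch_penalty = config$switch_penalty,
              min_del = config$min_del, del_quantile = config$del_quantile))
  }
  flat <- if ("deletions" %in% names(calls)) {
    dplyr::select(calls, -"deletions")
  } else calls
  readr::write_tsv(flat, file.path(outdir, "region_calls.tsv"))
  readr::write_tsv(deletions_table(calls), file.path(outdir, "deletions.tsv"))
  report <- region_report(calls)
  readr::write_tsv(report, file.path(outdir, "region_report.tsv"))

  depth_segments <- NULL
  conc <- NULL
  spectrum <- NULL
  if (!is.null(depth) && nrow(depth) >= 100) {
    nd <- normalize_depth(depth,
                          exclusion = if (!is.null(config$ref))
                            ref_exclusion(config$ref) else NULL)
    depth_segments <- segment_depth(nd, smooth_span = config$smooth_span,
                                    min_seg = config$min_seg) |>
      per_b_copies(n_b = config$n_b)
    readr::write_tsv(depth_segments, file.path(outdir, "depth_segments.tsv"))
    note("cnv", "depth.bedgraph",
         list(seed = config$seed, n_b = config$n_b,
              smooth_span = config$smooth_span, min_seg = config$min_seg))
    if (nrow(calls) > 0) {
      conc <- concordance(calls, depth_segments,
                          min_overlap = config$min_overlap)
      readr::write_tsv(glance(conc), file.path(outdir, "concordance.tsv"))
      spectrum <- copy_spectrum(depth_segments, calls)
      readr::write_tsv(spectrum, file.path(outdir, "copy_spectrum.tsv"))
      note("concordance", "region_calls.tsv,depth_segments.tsv",
           list(seed = config$seed, min_overlap = config$min_overlap))
    }
  }
  writeLines(log_lines, file.path(outdir, "provenance.log"))
  invisible(list(positions = positions, track = track, model = model,
                 calls = calls, report = report,
                 depth_segments = depth_segments, concordance = conc,
                 spectrum = spectrum))
}
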