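#' Assemble a pipeline run configuration
#'
#' Key-value configuration for [run_pipeline()]. Any parameter of the
#' underlying stages can be overridden; unset values take the stage
#' defaults.
#'
#' @param input path to a batch directory or zip of ABIF files.
#' @param sequence probed nucleotide string.
#' @param modifiers per-lane modifier kinds (length = total lane count).
#' @param out_dir output directory.
#' @param signal_channel,reference_channel 1-based channel indices.
#' @param roi_start,roi_end optional manual ROI (1-based, inclusive);
#'   both NULL means automatic edge detection.
#' @param offset display residue-numbering offset.
#' @param structure optional dot-bracket string for the RDAT export.
#' @param name dataset name for the RDAT export.
#' @param params named list of stage-parameter overrides (see
#'   [align_all()], [auto_annotate()], [fit_peaks()], [detect_roi()],
#'   [subtract_constant_baseline()]).
#' @return A `run_config` object.
#' @export
run_config <- function(input, sequence, modifiers, out_dir,
                       signal_channel = 1L, reference_channel = 2L,
                       roi_start = NULL, roi_end = NULL,
                       offset = 0L, structure = "", name = "dataset",
                       params = list()) {
  structure(list(input = input, sequence = toupper(sequence),
                 modifiers = modifiers, out_dir = out_dir,
                 signal_channel = signal_channel,
                 reference_channel = reference_channel,
                 roi_start = roi_start, roi_end = roi_end,
                 offset = as.integer(offset), structure = structure,
                 name = name, params = params),
            class = "run_config")
}

.pipeline_stages <- c("load", "preprocess", "align", "annotate", "fit",
                      "export")

.stage_log <- function(log, stage, t0) {
  msg <- sprintf("[%s] stage %-10s %.2fs", format(Sys.time(), "%H:%M:%S"),
                 stage, as.numeric(Sys.time()) - t0)
  message(msg)
  c(log, msg)
}

#' Run the full analysis pipeline
#'
#' Executes load -> preprocess -> align -> annotate -> fit -> export. Each
#' stage writes a checkpoint (`checkpoint_<stage>.rds`) into the output
#' directory, so a later stage can be re-run after a manual annotation edit
#' without recomputing alignment: with `from = "annotate"` the run resumes
#' from the align checkpoint, and if an (edited) `annotation.tsv` exists in
#' the output directory it is used instead of automatic annotation.
#'
#' Outputs: `quantification.tsv` (one row per residue, one column per
#' capillary), `amplitudes.tsv`, `dataset.rdat`, `annotation.tsv`,
#' `alignment_report.tsv`, `gel_aligned.png` and `gel_annotated.png`.
#'
#' @param config a [run_config()].
#' @param from stage to start at (earlier checkpoints must exist).
#' @return Invisibly, a list with the final trace set, annotation,
#'   quantification, RDAT record, report and the stage log.
#' @export
run_pipeline <- function(config, from = "load") {
  stopifnot(inherits(config, "run_config"))
  from <- match.arg(from, .pipeline_stages)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ckpt <- function(stage) file.path(config$out_dir,
                                    sprintf("checkpoint_%s.rds", stage))
  p <- config$params
  par_or <- function(key, default) if (!is.null(p[[key]])) p[[key]] else default
  log <- character()
  t0 <- as.numeric(Sys.time())
  start_at <- match(from, .pipeline_stages)
  run_stage <- function(stage, expr) {
    if (match(stage, .pipeline_stages) < start_at) {
      f <- ckpt(stage)
      if (!file.exists(f))
        stop(sprintf("run_pipeline: checkpoint for stage '%s' missing; %s",
                     stage, "run earlier stages first"))
      return(readRDS(f))
    }
    res <- tryCatch(expr, error = function(cond)
      stop(sprintf("run_pipeline: stage '%s' failed: %s", stage,
                   conditionMessage(cond)), call. = FALSE))
    saveRDS(res, ckpt(stage))
    log <<- .stage_log(log, stage, t0)
    res
  }

  batchset <- run_stage("load", load_batches(config$input))

  traces <- run_stage("preprocess", {
    tr <- select_channels(batchset, config$signal_channel,
                          config$reference_channel)
    n_lane <- ncol(tr$signal)
    if (length(config$modifiers) != n_lane)
      stop(sprintf("%d modifiers specified for %d lanes",
                   length(config$modifiers), n_lane))
    tr <- smooth_traces(tr, window = par_or("trace_smooth", 5L))
    tr$roi <- if (!is.null(config$roi_start) && !is.null(config$roi_end))
      region_of_interest(config$roi_start, config$roi_end)
    else detect_roi(tr, smooth_window = par_or("smooth_window", 50L),
                    threshold_frac = par_or("threshold_frac", 0.05))
    subtract_constant_baseline(tr, percentile = par_or("percentile", 0.02))
  })

  alignment <- run_stage("align", align_all(
    traces,
    pw_window = par_or("pw_window", 100L),
    pw_max_offset = par_or("pw_max_offset", 50L),
    pw_lambda = par_or("pw_lambda", 0.01),
    baseline_window = par_or("baseline_window", 201L)))

  annotation <- run_stage("annotate", {
    ann_path <- file.path(config$out_dir, "annotation.tsv")
    if (start_at > match("annotate", .pipeline_stages) - 1L &&
        file.exists(ann_path)) {
      read_annotation(ann_path, config$sequence, config$offset)
    } else {
      auto_annotate(alignment$traces, config$sequence, config$modifiers,
                    mu = par_or("mu", 1.0), offset = config$offset)
    }
  })

  quant <- run_stage("fit", {
    model <- fit_peaks(alignment$traces, annotation,
                       width_factor = par_or("width_factor", 0.25))
    quantify(model)
  })

  run_stage("export", {
    od <- config$out_dir
    write_quant_table(quant, annotation,
                      file.path(od, "quantification.tsv"), value = "area")
    write_quant_table(quant, annotation,
                      file.path(od, "amplitudes.tsv"), value = "amplitude")
    write_annotation(annotation, file.path(od, "annotation.tsv"))
    write_alignment_report(alignment$report,
                           file.path(od, "alignment_report.tsv"))
    rdat <- build_rdat(quant, annotation, config$modifiers,
                       name = config$name, structure = config$structure)
    write_rdat(rdat, file.path(od, "dataset.rdat"))
    render_gel(alignment$traces, file.path(od, "gel_aligned.png"))
    render_gel(alignment$traces, file.path(od, "gel_annotated.png"),
               annotation = annotation)
    writeLines(log, file.path(od, "run_log.txt"))
    rdat
  }) -> rdat

  invisible(list(traces = alignment$traces, transforms =
                   alignment$transforms, report = alignment$report,
                 annotation = annotation, quant = quant, rdat = rdat,
                 log = log))
}
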