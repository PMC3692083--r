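#' Construct an RDAT chemical-mapping record
#'
#' The line-oriented, tab-delimited container used to exchange per-residue
#' chemical-mapping measurements: sequence, optional dot-bracket structure,
#' display numbering offset, the residue numbers measured (`seqpos`), free
#' key:value annotations (global and per data row), and one reactivity row
#' per experimental condition.
#'
#' @param sequence nucleotide string.
#' @param rows numeric matrix `n_rows x length(seqpos)`.
#' @param seqpos integer residue numbers (display numbering), one per column.
#' @param name dataset name.
#' @param structure dot-bracket string (same length as `sequence`) or "".
#' @param offset integer display-numbering offset.
#' @param global_annotations character vector of `key:value` strings.
#' @param data_annotations list of character vectors, one per row (may be
#'   empty vectors).
#' @param version RDAT version string.
#' @return An `rdat_record` object.
#' @export
rdat_record <- function(sequence, rows, seqpos, name = "dataset",
                        structure = "", offset = 0L,
                        global_annotations = character(),
                        data_annotations = NULL, version = "0.34") {
  rows <- as.matrix(rows)
  if (nrow(rows) < 1L)
    stop("rdat_record: at least one data row required")
  if (length(seqpos) != ncol(rows))
    stop(sprintf("rdat_record: %d seqpos entries for %d data columns",
                 length(seqpos), ncol(rows)))
  if (nzchar(structure) && nchar(structure) != nchar(sequence))
    stop("rdat_record: structure length must match sequence length")
  if (is.null(data_annotations))
    data_annotations <- rep(list(character()), nrow(rows))
  if (length(data_annotations) != nrow(rows))
    stop("rdat_record: one data_annotations entry required per row")
  structure(list(version = as.character(version), name = as.character(name),
                 sequence = toupper(sequence),
                 structure = as.character(structure),
                 offset = as.integer(offset),
                 seqpos = as.integer(seqpos),
                 global_annotations = as.character(global_annotations),
                 data_annotations = data_annotations,
                 rows = rows),
            class = "rdat_record")
}

.rdat_num <- function(x) formatC(x, format = "g", digits = 6)

#' Write an RDAT file
#'
#' Emits the record as UTF-8 text with Unix line endings and tab delimiters;
#' numeric values carry 6 significant digits. Output is byte-identical for
#' identical input. Global annotations carrying the `raw:` prefix (unknown
#' record types kept by [read_rdat()]) are re-emitted verbatim.
#'
#' @param record an [rdat_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rdat <- function(record, path) {
  stopifnot(inherits(record, "rdat_record"))
  r <- record
  # re-validate before any bytes reach the disk
  if (length(r$seqpos) != ncol(r$rows))
    stop("write_rdat: seqpos length does not match data-row width")
  if (nzchar(r$structure) && nchar(r$structure) != nchar(r$sequence))
    stop("write_rdat: structure length does not match sequence length")
  if (length(r$data_annotations) != nrow(r$rows))
    stop("write_rdat: one data_annotations entry required per row")
  is_raw <- startsWith(r$global_annotations, "raw:")
  lines <- c(
    paste0("RDAT_VERSION\t", r$version),
    paste0("NAME\t", r$name),
    paste0("SEQUENCE\t", r$sequence),
    if (nzchar(r$structure)) paste0("STRUCTURE\t", r$structure),
    paste0("OFFSET\t", r$offset),
    paste("SEQPOS", paste(r$seqpos, collapse = "\t"), sep = "\t"),
    if (length(r$global_annotations[!is_raw]) > 0)
      paste("ANNOTATION",
            paste(r$global_annotations[!is_raw], collapse = "\t"),
            sep = "\t"),
    sub("^raw:", "", r$global_annotations[is_raw]))
  for (i in seq_len(nrow(r$rows))) {
    ann <- r$data_annotations[[i]]
    if (length(ann) > 0)
      lines <- c(lines, paste(sprintf("ANNOTATION_DATA:%d", i),
                              paste(ann, collapse = "\t"), sep = "\t"))
    lines <- c(lines, paste(sprintf("REACTIVITY:%d", i),
                            paste(.rdat_num(r$rows[i, ]), collapse = "\t"),
                            sep = "\t"))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an RDAT file
#'
#' Inverse of [write_rdat()] on its image. Record types this pipeline does
#' not produce (XSEL, trace blobs, ...) are tolerated and preserved verbatim
#' in `global_annotations` with a `raw:` prefix. The display `offset` is
#' parsed but never applied to row indexing.
#'
#' @param path RDAT file path.
#' @return An [rdat_record()].
#' @export
read_rdat <- function(path) {
  if (!file.exists(path)) stop(sprintf("RDAT read: no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  version <- "0.34"; name <- ""; sequence <- NULL; struct <- ""
  offset <- 0L; seqpos <- integer(); glob <- character()
  row_list <- list(); ann_list <- list()
  for (ln in seq_along(fields)) {
    f <- fields[[ln]]
    if (length(f) == 0L || !nzchar(f[1])) next
    key <- f[1]; payload <- f[-1]
    if (key == "RDAT_VERSION") version <- payload[1]
    else if (key == "NAME") name <- if (length(payload)) payload[1] else ""
    else if (key == "SEQUENCE") sequence <- payload[1]
    else if (key == "STRUCTURE") struct <- payload[1]
    else if (key == "OFFSET") offset <- as.integer(payload[1])
    else if (key == "SEQPOS") seqpos <- as.integer(payload)
    else if (key == "ANNOTATION") glob <- c(glob, payload)
    else if (startsWith(key, "ANNOTATION_DATA:")) {
      i <- as.integer(sub("ANNOTATION_DATA:", "", key, fixed = TRUE))
      ann_list[[i]] <- payload
    } else if (startsWith(key, "REACTIVITY:")) {
      i <- as.integer(sub("REACTIVITY:", "", key, fixed = TRUE))
      row_list[[i]] <- as.numeric(payload)
    } else {
      glob <- c(glob, paste0("raw:", lines[ln]))
    }
  }
  if (is.null(sequence))
    stop(sprintf("RDAT read: %s: no SEQUENCE record in %d lines",
                 path, length(lines)))
  if (length(row_list) == 0L)
    stop(sprintf("RDAT read: %s: no REACTIVITY records in %d lines",
                 path, length(lines)))
  widths <- lengths(row_list)
  if (any(widths != length(seqpos)))
    stop(sprintf(
      "RDAT read: %s: REACTIVITY:%d has %d values but SEQPOS has %d",
      path, which(widths != length(seqpos))[1],
      widths[widths != length(seqpos)][1], length(seqpos)))
  n <- length(row_list)
  anns <- lapply(seq_len(n), function(i)
    if (i <= length(ann_list) && !is.null(ann_list[[i]]))
      ann_list[[i]] else character())
  rdat_record(sequence, do.call(rbind, row_list), seqpos, name = name,
              structure = struct, offset = offset,
              global_annotations = glob, data_annotations = anns,
              version = version)
}

#' Build an RDAT record from quantification results
#'
#' One REACTIVITY row per lane (band areas), one column per annotated
#' residue; each row's annotations record the lane's modifier and capillary
#' id. `seqpos` uses display numbering (residue index + offset).
#'
#' @param quant a `quant_result` from [quantify()].
#' @param annotation the [band_annotation()] used for the fit.
#' @param modifiers list of [modifier_spec()] or kind strings, one per lane.
#' @param name dataset name.
#' @param structure optional dot-bracket string.
#' @param global_annotations extra global `key:value` strings.
#' @return An [rdat_record()].
#' @export
build_rdat <- function(quant, annotation, modifiers, name = "dataset",
                       structure = "", global_annotations = character()) {
  stopifnot(inherits(quant, "quant_result"),
            inherits(annotation, "band_annotation"))
  n_lane <- ncol(quant$areas)
  if (n_lane < 1L) stop("build_rdat: no lanes to export")
  if (length(modifiers) != n_lane)
    stop(sprintf("build_rdat: %d modifiers for %d lanes",
                 length(modifiers), n_lane))
  if (nrow(quant$areas) != length(annotation$positions))
    stop("build_rdat: quantification and annotation band counts differ")
  kinds <- vapply(modifiers, function(m)
    if (inherits(m, "modifier_spec")) m$kind else as.character(m), "")
  anns <- lapply(seq_len(n_lane), function(j) {
    lane_id <- if (!is.null(quant$lanes))
      sprintf("capillary:%s", quant$lanes$capillary_id[j]) else character()
    c(sprintf("modifier:%s", kinds[j]), lane_id)
  })
  rdat_record(annotation$sequence, t(quant$areas),
              seqpos = annotation$residues + annotation$offset,
              name = name, structure = structure,
              offset = annotation$offset,
              global_annotations = global_annotations,
              data_annotations = anns)
}
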