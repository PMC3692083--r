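# ABIF container constants. The format is big-endian throughout: a 4-byte
# magic "ABIF", a 2-byte version, then a 28-byte root directory entry whose
# data offset points at the table of 28-byte entries, one per tagged item.
.abif_magic <- charToRaw("ABIF")
.abif_dir_entry_size <- 28L

# element type codes we decode; everything else is kept as raw bytes in
# metadata (hex-encoded) so reads stay lossless
.abif_types <- list(
  `1`  = list(what = "integer", size = 1L, signed = FALSE),  # byte
  `2`  = list(what = "character", size = 1L),                # char
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # short
  `5`  = list(what = "integer", size = 4L, signed = TRUE),   # long
  `7`  = list(what = "double", size = 4L),                   # float
  `8`  = list(what = "double", size = 8L),                   # double
  `18` = list(what = "pString", size = 1L),
  `19` = list(what = "cString", size = 1L)
)

#' Construct a raw capillary record
#'
#' One capillary's multi-channel fluorescence time series plus identifying
#' metadata. `channels` is a samples-by-channels integer matrix (fluorescence
#' in the arbitrary units of the instrument; values are signed integers as
#' decoded from the file and are not rescaled at read time).
#'
#' @param channels numeric matrix, `n_samples x n_channels`, `n_channels >= 2`.
#' @param capillary_id identifier of the capillary (usually the file stem).
#' @param batch_id identifier of the sequencer batch the capillary belongs to.
#' @param sample_name sample name string stored in the file.
#' @param source_path path the record was read from ("" if synthetic).
#' @param metadata named character vector of ABIF tags kept verbatim.
#' @return An object of class `raw_capillary`.
#' @export
raw_capillary <- function(channels, capillary_id = "", batch_id = "",
                          sample_name = "", source_path = "",
                          metadata = character()) {
  channels <- as.matrix(channels)
  if (nrow(channels) < 1L)
    stop("raw_capillary: channels must have at least one sample")
  if (ncol(channels) < 2L)
    stop("raw_capillary: at least two channels required (signal + reference)")
  .new_raw_capillary(channels, capillary_id, batch_id, sample_name,
                     source_path, metadata)
}

# parsing-level constructor: a lone-channel file is still parseable even
# though downstream analysis needs signal + reference
.new_raw_capillary <- function(channels, capillary_id = "", batch_id = "",
                               sample_name = "", source_path = "",
                               metadata = character()) {
  structure(
    list(capillary_id = as.character(capillary_id),
         batch_id = as.character(batch_id),
         channels = channels,
         sample_name = as.character(sample_name),
         source_path = as.character(source_path),
         metadata = metadata),
    class = "raw_capillary")
}

#' @export
print.raw_capillary <- function(x, ...) {
  cat(sprintf("<raw_capillary> %s (batch %s): %d samples x %d channels\n",
              x$capillary_id, x$batch_id, nrow(x$channels), ncol(x$channels)))
  invisible(x)
}

.read_be <- function(con, what, n, size, signed = TRUE) {
  readBin(con, what = what, n = n, size = size, signed = signed,
          endian = "big")
}

.abif_read_entry <- function(raw28) {
  con <- rawConnection(raw28)
  on.exit(close(con))
  name <- rawToChar(readBin(con, "raw", 4L))
  number <- .read_be(con, "integer", 1L, 4L)
  elem_type <- .read_be(con, "integer", 1L, 2L)
  elem_size <- .read_be(con, "integer", 1L, 2L)
  n_elem <- .read_be(con, "integer", 1L, 4L)
  data_size <- .read_be(con, "integer", 1L, 4L)
  data_offset_raw <- readBin(con, "raw", 4L)
  data_offset <- sum(as.integer(data_offset_raw) * c(2^24, 2^16, 2^8, 1))
  list(name = name, number = number, elem_type = elem_type,
       elem_size = elem_size, n_elem = n_elem, data_size = data_size,
       data_offset = data_offset, data_offset_raw = data_offset_raw)
}

.abif_decode <- function(bytes, elem_type, n_elem) {
  spec <- .abif_types[[as.character(elem_type)]]
  if (is.null(spec)) return(NULL)
  con <- rawConnection(bytes)
  on.exit(close(con))
  if (spec$what == "character") {
    rawToChar(readBin(con, "raw", n_elem))
  } else if (spec$what == "pString") {
    len <- as.integer(readBin(con, "raw", 1L))
    rawToChar(readBin(con, "raw", len))
  } else if (spec$what == "cString") {
    s <- readBin(con, "raw", n_elem)
    rawToChar(s[s != as.raw(0)])
  } else if (spec$what == "integer") {
    .read_be(con, "integer", n_elem, spec$size, signed = spec$signed)
  } else {
    .read_be(con, "double", n_elem, spec$size)
  }
}

#' Read an ABIF-format sequencer trace file
#'
#' Parses the ABIF binary container used by .ab1/.fsa files. All
#' `DATA`-tagged series become columns of the `channels` matrix in tag-number
#' order; series of unequal length are right-padded with zeros to the longest.
#' Intensities are decoded as signed integers; no rescaling is applied.
#'
#' @param path path to an .ab1/.fsa file.
#' @param batch_id batch identifier to record on the returned object.
#' @return A [raw_capillary()].
#' @export
read_abif <- function(path, batch_id = "") {
  if (!file.exists(path)) stop(sprintf("ABIF read: no such file: %s", path))
  sz <- file.info(path)$size
  bytes <- readBin(path, "raw", n = sz)
  if (length(bytes) < 34L || !identical(bytes[1:4], .abif_magic))
    stop(sprintf("ABIF read: %s does not begin with the ABIF magic bytes",
                 path))
  root <- .abif_read_entry(bytes[7:34])
  n_entries <- root$n_elem
  dir_off <- root$data_offset
  dir_end <- dir_off + n_entries * .abif_dir_entry_size
  if (dir_end > length(bytes))
    stop(sprintf(
      "ABIF read: %s: truncated directory (needs byte %d, file has %d)",
      path, dir_end, length(bytes)))

  entries <- vector("list", n_entries)
  for (i in seq_len(n_entries)) {
    a <- dir_off + (i - 1L) * .abif_dir_entry_size
    entries[[i]] <- .abif_read_entry(bytes[(a + 1L):(a + 28L)])
  }

  entry_payload <- function(e) {
    if (e$data_size <= 4L) {
      e$data_offset_raw[seq_len(e$data_size)]
    } else {
      if (e$data_offset + e$data_size > length(bytes))
        stop(sprintf(
          "ABIF read: %s: tag %s%d data truncated at byte offset %d",
          path, e$name, e$number, e$data_offset))
      bytes[(e$data_offset + 1L):(e$data_offset + e$data_size)]
    }
  }

  is_data <- vapply(entries, function(e) e$name == "DATA", logical(1))
  data_entries <- entries[is_data]
  if (length(data_entries) == 0L)
    stop(sprintf("ABIF read: %s contains no DATA tags", path))
  data_entries <- data_entries[order(vapply(data_entries, `[[`, 0, "number"))]

  series <- lapply(data_entries, function(e) {
    v <- .abif_decode(entry_payload(e), e$elem_type, e$n_elem)
    if (is.null(v))
      stop(sprintf("ABIF read: %s: DATA%d has unsupported element type %d",
                   path, e$number, e$elem_type))
    as.numeric(v)
  })
  n_max <- max(vapply(series, length, 0L))
  channels <- vapply(series, function(v) c(v, rep(0, n_max - length(v))),
                     numeric(n_max))
  channels <- matrix(channels, nrow = n_max,
                     dimnames = list(NULL, paste0(
                       "DATA", vapply(data_entries, `[[`, 0, "number"))))

  sample_name <- ""
  metadata <- character()
  for (e in entries[!is_data]) {
    v <- tryCatch(.abif_decode(entry_payload(e), e$elem_type, e$n_elem),
                  error = function(cond) NULL)
    key <- sprintf("%s%d", e$name, e$number)
    metadata[[key]] <- if (is.null(v)) {
      paste(as.character(entry_payload(e)), collapse = "")
    } else paste(v, collapse = ",")
    if (e$name == "SMPL" && e$number == 1L && is.character(v))
      sample_name <- v
  }

  .new_raw_capillary(channels,
                     capillary_id = sub("\\.(ab1|fsa)$", "", basename(path),
                                        ignore.case = TRUE),
                     batch_id = batch_id, sample_name = sample_name,
                     source_path = path, metadata = metadata)
}

.write_be_int <- function(con, x, size) {
  writeBin(as.integer(x), con, size = size, endian = "big")
}

.abif_entry_bytes <- function(name, number, elem_type, elem_size, n_elem,
                              data_size, data_offset, inline = NULL) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("%-4s", substr(name, 1, 4))), con)
  .write_be_int(con, number, 4L)
  .write_be_int(con, elem_type, 2L)
  .write_be_int(con, elem_size, 2L)
  .write_be_int(con, n_elem, 4L)
  .write_be_int(con, data_size, 4L)
  if (is.null(inline)) {
    .write_be_int(con, data_offset, 4L)
  } else {
    writeBin(c(inline, raw(4L - length(inline))), con)
  }
  .write_be_int(con, 0L, 4L)  # data handle, reserved
  rawConnection_value <- rawConnectionValue(con)
  rawConnection_value
}

#' Write a raw capillary as a minimal valid ABIF file
#'
#' Emits an ABIF container holding one `DATA` tag per channel (16-bit
#' big-endian signed integers) plus a `SMPL1` sample-name tag, such that
#' [read_abif()] inverts it exactly. Fixture factory for tests and the
#' synthetic-data generator; real instrument files carry many more tags.
#'
#' @param capillary a [raw_capillary()]; channel values must fit in a signed
#'   16-bit integer (they are clamped to \[-32768, 32767\] with a warning).
#' @param path output path (.ab1 or .fsa).
#' @return `path`, invisibly.
#' @export
abif_write <- function(capillary, path) {
  if (is.matrix(capillary))
    capillary <- .new_raw_capillary(capillary)
  stopifnot(inherits(capillary, "raw_capillary"))
  ch <- capillary$channels
  if (length(ch) == 0L || nrow(ch) < 1L)
    stop("ABIF write: empty channel matrix")
  ch <- round(ch)
  if (any(ch > 32767 | ch < -32768)) {
    warning("ABIF write: channel values clamped to 16-bit signed range")
    ch <- pmin(pmax(ch, -32768), 32767)
  }

  n_ch <- ncol(ch)
  smpl <- charToRaw(capillary$sample_name)
  if (length(smpl) > 254L) smpl <- smpl[1:254]
  smpl_payload <- c(as.raw(length(smpl)), smpl)

  # layout: [header 128 bytes] [channel data blocks] [SMPL block] [directory];
  # payloads of <= 4 bytes are inlined in the entry's offset field per the
  # ABIF convention and occupy no block
  header_size <- 128L
  data_sizes <- rep(2L * nrow(ch), n_ch)
  block_sizes <- ifelse(data_sizes > 4L, data_sizes, 0L)
  offsets <- header_size + cumsum(c(0L, block_sizes[-n_ch]))
  smpl_off <- header_size + sum(block_sizes)
  dir_off <- smpl_off + if (length(smpl_payload) > 4L)
    length(smpl_payload) else 0L

  int16_be <- function(v) {
    v <- as.integer(v)
    v[v < 0] <- v[v < 0] + 65536L
    as.raw(as.vector(rbind(v %/% 256L, v %% 256L)))
  }

  entries <- raw(0)
  for (j in seq_len(n_ch)) {
    inline <- if (data_sizes[j] <= 4L) int16_be(ch[, j]) else NULL
    entries <- c(entries, .abif_entry_bytes(
      "DATA", j, 4L, 2L, nrow(ch), data_sizes[j], offsets[j],
      inline = inline))
  }
  if (length(smpl_payload) <= 4L) {
    entries <- c(entries, .abif_entry_bytes(
      "SMPL", 1L, 18L, 1L, length(smpl_payload), length(smpl_payload),
      0L, inline = smpl_payload))
  } else {
    entries <- c(entries, .abif_entry_bytes(
      "SMPL", 1L, 18L, 1L, length(smpl_payload), length(smpl_payload),
      smpl_off))
  }
  n_entries <- n_ch + 1L

  con <- tryCatch(file(path, "wb"),
                  error = function(cond)
                    stop(sprintf("ABIF write: cannot open %s", path)))
  on.exit(close(con))
  writeBin(.abif_magic, con)
  .write_be_int(con, 101L, 2L)  # format version 1.01
  root <- .abif_entry_bytes("tdir", 1L, 1023L, .abif_dir_entry_size,
                            n_entries, n_entries * .abif_dir_entry_size,
                            dir_off)
  writeBin(root, con)
  writeBin(raw(header_size - 6L - .abif_dir_entry_size), con)  # pad header
  for (j in seq_len(n_ch))
    if (data_sizes[j] > 4L) .write_be_int(con, ch[, j], 2L)
  if (length(smpl_payload) > 4L) writeBin(smpl_payload, con)
  writeBin(entries, con)
  invisible(path)
}

#' Load a batch-structured CE experiment
#'
#' Reads every .ab1/.fsa file under `root`, which may be a directory or a zip
#' archive. One subfolder per sequencer batch; a flat layout (trace files at
#' top level, no subfolder) yields a single batch `"batch0"`. Within a batch,
#' lanes are ordered lexicographically by filename, which defines the batch's
#' reference capillary (lane 1). Any unreadable trace file is an error: no
#' file is silently skipped.
#'
#' @param root directory or .zip path.
#' @return A `batch_set`: list with element `batches`, a named list
#'   (batch id -> list of [raw_capillary()]), batches in lexicographic order.
#' @export
load_batches <- function(root) {
  if (!file.exists(root))
    stop(sprintf("load_batches: no such path: %s", root))
  scanned <- root
  if (!dir.exists(root)) {
    if (!grepl("\\.zip$", root, ignore.case = TRUE))
      stop(sprintf("load_batches: %s is neither a directory nor a zip", root))
    exdir <- tempfile("cequant_zip_")
    dir.create(exdir)
    utils::unzip(root, exdir = exdir)
    scanned <- sprintf("%s (zip, extracted internally)", root)
    root <- exdir
  }
  pat <- "\\.(ab1|fsa)$"
  subdirs <- sort(list.dirs(root, recursive = TRUE, full.names = TRUE))
  subdirs <- subdirs[subdirs != root]
  batches <- list()
  for (d in subdirs) {
    files <- sort(list.files(d, pattern = pat, full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) == 0L) next
    bid <- basename(d)
    batches[[bid]] <- lapply(files, function(f) {
      tryCatch(read_abif(f, batch_id = bid),
               error = function(cond)
                 stop(sprintf("load_batches: failed on %s: %s",
                              f, conditionMessage(cond)), call. = FALSE))
    })
  }
  if (length(batches) == 0L) {
    files <- sort(list.files(root, pattern = pat, full.names = TRUE,
                             ignore.case = TRUE))
    if (length(files) > 0L)
      batches[["batch0"]] <- lapply(files, function(f) {
        tryCatch(read_abif(f, batch_id = "batch0"),
                 error = function(cond)
                   stop(sprintf("load_batches: failed on %s: %s",
                                f, conditionMessage(cond)), call. = FALSE))
      })
  }
  if (length(batches) == 0L)
    stop(sprintf(
      "load_batches: no .ab1/.fsa files found anywhere under %s", scanned))
  structure(list(batches = batches), class = "batch_set")
}

#' @export
print.batch_set <- function(x, ...) {
  cat(sprintf("<batch_set> %d batch(es): %s\n", length(x$batches),
              paste(sprintf("%s[%d]", names(x$batches),
                            lengths(x$batches)), collapse = ", ")))
  invisible(x)
}
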