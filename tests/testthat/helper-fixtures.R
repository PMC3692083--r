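# shared fixture builders; everything is generated in code at test time

# a random four-channel capillary with 16-bit-safe intensities
random_capillary <- function(n = 1000L, n_ch = 4L, id = "cap",
                             batch = "b1", name = "sample") {
  raw_capillary(matrix(sample(0:30000, n * n_ch, replace = TRUE), n, n_ch),
                capillary_id = id, batch_id = batch, sample_name = name)
}

# a sparse Gaussian-band profile on a flat floor
band_profile <- function(n, centers, amps, sigma = 10) {
  x <- seq_len(n)
  p <- numeric(n)
  for (i in seq_along(centers))
    p <- p + amps[i] * exp(-(x - centers[i])^2 / (2 * sigma^2))
  p
}

# a small aligned trace_set wrapping given signal/reference matrices
mini_traces <- function(signal, reference = signal, batch = "b1",
                        roi = NULL) {
  n_lane <- ncol(signal)
  trace_set(signal, reference,
            data.frame(capillary_id = sprintf("%s_l%02d", batch,
                                              seq_len(n_lane)),
                       batch_id = batch, batch_ordinal = seq_len(n_lane)),
            roi = roi)
}

# zip a directory (store-only, via the Python standard library: R's zip()
# needs an external binary that may be absent)
zip_dir <- function(dir, zipfile) {
  code <- sprintf(
    paste0("import zipfile, os\n",
           "z = zipfile.ZipFile(%s, 'w')\n",
           "for dp, _, fs in os.walk(%s):\n",
           "    for f in fs:\n",
           "        p = os.path.join(dp, f)\n",
           "        z.write(p, os.path.relpath(p, %s))\n",
           "z.close()\n"),
    deparse(zipfile), deparse(dir), deparse(dir))
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  stopifnot(system2("python", script) == 0)
  zipfile
}

# a valid random RDAT record
random_rdat <- function(n_rows = 3L, n_pos = 8L) {
  seqs <- paste(sample(c("A", "C", "G", "U"), n_pos + 4L, TRUE),
                collapse = "")
  rdat_record(
    sequence = seqs,
    rows = matrix(round(stats::runif(n_rows * n_pos, 0, 50), 3),
                  n_rows, n_pos),
    seqpos = seq_len(n_pos) + 2L,
    name = paste0("ds", sample(1000L, 1L)),
    offset = 2L,
    global_annotations = c("experimentType:StandardState",
                           "chemical:MgCl2:10mM"),
    data_annotations = replicate(n_rows,
      sprintf("modifier:%s", sample(c("SHAPE", "DMS", "nomod"), 1L)),
      simplify = FALSE))
}
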