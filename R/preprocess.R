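#' Select signal and reference channels across all batches
#'
#' Flattens a batch set into a trace set: one signal column and one reference
#' column per capillary, batches concatenated in order, lanes in lexicographic
#' order within each batch. Shorter lanes are zero-padded to the global
#' maximum length. Intensities are converted to double here; raw files stay
#' integer-valued.
#'
#' @param batchset a `batch_set` from [load_batches()].
#' @param signal_channel 1-based channel column carrying the chemical-probing
#'   signal.
#' @param reference_channel 1-based channel column carrying the co-loaded
#'   ladder used for alignment; must differ from `signal_channel`.
#' @return A `trace_set`: list with `signal` and `reference` matrices
#'   (`n_samples x n_lanes`), `lanes` data frame (capillary_id, batch_id,
#'   batch_ordinal) and `roi` (`NULL` until [detect_roi()] or a manual ROI).
#' @export
select_channels <- function(batchset, signal_channel = 1L,
                            reference_channel = 2L) {
  stopifnot(inherits(batchset, "batch_set"))
  if (signal_channel == reference_channel)
    stop("select_channels: signal and reference channel must differ")
  caps <- unlist(batchset$batches, recursive = FALSE)
  for (cp in caps) {
    if (max(signal_channel, reference_channel) > ncol(cp$channels) ||
        min(signal_channel, reference_channel) < 1L)
      stop(sprintf(
        "select_channels: channel index out of range for lane %s (%d channels)",
        cp$capillary_id, ncol(cp$channels)))
  }
  n_max <- max(vapply(caps, function(cp) nrow(cp$channels), 0L))
  pad <- function(v) c(v, rep(0, n_max - length(v)))
  signal <- vapply(caps, function(cp) pad(cp$channels[, signal_channel]),
                   numeric(n_max))
  reference <- vapply(caps, function(cp) pad(cp$channels[, reference_channel]),
                      numeric(n_max))
  lanes <- data.frame(
    capillary_id = vapply(caps, `[[`, "", "capillary_id"),
    batch_id = rep(names(batchset$batches), lengths(batchset$batches)),
    batch_ordinal = unlist(lapply(lengths(batchset$batches), seq_len)),
    stringsAsFactors = FALSE)
  trace_set(matrix(signal, nrow = n_max), matrix(reference, nrow = n_max),
            lanes)
}

#' Construct a trace set
#'
#' @param signal,reference numeric matrices `n_samples x n_lanes`, same shape.
#' @param lanes data frame with columns capillary_id, batch_id, batch_ordinal.
#' @param roi optional [region_of_interest()].
#' @return A `trace_set` object.
#' @export
trace_set <- function(signal, reference, lanes, roi = NULL) {
  signal <- as.matrix(signal); reference <- as.matrix(reference)
  stopifnot(identical(dim(signal), dim(reference)),
            nrow(lanes) == ncol(signal))
  structure(list(signal = signal, reference = reference,
                 lanes = lanes, roi = roi),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d samples x %d lanes (%d batch(es))%s\n",
              nrow(x$signal), ncol(x$signal),
              length(unique(x$lanes$batch_id)),
              if (is.null(x$roi)) "" else
                sprintf(", ROI [%d, %d]", x$roi$start, x$roi$end)))
  invisible(x)
}

#' Define a region of interest
#'
#' The informative sub-range of the electrophoresis run, as 1-based inclusive
#' sample indices.
#'
#' @param start,end sample indices, `1 <= start <= end`.
#' @return A `region_of_interest` object.
#' @export
region_of_interest <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 1L && start <= end))
    stop("region_of_interest: need 1 <= start <= end")
  structure(list(start = start, end = end), class = "region_of_interest")
}

.roi_idx <- function(roi, n) {
  if (is.null(roi)) seq_len(n) else seq.int(min(roi$start, n), min(roi$end, n))
}

#' Detect the region of interest by edge detection
#'
#' Sums intensity over all lanes and both channels, smooths the envelope with
#' a centered moving average, takes the absolute first difference as the edge
#' response, and returns the smallest range containing every sample whose
#' edge response exceeds `threshold_frac` of the maximum response, padded
#' outward by `smooth_window` samples and clipped to the trace. Scale-free:
#' multiplying all traces by a positive constant does not move the ROI.
#'
#' @param traces a `trace_set`.
#' @param smooth_window moving-average width in samples.
#' @param threshold_frac edge-response threshold as a fraction of its maximum.
#' @return A [region_of_interest()].
#' @export
detect_roi <- function(traces, smooth_window = 50L, threshold_frac = 0.05) {
  stopifnot(inherits(traces, "trace_set"))
  env <- rowSums(traces$signal) + rowSums(traces$reference)
  n <- length(env)
  if (max(env) == min(env))
    stop(paste("detect_roi: traces are constant; no edges found -",
               "set the region of interest manually"))
  k <- max(1L, as.integer(smooth_window))
  sm <- .ma_smooth(env, k)
  # smooth the signed first difference before rectifying: zero-mean noise
  # cancels, so the rectified response has no noise pedestal that a
  # relative threshold could drown in
  edge <- abs(.ma_smooth(diff(sm), k))
  # the filters lack real support within one window of either end; those
  # samples carry padding artifacts, not edges
  drop <- min(k, length(edge))
  edge[c(seq_len(drop), (length(edge) - drop + 1L):length(edge))] <- 0
  if (max(edge) == 0)
    stop(paste("detect_roi: no edge response above threshold -",
               "set the region of interest manually"))
  hits <- which(edge > threshold_frac * max(edge))
  if (length(hits) == 0L)
    stop(paste("detect_roi: no edge response above threshold -",
               "set the region of interest manually"))
  region_of_interest(max(1L, min(hits) - k), min(n, max(hits) + 1L + k))
}

#' Lightly smooth all traces
#'
#' Applies a short centered moving average to both channels of every lane.
#' Fluorescence sampling is much finer than the band width, so a window a
#' few samples wide cuts white detector noise by roughly the square root of
#' the window while broadening a typical band (sigma of ~10 samples) by
#' well under 1%. Part of preprocessing, before ROI detection.
#'
#' @param traces a `trace_set`.
#' @param window moving-average width in samples (1 disables smoothing).
#' @return The smoothed `trace_set`.
#' @export
smooth_traces <- function(traces, window = 5L) {
  stopifnot(inherits(traces, "trace_set"))
  window <- as.integer(window)
  if (window <= 1L) return(traces)
  for (ch in c("signal", "reference"))
    traces[[ch]] <- apply(traces[[ch]], 2, .ma_smooth, k = window)
  traces
}

#' Remove constant per-lane baselines
#'
#' Subtracts a low order statistic (default the 2nd percentile, more robust
#' than the minimum to single-sample undershoot) of each lane's values within
#' the ROI, independently for the signal and the reference channel. Values
#' are not clipped: small negatives are left for the least-squares stage.
#'
#' @param traces a `trace_set` with `roi` set.
#' @param percentile fraction in \[0, 1\) defining the order statistic.
#' @return The `trace_set` with baselines removed.
#' @export
subtract_constant_baseline <- function(traces, percentile = 0.02) {
  stopifnot(inherits(traces, "trace_set"))
  if (is.null(traces$roi))
    stop("subtract_constant_baseline: set or detect the ROI first")
  idx <- .roi_idx(traces$roi, nrow(traces$signal))
  for (ch in c("signal", "reference")) {
    m <- traces[[ch]]
    base <- apply(m[idx, , drop = FALSE], 2, stats::quantile,
                  probs = percentile, names = FALSE, type = 7)
    traces[[ch]] <- sweep(m, 2, base)
  }
  traces
}
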