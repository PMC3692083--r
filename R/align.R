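#' Linear lane transform
#'
#' A global shift + scale aligning one lane onto a reference: the warped
#' profile evaluated at reference position x reads source position
#' `(x - shift) / scale`.
#'
#' @param shift shift in samples.
#' @param scale dimensionless dilation, > 0.
#' @param score Pearson correlation achieved against the reference.
#' @return A `linear_transform` object.
#' @export
linear_transform <- function(shift = 0, scale = 1, score = NA_real_) {
  stopifnot(scale > 0)
  structure(list(shift = shift, scale = scale, score = score),
            class = "linear_transform")
}

#' Piecewise-linear lane warp
#'
#' A linear transform plus anchor pairs `(source_pos, target_pos)` refining
#' it locally. Anchors must be strictly increasing in both coordinates, so
#' warping never reorders bands.
#'
#' @param linear a [linear_transform()].
#' @param anchors numeric matrix `k x 2` (source, target), or NULL.
#' @return A `warp_transform` object.
#' @export
warp_transform <- function(linear = linear_transform(), anchors = NULL) {
  if (!is.null(anchors)) {
    anchors <- as.matrix(anchors)
    if (nrow(anchors) > 1L &&
        (any(diff(anchors[, 1]) <= 0) || any(diff(anchors[, 2]) <= 0)))
      stop("warp_transform: anchors must be strictly increasing in both coordinates")
  }
  structure(list(linear = linear, anchors = anchors),
            class = "warp_transform")
}

#' Apply a warp to a profile
#'
#' Evaluates the warped profile on the reference grid `1..length(profile)`
#' by linear interpolation: anchor pairs map each reference (target) position
#' to a source position (identity-slope continuation beyond the outer
#' anchors), then the linear transform maps that to the original coordinate
#' `(pos - shift) / scale`. Samples falling outside the profile read 0.
#'
#' @param profile numeric vector (length >= 2).
#' @param t a [warp_transform()] or [linear_transform()].
#' @return Numeric vector, same length as `profile`.
#' @export
warp_profile <- function(profile, t) {
  stopifnot(length(profile) >= 2L)
  if (inherits(t, "linear_transform")) t <- warp_transform(t)
  x <- seq_along(profile)
  y <- x
  a <- t$anchors
  if (!is.null(a) && nrow(a) >= 1L) {
    if (nrow(a) > 1L &&
        (any(diff(a[, 1]) <= 0) || any(diff(a[, 2]) <= 0)))
      stop("warp_profile: non-monotone anchors")
    if (nrow(a) == 1L) {
      y <- x + (a[1, 1] - a[1, 2])
    } else {
      y <- stats::approx(a[, 2], a[, 1], xout = x, rule = 1)$y
      lo <- x < a[1, 2]; hi <- x > a[nrow(a), 2]
      y[lo] <- a[1, 1] + (x[lo] - a[1, 2])
      y[hi] <- a[nrow(a), 1] + (x[hi] - a[nrow(a), 2])
    }
  }
  s <- (y - t$linear$shift) / t$linear$scale
  stats::approx(x, profile, xout = s, yleft = 0, yright = 0)$y
}

#' Compose two linear transforms
#'
#' Applying `first` then `second` equals applying the composed transform in
#' one interpolation pass: shift = `second$shift + second$scale * first$shift`,
#' scale = product of the scales.
#'
#' @param first,second [linear_transform()] objects, applied in that order.
#' @return The composed [linear_transform()] (score taken from `second`).
#' @export
compose_linear <- function(first, second) {
  linear_transform(shift = second$shift + second$scale * first$shift,
                   scale = first$scale * second$scale,
                   score = second$score)
}

# centered moving average (edge-padded), used to low-pass profiles before
# the coarse linear fit: global shift/scale is determined by the band-mass
# envelope, while band-scale detail belongs to the piecewise stage and can
# mislead the linear fit when local warps exceed the band width
.ma_smooth <- function(v, k) {
  k <- as.integer(k)
  if (k <= 1L) return(v)
  h <- k %/% 2L
  p <- c(rep(v[1], h), v, rep(v[length(v)], h))
  as.numeric(stats::filter(p, rep(1 / k, k),
                           sides = 2))[(h + 1L):(h + length(v))]
}

# score one (shift, scale) candidate: correlation of the warped profile with
# the reference over the ROI indices
.linear_score <- function(profile, ref_roi, idx, shift, scale) {
  s <- (idx - shift) / scale
  w <- stats::approx(seq_along(profile), profile, xout = s,
                     yleft = 0, yright = 0)$y
  if (stats::sd(w) == 0) return(-Inf)
  stats::cor(w, ref_roi)
}

#' Fit the optimal shift and scale by correlation maximization
#'
#' Exhaustive coarse grid search over shift and scale maximizing the Pearson
#' correlation between the warped profile and the reference over the ROI,
#' followed by one refinement pass at 10x finer steps around the coarse
#' optimum. Ties are broken toward the transform closest to the identity
#' (then smallest shift, then smallest scale), so aligning a profile to
#' itself returns exactly shift 0, scale 1, score 1.
#'
#' @param profile,reference numeric vectors of equal length; the reference
#'   must have nonzero variance over the ROI.
#' @param shift_grid numeric vector of candidate shifts (samples); default
#'   `seq(-300, 300, by = 10)`.
#' @param scale_grid numeric vector of candidate scales; default
#'   `seq(0.95, 1.05, by = 0.005)`.
#' @param roi optional [region_of_interest()]; default whole trace.
#' @return A [linear_transform()] with the achieved correlation as `score`.
#' @export
fit_linear <- function(profile, reference,
                       shift_grid = seq(-300, 300, by = 10),
                       scale_grid = seq(0.95, 1.05, by = 0.005),
                       roi = NULL) {
  stopifnot(length(profile) == length(reference))
  idx <- .roi_idx(roi, length(reference))
  ref_roi <- reference[idx]
  if (stats::sd(ref_roi) == 0)
    stop("fit_linear: reference has zero variance over the ROI")
  if (stats::sd(profile) == 0)
    stop("fit_linear: profile has zero variance")

  search <- function(shifts, scales) {
    grid <- expand.grid(shift = shifts, scale = scales)
    grid$score <- mapply(function(b, a)
      .linear_score(profile, ref_roi, idx, b, a), grid$shift, grid$scale)
    best <- max(grid$score)
    cand <- grid[grid$score >= best - 1e-12, , drop = FALSE]
    cand <- cand[order(abs(cand$shift) + abs(cand$scale - 1),
                       cand$shift, cand$scale), , drop = FALSE]
    cand[1, ]
  }

  coarse <- search(shift_grid, scale_grid)
  dshift <- if (length(shift_grid) > 1) min(diff(sort(shift_grid))) else 0
  dscale <- if (length(scale_grid) > 1) min(diff(sort(scale_grid))) else 0
  shifts <- if (dshift > 0)
    seq(coarse$shift - dshift, coarse$shift + dshift, by = dshift / 10)
  else coarse$shift
  scales <- if (dscale > 0)
    seq(coarse$scale - dscale, coarse$scale + dscale, by = dscale / 10)
  else coarse$scale
  fine <- search(shifts, scales[scales > 0])
  linear_transform(fine$shift, fine$scale, fine$score)
}

# coarse-to-fine linear fit: global placement on envelope-smoothed copies
# (immune to the ladder's comb ambiguity), then a local refinement on the
# raw traces, whose band-scale structure pins shift and scale sharply
.fit_linear_c2f <- function(profile, reference, coarse_smooth, roi, ...) {
  t0 <- fit_linear(.ma_smooth(profile, coarse_smooth),
                   .ma_smooth(reference, coarse_smooth), roi = roi, ...)
  if (coarse_smooth <= 1L) return(t0)
  fit_linear(profile, reference,
             shift_grid = t0$shift + seq(-2, 2, by = 1),
             scale_grid = t0$scale + seq(-0.001, 0.001, by = 0.0005),
             roi = roi)
}

#' Align every lane to the first capillary of its batch
#'
#' The first capillary of each batch is that batch's reference: it receives
#' the identity transform with score 1, and every other lane is fitted
#' against it with [fit_linear()]. Alignment is scored on the reference
#' (ladder) channel, which is present in every capillary and independent of
#' the chemical modification; the resulting transform is later applied to
#' both channels.
#'
#' @param traces a `trace_set`.
#' @param coarse_smooth moving-average width (samples) applied to both
#'   profiles before the linear fit; the global fit works on the band-mass
#'   envelope and leaves band-scale registration to the piecewise stage.
#'   1 disables smoothing.
#' @param ... passed to [fit_linear()] (`shift_grid`, `scale_grid`).
#' @return List of [linear_transform()], one per lane.
#' @export
align_within_batch <- function(traces, coarse_smooth = 51L, ...) {
  stopifnot(inherits(traces, "trace_set"))
  out <- vector("list", ncol(traces$reference))
  for (b in unique(traces$lanes$batch_id)) {
    cols <- which(traces$lanes$batch_id == b)
    ref <- traces$reference[, cols[1]]
    out[[cols[1]]] <- linear_transform(0, 1, 1)
    for (j in cols[-1]) {
      out[[j]] <- tryCatch(
        .fit_linear_c2f(traces$reference[, j], ref, coarse_smooth,
                        roi = traces$roi, ...),
        error = function(cond) stop(sprintf(
          "align_within_batch: lane %s (batch %s): %s",
          traces$lanes$capillary_id[j], b, conditionMessage(cond)),
          call. = FALSE))
    }
  }
  out
}

#' Align batches to the global reference
#'
#' The reference capillary of the first batch is the global reference. For
#' each later batch, its (within-batch-aligned) reference lane is fitted
#' against the global reference, and that single batch-level transform is
#' composed onto every lane of the batch.
#'
#' @param traces a `trace_set`.
#' @param within per-lane transforms from [align_within_batch()].
#' @param coarse_smooth see [align_within_batch()].
#' @param ... passed to [fit_linear()].
#' @return List of batch-level [linear_transform()], one per lane (identity
#'   for the first batch).
#' @export
align_between_batches <- function(traces, within, coarse_smooth = 51L, ...) {
  stopifnot(inherits(traces, "trace_set"))
  bids <- unique(traces$lanes$batch_id)
  global_ref <- traces$reference[, which(traces$lanes$batch_id ==
                                           bids[1])[1]]
  out <- vector("list", ncol(traces$reference))
  for (b in bids) {
    cols <- which(traces$lanes$batch_id == b)
    tb <- if (b == bids[1]) linear_transform(0, 1, 1) else {
      # lane 1 of the batch: its within-batch transform is the identity
      tryCatch(.fit_linear_c2f(traces$reference[, cols[1]], global_ref,
                               coarse_smooth, roi = traces$roi, ...),
               error = function(cond) stop(sprintf(
                 "align_between_batches: batch %s: %s", b,
                 conditionMessage(cond)), call. = FALSE))
    }
    for (j in cols) out[[j]] <- tb
  }
  out
}

#' Remove a smoothly varying baseline
#'
#' Estimates the baseline as a moving low-percentile filter (default the
#' 10th percentile over a 201-sample window), smooths that estimate with a
#' moving average of the same width, and subtracts it. Sparse bands riding
#' on a slow drift are preserved because the low order statistic of a window
#' ignores the band peaks.
#'
#' @param profile numeric vector.
#' @param window filter width in samples; odd, >= 3, <= length(profile).
#' @param percentile order statistic used for the baseline (fraction).
#' @return The baseline-subtracted profile.
#' @export
subtract_smooth_baseline <- function(profile, window = 201L,
                                     percentile = 0.10) {
  profile - .smooth_baseline_estimate(profile, window, percentile)
}

# strided approximation of .smooth_baseline_estimate: the windowed
# percentile is evaluated every `stride` samples and interpolated, then
# smoothed exactly. The baseline varies on the window scale, so a stride
# far below the window adds negligible error at a large constant-factor
# saving; used inside the iterative peak-fit compensation
.smooth_baseline_fast <- function(profile, window = 201L,
                                  percentile = 0.10, stride = 5L) {
  n <- length(profile)
  h <- (window - 1L) %/% 2L
  padded <- c(rep(profile[1], h), profile, rep(profile[n], h))
  at <- unique(c(seq(1L, n, by = stride), n))
  q <- vapply(at, function(i)
    stats::quantile(padded[i:(i + window - 1L)], probs = percentile,
                    names = FALSE, type = 7), 0)
  base <- stats::approx(at, q, xout = seq_len(n))$y
  .ma_smooth(base, window)
}

# the baseline the moving-percentile + moving-average filter extracts;
# exposed separately so the peak-fitting stage can compensate for the
# signal floor this filter removes from densely banded profiles
.smooth_baseline_estimate <- function(profile, window = 201L,
                                      percentile = 0.10) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("subtract_smooth_baseline: window must be odd and >= 3")
  n <- length(profile)
  if (window > n)
    stop("subtract_smooth_baseline: window exceeds profile length")
  h <- (window - 1L) %/% 2L
  padded <- c(rep(profile[1], h), profile, rep(profile[n], h))
  wins <- stats::embed(padded, window)  # row i = padded[i+window-1 .. i]
  base <- apply(wins, 1, stats::quantile, probs = percentile, names = FALSE)
  basep <- c(rep(base[1], h), base, rep(base[n], h))
  smooth <- as.numeric(stats::filter(basep, rep(1 / window, window),
                                     sides = 2))[(h + 1L):(h + n)]
  smooth
}

#' Piecewise-linear alignment by dynamic programming
#'
#' Partitions the ROI into contiguous windows, scores every candidate
#' integer offset of each window by the Pearson correlation between the
#' offset profile window and the reference window (zero-variance windows
#' score 0), penalizes offset changes between adjacent windows by
#' `lambda * |d - d'|`, and finds the offset path maximizing total score
#' minus total penalty by dynamic programming. Ties are broken toward the
#' smaller absolute offset, so a profile aligned to itself yields the all-zero
#' path. The optimal path becomes warp anchors at the window centers.
#'
#' @param profile,reference numeric vectors of equal length; `profile` should
#'   already be linearly aligned.
#' @param window window length in samples (the last window absorbs any
#'   remainder); must exceed `2 * max_offset`.
#' @param max_offset largest candidate offset magnitude in samples.
#' @param step offset grid step in samples.
#' @param lambda transition penalty per sample of offset discontinuity.
#' @param roi optional [region_of_interest()]; default whole trace.
#' @return A [warp_transform()] with identity linear part; attribute
#'   `"offsets"` carries the per-window offset path and `"objective"` the
#'   attained DP objective.
#' @export
fit_piecewise <- function(profile, reference, window = 100L,
                          max_offset = 50L, step = 1L, lambda = 0.01,
                          roi = NULL) {
  stopifnot(length(profile) == length(reference))
  window <- as.integer(window)
  if (2 * max_offset > window)
    stop("fit_piecewise: window must be >= 2 * max_offset")
  idx <- .roi_idx(roi, length(reference))
  n_roi <- length(idx)
  n_win <- max(1L, n_roi %/% window)
  starts <- idx[1] + (seq_len(n_win) - 1L) * window
  ends <- c(starts[-1] - 1L, idx[n_roi])
  offsets <- seq(-max_offset, max_offset, by = step)
  S <- length(offsets)
  n <- length(profile)

  score <- matrix(0, S, n_win)
  for (w in seq_len(n_win)) {
    ref_w <- reference[starts[w]:ends[w]]
    if (stats::sd(ref_w) == 0) next
    for (s in seq_len(S)) {
      src <- (starts[w]:ends[w]) + offsets[s]
      pw <- ifelse(src >= 1L & src <= n, profile[pmin(pmax(src, 1L), n)], 0)
      score[s, w] <- if (stats::sd(pw) == 0) 0 else stats::cor(pw, ref_w)
    }
  }

  # DP over windows; tie-break toward smaller |offset| via epsilon-strict
  # comparison in |offset| order
  ord <- order(abs(offsets), offsets)
  trans <- -lambda * abs(outer(offsets, offsets, `-`))  # [from, to]
  V <- score[, 1]
  back <- matrix(NA_integer_, S, n_win)
  for (w in seq_len(n_win)[-1]) {
    cand <- V + trans  # cand[from, to]
    best_from <- integer(S); best_val <- numeric(S)
    for (to in seq_len(S)) {
      v <- cand[, to]
      m <- max(v)
      from_ties <- which(v >= m - 1e-12)
      best_from[to] <- from_ties[which.min(match(from_ties, ord))]
      best_val[to] <- v[best_from[to]]
    }
    back[, w] <- best_from
    V <- best_val + score[, w]
  }
  final_ties <- which(V >= max(V) - 1e-12)
  s_end <- final_ties[which.min(match(final_ties, ord))]
  path <- integer(n_win)
  path[n_win] <- s_end
  if (n_win > 1L) for (w in rev(seq_len(n_win)[-1]))
    path[w - 1L] <- back[path[w], w]
  d <- offsets[path]

  centers <- (starts + ends) / 2
  anchors <- cbind(source = c(idx[1] + d[1], centers + d,
                              idx[n_roi] + d[n_win]),
                   target = c(idx[1], centers, idx[n_roi]))
  anchors <- anchors[!duplicated(anchors[, 2]), , drop = FALSE]
  out <- warp_transform(linear_transform(0, 1, NA_real_), anchors)
  attr(out, "offsets") <- d
  attr(out, "objective") <- max(V)
  out
}

#' Run the full alignment stage
#'
#' Executes, in order: within-batch linear alignment, between-batch linear
#' alignment, smooth-baseline removal, and piecewise-linear refinement of
#' every lane against the global reference (the first capillary of the first
#' batch). Transforms are estimated on the reference (ladder) channel and
#' applied to both channels; the composed linear transform is applied in a
#' single interpolation pass.
#'
#' @param traces a `trace_set` with ROI set and constant baselines removed.
#' @param shift_grid,scale_grid linear search grids, see [fit_linear()].
#' @param coarse_smooth envelope-smoothing width for the linear fits, see
#'   [align_within_batch()].
#' @param pw_window,pw_max_offset,pw_step,pw_lambda piecewise parameters,
#'   see [fit_piecewise()].
#' @param baseline_window smooth-baseline filter width
#'   (see [subtract_smooth_baseline()]).
#' @return List with `traces` (the aligned `trace_set`), `transforms` (list
#'   of [warp_transform()] per lane) and `report` (a data frame with one row
#'   per lane: lane, batch, shift, scale, score, mean_abs_offset).
#' @export
align_all <- function(traces,
                      shift_grid = seq(-300, 300, by = 10),
                      scale_grid = seq(0.95, 1.05, by = 0.005),
                      coarse_smooth = 51L,
                      pw_window = 100L, pw_max_offset = 50L, pw_step = 1L,
                      pw_lambda = 0.01, baseline_window = 201L) {
  stopifnot(inherits(traces, "trace_set"))
  within <- align_within_batch(traces, coarse_smooth = coarse_smooth,
                               shift_grid = shift_grid,
                               scale_grid = scale_grid)
  between <- align_between_batches(traces, within,
                                   coarse_smooth = coarse_smooth,
                                   shift_grid = shift_grid,
                                   scale_grid = scale_grid)
  lin <- Map(compose_linear, within, between)

  n_lane <- ncol(traces$signal)
  sig <- traces$signal; ref <- traces$reference
  for (j in seq_len(n_lane)) {
    sig[, j] <- warp_profile(traces$signal[, j], lin[[j]])
    ref[, j] <- warp_profile(traces$reference[, j], lin[[j]])
  }
  bw <- min(baseline_window,
            (nrow(sig) - 1L) %/% 2L * 2L + 1L)
  for (j in seq_len(n_lane)) {
    sig[, j] <- subtract_smooth_baseline(sig[, j], bw)
    ref[, j] <- subtract_smooth_baseline(ref[, j], bw)
  }

  global_ref <- ref[, 1]
  transforms <- vector("list", n_lane)
  for (j in seq_len(n_lane)) {
    pw <- fit_piecewise(ref[, j], global_ref, window = pw_window,
                        max_offset = pw_max_offset, step = pw_step,
                        lambda = pw_lambda, roi = traces$roi)
    transforms[[j]] <- warp_transform(lin[[j]], pw$anchors)
    attr(transforms[[j]], "offsets") <- attr(pw, "offsets")
    sig[, j] <- warp_profile(sig[, j], pw)
    ref[, j] <- warp_profile(ref[, j], pw)
  }

  report <- data.frame(
    lane = traces$lanes$capillary_id,
    batch = traces$lanes$batch_id,
    shift = vapply(lin, `[[`, 0, "shift"),
    scale = vapply(lin, `[[`, 0, "scale"),
    score = vapply(lin, `[[`, 0, "score"),
    mean_abs_offset = vapply(transforms, function(t)
      mean(abs(attr(t, "offsets"))), 0),
    stringsAsFactors = FALSE)

  aligned <- trace_set(sig, ref, traces$lanes, traces$roi)
  list(traces = aligned, transforms = transforms, report = report)
}

#' Write the alignment report as tab-delimited text
#'
#' @param report the `report` element of [align_all()]'s result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(report, path) {
  fmt <- report
  for (col in c("shift", "scale", "score", "mean_abs_offset"))
    fmt[[col]] <- formatC(report[[col]], format = "g", digits = 6)
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
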