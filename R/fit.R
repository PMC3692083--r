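#' Estimate Gaussian band widths from annotation spacing
#'
#' Band width scales with local band spacing: sigma_i is `width_factor`
#' times the median of the adjacent spacings in a window of 5 spacings
#' around band i. With the default factor 0.25, bands 40 samples apart get
#' sigma = 10.
#'
#' @param annotation a [band_annotation()] with >= 2 positions.
#' @param width_factor dimensionless multiplier (default 0.25).
#' @return Numeric vector of Gaussian sigmas (samples), one per band.
#' @export
estimate_widths <- function(annotation, width_factor = 0.25) {
  pos <- if (inherits(annotation, "band_annotation"))
    annotation$positions else as.numeric(annotation)
  if (length(pos) < 2L)
    stop("estimate_widths: need >= 2 bands; give an explicit width instead")
  gaps <- diff(pos)
  n <- length(pos)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - 3L); hi <- min(length(gaps), i + 1L)
    width_factor * stats::median(gaps[lo:hi])
  }, 0)
}

# unit-amplitude Gaussian column on the sample grid, truncated at +-5 sigma
.gauss_col <- function(grid, center, sigma) {
  g <- numeric(length(grid))
  in_rng <- which(abs(grid - center) <= 5 * sigma)
  g[in_rng] <- exp(-(grid[in_rng] - center)^2 / (2 * sigma^2))
  g
}

#' Fit non-negative Gaussian amplitudes to one profile
#'
#' Builds the design matrix whose column j is a unit-amplitude Gaussian at
#' `centers[j]` with width `widths[j]` (truncated at +-5 sigma) evaluated on
#' the sample grid, and solves the non-negative least-squares problem
#' `argmin_{a >= 0} || profile - G a ||_2`. Centers and widths are fixed;
#' the fit is a convex problem with a deterministic active-set solution.
#'
#' @param profile numeric vector (one lane, aligned and baseline-corrected).
#' @param centers band centers in samples (from the annotation).
#' @param widths Gaussian sigmas in samples, length 1 or `length(centers)`.
#' @param roi optional [region_of_interest()]: fit over that sample range
#'   only.
#' @return List with `amplitudes` (non-negative vector) and `residual_norm`
#'   (L2 norm of the fit residual over the fitted range).
#' @export
fit_amplitudes <- function(profile, centers, widths, roi = NULL) {
  if (any(!is.finite(profile)))
    stop("fit_amplitudes: non-finite values in profile")
  widths <- rep_len(widths, length(centers))
  stopifnot(all(widths > 0), !is.unsorted(centers, strictly = TRUE))
  idx <- .roi_idx(roi, length(profile))
  y <- profile[idx]
  G <- vapply(seq_along(centers),
              function(j) .gauss_col(idx, centers[j], widths[j]),
              numeric(length(idx)))
  G <- matrix(G, nrow = length(idx))
  if (all(y == 0))
    return(list(amplitudes = numeric(length(centers)), residual_norm = 0))
  sol <- pracma::lsqnonneg(G, y)
  list(amplitudes = as.numeric(sol$x),
       residual_norm = sqrt(sum((y - G %*% sol$x)^2)))
}

#' Fitted Gaussian peak model for a trace set
#'
#' @param centers strictly increasing band centers (samples).
#' @param widths Gaussian sigmas (samples, > 0), one per band.
#' @param amplitudes non-negative matrix `n_bands x n_lanes`.
#' @param residual_norms per-lane L2 residuals.
#' @param lanes lane metadata data frame.
#' @return A `peak_model` object.
#' @export
peak_model <- function(centers, widths, amplitudes, residual_norms = NULL,
                       lanes = NULL) {
  amplitudes <- as.matrix(amplitudes)
  stopifnot(!is.unsorted(centers, strictly = TRUE), all(widths > 0),
            all(amplitudes >= 0), nrow(amplitudes) == length(centers),
            length(widths) == length(centers))
  structure(list(centers = centers, widths = widths,
                 amplitudes = amplitudes,
                 residual_norms = residual_norms, lanes = lanes),
            class = "peak_model")
}

#' Fit the peak model for every lane
#'
#' Estimates widths from the annotation, then runs [fit_amplitudes()] on
#' each lane's signal channel. When bands are dense relative to the
#' smooth-baseline filter, that filter removes part of the genuine
#' inter-band signal floor along with the drift; with
#' `baseline_compensation = TRUE` (the default) a second fitting pass
#' corrects for this: the baseline the filter would extract from the fitted
#' model profile is added back to the data and the amplitudes are refit,
#' making the peak model self-consistent with the baseline stage.
#'
#' @param aligned an aligned `trace_set` (smooth baselines already removed
#'   by [align_all()]).
#' @param annotation a [band_annotation()].
#' @param width_factor see [estimate_widths()].
#' @param baseline_compensation logical; run the self-consistent
#'   compensation described above.
#' @param baseline_iterations fixed-point iterations of the compensation.
#'   Interior iterations use an unconstrained least-squares solve with a
#'   precomputed factorization; the final amplitudes always come from a
#'   non-negative solve on the compensated profile.
#' @param baseline_window,baseline_percentile the filter parameters the
#'   alignment stage used (see [subtract_smooth_baseline()]).
#' @return A [peak_model()].
#' @export
fit_peaks <- function(aligned, annotation, width_factor = 0.25,
                      baseline_compensation = TRUE,
                      baseline_iterations = 12L,
                      baseline_window = 201L, baseline_percentile = 0.10) {
  stopifnot(inherits(aligned, "trace_set"),
            inherits(annotation, "band_annotation"))
  widths <- estimate_widths(annotation, width_factor)
  centers <- annotation$positions
  n <- nrow(aligned$signal)
  idx <- .roi_idx(aligned$roi, n)
  bw <- min(as.integer(baseline_window), (n - 1L) %/% 2L * 2L + 1L)

  if (!baseline_compensation) {
    fits <- lapply(seq_len(ncol(aligned$signal)), function(j)
      fit_amplitudes(aligned$signal[, j], centers, widths,
                     roi = aligned$roi))
    return(peak_model(centers, widths,
                      vapply(fits, `[[`, numeric(length(widths)),
                             "amplitudes"),
                      residual_norms = vapply(fits, `[[`, 0,
                                              "residual_norm"),
                      lanes = aligned$lanes))
  }

  # shared design matrix and its normal-equations factorization: centers
  # and widths are common to all lanes, so the interior (unconstrained)
  # solves of the compensation loop reuse one Cholesky
  G <- vapply(seq_along(centers),
              function(i) .gauss_col(idx, centers[i], widths[i]),
              numeric(length(idx)))
  G <- matrix(G, nrow = length(idx))
  R <- chol(crossprod(G) + diag(1e-10, ncol(G)))
  ols <- function(y) backsolve(R, backsolve(R, crossprod(G, y),
                                            transpose = TRUE))
  model_profile <- function(a) {
    m <- numeric(n)
    m[idx] <- G %*% a
    m
  }
  fit_one <- function(j) {
    y <- aligned$signal[idx, j]
    a <- ols(y)
    fl <- NULL
    for (k in seq_len(max(0L, baseline_iterations - 1L))) {
      fl <- .smooth_baseline_fast(model_profile(pmax(a, 0)), bw,
                                  baseline_percentile)
      a <- ols(y + fl[idx])
    }
    fl <- .smooth_baseline_fast(model_profile(pmax(a, 0)), bw,
                                baseline_percentile)
    corrected <- aligned$signal[, j] + fl
    fit_amplitudes(corrected, centers, widths, roi = aligned$roi)
  }
  fits <- lapply(seq_len(ncol(aligned$signal)), fit_one)
  peak_model(centers, widths,
             vapply(fits, `[[`, numeric(length(widths)), "amplitudes"),
             residual_norms = vapply(fits, `[[`, 0, "residual_norm"),
             lanes = aligned$lanes)
}

#' Convert fitted amplitudes to band areas
#'
#' The area of a Gaussian band is `amplitude * sigma * sqrt(2 * pi)`.
#'
#' @param model a [peak_model()].
#' @return A `quant_result`: list with `areas` and `amplitudes` matrices
#'   (`n_bands x n_lanes`), `locations` (band centers), `widths`,
#'   `residual_norms` and `lanes`.
#' @export
quantify <- function(model) {
  stopifnot(inherits(model, "peak_model"))
  areas <- model$amplitudes * model$widths * sqrt(2 * pi)
  structure(list(areas = areas, amplitudes = model$amplitudes,
                 locations = model$centers, widths = model$widths,
                 residual_norms = model$residual_norms,
                 lanes = model$lanes),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> %d bands x %d lanes\n",
              nrow(x$areas), ncol(x$areas)))
  invisible(x)
}

#' Write the quantification table as tab-delimited text
#'
#' One row per residue and one column per capillary, with a header row of
#' lane ids and a first column `residue` combining display residue number
#' and base (e.g. `G17`).
#'
#' @param quant a `quant_result` from [quantify()].
#' @param annotation the [band_annotation()] the fit used.
#' @param path output path.
#' @param value `"area"` (default) or `"amplitude"`.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, annotation, path, value = "area") {
  m <- switch(value, area = quant$areas, amplitude = quant$amplitudes,
              stop("write_quant_table: value must be 'area' or 'amplitude'"))
  bases <- strsplit(annotation$sequence, "")[[1]]
  lane_ids <- if (!is.null(quant$lanes)) quant$lanes$capillary_id
              else paste0("lane", seq_len(ncol(m)))
  df <- data.frame(
    residue = paste0(bases[annotation$residues],
                     annotation$residues + annotation$offset))
  for (j in seq_along(lane_ids))
    df[[lane_ids[j]]] <- formatC(m[, j], format = "g", digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
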