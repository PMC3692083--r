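.base_colors <- c(G = "#00C000", C = "#00C8C8", U = "#0000FF", A = "#FF0000")

#' Render aligned lanes as a gel-style image
#'
#' Peaks appear as dark bands on a light background, one vertical strip per
#' lane, elution position running down the image. Intensities are clipped at
#' a percentile (default the 98th) before gray mapping, for robustness to
#' outliers. With an annotation, a colored marker is drawn at every residue
#' position in every lane using the conventional base palette (G green,
#' C cyan, U blue, A red). Output is deterministic: identical input and
#' configuration give a byte-identical PNG.
#'
#' @param traces a `trace_set` (ROI respected if set).
#' @param out_path output PNG path.
#' @param annotation optional [band_annotation()].
#' @param lane_width pixels per lane.
#' @param clip_percentile upper intensity clip (fraction).
#' @param max_rows image height cap; the ROI is downsampled to this many
#'   rows if longer.
#' @return `out_path`, invisibly.
#' @export
render_gel <- function(traces, out_path, annotation = NULL,
                       lane_width = 20L, clip_percentile = 0.98,
                       max_rows = 2000L) {
  stopifnot(inherits(traces, "trace_set"))
  idx <- .roi_idx(traces$roi, nrow(traces$signal))
  m <- traces$signal[idx, , drop = FALSE]
  n_lane <- ncol(m)
  if (length(idx) > max_rows) {
    pick <- unique(round(seq(1L, length(idx), length.out = max_rows)))
    m <- m[pick, , drop = FALSE]
    row_of <- function(pos) {
      rel <- (pos - idx[1]) / (idx[length(idx)] - idx[1])
      round(1 + rel * (nrow(m) - 1))
    }
  } else {
    row_of <- function(pos) round(pos - idx[1] + 1)
  }
  hi <- stats::quantile(m, clip_percentile, names = FALSE)
  lo <- min(m)
  rng <- if (hi > lo) hi - lo else 1
  gray <- 1 - pmin(pmax((m - lo) / rng, 0), 1)  # dark bands on light
  px <- array(0, dim = c(nrow(m), n_lane * lane_width, 3L))
  for (ch in 1:3)
    px[, , ch] <- gray[, rep(seq_len(n_lane), each = lane_width)]

  if (!is.null(annotation)) {
    cols <- grDevices::col2rgb(.base_colors) / 255
    bases <- strsplit(annotation$sequence, "")[[1]][annotation$residues]
    bases[bases == "T"] <- "U"
    for (i in seq_along(annotation$positions)) {
      r <- row_of(annotation$positions[i])
      if (is.na(r) || r < 1 || r > nrow(m)) next
      rgb_i <- cols[, bases[i]]
      for (j in seq_len(n_lane)) {
        cpix <- (j - 1L) * lane_width + c(1L, 2L, lane_width - 1L,
                                          lane_width)
        cpix <- cpix[cpix >= 1 & cpix <= dim(px)[2]]
        for (ch in 1:3) px[r, cpix, ch] <- rgb_i[ch]
      }
    }
  }
  png::writePNG(px, out_path)
  invisible(out_path)
}
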