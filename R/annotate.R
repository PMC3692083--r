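.modifier_kinds <- c("DMS", "CMCT", "SHAPE", "ddGTP", "ddATP", "ddTTP",
                     "ddCTP", "nomod", "other")

#' Declare the chemical modification applied to a lane
#'
#' One of the nine recognized per-capillary conditions: three probing
#' reagents (DMS, CMCT, SHAPE), four dideoxynucleotide sequencing ladders,
#' no modification, or "other".
#'
#' @param kind character scalar, one of `DMS, CMCT, SHAPE, ddGTP, ddATP,
#'   ddTTP, ddCTP, nomod, other`.
#' @return A `modifier_spec` object.
#' @export
modifier_spec <- function(kind) {
  kind <- as.character(kind)
  if (length(kind) != 1L || !(kind %in% .modifier_kinds))
    stop(sprintf("modifier_spec: kind must be one of %s",
                 paste(.modifier_kinds, collapse = ", ")))
  structure(list(kind = kind), class = "modifier_spec")
}

#' Per-residue band-intensity prior for a modification
#'
#' Where bands are expected for a given reagent: DMS modifies A and C, CMCT
#' modifies G and U, SHAPE acylates every residue's 2'-OH. A ddXTP ladder
#' terminates opposite its complementary template base (ddTTP marks A, ddATP
#' marks U, ddCTP marks G, ddGTP marks C). Unmodified or unknown lanes get a
#' flat uninformative weight. Probing lanes keep a small background weight at
#' unreactive residues because real traces show residual bands everywhere.
#'
#' @param sequence nucleotide string (A/C/G/U; T is treated as U).
#' @param modifier a [modifier_spec()] or kind string.
#' @return Numeric weight vector in \[0, 1\], one entry per residue.
#' @export
reactivity_mask <- function(sequence, modifier) {
  if (inherits(modifier, "modifier_spec")) modifier <- modifier$kind
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) == 0L) stop("reactivity_mask: empty sequence")
  bad <- which(!(bases %in% c("A", "C", "G", "U", "T")))
  if (length(bad) > 0L)
    stop(sprintf("reactivity_mask: invalid character '%s' at position %d",
                 bases[bad[1]], bad[1]))
  bases[bases == "T"] <- "U"
  switch(modifier,
    DMS   = ifelse(bases %in% c("A", "C"), 1, 0.1),
    CMCT  = ifelse(bases %in% c("G", "U"), 1, 0.1),
    SHAPE = rep(1, length(bases)),
    ddTTP = as.numeric(bases == "A"),
    ddATP = as.numeric(bases == "U"),
    ddCTP = as.numeric(bases == "G"),
    ddGTP = as.numeric(bases == "C"),
    nomod = rep(0.5, length(bases)),
    other = rep(0.5, length(bases)),
    stop(sprintf("reactivity_mask: unknown modifier '%s'", modifier)))
}

#' Band annotation: the residue-to-trace-position map
#'
#' A single consensus annotation shared by all aligned lanes: strictly
#' increasing trace positions, one per annotated residue.
#'
#' @param sequence probed nucleotide string.
#' @param positions numeric vector of trace positions (samples), strictly
#'   increasing.
#' @param residues 1-based residue indices into `sequence`, same length as
#'   `positions`.
#' @param offset integer added to residue numbering for display.
#' @return A `band_annotation` object.
#' @export
band_annotation <- function(sequence, positions, residues = NULL,
                            offset = 0L) {
  if (is.null(residues)) residues <- seq_along(positions)
  stopifnot(length(positions) == length(residues))
  if (length(positions) > 1L && any(diff(positions) <= 0))
    stop("band_annotation: positions must be strictly increasing")
  structure(list(sequence = toupper(sequence), offset = as.integer(offset),
                 positions = as.numeric(positions),
                 residues = as.integer(residues)),
            class = "band_annotation")
}

#' @export
print.band_annotation <- function(x, ...) {
  cat(sprintf("<band_annotation> %d residues of %d-nt sequence, positions %.0f..%.0f\n",
              length(x$positions), nchar(x$sequence),
              min(x$positions), max(x$positions)))
  invisible(x)
}

# DP over candidate positions: maximize sum of data terms minus the
# spacing-regularity penalty mu * ((gap - dhat)/dhat)^2, positions strictly
# increasing. data[k, i] = evidence for residue i at candidate k.
.annotate_dp <- function(cand, data, dhat, mu) {
  C <- length(cand); L <- ncol(data)
  gap_lo <- max(1, 0.2 * dhat); gap_hi <- 2.5 * dhat
  V <- data[, 1]  # residue 1 carries no spacing term
  back <- matrix(NA_integer_, C, L)
  for (i in seq_len(L)[-1]) {
    Vn <- rep(-Inf, C); bk <- rep(NA_integer_, C)
    for (k in seq_len(C)) {
      prev <- which(cand < cand[k] & cand >= cand[k] - gap_hi &
                    cand <= cand[k] - gap_lo)
      if (length(prev) == 0L) next
      pen <- mu * ((cand[k] - cand[prev] - dhat) / dhat)^2
      v <- V[prev] - pen
      j <- which.max(v)
      Vn[k] <- v[j] + data[k, i]
      bk[k] <- prev[j]
    }
    V <- Vn; back[, i] <- bk
  }
  if (!any(is.finite(V))) return(NULL)
  path <- integer(L)
  path[L] <- which.max(V)
  for (i in rev(seq_len(L)[-1])) path[i - 1L] <- back[path[i], i]
  if (anyNA(path)) return(NULL)
  path
}

#' Automatically assign residues to band positions
#'
#' Builds a composite evidence profile from all lanes, weighted per residue
#' by each lane's modification-specific [reactivity_mask()], and solves for
#' strictly increasing positions (one per residue) by dynamic programming:
#' the objective rewards placing residue i where its mask-weighted lane
#' intensities are high and penalizes deviations of consecutive spacings
#' from the local typical spacing by `mu * ((gap - dhat) / dhat)^2`.
#' Candidate positions are the local maxima of the summed evidence profile
#' plus a uniform fallback grid. Two passes are run: the first with
#' `dhat = ROI length / L`, the second with `dhat` re-estimated as the median
#' spacing of the first solution. Lane intensities are normalized by their
#' global maximum first, so the annotation is invariant under rescaling all
#' lanes by a positive constant.
#'
#' @param aligned an aligned `trace_set`.
#' @param sequence probed nucleotide string.
#' @param modifiers list of [modifier_spec()] (or kind strings), one per lane.
#' @param mu spacing-regularity weight (default 1).
#' @param offset display numbering offset.
#' @return A [band_annotation()] covering every residue of `sequence`.
#' @export
auto_annotate <- function(aligned, sequence, modifiers, mu = 1.0,
                          offset = 0L) {
  stopifnot(inherits(aligned, "trace_set"))
  n_lane <- ncol(aligned$signal)
  if (length(modifiers) != n_lane)
    stop(sprintf("auto_annotate: %d modifiers for %d lanes",
                 length(modifiers), n_lane))
  masks <- vapply(modifiers, function(m) reactivity_mask(sequence, m),
                  numeric(nchar(sequence)))  # [residue, lane]
  L <- nchar(sequence)
  idx <- .roi_idx(aligned$roi, nrow(aligned$signal))
  sig <- aligned$signal[idx, , drop = FALSE]
  sig <- pmax(sig, 0)
  mx <- max(sig)
  if (mx > 0) sig <- sig / mx

  evidence <- rowSums(sig)
  # candidates: local maxima of the composite evidence + uniform fallback
  n_roi <- length(idx)
  locmax <- which(diff(sign(diff(evidence))) < 0) + 1L
  fallback <- unique(round(seq(1L, n_roi, length.out = min(n_roi, 4L * L))))
  cand_rel <- sort(unique(c(locmax, fallback)))
  if (length(cand_rel) < L)
    stop(paste("auto_annotate: fewer candidate positions than residues -",
               "widen the ROI or shorten the sequence range"))
  # data term: evidence for residue i at candidate k, summed over lanes with
  # the lane's mask weight for that residue
  data <- sig[cand_rel, , drop = FALSE] %*% t(masks)  # [cand, residue]

  # initial spacing prior: the observed spacing of strong peaks of the
  # smoothed evidence (robust to a loose ROI), capped by ROI length / L,
  # which bounds the true mean spacing from above
  dhat <- n_roi / L
  sm <- as.numeric(stats::filter(evidence, rep(1 / 9, 9), sides = 2))
  sm[is.na(sm)] <- 0
  smax <- which(diff(sign(diff(sm))) < 0) + 1L
  strong <- smax[sm[smax] >= 0.3 * max(sm[smax])]
  if (length(strong) >= max(4L, L %/% 4L)) {
    gaps <- diff(strong)
    gaps <- gaps[gaps >= 3]
    if (length(gaps) >= 3L)
      dhat <- min(max(stats::median(gaps), 5), n_roi / L)
  }
  path <- .annotate_dp(cand_rel, data, dhat, mu)
  if (is.null(path))
    stop(paste("auto_annotate: no feasible monotone assignment -",
               "widen the ROI or shorten the sequence range"))
  dhat2 <- stats::median(diff(cand_rel[path]))
  if (is.finite(dhat2) && dhat2 > 0) {
    path2 <- .annotate_dp(cand_rel, data, dhat2, mu)
    if (!is.null(path2)) path <- path2
  }
  band_annotation(sequence, positions = idx[1] - 1L + cand_rel[path],
                  residues = seq_len(L), offset = offset)
}

#' Move one annotated residue
#'
#' Manual-adjustment primitive: returns a new annotation with a single
#' residue's position changed. Neighbors are never moved automatically; a
#' move that would break strict monotonicity is rejected, naming the
#' colliding neighbor.
#'
#' @param annotation a [band_annotation()].
#' @param residue 1-based residue index (must be annotated).
#' @param new_position new trace position in samples.
#' @return The adjusted [band_annotation()].
#' @export
adjust_annotation <- function(annotation, residue, new_position) {
  stopifnot(inherits(annotation, "band_annotation"))
  i <- match(residue, annotation$residues)
  if (is.na(i))
    stop(sprintf("adjust_annotation: residue %d is not annotated", residue))
  pos <- annotation$positions
  if (i > 1L && new_position <= pos[i - 1L])
    stop(sprintf(
      "adjust_annotation: position %.1f collides with residue %d at %.1f",
      new_position, annotation$residues[i - 1L], pos[i - 1L]))
  if (i < length(pos) && new_position >= pos[i + 1L])
    stop(sprintf(
      "adjust_annotation: position %.1f collides with residue %d at %.1f",
      new_position, annotation$residues[i + 1L], pos[i + 1L]))
  pos[i] <- new_position
  band_annotation(annotation$sequence, pos, annotation$residues,
                  annotation$offset)
}

#' Write an annotation as tab-delimited text
#'
#' Columns: residue_index (display numbering, i.e. index + offset), base,
#' position. Re-loadable with [read_annotation()], which is the scriptable
#' equivalent of adjusting band calls interactively.
#'
#' @param annotation a [band_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  bases <- strsplit(annotation$sequence, "")[[1]]
  df <- data.frame(
    residue_index = annotation$residues + annotation$offset,
    base = bases[annotation$residues],
    position = formatC(annotation$positions, format = "g", digits = 8))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation written by [write_annotation()]
#'
#' @param path annotation TSV path.
#' @param sequence the probed sequence the annotation refers to.
#' @param offset display numbering offset used when writing.
#' @return A [band_annotation()].
#' @export
read_annotation <- function(path, sequence, offset = 0L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  band_annotation(sequence, positions = as.numeric(df$position),
                  residues = as.integer(df$residue_index) - as.integer(offset),
                  offset = offset)
}
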