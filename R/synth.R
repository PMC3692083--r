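# run expr with a private, seeded RNG stream, restoring the caller's state
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration for the synthetic electropherogram generator
#'
#' Defaults emulate the benchmark condition used throughout the package's
#' tests: one sequencer batch of six capillaries probing a random 92-nt RNA
#' under six conditions (SHAPE, DMS, CMCT, a ddTTP sequencing ladder, an
#' unmodified control and one "other" lane), with ~40-sample band spacing,
#' gentle mobility curvature, per-lane linear and piecewise-linear
#' distortions, constant plus slow-drift baselines, and Gaussian noise at a
#' signal-to-noise ratio of 10 (mean reactive band peak over noise sigma).
#'
#' @param sequence_length residues (ignored if `sequence` given).
#' @param sequence explicit nucleotide string, or `"random"`.
#' @param n_batches,lanes_per_batch batch layout.
#' @param modifiers per-lane modifier kinds, recycled across batches.
#' @param n_samples samples per trace.
#' @param mobility_start first band center (samples).
#' @param mobility_spacing mean inter-band spacing (samples/residue).
#' @param mobility_curvature quadratic mobility term (samples/residue^2).
#' @param band_sigma Gaussian band width (samples).
#' @param intensity_scale fluorescence counts per unit reactivity.
#' @param reactivity_shape,reactivity_scale Gamma law of planted
#'   reactivities (long-tailed, as in real probing data).
#' @param decay_rate per-band multiplicative signal attenuation
#'   (1 = no decay, the default: decay correction is downstream work).
#' @param shift_max,scale_jitter planted linear distortion bounds: shifts
#'   uniform in +-`shift_max` samples, scales uniform in
#'   1 +- `scale_jitter`.
#' @param pw_offset_max planted piecewise distortion bound (samples).
#' @param baseline_const constant baseline (counts).
#' @param baseline_drift_amp slow sinusoidal drift amplitude (counts).
#' @param noise_sigma additive Gaussian noise sigma (counts).
#' @param seed integer RNG seed; mandatory, no implicit randomness.
#' @return A `synth_config` object.
#' @export
synth_config <- function(sequence_length = 92L, sequence = "random",
                         n_batches = 1L, lanes_per_batch = 6L,
                         modifiers = c("SHAPE", "DMS", "CMCT", "ddTTP",
                                       "nomod", "other"),
                         n_samples = 6000L,
                         mobility_start = 800, mobility_spacing = 40,
                         mobility_curvature = 0.02,
                         band_sigma = 10,
                         intensity_scale = 1000,
                         reactivity_shape = 1.5, reactivity_scale = 1.0,
                         decay_rate = 1.0,
                         shift_max = 60, scale_jitter = 0.01,
                         pw_offset_max = 20,
                         baseline_const = 200, baseline_drift_amp = 100,
                         noise_sigma = 150,
                         seed) {
  if (missing(seed)) stop("synth_config: a seed is mandatory")
  cfg <- as.list(environment())
  L <- if (identical(sequence, "random")) sequence_length
       else nchar(sequence)
  centers <- mobility_start + mobility_spacing * seq_len(L) +
    mobility_curvature * seq_len(L)^2
  if (any(diff(centers) <= 0))
    stop("synth_config: mobility curvature makes band centers non-monotone")
  if (max(centers) + 6 * band_sigma > n_samples)
    stop("synth_config: bands do not fit in n_samples")
  structure(cfg, class = "synth_config")
}

# planted distortion for one lane: linear + smooth piecewise offsets
.plant_distortion <- function(n, shift_max, scale_jitter, pw_offset_max,
                              identity = FALSE) {
  if (identity)
    return(warp_transform(linear_transform(0, 1, NA_real_)))
  b <- stats::runif(1, -shift_max, shift_max)
  a <- stats::runif(1, 1 - scale_jitter, 1 + scale_jitter)
  anchors <- NULL
  if (pw_offset_max > 0) {
    knots <- seq(1, n, length.out = 9)
    delta <- stats::runif(length(knots), -pw_offset_max, pw_offset_max)
    anchors <- cbind(source = knots + delta, target = knots)
  }
  warp_transform(linear_transform(b, a, NA_real_), anchors)
}

# exact inverse of a planted linear distortion, as the aligning transform
.invert_linear <- function(lin) {
  linear_transform(shift = -lin$shift / lin$scale, scale = 1 / lin$scale)
}

#' Generate a synthetic multi-batch CE experiment with ground truth
#'
#' Per lane: planted reactivities `r_i = mask_i * Gamma(shape, scale) +
#' 0.05` (mask from the lane's modifier), band centers on a monotone
#' quadratic mobility map, signal = sum of Gaussian bands (optionally
#' attenuated by `decay_rate^i`), reference channel = a uniform every-residue
#' ladder; both channels are then warped by the lane's planted linear +
#' piecewise distortion and receive constant + sinusoidal-drift baselines
#' and i.i.d. Gaussian noise. The first lane of the first batch is the
#' undistorted global reference. Deterministic given the seed.
#'
#' @param config a [synth_config()].
#' @return List with `batchset` (a `batch_set` of four-channel capillaries:
#'   signal, reference ladder, two dark channels) and `truth`, a list with
#'   `sequence`, `reactivities` (residues x lanes), `master_centers`
#'   (undistorted band centers), `observed_centers` (residues x lanes, in
#'   each lane's own distorted coordinates), `aligning` (per-lane
#'   [warp_transform()] that undoes the planted linear distortion exactly),
#'   `pw_delta` (per-lane function giving the planted piecewise offset at
#'   any position) and `modifiers`.
#' @export
generate_synth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  .with_seed(cfg$seed, {
    sequence <- if (identical(cfg$sequence, "random"))
      paste(sample(c("A", "C", "G", "U"), cfg$sequence_length, TRUE),
            collapse = "")
    else toupper(cfg$sequence)
    L <- nchar(sequence)
    ii <- seq_len(L)
    centers <- cfg$mobility_start + cfg$mobility_spacing * ii +
      cfg$mobility_curvature * ii^2
    x <- seq_len(cfg$n_samples)

    gauss_sum <- function(amps) {
      p <- numeric(cfg$n_samples)
      for (i in ii) {
        rng <- max(1, floor(centers[i] - 6 * cfg$band_sigma)):
               min(cfg$n_samples, ceiling(centers[i] + 6 * cfg$band_sigma))
        p[rng] <- p[rng] +
          amps[i] * exp(-(x[rng] - centers[i])^2 / (2 * cfg$band_sigma^2))
      }
      p
    }
    ladder_master <- gauss_sum(rep(2, L)) * cfg$intensity_scale

    n_lanes <- cfg$n_batches * cfg$lanes_per_batch
    mods <- rep_len(cfg$modifiers, n_lanes)
    reactivities <- matrix(0, L, n_lanes)
    observed_centers <- matrix(0, L, n_lanes)
    aligning <- vector("list", n_lanes)
    pw_delta <- vector("list", n_lanes)
    batches <- list()
    lane <- 0L
    for (b in seq_len(cfg$n_batches)) {
      bid <- sprintf("batch%d", b)
      caps <- vector("list", cfg$lanes_per_batch)
      for (k in seq_len(cfg$lanes_per_batch)) {
        lane <- lane + 1L
        mask <- reactivity_mask(sequence, mods[lane])
        r <- mask * stats::rgamma(L, cfg$reactivity_shape,
                                  scale = cfg$reactivity_scale) + 0.05
        if (cfg$decay_rate != 1) r <- r * cfg$decay_rate^ii
        reactivities[, lane] <- r
        dist <- .plant_distortion(cfg$n_samples, cfg$shift_max,
                                  cfg$scale_jitter, cfg$pw_offset_max,
                                  identity = (b == 1L && k == 1L))
        sig <- warp_profile(gauss_sum(r) * cfg$intensity_scale, dist)
        ref <- warp_profile(ladder_master, dist)
        drift_phase <- stats::runif(2, 0, 2 * pi)
        drift <- function(ph) cfg$baseline_drift_amp *
          sin(2 * pi * x / (cfg$n_samples / 3) + ph)
        sig <- sig + cfg$baseline_const + drift(drift_phase[1]) +
          stats::rnorm(cfg$n_samples, 0, cfg$noise_sigma)
        ref <- ref + cfg$baseline_const + drift(drift_phase[2]) +
          stats::rnorm(cfg$n_samples, 0, cfg$noise_sigma)
        dark1 <- stats::rnorm(cfg$n_samples, 50, 10)
        dark2 <- stats::rnorm(cfg$n_samples, 50, 10)
        ch <- round(cbind(sig, ref, dark1, dark2))
        ch <- pmin(pmax(ch, -32768), 32767)
        caps[[k]] <- raw_capillary(
          ch, capillary_id = sprintf("%s_lane%02d", bid, k),
          batch_id = bid,
          sample_name = sprintf("%s_%s", bid, mods[lane]))

        # where each master center lands in this lane's own coordinates
        lin <- dist$linear
        tgt_of_src <- function(src) {
          s <- lin$scale * src + lin$shift  # undo the linear read rule
          if (is.null(dist$anchors)) s
          else stats::approx(dist$anchors[, 1], dist$anchors[, 2],
                             xout = s, rule = 2)$y
        }
        observed_centers[, lane] <- tgt_of_src(centers)
        aligning[[lane]] <- warp_transform(.invert_linear(lin),
                                           dist$anchors)
        pw_delta[[lane]] <- if (is.null(dist$anchors)) {
          function(pos) rep(0, length(pos))
        } else local({
          anc <- dist$anchors
          function(pos) stats::approx(anc[, 2], anc[, 1] - anc[, 2],
                                      xout = pos, rule = 2)$y
        })
      }
      batches[[bid]] <- caps
    }
    list(batchset = structure(list(batches = batches), class = "batch_set"),
         truth = list(sequence = sequence, reactivities = reactivities,
                      master_centers = centers,
                      observed_centers = observed_centers,
                      aligning = aligning, pw_delta = pw_delta,
                      modifiers = mods, config = cfg))
  })
}

#' Write a synthetic experiment as an ABIF fixture directory
#'
#' One .fsa file per lane in per-batch subfolders (loadable unchanged by
#' [load_batches()]) plus tab-delimited ground-truth tables:
#' `truth_reactivities.tsv` (one row per residue, one column per lane),
#' `truth_centers.tsv` (observed band centers per lane) and
#' `truth_sequence.txt`.
#'
#' @param batchset,truth the two elements returned by [generate_synth()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(batchset, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (bid in names(batchset$batches)) {
    bdir <- file.path(dir, bid)
    dir.create(bdir, showWarnings = FALSE)
    for (cp in batchset$batches[[bid]])
      abif_write(cp, file.path(bdir, paste0(cp$capillary_id, ".fsa")))
  }
  lane_ids <- vapply(unlist(batchset$batches, recursive = FALSE),
                     `[[`, "", "capillary_id")
  write_mat <- function(m, path) {
    df <- as.data.frame(formatC(m, format = "g", digits = 8))
    names(df) <- lane_ids
    utils::write.table(cbind(residue = seq_len(nrow(m)), df), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(truth$reactivities, file.path(dir, "truth_reactivities.tsv"))
  write_mat(truth$observed_centers, file.path(dir, "truth_centers.tsv"))
  writeLines(truth$sequence, file.path(dir, "truth_sequence.txt"))
  invisible(dir)
}
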