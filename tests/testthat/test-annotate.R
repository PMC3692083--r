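test_that("reactivity masks encode the chemistry of each reagent", {
  expect_equal(reactivity_mask("GACU", "DMS"), c(0.1, 1, 1, 0.1))
  expect_equal(reactivity_mask("GACU", "CMCT"), c(1, 0.1, 0.1, 1))
  expect_equal(reactivity_mask("GACU", "SHAPE"), rep(1, 4))
  expect_equal(reactivity_mask("GACU", "ddTTP"), c(0, 1, 0, 0))
  expect_equal(reactivity_mask("GACU", "ddATP"), c(0, 0, 0, 1))
  expect_equal(reactivity_mask("GACU", "ddCTP"), c(1, 0, 0, 0))
  expect_equal(reactivity_mask("GACU", "ddGTP"), c(0, 0, 1, 0))
  expect_equal(reactivity_mask("GACU", "nomod"), rep(0.5, 4))
  # T is accepted and treated as U
  expect_equal(reactivity_mask("GACT", "ddATP"), c(0, 0, 0, 1))
})

test_that("invalid sequence characters are reported with their position", {
  expect_error(reactivity_mask("GAXU", "DMS"), "position 3")
  expect_error(modifier_spec("DMSO"), "one of")
})

test_that("band_annotation enforces strictly increasing positions", {
  expect_error(band_annotation("ACGU", c(10, 20, 20, 30)), "increasing")
  a <- band_annotation("ACGU", c(10, 20, 25, 30))
  expect_equal(a$residues, 1:4)
})

# one synthetic aligned lane set with bands at known centers
annotate_fixture <- function(sequence, modifiers, centers, amps_per_lane,
                             n = NULL, sigma = 8, noise = 0, seed = 1) {
  set.seed(seed)
  if (is.null(n)) n <- round(max(centers) + 200)
  sig <- vapply(amps_per_lane, function(a)
    band_profile(n, centers, a, sigma) + rnorm(n, 0, noise), numeric(n))
  mini_traces(sig, sig, roi = region_of_interest(
    max(1, round(min(centers) - 100)), n))
}

test_that("noiseless uniform bands are annotated at the planted centers", {
  L <- 50L
  seqs <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
  centers <- 300 + 40 * seq_len(L)
  tr <- annotate_fixture(seqs, "SHAPE", centers,
                         list(runif(L, 0.5, 2)))
  ann <- auto_annotate(tr, seqs, list("SHAPE"))
  expect_length(ann$positions, L)
  expect_lte(max(abs(ann$positions - centers)), 1)
})

test_that("a pure ddNTP ladder lane annotates its residues exactly", {
  set.seed(44)
  L <- 40L
  seqs <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
  centers <- 250 + 45 * seq_len(L)
  mask <- reactivity_mask(seqs, "ddTTP")
  amps <- mask * 2 + 0.05
  tr <- annotate_fixture(seqs, "ddTTP", centers, list(amps))
  ann <- auto_annotate(tr, seqs, list("ddTTP"))
  expect_lte(max(abs(ann$positions - centers)), 1)
})

test_that("annotation output is monotone and complete on random instances", {
  set.seed(45)
  for (i in 1:5) {
    L <- sample(20:40, 1)
    seqs <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    spacing <- runif(L, 34, 46)
    centers <- 300 + cumsum(spacing)
    tr <- annotate_fixture(seqs, "SHAPE", centers,
                           list(rgamma(L, 1.5) + 0.1), noise = 0.05,
                           seed = i)
    ann <- auto_annotate(tr, seqs, list("SHAPE"))
    expect_length(ann$positions, L)
    expect_true(all(diff(ann$positions) > 0))
  }
})

test_that("jittered spacing at SNR 10 is annotated within half a spacing", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    set.seed(s + 100)
    L <- 40L
    seqs <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    spacing <- 40 * runif(L, 0.85, 1.15)
    centers <- 300 + cumsum(spacing)
    amps <- rgamma(L, 1.5) + 0.1
    tr <- annotate_fixture(seqs, "SHAPE", centers, list(amps),
                           noise = mean(amps) / 10, seed = s)
    ann <- auto_annotate(tr, seqs, list("SHAPE"))
    hits <- hits + sum(abs(ann$positions - centers) <= 20)
    total <- total + L
  }
  expect_gte(hits / total, 0.95)
})

test_that("annotation is invariant under global intensity rescaling", {
  set.seed(46)
  L <- 30L
  seqs <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
  centers <- 300 + 40 * seq_len(L)
  amps <- rgamma(L, 1.5) + 0.1
  tr1 <- annotate_fixture(seqs, "SHAPE", centers, list(amps))
  tr2 <- tr1
  tr2$signal <- tr2$signal * 37.5
  a1 <- auto_annotate(tr1, seqs, list("SHAPE"))
  a2 <- auto_annotate(tr2, seqs, list("SHAPE"))
  expect_identical(a1$positions, a2$positions)
})

test_that("a lane whose mask is all zero does not influence annotation", {
  set.seed(47)
  L <- 30L
  seqs <- paste(rep(c("C", "G"), L / 2), collapse = "")  # no A anywhere
  centers <- 300 + 40 * seq_len(L)
  amps <- rgamma(L, 1.5) + 0.1
  n <- round(max(centers) + 200)
  lane1 <- band_profile(n, centers, amps)
  lane2 <- rnorm(n, 0, 0.01)^2    # ddTTP lane: no A residues, mask all 0
  roi <- region_of_interest(200, n)
  tr_both <- mini_traces(cbind(lane1, lane2), roi = roi)
  tr_one <- mini_traces(cbind(lane1), roi = roi)
  a_both <- auto_annotate(tr_both, seqs, list("SHAPE", "ddTTP"))
  a_one <- auto_annotate(tr_one, seqs, list("SHAPE"))
  expect_identical(a_both$positions, a_one$positions)
})

test_that("manual adjustment moves one residue and validates monotonicity", {
  ann <- band_annotation("ACGUACGUAC", seq(100, 1000, by = 100))
  moved <- adjust_annotation(ann, 4L, 410)
  expect_equal(moved$positions[4], 410)
  expect_equal(moved$positions[-4], ann$positions[-4])
  expect_error(adjust_annotation(ann, 4L, 510), "residue 5")
  expect_error(adjust_annotation(ann, 4L, 290), "residue 3")
  expect_error(adjust_annotation(ann, 11L, 500), "not annotated")
  # involution: adjust then adjust back
  back <- adjust_annotation(moved, 4L, 400)
  expect_identical(back, ann)
})

test_that("annotation TSV round-trips through write and read", {
  seqs <- "ACGUACGU"
  ann <- band_annotation(seqs, c(110.5, 150, 190.25, 230, 270, 310, 350,
                                 390), offset = 9L)
  f <- tempfile(fileext = ".tsv")
  write_annotation(ann, f)
  tab <- read.table(f, sep = "\t", header = TRUE)
  expect_equal(tab$residue_index, 10:17)
  expect_equal(tab$base[1:4], c("A", "C", "G", "U"))
  back <- read_annotation(f, seqs, offset = 9L)
  expect_equal(back$positions, ann$positions)
  expect_equal(back$residues, ann$residues)
})
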