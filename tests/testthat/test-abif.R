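test_that("ABIF write/read round trip is exact on channels and sample name", {
  set.seed(101)
  for (i in 1:5) {
    x <- random_capillary(n = sample(c(1L, 10L, 1000L), 1L),
                          n_ch = sample(2:6, 1L),
                          name = paste0("sample_", i))
    f <- tempfile(fileext = ".ab1")
    abif_write(x, f)
    y <- read_abif(f)
    expect_identical(unname(y$channels), unname(x$channels) * 1.0)
    expect_identical(y$sample_name, x$sample_name)
  }
})

test_that("negative intensities survive the 16-bit round trip", {
  x <- raw_capillary(matrix(c(-32768L, -1L, 0L, 32767L), 2, 2))
  f <- tempfile(fileext = ".fsa")
  abif_write(x, f)
  expect_equal(unname(read_abif(f)$channels), unname(x$channels) * 1.0)
})

test_that("a single 1x1 channel parses (inline payload path)", {
  f <- tempfile(fileext = ".fsa")
  abif_write(matrix(-5L, 1, 1), f)
  y <- read_abif(f)
  expect_equal(dim(y$channels), c(1L, 1L))
  expect_equal(unname(y$channels[1, 1]), -5)
})

test_that("non-ABIF and truncated files give format errors naming the path", {
  f <- tempfile(fileext = ".ab1")
  writeBin(charToRaw(strrep("X", 64)), f)
  expect_error(read_abif(f), "magic")
  expect_error(read_abif(f), basename(f), fixed = TRUE)

  # valid header, directory offset beyond end of file
  g <- tempfile(fileext = ".ab1")
  x <- random_capillary(n = 50L)
  abif_write(x, g)
  bytes <- readBin(g, "raw", file.info(g)$size)
  truncated <- bytes[1:200]
  writeBin(truncated, g)
  expect_error(read_abif(g), "truncated")

  expect_error(read_abif(tempfile()), "no such file")
})

test_that("writer rejects an empty channel matrix", {
  expect_error(abif_write(matrix(numeric(0), 0, 0), tempfile()),
               "empty")
})

test_that("load_batches maps subfolders to batches in lexicographic order", {
  root <- tempfile()
  dir.create(file.path(root, "b2"), recursive = TRUE)
  dir.create(file.path(root, "b1"))
  set.seed(5)
  # create b2 files first: creation order must not matter
  for (i in 1:2)
    abif_write(random_capillary(100L), file.path(root, "b2",
                                                 sprintf("f%d.ab1", i)))
  for (i in 3:1)
    abif_write(random_capillary(100L), file.path(root, "b1",
                                                 sprintf("f%d.ab1", i)))
  bs <- load_batches(root)
  expect_equal(names(bs$batches), c("b1", "b2"))
  expect_equal(unname(lengths(bs$batches)), c(3L, 2L))
  expect_equal(vapply(bs$batches$b1, `[[`, "", "capillary_id"),
               c("f1", "f2", "f3"))
  expect_equal(bs$batches$b1[[1]]$batch_id, "b1")
})

test_that("a flat directory yields a single batch called batch0", {
  root <- tempfile(); dir.create(root)
  set.seed(6)
  for (i in 1:5)
    abif_write(random_capillary(100L),
               file.path(root, sprintf("t%d.fsa", i)))
  bs <- load_batches(root)
  expect_equal(names(bs$batches), "batch0")
  expect_length(bs$batches$batch0, 5L)
})

test_that("zip archives load like directories, without caller-side extraction", {
  root <- tempfile()
  dir.create(file.path(root, "b1"), recursive = TRUE)
  dir.create(file.path(root, "b2"))
  set.seed(7)
  for (i in 1:3)
    abif_write(random_capillary(80L), file.path(root, "b1",
                                                sprintf("f%d.ab1", i)))
  for (i in 1:2)
    abif_write(random_capillary(80L), file.path(root, "b2",
                                                sprintf("f%d.ab1", i)))
  zf <- zip_dir(root, tempfile(fileext = ".zip"))
  bs <- load_batches(zf)
  expect_equal(names(bs$batches), c("b1", "b2"))
  expect_equal(unname(lengths(bs$batches)), c(3L, 2L))
})

test_that("a corrupt member is an error naming the file, not a silent skip", {
  root <- tempfile(); dir.create(file.path(root, "b1"), recursive = TRUE)
  set.seed(8)
  abif_write(random_capillary(80L), file.path(root, "b1", "good.ab1"))
  writeBin(charToRaw(strrep("Z", 64)), file.path(root, "b1", "bad.ab1"))
  expect_error(load_batches(root), "bad.ab1")
})

test_that("empty input reports what was scanned", {
  root <- tempfile(); dir.create(root)
  expect_error(load_batches(root), "no .ab1/.fsa files", fixed = TRUE)
})

test_that("DATA series of unequal length are right-padded with zeros", {
  # hand-built minimal ABIF file, independent of abif_write: two DATA tags
  # (int16), lengths 40 and 30, directory after the data blocks
  be <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "big")
  entry <- function(name, number, etype, esize, n, dsize, off) {
    writeBin(charToRaw(name), con)
    be(number, 4); be(etype, 2); be(esize, 2); be(n, 4); be(dsize, 4)
    be(off, 4); be(0, 4)
  }
  f <- tempfile(fileext = ".ab1")
  con <- file(f, "wb")
  writeBin(charToRaw("ABIF"), con); be(101, 2)
  dir_off <- 128 + 40 * 2 + 30 * 2
  entry("tdir", 1, 1023, 28, 2, 2 * 28, dir_off)
  writeBin(raw(128 - 6 - 28), con)
  be(1:40, 2)
  be(101:130, 2)
  entry("DATA", 1, 4, 2, 40, 80, 128)
  entry("DATA", 2, 4, 2, 30, 60, 128 + 80)
  close(con)

  y <- read_abif(f)
  expect_equal(dim(y$channels), c(40L, 2L))
  expect_equal(y$channels[, 1], as.numeric(1:40))
  expect_equal(y$channels[, 2], c(101:130, rep(0, 10)))
})

test_that("a file with no DATA tags is a format error", {
  be <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "big")
  f <- tempfile(fileext = ".ab1")
  con <- file(f, "wb")
  writeBin(charToRaw("ABIF"), con); be(101, 2)
  writeBin(charToRaw("tdir"), con)
  be(1, 4); be(1023, 2); be(28, 2); be(0, 4); be(0, 4); be(128, 4); be(0, 4)
  writeBin(raw(128 - 6 - 28), con)
  close(con)
  expect_error(read_abif(f), "no DATA tags")
})
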