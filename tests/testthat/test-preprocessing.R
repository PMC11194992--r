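test_that("DICOM files round-trip through the 8-bit window", {
  d <- withr::local_tempdir()
  # known ramp image: every 8-bit value appears
  ramp <- matrix(rep(0:255, length.out = 256 * 256), 256, 256)
  f <- file.path(d, "ramp.dcm")
  write_dicom(ramp * 257L, f, patient_id = "SUBJ1")
  raw <- read_dicom(f)
  expect_equal(raw$rows, 256L)
  expect_equal(raw$cols, 256L)
  expect_equal(raw$patient_id, "SUBJ1")
  expect_equal(max(raw$pixels), 255 * 257)
  rec <- convert_dicom(f)
  expect_lte(max(abs(rec$pixels - ramp)), 1)
  expect_true(all(rec$pixels >= 0 & rec$pixels <= 255))

  # constant-zero slice maps to an all-zero 8-bit image
  f0 <- file.path(d, "zero.dcm")
  write_dicom(matrix(0, 64, 64), f0)
  expect_true(all(convert_dicom(f0)$pixels == 0))

  # asymmetric geometry survives the row-major pixel order
  asym <- matrix(seq_len(32 * 48) %% 256, nrow = 32, ncol = 48)
  fa <- file.path(d, "asym.dcm")
  write_dicom(asym, fa)
  expect_equal(read_dicom(fa)$pixels, asym)

  expect_error(read_dicom(file.path(d, "missing.dcm")), "no such")
  not_dicom <- file.path(d, "plain.dcm")
  writeLines("hello", not_dicom)
  expect_error(read_dicom(not_dicom), "not a DICOM")
})

test_that("the empty-slice rule is mean intensity below 30", {
  blank <- pdgwo:::new_image_record(matrix(0, 64, 64), "a")
  expect_true(is_empty(blank))
  bright <- pdgwo:::new_image_record(matrix(200, 64, 64), "b")
  expect_false(is_empty(bright))
  # boundary: mean exactly at the threshold is kept
  at <- pdgwo:::new_image_record(matrix(30, 64, 64), "c")
  expect_false(is_empty(at))
  expect_true(is_empty(at, threshold = 31))
})

test_that("skull stripping recovers the phantom head mask", {
  spec <- phantom_spec(seed = 5)
  set.seed(5)
  im <- generate_image(spec, "HC")
  rec <- pdgwo:::new_image_record(im$pixels, "phantom")
  stripped <- skull_strip(rec)
  dice <- 2 * sum(stripped$mask & im$mask) /
    (sum(stripped$mask) + sum(im$mask))
  expect_gte(dice, 0.95)
  expect_true(all(stripped$pixels[!stripped$mask] == 0))
  expect_true(stripped$flags$stripped)

  # an image that is entirely foreground is untouched
  flat <- pdgwo:::new_image_record(matrix(200, 32, 32), "flat")
  expect_equal(skull_strip(flat)$pixels, flat$pixels)

  # a blank image has no foreground to strip
  expect_error(skull_strip(pdgwo:::new_image_record(matrix(0, 32, 32),
                                                    "blank")),
               "stripping failed")
})

test_that("morphology building blocks behave on known masks", {
  m <- matrix(FALSE, 9, 9)
  m[3:7, 3:7] <- TRUE
  m[5, 5] <- FALSE  # a hole
  expect_true(pdgwo:::fill_holes(m)[5, 5])
  # two components: largest wins
  m2 <- matrix(FALSE, 10, 10)
  m2[1:2, 1:2] <- TRUE
  m2[5:9, 5:9] <- TRUE
  big <- pdgwo:::largest_component(m2)
  expect_equal(sum(big), 25)
  expect_false(big[1, 1])
  # closing bridges a 1-px gap
  m3 <- matrix(FALSE, 8, 8)
  m3[4, c(2:3, 5:6)] <- TRUE
  expect_true(pdgwo:::binary_close(m3, iterations = 1)[4, 4])
})

test_that("crop/resize emits 224x224x3 and preserves the head centre", {
  spec <- phantom_spec(seed = 9)
  set.seed(9)
  im <- generate_image(spec, "PD")
  rec <- skull_strip(pdgwo:::new_image_record(im$pixels, "p"))
  out <- crop_and_resize(rec)
  expect_equal(dim(out$pixels), c(224L, 224L, 3L))
  expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  expect_identical(out$pixels[, , 1], out$pixels[, , 3])

  # identity: full-frame mask at target size already
  m224 <- matrix(runif(224 * 224, 0, 255), 224, 224)
  rec224 <- pdgwo:::new_image_record(m224, "id")
  rec224$mask <- matrix(TRUE, 224, 224)
  out224 <- crop_and_resize(rec224)
  expect_equal(out224$pixels[, , 1], m224, tolerance = 1e-12)

  # an off-centre disk lands on the output centre
  n <- 256
  xs <- matrix(seq_len(n), n, n) - 100
  ys <- t(matrix(seq_len(n), n, n)) - 140
  disk <- pdgwo:::new_image_record((sqrt(xs^2 + ys^2) <= 30) * 200, "disk")
  disk <- skull_strip(disk)
  res <- crop_and_resize(disk)
  plane <- res$pixels[, , 1]
  com_r <- sum(row(plane) * plane) / sum(plane)
  com_c <- sum(col(plane) * plane) / sum(plane)
  expect_lt(abs(com_r - 112.5), 1)
  expect_lt(abs(com_c - 112.5), 1)
})

test_that("the floor-rule splitter reproduces the published totals", {
  n1 <- 9070
  s1 <- split_dataset(data.frame(label = rep(c("PD", "HC"),
                                             length.out = n1)), seed = 1)
  tab1 <- table(s1$split)
  expect_equal(unname(tab1[["test"]]), 1814)
  expect_equal(unname(tab1[["train"]]) + unname(tab1[["validation"]]), 7256)
  expect_equal(unname(tab1[["validation"]]), 1451)
  expect_equal(unname(tab1[["train"]]), 5805)

  n2 <- 20096
  s2 <- split_dataset(data.frame(label = rep(c("PD", "HC"),
                                             length.out = n2)), seed = 1)
  tab2 <- table(s2$split)
  expect_equal(unname(tab2[["test"]]), 4019)
  expect_equal(unname(tab2[["train"]]) + unname(tab2[["validation"]]),
               16077)
  expect_equal(unname(tab2[["validation"]]), 3215)
})

test_that("splits are disjoint, exhaustive, stratified and seeded", {
  df <- data.frame(label = rep(c("PD", "HC"), each = 5))
  s <- split_dataset(df, seed = 4)
  expect_equal(as.vector(table(s$split)[c("train", "validation", "test")]),
               c(7L, 1L, 2L))
  expect_equal(nrow(s), 10)

  set.seed(123)
  df2 <- data.frame(label = sample(rep(c("PD", "HC"), c(300, 200))))
  s2 <- split_dataset(df2, seed = 8)
  expect_equal(sum(table(s2$split)), 500)
  # stratification: class shares in test within one record of ideal
  test_pd <- sum(s2$label == "PD" & s2$split == "test")
  expect_lte(abs(test_pd - 0.2 * 300), 1)
  # determinism
  expect_identical(split_dataset(df2, seed = 8), s2)
  expect_false(identical(split_dataset(df2, seed = 9)$split, s2$split))

  expect_error(split_dataset(data.frame(label = rep("PD", 10)), seed = 1),
               "class is absent")
})

test_that("subject-level splitting never splits a subject", {
  df <- data.frame(
    label = rep(c("PD", "HC"), each = 40),
    subject_id = paste0(rep(c("P", "H"), each = 40), rep(1:8, each = 10)))
  s <- split_dataset(df, seed = 2, by_subject = TRUE)
  leak <- tapply(s$split, s$subject_id, function(x) length(unique(x)))
  expect_true(all(leak == 1))
  expect_equal(sort(unique(as.character(s$split))),
               sort(c("train", "validation", "test")))
})

test_that("the full pipeline filters blanks, sizes outputs, and is idempotent", {
  raw <- withr::local_tempdir()
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  spec <- phantom_spec(size = 128L, blank_fraction = 0.2, seed = 21)
  truth <- generate_dataset(spec, 10, 10, raw)
  expect_equal(sum(truth$is_blank), 4)

  res <- run_pipeline(pipeline_config(raw, out1, seed = 6))
  expect_equal(res$summary$n_retained, 16)
  expect_equal(res$summary$n_filtered, 4)
  expect_equal(res$summary$n_retained + res$summary$n_filtered, 20)
  # flagged set is exactly the injected blank set
  expect_setequal(res$filtered$path, truth$path[truth$is_blank])
  # outputs all 224x224x3 in [0,255]
  for (p in file.path(out1, res$manifest$path)) {
    a <- png::readPNG(p)
    expect_equal(dim(a), c(224, 224, 3))
  }
  # labels joined from the truth manifest
  expect_true(all(res$manifest$label %in% c("PD", "HC")))

  res2 <- run_pipeline(pipeline_config(raw, out2, seed = 6))
  expect_identical(files_md5(file.path(out1, "manifest.csv")),
                   files_md5(file.path(out2, "manifest.csv")))
  expect_identical(files_md5(list.files(out1, "\\.png$",
                                        full.names = TRUE)),
                   files_md5(list.files(out2, "\\.png$",
                                        full.names = TRUE)))

  expect_error(run_pipeline(pipeline_config(withr::local_tempdir(),
                                            out1, seed = 1)),
               "no DICOM files")
})

test_that("per-file failures are logged and the pipeline continues", {
  raw <- withr::local_tempdir()
  spec <- phantom_spec(size = 96L, seed = 31)
  generate_dataset(spec, 3, 3, raw)
  writeLines("garbage", file.path(raw, "broken.dcm"))
  out <- withr::local_tempdir()
  res <- run_pipeline(pipeline_config(raw, out, seed = 1))
  expect_equal(res$summary$n_retained, 6)
  expect_equal(res$summary$n_filtered, 1)
  expect_match(res$filtered$reason[res$filtered$path == "broken.dcm"],
               "error")
})
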