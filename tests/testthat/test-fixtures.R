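# Synthetic dataset generator: determinism, balance, missingness structure
# and the clusterable-image property everything downstream relies on.

test_that("generation is deterministic and modality-balanced", {
  cfg <- fixture_config(n_exams = 100, seed = 5, files_per_exam_range = c(1, 3),
                        image_side_range = c(24, 32))
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)

  tab <- table(tapply(a$records$modality, a$records$exam_id, `[`, 1))
  expect_lte(max(tab) - min(tab), 1)  # balanced exams within +/- 1
  frac <- table(a$records$modality) / nrow(a$records)
  expect_true(all(abs(frac - 0.2) < 0.1))  # ~20% of records per modality

  n_files <- table(a$records$exam_id)
  expect_true(all(n_files >= 1 & n_files <= 3))
  # records of one exam share the diagnosis (one text per exam)
  expect_identical(sort(unique(a$records$exam_id)), sort(a$diagnoses$exam_id))
})

test_that("maskable tag cells go missing at the configured rate", {
  cfg <- fixture_config(n_exams = 500, seed = 9, tag_missing_rate = 0.3,
                        files_per_exam_range = c(2, 10),
                        image_side_range = c(16, 20))
  ds <- generate_dataset(cfg)
  maskable <- c("KVP", "ExposureTime", "PatientAge", "ProtocolGroup")
  cells <- unlist(lapply(ds$tags, function(t)
    vapply(maskable, function(m) length(t[[m]]) == 1L && is.na(t[[m]]), TRUE)))
  expect_gte(length(cells), 10000)
  expect_lt(abs(mean(cells) - 0.30), 0.02)
})

test_that("raw pixels honour the configured bit depth", {
  for (bits in c(12L, 16L)) {
    ds <- generate_dataset(fixture_config(n_exams = 5, seed = 2,
                                          bit_depth = bits,
                                          files_per_exam_range = c(1, 2),
                                          image_side_range = c(16, 20)))
    mx <- max(vapply(ds$pixels, max, 0L))
    expect_lt(mx, 2^bits)
    expect_gte(min(vapply(ds$pixels, min, 0L)), 0)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(fixture_config(n_exams = 0), "n_exams")
  expect_error(fixture_config(files_per_exam_range = c(5, 2)),
               "files_per_exam_range")
  expect_error(fixture_config(tag_missing_rate = 1), "tag_missing_rate")
  expect_error(fixture_config(bit_depth = 8), "bit_depth")
  expect_error(fixture_config(groups = list(c("ZZ", "HEAD"))), "groups")
})

test_that("images are more similar within a (modality, body part) group", {
  ds <- cached("grp_ds", generate_dataset(fixture_config(
    n_exams = 100, seed = 21, groups = planted_groups(),
    files_per_exam_range = c(1, 3), image_side_range = c(32, 32))))
  take <- seq_len(min(200L, nrow(ds$records)))
  imgs <- t(vapply(take, function(i) as.vector(ds$pixels[[i]]) / 4095,
                   numeric(32 * 32)))
  grp <- paste(ds$records$modality[take], ds$records$body_part[take])
  d <- as.matrix(dist(imgs))
  same <- outer(grp, grp, "==")
  diag(same) <- NA
  expect_lt(mean(d[which(same)]), mean(d[which(!same)]))
})

test_that("fixture files round-trip through the DICOM layer", {
  ds <- generate_dataset(fixture_config(n_exams = 6, seed = 3,
                                        files_per_exam_range = c(1, 2),
                                        image_side_range = c(16, 24)))
  dir <- withr::local_tempdir()
  paths <- write_dicom_fixtures(ds, dir)
  expect_length(paths, nrow(ds$records))
  back <- read_dicom_dataset(dir)
  expect_identical(back$pixels, ds$pixels)
  expect_identical(back$records$modality, ds$records$modality)
  expect_identical(back$diagnoses$text, ds$diagnoses$text)
  i <- 1L
  expect_identical(back$tags[[i]]$Modality, ds$tags[[i]]$Modality)
  expect_equal(back$tags[[i]]$WindowCenter, ds$tags[[i]]$WindowCenter)
  # blanked body parts stay blank (as NA after the read-side normalisation)
  blank_written <- vapply(ds$tags, function(t)
    identical(t$BodyPartExamined, ""), TRUE)
  blank_read <- vapply(back$tags, function(t)
    is.null(t$BodyPartExamined) || identical(t$BodyPartExamined, ""), TRUE)
  expect_identical(blank_read, blank_written)
  # stored bit depth propagates
  expect_true(all(vapply(back$tags, function(t) t$BitsStored == 12L, TRUE)))
})
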