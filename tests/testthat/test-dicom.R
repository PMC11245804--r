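# Minimal DICOM codec: round trips and conformance.

test_that("write/read round-trips pixels and tags exactly", {
  set.seed(1)
  px <- matrix(sample.int(4096L, 40 * 30, replace = TRUE) - 1L, 40, 30)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(path, px, tags = list(
    Modality = "CT", BodyPartExamined = "HEAD",
    StudyDescription = "skull lat", RescaleSlope = 1,
    RescaleIntercept = -1024, WindowCenter = c(40, 400),
    WindowWidth = c(80, 1500), KVP = 120.5, ExposureTime = 12L
  ), bits_stored = 12L)
  got <- read_dicom(path)
  expect_identical(got$pixels, px)
  expect_identical(got$tags$Modality, "CT")
  expect_identical(got$tags$BodyPartExamined, "HEAD")
  expect_equal(got$tags$WindowCenter, c(40, 400))
  expect_equal(got$tags$WindowWidth, c(80, 1500))
  expect_equal(got$tags$RescaleIntercept, -1024)
  expect_equal(got$tags$KVP, 120.5)
  expect_equal(got$tags$ExposureTime, 12)
  expect_identical(got$tags$BitsStored, 12L)
})

test_that("blank BodyPartExamined round-trips as present-but-empty", {
  px <- matrix(0:3, 2, 2)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(path, px, tags = list(BodyPartExamined = "",
                                    StudyDescription = "ankle ap lat"))
  got <- read_dicom(path)
  expect_true("BodyPartExamined" %in% names(got$tags))
  expect_identical(got$tags$BodyPartExamined, "")
})

test_that("pixel values exceeding the stored bit depth are rejected", {
  px <- matrix(c(0L, 4096L), 1, 2)
  expect_error(write_dicom(tempfile(), px, bits_stored = 12L),
               "do not fit")
})

test_that("files parse identically under an independent DICOM reader", {
  set.seed(2)
  px <- matrix(sample.int(4096L, 24 * 18, replace = TRUE) - 1L, 24, 18)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_dicom(path, px, tags = list(Modality = "MR",
                                    BodyPartExamined = "SPINE",
                                    WindowCenter = c(100, 200),
                                    WindowWidth = 300,
                                    RescaleSlope = 2, RescaleIntercept = 0),
              bits_stored = 12L)
  script <- sprintf(paste0(
    "import pydicom, json\n",
    "d = pydicom.dcmread(r'%s')\n",
    "arr = d.pixel_array\n",
    "print(json.dumps({'rows': int(d.Rows), 'cols': int(d.Columns),\n",
    "  'modality': str(d.Modality), 'bpe': str(d.BodyPartExamined),\n",
    "  'wc': [float(v) for v in d.WindowCenter],\n",
    "  'slope': float(d.RescaleSlope), 'bits': int(d.BitsStored),\n",
    "  'px_sum': int(arr.sum()), 'px_first': int(arr[0, 0]),\n",
    "  'px_last': int(arr[-1, -1])}))\n"), path)
  out <- system2("python", "-", input = script, stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(ref$rows, 24)
  expect_equal(ref$cols, 18)
  expect_equal(ref$modality, "MR")
  expect_equal(ref$bpe, "SPINE")
  expect_equal(ref$wc, c(100, 200))
  expect_equal(ref$slope, 2)
  expect_equal(ref$bits, 12)
  expect_equal(ref$px_sum, sum(px))
  expect_equal(ref$px_first, px[1, 1])
  expect_equal(ref$px_last, px[24, 18])
})
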