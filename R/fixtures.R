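# Synthetic multimodal fixtures: DICOM-like records with the statistical
# structure the pipeline assumes (clusterable image patterns per
# modality/body-part group, structured tag missingness, body-part-correlated
# pseudo-diagnosis text). No real patient data is involved; everything is
# procedurally generated from a seed.

.default_modalities <- c("CR", "CT", "MR", "XA", "RF")
.default_body_parts <- c("HEAD", "CHEST", "ABDOMEN", "FOOT", "SPINE")

.bpe_hints <- c(HEAD = "skull lat", CHEST = "thorax pa", ABDOMEN = "abdomen survey",
                FOOT = "ankle ap lat", SPINE = "lumbal spine")

#' Configuration for the synthetic dataset generator
#'
#' @param n_exams number of examinations; each exam has one diagnosis and
#'   between `files_per_exam_range[1]` and `files_per_exam_range[2]` records.
#' @param files_per_exam_range integer interval, default `c(1, 15)`.
#' @param modalities modality label set.
#' @param body_parts body-part label set.
#' @param groups optional list of `c(modality, body_part)` pairs; when given,
#'   exams are assigned to these planted groups in balanced rotation. When
#'   `NULL`, modalities are balanced across exams (counts within +/-1) and
#'   body parts drawn at random.
#' @param bit_depth stored pixel depth in `[12, 16]`.
#' @param image_side_range range of raw image side lengths (pixels); rows and
#'   columns are drawn independently so aspect ratios vary.
#' @param tag_missing_rate fraction in `[0, 1)` of maskable auxiliary tag
#'   cells set missing.
#' @param bpe_blank_rate fraction of records whose `BodyPartExamined` tag is
#'   blanked; a recoverable hint always remains in `StudyDescription`.
#' @param vocab_size_per_bodypart distinct diagnosis stems per body part.
#' @param shared_vocab_size stems shared across all body parts.
#' @param typo_rate per-token probability of a single-character corruption.
#' @param noise_sd standard deviation of the Gaussian pixel noise, on the
#'   unit intensity scale.
#' @param seed integer seed; the generated dataset is a deterministic
#'   function of the configuration.
#' @return an object of class `fixture_config`.
#' @export
fixture_config <- function(n_exams = 100L,
                           files_per_exam_range = c(1L, 15L),
                           modalities = .default_modalities,
                           body_parts = .default_body_parts,
                           groups = NULL,
                           bit_depth = 12L,
                           image_side_range = c(48L, 96L),
                           tag_missing_rate = 0.2,
                           bpe_blank_rate = 0.3,
                           vocab_size_per_bodypart = 30L,
                           shared_vocab_size = 20L,
                           typo_rate = 0.02,
                           noise_sd = 0.04,
                           seed = 1L) {
  assert_that(n_exams >= 1, "n_exams must be >= 1")
  assert_that(length(files_per_exam_range) == 2 &&
                files_per_exam_range[1] >= 1 &&
                files_per_exam_range[1] <= files_per_exam_range[2],
              "files_per_exam_range must be a valid integer interval with min >= 1")
  assert_that(bit_depth >= 12 && bit_depth <= 16, "bit_depth must lie in [12, 16]")
  assert_that(tag_missing_rate >= 0 && tag_missing_rate < 1,
              "tag_missing_rate must lie in [0, 1)")
  assert_that(bpe_blank_rate >= 0 && bpe_blank_rate <= 1,
              "bpe_blank_rate must lie in [0, 1]")
  if (!is.null(groups)) {
    ok <- all(vapply(groups, function(g) g[1] %in% modalities && g[2] %in% body_parts,
                     TRUE))
    assert_that(ok, "groups must be (modality, body_part) pairs from the label sets")
  }
  structure(as.list(environment()), class = "fixture_config")
}

# pseudo-word generator: deterministic pool of unique pronounceable stems
.make_words <- function(n) {
  syll <- c("ra", "ko", "mi", "tu", "la", "os", "fra", "den", "lum", "ka",
            "vi", "ne", "pro", "sta", "gle", "zlo", "bol", "net", "sur", "dia")
  out <- character(0)
  while (length(out) < n) {
    k <- sample(2:4, 1L)
    w <- paste(sample(syll, k, replace = TRUE), collapse = "")
    out <- unique(c(out, w))
  }
  out[seq_len(n)]
}

# procedural image on the unit intensity scale: per-group base gradient plus
# a modality-specific geometric primitive, so records sharing
# (modality, body part) are visually similar and groups are separable
.pattern_image <- function(nr, nc, mod_i, bp_i, noise_sd) {
  x <- matrix(rep(seq(0, 1, length.out = nc), each = nr), nr, nc)
  y <- matrix(rep(seq(0, 1, length.out = nr), times = nc), nr, nc)
  theta <- bp_i * pi / 3.1
  base <- 0.25 + 0.35 * (cos(theta) * x + sin(theta) * y)
  cx <- 0.3 + 0.08 * bp_i; cy <- 0.68 - 0.06 * bp_i
  prim <- switch(1L + (mod_i - 1L) %% 5L,
    (x - cx)^2 + (y - cy)^2 < 0.09,                          # disc
    abs(x - cx) < 0.22 & abs(y - cy) < 0.22,                 # square
    sin(10 * y + bp_i) > 0.3,                                # bands
    abs(x - y) < 0.08 | abs(x + y - 1) < 0.08,               # cross
    abs(sqrt((x - 0.5)^2 + (y - 0.5)^2) %% 0.18 - 0.09) < 0.035  # rings
  )
  d <- base + 0.4 * prim + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
  pmin(pmax(d, 0), 1)
}

#' Generate a synthetic multimodal dataset
#'
#' Produces DICOM-like records: a raw high-bit-depth pixel array whose
#' content is a procedural pattern parameterised by the record's
#' (modality, body part) group plus Gaussian noise; a tag mapping including
#' rescale/window parameters, maskable auxiliary tags with structured
#' missingness and a possibly blanked `BodyPartExamined` (with a recoverable
#' hint left in `StudyDescription`); and a per-exam pseudo-diagnosis whose
#' vocabulary is drawn from body-part-specific stems with Zipf weights and
#' occasional typographic corruption. All records of an exam share the
#' diagnosis. Deterministic given `config$seed`.
#'
#' @param config a [fixture_config()].
#' @return an object of class `radclust_dataset`: a list with `records`
#'   (data frame: `record_id`, `exam_id`, `modality`, `body_part`),
#'   `pixels` (list of integer matrices), `tags` (list of named lists),
#'   `diagnoses` (data frame: `exam_id`, `text`) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(config$seed)
  M <- config$modalities; B <- config$body_parts
  vmax <- 2L^config$bit_depth - 1L

  # vocabulary: disjoint per-body-part stem sets plus a shared set
  n_bp_words <- config$vocab_size_per_bodypart
  all_words <- .make_words(length(B) * n_bp_words + config$shared_vocab_size)
  bp_vocab <- split(all_words[seq_len(length(B) * n_bp_words)],
                    rep(seq_along(B), each = n_bp_words))
  names(bp_vocab) <- B
  shared_vocab <- tail(all_words, config$shared_vocab_size)

  # exam-level group assignment
  n <- config$n_exams
  if (!is.null(config$groups)) {
    gi <- rep_len(seq_along(config$groups), n)
    exam_mod <- vapply(config$groups, `[`, "", 1L)[gi]
    exam_bp <- vapply(config$groups, `[`, "", 2L)[gi]
  } else {
    exam_mod <- sample(rep_len(M, n))          # balanced to within +/-1
    exam_bp <- sample(B, n, replace = TRUE)
  }
  exam_ids <- sprintf("EX%05d", seq_len(n))

  zipf <- function(k) (1 / seq_len(k)) / sum(1 / seq_len(k))
  make_diag <- function(bp) {
    len <- sample(8:20, 1L)
    n_bp <- round(0.7 * len)
    words <- c(sample(bp_vocab[[bp]], n_bp, replace = TRUE, prob = zipf(n_bp_words)),
               sample(shared_vocab, len - n_bp, replace = TRUE,
                      prob = zipf(config$shared_vocab_size)))
    words <- sample(words)
    typo <- stats::runif(len) < config$typo_rate
    words[typo] <- vapply(words[typo], function(w) {
      i <- sample(nchar(w), 1L)
      substr(w, i, i) <- sample(letters, 1L)
      w
    }, "")
    # sprinkle punctuation the tokeniser must strip
    punct <- sample(c(",", ";", "", "", ""), len, replace = TRUE)
    paste0(paste0(words, punct), collapse = " ")
  }
  diagnoses <- data.frame(exam_id = exam_ids,
                          text = vapply(exam_bp, make_diag, ""),
                          stringsAsFactors = FALSE)

  n_files <- resample(seq(config$files_per_exam_range[1],
                          config$files_per_exam_range[2]),
                      n, replace = TRUE)
  rec_exam <- rep(seq_len(n), n_files)
  n_rec <- length(rec_exam)
  records <- data.frame(
    record_id = sprintf("R%06d", seq_len(n_rec)),
    exam_id = exam_ids[rec_exam],
    modality = exam_mod[rec_exam],
    body_part = exam_bp[rec_exam],
    stringsAsFactors = FALSE
  )

  pixels <- vector("list", n_rec)
  tags <- vector("list", n_rec)
  blank_bpe <- stats::runif(n_rec) < config$bpe_blank_rate
  maskable <- c("KVP", "ExposureTime", "PatientAge", "ProtocolGroup")
  for (i in seq_len(n_rec)) {
    mod <- records$modality[i]; bp <- records$body_part[i]
    mod_i <- match(mod, M); bp_i <- match(bp, B)
    nr <- resample(seq(config$image_side_range[1], config$image_side_range[2]), 1L)
    nc <- resample(seq(config$image_side_range[1], config$image_side_range[2]), 1L)
    d <- .pattern_image(nr, nc, mod_i, bp_i, config$noise_sd)
    # modality-specific rescale model; window parameters live in rescaled units
    slope <- if (mod == "MR") 2 else 1
    intercept <- if (mod == "CT") -1024 else 0
    wc <- round(0.5 * vmax * slope + intercept)
    ww <- round(0.8 * vmax * slope)
    # invert display -> rescaled -> raw so that windowing recovers the pattern
    rescaled <- (d - 0.5) * (ww - 1) + (wc - 0.5)
    raw <- round((rescaled - intercept) / slope)
    pixels[[i]] <- matrix(as.integer(pmin(pmax(raw, 0), vmax)), nr, nc)
    win_c <- if (mod == "CT") c(wc, wc + 200) else wc   # array-like on CT
    win_w <- if (mod == "CT") c(ww, round(ww / 2)) else ww
    tg <- list(
      SOPInstanceUID = sprintf("1.2.826.0.1.%06d", i),
      StudyInstanceUID = sprintf("1.2.826.0.2.%05d", rec_exam[i]),
      PatientID = sprintf("P%05d", rec_exam[i]),
      Modality = mod,
      BodyPartExamined = if (blank_bpe[i]) "" else bp,
      StudyDescription = .bpe_hints[[bp]],
      RescaleSlope = slope, RescaleIntercept = intercept,
      WindowCenter = win_c, WindowWidth = win_w,
      BitsStored = config$bit_depth,
      KVP = round(stats::rnorm(1, 40 + 15 * mod_i, 3), 1),
      ExposureTime = round(stats::rnorm(1, 30 + 10 * mod_i, 4)),
      PatientAge = sample(1:95, 1L),
      ProtocolGroup = paste0("PG", bp_i),
      SliceThickness = if (mod %in% c("CT", "MR"))
        round(stats::runif(1, 0.5, 5), 2) else NA
    )
    for (mt in maskable) if (stats::runif(1) < config$tag_missing_rate) tg[[mt]] <- NA
    tags[[i]] <- tg
  }

  structure(list(records = records, pixels = pixels, tags = tags,
                 diagnoses = diagnoses, config = config),
            class = "radclust_dataset")
}

#' @export
print.radclust_dataset <- function(x, ...) {
  cat("<radclust_dataset> ", nrow(x$records), " records / ",
      nrow(x$diagnoses), " exams\n", sep = "")
  cat("  modalities: ", paste(sort(unique(x$records$modality)), collapse = " "), "\n",
      "  body parts: ", paste(sort(unique(x$records$body_part)), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' Default body-part reconstruction rules matched to the fixture generator
#'
#' An ordered rule table mapping regular-expression patterns on a source tag
#' to `BodyPartExamined` values. In clinical archives such tables are written
#' by radiologists against local study-description conventions; this default
#' matches the hints emitted by [generate_dataset()].
#'
#' @return data frame with columns `pattern`, `source`, `value`.
#' @export
default_bpe_rules <- function() {
  data.frame(
    pattern = c("skull|cranium|head", "thorax|chest|pulmo", "abdomen|pelvis",
                "ankle|foot|tarsal", "spine|lumbal|cervical"),
    source = "StudyDescription",
    value = c("HEAD", "CHEST", "ABDOMEN", "FOOT", "SPINE"),
    stringsAsFactors = FALSE
  )
}

#' Write a dataset as DICOM files with a ground-truth sidecar
#'
#' One DICOM file per record (pixel data plus the record's tag mapping), a
#' `labels.json` sidecar carrying the generator's ground-truth labels and a
#' `diagnoses.csv` with the per-exam narrative text.
#'
#' @param dataset a `radclust_dataset`.
#' @param directory output directory (created if absent).
#' @return character vector of DICOM file paths, invisibly.
#' @export
write_dicom_fixtures <- function(dataset, directory) {
  stopifnot(inherits(dataset, "radclust_dataset"))
  assert_that(nrow(dataset$records) > 0, "dataset is empty")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(directory), "cannot create output directory")
  paths <- file.path(directory, paste0(dataset$records$record_id, ".dcm"))
  for (i in seq_len(nrow(dataset$records))) {
    tg <- dataset$tags[[i]]
    tg <- tg[!vapply(tg, function(v) length(v) == 1L && is.na(v), TRUE)]
    tg$ProtocolGroup <- NULL  # not a standard element; kept in the sidecar
    write_dicom(paths[i], dataset$pixels[[i]], tags = tg,
                bits_stored = dataset$config$bit_depth)
  }
  truth <- dataset$records
  truth$protocol_group <- vapply(dataset$tags, function(t)
    if (is.null(t$ProtocolGroup) || is.na(t$ProtocolGroup)) NA_character_
    else t$ProtocolGroup, "")
  jsonlite::write_json(truth, file.path(directory, "labels.json"),
                       dataframe = "rows", na = "null")
  utils::write.csv(dataset$diagnoses, file.path(directory, "diagnoses.csv"),
                   row.names = FALSE)
  invisible(paths)
}

#' Read a fixture directory back into a dataset
#'
#' Inverse of [write_dicom_fixtures()]: reads every `.dcm` file, the label
#' sidecar and the diagnoses table.
#'
#' @param directory directory written by [write_dicom_fixtures()].
#' @return a `radclust_dataset`.
#' @export
read_dicom_dataset <- function(directory) {
  truth <- jsonlite::read_json(file.path(directory, "labels.json"),
                               simplifyVector = TRUE)
  diagnoses <- utils::read.csv(file.path(directory, "diagnoses.csv"),
                               stringsAsFactors = FALSE)
  pixels <- vector("list", nrow(truth))
  tags <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    dcm <- read_dicom(file.path(directory, paste0(truth$record_id[i], ".dcm")))
    pixels[[i]] <- dcm$pixels
    tg <- dcm$tags
    if (!is.na(truth$protocol_group[i])) tg$ProtocolGroup <- truth$protocol_group[i]
    tags[[i]] <- tg
  }
  structure(list(
    records = truth[, c("record_id", "exam_id", "modality", "body_part")],
    pixels = pixels, tags = tags, diagnoses = diagnoses, config = NULL
  ), class = "radclust_dataset")
}
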