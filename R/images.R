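# Image export: raw stored pixel values -> modality-corrected real values
# (rescale slope/intercept) -> 8-bit display values (linear VOI windowing)
# -> policy checks -> aspect-preserving bilinear resize with centred zero
# padding to 128 x 128.

#' Apply the DICOM rescale transform
#'
#' Maps stored pixel values to modality units: `output = raw * slope +
#' intercept` elementwise. Records lacking the rescale tags are excluded
#' upstream by the eligibility check rather than silently defaulted.
#'
#' @param raw integer matrix of stored values.
#' @param slope,intercept finite rescale parameters.
#' @return numeric matrix.
#' @export
rescale_pixels <- function(raw, slope, intercept) {
  assert_that(length(slope) == 1 && is.finite(slope) &&
                length(intercept) == 1 && is.finite(intercept),
              "rescale tags missing or non-finite: record not eligible")
  raw * slope + intercept
}

#' Window rescaled values into 8-bit display values
#'
#' The linear value-of-interest mapping: values inside the window
#' `[center - width/2, center + width/2]` are mapped linearly onto
#' `[0, 255]`, values outside are clipped:
#' `y = clip(((x - (center - 0.5)) / (width - 1) + 0.5) * 255, 0, 255)`,
#' rounded half-up to integers.
#'
#' @param rescaled numeric matrix from [rescale_pixels()].
#' @param center,width window parameters; `width` must exceed 1. For
#'   multi-valued window tags pass the first value pair (the default
#'   display window).
#' @param invert apply photometric inversion (MONOCHROME1) before
#'   windowing output, i.e. return `255 - y`.
#' @return integer matrix with values in `[0, 255]`.
#' @export
window_to_8bit <- function(rescaled, center, width, invert = FALSE) {
  assert_that(length(width) == 1 && is.finite(width) && width > 1,
              "window width must be a finite value > 1: record not eligible")
  assert_that(length(center) == 1 && is.finite(center),
              "window center missing: record not eligible")
  y <- ((rescaled - (center - 0.5)) / (width - 1) + 0.5) * 255
  y <- pmin(pmax(y, 0), 255)
  out <- floor(y + 0.5)  # round half-up
  if (invert) out <- 255 - out
  storage.mode(out) <- "integer"
  out
}

#' Value policy: reject single-coloured images
#'
#' @param img integer matrix.
#' @return `TRUE` (pass) unless all pixels are equal.
#' @export
value_policy <- function(img) {
  length(img) > 0 && min(img) != max(img)
}

#' Shape policy: reject degenerate pixel arrays
#'
#' @param raw candidate pixel array.
#' @return `TRUE` only for 2-D arrays with both dimensions positive.
#' @export
shape_policy <- function(raw) {
  is.matrix(raw) && all(dim(raw) > 0)
}

#' Resize an 8-bit image to a square with aspect-preserving padding
#'
#' The longer side is scaled to `side` pixels with bilinear interpolation,
#' the shorter side by the same factor, and the result is zero-padded to
#' `side x side` with the content centred (odd remainders put the extra
#' row/column at the bottom/right).
#'
#' @param img integer matrix in `[0, 255]` that passed both policies.
#' @param side target side length, default 128.
#' @return an object of class `exported_image`: list with `pixels`
#'   (`side x side` integer matrix) and `pad_box`
#'   (`c(top, bottom, left, right)` zero-padding widths).
#' @export
resize_pad <- function(img, side = 128L) {
  assert_that(shape_policy(img), "resize_pad requires a 2-D array")
  nr <- nrow(img); nc <- ncol(img)
  f <- side / max(nr, nc)
  new_r <- max(1L, round(nr * f)); new_c <- max(1L, round(nc * f))
  if (new_r == nr && new_c == nc) {
    content <- img
  } else {
    content <- EBImage::resize(EBImage::Image(img / 255), w = new_r, h = new_c,
                               filter = "bilinear")
    content <- matrix(pmin(pmax(floor(EBImage::imageData(content) * 255 + 0.5),
                                0), 255), new_r, new_c)
  }
  pad_r <- side - new_r; pad_c <- side - new_c
  top <- pad_r %/% 2L; left <- pad_c %/% 2L
  out <- matrix(0L, side, side)
  out[top + seq_len(new_r), left + seq_len(new_c)] <- content
  storage.mode(out) <- "integer"
  structure(list(pixels = out,
                 pad_box = c(top = top, bottom = pad_r - top,
                             left = left, right = pad_c - left)),
            class = "exported_image")
}

# first value of a possibly multi-valued window tag (DICOM default window)
.first_value <- function(v) if (length(v) >= 1L) v[[1L]] else NA_real_

#' Check export eligibility of a record's tags
#'
#' A record is eligible when all four rescale/window parameters are present
#' and usable (`RescaleSlope`, `RescaleIntercept`, `WindowCenter`,
#' `WindowWidth`, with width > 1).
#'
#' @param tags named tag list of one record.
#' @return `TRUE` or `FALSE`.
#' @export
export_eligible <- function(tags) {
  s <- .first_value(tags$RescaleSlope); i <- .first_value(tags$RescaleIntercept)
  c <- .first_value(tags$WindowCenter); w <- .first_value(tags$WindowWidth)
  all(is.finite(c(s, i, c, w))) && w > 1
}

#' Export a dataset's images to clean 8-bit 128 x 128 arrays
#'
#' Runs the full export on every record: eligibility check, rescale,
#' windowing (first window value pair; photometric inversion when the
#' record is flagged MONOCHROME1), value and shape policies, then
#' aspect-preserving resize with centred zero padding. The export is
#' deterministic and idempotent: re-exporting an exported image under an
#' identity window returns it unchanged.
#'
#' @param dataset a `radclust_dataset`.
#' @param side output side length, default 128.
#' @return list with `images` (n_kept x side^2 matrix of values in
#'   `[0, 255]`, rows named by record id, each row a flattened image),
#'   `manifest` (data frame: record id, per-policy outcomes, kept flag,
#'   pad box) and `side`.
#' @export
export_images <- function(dataset, side = 128L) {
  stopifnot(inherits(dataset, "radclust_dataset"))
  n <- nrow(dataset$records)
  manifest <- data.frame(record_id = dataset$records$record_id,
                         eligible = FALSE, shape_ok = FALSE, value_ok = FALSE,
                         kept = FALSE, pad_top = NA_integer_,
                         pad_bottom = NA_integer_, pad_left = NA_integer_,
                         pad_right = NA_integer_, stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    tg <- dataset$tags[[i]]
    raw <- dataset$pixels[[i]]
    manifest$eligible[i] <- export_eligible(tg)
    manifest$shape_ok[i] <- shape_policy(raw)
    if (!manifest$eligible[i] || !manifest$shape_ok[i]) next
    resc <- rescale_pixels(raw, .first_value(tg$RescaleSlope),
                           .first_value(tg$RescaleIntercept))
    img8 <- window_to_8bit(resc, .first_value(tg$WindowCenter),
                           .first_value(tg$WindowWidth),
                           invert = identical(tg$PhotometricInterpretation,
                                              "MONOCHROME1"))
    manifest$value_ok[i] <- value_policy(img8)
    if (!manifest$value_ok[i]) next
    ex <- resize_pad(img8, side = side)
    manifest$kept[i] <- TRUE
    manifest[i, c("pad_top", "pad_bottom", "pad_left", "pad_right")] <-
      as.list(ex$pad_box)
    rows[[dataset$records$record_id[i]]] <- as.vector(ex$pixels)
  }
  images <- do.call(rbind, rows)
  list(images = images, manifest = manifest, side = side)
}

#' Write exported images as PNG files with a manifest
#'
#' @param export result of [export_images()].
#' @param directory output directory.
#' @return paths of the written PNGs, invisibly.
#' @export
write_exported_images <- function(export, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ids <- rownames(export$images)
  paths <- file.path(directory, paste0(ids, ".png"))
  for (i in seq_along(ids)) {
    png::writePNG(matrix(export$images[i, ] / 255, export$side, export$side),
                  paths[i])
  }
  utils::write.csv(export$manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE)
  invisible(paths)
}
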