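# DICOM tag preprocessing: body-part reconstruction, array-tag splitting,
# fill-rate/identifier/constant filtering, forest-based imputation and
# one-hot/min-max encoding. The table representation is a plain data frame
# with one row per record; multi-valued tags are list columns until
# split_array_tags() expands them; missing is NA throughout.

#' Build a tag table from a dataset
#'
#' Assembles the per-record tag mappings into a rectangular table: one row
#' per record, one column per tag name seen anywhere in the dataset. Tags
#' with multi-valued entries become list columns (see [split_array_tags()]);
#' empty strings and absent tags become `NA`.
#'
#' @param dataset a `radclust_dataset`.
#' @param exclude tag names to leave out (pixel-geometry tags by default,
#'   since they describe storage rather than acquisition semantics).
#' @return a data frame with attribute `record_id`.
#' @export
build_tag_table <- function(dataset,
                            exclude = c("Rows", "Columns", "BitsAllocated",
                                        "HighBit", "SamplesPerPixel",
                                        "PhotometricInterpretation",
                                        "PixelRepresentation")) {
  stopifnot(inherits(dataset, "radclust_dataset"))
  nms <- unique(unlist(lapply(dataset$tags, names)))
  nms <- setdiff(nms, exclude)
  n <- length(dataset$tags)
  cols <- lapply(nms, function(nm) {
    vals <- lapply(dataset$tags, function(t) {
      v <- t[[nm]]
      if (is.null(v) || length(v) == 0L) return(NA)
      if (is.character(v) && length(v) == 1L && !nzchar(v)) return(NA)
      v
    })
    lens <- lengths(vals)
    if (all(lens <= 1L)) {
      unlist(lapply(vals, function(v) if (length(v)) v else NA))
    } else {
      I(vals)
    }
  })
  names(cols) <- nms
  tab <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  attr(tab, "record_id") <- dataset$records$record_id
  tab
}

#' Reconstruct missing BodyPartExamined values from other tags
#'
#' Clinical archives leave the body-part tag blank in a large share of
#' records, but the information frequently survives in free-text tags such
#' as the study description. An ordered rule table of regular expressions is
#' applied: for each record with a missing body part, the first rule whose
#' pattern matches its source tag supplies the value. Non-missing body parts
#' are never overwritten.
#'
#' @param table tag table (data frame).
#' @param rules data frame with columns `pattern`, `source`, `value`;
#'   see [default_bpe_rules()].
#' @param bpe_col name of the body-part column.
#' @return the table with blanks filled where possible; the number of
#'   reconstructions is attached as attribute `n_reconstructed`.
#' @export
reconstruct_bpe <- function(table, rules = default_bpe_rules(),
                            bpe_col = "BodyPartExamined") {
  assert_that(is.data.frame(rules) && nrow(rules) > 0 &&
                all(c("pattern", "source", "value") %in% names(rules)),
              "rules must be a nonempty data frame with pattern/source/value")
  for (p in rules$pattern) {
    ok <- tryCatch({ grepl(p, "x"); TRUE }, error = function(e) FALSE,
                   warning = function(w) FALSE)
    assert_that(ok, sprintf("malformed regular expression in rules: '%s'", p))
  }
  if (!bpe_col %in% names(table)) return(structure(table, n_reconstructed = 0L))
  bpe <- table[[bpe_col]]
  missing_bpe <- is.na(bpe) | !nzchar(as.character(bpe))
  filled <- 0L
  for (i in which(missing_bpe)) {
    for (r in seq_len(nrow(rules))) {
      src <- table[[rules$source[r]]]
      if (is.null(src)) next
      v <- src[[i]]
      if (length(v) == 1L && !is.na(v) && grepl(rules$pattern[r], v,
                                                ignore.case = TRUE)) {
        bpe[i] <- rules$value[r]
        filled <- filled + 1L
        break
      }
    }
  }
  table[[bpe_col]] <- bpe
  structure(table, n_reconstructed = filled,
            record_id = attr(table, "record_id"))
}

#' Split array-valued tags into scalar columns
#'
#' A column holding n-element arrays becomes n scalar columns named
#' `<tag>_0 ... <tag>_{n-1}`; scalar columns pass through unchanged. Ragged
#' arrays are padded with `NA` (and noted via a message).
#'
#' @param table tag table possibly containing list columns.
#' @return a data frame with only atomic columns.
#' @export
split_array_tags <- function(table) {
  out <- list()
  for (nm in names(table)) {
    col <- table[[nm]]
    if (!is.list(col)) { out[[nm]] <- col; next }
    lens <- vapply(col, function(v) if (all(is.na(v[1])) && length(v) <= 1L) 0L
                   else length(v), 0L)
    width <- max(lens, 1L)
    if (length(unique(lens[lens > 0L])) > 1L) {
      message(sprintf("ragged array tag '%s': padding to %d values with NA",
                      nm, width))
    }
    for (j in seq_len(width)) {
      out[[sprintf("%s_%d", nm, j - 1L)]] <-
        unlist(lapply(col, function(v) if (length(v) >= j) v[j] else NA))
    }
  }
  res <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  attr(res, "record_id") <- attr(table, "record_id")
  res
}

#' Filter uninformative tag columns
#'
#' Drops columns that are (a) non-missing in less than `fill_threshold` of
#' rows (a column filled in exactly the threshold fraction is kept),
#' (b) identifier-like -- every non-missing value distinct, applied to
#' character columns, supplemented by the explicit `drop_tags` list,
#' (c) flagged as free text by name, or (d) constant (fewer than two
#' distinct non-missing values). Fill rates are computed on `fill_rows`
#' (the training subset) when given, to avoid leaking validation/test
#' missingness into the design.
#'
#' @param table tag table with atomic columns.
#' @param fill_threshold minimum fill rate in `(0, 1]`, default 0.35.
#' @param freetext_tags column names treated as natural language.
#' @param drop_tags additional columns to drop unconditionally; defaults
#'   to the standard DICOM instance/patient identifier tags, which repeat
#'   across records of one exam and so evade the distinctness heuristic.
#' @param fill_rows optional integer/logical row index for fill-rate and
#'   distinctness computation.
#' @return the filtered table; dropped columns and reasons are attached as
#'   attribute `dropped` (named character vector).
#' @export
filter_tags <- function(table, fill_threshold = 0.35,
                        freetext_tags = c("StudyDescription",
                                          "SeriesDescription"),
                        drop_tags = c("SOPInstanceUID", "StudyInstanceUID",
                                      "SeriesInstanceUID", "PatientID"),
                        fill_rows = NULL) {
  assert_that(fill_threshold > 0 && fill_threshold <= 1,
              "fill_threshold must lie in (0, 1]")
  sub <- if (is.null(fill_rows)) table else table[fill_rows, , drop = FALSE]
  dropped <- character(0)
  keep <- character(0)
  for (nm in names(table)) {
    v <- sub[[nm]]
    nonmiss <- v[!is.na(v)]
    reason <- NULL
    fill <- length(nonmiss) / length(v)
    if (nm %in% drop_tags) reason <- "drop list"
    else if (nm %in% freetext_tags) reason <- "free text"
    else if (fill < fill_threshold) reason <- sprintf("fill rate %.2f", fill)
    else if (length(unique(nonmiss)) < 2L) reason <- "constant"
    else if (is.character(v) && length(nonmiss) > 1L &&
             !anyDuplicated(nonmiss)) reason <- "identifier"
    if (is.null(reason)) keep <- c(keep, nm) else dropped[nm] <- reason
  }
  assert_that(length(keep) > 0, "no tag columns survive filtering")
  res <- table[, keep, drop = FALSE]
  attr(res, "dropped") <- dropped
  attr(res, "record_id") <- attr(table, "record_id")
  res
}

.col_mode <- function(v) {
  tb <- table(v)
  names(tb)[which.max(tb)]
}

#' Iterative forest-based imputation of missing tag values
#'
#' Fills missing cells in the MissForest style: cells are initialised with
#' the column mean (continuous) or mode (categorical); columns are then
#' visited in order of ascending missingness, each being re-predicted from
#' all other columns by a random forest fit on its observed rows. Iteration
#' stops when the change measure (sum of squared changes on continuous
#' columns plus mismatch count on categorical ones, each normalised) first
#' rises, or after `max_iter` sweeps; the previous iterate is returned.
#'
#' @param table tag table with atomic columns, no all-missing column.
#' @param n_trees trees per forest (default 100).
#' @param max_iter maximum sweeps (default 10).
#' @param seed integer seed; the imputation is deterministic given it.
#' @return the completed table (no `NA` cells).
#' @export
impute_missing <- function(table, n_trees = 100L, max_iter = 10L, seed = 1L) {
  rid <- attr(table, "record_id")
  n <- nrow(table)
  miss <- vapply(table, function(v) sum(is.na(v)), 0L)
  assert_that(all(miss < n), "all-missing column: should have been filtered out")
  if (sum(miss) == 0L) return(table)

  is_cat <- vapply(table, is.character, TRUE)
  work <- table
  for (nm in names(table)) {
    idx <- is.na(work[[nm]])
    if (!any(idx)) next
    work[[nm]][idx] <- if (is_cat[[nm]]) .col_mode(work[[nm]][!idx])
                       else mean(as.numeric(work[[nm]][!idx]))
  }
  for (nm in names(work)[is_cat]) work[[nm]] <- factor(work[[nm]])

  order_cols <- names(sort(miss[miss > 0L]))
  prev <- work
  prev_delta <- Inf
  set.seed(seed)
  for (iter in seq_len(max_iter)) {
    for (nm in order_cols) {
      obs <- !is.na(table[[nm]])
      dat <- work[, setdiff(names(work), nm), drop = FALSE]
      if (ncol(dat) == 0L) next
      y <- work[[nm]]
      fit <- tryCatch(
        ranger::ranger(x = dat[obs, , drop = FALSE], y = y[obs],
                       num.trees = n_trees, seed = seed + iter,
                       num.threads = 1),
        error = function(e) NULL)
      if (is.null(fit)) next   # degenerate column (e.g. single factor level)
      pred <- stats::predict(fit, data = dat[!obs, , drop = FALSE],
                             num.threads = 1)$predictions
      work[[nm]][!obs] <- pred
    }
    # normalised change measure between successive iterates, imputed cells only
    d_cont <- 0; d_cat <- 0
    for (nm in order_cols) {
      idx <- is.na(table[[nm]])
      if (is_cat[[nm]]) {
        d_cat <- d_cat + sum(work[[nm]][idx] != prev[[nm]][idx]) / sum(idx)
      } else {
        denom <- sum(as.numeric(work[[nm]])^2)
        if (denom > 0) {
          d_cont <- d_cont +
            sum((as.numeric(work[[nm]][idx]) - as.numeric(prev[[nm]][idx]))^2) / denom
        }
      }
    }
    delta <- d_cont + d_cat
    if (delta >= prev_delta) { work <- prev; break }
    prev <- work
    prev_delta <- delta
    if (delta == 0) break
  }
  for (nm in names(work)[is_cat]) work[[nm]] <- as.character(work[[nm]])
  attr(work, "record_id") <- rid
  work
}

#' Fit a tag encoder on the training subset
#'
#' Learns the encoding design: categorical (character) columns are one-hot
#' encoded over their training levels; continuous columns are min-max scaled
#' to `[0, 1]` with training ranges. The fitted encoder is re-applicable to
#' validation/test tables via [encode_tags()]; values outside the training
#' range are clipped, and unseen categories yield an all-zero one-hot block.
#'
#' @param table complete (imputed) tag table.
#' @return an object of class `tag_encoder`.
#' @export
fit_tag_encoder <- function(table) {
  is_cat <- vapply(table, is.character, TRUE)
  enc <- list(columns = names(table), is_cat = is_cat,
              levels = lapply(table[is_cat], function(v) sort(unique(v))),
              ranges = lapply(table[!is_cat], function(v) fit_minmax(as.numeric(v))))
  structure(enc, class = "tag_encoder")
}

#' Encode a tag table as a numeric matrix
#'
#' @param table complete tag table.
#' @param encoder a fitted [fit_tag_encoder()]; when `NULL`, fitted on
#'   `table` itself.
#' @return numeric matrix with all values in `[0, 1]`, one-hot blocks for
#'   categorical columns and scaled continuous columns.
#' @export
encode_tags <- function(table, encoder = NULL) {
  assert_that(!anyNA(table), "encode_tags requires a complete table (impute first)")
  if (is.null(encoder)) encoder <- fit_tag_encoder(table)
  stopifnot(inherits(encoder, "tag_encoder"))
  blocks <- list()
  unseen <- character(0)
  for (nm in encoder$columns) {
    v <- table[[nm]]
    if (isTRUE(encoder$is_cat[[nm]])) {
      lev <- encoder$levels[[nm]]
      m <- matrix(0, nrow(table), length(lev),
                  dimnames = list(NULL, paste0(nm, "=", lev)))
      hit <- match(v, lev)
      bad <- is.na(hit)
      if (any(bad)) unseen <- c(unseen, paste0(nm, ":", unique(v[bad])))
      m[cbind(which(!bad), hit[!bad])] <- 1
      blocks[[nm]] <- m
    } else {
      blocks[[nm]] <- matrix(apply_minmax(as.numeric(v), encoder$ranges[[nm]]),
                             ncol = 1, dimnames = list(NULL, nm))
    }
  }
  if (length(unseen)) {
    message("unseen categories at transform time (zero block): ",
            paste(unique(unseen), collapse = ", "))
  }
  do.call(cbind, blocks)
}
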