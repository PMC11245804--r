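# End-to-end unsupervised labelling: exam-level split, per-source
# preprocessing and embedding, fusion, final clustering, evaluation and
# cluster filtering, wrapped as a classic fit-object interface. radclust()
# fits everything and predict() assigns previously unseen records through
# the persisted transforms (nearest final centre in fused space).

#' Split records into train/validation/test at examination level
#'
#' All records of one exam land in the same subset, so diagnosis text never
#' leaks across subsets. Exam counts match the requested ratios exactly up
#' to integer rounding (largest-remainder allocation); record counts match
#' only approximately when exams have variable file counts.
#'
#' @param records data frame with an `exam_id` column, or a
#'   `radclust_dataset`.
#' @param ratios subset fractions summing to 1, default
#'   `c(train = 0.8, validation = 0.1, test = 0.1)`.
#' @param seed integer seed.
#' @return factor of subset names per record, with the per-exam assignment
#'   attached as attribute `exam_subset` (named character vector).
#' @export
split_dataset <- function(records,
                          ratios = c(train = 0.8, validation = 0.1,
                                     test = 0.1),
                          seed = 1L) {
  if (inherits(records, "radclust_dataset")) records <- records$records
  assert_that(abs(sum(ratios) - 1) < 1e-8, "split ratios must sum to 1")
  if (is.null(names(ratios))) {
    names(ratios) <- c("train", "validation", "test")[seq_along(ratios)]
  }
  exams <- unique(records$exam_id)
  assert_that(length(exams) >= sum(ratios > 0),
              "fewer exams than requested subsets")
  set.seed(seed)
  exams <- sample(exams)
  n <- length(exams)
  counts <- floor(ratios * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- ratios * n - counts
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1
  }
  subset_by_exam <- rep(names(ratios), counts)
  names(subset_by_exam) <- exams
  out <- factor(subset_by_exam[records$exam_id], levels = names(ratios))
  attr(out, "exam_subset") <- subset_by_exam
  out
}

#' Pipeline configuration
#'
#' Defaults reproduce the selected end-to-end configuration: tag
#' autoencoder 512 -> 200 -> 125 -> 32 at learning rate 1e-2; image
#' convolutional autoencoder at learning rate 1e-6 with randomized PCA to
#' 500 components; PV-DBOW diagnosis vectors of length 1000 (window 7, 50
#' epochs, minimum word frequency 50); direct embedding concatenation; and
#' a final k-means (Euclidean) clustering with 50 groups. Every component
#' can be swapped or scaled through its own config object.
#'
#' @param split exam-level subset ratios.
#' @param bpe_rules body-part reconstruction rule table.
#' @param fill_threshold tag fill-rate threshold, default 0.35.
#' @param impute_trees trees per imputation forest.
#' @param tag_extractor `"ae"` or `"pca"`.
#' @param tag_ae a [tag_ae_config()].
#' @param tag_pca_components,tag_pca_solver PCA alternative for tags.
#' @param image_side exported image side length, default 128.
#' @param cae a [cae_config()].
#' @param image_pca_components components for image embedding reduction
#'   (`NULL` to skip), default 500.
#' @param image_pca_solver solver for the image PCA, default randomized.
#' @param stemmer stemmer injected into text preprocessing.
#' @param text_extractor `"pvdbow"`, `"pvdm"`, `"bow"` or `"tfidf"`.
#' @param doc2vec a [doc2vec_config()] (mode is set from `text_extractor`).
#' @param min_word_frequency corpus threshold for bow/tfidf extractors.
#' @param fusion `"embeddings"`, `"clusterdists"` or `"clusterprobs"`.
#' @param source_clusters per-source clustering used by the
#'   distance-based fusion methods: named list (`diagnosis`, `tags`,
#'   `image`) of `list(algorithm, metric, kappa)`.
#' @param final final clustering: `list(algorithm, metric, kappa)`.
#' @param min_size,entropy_cutoff cluster post-filter parameters.
#' @param metrics_subset subset on which the quality metrics and
#'   dissimilarity report are computed (`"validation"`, `"test"`,
#'   `"train"`); overall metrics are always reported as well.
#' @param seed master seed; each stage derives its own child seed.
#' @return an object of class `radclust_config`.
#' @export
radclust_config <- function(split = c(train = 0.8, validation = 0.1,
                                      test = 0.1),
                            bpe_rules = default_bpe_rules(),
                            fill_threshold = 0.35,
                            impute_trees = 100L,
                            tag_extractor = c("ae", "pca"),
                            tag_ae = tag_ae_config(),
                            tag_pca_components = 50L,
                            tag_pca_solver = "lapack",
                            image_side = 128L,
                            cae = cae_config(),
                            image_pca_components = 500L,
                            image_pca_solver = "randomised",
                            stemmer = stemmer_suffix,
                            text_extractor = c("pvdbow", "pvdm", "bow",
                                               "tfidf"),
                            doc2vec = doc2vec_config(),
                            min_word_frequency = 50L,
                            fusion = c("embeddings", "clusterdists",
                                       "clusterprobs"),
                            source_clusters = list(
                              diagnosis = list(algorithm = "kmeans",
                                               metric = "euclidean",
                                               kappa = 20L),
                              tags = list(algorithm = "kmedoids",
                                          metric = "cosine", kappa = 25L),
                              image = list(algorithm = "kmeans",
                                           metric = "euclidean",
                                           kappa = 40L)),
                            final = list(algorithm = "kmeans",
                                         metric = "euclidean", kappa = 50L),
                            min_size = 100L, entropy_cutoff = 0.9,
                            metrics_subset = "validation",
                            seed = 1L) {
  tag_extractor <- match.arg(tag_extractor)
  text_extractor <- match.arg(text_extractor)
  fusion <- match.arg(fusion)
  assert_that(abs(sum(split) - 1) < 1e-8, "split ratios must sum to 1")
  assert_that(final$kappa >= 2, "final kappa must be >= 2")
  structure(as.list(environment()), class = "radclust_config")
}

# training-subset fill values (mean/mode) used to complete unseen records
.impute_defaults <- function(table) {
  lapply(table, function(v) {
    if (is.character(v)) .col_mode(v[!is.na(v)]) else mean(as.numeric(v),
                                                           na.rm = TRUE)
  })
}

.apply_impute_defaults <- function(table, defaults) {
  for (nm in names(defaults)) {
    if (!nm %in% names(table)) table[[nm]] <- NA
    idx <- is.na(table[[nm]])
    if (any(idx)) table[[nm]][idx] <- defaults[[nm]]
  }
  table[names(defaults)]
}

# tag table -> preprocessed (reconstructed, split, column-selected) form
.prep_tag_table <- function(dataset, config, kept_cols = NULL,
                            fill_rows = NULL) {
  tab <- build_tag_table(dataset)
  tab <- reconstruct_bpe(tab, config$bpe_rules)
  n_rec <- attr(tab, "n_reconstructed")
  tab <- split_array_tags(tab)
  if (is.null(kept_cols)) {
    tab <- filter_tags(tab, fill_threshold = config$fill_threshold,
                       fill_rows = fill_rows)
  } else {
    for (nm in setdiff(kept_cols, names(tab))) tab[[nm]] <- NA
    tab <- tab[kept_cols]
  }
  attr(tab, "n_reconstructed") <- n_rec
  tab
}

.exam_stems <- function(dataset, stemmer) {
  stems <- lapply(dataset$diagnoses$text, preprocess_text, stemmer = stemmer)
  names(stems) <- dataset$diagnoses$exam_id
  stems
}

# per-record text embedding matrix from per-exam embeddings
.per_record <- function(exam_mat, exam_ids, rec_exam) {
  out <- exam_mat[match(rec_exam, exam_ids), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the full multimodal labelling pipeline
#'
#' Runs the complete unsupervised annotation procedure on a dataset of
#' records: exam-level split; tag preprocessing (body-part reconstruction,
#' array splitting, fill-rate filtering on the training subset, forest
#' imputation, one-hot/min-max encoding) and tag embedding; image export
#' (rescale, window, policies, resize) and convolutional-autoencoder
#' embedding with optional PCA reduction; diagnosis preprocessing and
#' text embedding; fusion of the three sources; final clustering; quality
#' metrics; and cluster post-filtering with an oversampling plan. All
#' extractors are fitted on the training subset only and applied to the
#' rest through persisted transforms.
#'
#' @param dataset a `radclust_dataset` (see [generate_dataset()] /
#'   [read_dicom_dataset()]).
#' @param config a [radclust_config()].
#' @return an object of class `radclust` with, among others, `labels`
#'   (per-record data frame: record id, subset, cluster, filtered
#'   cluster), `metrics` (overall and per the configured metrics subset),
#'   `dissimilarity` (image/diagnosis reports and `d_score`),
#'   `filter` (removal log), `oversampling` and `manifest`.
#'   Methods: [print.radclust()], [summary.radclust()],
#'   [predict.radclust()].
#' @export
radclust <- function(dataset, config = radclust_config()) {
  stopifnot(inherits(dataset, "radclust_dataset"),
            inherits(config, "radclust_config"))
  seed <- config$seed
  subset <- split_dataset(dataset, config$split,
                          seed = derive_seed(seed, "split"))
  train <- subset == "train"
  validation <- subset == "validation"

  ## ---- tags ----
  tab <- .prep_tag_table(dataset, config, fill_rows = which(train))
  tab_i <- impute_missing(tab, n_trees = config$impute_trees,
                          seed = derive_seed(seed, "impute"))
  impute_defaults <- .impute_defaults(tab_i[train, , drop = FALSE])
  encoder <- fit_tag_encoder(tab_i[train, , drop = FALSE])
  x_tags <- encode_tags(tab_i, encoder)
  if (config$tag_extractor == "ae") {
    cfg <- config$tag_ae
    cfg$seed <- derive_seed(seed, "tag_ae")
    tag_fit <- fit_tag_autoencoder(x_tags[train, , drop = FALSE], cfg,
                                   x_val = if (any(validation))
                                     x_tags[validation, , drop = FALSE])
  } else {
    tag_fit <- fit_pca(x_tags[train, , drop = FALSE],
                       n_components = min(config$tag_pca_components,
                                          sum(train), ncol(x_tags)),
                       solver = config$tag_pca_solver,
                       seed = derive_seed(seed, "tag_pca"))
  }
  emb_tags <- predict(tag_fit, x_tags)

  ## ---- images ----
  export <- export_images(dataset, side = config$image_side)
  kept_ids <- rownames(export$images)
  kept <- dataset$records$record_id %in% kept_ids
  img_rows <- match(dataset$records$record_id[kept], kept_ids)
  train_img <- which(kept_ids %in% dataset$records$record_id[train & kept])
  val_img <- which(kept_ids %in% dataset$records$record_id[validation & kept])
  cae_cfg <- config$cae
  cae_cfg$seed <- derive_seed(seed, "cae")
  cae_fit <- fit_cae(export$images[train_img, , drop = FALSE], cae_cfg,
                     images_val = if (length(val_img))
                       export$images[val_img, , drop = FALSE],
                     side = config$image_side)
  emb_img_raw <- predict(cae_fit, export$images)
  if (!is.null(config$image_pca_components)) {
    img_pca <- fit_pca(emb_img_raw[train_img, , drop = FALSE],
                       n_components = min(config$image_pca_components,
                                          length(train_img),
                                          ncol(emb_img_raw)),
                       solver = config$image_pca_solver,
                       seed = derive_seed(seed, "img_pca"))
    emb_img_all <- predict(img_pca, emb_img_raw)
  } else {
    img_pca <- NULL
    emb_img_all <- emb_img_raw
  }

  ## ---- diagnoses ----
  stems <- .exam_stems(dataset, config$stemmer)
  exam_subset <- attr(subset, "exam_subset")
  train_exams <- names(exam_subset)[exam_subset == "train"]
  train_stems <- stems[names(stems) %in% train_exams]
  if (config$text_extractor %in% c("pvdbow", "pvdm")) {
    d2v_cfg <- config$doc2vec
    d2v_cfg$mode <- if (config$text_extractor == "pvdbow") "PV-DBOW" else "PV-DM"
    d2v_cfg$seed <- derive_seed(seed, "doc2vec")
    text_fit <- fit_doc2vec(train_stems, d2v_cfg)
    exam_emb <- matrix(0, length(stems), d2v_cfg$embedding_size)
    tr_idx <- match(names(train_stems), names(stems))
    exam_emb[tr_idx, ] <- text_fit$doc_vectors
    other <- setdiff(seq_along(stems), tr_idx)
    if (length(other)) {
      exam_emb[other, ] <- predict(text_fit, stems[other],
                                   seed = derive_seed(seed, "d2v_infer"))
    }
    corpus <- text_fit$corpus
  } else {
    corpus <- build_corpus(train_stems, config$min_word_frequency)
    text_fit <- corpus
    exam_emb <- if (config$text_extractor == "bow") bow_embed(stems, corpus)
                else tfidf_embed(stems, corpus)
  }
  emb_text <- .per_record(exam_emb, names(stems), dataset$records$exam_id)

  ## ---- alignment & fusion ----
  parts <- list(diagnosis = emb_text[kept, , drop = FALSE],
                tags = emb_tags[kept, , drop = FALSE],
                image = emb_img_all[img_rows, , drop = FALSE])
  train_k <- train[kept]
  source_models <- NULL; normalisers <- NULL
  if (config$fusion == "embeddings") {
    fused <- fuse_embeddings(parts)
  } else {
    source_models <- lapply(names(parts), function(nm) {
      sc <- config$source_clusters[[nm]]
      fit_cluster(parts[[nm]][train_k, , drop = FALSE], sc$algorithm,
                  sc$metric, sc$kappa,
                  seed = derive_seed(seed, paste0("src_", nm)))
    })
    names(source_models) <- names(parts)
    train_parts <- lapply(parts, function(p) p[train_k, , drop = FALSE])
    fuse_fun <- if (config$fusion == "clusterdists") fuse_clusterdists
                else fuse_clusterprobs
    tr_fused <- fuse_fun(train_parts, source_models)
    normalisers <- attr(tr_fused, "normalisers")
    fused <- fuse_fun(parts, source_models, normalisers = normalisers)
  }

  ## ---- final clustering ----
  final_model <- fit_cluster(fused[train_k, , drop = FALSE],
                             config$final$algorithm, config$final$metric,
                             min(config$final$kappa, sum(train_k) - 1L),
                             seed = derive_seed(seed, "final"))
  assign_all <- predict(final_model, fused)
  cluster <- assign_all$cluster

  ## ---- evaluation ----
  labels_kept <- list(modality = dataset$records$modality[kept],
                      body_part = dataset$records$body_part[kept])
  subset_k <- subset[kept]
  eval_metrics <- function(idx) {
    yhat <- cluster[idx]
    m <- list(nmi_m = nmi(labels_kept$modality[idx], yhat),
              nmi_b = nmi(labels_kept$body_part[idx], yhat),
              hs_m = hs(labels_kept$modality[idx], yhat),
              hs_b = hs(labels_kept$body_part[idx], yhat))
    m$s <- score_s(m$hs_b, m$hs_m, m$nmi_b, m$nmi_m)
    m
  }
  ms <- config$metrics_subset
  eval_idx <- if (any(subset_k == ms)) which(subset_k == ms)
              else seq_along(cluster)
  metrics <- list(overall = eval_metrics(seq_along(cluster)))
  metrics[[ms]] <- eval_metrics(eval_idx)
  diss_i <- cluster_dissimilarity(parts$image[eval_idx, , drop = FALSE],
                                  cluster[eval_idx],
                                  seed = derive_seed(seed, "diss_i"))
  diss_d <- cluster_dissimilarity(parts$diagnosis[eval_idx, , drop = FALSE],
                                  cluster[eval_idx],
                                  seed = derive_seed(seed, "diss_d"))
  dissimilarity <- list(image = diss_i, diagnosis = diss_d,
                        d_score = d_score(diss_i$D, diss_d$D))

  ## ---- post-filters ----
  filt <- filter_clusters(cluster, labels_kept, min_size = config$min_size,
                          entropy_cutoff = config$entropy_cutoff)
  train_filtered <- filt$cluster[train_k]
  plan <- if (any(!is.na(train_filtered)))
    oversample_plan(train_filtered) else NULL

  labels_df <- data.frame(record_id = dataset$records$record_id[kept],
                          exam_id = dataset$records$exam_id[kept],
                          subset = as.character(subset_k),
                          cluster = cluster,
                          filtered_cluster = filt$cluster,
                          stringsAsFactors = FALSE)

  manifest <- list(
    seed = seed,
    stage_seeds = sapply(c("split", "impute", "tag_ae", "tag_pca", "cae",
                           "img_pca", "doc2vec", "d2v_infer", "final"),
                         function(s) derive_seed(seed, s)),
    n_records = nrow(dataset$records), n_exams = nrow(dataset$diagnoses),
    n_kept = sum(kept),
    fusion = config$fusion, fused_length = ncol(fused),
    final = config$final,
    r_version = as.character(getRversion())
  )

  structure(list(
    config = config, subset = subset, kept = kept,
    tag_pipeline = list(kept_cols = names(tab_i),
                        impute_defaults = impute_defaults,
                        encoder = encoder, extractor = tag_fit,
                        n_bpe_reconstructed = attr(tab, "n_reconstructed")),
    image_pipeline = list(cae = cae_fit, pca = img_pca,
                          manifest = export$manifest),
    text_pipeline = list(extractor = text_fit, corpus = corpus),
    fusion = list(method = config$fusion, models = source_models,
                  normalisers = normalisers,
                  spans = attr(fused, "component_spans")),
    final_model = final_model,
    labels = labels_df, metrics = metrics,
    dissimilarity = dissimilarity,
    filter = filt, oversampling = plan,
    manifest = manifest
  ), class = "radclust")
}

# shared transform: dataset -> fused embedding matrix + kept mask
.transform_dataset <- function(object, dataset) {
  config <- object$config
  tp <- object$tag_pipeline
  tab <- .prep_tag_table(dataset, config, kept_cols = tp$kept_cols)
  tab <- .apply_impute_defaults(tab, tp$impute_defaults)
  x_tags <- encode_tags(tab, tp$encoder)
  emb_tags <- predict(tp$extractor, x_tags)

  export <- export_images(dataset, side = config$image_side)
  kept_ids <- rownames(export$images)
  kept <- dataset$records$record_id %in% kept_ids
  img_rows <- match(dataset$records$record_id[kept], kept_ids)
  emb_img <- predict(object$image_pipeline$cae, export$images)
  if (!is.null(object$image_pipeline$pca)) {
    emb_img <- predict(object$image_pipeline$pca, emb_img)
  }

  stems <- .exam_stems(dataset, config$stemmer)
  if (config$text_extractor %in% c("pvdbow", "pvdm")) {
    exam_emb <- predict(object$text_pipeline$extractor, stems,
                        seed = derive_seed(config$seed, "d2v_infer"))
  } else {
    exam_emb <- if (config$text_extractor == "bow")
      bow_embed(stems, object$text_pipeline$corpus)
    else tfidf_embed(stems, object$text_pipeline$corpus)
  }
  emb_text <- .per_record(exam_emb, names(stems), dataset$records$exam_id)

  parts <- list(diagnosis = emb_text[kept, , drop = FALSE],
                tags = emb_tags[kept, , drop = FALSE],
                image = emb_img[img_rows, , drop = FALSE])
  fused <- switch(object$fusion$method,
    embeddings = fuse_embeddings(parts),
    clusterdists = fuse_clusterdists(parts, object$fusion$models,
                                     normalisers = object$fusion$normalisers),
    clusterprobs = fuse_clusterprobs(parts, object$fusion$models,
                                     normalisers = object$fusion$normalisers))
  list(fused = fused, kept = kept, parts = parts)
}

#' Assign previously unseen records to the fitted clusters
#'
#' Runs every persisted transform on the new dataset (tag preprocessing
#' with the stored column set, encoder and training fill values; image
#' export and embedding; text inference; fusion with the stored models and
#' normalisation constants) and assigns each record to the nearest final
#' cluster centre.
#'
#' @param object a fitted [radclust()] model.
#' @param newdata a `radclust_dataset`.
#' @param ... unused.
#' @return data frame with `record_id`, `cluster` (`NA` for records
#'   rejected by the image export policies) and `distance` to the
#'   assigned centre.
#' @export
predict.radclust <- function(object, newdata, ...) {
  tr <- .transform_dataset(object, newdata)
  a <- predict(object$final_model, tr$fused)
  out <- data.frame(record_id = newdata$records$record_id,
                    cluster = NA_integer_, distance = NA_real_,
                    stringsAsFactors = FALSE)
  out$cluster[tr$kept] <- a$cluster
  out$distance[tr$kept] <- a$distances[cbind(seq_along(a$cluster), a$cluster)]
  out
}

#' @export
print.radclust <- function(x, ...) {
  m <- x$metrics$overall
  cat("<radclust> ", x$manifest$n_kept, "/", x$manifest$n_records,
      " records in ", x$final_model$k, " clusters (",
      x$final_model$algorithm, ", ", x$final_model$metric, ", fusion: ",
      x$fusion$method, ", fused length ", x$manifest$fused_length, ")\n",
      sep = "")
  cat(sprintf("  overall  NMI_M %.3f  NMI_B %.3f  HS_M %.3f  HS_B %.3f  S %.3f\n",
              m$nmi_m, m$nmi_b, m$hs_m, m$hs_b, m$s))
  cat("  clusters kept after filtering: ", length(x$filter$kept), "\n",
      sep = "")
  invisible(x)
}

#' Summarise a fitted labelling pipeline
#'
#' @param object a fitted [radclust()] model.
#' @param ... unused.
#' @return the object, invisibly; prints subset sizes, quality metrics,
#'   the dissimilarity report and the cluster filter log.
#' @export
summary.radclust <- function(object, ...) {
  print(object)
  cat("\nSubset sizes (records):\n")
  print(table(object$labels$subset))
  ms <- object$config$metrics_subset
  if (!is.null(object$metrics[[ms]])) {
    m <- object$metrics[[ms]]
    cat(sprintf("\n%s  NMI_M %.3f  NMI_B %.3f  HS_M %.3f  HS_B %.3f  S %.3f\n",
                ms, m$nmi_m, m$nmi_b, m$hs_m, m$hs_b, m$s))
  }
  cat(sprintf("\nDissimilarity: D_I %.4f  D_D %.4f  D_score %.4f\n",
              object$dissimilarity$image$D, object$dissimilarity$diagnosis$D,
              object$dissimilarity$d_score))
  cat("\nCluster filter log:\n")
  print(object$filter$removal_log, row.names = FALSE)
  invisible(object)
}
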