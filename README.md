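# radclust

Unsupervised multimodal clustering and annotation of radiology archives.

Clinical picture archives hold millions of DICOM files — raw pixel data
plus a tag-based metadata header, linked per examination to a narrative
diagnosis — but almost no labels usable for model training. radclust
assigns every record a semantic group label with no supervision at all,
by mining the three data sources together:

1. **Tags** — body-part reconstruction from free-text tags via
   regular-expression rules, array-tag splitting, fill-rate/identifier/
   constant filtering (35% fill threshold), iterative random-forest
   imputation, one-hot + min–max encoding, then a dense autoencoder
   (512 → 200 → 125 → 32) or PCA.
2. **Images** — rescale (`RescaleSlope`/`Intercept`), linear VOI
   windowing to 8 bits, value/shape policies, aspect-preserving bilinear
   resize to 128 × 128 with centred zero padding, then a convolutional
   autoencoder (3×3 convs of 64/128/256/512 filters with 2×2 pooling,
   1024-filter final layer) with optional PCA reduction.
3. **Diagnoses** — tokenise, strip specials, stem (pluggable stemmer),
   minimum-word-frequency corpus, then bag-of-words, TF-IDF, or
   paragraph vectors (PV-DM / PV-DBOW).

The per-source embeddings `[f(x_D), f(x_T), f(x_I)]` are fused by flat
concatenation, by concatenated normalised distances to each source's
cluster centres (*clusterdists*), or by their softmax probabilities
`p_c = exp(-d_c) / Σ_j exp(-d_j)` (*clusterprobs*), and the fused vectors
are clustered with k-means or k-medoids (Euclidean or cosine), sweeping
κ ∈ {5, 10, 15, 20, 25, 30, 40, 50, 75, 100, 150} and picking the elbow
with the Kneedle algorithm. Quality is measured by normalized mutual
information and homogeneity against the modality and body-part tags
(`NMI = 2·I(y, ŷ)/(H(y)+H(ŷ))`, `HS = 1 − H(y|ŷ)/H(y)`, and their
harmonic-mean summary `S`), and by the mean within-cluster cosine
dissimilarities `D_I`, `D_D` and their harmonic mean `D_score`. Clusters
with fewer than 100 members or with normalised label entropy ≥ 0.9 are
filtered out before the labels feed downstream training, and an
oversampling plan balances the survivors.

Because hospital data cannot ship with a package, a synthetic generator
(`generate_dataset()`) produces DICOM-like records with planted
(modality, body part) structure — procedural image patterns, structured
tag missingness, body-part-correlated pseudo-diagnoses — and a minimal
DICOM writer/reader round-trips them through real files. See the
vignette `vignettes/multimodal-annotation.Rmd` for the full methods
account.

## Worked example

Generate a small synthetic archive with five planted groups, fit the
pipeline, and assign labels:

```r
library(radclust)

groups <- list(c("CR","HEAD"), c("CT","CHEST"), c("MR","ABDOMEN"),
               c("XA","FOOT"), c("RF","SPINE"))
ds <- generate_dataset(fixture_config(n_exams = 60, seed = 11,
                                      groups = groups,
                                      files_per_exam_range = c(1, 5)))
ds
#> <radclust_dataset> 175 records / 60 exams
#>   modalities: CR CT MR RF XA
#>   body parts: ABDOMEN CHEST FOOT HEAD SPINE

cfg <- radclust_config(
  tag_ae = tag_ae_config(layer_sizes = c(64L, 48L, 32L), bottleneck = 8L,
                         max_epochs = 30L),
  cae = cae_config(encoder_filters = c(4L, 8L), final_filters = 8L,
                   learning_rate = 1e-3, max_epochs = 2L,
                   batch_size = 16L, train_sample = 64L),
  image_pca_components = 32L,
  doc2vec = doc2vec_config(embedding_size = 50L, epochs = 10L,
                           min_word_frequency = 5L),
  fusion = "clusterprobs",
  final = list(algorithm = "kmeans", metric = "euclidean", kappa = 5L),
  min_size = 10L, impute_trees = 30L, seed = 3L)
fit <- radclust(ds, cfg)
fit
#> <radclust> 175/175 records in 5 clusters (kmeans, euclidean, fusion: clusterprobs, fused length 85)
#>   overall  NMI_M 0.841  NMI_B 0.841  HS_M 0.842  HS_B 0.842  S 0.841
#>   clusters kept after filtering: 5

head(predict(fit, ds), 3)
#>   record_id cluster   distance
#> 1   R000001       3 0.01916607
#> 2   R000002       3 0.02002718
#> 3   R000003       3 0.03919573
```

The printout reads: all 175 records were exported and labelled; the fused
clusterprobs vector has length 85 (the per-source cluster counts
20 + 25 + 40); clustering agrees strongly with both the planted modality
(`NMI_M`, `HS_M`) and body part (`NMI_B`, `HS_B`); all five clusters
survive the size/entropy filters. At the package's full study scale
(250 exams ≈ 2,000 records) the recovery is exact (all metrics 1.0).
`predict()` pushes new records through every persisted transform and
assigns the nearest final centre; `summary(fit)` adds subset sizes, the
dissimilarity report and the per-cluster filter log.

A thin CLI wraps the same functions: `exec/radclust fixtures --n-exams
100 --seed 1 --out dir/` writes a DICOM fixture directory, and
`exec/radclust run --in dir/ --out results/` fits the pipeline on it.

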