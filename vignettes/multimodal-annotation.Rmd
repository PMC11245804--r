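---
title: "Unsupervised multimodal annotation of radiology archives"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised multimodal annotation of radiology archives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radclust)
```

## The problem

Hospital picture archives hold enormous numbers of DICOM files — each one a
bundle of raw pixel data and a tag-based metadata header — linked per
examination to a narrative diagnosis, but essentially never to a label a
machine-learning model could train on. Annotating such archives by hand is
prohibitively expensive, so radclust groups records into clusters of
semantically similar images entirely without supervision, using the three
data sources every archive already has: the image, the header tags, and the
diagnosis text. The cluster index then serves as a semantic label for
pretraining image models.

The pipeline treats each source independently, turns each into a
fixed-length embedding, fuses the three embeddings into one vector per
record, and clusters the fused representation. Cluster quality is judged
against the two header tags that carry coarse semantics — imaging modality
and body part examined — and by how visually and textually coherent each
cluster is.

## Per-source preprocessing and embedding

**DICOM tags.** Tag tables from clinical archives are dominated by
missingness and junk columns, so five steps precede any model: (1) blank
`BodyPartExamined` values are reconstructed from other tags through an
ordered table of regular-expression rules (in practice written against
local study-description conventions; the packaged default matches the
synthetic generator); (2) array-valued tags are split into scalar columns;
(3) columns are dropped when their fill rate on the training subset is
below 0.35 (a column at exactly 0.35 is kept), when they are
identifier-like (every non-missing value distinct — applied to character
columns, supplemented by a drop-list of standard instance/patient UID tags,
which repeat within an exam and so evade the distinctness heuristic), when
they are free text by name, or when they are constant; (4) remaining gaps
are filled by iterative forest imputation: mean/mode initialisation, then
columns revisited in order of ascending missingness, each re-predicted by a
random forest on the observed rows, stopping when the change measure (sum
of squared changes on continuous columns plus category mismatch count,
each normalised) first rises; (5) categoricals are one-hot encoded and
continuous columns min–max scaled to $[0,1]$ with constants fitted on the
training subset and clipped at transform time. The encoded matrix feeds
either a dense autoencoder (default: encoder $512 \to 200 \to 125$ with
ReLU, linear bottleneck of 32, symmetric decoder, MSE, Adam at $10^{-2}$,
batch 32, at most 100 epochs, early stop after 5 epochs without
improvement) or PCA; the 32-length bottleneck is the default tag embedding.

**Images.** Raw pixel arrays are 12–16-bit; export to analysis-ready form
is: rescale by `RescaleSlope`/`RescaleIntercept`; window with
`WindowCenter`/`WindowWidth` through the linear value-of-interest mapping
$y = \mathrm{clip}\!\left(\left(\frac{x - (c - 0.5)}{w - 1} + 0.5\right)
\cdot 255,\, 0,\, 255\right)$, rounded half-up — the linear form is
implemented because the standard also admits exact-linear and sigmoid
variants and nothing in the source material selects one; records missing
any of the four parameters are excluded rather than defaulted; reject
single-valued images (value policy) and non-2-D arrays (shape policy);
resize so the longer side is 128 with bilinear interpolation and centre
with zero padding (odd remainders go bottom/right). Multi-valued window
tags use their first value pair, the DICOM convention for the default
display window; MONOCHROME1 images are inverted before use so polarity
does not split clusters. The embedding model is a convolutional
autoencoder: 3×3 convolutions of 64, 128, 256 and 512 filters, each
followed by ReLU and 2×2 max-pooling, a final 1024-filter convolution
whose flattened 8×8 map is the 65,536-length embedding, and a mirrored
decoder (nearest-neighbour upsampling between convolutions). Validation
loss is evaluated twice per epoch with early stopping after five checks.
A randomized-solver PCA reduces the flattened features to 500 by default.

**Diagnoses.** Text is lowercased, the specials `, ; : . ( ) / \ -` are
stripped (digits are kept, since protocol codes carry signal), tokens are
reduced by an injected stemmer — identity and a minimal suffix-stripper
ship with the package; a full rule-based stemmer for the archive's
language can be plugged in — and a corpus is built from the training
subset only, admitting stems whose count reaches the minimum word
frequency. Embeddings are bag-of-words, TF-IDF (raw term frequency times
smoothed inverse document frequency $\ln\frac{1+N}{1+df} + 1$, a variant
fixed here because several are in circulation), or paragraph vectors
(PV-DM and PV-DBOW) trained with negative sampling; the default is
PV-DBOW with embedding size 1000, window 7, 50 epochs and minimum word
frequency 50. Paragraph-vector training and inference are single-worker
and seeded, so both are reproducible to the bit.

## Fusion, clustering, selection

Three fusion methods are implemented over the per-source embeddings
$f(x_D), f(x_T), f(x_I)$ (diagnosis, tags, image order):

* **embeddings** — flat concatenation;
* **clusterdists** — each source is clustered on the training subset
  (defaults follow the per-source winners: diagnosis k-means/Euclidean
  $\kappa=20$, tags k-medoids/cosine $\kappa=25$, image k-means/Euclidean
  $\kappa=40$), and the record's distances to the $\kappa$ centres,
  min–max normalised to $[0,1]$ with per-source training constants, are
  concatenated;
* **clusterprobs** — the normalised distance blocks pass through a
  softmax of negated distances,
  $p_c = e^{-d_c} / \sum_j e^{-d_j}$, so nearer centres get higher
  probability. Feeding the *normalised* distances to the softmax is a
  deliberate choice: raw distances differ by orders of magnitude across
  sources and saturate the exponential; a flag restores raw-distance
  behaviour.

Clustering itself is k-means (Euclidean only, k-means++ seeding, Lloyd
refinement, best of 10 seedings) or k-medoids under Euclidean or cosine
distance. The k-medoids update is the alternating (Voronoi) heuristic —
assign to nearest medoid, re-select each medoid as the member minimising
total within-cluster distance — chosen over PAM for its linear per-sweep
cost; the heuristic is a documented knob, and repeated-run dispersion is
quantified by `stability_check()` (11 independent seeds by default).
Cluster counts are swept over
$\kappa \in \{5, 10, 15, 20, 25, 30, 40, 50, 75, 100, 150\}$ and the
working $\kappa$ is the Kneedle knee of the inertia curve: normalise to
the unit square, flip the decreasing curve, take the maximum of the
difference against the diagonal; a curve with no curvature has no knee,
in which case the largest discrete second difference is returned flagged.

Model selection across extractors follows a two-stage protocol: image and
diagnosis extractors are ranked by the summary score $S$ — the harmonic
mean of $NMI_M$, $NMI_B$, $HS_M$, $HS_B$, defined as 0 when any component
is 0 — at their elbow; tag extractors, whose modality-specific values make
label-based ranking circular, are ranked instead by the lowest $D_{score}$,
the harmonic mean of the mean within-cluster cosine dissimilarities of the
already-selected image and diagnosis embeddings under the tag clustering.

Two numerical notes on the dissimilarity $D^{(c)}$: the mean over all
$k(k-1)/2$ member pairs is computed in closed form from the resultant of
the unit-normalised member vectors
($\sum_{i \ne j} \hat v_i \cdot \hat v_j = \lVert \sum_i \hat v_i
\rVert^2 - k$), which is algebraically identical to enumerating every
pair at $O(kd)$ cost; a seeded pair-sampling mode exists for the pair
standard deviation on very large clusters. Clusters with fewer than two
members are excluded from the average (not counted as zero) and reported.

## Post-filters and oversampling

Before cluster labels feed downstream training, clusters with fewer than
100 members are removed, as are clusters whose label entropy reaches 0.9
for either modality or body part. The entropy is normalised — divided by
the log of the global label-set size — so that a uniform mixture scores
exactly 1 regardless of how many labels exist; the threshold would
otherwise change meaning with the archive's label vocabulary. Both the
cutoff and the normalisation are configurable. Surviving clusters are
re-indexed densely, and `oversample_plan()` computes per-cluster
replication counts matching every training cluster to the largest one;
the augmentation applied to replicas is a downstream hook, not implemented
here.

## The synthetic data generator

Because clinical archives cannot be redistributed, `generate_dataset()`
produces records with the statistical structure the pipeline assumes, and
it is first-class, tested code. Exams (1–15 files each, one diagnosis per
exam) are assigned to (modality, body part) groups — balanced across the
five standard modalities, or planted from an explicit group list. Images
are procedural: a body-part-dependent intensity gradient plus a
modality-dependent geometric primitive (disc, square, bands, cross,
rings) and Gaussian noise, written as 12–16-bit arrays whose
rescale/window tags invert the export transform, so records within a
group are visually similar and groups separate. Tags include
modality-dependent rescale models (a CT-style negative intercept, an
MR-style non-unit slope, array-valued window tags on CT) and maskable
auxiliary tags blanked at a configurable rate; `BodyPartExamined` is
blanked at a configurable rate with the body part always recoverable from
a study-description hint, giving the reconstruction step a known answer.
Diagnoses draw stems from disjoint per-body-part vocabularies (30 stems
each) plus a shared pool (20 stems) with Zipf weights, a typo rate, and
punctuation for the tokeniser to strip.

What the generator does **not** emulate: real anatomy, realistic tag
dictionaries (a dozen tags, not hundreds), informative missingness
mechanisms, multi-frame or colour images, and diagnosis language with
grammar. Passing tests therefore demonstrate that the machinery is
correct and that the pipeline recovers planted structure under realistic
noise — not that it attains any particular quality on hospital data.

## Problem sizes and reduced training scales

The package's desk-scale study runs on one CPU: 250 exams (about 2,000
records, matching the 1–15 files-per-exam distribution), exam-level
80/10/10 split, the full tag branch at its published defaults, PV-DBOW at
its published defaults (size 1000, window 7, 50 epochs, minimum word
frequency 50), and a reduced image branch — convolution filters 8/16/32
with a 64-filter final layer, learning rate $10^{-3}$, two epochs on a
256-image training subsample — followed by the standard 500-component
PCA. The reduced image autoencoder trades reconstruction fidelity for
speed; at this scale the higher learning rate replaces the $10^{-6}$
default, which is tuned for much longer schedules on much larger
archives. Under these conditions the full pipeline with
cluster-probability fusion and k-means at $\kappa = 5$ recovers five
planted groups exactly (NMI and homogeneity 1.0 for both labels); the
unit suites run the same components at smaller sizes. The
cluster-probability route is used for the recovery study because it is
the configuration that drives modality homogeneity hardest, which is the
behaviour the study measures.

## Known limitations

* The neural components (dense autoencoder, convolutional autoencoder,
  paragraph vectors) are implemented directly in R matrix algebra. They
  are exact in their gradients (finite-difference checked) and fully
  seeded, but they are not GPU code: archive-scale corpora need hours,
  not minutes.
* The minimal DICOM codec reads and writes Explicit VR Little Endian with
  the tag dictionary the pipeline touches; it is not a general DICOM
  implementation (no sequences, no compressed transfer syntaxes).
* `filter_tags`' identifier heuristic can in principle drop a legitimate
  high-cardinality character column in small tables; the drop-list and
  the name lists are the escape hatches.
* Imputation runs once over the assembled table; records assigned later
  through `predict()` fill residual gaps with stored training means and
  modes rather than re-running the forests.
* The elbow, like all knee detection, is ambiguous on curves with broad
  flat maxima; exact ties resolve to the smaller $\kappa$ and the
  fallback path is always flagged.
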