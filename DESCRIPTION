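Package: radclust
Title: Unsupervised Multimodal Clustering and Annotation of Radiology Archives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for annotating large radiology archives without ground-truth
    labels. Raw DICOM-like records (pixel data, header tags and narrative
    diagnoses) are preprocessed per source, embedded with autoencoders, PCA and
    document-vector models, fused into a single multimodal representation, and
    clustered with k-means or k-medoids over a sweep of cluster counts. Cluster
    quality is assessed with normalized mutual information, homogeneity scores
    and within-cluster cosine dissimilarity, and low-quality clusters are
    filtered before the labels are used to train downstream models. Includes a
    synthetic DICOM fixture generator so the whole pipeline can be exercised
    without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
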