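# Top-feature selection, sample clustering on variance-stabilized data, and
# export-ready heatmap/volcano tables. Rendering is delegated; outputs are
# matrices, newick strings and plain tables.

#' Select the n most highly expressed features
#'
#' "Most highly expressed" is the highest mean value across samples (on the
#' supplied matrix, typically variance-stabilized data); ties are broken by
#' feature id lexicographically for determinism.
#'
#' @param mat features x samples numeric matrix with rownames.
#' @param n number of features to keep.
#' @return character vector of feature ids, highest first.
#' @export
top_n_features <- function(mat, n) {
  mat <- as.matrix(mat)
  if (n > nrow(mat)) {
    warning("n exceeds the number of features; returning all features")
    n <- nrow(mat)
  }
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  ord <- order(-rowMeans(mat), ids)
  ids[ord][seq_len(n)]
}

#' Hierarchical clustering of samples
#'
#' Euclidean distances between samples over the chosen feature subset,
#' agglomerated by complete linkage.
#'
#' @param mat features x samples matrix (typically [vst()] output).
#' @param features optional feature ids to cluster on (e.g. from
#'   [top_n_features()]); all features otherwise.
#' @return an [stats::hclust] tree over the samples.
#' @export
cluster_samples <- function(mat, features = NULL) {
  mat <- as.matrix(mat)
  if (!is.null(features)) mat <- mat[features, , drop = FALSE]
  if (ncol(mat) < 2) stop("at least two samples are required for clustering")
  hclust(dist(t(mat), method = "euclidean"), method = "complete")
}

#' Newick serialization of a sample dendrogram
#'
#' @param hc an [stats::hclust] tree.
#' @return single newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Purity of a k-cut dendrogram against known labels
#'
#' Cuts the tree into `k` clusters and reports the fraction of samples whose
#' cluster's majority label matches their own.
#'
#' @param hc an [stats::hclust] tree.
#' @param labels named or ordered vector of true sample labels.
#' @param k number of clusters.
#' @return purity in \[0, 1\].
#' @export
cluster_purity <- function(hc, labels, k = 2) {
  ct <- cutree(hc, k = k)
  if (!is.null(names(labels))) labels <- labels[names(ct)]
  sum(apply(table(ct, labels), 1, max)) / length(labels)
}

#' Plot-ready volcano table
#'
#' Adds -log10 adjusted p and a significance flag; infinite fold changes are
#' clamped to +/-(max finite |log2FC| + 1) for plotting, with an
#' `is_infinite` marker (the flag itself is evaluated on the unclamped
#' values, so infinite fold changes can be significant).
#'
#' @param results a [nbinom_de()] result.
#' @param sig_padj,sig_lfc flag thresholds: adjusted p below `sig_padj` and
#'   |log2FC| above `sig_lfc` (defaults mirror the p < 1e-8, |log2FC| > 5
#'   volcano marking rule).
#' @return data.frame with `feature`, `log2FC`, `neg_log10_padj`,
#'   `baseMean`, `significant`, `is_infinite`.
#' @export
volcano_table <- function(results, sig_padj = 1e-8, sig_lfc = 5) {
  lfc <- results$log2FoldChange
  fin <- lfc[is.finite(lfc)]
  clamp <- if (length(fin)) max(abs(fin)) + 1 else 1
  data.frame(
    feature = results$id,
    log2FC = ifelse(is.infinite(lfc), sign(lfc) * clamp, lfc),
    neg_log10_padj = -log10(results$padj),
    baseMean = results$baseMean,
    significant = !is.na(results$padj) & results$padj < sig_padj &
      !is.na(lfc) & abs(lfc) > sig_lfc,
    is_infinite = is.infinite(lfc),
    stringsAsFactors = FALSE
  )
}

#' Heatmap export data
#'
#' The matrix restricted to the chosen features with rows ordered by
#' decreasing mean and columns ordered by the sample dendrogram; data for
#' rendering elsewhere.
#'
#' @param mat features x samples matrix.
#' @param features feature subset (ids).
#' @param hc sample dendrogram from [cluster_samples()].
#' @return the reordered matrix.
#' @export
heatmap_data <- function(mat, features = NULL, hc = NULL) {
  mat <- as.matrix(mat)
  if (!is.null(features)) mat <- mat[features, , drop = FALSE]
  mat <- mat[order(-rowMeans(mat)), , drop = FALSE]
  if (!is.null(hc)) mat <- mat[, hc$order, drop = FALSE]
  mat
}
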