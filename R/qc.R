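# Array-level quality control: inter-array correlation, average-linkage
# hierarchical clustering, static branch cutting, and outlier flagging.
# Arrays of the same tissue are expected to correlate above ~0.9; a sample
# that merges into the tree at a large height (equivalently, with low mean
# correlation to all others) is a technical outlier candidate.

#' Inter-array Pearson correlation matrix
#'
#' Pairwise Pearson correlation between sample columns across all CpG
#' probes, pairwise-complete over missing values. With missing data each
#' pair must share at least `min_shared` probes, else the estimate is
#' considered too noisy and an error is raised.
#'
#' @param betas probes x samples beta matrix, >= 2 samples.
#' @param min_shared minimum number of shared (jointly non-missing) probes
#'   per sample pair; default 1000. Lower it explicitly for small matrices.
#' @return symmetric samples x samples correlation matrix with unit
#'   diagonal.
#' @export
interarray_correlation <- function(betas, min_shared = 1000) {
  validate_betas(betas)
  if (ncol(betas) < 2) stop("need at least 2 samples", call. = FALSE)
  sds <- apply(betas, 2, stats::sd, na.rm = TRUE)
  if (any(!is.na(sds) & sds == 0)) {
    stop("sample(s) with zero variance across probes (correlation ",
         "undefined): ",
         paste(colnames(betas)[!is.na(sds) & sds == 0], collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(betas)) {
    ok <- !is.na(betas)
    shared <- crossprod(ok)  # pairwise complete counts
    low <- shared < min_shared
    diag(low) <- FALSE
    if (any(low)) {
      idx <- which(low, arr.ind = TRUE)[1, ]
      stop("sample pair (", colnames(betas)[idx[1]], ", ",
           colnames(betas)[idx[2]], ") shares only ",
           shared[idx[1], idx[2]], " probes (< min_shared = ", min_shared,
           ")", call. = FALSE)
    }
  }
  cc <- stats::cor(betas, use = "pairwise.complete.obs")
  diag(cc) <- 1
  cc
}

#' Hierarchical clustering of samples from a correlation matrix
#'
#' Agglomerative clustering on the dissimilarity `d = 1 - corr` using
#' `stats::hclust`. Average linkage is the field default; complete and
#' single are also available.
#'
#' @param corr symmetric correlation matrix (e.g. from
#'   [interarray_correlation()]).
#' @param linkage `"average"` (default), `"complete"`, or `"single"`.
#' @return an `hclust` tree.
#' @export
cluster_samples <- function(corr, linkage = c("average", "complete",
                                              "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) {
    stop("correlation matrix is not symmetric", call. = FALSE)
  }
  d <- 1 - corr
  stopifnot(all(d >= -1e-12), all(abs(diag(d)) < 1e-12))
  d[d < 0] <- 0
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Static branch cut of a sample dendrogram
#'
#' Cuts the tree at a fixed height; each connected component below the cut
#' is a cluster. Components smaller than `min_cluster_size` get label 0
#' (unassigned/outlier); remaining clusters are renumbered 1..k in leaf
#' order of first appearance.
#'
#' @param tree an `hclust` object (from [cluster_samples()]).
#' @param height cut height on the 1 - correlation scale, >= 0.
#' @param min_cluster_size minimum size for a real cluster (default 3).
#' @return named integer vector, sample id -> cluster label (0 = outlier).
#' @export
static_cut <- function(tree, height, min_cluster_size = 3) {
  stopifnot(inherits(tree, "hclust"), height >= 0)
  labels <- stats::cutree(tree, h = height)
  sizes <- table(labels)
  small <- as.integer(names(sizes)[sizes < min_cluster_size])
  out <- ifelse(labels %in% small, 0L, labels)
  # renumber surviving clusters compactly, in order of first appearance
  surv <- unique(out[out != 0L])
  remap <- stats::setNames(seq_along(surv), surv)
  out[out != 0L] <- remap[as.character(out[out != 0L])]
  stats::setNames(as.integer(out), names(labels))
}

#' Flag low-correlation outlier arrays
#'
#' Flags every sample whose mean correlation to all other samples falls
#' below `corr_threshold` (default 0.9, the expected floor for same-tissue
#' arrays). A simple monotone surrogate for "merges at a large tree
#' height"; the tree route is available via [static_cut()].
#'
#' @param betas probes x samples beta matrix, >= 3 samples.
#' @param corr_threshold mean-correlation threshold (default 0.9).
#' @param min_shared passed to [interarray_correlation()].
#' @return `data.frame` (sample_id, mean_corr, max_corr) of flagged
#'   samples, sorted ascending by mean_corr; zero rows when none flagged.
#' @export
flag_outliers <- function(betas, corr_threshold = 0.9, min_shared = 1000) {
  if (ncol(betas) < 3) stop("need at least 3 samples", call. = FALSE)
  cc <- interarray_correlation(betas, min_shared = min_shared)
  diag(cc) <- NA
  mean_corr <- rowMeans(cc, na.rm = TRUE)
  max_corr <- apply(cc, 1, max, na.rm = TRUE)
  flag <- mean_corr < corr_threshold
  out <- data.frame(sample_id = colnames(betas)[flag],
                    mean_corr = unname(mean_corr[flag]),
                    max_corr = unname(max_corr[flag]),
                    stringsAsFactors = FALSE)
  out[order(out$mean_corr), , drop = FALSE]
}
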