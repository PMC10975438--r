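#' Pairwise distances between fingerprints
#'
#' @param fps List of `nmr_fingerprint` tibbles (all the same length, i.e.
#'   produced with identical bucketing), or a numeric matrix with one row
#'   per fingerprint.
#' @param metric `"euclidean"` or `"manhattan"`.
#' @return Symmetric numeric matrix with zero diagonal; row/col names are
#'   fingerprint names when the list is named.
#' @export
distance_matrix <- function(fps, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  m <- fingerprint_matrix(fps)
  as.matrix(stats::dist(m, method = metric))
}

# Stack fingerprints into a samples x buckets level matrix.
fingerprint_matrix <- function(fps) {
  if (is.matrix(fps)) return(fps)
  if (inherits(fps, "nmr_fingerprint")) fps <- list(fps)
  lens <- vapply(fps, nrow, integer(1))
  if (length(unique(lens)) != 1L) {
    abort_cinnamr("fingerprints have differing lengths", "bad_fingerprint")
  }
  m <- do.call(rbind, lapply(fps, function(f) f$level))
  rownames(m) <- names(fps) %||% paste0("fp", seq_along(fps))
  m
}

#' Hierarchical clustering of fingerprints
#'
#' Agglomerative clustering of a distance matrix. `"ward"` (Ward's minimum
#' variance on the distances, the standard chemometric default for binned
#' NMR data) maps to `hclust`'s `ward.D2`; `"single"`, `"complete"` and
#' `"average"` are passed through. Agglomeration in `hclust` is
#' deterministic, with ties broken by lowest pair index.
#'
#' @param d Symmetric non-negative distance matrix (zero diagonal).
#' @param linkage Linkage method.
#' @return An object of class `nmr_hclust` wrapping the `hclust` tree with
#'   the distance input.
#' @export
hierarchical_cluster <- function(d, linkage = c("ward", "single", "complete",
                                                "average")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8 || any(d < 0)) {
    abort_cinnamr("input must be a symmetric non-negative distance matrix",
                  "bad_distance")
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::as.dist(d), method = method)
  structure(list(hclust = hc, linkage = linkage, n = nrow(d)),
            class = "nmr_hclust")
}

#' @export
print.nmr_hclust <- function(x, ...) {
  cat(sprintf("<nmr_hclust> %d leaves, %s linkage\n", x$n, x$linkage))
  invisible(x)
}

#' Cluster purity at a k-cluster cut
#'
#' Cuts the dendrogram into `k` clusters and computes
#' `sum_c max_label count(c, label) / n`: the fraction of samples whose
#' cluster's majority label matches their own.
#'
#' @param tree An `nmr_hclust`.
#' @param labels Vector of true labels, one per leaf (in input order).
#' @param k Number of clusters (1..n).
#' @return Purity in \[0, 1\].
#' @export
cluster_purity <- function(tree, labels, k) {
  if (k < 1) abort_cinnamr("k must be >= 1", "bad_k")
  if (k > tree$n) abort_cinnamr("k exceeds number of leaves", "bad_k")
  if (length(labels) != tree$n) {
    abort_cinnamr("one label per leaf required", "bad_labels")
  }
  cl <- stats::cutree(tree$hclust, k = k)
  sum(tapply(labels, cl, function(l) max(table(l)))) / tree$n
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths derive from merge heights (each child branch spans the
#' height difference to its parent merge), so the tree parses back to the
#' same topology with [ape::read.tree()].
#'
#' @param tree An `nmr_hclust`.
#' @return A single Newick string, semicolon-terminated.
#' @export
export_newick <- function(tree) {
  phy <- ape::as.phylo(tree$hclust)
  ape::write.tree(phy)
}
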