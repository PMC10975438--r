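#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ordination: one row per sample score
#'
#' @param x An `nmr_ordination`.
#' @param matrix `"scores"` (default) or `"loadings"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nmr_ordination <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") x$scores else x$loadings
}

#' One-row ordination summary
#'
#' @param x An `nmr_ordination`.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `n_components`, `scaling`, `pc1_pct`,
#'   `pc2_pct`, `pc12_pct`.
#' @export
glance.nmr_ordination <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_components = length(x$var_explained_pct),
    scaling = x$scaling,
    pc1_pct = x$var_explained_pct[1],
    pc2_pct = x$var_explained_pct[2],
    pc12_pct = x$var_explained_pct[1] + x$var_explained_pct[2]
  )
}

#' Tidy a cluster tree: one row per merge
#'
#' @param x An `nmr_hclust`.
#' @param ... Unused.
#' @return Tibble with `merge1`, `merge2` (negative = leaf index) and
#'   `height`.
#' @export
tidy.nmr_hclust <- function(x, ...) {
  tibble::tibble(merge1 = x$hclust$merge[, 1],
                 merge2 = x$hclust$merge[, 2],
                 height = x$hclust$height)
}

#' One-row cluster summary
#'
#' @param x An `nmr_hclust`.
#' @param ... Unused.
#' @return Tibble with `n_leaves`, `linkage`, `max_height`.
#' @export
glance.nmr_hclust <- function(x, ...) {
  tibble::tibble(n_leaves = x$n, linkage = x$linkage,
                 max_height = max(x$hclust$height))
}
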