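# Wide samples x metabolites mean matrix from the long table, with ND
# handled per policy.
conc_matrix <- function(table, nd_policy = c("zero", "lod_half")) {
  nd_policy <- match.arg(nd_policy)
  fill <- switch(nd_policy, zero = 0, lod_half = 0.025)
  wide <- table |>
    dplyr::mutate(value = dplyr::if_else(.data$nd, fill, .data$mean)) |>
    dplyr::select("sample_id", "metabolite", "value") |>
    tidyr::pivot_wider(names_from = "metabolite", values_from = "value")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$sample_id
  m[, intersect(list_metabolites(), colnames(m)), drop = FALSE]
}

scale_matrix <- function(m, scaling) {
  switch(scaling,
         none = m,
         center = scale(m, center = TRUE, scale = FALSE),
         autoscale = scale(m, center = TRUE, scale = TRUE),
         pareto = scale(m, center = TRUE,
                        scale = sqrt(apply(m, 2, stats::sd))))
}

#' Principal-component ordination of a concentration table
#'
#' PCA of the samples x metabolites mean matrix after ND imputation and the
#' chosen preprocessing. `"autoscale"` (mean-center, unit variance; each
#' metabolite gets equal prior weight) is the pinned default for the bundled
#' reference table. Component signs are fixed so the largest-magnitude
#' loading of each component is positive, making results deterministic.
#'
#' @param table Long concentration tibble.
#' @param scaling One of `"autoscale"`, `"none"`, `"center"`, `"pareto"`.
#' @param nd_policy ND imputation: `"zero"` (default; ND means below the
#'   detection limit, numerically near zero) or `"lod_half"` (0.025 mg/g).
#' @return An object of class `nmr_ordination` with elements `scores`
#'   (tibble: `sample_id`, `species`, `PC1`, ...), `loadings` (tibble:
#'   `metabolite`, `PC1`, ...), `var_explained_pct`, `scaling`, `nd_policy`.
#'   Metabolite columns with zero variance are dropped with a warning under
#'   variance-based scalings.
#' @examples
#' ord <- pca_ordination(load_concentration_table())
#' sum(ord$var_explained_pct[1:2])
#' @export
pca_ordination <- function(table,
                           scaling = c("autoscale", "none", "center",
                                       "pareto"),
                           nd_policy = "zero") {
  scaling <- match.arg(scaling)
  m <- conc_matrix(table, nd_policy)
  if (nrow(m) < 3L) abort_cinnamr("need at least 3 samples", "bad_table")
  if (scaling %in% c("autoscale", "pareto")) {
    sds <- apply(m, 2, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping zero-variance metabolite column(s): %s",
                      paste(colnames(m)[sds == 0], collapse = ", ")))
      m <- m[, sds > 0, drop = FALSE]
    }
  }
  z <- scale_matrix(m, scaling)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  var_pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  species <- table$species[match(rownames(m), table$sample_id)]
  scores <- tibble::as_tibble(p$x, .name_repair = "minimal")
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(m),
                                            species = species), scores)
  loadings <- dplyr::bind_cols(tibble::tibble(metabolite = rownames(p$rotation)),
                               tibble::as_tibble(p$rotation,
                                                 .name_repair = "minimal"))
  structure(list(scores = scores, loadings = loadings,
                 var_explained_pct = var_pct, scaling = scaling,
                 nd_policy = nd_policy, scaled_matrix = z),
            class = "nmr_ordination")
}

#' @export
print.nmr_ordination <- function(x, ...) {
  cat(sprintf("<nmr_ordination> %d samples, %s scaling; PC1+PC2 explain %.2f%%\n",
              nrow(x$scores), x$scaling, sum(x$var_explained_pct[1:2])))
  invisible(x)
}

#' Sweep PCA preprocessing options
#'
#' Runs [pca_ordination()] under each standard preprocessing option and
#' reports the two-component variance explained, the diagnostic used to pin
#' the default preprocessing for the reference table.
#'
#' @inheritParams pca_ordination
#' @param options Scaling options to sweep.
#' @return Tibble: `scaling`, `pc1_pct`, `pc2_pct`, `pc12_pct`.
#' @export
pca_scaling_sweep <- function(table, options = c("none", "center",
                                                 "autoscale", "pareto"),
                              nd_policy = "zero") {
  purrr::map_dfr(options, function(sc) {
    v <- suppressWarnings(pca_ordination(table, sc, nd_policy))$var_explained_pct
    tibble::tibble(scaling = sc, pc1_pct = v[1], pc2_pct = v[2],
                   pc12_pct = v[1] + v[2])
  })
}

#' Nearest-centroid species classification
#'
#' Assigns each sample to the species whose centroid is closest in the
#' autoscaled metabolite space (Euclidean distance). In leave-one-out mode
#' each sample is scored against centroids (and scaling statistics) computed
#' without it. Ties break to the lexicographically first species and are
#' recorded in the evidence.
#'
#' @param table Long concentration tibble with species labels; every
#'   species needs >= 2 samples.
#' @param loo Leave-one-out evaluation (default `FALSE`).
#' @param nd_policy ND imputation, as in [pca_ordination()].
#' @return Tibble of class `species_calls`: `sample_id`, `species` (true),
#'   `predicted`, `tie`, one `dist_*` column per species. The LOO accuracy
#'   is attached as attribute `accuracy` when `loo = TRUE`.
#' @export
nearest_centroid_classify <- function(table, loo = FALSE,
                                      nd_policy = "zero") {
  m <- conc_matrix(table, nd_policy)
  species <- table$species[match(rownames(m), table$sample_id)]
  if (any(table(species) < 2L)) {
    abort_cinnamr("every species needs at least 2 training samples",
                  "bad_training")
  }
  cls <- sort(unique(species))
  classify_one <- function(i) {
    train <- if (loo) -i else seq_len(nrow(m))
    mu <- colMeans(m[train, , drop = FALSE])
    sds <- apply(m[train, , drop = FALSE], 2, stats::sd)
    sds[sds == 0] <- 1
    z <- scale(m[train, , drop = FALSE], center = mu, scale = sds)
    zi <- (m[i, ] - mu) / sds
    cents <- do.call(rbind, lapply(cls, function(sp) {
      colMeans(z[species[train] == sp, , drop = FALSE])
    }))
    d <- sqrt(rowSums((cents - matrix(zi, nrow(cents), ncol(cents),
                                      byrow = TRUE))^2))
    names(d) <- cls
    best <- d == min(d)
    tibble::tibble(sample_id = rownames(m)[i], species = species[i],
                   predicted = cls[which(best)[1]],
                   tie = sum(best) > 1L,
                   !!!stats::setNames(as.list(d), paste0("dist_", cls)))
  }
  out <- purrr::map_dfr(seq_len(nrow(m)), classify_one)
  class(out) <- c("species_calls", class(out))
  if (loo) attr(out, "accuracy") <- mean(out$predicted == out$species)
  out
}

#' Authentication ratios of the marker metabolites
#'
#' Per sample: coumarin:cinnamaldehyde, methoxycinnamaldehyde:coumarin and
#' cinnamic-acid:coumarin ratios plus the eugenol level, the marker panel
#' used for species authentication. Ratios whose denominator is ND or zero
#' are returned as `NA` with `defined = FALSE` rather than raising.
#'
#' @param table Long concentration tibble (one or more samples).
#' @return Tibble: `sample_id`, `ratio`, `value`, `defined`.
#' @export
ratio_features <- function(table) {
  val <- function(df, met) {
    v <- df$mean[df$metabolite == met]
    nd <- df$nd[df$metabolite == met]
    if (!length(v) || isTRUE(nd)) NA_real_ else v
  }
  purrr::map_dfr(unique(table$sample_id), function(sid) {
    df <- table[table$sample_id == sid, ]
    cou <- val(df, "Coumarin")
    cin <- val(df, "Cinnamaldehyde")
    mca <- val(df, "Methoxy cinnamaldehyde")
    cac <- val(df, "Cinnamic acid")
    eug <- val(df, "Eugenol")
    ratio <- function(num, den) {
      if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
    }
    tibble::tibble(
      sample_id = sid,
      ratio = c("coumarin:cinnamaldehyde", "methoxycinnamaldehyde:coumarin",
                "cinnamic_acid:coumarin", "eugenol"),
      value = c(ratio(cou, cin), ratio(mca, cou), ratio(cac, cou), eug)
    ) |>
      dplyr::mutate(defined = !is.na(.data$value))
  })
}
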