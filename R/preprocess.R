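#' Standard solvent-exclusion windows
#'
#' The residual-signal regions removed before fingerprinting: water
#' (4.75-5.06 ppm), methanol (3.16-3.45 ppm) and TMSP (-0.05-0.05 ppm).
#'
#' @return Tibble with columns `solvent`, `lo`, `hi`.
#' @export
solvent_windows <- function() {
  tibble::tibble(
    solvent = c("water", "methanol", "tmsp"),
    lo = c(4.75, 3.16, -0.05),
    hi = c(5.06, 3.45, 0.05)
  )
}

#' Bucket a spectrum into fixed-width rectangular bins
#'
#' Tiles `[range_lo, range_hi)` with half-open cells of the given width and
#' integrates `max(intensity, 0)` (positive intensities only, no scaling)
#' over each cell by exact trapezoidal integration of the piecewise-linear
#' spectrum. The defaults (1-12 ppm, 0.01 ppm) give 1100 buckets.
#'
#' @param spectrum An `nmr_spectrum` whose grid covers the range.
#' @param range_lo,range_hi Bucketed chemical-shift range (ppm).
#' @param width Bucket width (ppm), > 0 and dividing the range.
#' @return A tibble of class `bucket_vector` with columns `lo`, `hi`,
#'   `center_ppm`, `value`, `retained` (all `TRUE` until exclusion).
#' @examples
#' s <- simulate_spectrum(c(Coumarin = 9.2), sim_params(noise_sd = 0))
#' nrow(bucket_spectrum(s)) # 1100
#' @export
bucket_spectrum <- function(spectrum, range_lo = 1.0, range_hi = 12.0,
                            width = 0.01) {
  if (width <= 0) abort_cinnamr("bucket width must be > 0", "bad_bucket")
  if (min(spectrum$ppm) > range_lo || max(spectrum$ppm) < range_hi) {
    abort_cinnamr("spectrum grid does not cover the bucketing range",
                  "bad_bucket")
  }
  nb <- as.integer(floor((range_hi - range_lo) / width + 1e-9))
  if (abs(nb * width - (range_hi - range_lo)) > 1e-6) {
    abort_cinnamr("bucket width must tile the range exactly", "bad_bucket")
  }
  edges <- range_lo + width * (0:nb)
  y <- pmax(spectrum$intensity, 0)
  cum <- cumtrap_at(spectrum$ppm, y, edges)
  out <- tibble::tibble(
    lo = edges[-(nb + 1L)],
    hi = edges[-1L],
    center_ppm = (edges[-(nb + 1L)] + edges[-1L]) / 2,
    value = pmax(diff(cum), 0),
    retained = TRUE
  )
  attr(out, "width") <- width
  class(out) <- c("bucket_vector", class(out))
  out
}

#' Mask buckets overlapping solvent-exclusion windows
#'
#' A bucket is dropped when its cell has a nonzero-length intersection with
#' any window (any overlap, not containment). With the default 1-12 ppm
#' bucketing and the standard windows, 1040 of 1100 buckets are retained
#' (31 removed for water, 29 for methanol; the TMSP window lies outside the
#' bucketed range). Idempotent.
#'
#' @param buckets A `bucket_vector`.
#' @param windows Data frame with columns `lo`, `hi`; defaults to
#'   [solvent_windows()].
#' @return The `bucket_vector` with `retained` updated.
#' @export
apply_exclusions <- function(buckets, windows = solvent_windows()) {
  if (nrow(windows) > 0) {
    for (i in seq_len(nrow(windows))) {
      ov <- interval_overlap(buckets$lo, buckets$hi,
                             windows$lo[i], windows$hi[i])
      buckets$retained <- buckets$retained & (ov <= 1e-9)
    }
  }
  buckets
}

#' Normalize a bucket vector into a 0 / 1-100 fingerprint
#'
#' Let mu be the mean of the retained bucket values. Values at or below mu
#' map to level 0; values above mu map onto the integers 1..100 by a min-max
#' affine map over the above-mean values, with round-half-up. If all
#' above-mean values are equal they map to 100; if all retained values are
#' equal every level is 0.
#'
#' This "below-mean to zero, above-mean binned 1-100" rule is one reading of
#' a per-spectrum normalization convention; it is isolated here so that
#' alternatives remain pluggable.
#'
#' @param buckets A `bucket_vector` with at least one retained bucket.
#' @return A tibble of class `nmr_fingerprint` with columns `center_ppm`
#'   and integer `level` (retained buckets only).
#' @examples
#' # retained values 0, 2, 4, 6 (mean 3) -> levels 0, 0, 1, 100
#' @export
normalize_fingerprint <- function(buckets) {
  keep <- buckets[buckets$retained, ]
  if (!nrow(keep)) abort_cinnamr("no retained buckets", "bad_bucket")
  v <- keep$value
  mu <- mean(v)
  above <- v > mu
  level <- integer(length(v))
  if (any(above)) {
    vmin <- min(v[above])
    vmax <- max(v[above])
    level[above] <- if (vmax > vmin) {
      as.integer(floor(1 + 99 * (v[above] - vmin) / (vmax - vmin) + 0.5))
    } else {
      100L
    }
  }
  out <- tibble::tibble(center_ppm = keep$center_ppm, level = level)
  class(out) <- c("nmr_fingerprint", class(out))
  out
}

#' Full spectrum-to-fingerprint preprocessing
#'
#' Convenience chain: [bucket_spectrum()] then [apply_exclusions()] then
#' [normalize_fingerprint()].
#'
#' @param spectrum An `nmr_spectrum`.
#' @param range_lo,range_hi,width Bucketing parameters.
#' @param exclusions Exclusion windows, defaults to [solvent_windows()].
#' @return An `nmr_fingerprint` tibble.
#' @export
fingerprint_spectrum <- function(spectrum, range_lo = 1.0, range_hi = 12.0,
                                 width = 0.01,
                                 exclusions = solvent_windows()) {
  spectrum |>
    bucket_spectrum(range_lo, range_hi, width) |>
    apply_exclusions(exclusions) |>
    normalize_fingerprint()
}
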