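# Shared helpers: small fast spectra, synthetic concentration tables, and
# independent oracles kept deliberately separate from package internals.

# Compact grid spanning the bucketing range; fast for property loops.
toy_params <- function(...) {
  sim_params(n_points = 8192L, ...)
}

flat_spectrum <- function(value = 0, n = 512, lo = -0.5, hi = 12.5) {
  new_spectrum(seq(lo, hi, length.out = n), rep(value, n))
}

random_spectrum <- function(n = 2048, lo = 0.5, hi = 12.5) {
  new_spectrum(seq(lo, hi, length.out = n), rnorm(n))
}

# Independent molecular-weight oracle: char-by-char formula scan (distinct
# from the package's regex parser).
oracle_formula_weight <- function(f) {
  w <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)
  f <- sub("[+-]$", "", f)
  chars <- strsplit(f, "")[[1]]
  total <- 0
  i <- 1
  while (i <= length(chars)) {
    el <- chars[i]
    i <- i + 1
    digs <- ""
    while (i <= length(chars) && grepl("[0-9]", chars[i])) {
      digs <- paste0(digs, chars[i])
      i <- i + 1
    }
    cnt <- if (nzchar(digs)) as.numeric(digs) else 1
    total <- total + w[[el]] * cnt
  }
  total
}

# Independent trapezoidal integral of clipped intensity over [lo, hi],
# interpolating the endpoints (single-pass accumulation oracle).
oracle_clipped_integral <- function(s, lo, hi) {
  y <- pmax(s$intensity, 0)
  xs <- s$ppm
  ylo <- approx(xs, y, lo)$y
  yhi <- approx(xs, y, hi)$y
  inside <- xs > lo & xs < hi
  xx <- c(lo, xs[inside], hi)
  yy <- c(ylo, y[inside], yhi)
  sum(diff(xx) * (head(yy, -1) + tail(yy, -1)) / 2)
}

# Hand-built bucket vector for normalization tests.
make_buckets <- function(values, retained = rep(TRUE, length(values))) {
  n <- length(values)
  out <- tibble::tibble(
    lo = seq_len(n) - 1, hi = seq_len(n),
    center_ppm = seq_len(n) - 0.5,
    value = values, retained = retained
  )
  class(out) <- c("bucket_vector", class(out))
  out
}

# Long concentration table from a samples x metabolites matrix.
make_conc_table <- function(m, species) {
  mets <- list_metabolites()
  stopifnot(ncol(m) == length(mets))
  ids <- rownames(m) %||% paste0("s", seq_len(nrow(m)))
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    tibble::tibble(sample_id = ids[i], species = species[i],
                   metabolite = mets, mean = m[i, ], sd = 0, nd = FALSE)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Three cleanly separated species profiles: every metabolite carries a
# species-dependent level (a rotating high/low pattern) with small
# within-species spread, so all feature columns are informative. Used to
# exercise the clustering and classification machinery.
separated_profiles <- function() {
  mets <- list_metabolites()
  species <- c("C. burmannii", "C. cassia", "C. verum")
  purrr::map_dfr(seq_along(species), function(s) {
    tibble::tibble(
      species = species[s],
      metabolite = mets,
      location = 1 + 9 * ((seq_along(mets) + s) %% 3 == 0),
      scale = 0.05
    )
  })
}
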