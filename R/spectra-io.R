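#' Construct a 1-D NMR spectrum object
#'
#' A spectrum is a tibble with columns `ppm` (strictly increasing chemical
#' shift) and `intensity`, carrying acquisition metadata as attributes.
#'
#' @param ppm Numeric vector of chemical shifts (ppm). Descending input is
#'   reversed together with `intensity`.
#' @param intensity Numeric vector, same length as `ppm`.
#' @param sample_id,replicate,field_mhz,notes Metadata stored in the
#'   `meta` attribute.
#' @return A tibble of class `nmr_spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, sample_id = NA_character_,
                         replicate = NA_integer_, field_mhz = NA_real_,
                         notes = character()) {
  if (length(ppm) != length(intensity)) {
    abort_cinnamr("ppm and intensity lengths differ", "bad_spectrum")
  }
  if (length(ppm) < 2L) {
    abort_cinnamr("a spectrum needs at least 2 points", "bad_spectrum")
  }
  d <- diff(ppm)
  if (all(d < 0)) {
    ppm <- rev(ppm)
    intensity <- rev(intensity)
  } else if (any(d <= 0)) {
    abort_cinnamr("ppm axis must be strictly monotone", "bad_spectrum")
  }
  out <- tibble::tibble(ppm = as.numeric(ppm), intensity = as.numeric(intensity))
  attr(out, "meta") <- list(sample_id = sample_id,
                            replicate = replicate,
                            field_mhz = field_mhz,
                            n_points = length(ppm),
                            notes = notes)
  class(out) <- c("nmr_spectrum", class(out))
  out
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<nmr_spectrum> %s points, %.2f..%.2f ppm, sample %s\n",
              nrow(x), min(x$ppm), max(x$ppm),
              m$sample_id %||% NA))
  NextMethod()
}

spectrum_meta <- function(s) attr(s, "meta") %||% list()

#' Write a spectrum to a two-column text file
#'
#' Format: `#`-prefixed header lines carrying metadata (`# key: value`),
#' then one `ppm intensity` pair per line at full double precision, so a
#' write/read round trip reproduces the arrays exactly.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  m <- spectrum_meta(spectrum)
  hdr <- c(
    sprintf("# sample_id: %s", m$sample_id %||% NA),
    sprintf("# replicate: %s", m$replicate %||% NA),
    sprintf("# field_mhz: %s", m$field_mhz %||% NA)
  )
  body <- sprintf("%.17g %.17g", spectrum$ppm, spectrum$intensity)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a spectrum from disk
#'
#' Accepts the package's two-column text format (whitespace- or
#' comma-delimited `ppm intensity` rows, optional `#` comment header) or a
#' minimal JCAMP-DX file with an `##XYDATA=(X++(Y..Y))` block. Files stored
#' with a descending ppm axis are reversed so the returned axis is strictly
#' increasing.
#'
#' @param path Input file path.
#' @return An `nmr_spectrum` tibble.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^##TITLE", lines))) {
    return(read_jcamp(lines, path))
  }
  meta <- list(sample_id = NA_character_, replicate = NA_integer_,
               field_mhz = NA_real_)
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    kv <- regmatches(cl, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+)$", cl))[[1]]
    if (length(kv) == 3 && kv[2] %in% names(meta)) {
      v <- kv[3]
      meta[[kv[2]]] <- switch(kv[2],
                              sample_id = v,
                              replicate = suppressWarnings(as.integer(v)),
                              field_mhz = suppressWarnings(as.numeric(v)))
    }
  }
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_idx) < 2L) {
    abort_cinnamr(sprintf("%s: fewer than 2 data rows", path), "parse")
  }
  fields <- strsplit(trimws(lines[data_idx]), "[,[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 2L)) {
    bad <- data_idx[which(nf != 2L)[1]]
    abort_cinnamr(sprintf("%s:%d: expected 2 fields, found %d",
                          path, bad, nf[which(nf != 2L)[1]]), "parse")
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(2)))
  if (anyNA(vals)) {
    bad <- data_idx[which(colSums(is.na(vals)) > 0)[1]]
    abort_cinnamr(sprintf("%s:%d: non-numeric field", path, bad), "parse")
  }
  new_spectrum(vals[1, ], vals[2, ],
               sample_id = meta$sample_id, replicate = meta$replicate,
               field_mhz = meta$field_mhz)
}

# Minimal JCAMP-DX (AFFN, X++(Y..Y)) reader: enough for exported 1D traces.
read_jcamp <- function(lines, path) {
  get_field <- function(key) {
    ln <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(ln)) return(NA_real_)
    suppressWarnings(as.numeric(sub(paste0("^##", key, "="), "", ln[1])))
  }
  firstx <- get_field("FIRSTX")
  lastx <- get_field("LASTX")
  npoints <- get_field("NPOINTS")
  xfactor <- get_field("XFACTOR"); if (is.na(xfactor)) xfactor <- 1
  yfactor <- get_field("YFACTOR"); if (is.na(yfactor)) yfactor <- 1
  start <- grep("^##XYDATA=", lines)
  if (!length(start) || is.na(firstx) || is.na(lastx) || is.na(npoints)) {
    abort_cinnamr(sprintf("%s: unsupported or incomplete JCAMP-DX", path),
                  "parse")
  }
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) - 1L else length(lines)
  y <- numeric(0)
  for (ln in lines[(start[1] + 1L):end]) {
    toks <- strsplit(trimws(ln), "[[:space:],]+")[[1]]
    if (length(toks) < 2) next
    y <- c(y, as.numeric(toks[-1]))
  }
  if (length(y) != npoints) {
    abort_cinnamr(sprintf("%s: NPOINTS=%d but %d ordinates read",
                          path, npoints, length(y)), "parse")
  }
  x <- seq(firstx * xfactor, lastx * xfactor, length.out = npoints)
  new_spectrum(x, y * yfactor)
}

.species_prefixes <- c(Cin_veru = "C. verum", Cin_cass = "C. cassia",
                       Cin_burm = "C. burmannii")

species_from_id <- function(sample_id) {
  prefix <- substr(sample_id, 1, 8)
  sp <- .species_prefixes[prefix]
  if (anyNA(sp)) {
    bad <- sample_id[is.na(sp)][1]
    abort_cinnamr(sprintf("unknown species prefix in sample id '%s'", bad),
                  "bad_species")
  }
  unname(sp)
}

#' Load a concentration table (48 x 16 reference fixture by default)
#'
#' Reads a CSV whose header is `sample_id` followed by a `<metabolite>_mean`,
#' `<metabolite>_sd` pair for each of the 16 catalogued metabolites. The
#' literal `ND` ("not detected", below the limit of detection) must appear in
#' both members of a pair or neither. ND is kept as missing-with-flag, not
#' zero; imputation is an explicit downstream choice.
#'
#' The bundled default is the package's reference quantification of 48
#' commercial cinnamon samples (mg/g, triplicate mean and SD), whose species
#' labels are parsed from the `Cin_veru` / `Cin_cass` / `Cin_burm` sample-id
#' prefixes.
#'
#' @param path CSV path; defaults to the bundled reference table.
#' @return A long tibble with columns `sample_id`, `species`, `metabolite`,
#'   `mean`, `sd`, `nd`.
#' @examples
#' tbl <- load_concentration_table()
#' dplyr::filter(tbl, sample_id == "Cin_cass_20", metabolite == "Coumarin")
#' @export
load_concentration_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "table2_concentrations.csv",
                                package = "cinnamr", mustWork = TRUE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character())
  if (names(raw)[1] != "sample_id") {
    abort_cinnamr("first column must be sample_id", "parse")
  }
  keys <- metabolite_keys()
  expected <- as.vector(rbind(paste0(keys, "_mean"), paste0(keys, "_sd")))
  if (!identical(names(raw)[-1], expected)) {
    abort_cinnamr("concentration table columns do not match the catalogue",
                  "parse")
  }
  long <- tidyr::pivot_longer(raw, -"sample_id",
                              names_to = c("key", ".value"),
                              names_pattern = "^(.*)_(mean|sd)$")
  nd_mean <- long$mean == "ND"
  nd_sd <- long$sd == "ND"
  if (any(nd_mean != nd_sd)) {
    bad <- long[nd_mean != nd_sd, ]
    abort_cinnamr(sprintf("inconsistent ND pair for %s / %s",
                          bad$sample_id[1], bad$key[1]), "parse")
  }
  out <- long |>
    dplyr::mutate(
      nd = nd_mean,
      mean = suppressWarnings(as.numeric(dplyr::if_else(.data$nd, NA_character_,
                                                        .data$mean))),
      sd = suppressWarnings(as.numeric(dplyr::if_else(.data$nd, NA_character_,
                                                      .data$sd))),
      metabolite = names(keys)[match(.data$key, keys)],
      species = species_from_id(.data$sample_id)
    ) |>
    dplyr::select("sample_id", "species", "metabolite", "mean", "sd", "nd")
  if (any(stats::na.omit(out$mean) < 0) || any(stats::na.omit(out$sd) < 0)) {
    abort_cinnamr("negative concentration in table", "parse")
  }
  out
}

# Canonical name -> column key used in the CSV schema.
metabolite_keys <- function() {
  nm <- list_metabolites()
  stats::setNames(gsub("[ -]", "_", nm), nm)
}

#' Write a concentration table in the bundled CSV schema
#'
#' Means and SDs are reported rounded to 2 decimals (the reporting precision
#' of the reference table); ND pairs are written as the literal `ND`.
#'
#' @param table Long concentration tibble as returned by
#'   [load_concentration_table()] or [quantify_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path) {
  keys <- metabolite_keys()
  wide <- table |>
    dplyr::mutate(
      key = keys[.data$metabolite],
      mean = dplyr::if_else(.data$nd, "ND", sprintf("%.2f", .data$mean)),
      sd = dplyr::if_else(.data$nd, "ND", sprintf("%.2f", .data$sd))
    ) |>
    dplyr::select("sample_id", "key", "mean", "sd") |>
    tidyr::pivot_wider(names_from = "key", values_from = c("mean", "sd"),
                       names_glue = "{key}_{.value}")
  ordered <- c("sample_id", as.vector(rbind(paste0(keys, "_mean"),
                                            paste0(keys, "_sd"))))
  readr::write_csv(wide[, ordered], path)
  invisible(path)
}
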