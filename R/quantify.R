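#' Integrate a spectral region
#'
#' Trapezoidal integral of intensity over a closed ppm window, evaluating
#' the piecewise-linear spectrum exactly at the window edges.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param window Closed ppm interval `c(lo, hi)` inside the grid.
#' @return The integrated area.
#' @export
integrate_region <- function(spectrum, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (window[1] < min(spectrum$ppm) || window[2] > max(spectrum$ppm)) {
    abort_cinnamr("integration window outside the spectrum grid",
                  "bad_window")
  }
  trap_integral(spectrum$ppm, spectrum$intensity, window[1], window[2])
}

#' Noise floor of a spectrum
#'
#' SD of intensity over a signal-free region (11.5-12 ppm by default, above
#' every catalogued signal), used for the detection rule.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param window Signal-free ppm interval.
#' @return Non-negative scalar.
#' @export
noise_floor <- function(spectrum, window = c(11.5, 12)) {
  y <- spectrum$intensity[spectrum$ppm >= window[1] &
                            spectrum$ppm <= window[2]]
  if (length(y) < 2L) return(0)
  stats::sd(y)
}

#' Quantify one metabolite by external reference calibration (qNMR)
#'
#' The analyte's molar concentration follows from ratioing its window
#' integral against the calibration signal:
#' `C = (A_met / A_ref) * (ref_n_protons / n_protons) * ref_conc_molar`,
#' then converts to mg of analyte per g of sample through the extraction
#' constants: `mg/g = C * V_extract * MW * 1000 / m_sample`.
#' The result is flagged ND (not detected) when `A_met / noise_floor < 3`.
#'
#' @param spectrum An `nmr_spectrum` covering both windows.
#' @param metabolite Catalogue name or a one-row catalogue tibble.
#' @param calibration A [reference_calibration()].
#' @param extract_volume_l Extraction volume (L), default 0.002.
#' @param sample_mass_g Sample mass (g), default 0.300.
#' @return One-row tibble: `metabolite`, `mg_per_g`, `nd`.
#' @export
quantify_metabolite <- function(spectrum, metabolite,
                                calibration = reference_calibration(),
                                extract_volume_l = 0.002,
                                sample_mass_g = 0.300) {
  def <- if (is.character(metabolite)) get_metabolite(metabolite) else metabolite
  a_ref <- integrate_region(spectrum, calibration$ref_window)
  if (a_ref <= 0) {
    abort_cinnamr("invalid calibration: reference integral is not positive",
                  "invalid_calibration")
  }
  a_met <- integrate_region(spectrum, c(def$window_lo, def$window_hi))
  nf <- noise_floor(spectrum)
  nd <- if (nf > 0) a_met / nf < 3 else a_met <= 0
  c_molar <- (a_met / a_ref) * (calibration$ref_n_protons / def$n_protons) *
    calibration$ref_conc_molar
  mg_per_g <- max(c_molar, 0) * extract_volume_l * def$mol_weight * 1000 /
    sample_mass_g
  tibble::tibble(metabolite = def$name,
                 mg_per_g = if (nd) 0 else mg_per_g,
                 nd = nd)
}

#' Quantify all catalogued metabolites in one spectrum
#'
#' @inheritParams quantify_metabolite
#' @return Tibble with one row per catalogue metabolite.
#' @export
quantify_spectrum <- function(spectrum,
                              calibration = reference_calibration(),
                              extract_volume_l = 0.002,
                              sample_mass_g = 0.300) {
  purrr::map_dfr(seq_len(nrow(cinnamon_metabolites())), function(i) {
    quantify_metabolite(spectrum, cinnamon_metabolites()[i, ], calibration,
                        extract_volume_l, sample_mass_g)
  })
}

#' Quantify a sample from replicate spectra
#'
#' Per metabolite: mean and sample SD over the replicate quantifications
#' (triplicates in the reference protocol). The metabolite is ND only when
#' every replicate is ND; replicates flagged ND enter the mean as 0.
#' Values are reported at full precision; use [write_concentration_table()]
#' for 2-decimal reporting.
#'
#' @param replicates List of >= 2 `nmr_spectrum` objects on identical grids.
#' @inheritParams quantify_metabolite
#' @return Long tibble: `sample_id`, `species` (if parseable from the id,
#'   else `NA`), `metabolite`, `mean`, `sd`, `nd`.
#' @export
quantify_sample <- function(replicates,
                            calibration = reference_calibration(),
                            extract_volume_l = 0.002,
                            sample_mass_g = 0.300) {
  if (length(replicates) < 2L) {
    abort_cinnamr("at least 2 replicate spectra required", "bad_replicates")
  }
  grids <- lapply(replicates, function(s) s$ppm)
  if (!all(vapply(grids[-1], identical, logical(1), grids[[1]]))) {
    abort_cinnamr("replicate grids are inconsistent", "bad_replicates")
  }
  sid <- spectrum_meta(replicates[[1]])$sample_id %||% NA_character_
  sp <- tryCatch(species_from_id(sid), error = function(e) NA_character_)
  per_rep <- purrr::imap_dfr(replicates, function(s, i) {
    dplyr::mutate(quantify_spectrum(s, calibration, extract_volume_l,
                                    sample_mass_g),
                  replicate = i)
  })
  per_rep |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(
      mean = mean(.data$mg_per_g),
      sd = stats::sd(.data$mg_per_g),
      nd = all(.data$nd),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean = dplyr::if_else(.data$nd, NA_real_, .data$mean),
      sd = dplyr::if_else(.data$nd, NA_real_, .data$sd),
      sample_id = sid, species = sp
    ) |>
    dplyr::select("sample_id", "species", "metabolite", "mean", "sd", "nd") |>
    dplyr::arrange(match(.data$metabolite, list_metabolites()))
}

#' Quantify a simulated cohort
#'
#' Groups a flat spectrum list by sample id and quantifies each sample from
#' its replicates, producing a table in the same schema as
#' [load_concentration_table()] so it feeds ordination and the safety
#' screen directly.
#'
#' @param spectra List of `nmr_spectrum` objects (replicates identified by
#'   their `sample_id` metadata).
#' @inheritParams quantify_metabolite
#' @return Long concentration tibble.
#' @export
quantify_cohort <- function(spectra,
                            calibration = reference_calibration(),
                            extract_volume_l = 0.002,
                            sample_mass_g = 0.300) {
  ids <- vapply(spectra, function(s) spectrum_meta(s)$sample_id %||%
                  NA_character_, character(1))
  purrr::map_dfr(unique(ids), function(sid) {
    quantify_sample(spectra[ids == sid], calibration, extract_volume_l,
                    sample_mass_g)
  })
}
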