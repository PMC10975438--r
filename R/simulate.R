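#' Reference-signal calibration for qNMR
#'
#' Describes the external calibration signal against which analyte integrals
#' are ratioed: its integration window, its known equivalent molar
#' concentration and its proton count. The default places the reference at
#' 0.0 ppm (the TMS/TMSP region) with a 12-proton singlet at 10 mM, the
#' order of magnitude of the analytes in a 300 mg / 2 mL cinnamon extract.
#'
#' @param ref_window Closed ppm interval of the calibration signal.
#' @param ref_conc_molar Known equivalent concentration (mol/L), > 0.
#' @param ref_n_protons Number of equivalent protons in the signal.
#' @return A list of class `ref_calibration`.
#' @export
reference_calibration <- function(ref_window = c(-0.1, 0.1),
                                  ref_conc_molar = 0.01,
                                  ref_n_protons = 12L) {
  stopifnot(length(ref_window) == 2L, ref_window[1] < ref_window[2],
            ref_conc_molar > 0, ref_n_protons >= 1)
  structure(list(ref_window = as.numeric(ref_window),
                 ref_conc_molar = ref_conc_molar,
                 ref_n_protons = as.integer(ref_n_protons)),
            class = "ref_calibration")
}

default_solvent_peaks <- function() {
  tibble::tibble(
    solvent = c("water", "methanol"),
    center_ppm = c(4.87, 3.31),
    lo = c(4.78, 3.27),
    hi = c(5.03, 3.35),
    area = c(50, 80)
  )
}

#' Simulation parameters for synthetic 1H-NMR spectra
#'
#' Defaults emulate the acquisition conditions of the reference dataset:
#' a 400 MHz instrument, 32768-point grid over \[-0.5, 12.5\] ppm,
#' 1 Hz Lorentzian linewidth, a TMS-region reference signal, and methanol /
#' water residual solvent peaks lying inside the standard exclusion windows.
#' Multi-scan signal averaging is modelled only through `noise_sd`; the
#' default (0.002 intensity units) gives the high signal-to-noise of a
#' 64-scan acquisition and places the detection limit near the smallest
#' tabulated concentrations (about 0.03 mg/g for a one-proton signal).
#'
#' @param field_mhz Spectrometer frequency (MHz).
#' @param n_points Grid size.
#' @param ppm_range Closed ppm interval of the grid; must span \[1, 12\].
#' @param linewidth_hz Lorentzian full width at half maximum (Hz).
#' @param noise_sd SD of additive Gaussian intensity noise.
#' @param solvent_peaks Tibble of residual solvent peaks
#'   (`center_ppm`, `lo`, `hi`, `area`).
#' @param reference_area Integrated area contributed per (mol/L x proton);
#'   the single spectrometer response constant shared by analytes and the
#'   calibration signal.
#' @param sample_mass_g Extracted sample mass (g); 0.300 g of homogenized
#'   powder by default.
#' @param extract_volume_l Extraction solvent volume (L); 2.0 mL by default
#'   (200 uL methanol-d4 + 1800 uL methanol).
#' @param calibration A [reference_calibration()].
#' @param seed Optional integer; when set, [simulate_spectrum()] is
#'   bit-reproducible.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(field_mhz = 400, n_points = 32768L,
                       ppm_range = c(-0.5, 12.5), linewidth_hz = 1.0,
                       noise_sd = 0.002,
                       solvent_peaks = default_solvent_peaks(),
                       reference_area = 100,
                       sample_mass_g = 0.300, extract_volume_l = 0.002,
                       calibration = reference_calibration(),
                       seed = NULL) {
  if (n_points < 2L) abort_cinnamr("n_points must be >= 2", "bad_params")
  if (!(ppm_range[1] <= 1 && ppm_range[2] >= 12)) {
    abort_cinnamr("ppm_range must span the bucketing range [1, 12]",
                  "bad_params")
  }
  if (linewidth_hz <= 0) abort_cinnamr("linewidth_hz must be > 0", "bad_params")
  if (noise_sd < 0) abort_cinnamr("noise_sd must be >= 0", "bad_params")
  structure(list(field_mhz = field_mhz, n_points = as.integer(n_points),
                 ppm_range = as.numeric(ppm_range),
                 linewidth_hz = linewidth_hz, noise_sd = noise_sd,
                 solvent_peaks = solvent_peaks,
                 reference_area = reference_area,
                 sample_mass_g = sample_mass_g,
                 extract_volume_l = extract_volume_l,
                 calibration = calibration, seed = seed),
            class = "sim_params")
}

# mg analyte per g sample -> mol/L in the extraction tube (100% recovery).
conc_to_molar <- function(mg_per_g, mol_weight, sample_mass_g,
                          extract_volume_l) {
  mg_per_g * sample_mass_g / 1000 / mol_weight / extract_volume_l
}

# Add a Lorentzian peak of the given total area, truncated to its window and
# renormalized so the integral over [lo, hi] equals `area` exactly. Finite
# support keeps quantification windows free of foreign tails and makes
# noise-free baselines exactly zero.
add_peak <- function(intensity, ppm, center, lo, hi, area, hwhm) {
  idx <- which(ppm >= lo & ppm <= hi)
  if (!length(idx)) return(intensity)
  frac <- (atan((hi - center) / hwhm) + atan((center - lo) / hwhm)) / pi
  dens <- (hwhm / pi) / ((ppm[idx] - center)^2 + hwhm^2)
  intensity[idx] <- intensity[idx] + area / frac * dens
  intensity
}

#' Simulate a 1-D 1H-NMR spectrum from known concentrations
#'
#' Each metabolite contributes Lorentzian peaks at its catalogued
#' quantification and secondary signals. The integrated area of a signal is
#' `reference_area x molarity x n_protons`, with molarity derived from the
#' mg/g ground truth via the extraction constants (sample mass / extract
#' volume), i.e. the qNMR proportionality that quantification later inverts.
#' A reference peak sized by the calibration and residual solvent peaks are
#' added, then Gaussian noise.
#'
#' @param truth Named numeric vector or two-column data frame
#'   (`metabolite`, `mg_per_g`) of ground-truth concentrations; names must
#'   be catalogue entries. May carry `sample_id` / `species` attributes.
#' @param params A [sim_params()].
#' @param sample_id,replicate Metadata for the returned spectrum.
#' @return An `nmr_spectrum`. If the grid resolves the linewidth with fewer
#'   than 3 points per FWHM, a warning note is recorded in the metadata.
#' @examples
#' s <- simulate_spectrum(c(Coumarin = 9.2), sim_params(seed = 1))
#' @export
simulate_spectrum <- function(truth, params = sim_params(),
                              sample_id = NULL, replicate = 1L) {
  conc <- as_truth_vector(truth)
  cat_tbl <- cinnamon_metabolites()
  unknown <- setdiff(names(conc), cat_tbl$name)
  if (length(unknown)) {
    abort_cinnamr(sprintf("metabolite not in catalogue: %s",
                          paste(unknown, collapse = ", ")),
                  "unknown_metabolite")
  }
  ppm <- seq(params$ppm_range[1], params$ppm_range[2],
             length.out = params$n_points)
  hwhm <- params$linewidth_hz / 2 / params$field_mhz
  notes <- character()
  pts_per_fwhm <- 2 * hwhm / (ppm[2] - ppm[1])
  if (pts_per_fwhm < 3) {
    notes <- sprintf("grid too coarse: %.2f points per FWHM", pts_per_fwhm)
  }
  intensity <- numeric(params$n_points)
  sec <- metabolite_secondary_signals()
  for (nm in names(conc)) {
    if (conc[[nm]] <= 0) next
    def <- cat_tbl[cat_tbl$name == nm, ]
    molar <- conc_to_molar(conc[[nm]], def$mol_weight,
                           params$sample_mass_g, params$extract_volume_l)
    sigs <- dplyr::bind_rows(
      def[, c("center_ppm", "window_lo", "window_hi", "n_protons")],
      sec[sec$name == nm, c("center_ppm", "window_lo", "window_hi",
                            "n_protons")]
    )
    for (i in seq_len(nrow(sigs))) {
      intensity <- add_peak(intensity, ppm, sigs$center_ppm[i],
                            sigs$window_lo[i], sigs$window_hi[i],
                            params$reference_area * molar * sigs$n_protons[i],
                            hwhm)
    }
  }
  cal <- params$calibration
  ref_center <- mean(cal$ref_window)
  intensity <- add_peak(intensity, ppm, ref_center,
                        cal$ref_window[1], cal$ref_window[2],
                        params$reference_area * cal$ref_conc_molar *
                          cal$ref_n_protons, hwhm)
  sp <- params$solvent_peaks
  for (i in seq_len(nrow(sp))) {
    intensity <- add_peak(intensity, ppm, sp$center_ppm[i], sp$lo[i],
                          sp$hi[i], sp$area[i], hwhm)
  }
  if (params$noise_sd > 0) {
    noise <- if (is.null(params$seed)) {
      stats::rnorm(params$n_points, 0, params$noise_sd)
    } else {
      with_local_seed(params$seed,
                      stats::rnorm(params$n_points, 0, params$noise_sd))
    }
    intensity <- intensity + noise
  }
  new_spectrum(ppm, intensity,
               sample_id = sample_id %||% attr(truth, "sample_id") %||%
                 NA_character_,
               replicate = as.integer(replicate),
               field_mhz = params$field_mhz, notes = notes)
}

as_truth_vector <- function(truth) {
  if (is.data.frame(truth)) {
    stopifnot(all(c("metabolite", "mg_per_g") %in% names(truth)))
    conc <- stats::setNames(truth$mg_per_g, truth$metabolite)
  } else {
    conc <- truth
  }
  if (is.null(names(conc)) || any(!nzchar(names(conc)))) {
    abort_cinnamr("truth concentrations must be named by metabolite",
                  "bad_truth")
  }
  if (any(conc < 0)) abort_cinnamr("concentrations must be >= 0", "bad_truth")
  conc
}

#' Species concentration profiles from a concentration table
#'
#' For each species and metabolite, the location is the mean observed mg/g
#' (ND treated as 0) and the scale is the SD across that species' samples.
#' These moments parameterize the zero-truncated normal used by
#' [generate_cohort()].
#'
#' @param table Long concentration tibble ([load_concentration_table()]).
#' @return Tibble with columns `species`, `metabolite`, `location`, `scale`.
#' @export
species_profiles <- function(table = load_concentration_table()) {
  if (!nrow(table)) abort_cinnamr("empty concentration table", "bad_table")
  table |>
    dplyr::mutate(value = dplyr::if_else(.data$nd, 0, .data$mean)) |>
    dplyr::group_by(.data$species, .data$metabolite) |>
    dplyr::summarise(
      location = mean(.data$value),
      scale = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      .groups = "drop"
    )
}

.species_codes <- c("C. verum" = "veru", "C. cassia" = "cass",
                    "C. burmannii" = "burm")

#' Generate a synthetic cohort of spectra with known ground truth
#'
#' Draws `n_per_species` concentration vectors per species from zero-
#' truncated normals parameterized by the profiles, then simulates
#' `n_replicates` spectra per sample with independent noise (mirroring
#' triplicate extraction). Fully reproducible given `seed`.
#'
#' @param profiles Tibble from [species_profiles()].
#' @param n_per_species Samples to draw per species (>= 1).
#' @param params A [sim_params()]; its `seed` field is ignored in favour of
#'   per-replicate seeds derived from `seed`.
#' @param seed Integer seed for the whole cohort.
#' @param n_replicates Spectra per sample (default 3).
#' @param lod Concentrations drawn below this limit of detection (mg/g) are
#'   flagged ND in the returned truth table (default 0.05).
#' @return List with `spectra` (list of `nmr_spectrum`, `n_replicates` per
#'   sample) and `truth` (long tibble: `sample_id`, `species`, `metabolite`,
#'   `mg_per_g`, `nd`).
#' @export
generate_cohort <- function(profiles, n_per_species, params = sim_params(),
                            seed = 1L, n_replicates = 3L, lod = 0.05) {
  if (n_per_species < 1) abort_cinnamr("n_per_species must be >= 1",
                                       "bad_params")
  species <- unique(profiles$species)
  with_local_seed(seed, {
    truth <- purrr::map_dfr(species, function(sp) {
      prof <- profiles[profiles$species == sp, ]
      purrr::map_dfr(seq_len(n_per_species), function(i) {
        draws <- rnorm_trunc0(nrow(prof), prof$location, prof$scale)
        tibble::tibble(
          sample_id = sprintf("Cin_%s_s%02d", .species_codes[[sp]], i),
          species = sp,
          metabolite = prof$metabolite,
          mg_per_g = draws,
          nd = draws < lod
        )
      })
    })
    samples <- unique(truth$sample_id)
    spectra <- purrr::map(samples, function(sid) {
      rows <- truth[truth$sample_id == sid, ]
      conc <- stats::setNames(rows$mg_per_g, rows$metabolite)
      purrr::map(seq_len(n_replicates), function(rep) {
        p <- params
        p$seed <- sample.int(.Machine$integer.max, 1)
        simulate_spectrum(conc, p, sample_id = sid, replicate = rep)
      })
    })
    list(spectra = purrr::flatten(spectra), truth = truth)
  })
}
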