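#' The cinnamon metabolite catalogue
#'
#' Sixteen bioactive metabolites quantified in commercial cinnamon
#' (*Cinnamomum burmannii*, *C. cassia*, *C. verum*), each with its molecular
#' formula, molecular weight (g/mol) and the proton signal used for
#' quantification: a chemical-shift window (ppm), the shift of the signal
#' centre, and the number of equivalent protons contributing to it.
#'
#' Quantification windows of distinct metabolites are pairwise disjoint, and
#' no secondary signal of any catalogued compound resonates inside another
#' compound's quantification window, so window integrals are attributable to
#' a single analyte. The glucose anomers are separate entries sharing one
#' formula but distinct anomeric-proton signals; choline is catalogued as the
#' free cation (104.17 g/mol) because the counterion of the analyte is
#' unknown.
#'
#' @return A tibble with one row per metabolite and columns `name`,
#'   `formula`, `mol_weight`, `center_ppm`, `window_lo`, `window_hi`,
#'   `n_protons`, `multiplicity`.
#' @examples
#' cinnamon_metabolites()
#' @export
cinnamon_metabolites <- function() {
  cache_get("catalogue", {
    path <- system.file("extdata", "metabolite_catalogue.csv",
                        package = "cinnamr", mustWork = TRUE)
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = "ccddddic")
  })
}

#' Secondary (non-quantification) signals of the catalogued metabolites
#'
#' Additional proton signals used only by the spectrum simulator to give
#' fingerprints a realistic multi-peak structure. These windows may overlap
#' one another (as crowded spectral regions do) but never overlap any
#' quantification window.
#'
#' @return A tibble with columns `name`, `center_ppm`, `window_lo`,
#'   `window_hi`, `n_protons`, `multiplicity`.
#' @export
metabolite_secondary_signals <- function() {
  cache_get("secondary", {
    path <- system.file("extdata", "metabolite_secondary_signals.csv",
                        package = "cinnamr", mustWork = TRUE)
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = "cdddic")
  })
}

.cinnamr_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .cinnamr_cache)) {
    assign(key, force(expr), envir = .cinnamr_cache)
  }
  get(key, envir = .cinnamr_cache)
}

#' List the canonical metabolite names
#'
#' @return Character vector of the 16 catalogue names, in stable catalogue
#'   order (the column order of the bundled concentration table).
#' @examples
#' list_metabolites()
#' @export
list_metabolites <- function() {
  cinnamon_metabolites()$name
}

#' Look up one metabolite definition
#'
#' @param name Metabolite name; matching is case-insensitive.
#' @return A one-row tibble with the catalogue fields for the metabolite.
#' @examples
#' get_metabolite("Coumarin")$mol_weight
#' @export
get_metabolite <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  cat_tbl <- cinnamon_metabolites()
  hit <- match(tolower(name), tolower(cat_tbl$name))
  if (is.na(hit)) {
    nearest <- cat_tbl$name[which.min(utils::adist(tolower(name),
                                                   tolower(cat_tbl$name)))]
    abort_cinnamr(
      sprintf("unknown metabolite '%s'; nearest catalogue entry is '%s'",
              name, nearest),
      "unknown_metabolite"
    )
  }
  cat_tbl[hit, ]
}

# Monoatomic weights used to audit catalogued molecular weights.
.atomic_weights <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)

#' Molecular weight from a molecular formula
#'
#' Parses simple organic formulas (C, H, N, O with optional counts; a
#' trailing charge sign is ignored) and sums standard atomic weights.
#'
#' @param formula Molecular formula string, e.g. `"C9H6O2"`.
#' @return Molecular weight in g/mol.
#' @examples
#' formula_weight("C9H6O2") # coumarin, 146.14
#' @export
formula_weight <- function(formula) {
  vapply(formula, function(f) {
    f <- gsub("[+-]$", "", f)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    parts <- regmatches(f, list(m))[[1]]
    if (sum(nchar(parts)) != nchar(f)) {
      abort_cinnamr(sprintf("cannot parse formula '%s'", f), "bad_formula")
    }
    total <- 0
    for (p in parts) {
      el <- gsub("[0-9]", "", p)
      cnt <- gsub("[A-Za-z]", "", p)
      cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
      if (!el %in% names(.atomic_weights)) {
        abort_cinnamr(sprintf("unsupported element '%s' in '%s'", el, f),
                      "bad_formula")
      }
      total <- total + .atomic_weights[[el]] * cnt
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}
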