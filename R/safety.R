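#' Maximum daily product intake at the coumarin TDI
#'
#' The tolerable daily intake (TDI) for coumarin is 0.1 mg per kg body
#' weight per day. The grams of product that reach the TDI are therefore
#' `0.1 * body_weight_kg / coumarin_mg_per_g`, an exact identity:
#' `max_daily_g * coumarin_mg_per_g = 0.1 * body_weight_kg`.
#'
#' @param coumarin_mg_per_g Coumarin content (mg/g), > 0. `NA` or 0 returns
#'   `NA` ("no limit computable, below LOD") rather than erroring.
#' @param body_weight_kg Body weight (kg), > 0; default 60.
#' @return Grams of product per day, or `NA` when coumarin is ND/zero.
#' @examples
#' tdi_max_daily_grams(9.2, 60) # 0.652 g/day
#' @export
tdi_max_daily_grams <- function(coumarin_mg_per_g, body_weight_kg = 60) {
  stopifnot(body_weight_kg > 0)
  out <- 0.1 * body_weight_kg / coumarin_mg_per_g
  out[is.na(coumarin_mg_per_g) | coumarin_mg_per_g <= 0] <- NA_real_
  out
}

#' Screen a concentration table against the coumarin TDI
#'
#' Flags a sample when a daily serving would exceed the tolerable daily
#' intake: `serving_g * coumarin_mg_per_g > 0.1 * body_weight_kg`. Defaults
#' (60 kg adult, 1 g/day serving) are reported in the output and
#' configurable. Samples are ordered by descending coumarin content, so the
#' most concerning sample is first.
#'
#' @param table Long concentration tibble.
#' @param body_weight_kg Body weight (kg); default 60.
#' @param serving_g Daily serving of product (g); default 1.
#' @return Tibble: `sample_id`, `species`, `coumarin_mg_per_g`,
#'   `body_weight_kg`, `serving_g`, `max_daily_g`, `flagged`; ND-coumarin
#'   samples have `max_daily_g = NA` and are never flagged.
#' @examples
#' screen_tdi(load_concentration_table())
#' @export
screen_tdi <- function(table, body_weight_kg = 60, serving_g = 1) {
  stopifnot(serving_g > 0)
  cou <- table |>
    dplyr::filter(.data$metabolite == "Coumarin") |>
    dplyr::transmute(
      sample_id = .data$sample_id,
      species = .data$species,
      coumarin_mg_per_g = dplyr::if_else(.data$nd, NA_real_, .data$mean),
      body_weight_kg = body_weight_kg,
      serving_g = serving_g,
      max_daily_g = tdi_max_daily_grams(.data$coumarin_mg_per_g,
                                        body_weight_kg),
      flagged = !is.na(.data$coumarin_mg_per_g) &
        serving_g * .data$coumarin_mg_per_g > 0.1 * body_weight_kg
    ) |>
    dplyr::arrange(dplyr::desc(!is.na(.data$coumarin_mg_per_g)),
                   dplyr::desc(.data$coumarin_mg_per_g))
  class(cou) <- c("tdi_report", class(cou))
  cou
}
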