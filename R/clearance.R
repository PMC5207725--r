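#' Scaling factors for in vitro - in vivo clearance extrapolation
#'
#' Collects the assay and physiology constants that turn a depletion rate
#' constant into an intrinsic clearance. Defaults follow the trout liver
#' spheroid assay: 500 hepatocytes per spheroid and 100 spheroids per well
#' (50,000 cells per well) in 75 uL, a spheroid-derived trout
#' hepatocellularity of 91 x 10^6 cells per g liver, and the human
#' literature factors of 120 x 10^6 hepatocytes and 50 mg S9/microsomal
#' protein per g liver.
#'
#' @param cells_per_spheroid,spheroids_per_well Assay seeding constants.
#' @param cells_per_well Total hepatocytes per well; defaults to the product
#'   of the previous two.
#' @param well_volume_mL Incubation volume per well (mL).
#' @param trout_spheroid_hepatocellularity_per_g Trout hepatocytes per g
#'   liver (spheroid-derived).
#' @param human_hepatocellularity_per_g Human hepatocytes per g liver.
#' @param human_s9_protein_mg_per_g Human S9/microsomal protein per g liver
#'   (mg/g).
#' @return A list of class `"scaling_factors"`.
#' @export
scaling_factors <- function(cells_per_spheroid = 500,
                            spheroids_per_well = 100,
                            cells_per_well = cells_per_spheroid * spheroids_per_well,
                            well_volume_mL = 0.075,
                            trout_spheroid_hepatocellularity_per_g = 91e6,
                            human_hepatocellularity_per_g = 120e6,
                            human_s9_protein_mg_per_g = 50) {
  f <- list(
    cells_per_spheroid = cells_per_spheroid,
    spheroids_per_well = spheroids_per_well,
    cells_per_well = cells_per_well,
    well_volume_mL = well_volume_mL,
    trout_spheroid_hepatocellularity_per_g = trout_spheroid_hepatocellularity_per_g,
    human_hepatocellularity_per_g = human_hepatocellularity_per_g,
    human_s9_protein_mg_per_g = human_s9_protein_mg_per_g
  )
  vals <- unlist(f)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all scaling factors must be finite and strictly positive", call. = FALSE)
  }
  structure(f, class = "scaling_factors")
}

#' In vitro intrinsic clearance from a depletion rate constant
#'
#' Two scaling conventions are supported and always recorded in the result:
#' `"paper_literal"` divides the rate constant by the total cell number
#' (`k / cells_per_well`), the convention used in the source assay write-up;
#' `"volume_corrected"` applies the standard substrate-depletion scaling
#' `k * V / N` which carries the incubation volume and is dimensionally a
#' clearance (mL h^-1 cell^-1). The two differ by exactly the well volume.
#'
#' @param k_h Depletion rate constant (h^-1), non-negative. Vectorised.
#' @param factors A [scaling_factors()].
#' @param mode `"paper_literal"` (default) or `"volume_corrected"`.
#' @return Intrinsic clearance per cell (mL h^-1 cell^-1 under
#'   `volume_corrected`; h^-1 cell^-1 scale under `paper_literal`).
#' @export
#' @examples
#' clint_in_vitro(0.022, scaling_factors())
clint_in_vitro <- function(k_h, factors = scaling_factors(),
                           mode = c("paper_literal", "volume_corrected")) {
  mode <- match.arg(mode)
  if (any(!is.finite(k_h)) || any(k_h < 0)) {
    stop("k_h must be finite and >= 0", call. = FALSE)
  }
  switch(mode,
    paper_literal = k_h / factors$cells_per_well,
    volume_corrected = k_h * factors$well_volume_mL / factors$cells_per_well
  )
}

#' Intrinsic hepatic clearance from per-cell clearance
#'
#' Multiplies the per-cell in vitro clearance by hepatocellularity (cells
#' per g liver) to reach the per-gram-liver scale used for cross-study
#' comparison.
#'
#' @param cl_in_vitro Per-cell clearance (mL h^-1 cell^-1). Vectorised.
#' @param factors A [scaling_factors()].
#' @param species `"trout"` (spheroid-derived 91 x 10^6 cells/g, default) or
#'   `"human"` (120 x 10^6 cells/g).
#' @return Intrinsic hepatic clearance (mL h^-1 g liver^-1).
#' @export
#' @examples
#' clint_hepatic(clint_in_vitro(0.022, scaling_factors()))
clint_hepatic <- function(cl_in_vitro, factors = scaling_factors(),
                          species = c("trout", "human")) {
  species <- match.arg(species)
  if (any(!is.finite(cl_in_vitro)) || any(cl_in_vitro < 0)) {
    stop("cl_in_vitro must be finite and >= 0", call. = FALSE)
  }
  hep <- switch(species,
    trout = factors$trout_spheroid_hepatocellularity_per_g,
    human = factors$human_hepatocellularity_per_g
  )
  cl_in_vitro * hep
}

#' Clearance table for a set of depletion fits
#'
#' @param fits Output of [fit_all()] (or any tibble with `fish_id`,
#'   `compound`, `k_h`, `nsd`).
#' @param factors A [scaling_factors()].
#' @param mode Passed to [clint_in_vitro()].
#' @return Tibble with per-fish in vitro and hepatic intrinsic clearance;
#'   NSD fits get zero clearance.
#' @export
clearance_table <- function(fits, factors = scaling_factors(),
                            mode = c("paper_literal", "volume_corrected")) {
  mode <- match.arg(mode)
  k <- ifelse(!is.na(fits$nsd) & fits$nsd, 0, fits$k_h)
  civ <- clint_in_vitro(k, factors, mode)
  tibble::tibble(
    fish_id = fits$fish_id,
    compound = fits$compound,
    mode = mode,
    cl_int_in_vitro_mL_per_h_per_cell = civ,
    cl_int_hepatic_mL_per_h_per_g = clint_hepatic(civ, factors, species = "trout")
  )
}

#' Convert literature clearance values to mL h^-1 per g liver
#'
#' Puts published human/fish clearance values on the per-gram-liver scale:
#' S9 values (uL min^-1 per mg protein) are scaled by 0.06 (uL/min to mL/h)
#' and the S9 protein yield per g liver; hepatocyte-suspension values
#' (uL min^-1 per 10^6 cells) by 0.06 and hepatocellularity in millions;
#' per-gram values pass through unchanged.
#'
#' @param value Clearance value(s), non-negative.
#' @param unit One of `"uL/min/mg_s9"`, `"uL/min/1e6_cells"`,
#'   `"mL/h/g_liver"`.
#' @param factors A [scaling_factors()].
#' @param species `"human"` (default) or `"trout"`; selects the
#'   hepatocellularity used for cell-based units.
#' @return Clearance in mL h^-1 g liver^-1.
#' @export
#' @examples
#' convert_literature_clearance(17.5, "uL/min/mg_s9") # human S9 propranolol
convert_literature_clearance <- function(value,
                                         unit,
                                         factors = scaling_factors(),
                                         species = c("human", "trout")) {
  species <- match.arg(species)
  accepted <- c("uL/min/mg_s9", "uL/min/1e6_cells", "mL/h/g_liver")
  if (!is.character(unit) || length(unit) != 1L || !(unit %in% accepted)) {
    stop("unknown clearance unit '", unit, "'; accepted units: ",
         paste(accepted, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop("clearance value must be finite and >= 0", call. = FALSE)
  }
  hep <- switch(species,
    human = factors$human_hepatocellularity_per_g,
    trout = factors$trout_spheroid_hepatocellularity_per_g
  )
  switch(unit,
    "uL/min/mg_s9" = value * (60 / 1000) * factors$human_s9_protein_mg_per_g,
    "uL/min/1e6_cells" = value * (60 / 1000) * (hep / 1e6),
    "mL/h/g_liver" = value
  )
}

#' Invert [convert_literature_clearance()]
#'
#' @param value Clearance in mL h^-1 g liver^-1.
#' @param unit,factors,species As in [convert_literature_clearance()].
#' @return The value expressed back in `unit`.
#' @export
invert_literature_clearance <- function(value, unit,
                                        factors = scaling_factors(),
                                        species = c("human", "trout")) {
  species <- match.arg(species)
  one <- convert_literature_clearance(1, unit, factors, species)
  value / one
}
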