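#' Scale per-cell heat to heat per unit tissue area
#'
#' Multiplies a per-cell total heat by an areal cell density, converting µJ to
#' mJ. Used to compare projected heat output of healthy versus osteoarthritic
#' superficial cartilage, whose cell densities differ several-fold.
#'
#' @param per_cell_heat_uJ Heat per cell (µJ/cell), non-negative.
#' @param cell_density_per_mm2 Cells per mm² of tissue, non-negative.
#' @return Heat per unit area in mJ/mm².
#' @examples
#' heat_per_area(2.7925, 4363) # healthy superficial cartilage
#' heat_per_area(2.7925, 1622) # osteoarthritic
#' @export
heat_per_area <- function(per_cell_heat_uJ, cell_density_per_mm2) {
  if (any(per_cell_heat_uJ < 0) || any(cell_density_per_mm2 < 0)) {
    stop("per-cell heat and cell density must be non-negative", call. = FALSE)
  }
  per_cell_heat_uJ * cell_density_per_mm2 / 1000
}

#' Scale areal heat to heat per unit depth
#'
#' @param area_heat_mJ_mm2 Heat per unit area (mJ/mm²), non-negative.
#' @param thickness_mm Cartilage thickness (mm), non-negative.
#' @return Heat per unit depth in the sagittal plane, mJ/mm.
#' @examples
#' heat_per_depth(4.53, 3.68)
#' @export
heat_per_depth <- function(area_heat_mJ_mm2, thickness_mm) {
  if (any(area_heat_mJ_mm2 < 0) || any(thickness_mm < 0)) {
    stop("areal heat and thickness must be non-negative", call. = FALSE)
  }
  area_heat_mJ_mm2 * thickness_mm
}

#' Describe a sealed capsule's media for the electron balance
#'
#' @param donors A data frame with one row per electron donor and columns
#'   `name`, `conc_mol_per_l` (concentration in the undiluted stock) and
#'   `electrons_per_mol` (degree of reduction: electrons released on complete
#'   oxidation -- glucose 24, pyruvate 10, glutamine 18).
#' @param dilution_factor Dimensionless fraction of stock in the final liquid
#'   (0.25 for 1 part stock to 3 parts PBS).
#' @param liquid_volume_l Liquid volume carrying the donors, litres. The
#'   default combines the hydrogel (150 µL) and the supplemental media
#'   (186 µL) of a 656 µL capsule.
#' @param headspace_volume_l Sealed air/O2 headspace, litres (default 320 µL).
#' @param o2_mol_per_l Dissolved/available O2 concentration in the headspace
#'   (mol/L); the default 6.84e-3 is elevation-corrected laboratory air.
#' @param electrons_per_o2 Electrons accepted per O2 (4).
#' @return A list of class `media_composition`.
#' @export
media_composition <- function(donors,
                              dilution_factor = 0.25,
                              liquid_volume_l = 336e-6,
                              headspace_volume_l = 320e-6,
                              o2_mol_per_l = 6.84e-3,
                              electrons_per_o2 = 4L) {
  stopifnot(
    is.data.frame(donors),
    all(c("name", "conc_mol_per_l", "electrons_per_mol") %in% names(donors)),
    dilution_factor >= 0, liquid_volume_l >= 0, headspace_volume_l >= 0,
    o2_mol_per_l >= 0
  )
  if (nrow(donors) > 0) {
    if (any(donors$conc_mol_per_l < 0)) {
      stop("donor concentrations must be non-negative", call. = FALSE)
    }
    e <- donors$electrons_per_mol
    if (any(e <= 0) || any(e != round(e))) {
      stop("electrons_per_mol must be positive integers", call. = FALSE)
    }
  }
  if (electrons_per_o2 <= 0 || electrons_per_o2 != round(electrons_per_o2)) {
    stop("electrons_per_o2 must be a positive integer", call. = FALSE)
  }
  structure(
    list(donors = tibble::as_tibble(donors),
         dilution_factor = dilution_factor,
         liquid_volume_l = liquid_volume_l,
         headspace_volume_l = headspace_volume_l,
         o2_mol_per_l = o2_mol_per_l,
         electrons_per_o2 = as.integer(electrons_per_o2)),
    class = "media_composition"
  )
}

#' Electron donor-to-acceptor ratio of a sealed capsule
#'
#' Total electrons the media's carbon sources can donate on complete
#' oxidation, divided by the electrons the sealed headspace O2 can accept.
#' A ratio above 1 means the capsule is oxygen-limited.
#'
#' @param media A [media_composition()].
#' @return A one-row tibble with `donor_electrons_mol`,
#'   `acceptor_electrons_mol` and `ratio`.
#' @examples
#' donor_acceptor_ratio(media_glucose())
#' @export
donor_acceptor_ratio <- function(media) {
  stopifnot(inherits(media, "media_composition"))
  acceptor <- media$o2_mol_per_l * media$headspace_volume_l *
    media$electrons_per_o2
  if (acceptor <= 0) {
    stop("acceptor electrons must be positive (empty or O2-free headspace)",
         call. = FALSE)
  }
  donor <- if (nrow(media$donors) == 0) 0 else {
    sum(media$donors$conc_mol_per_l * media$dilution_factor *
          media$liquid_volume_l * media$donors$electrons_per_mol)
  }
  tibble::tibble(
    donor_electrons_mol = donor,
    acceptor_electrons_mol = acceptor,
    ratio = donor / acceptor
  )
}

#' Preset capsule media compositions
#'
#' Glucose-enriched media: 4.5 g/L glucose (25.0 mM) plus 110 mg/L sodium
#' pyruvate (1.0 mM) in the stock, diluted 1:3 with PBS. Glutamine-enriched
#' media: 2 mM glutamine plus 110 mg/L sodium pyruvate, same dilution.
#' Capsule geometry defaults: 656 µL capsule holding a 150 µL hydrogel and
#' 186 µL supplemental media, leaving a 320 µL headspace.
#'
#' @param ... Overrides passed to [media_composition()].
#' @return A [media_composition()].
#' @export
media_glucose <- function(...) {
  media_composition(
    donors = tibble::tibble(
      name = c("glucose", "pyruvate"),
      conc_mol_per_l = c(4.5 / 180.156, 0.110 / 110.04),
      electrons_per_mol = c(24L, 10L)
    ),
    ...
  )
}

#' @rdname media_glucose
#' @export
media_glutamine <- function(...) {
  media_composition(
    donors = tibble::tibble(
      name = c("glutamine", "pyruvate"),
      conc_mol_per_l = c(0.002, 0.110 / 110.04),
      electrons_per_mol = c(18L, 10L)
    ),
    ...
  )
}
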