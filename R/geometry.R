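# Droplet geometry, Poisson encapsulation statistics, OD600 -> CFU
# calibration and multiplicity-of-infection arithmetic.
#
# Unit conventions used package-wide: droplet dimensions in micrometres,
# droplet volumes in picolitres (1 pL = 1000 um^3), culture volumes in
# microlitres, concentrations in CFU/mL or PFU/mL.

#' Droplet geometry
#'
#' A shallow anchored water-in-oil droplet is modelled as an oblate ellipsoid
#' whose equatorial diameter equals the circular trap diameter and whose polar
#' axis equals the chamber height. Defaults describe a 60 um diameter, 6 um
#' high trap (about 11 pL).
#'
#' @param diameter_um equatorial diameter in micrometres.
#' @param height_um polar height in micrometres; must not exceed the diameter.
#' @return an object of class `droplet_geometry`.
#' @examples
#' droplet_geometry(60, 6)
#' @export
droplet_geometry <- function(diameter_um = 60, height_um = 6) {
  stopifnot_scalar_num(diameter_um, "diameter_um", positive = TRUE)
  stopifnot_scalar_num(height_um, "height_um", positive = TRUE)
  if (height_um > diameter_um)
    stop("height_um must not exceed diameter_um (oblate droplet)",
         call. = FALSE)
  structure(list(diameter_um = diameter_um, height_um = height_um),
            class = "droplet_geometry")
}

#' Ellipsoidal droplet volume in picolitres
#'
#' Volume of the oblate ellipsoid (4/3) * pi * (d/2)^2 * (h/2), converted from
#' cubic micrometres to picolitres (1 pL = 1000 um^3). A 60 x 6 um trap gives
#' 11.31 pL, the "~11 pL" working volume of the platform.
#'
#' @param geometry a [droplet_geometry()].
#' @return volume in pL.
#' @examples
#' ellipsoid_volume_pl(droplet_geometry(60, 6)) # 11.31
#' @export
ellipsoid_volume_pl <- function(geometry) {
  if (!inherits(geometry, "droplet_geometry"))
    geometry <- do.call(droplet_geometry, as.list(geometry))
  a <- geometry$diameter_um / 2
  c_axis <- geometry$height_um / 2
  (4 / 3) * pi * a * a * c_axis / 1000
}

#' Species OD600 to CFU/mL calibration
#'
#' Linear-through-origin calibration (Beer-Lambert proportionality at low
#' optical density): `cfu_per_ml = slope * od600`. Default slopes are
#' least-squares through-origin fits to the paired OD/CFU loading conditions
#' used on the platform for each species.
#'
#' @param species_id `"PA"` (rod-shaped *P. aeruginosa*) or `"SA"`
#'   (cocci-shaped *S. aureus*).
#' @param cfu_per_ml_per_od positive slope in CFU/mL per OD600 unit. `NULL`
#'   selects the built-in per-species default.
#' @return an object of class `species_calibration`.
#' @export
species_calibration <- function(species_id = c("PA", "SA"),
                                cfu_per_ml_per_od = NULL) {
  species_id <- match.arg(species_id)
  if (is.null(cfu_per_ml_per_od))
    cfu_per_ml_per_od <- default_calibration_slope(species_id)
  stopifnot_scalar_num(cfu_per_ml_per_od, "cfu_per_ml_per_od", positive = TRUE)
  structure(list(species_id = species_id,
                 cfu_per_ml_per_od = cfu_per_ml_per_od),
            class = "species_calibration")
}

# Through-origin least squares (slope = sum(x*y)/sum(x^2)) on the platform's
# published loading conditions (OD600, CFU/mL) per species.
default_calibration_slope <- function(species_id) {
  pairs <- calibration_pairs(species_id)
  sum(pairs$od600 * pairs$cfu_per_ml) / sum(pairs$od600^2)
}

#' Paired OD600/CFU loading conditions per species
#'
#' The growth-experiment loading table: each row is one experiment's measured
#' OD600 and its plate-count CFU/mL for the given species. Used to fit the
#' default calibration slopes.
#'
#' @param species_id `"PA"` or `"SA"`.
#' @return data frame with columns `od600`, `cfu_per_ml`.
#' @export
calibration_pairs <- function(species_id = c("PA", "SA")) {
  species_id <- match.arg(species_id)
  if (species_id == "PA") {
    data.frame(od600 = c(0.11, 0.14, 0.14, 0.10, 0.31),
               cfu_per_ml = c(6e7, 9e7, 9e7, 4e7, 2.25e8))
  } else {
    data.frame(od600 = c(0.14, 0.13, 0.14, 0.16, 0.40),
               cfu_per_ml = c(1.3e7, 1.1e7, 1.2e7, 1.5e7, 5e7))
  }
}

#' Convert OD600 to CFU/mL
#'
#' @param cal a [species_calibration()].
#' @param od600 nonnegative optical density at 600 nm.
#' @return estimated CFU/mL.
#' @export
od_to_cfu <- function(cal, od600) {
  if (!inherits(cal, "species_calibration"))
    stop("'cal' must be a species_calibration", call. = FALSE)
  if (!is.numeric(od600) || any(!is.finite(od600)) || any(od600 < 0))
    stop("od600 must be nonnegative", call. = FALSE)
  cal$cfu_per_ml_per_od * od600
}

#' Expected number of cells per droplet
#'
#' The Poisson mean for stochastic encapsulation: concentration times droplet
#' volume, with 1 mL = 1e9 pL.
#'
#' @param cfu_per_ml bacterial concentration (CFU/mL).
#' @param volume_pl droplet volume (pL).
#' @return the Poisson mean lambda.
#' @examples
#' expected_cells_per_droplet(4e8, 11.31) # about 4.5 cells per droplet
#' @export
expected_cells_per_droplet <- function(cfu_per_ml, volume_pl) {
  stopifnot_scalar_num(cfu_per_ml, "cfu_per_ml", nonneg = TRUE)
  stopifnot_scalar_num(volume_pl, "volume_pl", positive = TRUE)
  cfu_per_ml * volume_pl * 1e-9
}

#' Droplet occupancy distribution
#'
#' Poisson probabilities of finding 0..`k_max` cells in a droplet loaded at
#' mean occupancy `lambda`.
#'
#' @param lambda nonnegative Poisson mean.
#' @param k_max largest occupancy to tabulate.
#' @return numeric vector of length `k_max + 1`, named `"0"`.. `"k_max"`.
#' @export
occupancy_distribution <- function(lambda, k_max = 10L) {
  stopifnot_scalar_num(lambda, "lambda", nonneg = TRUE)
  if (!is.numeric(k_max) || length(k_max) != 1L || k_max < 0 ||
      k_max != floor(k_max))
    stop("k_max must be a nonnegative integer", call. = FALSE)
  k <- 0:k_max
  stats::setNames(stats::dpois(k, lambda), as.character(k))
}

#' Inoculum mixture for an encapsulation experiment
#'
#' Describes the aqueous phase loaded into the chip: one entry per bacterial
#' species (concentration and pipetted volume; OD600 is converted through the
#' calibration when CFU/mL is not given directly) plus the phage lysate titer
#' and volume.
#'
#' @param species a list of species entries; each entry is a list with
#'   `species_id`, `volume_ul`, and either `cfu_per_ml` or `od600` (requiring
#'   a calibration in `cals`).
#' @param phage_titer_pfu_per_ml phage lysate titer (PFU/mL); 0 for none.
#' @param phage_volume_ul volume of phage lysate mixed in (uL).
#' @param cals optional named list of [species_calibration()] objects keyed by
#'   species id, used to resolve `od600` entries.
#' @return an object of class `inoculum_mix`.
#' @examples
#' # PA lysis condition: 4.00e8 CFU/mL x 200 uL vs 8e9 PFU/mL x 200 uL
#' mix <- inoculum_mix(
#'   species = list(list(species_id = "PA", cfu_per_ml = 4e8,
#'                       volume_ul = 200)),
#'   phage_titer_pfu_per_ml = 8e9, phage_volume_ul = 200)
#' compute_moi(mix) # 20
#' @export
inoculum_mix <- function(species, phage_titer_pfu_per_ml = 0,
                         phage_volume_ul = 0, cals = NULL) {
  stopifnot_scalar_num(phage_titer_pfu_per_ml, "phage_titer_pfu_per_ml",
                       nonneg = TRUE)
  stopifnot_scalar_num(phage_volume_ul, "phage_volume_ul", nonneg = TRUE)
  if (!is.list(species) || length(species) == 0)
    stop("'species' must be a nonempty list of species entries", call. = FALSE)
  species <- lapply(species, function(sp) {
    if (is.null(sp$species_id) || !sp$species_id %in% c("PA", "SA"))
      stop("each species entry needs species_id 'PA' or 'SA'", call. = FALSE)
    stopifnot_scalar_num(sp$volume_ul, "volume_ul", nonneg = TRUE)
    if (is.null(sp$cfu_per_ml)) {
      if (is.null(sp$od600))
        stop("species entry needs cfu_per_ml or od600", call. = FALSE)
      cal <- cals[[sp$species_id]]
      if (is.null(cal)) cal <- species_calibration(sp$species_id)
      sp$cfu_per_ml <- od_to_cfu(cal, sp$od600)
    }
    stopifnot_scalar_num(sp$cfu_per_ml, "cfu_per_ml", nonneg = TRUE)
    sp
  })
  if (all(vapply(species, function(sp) sp$volume_ul, 0) == 0))
    stop("at least one species volume must be > 0", call. = FALSE)
  structure(list(species = species,
                 phage_titer_pfu_per_ml = phage_titer_pfu_per_ml,
                 phage_volume_ul = phage_volume_ul),
            class = "inoculum_mix")
}

#' Multiplicity of infection of an inoculum mixture
#'
#' MOI is the ratio between total phage particles and total bacterial cells in
#' the mixed inoculum: `(titer * phage_volume) / sum(cfu * volume)`. The
#' common dilution factor cancels, so absolute particle counts are used.
#'
#' @param mix an [inoculum_mix()].
#' @return the MOI (dimensionless).
#' @export
compute_moi <- function(mix) {
  if (!inherits(mix, "inoculum_mix"))
    stop("'mix' must be an inoculum_mix", call. = FALSE)
  cells <- sum(vapply(mix$species,
                      function(sp) sp$cfu_per_ml * sp$volume_ul, 0))
  if (cells <= 0)
    stop("MOI undefined: no bacterial cells in the mixture", call. = FALSE)
  mix$phage_titer_pfu_per_ml * mix$phage_volume_ul / cells
}

#' Lysis-experiment loading conditions
#'
#' The phage-challenge loading table: host concentration, phage titer,
#' pipetted volumes and the multiplicity of infection printed for each
#' condition. MOI is defined against the susceptible host (PA); SA, when
#' present, is refractory to the phage and enters as OD600 only.
#'
#' @return data frame, one row per lysis condition.
#' @export
lysis_conditions <- function() {
  data.frame(
    experiment = c("PA lysis 1", "PA lysis 2", "PA lysis 3",
                   "Poly lysis 1", "Poly lysis 2"),
    pa_cfu_per_ml = c(4.00e8, 6.00e8, 5.40e8, 6.40e8, 3.50e8),
    phage_titer_pfu_per_ml = rep(8e9, 5),
    cell_volume_ul = rep(200, 5),
    phage_volume_ul = c(200, 10, 5, 40, 25),
    printed_moi = c(20, 0.6, 0.2, 2.5, 5),
    stringsAsFactors = FALSE
  )
}
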