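#' Lattice geometry of the simulation box
#'
#' The simulated contact interface is a square box divided into
#' \code{n_side} x \code{n_side} chambers of side \code{l0}. Molecules are
#' well mixed within a chamber; diffusion is nearest-neighbour hopping
#' between chambers. The chamber height used for propensity conversion
#' depends on where a species resides: \code{l0} for membrane species,
#' \code{z_cytosol} for cytosolic species, and the receptor--ligand contact
#' gap \code{d_contact} for trans-membrane binding.
#'
#' @param l0 chamber side length in nm (default 40).
#' @param n_side number of chambers per box edge (default 91).
#' @param d_contact receptor--ligand reaction gap in nm (default 2).
#' @param z_cytosol cytosolic chamber height in micrometres (default 1).
#' @return An object of class \code{nk_geometry}: a list with the inputs plus
#'   \code{n_chambers} and \code{box_area_um2} (\code{n_side^2 * l0^2}).
#' @examples
#' g <- geometry_params()
#' g$n_chambers    # 8281
#' g$box_area_um2  # 13.2496
#' @export
geometry_params <- function(l0 = 40, n_side = 91, d_contact = 2,
                            z_cytosol = 1.0) {
  stopifnot(l0 > 0, d_contact > 0, z_cytosol > 0)
  if (n_side < 1 || n_side != round(n_side))
    stop("n_side must be a positive integer")
  g <- list(
    l0 = l0, n_side = as.integer(n_side), d_contact = d_contact,
    z_cytosol = z_cytosol,
    n_chambers = as.integer(n_side) * as.integer(n_side),
    box_area_um2 = n_side^2 * (l0 * 1e-3)^2
  )
  class(g) <- "nk_geometry"
  g
}

#' @export
print.nk_geometry <- function(x, ...) {
  cat(sprintf(
    "<nk_geometry> %d x %d chambers of %g nm (%d chambers, %.4f um^2)\n",
    x$n_side, x$n_side, x$l0, x$n_chambers, x$box_area_um2))
  invisible(x)
}

# reaction volumes (litres) for the three bimolecular volume classes
reaction_volume_litres <- function(volume_class, geom) {
  nm3 <- switch(volume_class,
    "recep-lig" = geom$l0 * geom$l0 * geom$d_contact,
    "membrane-membrane" = geom$l0^3,
    "cytosol-recep" = geom$l0 * geom$l0 * (geom$z_cytosol * 1e3),
    stop("unknown volume class: ", volume_class)
  )
  nm3 * 1e-24
}

#' Convert a rate constant to a per-chamber event propensity
#'
#' Bimolecular rate constants (per molar or per surface-density) are divided
#' by the reaction volume of their class to give the rate at which one
#' reactant pair sharing a chamber reacts. Unimolecular rates are already
#' per-event rates and must not carry a volume class.
#'
#' @param rate rate constant value.
#' @param unit one of \code{"uM-1s-1"}, \code{"um2s-1"}
#'   (\eqn{(molecules/\mu m^2)^{-1} s^{-1}}), or \code{"s-1"}.
#' @param volume_class \code{"recep-lig"}, \code{"membrane-membrane"},
#'   \code{"cytosol-recep"}, or \code{NULL} for unimolecular rates.
#' @param geom an \code{nk_geometry}.
#' @return per reactant-combination event rate in 1/s.
#' @examples
#' # NKG2D--NKG2DL binding: 2.387e-2 uM^-1 s^-1 across a 2 nm contact gap
#' rate_to_propensity(2.387e-2, "uM-1s-1", "recep-lig", geometry_params())
#' @export
rate_to_propensity <- function(rate, unit, volume_class = NULL,
                               geom = geometry_params()) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  if (unit == "s-1") {
    if (!is.null(volume_class))
      stop("unimolecular rate (s-1) must not carry a volume class")
    return(rate)
  }
  if (is.null(volume_class))
    stop("bimolecular rate requires a volume class")
  if (unit == "uM-1s-1") {
    avogadro <- 6.02214076e23
    k_molar <- rate * 1e6                       # uM^-1 -> M^-1
    return(k_molar / (avogadro * reaction_volume_litres(volume_class, geom)))
  }
  if (unit == "um2s-1") {
    # per (molecules / um^2): divide by the chamber footprint area
    return(rate / (geom$l0 * 1e-3)^2)
  }
  stop("unknown rate unit: ", unit)
}

#' Convert a surface density to an integer copy number for the box
#'
#' Counts are \code{round(density * box_area)}. A table of canonical
#' overrides pins densities corresponding to printed copy numbers (53, 20,
#' 40, 100, 200, 400, 4213, 11686 in the default box) to those integers
#' exactly, since the printed densities are themselves rounded.
#'
#' @param density molecules per square micrometre (>= 0).
#' @param geom an \code{nk_geometry}.
#' @return integer copy number.
#' @examples
#' counts_from_density(4, geometry_params())    # 53 NKG2D
#' counts_from_density(882, geometry_params())  # 11686 KIR2DL1
#' @export
counts_from_density <- function(density, geom = geometry_params()) {
  stopifnot(is.numeric(density), length(density) == 1L)
  if (density < 0) stop("density must be non-negative")
  canonical <- c(53, 20, 40, 100, 200, 400, 4213, 11686)
  for (cc in canonical) {
    d0 <- cc / geom$box_area_um2
    if (d0 > 0 && abs(density - d0) / d0 < 0.01) return(as.integer(cc))
  }
  as.integer(round(density * geom$box_area_um2))
}
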