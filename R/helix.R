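#' Helical symmetry parameters
#'
#' The 1-start helical symmetry of a pilus filament is described by the
#' azimuthal rotation per subunit (twist, degrees) and the axial rise per
#' subunit (Angstrom). Handedness is an explicit input, never inferred:
#' for a right-handed helix the rotation advances positively with +z.
#'
#' @param twist_deg azimuthal rotation per subunit in degrees, 0 < twist < 360.
#' @param rise_ang axial rise per subunit in Angstrom, > 0.
#' @param handedness `"right"` or `"left"`.
#' @return An object of class `HelicalParams`.
#' @export
helical_params <- function(twist_deg, rise_ang, handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  if (!is.finite(twist_deg) || twist_deg <= 0 || twist_deg >= 360) {
    stop("twist_deg must be in (0, 360)")
  }
  if (!is.finite(rise_ang) || rise_ang <= 0) stop("rise_ang must be > 0")
  structure(list(twist_deg = twist_deg, rise_ang = rise_ang,
                 handedness = handedness),
            class = "HelicalParams")
}

#' Descriptors derived from helical parameters
#'
#' Computes the standard descriptors of a 1-start helix: subunits per turn
#' (360/twist), pitch (subunits-per-turn x rise, Angstrom) and subunits per
#' micron of filament (10000/rise). No rounding is applied; presentation
#' layers round. For the tight filament symmetry of twist 100.7 deg and rise
#' 10.0 A this gives 3.575 subunits/turn (3.6 at one decimal), a pitch of
#' 35.75 A (~36 A) and 1000 subunits per micron.
#'
#' @param params a [helical_params()] object.
#' @return list with `subunits_per_turn`, `pitch_ang`, `subunits_per_micron`,
#'   `start_number` (fixed at 1).
#' @export
derived_descriptors <- function(params) {
  stopifnot(inherits(params, "HelicalParams"))
  spt <- 360 / params$twist_deg
  list(subunits_per_turn = spt,
       pitch_ang = spt * params$rise_ang,
       subunits_per_micron = 1e4 / params$rise_ang,
       start_number = 1L)
}

#' Helical symmetry operator for neighbour index k
#'
#' Returns the rigid transform relating subunit 0 to subunit k: rotation by
#' `k * twist` about the z axis composed with translation `(0, 0, k * rise)`.
#' Right-handed helices rotate positively with increasing z; left-handed
#' negate the rotation angle.
#'
#' @param params a [helical_params()] object.
#' @param k integer subunit offset (may be negative).
#' @return A [rigid_transform()].
#' @export
symmetry_operator <- function(params, k) {
  stopifnot(inherits(params, "HelicalParams"), length(k) == 1, k == round(k))
  sgn <- if (params$handedness == "right") 1 else -1
  ang <- sgn * k * params$twist_deg * pi / 180
  rot <- matrix(c(cos(ang), -sin(ang), 0,
                  sin(ang),  cos(ang), 0,
                  0,         0,        1), 3, 3, byrow = TRUE)
  rigid_transform(rot, c(0, 0, k * params$rise_ang))
}

#' Build an n-subunit filament from one asymmetric unit
#'
#' Applies the helical symmetry operator repeatedly to a subunit already posed
#' in the filament frame (helix axis on z). Subunit `k = 0` is the
#' untransformed input; each copy gets chain identifiers suffixed with the
#' signed subunit index.
#'
#' @param asym a `StructureModel` posed with the filament axis on z.
#' @param params a [helical_params()] object.
#' @param k_min,k_max inclusive subunit index range, `k_min <= 0 <= k_max`.
#' @return An object of class `FilamentModel`: list with `subunits` (named
#'   list, names are the signed indices), `params`, `k_range`.
#' @export
build_filament <- function(asym, params, k_min = -9, k_max = 9) {
  stopifnot(inherits(asym, "StructureModel"), inherits(params, "HelicalParams"))
  if (!(k_min <= 0 && 0 <= k_max)) stop("need k_min <= 0 <= k_max")
  ks <- seq.int(k_min, k_max)
  subunits <- lapply(ks, function(k) {
    m <- apply_transform(asym, symmetry_operator(params, k))
    m$atoms$chain_id <- paste0(m$atoms$chain_id, "_", k)
    m$label <- sprintf("%s[k=%+d]", asym$label, k)
    m
  })
  names(subunits) <- as.character(ks)
  structure(list(subunits = subunits, params = params,
                 k_range = c(k_min, k_max), axis = "z"),
            class = "FilamentModel")
}

#' @export
print.FilamentModel <- function(x, ...) {
  cat(sprintf("FilamentModel: %d subunits (k in [%d, %d]), twist %.2f deg, rise %.2f A\n",
              length(x$subunits), x$k_range[1], x$k_range[2],
              x$params$twist_deg, x$params$rise_ang))
  invisible(x)
}

#' Fetch one subunit of a filament
#' @param filament a `FilamentModel`.
#' @param k signed subunit index.
#' @return The subunit `StructureModel`.
#' @export
get_subunit <- function(filament, k) {
  m <- filament$subunits[[as.character(k)]]
  if (is.null(m)) {
    stop(sprintf("subunit %d not in filament (k range [%d, %d])",
                 k, filament$k_range[1], filament$k_range[2]))
  }
  m
}

#' Flatten a filament into one StructureModel
#' @param filament a `FilamentModel`.
#' @return A single `StructureModel` with all subunit copies.
#' @export
filament_to_model <- function(filament) {
  atoms <- do.call(rbind, lapply(filament$subunits, function(m) m$atoms))
  rownames(atoms) <- NULL
  structure_model(atoms, label = "filament",
                  provenance = list(source = "build_filament"))
}

#' Radial profile of a filament
#'
#' Reports the maximal atomic radial extent (including van der Waals radii),
#' the corresponding diameter, and the fourth radial moment per subunit
#' `sum((x^2+y^2)^2)/n_subunits` - a comparative proxy for bending stiffness,
#' since resistance to bending scales with the fourth power of the radial
#' mass distribution. Not an absolute rigidity.
#'
#' @param filament a `FilamentModel` whose subunits carry assigned radii.
#' @return list with `max_radius`, `diameter` (Angstrom) and `r4_moment`
#'   (Angstrom^4 per subunit).
#' @export
radial_profile <- function(filament) {
  stopifnot(inherits(filament, "FilamentModel"))
  atoms <- do.call(rbind, lapply(filament$subunits, function(m) m$atoms))
  if (is.null(atoms) || nrow(atoms) == 0) stop("empty filament model")
  if (anyNA(atoms$vdw_radius)) stop("assign_radii() must be run before radial_profile()")
  r2 <- atoms$x^2 + atoms$y^2
  max_radius <- max(sqrt(r2) + atoms$vdw_radius)
  list(max_radius = max_radius,
       diameter = 2 * max_radius,
       r4_moment = sum(r2^2) / length(filament$subunits))
}
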