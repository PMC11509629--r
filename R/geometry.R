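#' Describe an AFM indenter tip
#'
#' Constructs an indenter geometry object used by all contact models. Real
#' pyramidal AFM probes are best approximated as a blunted cone or a blunted
#' regular pyramid: a spherical cap of apex radius `R` that merges
#' tangentially with a conical (or pyramidal) body of half-angle `theta`.
#' The cap meets the body at the transition radius `b = R cos(theta)`, at
#' which the indentation depth equals the transition depth `h_T = b^2 / R`.
#'
#' @param family One of `"sphero_conical"`, `"blunted_pyramid"`,
#'   `"perfect_cone"`, `"sphere"`.
#' @param R Tip apex radius in meters. Required for every family with a
#'   spherical cap (all but `"perfect_cone"`).
#' @param theta_deg Half-angle of the conical/pyramidal body in degrees,
#'   measured from the indentation axis (a larger angle means a blunter
#'   probe). Required for all families except `"sphere"`. Exactly one of
#'   `theta_deg` or `theta` must be given.
#' @param theta Half-angle in radians (alternative to `theta_deg`).
#' @param k Number of pyramid sides (integer, >= 3); only for
#'   `"blunted_pyramid"`.
#'
#' @return An object of class `indenter_geometry` with fields `family`, `R`,
#'   `theta` (radians) and `k`.
#'
#' @examples
#' geom <- indenter_geometry("sphero_conical", R = 20e-9, theta_deg = 25)
#' transition_radius(geom)  # ~18.1 nm
#' @export
indenter_geometry <- function(family = c("sphero_conical", "blunted_pyramid",
                                         "perfect_cone", "sphere"),
                              R = NULL, theta_deg = NULL, theta = NULL,
                              k = NULL) {
  family <- match.arg(family)

  needs_R <- family != "perfect_cone"
  needs_theta <- family != "sphere"

  if (needs_R) {
    if (is.null(R) || !is.numeric(R) || length(R) != 1L || !is.finite(R) ||
        R <= 0)
      stop("`R` must be a single positive tip radius in meters for family '",
           family, "'", call. = FALSE)
  } else {
    R <- NA_real_
  }

  if (needs_theta) {
    if (!is.null(theta_deg) && !is.null(theta))
      stop("give either `theta_deg` or `theta`, not both", call. = FALSE)
    if (!is.null(theta_deg)) theta <- theta_deg * pi / 180
    if (is.null(theta) || !is.numeric(theta) || length(theta) != 1L ||
        !is.finite(theta) || theta <= 0 || theta >= pi / 2)
      stop("the half-angle must lie strictly between 0 and 90 degrees",
           call. = FALSE)
  } else {
    theta <- NA_real_
  }

  if (family == "blunted_pyramid") {
    if (is.null(k) || length(k) != 1L || !is.finite(k) || k != round(k) ||
        k < 3)
      stop("`k` must be an integer number of pyramid sides >= 3",
           call. = FALSE)
    k <- as.integer(k)
  } else {
    if (!is.null(k))
      warning("`k` is ignored for family '", family, "'", call. = FALSE)
    k <- NA_integer_
  }

  structure(list(family = family, R = R, theta = theta, k = k),
            class = "indenter_geometry")
}

#' @export
print.indenter_geometry <- function(x, ...) {
  cat("<indenter_geometry>\n")
  cat("  family:    ", x$family, "\n")
  if (is.finite(x$R)) cat("  R:         ", format(x$R * 1e9), "nm\n")
  if (is.finite(x$theta))
    cat("  theta:     ", format(x$theta * 180 / pi), "deg\n")
  if (!is.na(x$k)) cat("  sides k:   ", x$k, "\n")
  if (has_cap_transition(x)) {
    cat("  b:         ", format(transition_radius(x) * 1e9), "nm\n")
    cat("  h_T:       ", format(transition_depth(x) * 1e9), "nm\n")
  }
  invisible(x)
}

has_cap_transition <- function(geom)
  geom$family %in% c("sphero_conical", "blunted_pyramid")

stopifnot_blunted <- function(geom) {
  if (!inherits(geom, "indenter_geometry"))
    stop("`geom` must be an `indenter_geometry` object", call. = FALSE)
  if (!has_cap_transition(geom))
    stop("geometry family '", geom$family,
         "' has no spherical-cap/body transition; ",
         "use a sphero_conical or blunted_pyramid geometry", call. = FALSE)
  invisible(geom)
}

#' Transition radius of a blunted tip
#'
#' Contact radius at which the spherical cap of a blunted cone or pyramid
#' merges tangentially with the conical/pyramidal body: `b = R cos(theta)`.
#'
#' @param geom An [indenter_geometry()] of family `sphero_conical` or
#'   `blunted_pyramid`.
#' @return The transition radius `b` in meters, strictly between 0 and `R`.
#' @export
transition_radius <- function(geom) {
  stopifnot_blunted(geom)
  geom$R * cos(geom$theta)
}

#' Transition depth of a blunted tip
#'
#' Indentation depth at which the contact radius reaches the transition
#' radius `b`. Under Hertzian cap contact (`a = sqrt(R h)`) this is
#' `h_T = b^2 / R = R cos^2(theta)`; the blunted-body depth relation
#' reduces to the same value at `a = b`, so the piecewise model is
#' continuous there.
#'
#' @inheritParams transition_radius
#' @return The transition depth `h_T` in meters.
#' @export
transition_depth <- function(geom) {
  b <- transition_radius(geom)
  b^2 / geom$R
}

## (k/pi) sin(pi/k): ratio of a regular k-gon cross-section to the
## circumscribed circle; multiplies the conical terms for blunted pyramids
## and tends to 1 as k -> infinity.
pyramid_factor <- function(geom) {
  if (geom$family == "blunted_pyramid") (geom$k / pi) * sin(pi / geom$k)
  else 1
}

#' Define the elastic sample material
#'
#' @param E Young's modulus in pascals (> 0).
#' @param nu Poisson's ratio, in (-1, 0.5]; use 0.5 for incompressible soft
#'   matter such as hydrated cells and gels.
#' @return An object of class `afm_material` with fields `E`, `nu` and the
#'   reduced modulus `E_star = E / (1 - nu^2)`.
#' @examples
#' material(20e3, 0.5)  # a 20 kPa incompressible sample
#' @export
material <- function(E, nu = 0.5) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0)
    stop("`E` must be a single positive Young's modulus in pascals",
         call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu <= -1 ||
      nu > 0.5)
    stop("`nu` must lie in (-1, 0.5]", call. = FALSE)
  structure(list(E = E, nu = nu, E_star = E / (1 - nu^2)),
            class = "afm_material")
}

#' @export
print.afm_material <- function(x, ...) {
  cat("<afm_material>  E =", format(x$E), "Pa,  nu =", x$nu,
      ",  E* =", format(x$E_star), "Pa\n")
  invisible(x)
}

## Material with unit reduced modulus; forward models scale linearly in E*,
## so curves generated with this material are F/E* curves.
unit_material <- function() {
  structure(list(E = 1, nu = 0, E_star = 1), class = "afm_material")
}

as_material <- function(mat) {
  if (is.null(mat)) return(unit_material())
  if (!inherits(mat, "afm_material"))
    stop("`mat` must be an `afm_material` object (see material())",
         call. = FALSE)
  mat
}

#' Coefficients of the depth-corrected spherical contact model
#'
#' Dimensionless constants of the three-term depth correction to the
#' Hertzian sphere, valid for indentation depths up to the tip radius
#' (`h < R`).
#'
#' @param c1,c2,c3 Correction coefficients. The defaults are the published
#'   values for the `N = 3` expansion.
#' @return An object of class `sphere_correction_coefficients`.
#' @export
sphere_correction_coefficients <- function(c1 = 1.014, c2 = -0.09059,
                                           c3 = -0.09431) {
  structure(list(c1 = c1, c2 = c2, c3 = c3),
            class = "sphere_correction_coefficients")
}
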