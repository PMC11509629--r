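## Exact forward contact mechanics for blunted (sphero-conical and
## blunted-pyramidal) indenters on an elastic half-space, plus the classic
## Hertz / Sneddon limits, the general axisymmetric power-law indenter, a
## depth-corrected spherical model and a large-depth approximation.
##
## Conventions: strict SI internally (meters, newtons, pascals); the
## half-angle theta is measured from the indentation axis, so tan(theta)
## multiplies h^2 in the Sneddon cone law and a larger theta means a
## blunter probe. The blunted models are valid for contact radii a >= b;
## below the transition the spherical cap is Hertzian with a = sqrt(R h).

#' Indentation depth at a given contact radius (blunted tip)
#'
#' Depth-vs-contact-radius relation for the blunted cone and blunted
#' pyramid, valid in the blunted regime `a >= b`:
#' \deqn{h = s \frac{a}{\tan\theta}\left(\frac{\pi}{2} -
#'   \arcsin\frac{b}{a}\right) + \frac{a}{R}\left(a -
#'   \sqrt{a^2-b^2}\right)}
#' where `s = (k/pi) sin(pi/k)` for a k-sided pyramid and `s = 1` for the
#' cone. At `a = b` both correction terms vanish analytically and
#' `h = b^2/R = h_T`, matching the Hertzian cap relation `a = sqrt(R h)`.
#'
#' @param a Contact radius in meters (scalar or vector), `a >= b`.
#' @param geom An [indenter_geometry()] with a cap transition.
#' @return Indentation depth(s) in meters; strictly increasing in `a`.
#' @export
depth_from_contact_radius <- function(a, geom) {
  stopifnot_blunted(geom)
  b <- transition_radius(geom)
  if (any(a < b * (1 - 1e-12)))
    stop("depth_from_contact_radius() requires a >= b (blunted regime); ",
         "below the transition use the Hertzian cap relation a = sqrt(R h)",
         call. = FALSE)
  depth_from_excess(pmax(a - b, 0), geom)
}

## depth as a function of the contact-radius excess d = a - b, written in
## cancellation-free form: pi/2 - asin(b/a) = atan2(sqrt(a^2-b^2), b) with
## a^2 - b^2 = d (a + b), and a - sqrt(a^2-b^2) = b^2 / (a + sqrt(...)).
## This stays accurate to machine precision arbitrarily close to the
## transition, where the naive expressions lose all significance.
depth_from_excess <- function(d, geom) {
  b <- transition_radius(geom)
  a <- b + d
  root <- sqrt(d * (a + b))
  s <- pyramid_factor(geom)
  s * (a / tan(geom$theta)) * atan2(root, b) +
    (a / geom$R) * b^2 / (a + root)
}

#' Contact radius (and regime) at a given indentation depth
#'
#' Inverts the piecewise depth relation. For `h <= h_T` the spherical cap
#' is in contact and `a = sqrt(R h)` (Hertzian). For `h > h_T` the blunted
#' relation is inverted numerically with a bracketing root finder: the
#' depth is strictly increasing in `a`, so the root in `[b, a_hi]` is
#' unique; the upper bracket is grown geometrically until the residual
#' changes sign.
#'
#' @param h Indentation depth(s) in meters, `h >= 0`.
#' @inheritParams depth_from_contact_radius
#' @return A data frame with columns `h`, `a` and `regime`
#'   (`"spherical_cap"` for `a < b`, `"blunted"` otherwise).
#' @export
contact_radius_from_depth <- function(h, geom) {
  stopifnot_blunted(geom)
  if (any(h < 0)) stop("`h` must be non-negative", call. = FALSE)
  b <- transition_radius(geom)
  h_T <- transition_depth(geom)

  one <- function(hi) {
    if (hi <= h_T) return(sqrt(geom$R * hi))
    ## root in u = sqrt(a - b): the depth approaches h_T with a
    ## square-root law in (a - b), so h(b + u^2) is smooth in u and the
    ## bracketed inversion stays well-conditioned arbitrarily close to
    ## the transition
    f <- function(u) depth_from_excess(u^2, geom) - hi
    u_hi <- sqrt(b)
    n_grow <- 0L
    while (f(u_hi) < 0) {
      u_hi <- 2 * u_hi
      n_grow <- n_grow + 1L
      if (n_grow > 200L)
        stop("contact_radius_from_depth() failed to bracket the root; ",
             "pathological geometry?", call. = FALSE)
    }
    u <- stats::uniroot(f, lower = 0, upper = u_hi,
                        tol = u_hi * 1e-13, maxiter = 2000L)$root
    r <- b + u^2
    if (abs(depth_from_excess(u^2, geom) - hi) / hi > 1e-10)
      stop("contact_radius_from_depth() did not converge to the requested ",
           "tolerance", call. = FALSE)
    r
  }

  a <- vapply(h, one, numeric(1))
  data.frame(h = h, a = a,
             regime = ifelse(a < b, "spherical_cap", "blunted"),
             stringsAsFactors = FALSE)
}

## shared body of the blunted cone/pyramid force; s is the pyramid
## factor. Uses the same cancellation-free forms as depth_from_excess().
blunted_force <- function(a, geom, mat, s) {
  b <- transition_radius(geom)
  d <- pmax(a - b, 0)
  h <- depth_from_excess(d, geom)
  tt <- tan(geom$theta)
  R <- geom$R
  sq <- d * (a + b)            # a^2 - b^2, factored
  root <- sqrt(sq)
  2 * mat$E_star * (
    a * h -
      s * (a^2 / (2 * tt)) * atan2(root, b) -
      a^3 / (3 * R) +
      root * (s * b / (2 * tt) + sq / (3 * R))
  )
}

#' Force on a sphero-conical (blunted cone) indenter
#'
#' Exact force at contact radius `a >= b`:
#' \deqn{F = 2E^*\left[a h - \frac{a^2}{2\tan\theta}\left(\frac{\pi}{2} -
#'  \arcsin\frac{b}{a}\right) - \frac{a^3}{3R} + \sqrt{a^2-b^2}
#'  \left(\frac{b}{2\tan\theta} + \frac{a^2-b^2}{3R}\right)\right]}
#' with `h` given by [depth_from_contact_radius()]. At `a = b` this
#' reduces exactly to the Hertzian value at the transition depth, and for
#' `a >> b` it approaches the Sneddon cone law.
#'
#' @inheritParams depth_from_contact_radius
#' @param mat An [material()] object (or `NULL` for a unit reduced modulus,
#'   giving `F/E*` curves).
#' @return Force(s) in newtons.
#' @export
force_blunted_cone <- function(a, geom, mat = NULL) {
  stopifnot_blunted(geom)
  if (geom$family != "sphero_conical")
    stop("force_blunted_cone() expects a sphero_conical geometry",
         call. = FALSE)
  blunted_force(a, geom, as_material(mat), s = 1)
}

#' Force on a blunted regular pyramid indenter
#'
#' Identical in structure to [force_blunted_cone()], with every conical
#' `1/tan(theta)` term multiplied by `(k/pi) sin(pi/k)` for a k-sided
#' regular pyramid. Converges to the blunted cone as `k` grows.
#'
#' @inheritParams force_blunted_cone
#' @export
force_blunted_pyramid <- function(a, geom, mat = NULL) {
  stopifnot_blunted(geom)
  if (geom$family != "blunted_pyramid")
    stop("force_blunted_pyramid() expects a blunted_pyramid geometry",
         call. = FALSE)
  blunted_force(a, geom, as_material(mat), s = pyramid_factor(geom))
}

#' Hertzian force for a spherical/parabolic tip
#'
#' `F = (4/3) E* sqrt(R) h^(3/2)`. For blunted tips this is the exact
#' contact law below the cap transition (`a < b`); as a stand-alone model
#' it is accurate only for shallow indentation (`h/R < 0.1`).
#'
#' @param h Indentation depth(s), meters.
#' @param R Tip (cap) radius, meters.
#' @param mat An [material()] or `NULL` for unit reduced modulus.
#' @export
force_hertz <- function(h, R, mat = NULL) {
  if (any(h < 0)) stop("`h` must be non-negative", call. = FALSE)
  mat <- as_material(mat)
  (4 / 3) * mat$E_star * sqrt(R) * h^1.5
}

#' Sneddon force for a perfect cone
#'
#' `F = (2/pi) E* tan(theta) h^2`, the sharp-tip limit of the blunted
#' models, appropriate when `h/R >> 1`.
#'
#' @param h Indentation depth(s), meters.
#' @param theta Half-angle in radians (use `theta_deg` for degrees).
#' @param mat An [material()] or `NULL`.
#' @param theta_deg Half-angle in degrees (alternative to `theta`).
#' @export
force_sneddon_cone <- function(h, theta = NULL, mat = NULL,
                               theta_deg = NULL) {
  if (!is.null(theta_deg)) theta <- theta_deg * pi / 180
  if (is.null(theta)) stop("give `theta` or `theta_deg`", call. = FALSE)
  if (any(h < 0)) stop("`h` must be non-negative", call. = FALSE)
  mat <- as_material(mat)
  (2 / pi) * mat$E_star * tan(theta) * h^2
}

## [Gamma(n/2 + 1/2) / Gamma(n/2 + 1)]^(1/n), the shape factor of the
## general axisymmetric solution
gamma_shape_factor <- function(n)
  (gamma(n / 2 + 0.5) / gamma(n / 2 + 1))^(1 / n)

#' Force for a general axisymmetric power-law indenter
#'
#' For an indenter of profile `f(r) = B r^n` on an elastic half-space:
#' \deqn{F = \frac{2E^*}{\pi^{1/(2n)} B^{1/n}}\,\frac{n}{n+1}
#'   \left[\frac{\Gamma(n/2+1/2)}{\Gamma(n/2+1)}\right]^{1/n} h^{1+1/n}.}
#' The exponent of `h` is `m = 1 + 1/n`. With `n = 2, B = 1/(2R)` this is
#' the Hertz sphere; with `n = 1, B = 1/tan(theta)` the Sneddon cone.
#'
#' @param h Indentation depth(s), meters.
#' @param B Profile coefficient; units meters^(1-n) so that `B r^n` is a
#'   length.
#' @param n Shape exponent, `n > 0`.
#' @param mat An [material()] or `NULL`.
#' @export
force_axisymmetric <- function(h, B, n, mat = NULL) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("`n` must be a single positive shape exponent", call. = FALSE)
  if (any(B <= 0)) stop("`B` must be positive", call. = FALSE)
  if (any(h < 0)) stop("`h` must be non-negative", call. = FALSE)
  mat <- as_material(mat)
  2 * mat$E_star * pi^(-1 / (2 * n)) * B^(-1 / n) * (n / (n + 1)) *
    gamma_shape_factor(n) * h^(1 + 1 / n)
}

#' Depth-corrected spherical contact force
#'
#' The Hertz sphere law with a multiplicative depth correction, valid for
#' `h < R`:
#' \deqn{F = \frac{4 E^* \sqrt{R}}{3} h^{3/2} Z,\qquad
#'  Z = c_1 + \frac{3}{4} c_2 \sqrt{h/R} + \frac{3}{6} c_3 (h/R)^{3/2}.}
#' `Z` tends to `c1` as `h -> 0` and drops below 1 as `h` approaches `R`,
#' which is why a naive Hertz fit of deep spherical indentation
#' underestimates the modulus.
#'
#' @inheritParams force_hertz
#' @param coeff A [sphere_correction_coefficients()] object.
#' @export
force_sphere_corrected <- function(h, R, mat = NULL,
                                   coeff = sphere_correction_coefficients()) {
  if (any(h < 0)) stop("`h` must be non-negative", call. = FALSE)
  if (any(h >= R))
    warning("depth-corrected sphere model applied at h >= R, outside its ",
            "stated validity domain", call. = FALSE)
  mat <- as_material(mat)
  x <- sqrt(h / R)
  Z <- coeff$c1 + (3 / 4) * coeff$c2 * x + (3 / 6) * coeff$c3 * x^3
  (4 / 3) * mat$E_star * sqrt(R) * h^1.5 * Z
}

## Effective contact radius of the large-depth approximation, obtained
## from the large-a asymptote of the blunted-cone relations under the
## approximation h_T ~ R (cap treated as a full hemisphere):
## r_c ~ (2/pi) [h tan(theta) + R (2 - tan(theta))].
large_depth_contact_radius <- function(h, geom) {
  (2 / pi) * (h * tan(geom$theta) + geom$R * (2 - tan(geom$theta)))
}

#' Large-depth approximation for blunted tips
#'
#' Closed-form force for deep indentation (`h > 3R`), built from the
#' contact-stiffness relation `S = 2 E* r_c` of a power law `F = c h^m`:
#' \deqn{F = \frac{2}{m} E^* r_c h,\qquad
#'  r_c \approx \frac{2}{\pi}\left[h\tan\theta + R(2 - \tan\theta)\right].}
#' With the default `m = 2` the model tends to the Sneddon cone as
#' `h/R -> infinity` and agrees with the exact blunted-cone force to about
#' 1% over `3R < h < 10R`.
#'
#' @param h Indentation depth(s), meters. A warning is issued for
#'   `h <= 3R` (outside the stated validity domain).
#' @param geom An [indenter_geometry()] with `R` and `theta`.
#' @param mat An [material()] or `NULL`.
#' @param m Power-law exponent of the underlying force law; default 2
#'   (conical regime).
#' @export
force_large_depth <- function(h, geom, mat = NULL, m = 2) {
  stopifnot_blunted(geom)
  if (any(h <= 3 * geom$R))
    warning("large-depth approximation applied at h <= 3R, outside its ",
            "stated validity domain", call. = FALSE)
  mat <- as_material(mat)
  (2 / m) * mat$E_star * large_depth_contact_radius(h, geom) * h
}

#' Generate a noiseless force-indentation curve from the exact model
#'
#' Evaluates the piecewise exact contact model (Hertzian cap below the
#' transition, blunted cone/pyramid above it; pure Hertz for spheres, pure
#' Sneddon for perfect cones) on a uniform grid of the chosen domain
#' variable.
#'
#' @param geom An [indenter_geometry()].
#' @param mat An [material()], or `NULL` to generate `F/E*` curves (unit
#'   reduced modulus).
#' @param domain Length-2 numeric interval, in meters, of the domain
#'   variable.
#' @param n_points Number of samples (>= 2); sampling is uniform in the
#'   domain variable.
#' @param domain_var Either `"depth"` (`domain` is an `h` interval) or
#'   `"contact_radius"` (`domain` is an `a` interval; blunted families
#'   only).
#' @return A [force_curve()] with strictly increasing depth and force.
#' @examples
#' geom <- indenter_geometry("sphero_conical", R = 200e-9, theta_deg = 35)
#' crv <- generate_exact_curve(geom, material(20e3, 0.5),
#'                             domain = c(1.5e-9, 300e-9), n_points = 200)
#' @export
generate_exact_curve <- function(geom, mat = NULL, domain, n_points = 200,
                                 domain_var = c("depth", "contact_radius")) {
  domain_var <- match.arg(domain_var)
  if (!inherits(geom, "indenter_geometry"))
    stop("`geom` must be an `indenter_geometry`", call. = FALSE)
  mat <- as_material(mat)
  if (length(domain) != 2L || !all(is.finite(domain)) ||
      domain[2] <= domain[1] || domain[1] < 0)
    stop("`domain` must be an increasing non-negative interval",
         call. = FALSE)
  if (n_points < 2L) stop("`n_points` must be at least 2", call. = FALSE)

  if (domain_var == "contact_radius") {
    stopifnot_blunted(geom)
    a <- seq(domain[1], domain[2], length.out = n_points)
    b <- transition_radius(geom)
    h <- ifelse(a < b, a^2 / geom$R, depth_from_contact_radius(pmax(a, b), geom))
    Fv <- ifelse(a < b, force_hertz(a^2 / geom$R, geom$R, mat),
                 blunted_force(pmax(a, b), geom, mat, pyramid_factor(geom)))
  } else {
    h <- seq(domain[1], domain[2], length.out = n_points)
    Fv <- switch(geom$family,
      sphere = force_hertz(h, geom$R, mat),
      perfect_cone = force_sneddon_cone(h, theta = geom$theta, mat = mat),
      {
        h_T <- transition_depth(geom)
        cs <- contact_radius_from_depth(h, geom)
        ifelse(h <= h_T, force_hertz(h, geom$R, mat),
               blunted_force(pmax(cs$a, transition_radius(geom)), geom, mat,
                             pyramid_factor(geom)))
      })
  }

  force_curve(h, Fv, geometry = geom, material = mat,
              meta = list(source = "exact_model", domain_var = domain_var,
                          domain = domain, n_points = n_points))
}
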