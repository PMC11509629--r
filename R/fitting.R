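## Curve fitting: the free power-law fit, the classic one-parameter exact
## model fit (linear in E*, solved in closed form), fixed-exponent Hertz
## and Sneddon fits, the large-depth fit, and the method-selection
## flowchart.

r_squared <- function(obs, pred) {
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  1 - ss_res / ss_tot
}

#' Fit a free power law F = c h^m to a force curve
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) on the raw
#' `(h, F)` data, initialised from an ordinary linear regression of
#' `log F` on `log h` over the points with positive force. The curve must
#' be baseline-corrected (contact point at the origin).
#'
#' @param curve A [force_curve()] with at least 5 points, `h > 0`.
#' @param min_points Minimum number of points required.
#' @return A `power_law_fit` object: `c` (prefactor, N m^-m), `m`
#'   (exponent), `n = 1/(m-1)` (`NA` if `m <= 1`), `r_squared` on the
#'   untransformed data, `residual_norm`, `n_points`, `converged`.
#' @export
fit_power_law <- function(curve, min_points = 5L) {
  h <- curve$h
  Fv <- curve$force
  if (length(h) < min_points)
    stop("fit_power_law() needs at least ", min_points, " points",
         call. = FALSE)
  if (any(h <= 0))
    stop("fit_power_law() requires strictly positive depths (baseline-",
         "corrected curve)", call. = FALSE)

  pos <- Fv > 0
  if (sum(pos) < min_points)
    stop("too few points with positive force for log-log initialisation",
         call. = FALSE)
  init <- stats::lm(log(Fv[pos]) ~ log(h[pos]))
  start <- list(c = exp(unname(stats::coef(init)[1])),
                m = unname(stats::coef(init)[2]))

  fit <- tryCatch(
    minpack.lm::nlsLM(Fv ~ c * h^m, start = start,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000L, ftol = 1e-15, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(c = NA_real_, m = NA_real_, n = NA_real_,
                          r_squared = NA_real_, residual_norm = NA_real_,
                          n_points = length(h), converged = FALSE),
                     class = "power_law_fit"))
  }
  cc <- stats::coef(fit)[["c"]]
  m <- stats::coef(fit)[["m"]]
  pred <- cc * h^m
  structure(list(c = cc, m = m,
                 n = if (m > 1) 1 / (m - 1) else NA_real_,
                 r_squared = r_squared(Fv, pred),
                 residual_norm = sqrt(sum((Fv - pred)^2)),
                 n_points = length(h), converged = TRUE),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<power_law_fit>  NOT converged (", x$n_points, "points )\n")
    return(invisible(x))
  }
  cat(sprintf("<power_law_fit>  F = %.6g * h^%.4f   (R^2 = %.6f, %d points)\n",
              x$c, x$m, x$r_squared, x$n_points))
  invisible(x)
}

predict_force <- function(fit, h) UseMethod("predict_force")

#' @export
predict_force.power_law_fit <- function(fit, h) fit$c * h^fit$m

#' @export
predict_force.classic_fit <- function(fit, h) {
  mat <- material(fit$E, fit$nu)
  unit_curve_force(h, fit$geometry) * mat$E_star
}

## unit-reduced-modulus prediction of the piecewise exact model
unit_curve_force <- function(h, geom) {
  switch(geom$family,
    sphere = force_hertz(h, geom$R),
    perfect_cone = force_sneddon_cone(h, theta = geom$theta),
    {
      h_T <- transition_depth(geom)
      cs <- contact_radius_from_depth(h, geom)
      ifelse(h <= h_T, force_hertz(h, geom$R),
             blunted_force(pmax(cs$a, transition_radius(geom)), geom,
                           unit_material(), pyramid_factor(geom)))
    })
}

#' Classic one-parameter fit of the exact contact model
#'
#' Least-squares fit of the Young's modulus with the piecewise exact
#' model (Hertzian cap below the transition depth, blunted cone or
#' pyramid above it; Hertz for spheres, Sneddon for perfect cones). The
#' force is linear in the reduced modulus, so the solution is the
#' closed-form projection
#' `E* = sum(F_i g_i) / sum(g_i^2)` where `g_i` is the unit-modulus model
#' prediction; no iteration is involved and the fit is exact on
#' self-generated noiseless data.
#'
#' @param curve A [force_curve()].
#' @param geom An [indenter_geometry()]; defaults to the curve's own.
#' @param nu Poisson's ratio.
#' @return A `classic_fit` object with `E` (Pa), `r_squared`,
#'   `n_points`, plus the geometry used.
#' @export
fit_classic <- function(curve, geom = NULL, nu = 0.5) {
  geom <- geom %||% curve_geometry(curve)
  if (is.null(geom))
    stop("no geometry: supply `geom` or use a curve with geometry metadata",
         call. = FALSE)
  h <- curve$h
  Fv <- curve$force
  if (any(h < 0)) stop("negative depths in curve", call. = FALSE)
  g <- unit_curve_force(h, geom)
  E_star <- sum(Fv * g) / sum(g^2)
  structure(list(E = E_star * (1 - nu^2), E_star = E_star, nu = nu,
                 r_squared = r_squared(Fv, E_star * g),
                 n_points = length(h), geometry = geom, converged = TRUE),
            class = "classic_fit")
}

#' @export
print.classic_fit <- function(x, ...) {
  cat(sprintf("<classic_fit>  E = %.4g kPa  (R^2 = %.6f, %d points)\n",
              x$E / 1e3, x$r_squared, x$n_points))
  invisible(x)
}

## fixed-exponent linear fits: F = coef * h^m_fixed, with coef linear in E*
fixed_exponent_estimate <- function(curve, m_fixed, c_unit, nu, method) {
  h <- curve$h
  Fv <- curve$force
  g <- h^m_fixed
  coef <- sum(Fv * g) / sum(g^2)
  E_star <- coef / c_unit
  modulus_estimate(E = E_star * (1 - nu^2), method = method, m = m_fixed,
                   r_squared = r_squared(Fv, coef * g))
}

#' Large-depth modulus fit (h > 3R)
#'
#' Linear least squares of the reduced modulus with the large-depth model
#' [force_large_depth()]. Intended for curves whose maximum depth exceeds
#' three tip radii, where the simplified shallow-depth estimator starts to
#' accumulate error.
#'
#' @inheritParams fit_classic
#' @param m Power-law exponent of the underlying law (default 2, the
#'   conical regime).
#' @export
fit_large_depth <- function(curve, geom = NULL, nu = 0.5, m = 2) {
  geom <- geom %||% curve_geometry(curve)
  if (is.null(geom)) stop("no geometry", call. = FALSE)
  warn <- character()
  if (max(curve$h) <= 3 * geom$R)
    warn <- "h_max <= 3R: the large-depth approximation is outside its validity domain"
  g <- suppressWarnings((2 / m) * large_depth_contact_radius(curve$h, geom) *
                          curve$h)
  E_star <- sum(curve$force * g) / sum(g^2)
  est <- modulus_estimate(E = E_star * (1 - nu^2), method = "large_depth",
                          m = m,
                          r_squared = r_squared(curve$force, E_star * g),
                          domain_ratio = max(curve$h) / geom$R,
                          warnings = warn)
  for (w in warn) warning(w, call. = FALSE)
  est
}

#' Choose an analysis method from depth range and tip geometry
#'
#' Implements the method-selection flowchart for blunted probes, by
#' precedence:
#' \itemize{
#' \item `h_max/R < 0.1`: `"hertz"` (fixed `m = 3/2`; cap contact only);
#' \item `h_max < 3R`: `"simplified_blunt"` (free `m`, closed-form
#'   prefactor inversion);
#' \item `h_max/R > 10`: `"sneddon_cone"` (fixed `m = 2`, sharp-tip
#'   limit);
#' \item otherwise (`3 < h_max/R <= 10`): `"large_depth"`.
#' }
#'
#' @param h_max Maximum indentation depth, meters.
#' @param geom An [indenter_geometry()] (only `R` is used).
#' @return One of `"hertz"`, `"simplified_blunt"`, `"sneddon_cone"`,
#'   `"large_depth"`.
#' @export
select_method <- function(h_max, geom) {
  if (!is.numeric(h_max) || h_max <= 0)
    stop("`h_max` must be positive", call. = FALSE)
  R <- geom$R
  if (!is.finite(R)) stop("geometry has no tip radius", call. = FALSE)
  ratio <- h_max / R
  if (ratio < 0.1) "hertz"
  else if (h_max < 3 * R) "simplified_blunt"
  else if (ratio > 10) "sneddon_cone"
  else "large_depth"
}

#' Fit a force curve and estimate the Young's modulus
#'
#' One-stop dispatcher over the package's estimators. With
#' `method = "auto"` the method is chosen by [select_method()] from
#' `h_max/R`.
#'
#' @param curve A [force_curve()].
#' @param geom An [indenter_geometry()]; defaults to the curve's own
#'   metadata.
#' @param nu Poisson's ratio of the sample.
#' @param method `"auto"`, `"hertz"` (fixed m = 3/2), `"sneddon"` (fixed
#'   m = 2), `"simplified"` (free power law + closed-form inversion),
#'   `"classic"` (exact piecewise model), or `"large_depth"`.
#' @return A `modulus_estimate`.
#' @examples
#' geom <- indenter_geometry("sphero_conical", R = 200e-9, theta_deg = 35)
#' crv <- generate_exact_curve(geom, material(20e3, 0.5),
#'                             domain = c(1.5e-9, 300e-9))
#' fit_curve(crv, method = "auto")  # selects the simplified estimator
#' @export
fit_curve <- function(curve, geom = NULL, nu = 0.5,
                      method = c("auto", "hertz", "sneddon", "simplified",
                                 "classic", "large_depth")) {
  method <- match.arg(method)
  geom <- geom %||% curve_geometry(curve)
  if (is.null(geom))
    stop("no geometry: supply `geom` or use a curve with geometry metadata",
         call. = FALSE)
  h_max <- max(curve$h)
  if (method == "auto") {
    method <- switch(select_method(h_max, geom),
                     hertz = "hertz", simplified_blunt = "simplified",
                     sneddon_cone = "sneddon", large_depth = "large_depth")
  }

  est <- switch(method,
    hertz = fixed_exponent_estimate(
      curve, 1.5, (4 / 3) * sqrt(geom$R), nu, "hertz"),
    sneddon = fixed_exponent_estimate(
      curve, 2, (2 / pi) * tan(geom$theta), nu, "sneddon_cone"),
    simplified = {
      plf <- fit_power_law(curve)
      if (!plf$converged)
        stop("power-law fit did not converge", call. = FALSE)
      modulus_from_powerlaw(plf, geom, nu)
    },
    classic = {
      cf <- fit_classic(curve, geom, nu)
      modulus_estimate(E = cf$E, method = "classic_blunt",
                       r_squared = cf$r_squared)
    },
    large_depth = fit_large_depth(curve, geom, nu))

  est$domain_ratio <- h_max / geom$R
  est
}

`%||%` <- function(a, b) if (is.null(a)) b else a
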