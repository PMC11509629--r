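#' Force-indentation curve container
#'
#' A data frame with columns `h` (indentation depth, meters) and `force`
#' (newtons) plus provenance attributes: the generating geometry and
#' material (when known) and a free-form metadata list (noise level, seed,
#' source file, ...).
#'
#' @param h Indentation depths in meters.
#' @param force Forces in newtons (same length as `h`).
#' @param geometry Optional [indenter_geometry()].
#' @param material Optional [material()].
#' @param meta Named list of metadata; kept on read/write round-trips.
#' @return An object of classes `force_curve` and `data.frame`.
#' @export
force_curve <- function(h, force, geometry = NULL, material = NULL,
                        meta = list()) {
  if (length(h) != length(force))
    stop("`h` and `force` must have the same length", call. = FALSE)
  if (any(!is.finite(h)) || any(!is.finite(force)))
    stop("`h` and `force` must be finite", call. = FALSE)
  df <- data.frame(h = as.numeric(h), force = as.numeric(force))
  structure(df,
            geometry = geometry, material = material, meta = meta,
            class = c("force_curve", "data.frame"))
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve>  %d points,  h: %.4g-%.4g nm,  F: %.4g-%.4g nN\n",
              nrow(x), min(x$h) * 1e9, max(x$h) * 1e9,
              min(x$force) * 1e9, max(x$force) * 1e9))
  g <- attr(x, "geometry")
  if (!is.null(g))
    cat("  geometry:", g$family,
        if (is.finite(g$R)) paste0("R=", format(g$R * 1e9), "nm"),
        if (is.finite(g$theta))
          paste0("theta=", format(g$theta * 180 / pi), "deg"), "\n")
  m <- attr(x, "material")
  if (!is.null(m)) cat("  material: E =", format(m$E), "Pa, nu =", m$nu, "\n")
  invisible(x)
}

#' Plot a force curve with an optional fitted overlay
#'
#' @param x A [force_curve()].
#' @param fit Optional fit object from [fit_power_law()] or [fit_curve()];
#'   its prediction is drawn over the data.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.force_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$h * 1e9, x$force * 1e9, xlab = "indentation depth (nm)",
                 ylab = "force (nN)", pch = 16, cex = 0.5, ...)
  if (!is.null(fit)) {
    hh <- seq(min(x$h), max(x$h), length.out = 200)
    graphics::lines(hh * 1e9, predict_force(fit, hh) * 1e9, col = 2, lwd = 2)
  }
  invisible(x)
}

curve_geometry <- function(curve) attr(curve, "geometry")
curve_material <- function(curve) attr(curve, "material")
curve_meta <- function(curve) attr(curve, "meta")
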