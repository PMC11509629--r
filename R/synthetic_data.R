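## Synthetic force-curve simulator emulating the simulation protocol of
## the validation study: an elastic half-space of known modulus indented
## by a blunted cone or pyramid, with i.i.d. zero-mean Gaussian noise on
## the force channel. Everything is deterministic under a fixed seed, so
## every fitting path is testable offline.

#' Configuration for the synthetic-curve simulator
#'
#' The defaults mirror the reference simulation conditions: an elastic
#' half-space with Young's modulus 20 kPa and Poisson's ratio 0.5, probed
#' by a blunted tip mounted on a 0.1 N/m cantilever, with Gaussian force
#' noise of 2% of the maximum force.
#'
#' @param geom An [indenter_geometry()].
#' @param E Young's modulus, pascals.
#' @param nu Poisson's ratio.
#' @param h_max Maximum indentation depth, meters.
#' @param n_points Samples per curve (uniform in depth on
#'   `[h_max/n_points, h_max]`; the zero-depth point is excluded so that
#'   log-log initialisation is defined).
#' @param noise_sigma Noise level: a fraction of the curve's maximum force
#'   when `noise_mode = "fraction_of_max"` (default 0.02), or newtons when
#'   `"absolute"` (meters of deflection if `noise_space = "deflection"`).
#' @param noise_mode `"fraction_of_max"` or `"absolute"`.
#' @param noise_space `"force"` (default) or `"deflection"`: deflection
#'   noise is divided/multiplied through the cantilever spring constant.
#' @param spring_constant Cantilever spring constant, N/m (metadata;
#'   used only for deflection-space noise).
#' @param seed Integer RNG seed; a fixed seed makes [simulate_curves()]
#'   bit-reproducible.
#' @param n_curves Number of replicate noisy curves.
#' @export
simulation_config <- function(geom, E = 20e3, nu = 0.5, h_max = 300e-9,
                              n_points = 200L, noise_sigma = 0.02,
                              noise_mode = c("fraction_of_max", "absolute"),
                              noise_space = c("force", "deflection"),
                              spring_constant = 0.1, seed = 1L,
                              n_curves = 1L) {
  noise_mode <- match.arg(noise_mode)
  noise_space <- match.arg(noise_space)
  if (!inherits(geom, "indenter_geometry"))
    stop("`geom` must be an `indenter_geometry`", call. = FALSE)
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0", call. = FALSE)
  if (h_max <= 0 || n_points < 2L || n_curves < 1L)
    stop("invalid simulation domain", call. = FALSE)
  structure(list(geom = geom, E = E, nu = nu, h_max = h_max,
                 n_points = as.integer(n_points),
                 noise_sigma = noise_sigma, noise_mode = noise_mode,
                 noise_space = noise_space,
                 spring_constant = spring_constant,
                 seed = as.integer(seed), n_curves = as.integer(n_curves)),
            class = "simulation_config")
}

#' Simulate noisy force-indentation curves
#'
#' Evaluates the exact forward model once on the configured depth grid and
#' adds independent zero-mean Gaussian noise per replicate. With
#' `noise_sigma = 0` the output equals [generate_exact_curve()].
#'
#' @param cfg A [simulation_config()].
#' @return A list of [force_curve()] objects; each carries the full
#'   generating parameters (including the seed and replicate index) in its
#'   metadata.
#' @export
simulate_curves <- function(cfg) {
  if (!inherits(cfg, "simulation_config"))
    stop("`cfg` must be a `simulation_config`", call. = FALSE)
  mat <- material(cfg$E, cfg$nu)
  base <- generate_exact_curve(cfg$geom, mat,
                               domain = c(cfg$h_max / cfg$n_points,
                                          cfg$h_max),
                               n_points = cfg$n_points,
                               domain_var = "depth")
  sigma_F <- switch(cfg$noise_mode,
                    fraction_of_max = cfg$noise_sigma * max(base$force),
                    absolute = if (cfg$noise_space == "deflection")
                      cfg$noise_sigma * cfg$spring_constant
                    else cfg$noise_sigma)

  set.seed(cfg$seed)
  lapply(seq_len(cfg$n_curves), function(i) {
    noisy <- base$force + stats::rnorm(cfg$n_points, 0, sigma_F)
    force_curve(base$h, noisy, geometry = cfg$geom, material = mat,
                meta = list(source = "simulated",
                            noise_sigma = cfg$noise_sigma,
                            noise_mode = cfg$noise_mode,
                            noise_space = cfg$noise_space,
                            noise_sigma_newtons = sigma_F,
                            spring_constant = cfg$spring_constant,
                            seed = cfg$seed, replicate = i))
  })
}

#' Write the standard synthetic fixture suite
#'
#' Generates the full set of test fixtures used across the package:
#' four noiseless shallow-domain curves (two half-angles x two tip radii),
#' four noisy single curves at increasing depth, two 30-replicate batches
#' (blunted cone and 4-sided blunted pyramid at 20 kPa), and one
#' damaged-tip-like curve whose exponent is far below 3/2. A JSON manifest
#' records every file with its generating parameters and seed.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Base RNG seed.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  add <- function(name, file, params) {
    manifest[[name]] <<- c(list(file = file), params)
  }

  ## noiseless shallow-domain curves over the blunted segment b < a < k b
  noiseless <- list(
    list(name = "noiseless_25deg_R20", theta = 25, R = 20e-9, frac = 1.25),
    list(name = "noiseless_25deg_R50", theta = 25, R = 50e-9, frac = 1.25),
    list(name = "noiseless_35deg_R20", theta = 35, R = 20e-9, frac = 1.5),
    list(name = "noiseless_35deg_R50", theta = 35, R = 50e-9, frac = 1.5))
  for (cs in noiseless) {
    geom <- indenter_geometry("sphero_conical", R = cs$R,
                              theta_deg = cs$theta)
    b <- transition_radius(geom)
    crv <- generate_exact_curve(geom, NULL, domain = c(b, cs$frac * b),
                                n_points = 200,
                                domain_var = "contact_radius")
    f <- file.path(outdir, paste0(cs$name, ".txt"))
    write_force_curve(crv, f)
    add(cs$name, basename(f),
        list(theta_deg = cs$theta, R_m = cs$R, a_domain_over_b = c(1, cs$frac),
             noise_sigma = 0, data = "F_over_Estar"))
  }

  ## noisy single curves, increasing depth
  noisy <- list(
    list(name = "noisy_R100_h100", R = 100e-9, h_max = 100e-9),
    list(name = "noisy_R100_h200", R = 100e-9, h_max = 200e-9),
    list(name = "noisy_R200_h200", R = 200e-9, h_max = 200e-9),
    list(name = "noisy_R200_h300", R = 200e-9, h_max = 300e-9))
  for (i in seq_along(noisy)) {
    cs <- noisy[[i]]
    geom <- indenter_geometry("sphero_conical", R = cs$R, theta_deg = 35)
    cfg <- simulation_config(geom, E = 20e3, nu = 0.5, h_max = cs$h_max,
                             seed = seed + i)
    crv <- simulate_curves(cfg)[[1]]
    f <- file.path(outdir, paste0(cs$name, ".txt"))
    write_force_curve(crv, f)
    add(cs$name, basename(f),
        list(theta_deg = 35, R_m = cs$R, h_max_m = cs$h_max, E_Pa = 20e3,
             nu = 0.5, noise_sigma = 0.02, seed = seed + i))
  }

  ## 30-replicate batches: cone and 4-sided pyramid
  batches <- list(
    list(name = "batch_cone", family = "sphero_conical", k = NULL),
    list(name = "batch_pyramid", family = "blunted_pyramid", k = 4L))
  for (j in seq_along(batches)) {
    bs <- batches[[j]]
    geom <- indenter_geometry(bs$family, R = 200e-9, theta_deg = 35,
                              k = bs$k)
    cfg <- simulation_config(geom, E = 20e3, nu = 0.5, h_max = 300e-9,
                             seed = seed + 100 + j, n_curves = 30L)
    curves <- simulate_curves(cfg)
    subdir <- file.path(outdir, bs$name)
    dir.create(subdir, showWarnings = FALSE)
    files <- vapply(seq_along(curves), function(i) {
      f <- file.path(subdir, sprintf("curve_%03d.txt", i))
      write_force_curve(curves[[i]], f)
      file.path(bs$name, basename(f))
    }, character(1))
    add(bs$name, files,
        list(family = bs$family, k = bs$k, theta_deg = 35, R_m = 200e-9,
             E_Pa = 20e3, nu = 0.5, h_max_m = 300e-9, n_curves = 30,
             noise_sigma = 0.02, seed = seed + 100 + j))
  }

  ## damaged-tip-like curve: exponent well below 3/2 despite deep
  ## indentation (flattened apex, near-constant contact area)
  set.seed(seed + 999)
  h <- seq(5e-9, 1000e-9, length.out = 200)
  Fv <- 0.0367 * h^1.295
  Fv <- Fv + stats::rnorm(length(h), 0, 0.005 * max(Fv))
  crv <- force_curve(h, Fv,
                     meta = list(source = "synthetic_damaged_tip",
                                 c_true = 0.0367, m_true = 1.295,
                                 noise_sigma = 0.005, seed = seed + 999))
  f <- file.path(outdir, "damaged_tip.txt")
  write_force_curve(crv, f)
  add("damaged_tip", basename(f),
      list(c_SI = 0.0367, m = 1.295, noise_sigma = 0.005,
           seed = seed + 999))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
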