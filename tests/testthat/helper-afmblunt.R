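## shared fixtures: all geometries are MLCT-like probe shapes used
## throughout the tests

sc_geom <- function(R = 20e-9, theta_deg = 25)
  indenter_geometry("sphero_conical", R = R, theta_deg = theta_deg)

pyr_geom <- function(R = 200e-9, theta_deg = 35, k = 4L)
  indenter_geometry("blunted_pyramid", R = R, theta_deg = theta_deg, k = k)

soft_sample <- function() material(20e3, 0.5)

## noiseless F/E* curve over the blunted contact-radius window [b, frac*b]
blunted_window_curve <- function(theta_deg, R = 20e-9, frac, n = 200) {
  g <- sc_geom(R, theta_deg)
  b <- transition_radius(g)
  generate_exact_curve(g, NULL, domain = c(b, frac * b), n_points = n,
                       domain_var = "contact_radius")
}
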