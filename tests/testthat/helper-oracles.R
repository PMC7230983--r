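# Independent brute-force oracles used to validate closed forms.

# Truncated-sphere oracle for the adhesion area increase: a sphere of
# radius R cut by a plane at polar angle theta has
#   volume V(R, theta) = (pi/3) R^3 (1 + cos)^2 (2 - cos)
#   membrane area    = curved cap 4 pi R^2 - 2 pi R^2 (1 - cos)
#                      + flat patch disc pi R^2 sin^2
# Conserve the original sphere's volume by solving numerically for R,
# then report the relative area change. Independent of the closed form.
oracle_area_increase <- function(theta, r0 = 1) {
  ct <- cos(theta)
  v0 <- 4 / 3 * pi * r0^3
  vol <- function(r) pi / 3 * r^3 * (1 + ct)^2 * (2 - ct)
  r <- stats::uniroot(function(r) vol(r) - v0,
                      lower = r0 * 0.5, upper = r0 * 4,
                      tol = .Machine$double.eps^0.9)$root
  area <- 4 * pi * r^2 - 2 * pi * r^2 * (1 - ct) + pi * r^2 * sin(theta)^2
  area / (4 * pi * r0^2) - 1
}

# Bisection inversion of the nanoparticle temperature field, independent
# of the closed-form hot_zone_extent.
oracle_hot_zone <- function(source, threshold_c) {
  f <- function(r) temperature_at(source, r) - threshold_c
  upper <- source$np_radius_nm * 2
  while (f(upper) > 0) upper <- upper * 2
  stats::uniroot(f, lower = source$np_radius_nm, upper = upper,
                 tol = 1e-11 * source$np_radius_nm)$root
}

iso_internal <- function() solute_mixture(sucrose = 0.75)
iso_external <- function() solute_mixture(glucose = 0.35, nacl = 0.2)
deflated_external <- function() solute_mixture(glucose = 0.4, nacl = 0.2)
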