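#' Spray injection specification
#'
#' Describes one monodispersed spray release: a solid-cone injection from
#' the nozzle tip with every droplet leaving at the same speed, directions
#' filling the cone uniformly over solid angle.
#'
#' @param axis a \code{spray_axis}; the nozzle tip is
#'   \code{axis_injection_point(axis)}.
#' @param diameter_um droplet diameter, micrometres.
#' @param cone_half_angle half-angle at the spray cone vertex, degrees.
#' @param speed initial droplet speed, m/s.
#' @param n_droplets droplets per release.
#' @param density_kg_m3 drug formulation density (1.5 g/mL default).
#' @param seed RNG seed for the cone sampling.
#' @return object of class \code{spray_injection}.
#' @export
spray_injection <- function(axis, diameter_um,
                            cone_half_angle = 27.93,
                            speed = 10,
                            n_droplets = 3000,
                            density_kg_m3 = 1500,
                            seed = 1L) {
  if (cone_half_angle <= 0 || cone_half_angle >= 90)
    stop("cone half-angle must lie in (0, 90) degrees")
  if (speed <= 0) stop("injection speed must be positive")
  if (n_droplets < 1) stop("need at least one droplet")
  if (diameter_um <= 0) stop("droplet diameter must be positive")
  if (density_kg_m3 <= 0) stop("droplet density must be positive")
  structure(list(axis = axis,
                 origin = axis_injection_point(axis),
                 diameter_um = diameter_um,
                 cone_half_angle = cone_half_angle,
                 speed = speed,
                 n_droplets = as.integer(n_droplets),
                 density_kg_m3 = density_kg_m3,
                 seed = as.integer(seed)),
            class = "spray_injection")
}

#' Initial droplet states for a solid-cone injection
#'
#' Samples \code{n_droplets} velocity directions uniformly over the solid
#' cone of the given half-angle about the spray axis (uniform in azimuth and
#' in the cosine of the polar angle), all at the injection speed, all
#' starting at the nozzle tip. Reproducible for a fixed seed.
#'
#' @param inj a \code{spray_injection}.
#' @param model optional \code{airway_model}; if supplied, the nozzle tip is
#'   checked to lie inside the lumen (placement error otherwise).
#' @return list with \code{position} and \code{velocity} (both
#'   \code{n x 3} matrices).
#' @export
cone_injection <- function(inj, model = NULL) {
  if (!is.null(model) &&
      classify_point(model, inj$origin)$wall_distance <= 0)
    stop("spray injection origin lies outside the airway lumen")
  n <- inj$n_droplets
  d <- inj$axis$direction
  # orthonormal frame about the axis
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  set.seed(inj$seed)
  cos_a <- cos(inj$cone_half_angle * pi / 180)
  ct <- runif(n, min = cos_a, max = 1)
  st <- sqrt(pmax(0, 1 - ct^2))
  phi <- runif(n, 0, 2 * pi)
  dirs <- outer(ct, d) + outer(st * cos(phi), e1) + outer(st * sin(phi), e2)
  list(position = matrix(rep(inj$origin, each = n), n, 3),
       velocity = inj$speed * dirs)
}

#' Cunningham slip correction factor
#'
#' Millikan-fit slip correction
#' \eqn{C_c = 1 + \frac{2\lambda}{D}\left(1.257 + 0.4 e^{-1.1 D /(2\lambda)}\right)},
#' relevant for droplets whose diameter approaches the air mean free path.
#'
#' @param diameter_um droplet diameter, micrometres.
#' @param mean_free_path air mean free path, metres.
#' @return dimensionless factor \eqn{\ge 1}.
#' @export
cunningham_slip <- function(diameter_um, mean_free_path = 6.6e-8) {
  if (any(diameter_um <= 0)) stop("droplet diameter must be positive")
  D <- diameter_um * 1e-6
  1 + (2 * mean_free_path / D) *
    (1.257 + 0.4 * exp(-1.1 * D / (2 * mean_free_path)))
}

#' Droplet relaxation time and terminal settling speed
#'
#' Stokes-drag relaxation time
#' \eqn{\tau = \rho_D D^2 C_c / (18 \mu)} and the still-air terminal
#' settling speed \eqn{v_t = \tau g}.
#'
#' @inheritParams cunningham_slip
#' @param density_kg_m3 droplet material density.
#' @param air_viscosity dynamic viscosity of air, kg/(m s).
#' @param Cc Cunningham slip factor; computed from \code{mean_free_path}
#'   when \code{NULL}.
#' @return seconds (\code{relaxation_time}) or m/s
#'   (\code{terminal_velocity}).
#' @export
relaxation_time <- function(diameter_um, density_kg_m3 = 1500,
                            air_viscosity = 1.825e-5, Cc = NULL,
                            mean_free_path = 6.6e-8) {
  if (is.null(Cc)) Cc <- cunningham_slip(diameter_um, mean_free_path)
  density_kg_m3 * (diameter_um * 1e-6)^2 * Cc / (18 * air_viscosity)
}

#' @rdname relaxation_time
#' @param g gravitational acceleration magnitude, m/s^2.
#' @export
terminal_velocity <- function(diameter_um, density_kg_m3 = 1500,
                              air_viscosity = 1.825e-5, Cc = NULL,
                              mean_free_path = 6.6e-8, g = 9.81) {
  relaxation_time(diameter_um, density_kg_m3, air_viscosity, Cc,
                  mean_free_path) * g
}
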