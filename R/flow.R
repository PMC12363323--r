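#' Inhalation flow field
#'
#' Analytic laminar stand-in for the inhaled airflow: at every station along
#' the passage the axial velocity follows a parabolic (Poiseuille) profile on
#' the local circular cross-section, scaled so that the volumetric flux
#' through every section equals the inhalation rate \code{Q}. Velocity is
#' parallel to the local centerline tangent and vanishes at the wall.
#'
#' The 15 L/min condition corresponds to resting breathing and is laminar;
#' 30 L/min stands for moderately heavy breathing and is treated with the
#' same quasi-steady laminar profile (turbulence modelling is out of scope
#' of this reduced-order model).
#'
#' @param rate_lpm inhalation rate in L/min (15 and 30 are the study
#'   conditions).
#' @param air_density kg/m^3.
#' @param air_viscosity dynamic viscosity, kg/(m s).
#' @return object of class \code{flow_field} with \code{Q_m3s} precomputed.
#' @examples
#' fl <- flow_field(15)
#' aw <- airway_model()
#' velocity_at(aw, fl, centerline_point(aw, 0.5))
#' @export
flow_field <- function(rate_lpm, air_density = 1.204,
                       air_viscosity = 1.825e-5) {
  if (rate_lpm <= 0) stop("inhalation rate must be positive")
  if (air_density <= 0 || air_viscosity <= 0)
    stop("air properties must be positive")
  structure(list(rate_lpm = rate_lpm,
                 Q_m3s = rate_lpm * 1e-3 / 60,
                 air_density = air_density,
                 air_viscosity = air_viscosity),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("Inhalation flow: %g L/min (%.3e m^3/s), rho = %g kg/m^3, mu = %g kg/m.s\n",
              x$rate_lpm, x$Q_m3s, x$air_density, x$air_viscosity))
  invisible(x)
}

#' Air velocity at a point
#'
#' Axial speed \eqn{u(\rho) = \frac{2Q}{\pi r^2}\left(1 - \rho^2/r^2\right)}
#' along the local centerline tangent, where \eqn{\rho} is the distance to
#' the centerline and \eqn{r} the local tube radius; the peak (centerline)
#' speed is twice the section-mean speed \eqn{Q/(\pi r^2)}.
#'
#' @param model an \code{airway_model}.
#' @param flow a \code{flow_field}.
#' @param position 3-vector, model frame, metres; must lie inside the lumen.
#' @return velocity 3-vector, m/s.
#' @export
velocity_at <- function(model, flow, position) {
  cl <- classify_point(model, position)
  if (cl$wall_distance < 0)
    stop("position lies outside the airway lumen")
  r <- airway_radius(model, cl$s)
  umax <- 2 * flow$Q_m3s / (pi * r^2)
  u <- umax * (1 - (cl$radial_distance / r)^2)
  u * centerline_tangent(model, cl$s)
}

#' Volumetric flux through a cross-section
#'
#' Numerical check of mass conservation: integrates the axial velocity over
#' the circular section at arc-length fraction \code{s} with a polar product
#' rule (midpoint in \eqn{\rho^2} and in azimuth, which integrates the
#' parabolic profile exactly up to round-off).
#'
#' @inheritParams velocity_at
#' @param s arc-length fraction of the section.
#' @param n_r,n_phi radial and azimuthal quadrature resolution.
#' @return flux in m^3/s (should equal \code{flow$Q_m3s}).
#' @export
section_flux <- function(model, flow, s, n_r = 64, n_phi = 32) {
  r <- airway_radius(model, s)
  q <- centerline_point(model, s)
  tg <- centerline_tangent(model, s)
  # orthonormal frame of the section plane
  e1 <- c(0, 1, 0)
  e2 <- c(tg[3], 0, -tg[1]) # tangent rotated -90 deg in the bend plane
  rho <- sqrt((seq_len(n_r) - 0.5) / n_r) * r
  phi <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  flux <- 0
  for (i in seq_len(n_r)) {
    for (j in seq_len(n_phi)) {
      p <- q + rho[i] * (cos(phi[j]) * e1 + sin(phi[j]) * e2)
      u <- velocity_at(model, flow, p)
      flux <- flux + sum(u * tg)
    }
  }
  flux * (r^2 / n_r) / 2 * (2 * pi / n_phi)
}
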