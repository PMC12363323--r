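#' Idealized nasal-passage geometry
#'
#' Builds a parametric stand-in for an anatomically realistic nasal airway:
#' a curved tube whose planar centerline turns through 90 degrees in total,
#' from an upward-posterior nostril inlet, through a long nearly horizontal
#' main passage, to a posterior-inferior nasopharyngeal outlet — the
#' entrance bend, horizontal barrel and nasopharyngeal down-turn of a real
#' nasal cavity, reduced to a tube. The centerline is defined by a
#' piecewise-linear tangent-elevation profile over normalized arc length
#' \eqn{s \in [0,1]} and carries a piecewise-linear radius profile. Named
#' deposition regions partition \eqn{s}; the terminal band is the
#' nasopharynx. The model is inclined forward by \code{tilt_deg} (head
#' tilt), which determines how laboratory gravity and a "vertical" spray
#' bottle map into the model frame.
#'
#' Model-frame convention: right-handed, \code{+z} superior (head up),
#' \code{+x} posterior, \code{+y} medial for the default left passage. The
#' nostril plane is the inlet cross-section plane, centroid at the origin.
#' In the laboratory frame gravity acts along \code{-z}; a forward head
#' tilt of \eqn{\alpha} makes the laboratory vertical equal
#' \eqn{(\sin\alpha, 0, \cos\alpha)} in model coordinates.
#'
#' @param length_m total centerline length in metres.
#' @param elevation_profile two-column matrix or list of \code{c(s,
#'   elevation_deg)} control points: the angle of the centerline tangent
#'   above the horizontal, interpolated linearly in \code{s}; must be
#'   strictly decreasing (the passage turns monotonically from the inlet to
#'   the outlet).
#' @param radius_profile two-column matrix or list of \code{c(s, r_mm)}
#'   control points; tube radius in mm, interpolated linearly in \code{s}.
#' @param tilt_deg forward head-tilt angle in degrees.
#' @param nasopharynx_start_s arc-length fraction where the nasopharynx
#'   region begins.
#' @param vestibule_end_s,anterior_end_s region boundaries in \code{s}.
#' @param side \code{"left"} or \code{"right"}; right mirrors the lateral /
#'   septal sides in \code{y}.
#' @param septum_frac septal-plane offset as a fraction of the nostril
#'   radius (the spray axis must stay medial of this plane).
#' @param n_table resolution of the internal centerline table.
#' @return an object of class \code{airway_model}.
#' @examples
#' aw <- airway_model()
#' aw$region_bounds
#' airway_radius(aw, 0.5)
#' @export
airway_model <- function(length_m = 0.10,
                         elevation_profile = cbind(
                           s = c(0, 0.12, 0.8, 1),
                           elevation_deg = c(45, 12, 5, -45)),
                         radius_profile = cbind(
                           s = c(0, 0.12, 0.5, 0.85, 1),
                           r_mm = c(7.0, 5.5, 6.5, 5.5, 6.0)),
                         tilt_deg = 22.5,
                         nasopharynx_start_s = 0.85,
                         vestibule_end_s = 0.10,
                         anterior_end_s = 0.45,
                         side = c("left", "right"),
                         septum_frac = 0.5,
                         n_table = 1025) {
  side <- match.arg(side)
  rp <- as.matrix(radius_profile)
  ep <- as.matrix(elevation_profile)
  if (ncol(rp) != 2L) stop("radius_profile must have two columns (s, r_mm)")
  if (ncol(ep) != 2L) stop("elevation_profile must have two columns (s, elevation_deg)")
  if (length_m <= 0) stop("airway length must be positive")
  if (any(rp[, 2] <= 0)) stop("radius control points must be positive")
  if (any(rp[, 1] < 0 | rp[, 1] > 1)) stop("radius profile s must lie in [0,1]")
  if (is.unsorted(rp[, 1], strictly = TRUE)) stop("radius profile s must be strictly increasing")
  if (rp[1, 1] != 0 || rp[nrow(rp), 1] != 1) stop("radius profile must cover s = 0 and s = 1")
  if (is.unsorted(ep[, 1], strictly = TRUE) || ep[1, 1] != 0 || ep[nrow(ep), 1] != 1)
    stop("elevation profile s must be strictly increasing and cover [0, 1]")
  if (is.unsorted(rev(ep[, 2]), strictly = TRUE))
    stop("elevation profile must be strictly decreasing (monotone turn)")
  if (any(abs(ep[, 2]) >= 90))
    stop("elevation angles must lie in (-90, 90) degrees")
  if (!(0 < vestibule_end_s && vestibule_end_s < anterior_end_s &&
        anterior_end_s < nasopharynx_start_s && nasopharynx_start_s < 1))
    stop("region bounds must satisfy 0 < vestibule < anterior < nasopharynx start < 1")

  # dense centerline table: cumulative trapezoid of the unit tangent
  s_tab <- seq(0, 1, length.out = n_table)
  eps_tab <- stats::approx(ep[, 1], ep[, 2] * pi / 180, xout = s_tab)$y
  cx <- cos(eps_tab); cz <- sin(eps_tab)
  h <- length_m / (n_table - 1)
  x_tab <- c(0, cumsum((cx[-1] + cx[-n_table]) / 2 * h))
  z_tab <- c(0, cumsum((cz[-1] + cz[-n_table]) / 2 * h))

  model <- structure(list(
    length_m = length_m,
    bend_angle_deg = unname(ep[1, 2] - ep[nrow(ep), 2]),
    elevation_s = ep[, 1],
    elevation_deg = ep[, 2],
    radius_s = rp[, 1],
    radius_m = rp[, 2] * 1e-3,
    s_tab = s_tab, x_tab = x_tab, z_tab = z_tab, eps_tab = eps_tab,
    head_tilt = tilt_deg,
    side = side,
    lat_sign = if (side == "left") -1 else 1,
    septum_frac = septum_frac,
    region_bounds = list(
      vestibule = c(0, vestibule_end_s),
      anterior = c(vestibule_end_s, anterior_end_s),
      mid = c(anterior_end_s, nasopharynx_start_s),
      nasopharynx = c(nasopharynx_start_s, 1))
  ), class = "airway_model")
  t0 <- centerline_tangent(model, 0)
  model$nostril_plane <- list(centroid = c(0, 0, 0), normal = t0)
  model$septal_plane <- list(
    normal = c(0, -model$lat_sign, 0),
    offset = septum_frac * airway_radius(model, 0))
  model
}

#' @export
print.airway_model <- function(x, ...) {
  cat("Idealized nasal airway (", x$side, " passage)\n", sep = "")
  cat(sprintf("  centerline: %.3f m arc, %g deg bend, head tilt %g deg\n",
              x$length_m, x$bend_angle_deg, x$head_tilt))
  cat(sprintf("  tube radius: %.1f-%.1f mm\n",
              1e3 * min(x$radius_m), 1e3 * max(x$radius_m)))
  b <- x$region_bounds
  cat("  regions (s):",
      paste(sprintf("%s [%.2f, %.2f]", names(b),
                    vapply(b, `[`, 0, 1), vapply(b, `[`, 0, 2)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Tube radius at an arc-length fraction
#' @param model an \code{airway_model}.
#' @param s arc-length fraction(s) in \[0, 1\] (clamped).
#' @return radius in metres.
#' @export
airway_radius <- function(model, s) {
  s <- pmin(pmax(s, 0), 1)
  stats::approx(model$radius_s, model$radius_m, xout = s, rule = 2)$y
}

#' Centerline point and tangent
#'
#' The planar centerline runs in the \code{y = 0} plane from the nostril
#' centroid (origin) to the nasopharyngeal outlet; the tangent elevation
#' above horizontal follows the model's elevation profile.
#'
#' @inheritParams airway_radius
#' @return \code{centerline_point}: 3-vector (or \code{n x 3} matrix) in
#'   metres; \code{centerline_tangent}: unit tangent(s).
#' @export
centerline_point <- function(model, s) {
  s <- pmin(pmax(s, 0), 1)
  out <- cbind(stats::approx(model$s_tab, model$x_tab, xout = s)$y,
               0,
               stats::approx(model$s_tab, model$z_tab, xout = s)$y)
  if (length(s) == 1L) drop(out) else out
}

#' @rdname centerline_point
#' @export
centerline_tangent <- function(model, s) {
  s <- pmin(pmax(s, 0), 1)
  eps <- stats::approx(model$s_tab, model$eps_tab, xout = s)$y
  out <- cbind(cos(eps), 0, sin(eps))
  if (length(s) == 1L) drop(out) else out
}

#' Sampled centerline
#' @inheritParams airway_radius
#' @param n number of samples.
#' @return \code{n x 3} matrix of points from nostril to outlet.
#' @export
centerline_points <- function(model, n = 201) {
  centerline_point(model, seq(0, 1, length.out = n))
}

#' Locate a point relative to the airway
#'
#' Total function: any 3D point (model frame, metres) is mapped to its
#' nearest arc-length fraction, the deposition region there, and the signed
#' distance to the tube wall (positive inside the lumen, negative outside).
#' Points below the nostril plane are referred to the inlet section.
#'
#' @param model an \code{airway_model}.
#' @param position numeric 3-vector, model frame, metres.
#' @return list with \code{s}, \code{region}, \code{wall_distance} (m) and
#'   \code{radial_distance} (m, distance to the centerline).
#' @export
classify_point <- function(model, position) {
  p <- as.numeric(position)
  stopifnot(length(p) == 3L)
  loc <- .locate_cpp(p, geometry_params(model))
  list(s = loc$s, region = region_of(model, loc$s),
       wall_distance = loc$wall_distance,
       radial_distance = loc$radial_distance)
}

#' Region name at an arc-length fraction
#' @inheritParams airway_radius
#' @return character region name(s).
#' @export
region_of <- function(model, s) {
  b <- model$region_bounds
  vapply(s, function(si) {
    if (si >= b$nasopharynx[1]) "nasopharynx"
    else if (si >= b$mid[1]) "mid"
    else if (si >= b$anterior[1]) "anterior"
    else "vestibule"
  }, character(1))
}

#' Laboratory / model frame conversions
#'
#' With a forward head tilt \eqn{\alpha}, the model's posterior axis
#' \code{+x} maps to laboratory \eqn{(\cos\alpha, 0, \sin\alpha)} and the
#' superior axis \code{+z} to \eqn{(-\sin\alpha, 0, \cos\alpha)}.
#'
#' @param model an \code{airway_model}.
#' @param v numeric 3-vector.
#' @return transformed 3-vector.
#' @export
lab_to_model <- function(model, v) {
  a <- model$head_tilt * pi / 180
  c(cos(a) * v[1] + sin(a) * v[3],
    v[2],
    -sin(a) * v[1] + cos(a) * v[3])
}

#' @rdname lab_to_model
#' @export
model_to_lab <- function(model, v) {
  a <- model$head_tilt * pi / 180
  c(cos(a) * v[1] - sin(a) * v[3],
    v[2],
    sin(a) * v[1] + cos(a) * v[3])
}

#' Physical constants for droplet transport
#'
#' Gravity is \eqn{9.81 \, m/s^2} along laboratory \code{-z}, expressed in
#' the (tilted) model frame; the air mean free path sets the Cunningham slip
#' correction.
#'
#' @param model an \code{airway_model} (for the head tilt).
#' @param g_magnitude gravitational acceleration, m/s^2.
#' @param mean_free_path air mean free path, m.
#' @return list with \code{g} (3-vector, model frame), \code{g_magnitude},
#'   \code{mean_free_path}.
#' @export
physical_constants <- function(model, g_magnitude = 9.81,
                               mean_free_path = 6.6e-8) {
  list(g = lab_to_model(model, c(0, 0, -g_magnitude)),
       g_magnitude = g_magnitude,
       mean_free_path = mean_free_path)
}
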