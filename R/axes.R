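#' Spray axis objects
#'
#' A spray axis is an anchor point on the nostril plane plus a unit
#' direction pointing into the airway; the nozzle tip (injection origin)
#' sits \code{insertion_mm} beyond the anchor along the axis, mimicking the
#' recommended shallow nozzle placement.
#'
#' @param protocol one of \code{"CU"}, \code{"IU"}, \code{"PD"}.
#' @param origin anchor point on the nostril plane (model frame, metres).
#' @param direction direction vector (normalized internally).
#' @param insertion_mm nozzle insertion depth beyond the anchor, mm.
#' @return object of class \code{spray_axis}.
#' @export
spray_axis <- function(protocol, origin, direction, insertion_mm = 5) {
  nd <- sqrt(sum(direction^2))
  if (nd <= 0) stop("spray axis direction must be non-zero")
  if (insertion_mm <= 0) stop("insertion depth must be positive")
  structure(list(protocol = protocol,
                 origin = as.numeric(origin),
                 direction = as.numeric(direction) / nd,
                 insertion_mm = insertion_mm),
            class = "spray_axis")
}

#' @export
print.spray_axis <- function(x, ...) {
  cat(sprintf("%s spray axis: anchor (%.1f, %.1f, %.1f) mm, direction (%.3f, %.3f, %.3f), insertion %g mm\n",
              x$protocol, 1e3 * x$origin[1], 1e3 * x$origin[2], 1e3 * x$origin[3],
              x$direction[1], x$direction[2], x$direction[3], x$insertion_mm))
  invisible(x)
}

#' Nozzle tip position of a spray axis
#' @param axis a \code{spray_axis}.
#' @return 3-vector, metres.
#' @export
axis_injection_point <- function(axis) {
  axis$origin + axis$insertion_mm * 1e-3 * axis$direction
}

#' Current Use (CU) spray axis
#'
#' The package-insert orientation: spray bottle held upright (axis vertical
#' in the laboratory frame, i.e. tilted posteriorly by the head-tilt angle in
#' the model frame), anchored at one-third of the distance from the lateral
#' wall toward the septal wall on the nostril plane, nozzle inserted 5 mm.
#'
#' @param model an \code{airway_model}.
#' @param insertion_mm nozzle insertion depth, mm.
#' @return a \code{spray_axis}.
#' @export
cu_axis <- function(model, insertion_mm = 5) {
  r0 <- airway_radius(model, 0)
  # lateral wall at y = lat_sign * r0, septal wall at y = -lat_sign * r0;
  # one third of the way from lateral toward septal:
  anchor <- c(0, model$lat_sign * r0 / 3, 0)
  spray_axis("CU", anchor, lab_to_model(model, c(0, 0, 1)), insertion_mm)
}

#' Improved Use (IU) spray axis
#'
#' A shallower, nearly horizontal orientation aimed through the nasopharynx
#' and slightly toward the cheek (lateral wall): the axis runs from the
#' nostril-plane centroid toward a point in the nasopharyngeal band, offset
#' laterally by a fraction of the local tube radius.
#'
#' @param model an \code{airway_model}.
#' @param target_s arc-length fraction of the aim point (inside the
#'   nasopharynx band).
#' @param lateral_frac lateral offset of the aim point as a fraction of the
#'   local tube radius (positive = toward the cheek).
#' @param insertion_mm nozzle insertion depth, mm.
#' @return a \code{spray_axis}.
#' @export
iu_axis <- function(model, target_s = 0.925, lateral_frac = 0.5,
                    insertion_mm = 5) {
  target <- centerline_point(model, target_s) +
    lateral_frac * airway_radius(model, target_s) * c(0, model$lat_sign, 0)
  spray_axis("IU", model$nostril_plane$centroid, target - model$nostril_plane$centroid,
             insertion_mm)
}

#' Validate an Improved Use spray axis
#'
#' Checks the three placement criteria for an improved-orientation axis:
#' (i) the extended axis must pass through the nasopharyngeal sector;
#' (ii) it must not cut through the septal plane while inside the airway;
#' (iii) its first wall intersection must be on the lateral side in the
#' posterior part of the passage (or the axis must leave via the outlet).
#'
#' @param axis a \code{spray_axis} anchored on the nostril plane.
#' @param model an \code{airway_model}.
#' @param posterior_min_s smallest arc-length fraction counted as
#'   "posterior" for criterion (iii).
#' @param t_max,n ray-march extent (m) and resolution.
#' @return list with logical \code{valid} and per-criterion logicals
#'   \code{intersects_nasopharynx}, \code{avoids_septum},
#'   \code{posterior_lateral_wall}.
#' @export
validate_iu_axis <- function(axis, model, posterior_min_s = NULL,
                             t_max = 0.3, n = 1200) {
  if (abs(sum((axis$origin - model$nostril_plane$centroid) *
              model$nostril_plane$normal)) > 1e-9)
    stop("spray axis must be anchored on the nostril plane")
  if (is.null(posterior_min_s)) posterior_min_s <- model$region_bounds$mid[1]

  tt <- seq(t_max / n, t_max, length.out = n)
  s_seen <- numeric(n); wd <- numeric(n); medial <- numeric(n)
  for (i in seq_len(n)) {
    p <- axis$origin + tt[i] * axis$direction
    cl <- classify_point(model, p)
    s_seen[i] <- cl$s
    wd[i] <- cl$wall_distance
    medial[i] <- -model$lat_sign * p[2]
  }
  exit_idx <- which(wd < 0)[1] # first point outside the lumen
  inside <- if (is.na(exit_idx)) seq_len(n) else seq_len(exit_idx)

  crit_i <- any(s_seen >= model$region_bounds$nasopharynx[1])
  crit_ii <- all(medial[inside] <= model$septal_plane$offset)
  if (is.na(exit_idx)) {
    crit_iii <- TRUE # never leaves through a wall within reach: exits posteriorly
  } else {
    p_exit <- axis$origin + tt[exit_idx] * axis$direction
    lateral_side <- model$lat_sign * p_exit[2] >= 0
    crit_iii <- s_seen[exit_idx] >= posterior_min_s && lateral_side
  }
  list(valid = crit_i && crit_ii && crit_iii,
       intersects_nasopharynx = crit_i,
       avoids_septum = crit_ii,
       posterior_lateral_wall = crit_iii)
}

#' Perturbed spray directions around a base axis
#'
#' Low-level direction construction: a circle of radius \code{radius_mm} is
#' placed perpendicular to the base direction at \code{offset_mm} from the
#' anchor; five points equidistant on the circle (72 degrees apart, starting
#' at \code{phase}) define the perturbed directions through the anchor. The
#' perturbation half-angle is \code{atan(radius/offset)}.
#'
#' @param direction base unit direction.
#' @param offset_mm circle offset along the base direction, mm.
#' @param radius_mm circle radius, mm.
#' @param phase azimuthal phase of the first point, degrees.
#' @param ref reference vector fixing the azimuthal origin (projected
#'   perpendicular to \code{direction}).
#' @return 5 x 3 matrix of unit direction vectors.
#' @export
perturb_axis_directions <- function(direction, offset_mm, radius_mm = 1,
                                    phase = 0, ref = c(0, 1, 0)) {
  d <- direction / sqrt(sum(direction^2))
  e1 <- ref - sum(ref * d) * d
  if (sqrt(sum(e1^2)) < 1e-9) { # ref parallel to axis: fall back
    ref <- c(1, 0, 0)
    e1 <- ref - sum(ref * d) * d
  }
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  ang <- (phase + (0:4) * 72) * pi / 180
  centre <- offset_mm * d
  pts <- t(vapply(ang, function(a)
    centre + radius_mm * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  dirs <- pts / sqrt(rowSums(pts^2))
  rownames(dirs) <- paste0("PD", 1:5)
  dirs
}

#' Perturbation set for sensitivity analysis
#'
#' Constructs the five perturbed spray axes (PD1-PD5) around a base
#' improved-orientation axis: a 1-mm-radius circle perpendicular to the
#' perturbed direction at 5 or 10 mm from the nostril-plane centroid, five
#' equidistant peripheral points, each joined to the centroid. The nozzle
#' tip for each PD axis sits 5 mm from the centroid along the axis. Axes
#' failing the improved-use validity criteria are reported, not dropped.
#'
#' @param base a \code{spray_axis} anchored at the nostril-plane centroid.
#' @param model an \code{airway_model}.
#' @param offset_mm 5 or 10 (the tested perturbation levels).
#' @param radius_mm circle radius, mm.
#' @param phase azimuthal phase, degrees.
#' @return object of class \code{perturbation_set}: list with \code{base},
#'   \code{axes} (list of 5 \code{spray_axis}), \code{validity} (per-axis
#'   validation reports), \code{offset_mm}, \code{radius_mm}.
#' @export
perturbed_directions <- function(base, model, offset_mm = 5, radius_mm = 1,
                                 phase = 0) {
  if (!offset_mm %in% c(5, 10))
    stop("offset_mm must be 5 or 10 (the tested perturbation levels)")
  if (sqrt(sum((base$origin - model$nostril_plane$centroid)^2)) > 1e-9)
    stop("base axis must be anchored at the nostril-plane centroid")
  dirs <- perturb_axis_directions(base$direction, offset_mm, radius_mm,
                                  phase, ref = c(0, model$lat_sign, 0))
  axes <- lapply(seq_len(5), function(k)
    spray_axis("PD", base$origin, dirs[k, ], insertion_mm = base$insertion_mm))
  names(axes) <- rownames(dirs)
  validity <- lapply(axes, validate_iu_axis, model = model)
  structure(list(base = base, axes = axes, validity = validity,
                 offset_mm = offset_mm, radius_mm = radius_mm, phase = phase),
            class = "perturbation_set")
}

#' @export
print.perturbation_set <- function(x, ...) {
  cat(sprintf("Perturbation set: 1-mm circle at %g mm offset (half-angle %.2f deg)\n",
              x$offset_mm, atan(x$radius_mm / x$offset_mm) * 180 / pi))
  ok <- vapply(x$validity, `[[`, TRUE, "valid")
  cat("  validity:", paste(sprintf("%s=%s", names(ok), ok), collapse = " "), "\n")
  invisible(x)
}
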