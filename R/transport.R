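geometry_params <- function(model) {
  list(length_m = model$length_m,
       x_tab = model$x_tab, z_tab = model$z_tab, eps_tab = model$eps_tab,
       r_tab = stats::approx(model$radius_s, model$radius_m,
                             xout = model$s_tab)$y,
       vestibule_end = model$region_bounds$vestibule[2],
       anterior_end = model$region_bounds$anterior[2],
       naso_start = model$region_bounds$nasopharynx[1])
}

#' Track a sprayed droplet cloud
#'
#' Integrates every droplet of a monodispersed solid-cone release through
#' the airway under Stokes drag (with Cunningham slip), gravity, and Saffman
#' shear lift, with a trap condition at the cavity wall. Classical RK4 with
#' per-diameter sub-stepping (\eqn{h \le 2\tau}) keeps the stiff drag term
#' of small droplets stable; the flow time-step is \code{dt}.
#'
#' @param model an \code{airway_model}.
#' @param flow a \code{flow_field}.
#' @param inj a \code{spray_injection}.
#' @param constants output of \code{\link{physical_constants}}; computed
#'   from \code{model} when \code{NULL}.
#' @param dt flow time-step, s.
#' @param t_max simulated transport horizon, s; droplets still airborne at
#'   \code{t_max} are counted as such.
#' @return data.frame with one row per droplet: \code{status} (one of
#'   \code{airborne}, \code{trapped}, \code{escaped_outlet},
#'   \code{escaped_nostril}), \code{region} (for trapped droplets),
#'   \code{s_final}, \code{t_final}, final position and velocity columns.
#' @export
track_droplets <- function(model, flow, inj, constants = NULL,
                           dt = 1e-4, t_max = 0.25) {
  if (dt <= 0 || t_max <= 0) stop("dt and t_max must be positive")
  if (is.null(constants)) constants <- physical_constants(model)
  init <- cone_injection(inj, model)
  Cc <- cunningham_slip(inj$diameter_um, constants$mean_free_path)
  res <- .track_cloud_cpp(init$position, init$velocity,
                          inj$diameter_um * 1e-6, inj$density_kg_m3, Cc,
                          geometry_params(model), flow$Q_m3s,
                          flow$air_density, flow$air_viscosity,
                          constants$g, dt, t_max)
  status <- c("airborne", "trapped", "escaped_outlet", "escaped_nostril")[res$status + 1L]
  region <- rep(NA_character_, length(status))
  trapped <- res$status == 1L
  region[trapped] <- c("vestibule", "anterior", "mid", "nasopharynx")[res$region[trapped] + 1L]
  data.frame(status = status, region = region,
             s_final = res$s_final, t_final = res$t_final,
             x = res$position[, 1], y = res$position[, 2],
             z = res$position[, 3],
             vx = res$velocity[, 1], vy = res$velocity[, 2],
             vz = res$velocity[, 3])
}

#' Nasopharyngeal deposition-efficiency curve
#'
#' Runs one monodispersed release per droplet diameter and records the
#' fraction of droplets delivered to the nasopharynx: trapped in the
#' terminal arc-length band, plus droplets leaving through the outlet plane
#' (the bench-experiment convention, where the cast terminated just before
#' the nasopharynx and outflow was counted as nasopharyngeal delivery).
#' Droplets still airborne at the transport horizon count as non-deposited.
#'
#' Each diameter uses its own derived seed (\code{seed + diameter index}),
#' so the curve does not depend on the order in which diameters are run.
#'
#' @param model an \code{airway_model}.
#' @param flow a \code{flow_field}.
#' @param axis a \code{spray_axis} (CU, IU, or a perturbed direction).
#' @param diameters_um droplet diameter grid, micrometres.
#' @param n_droplets droplets per diameter.
#' @param seed base RNG seed.
#' @param cone_half_angle,speed,density_kg_m3 injection parameters, see
#'   \code{\link{spray_injection}}.
#' @param dt,t_max integration controls, see \code{\link{track_droplets}}.
#' @return object of class \code{deposition_curve}: a data.frame with
#'   columns \code{diameter_um}, \code{efficiency}, per-status counts and
#'   \code{mean_final_s}, with protocol / flow / provenance attributes.
#' @export
deposition_curve <- function(model, flow, axis, diameters_um = 1:24,
                             n_droplets = 3000, seed = 1L,
                             cone_half_angle = 27.93, speed = 10,
                             density_kg_m3 = 1500,
                             dt = 1e-4, t_max = 0.25) {
  if (length(diameters_um) < 1 || any(diameters_um <= 0))
    stop("diameter grid must be positive")
  if (is.unsorted(diameters_um, strictly = TRUE))
    stop("diameter grid must be strictly increasing")
  constants <- physical_constants(model)
  rows <- vector("list", length(diameters_um))
  for (i in seq_along(diameters_um)) {
    inj <- spray_injection(axis, diameters_um[i],
                           cone_half_angle = cone_half_angle, speed = speed,
                           n_droplets = n_droplets,
                           density_kg_m3 = density_kg_m3,
                           seed = seed + i)
    tr <- track_droplets(model, flow, inj, constants, dt = dt, t_max = t_max)
    naso <- sum(tr$status == "trapped" & tr$region == "nasopharynx",
                na.rm = TRUE) + sum(tr$status == "escaped_outlet")
    rows[[i]] <- data.frame(
      diameter_um = diameters_um[i],
      efficiency = naso / n_droplets,
      n_trapped = sum(tr$status == "trapped"),
      n_escaped_outlet = sum(tr$status == "escaped_outlet"),
      n_escaped_nostril = sum(tr$status == "escaped_nostril"),
      n_airborne = sum(tr$status == "airborne"),
      mean_final_s = mean(tr$s_final))
  }
  curve <- do.call(rbind, rows)
  structure(curve,
            class = c("deposition_curve", "data.frame"),
            protocol = axis$protocol, flow_lpm = flow$rate_lpm,
            side = model$side, n_droplets = as.integer(n_droplets),
            seed = as.integer(seed))
}

#' Construct a deposition curve from raw efficiencies
#'
#' Used by the synthetic fixture generator and the CSV reader; validates the
#' deposition-curve invariants (efficiencies in \[0,1\], strictly increasing
#' diameter grid).
#'
#' @param diameters_um diameter grid, micrometres.
#' @param efficiency per-diameter nasopharyngeal deposition fraction.
#' @param protocol,flow_lpm,side,n_droplets,seed provenance metadata.
#' @return a \code{deposition_curve}.
#' @export
as_deposition_curve <- function(diameters_um, efficiency, protocol = "IU",
                                flow_lpm = 15, side = "left",
                                n_droplets = NA_integer_, seed = NA_integer_) {
  if (length(diameters_um) != length(efficiency))
    stop("diameters and efficiencies must have equal length")
  if (is.unsorted(diameters_um, strictly = TRUE))
    stop("diameter grid must be strictly increasing")
  if (any(efficiency < 0 | efficiency > 1))
    stop("efficiencies must lie in [0, 1]")
  structure(data.frame(diameter_um = diameters_um, efficiency = efficiency),
            class = c("deposition_curve", "data.frame"),
            protocol = protocol, flow_lpm = flow_lpm, side = side,
            n_droplets = as.integer(n_droplets), seed = as.integer(seed))
}

#' @export
print.deposition_curve <- function(x, ...) {
  cat(sprintf("Nasopharyngeal deposition curve: %s protocol, %g L/min, %s passage\n",
              attr(x, "protocol"), attr(x, "flow_lpm"), attr(x, "side")))
  cat(sprintf("  %d diameters (%g-%g um), peak efficiency %.3f at %g um\n",
              nrow(x), min(x$diameter_um), max(x$diameter_um),
              max(x$efficiency), x$diameter_um[which.max(x$efficiency)]))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Deposition-curve CSV exchange
#'
#' One row per diameter with columns \code{protocol, flow_lpm, side,
#' diameter_um, efficiency, n_droplets, seed}; UTF-8, '.' decimal separator.
#'
#' @param curve a \code{deposition_curve}.
#' @param path file path.
#' @return \code{write_deposition_curve}: the path, invisibly;
#'   \code{read_deposition_curve}: a \code{deposition_curve}.
#' @export
write_deposition_curve <- function(curve, path) {
  df <- data.frame(protocol = attr(curve, "protocol"),
                   flow_lpm = attr(curve, "flow_lpm"),
                   side = attr(curve, "side"),
                   diameter_um = curve$diameter_um,
                   efficiency = curve$efficiency,
                   n_droplets = attr(curve, "n_droplets"),
                   seed = attr(curve, "seed"))
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_deposition_curve
#' @export
read_deposition_curve <- function(path) {
  df <- read.csv(path, fileEncoding = "UTF-8")
  need <- c("protocol", "flow_lpm", "side", "diameter_um", "efficiency")
  if (!all(need %in% names(df)))
    stop("curve CSV must contain columns: ", paste(need, collapse = ", "))
  as_deposition_curve(df$diameter_um, df$efficiency,
                      protocol = df$protocol[1], flow_lpm = df$flow_lpm[1],
                      side = df$side[1],
                      n_droplets = if ("n_droplets" %in% names(df)) df$n_droplets[1] else NA_integer_,
                      seed = if ("seed" %in% names(df)) df$seed[1] else NA_integer_)
}

#' Base plot of one or more deposition curves
#' @param x a \code{deposition_curve}.
#' @param ... further curves to overlay.
#' @param col line colours.
#' @export
plot.deposition_curve <- function(x, ..., col = NULL) {
  curves <- c(list(x), Filter(function(e) inherits(e, "deposition_curve"),
                              list(...)))
  if (is.null(col)) col <- seq_along(curves)
  plot(NA, xlim = range(x$diameter_um),
       ylim = c(0, max(vapply(curves, function(cv) max(cv$efficiency), 0))),
       xlab = "droplet diameter (um)",
       ylab = "nasopharyngeal deposition efficiency")
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$diameter_um, curves[[i]]$efficiency,
                    col = col[i], lwd = 2)
  graphics::legend("topright",
                   legend = vapply(curves, attr, "", "protocol"),
                   col = col, lwd = 2, bty = "n")
  invisible(x)
}
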