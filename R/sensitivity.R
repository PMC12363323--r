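#' Pearson correlation between two deposition curves
#'
#' Sample Pearson correlation over the shared diameter grid, with a
#' two-sided p-value from the t-transform on n - 2 degrees of freedom
#' (optionally an exact permutation p-value). Used to quantify how
#' congruent a perturbed-axis curve is with the base improved-orientation
#' curve.
#'
#' @param curve_a,curve_b \code{deposition_curve}s on identical grids.
#' @param method \code{"t"} for the t-distribution p-value,
#'   \code{"permutation"} for a Monte-Carlo permutation p-value.
#' @param n_perm permutations when \code{method = "permutation"}.
#' @return list with \code{r}, \code{p}, \code{n}, and logical
#'   \code{undefined} (zero variance in either curve).
#' @export
pearson_with_p <- function(curve_a, curve_b, method = c("t", "permutation"),
                           n_perm = 10000) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(curve_a$diameter_um, curve_b$diameter_um)))
    stop("curves must share the same diameter grid")
  a <- curve_a$efficiency; b <- curve_b$efficiency
  n <- length(a)
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  if (method == "t") {
    ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
    return(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                undefined = FALSE))
  }
  r_obs <- stats::cor(a, b)
  r_perm <- replicate(n_perm, stats::cor(a, sample(b)))
  list(r = r_obs, p = (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + n_perm),
       n = n, undefined = FALSE)
}

#' Tolerance report for perturbed spray directions
#'
#' One Pearson (r, p) pair per perturbed direction against the base
#' improved-orientation curve; a direction is flagged robust when r exceeds
#' the congruity threshold and p is below the significance level.
#'
#' @param iu_curve the base-axis \code{deposition_curve}.
#' @param pd_curves named list of perturbed-direction curves on the same
#'   grid and flow rate.
#' @param r_threshold congruity threshold on the correlation.
#' @param alpha significance level.
#' @param ... passed to \code{\link{pearson_with_p}}.
#' @return object of class \code{correlation_report}: data.frame with
#'   columns \code{pd_id, r, p, n, robust, undefined}.
#' @export
tolerance_report <- function(iu_curve, pd_curves, r_threshold = 0.5,
                             alpha = 0.05, ...) {
  flows <- vapply(pd_curves, attr, 0, "flow_lpm")
  if (any(flows != attr(iu_curve, "flow_lpm")))
    stop("all curves must share the inhalation rate")
  ids <- names(pd_curves)
  if (is.null(ids)) ids <- paste0("PD", seq_along(pd_curves))
  rows <- lapply(seq_along(pd_curves), function(k) {
    pw <- pearson_with_p(iu_curve, pd_curves[[k]], ...)
    data.frame(pd_id = ids[k], r = pw$r, p = pw$p, n = pw$n,
               undefined = pw$undefined,
               robust = !pw$undefined && pw$r > r_threshold && pw$p < alpha)
  })
  structure(do.call(rbind, rows),
            class = c("correlation_report", "data.frame"),
            r_threshold = r_threshold, alpha = alpha)
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Spray-axis tolerance report (r > %g, alpha = %g):\n",
              attr(x, "r_threshold"), attr(x, "alpha")))
  print.data.frame(as.data.frame(x), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Simulator-driven sensitivity analysis
#'
#' End-to-end robustness check of the improved spray orientation: builds
#' the base axis and its five perturbed directions, simulates a deposition
#' curve for each, and reports the per-direction Pearson congruity.
#'
#' @param model an \code{airway_model}.
#' @param flow a \code{flow_field}.
#' @param offset_mm perturbation offset (5 or 10 mm).
#' @param seed base seed (each axis derives its own per-diameter seeds).
#' @param diameters_um,n_droplets,dt,t_max simulation controls, see
#'   \code{\link{deposition_curve}}.
#' @param phase azimuthal phase of the perturbation circle, degrees.
#' @param ... passed to \code{\link{tolerance_report}}.
#' @return list with \code{report} (a \code{correlation_report}),
#'   \code{iu_curve}, \code{pd_curves}, \code{perturbation}.
#' @export
sensitivity_analysis <- function(model, flow, offset_mm = 5, seed = 1L,
                                 diameters_um = 1:24, n_droplets = 3000,
                                 dt = 1e-4, t_max = 0.25, phase = 0, ...) {
  base <- iu_axis(model)
  ps <- perturbed_directions(base, model, offset_mm = offset_mm,
                             phase = phase)
  iu_curve <- deposition_curve(model, flow, base, diameters_um,
                               n_droplets = n_droplets, seed = seed,
                               dt = dt, t_max = t_max)
  pd_curves <- lapply(seq_along(ps$axes), function(k)
    deposition_curve(model, flow, ps$axes[[k]], diameters_um,
                     n_droplets = n_droplets, seed = seed + 100 * k,
                     dt = dt, t_max = t_max))
  names(pd_curves) <- names(ps$axes)
  list(report = tolerance_report(iu_curve, pd_curves, ...),
       iu_curve = iu_curve, pd_curves = pd_curves, perturbation = ps)
}
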