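#' Synthetic deposition-curve template
#'
#' Parametric generator of deposition curves with the statistical structure
#' of the study's results — a single Gaussian bump in diameter (improved
#' orientation curves peak in the low teens of micrometres; package-insert
#' orientation curves are near zero) plus truncated Gaussian noise — so the
#' dose and sensitivity layers can be exercised without running the
#' transport simulator.
#'
#' @param peak_efficiency bump height (fraction in \[0, 1\]).
#' @param peak_diameter_um bump centre, micrometres.
#' @param width_um Gaussian bump scale, micrometres.
#' @param noise_sd additive noise standard deviation (fraction).
#' @return object of class \code{curve_template}.
#' @examples
#' iu <- curve_template(0.465, 13)   # the reported IU peak
#' cu <- curve_template(0.0053, 14)  # the reported CU peak
#' make_curve(iu, "IU", 15, seed = 1)
#' @export
curve_template <- function(peak_efficiency, peak_diameter_um, width_um = 4,
                           noise_sd = 0) {
  if (peak_efficiency < 0 || peak_efficiency > 1)
    stop("peak efficiency must lie in [0, 1]")
  if (peak_diameter_um <= 0 || width_um <= 0)
    stop("peak diameter and width must be positive")
  if (noise_sd < 0) stop("noise sd cannot be negative")
  structure(list(peak_efficiency = peak_efficiency,
                 peak_diameter_um = peak_diameter_um,
                 width_um = width_um, noise_sd = noise_sd),
            class = "curve_template")
}

#' Generate a synthetic deposition curve
#'
#' \eqn{\eta(x) = \eta_{peak} e^{-(x - x_{peak})^2 / (2 w^2)}} on the
#' diameter grid, plus Gaussian noise, clipped to \[0, 1\]. Deterministic
#' for a fixed seed; an exact closed form when \code{noise_sd = 0}.
#'
#' @param template a \code{curve_template}.
#' @param protocol,flow_lpm,side curve metadata.
#' @param diameters_um diameter grid.
#' @param seed RNG seed for the noise.
#' @return a \code{deposition_curve}.
#' @export
make_curve <- function(template, protocol = "IU", flow_lpm = 15,
                       side = "left", diameters_um = 1:24, seed = 1L) {
  x <- diameters_um
  eta <- template$peak_efficiency *
    exp(-(x - template$peak_diameter_um)^2 / (2 * template$width_um^2))
  if (template$noise_sd > 0) {
    set.seed(seed)
    eta <- eta + rnorm(length(x), sd = template$noise_sd)
  }
  as_deposition_curve(x, pmin(pmax(eta, 0), 1), protocol = protocol,
                      flow_lpm = flow_lpm, side = side, seed = seed)
}

#' Paired synthetic case set
#'
#' Generates matched IU/CU curve pairs emulating a multi-case study
#' (two subjects x two nostrils x two inhalation rates gives the eight
#' cases of the source design): per case the peak height and position are
#' jittered multiplicatively around the templates.
#'
#' @param iu_template,cu_template \code{curve_template}s for the two
#'   protocols.
#' @param n_cases number of matched cases.
#' @param seed base seed; case k uses \code{seed + k}.
#' @param peak_jitter_sd log-normal jitter sd on the peak height.
#' @param center_jitter_sd Gaussian jitter sd (um) on the peak position.
#' @param diameters_um diameter grid.
#' @return list with \code{iu} and \code{cu} (lists of
#'   \code{deposition_curve}s).
#' @export
make_case_set <- function(iu_template, cu_template, n_cases = 8, seed = 1L,
                          peak_jitter_sd = 0, center_jitter_sd = 0,
                          diameters_um = 1:24) {
  if (n_cases < 1) stop("need at least one case")
  iu <- vector("list", n_cases)
  cu <- vector("list", n_cases)
  for (k in seq_len(n_cases)) {
    set.seed(seed + k)
    jp <- exp(rnorm(2, sd = peak_jitter_sd))
    jc <- rnorm(2, sd = center_jitter_sd)
    iu_t <- curve_template(min(1, iu_template$peak_efficiency * jp[1]),
                           max(1, iu_template$peak_diameter_um + jc[1]),
                           iu_template$width_um, iu_template$noise_sd)
    cu_t <- curve_template(min(1, cu_template$peak_efficiency * jp[2]),
                           max(1, cu_template$peak_diameter_um + jc[2]),
                           cu_template$width_um, cu_template$noise_sd)
    iu[[k]] <- make_curve(iu_t, "IU", diameters_um = diameters_um,
                          seed = seed + 1000 + k)
    cu[[k]] <- make_curve(cu_t, "CU", diameters_um = diameters_um,
                          seed = seed + 2000 + k)
  }
  list(iu = iu, cu = cu)
}
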