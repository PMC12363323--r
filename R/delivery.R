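#' Ideal droplet size range from a deposition curve
#'
#' The interval of simulated diameters whose nasopharyngeal deposition
#' efficiency meets the cutoff (at least 2 percent by default). Returns an
#' empty-flagged range when no diameter qualifies.
#'
#' @param curve a \code{deposition_curve}.
#' @param cutoff efficiency threshold (fraction).
#' @return a \code{size_range}.
#' @export
ideal_size_range <- function(curve, cutoff = 0.02) {
  if (nrow(curve) < 1) stop("deposition curve is empty")
  ok <- curve$efficiency >= cutoff
  if (!any(ok))
    return(size_range(NA_real_, NA_real_, attr(curve, "flow_lpm"),
                      cutoff = cutoff, empty = TRUE))
  size_range(min(curve$diameter_um[ok]), max(curve$diameter_um[ok]),
             attr(curve, "flow_lpm"), cutoff = cutoff)
}

#' Generic ideal size range over test cases
#'
#' Averages the per-case minimum and maximum ideal diameters (arithmetic
#' mean of the lower limits, arithmetic mean of the upper limits), the way
#' a multi-case study pools its per-case extrema into one practical range.
#'
#' @param ranges list of non-empty \code{size_range} objects.
#' @return a \code{size_range} (flow rate is dropped: the pooled range
#'   spans cases at different rates).
#' @export
generic_range <- function(ranges) {
  if (length(ranges) < 1) stop("need at least one size range")
  if (any(vapply(ranges, `[[`, TRUE, "empty")))
    stop("cannot average empty size ranges")
  size_range(mean(vapply(ranges, `[[`, 0, "D_min")),
             mean(vapply(ranges, `[[`, 0, "D_max")),
             flow_lpm = NA_real_,
             cutoff = ranges[[1]]$cutoff)
}

#' Distribution-weighted nasopharyngeal deposition per pump
#'
#' Links a deposition-efficiency curve with a product's droplet mass
#' distribution: the deposited formulation mass per pump is
#' \deqn{m_{dep} = M_{shot} \int \eta(x)\, m(x)\, dx}
#' over the simulated 1-24 um window, with the efficiency \eqn{\eta}
#' linearly interpolated between grid diameters and taken as zero outside
#' the simulated range (droplets larger than 24 um mostly deposit
#' anteriorly and miss the nasopharynx).
#'
#' @param curve a \code{deposition_curve} covering \code{window}.
#' @param product a \code{spray_product}.
#' @param window diameter interval (um) over which deposition is credited.
#' @return deposited formulation mass, mg per pump.
#' @export
weighted_deposition <- function(curve, product, window = c(1, 24)) {
  d <- curve$diameter_um
  if (min(d) > window[1] || max(d) < window[2])
    stop("deposition curve must cover the weighting window [",
         window[1], ", ", window[2], "] um")
  eta <- approxfun(d, curve$efficiency, rule = 2)
  dist <- product$distribution
  integrand <- function(x) eta(x) * mass_pdf(dist, x)
  # integrate per grid segment: the integrand is piecewise smooth there
  knots <- sort(unique(c(window, d[d > window[1] & d < window[2]])))
  total <- 0
  for (i in seq_len(length(knots) - 1))
    total <- total + integrate(integrand, knots[i], knots[i + 1],
                               rel.tol = 1e-10)$value
  product$shot_mass_mg * total
}

#' API mass delivered per pump
#'
#' Active pharmaceutical ingredient mass corresponding to a deposited
#' formulation mass, \code{deposited_mg * api_mcg_per_mg}. Values are
#' returned at full precision; reports round to two significant figures
#' (see \code{round_api}), the convention the printed product estimates
#' follow.
#'
#' @param deposited_mg deposited formulation mass, mg.
#' @param product a \code{spray_product} (or a numeric concentration in
#'   mcg per mg).
#' @return API mass, mcg.
#' @examples
#' round_api(api_mass(1.9187, 0.5)) # 0.96
#' @export
api_mass <- function(deposited_mg, product) {
  if (any(deposited_mg < 0)) stop("deposited mass cannot be negative")
  conc <- if (inherits(product, "spray_product")) product$api_mcg_per_mg
          else as.numeric(product)
  deposited_mg * conc
}

#' @rdname api_mass
#' @param x API mass, mcg.
#' @export
round_api <- function(x) signif(x, 2)

#' Per-pump delivery estimate
#'
#' @param product a \code{spray_product}.
#' @param curve a \code{deposition_curve} for one protocol / flow case.
#' @param window diameter weighting window, um.
#' @return object of class \code{delivery_estimate} with
#'   \code{deposited_mass_mg}, \code{api_mcg}, protocol and provenance.
#' @export
delivery_estimate <- function(product, curve, window = c(1, 24)) {
  dep <- weighted_deposition(curve, product, window)
  structure(list(product = product$name,
                 protocol = attr(curve, "protocol"),
                 flow_lpm = attr(curve, "flow_lpm"),
                 side = attr(curve, "side"),
                 deposited_mass_mg = dep,
                 api_mcg = api_mass(dep, product)),
            class = "delivery_estimate")
}

#' @export
print.delivery_estimate <- function(x, ...) {
  cat(sprintf("%s, %s protocol @ %g L/min: %.4f mg formulation, %.2g mcg API per pump\n",
              x$product, x$protocol, x$flow_lpm, x$deposited_mass_mg,
              round_api(x$api_mcg)))
  invisible(x)
}

#' Orders-of-magnitude improvement of IU over CU delivery
#'
#' \eqn{\log_{10}} of the ratio of the improved-orientation deposited mass
#' to the package-insert-orientation deposited mass for one matched case.
#'
#' @param iu,cu \code{delivery_estimate} objects (or deposited masses, mg)
#'   for the same product and flow case.
#' @return orders of magnitude (dimensionless); \code{Inf} with a warning
#'   when the CU mass is zero.
#' @examples
#' improvement_oom(1.9187, 0.0495) # 1.588
#' @export
improvement_oom <- function(iu, cu) {
  m_iu <- if (inherits(iu, "delivery_estimate")) iu$deposited_mass_mg else iu
  m_cu <- if (inherits(cu, "delivery_estimate")) cu$deposited_mass_mg else cu
  if (m_cu < 0 || m_iu < 0) stop("deposited masses cannot be negative")
  if (m_cu == 0) {
    warning("CU deposited mass is zero: improvement is unbounded")
    return(Inf)
  }
  log10(m_iu / m_cu)
}

#' Summary of improvement over a set of cases
#'
#' Sample mean and standard deviation (n-1 denominator) of the per-case
#' orders-of-magnitude improvements; unbounded (infinite) cases are
#' excluded with a warning.
#'
#' @param iu_list,cu_list matched lists of \code{delivery_estimate}s or
#'   deposited masses.
#' @return list with \code{mean}, \code{sd}, \code{n}, \code{oom}
#'   (per-case values).
#' @export
summarize_improvement <- function(iu_list, cu_list) {
  if (length(iu_list) != length(cu_list))
    stop("IU and CU case lists must be matched")
  oom <- suppressWarnings(
    mapply(improvement_oom, iu_list, cu_list))
  if (any(!is.finite(oom))) {
    warning(sum(!is.finite(oom)),
            " case(s) with zero CU mass excluded from the summary")
    oom_f <- oom[is.finite(oom)]
  } else oom_f <- oom
  list(mean = mean(oom_f), sd = sd(oom_f), n = length(oom_f), oom = oom)
}
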