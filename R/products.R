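#' Log-normal spray droplet size distribution
#'
#' Mass probability density of droplet diameters in an administered shot,
#' \deqn{m(x) = \frac{1}{\sqrt{2\pi}\, x \ln\sigma_g}
#'   \exp\!\left(-\frac{(\ln x - \ln x_{50})^2}{2 \ln^2\sigma_g}\right),}
#' parameterized by the mass median diameter \eqn{x_{50}} (50 percent of the
#' sprayed mass is in droplets smaller than \eqn{x_{50}}) and the geometric
#' standard deviation \eqn{\sigma_g > 1}.
#'
#' @param x50 mass median diameter, micrometres.
#' @param sigma_g geometric standard deviation (dimensionless, > 1).
#' @return object of class \code{size_distribution}.
#' @examples
#' fl <- size_distribution(37.16, 2.080)
#' mass_pdf(fl, 37.16)
#' mass_fraction(fl, 1, 24)
#' @export
size_distribution <- function(x50, sigma_g) {
  if (x50 <= 0) stop("mass median diameter must be positive")
  if (sigma_g <= 1) stop("geometric standard deviation must exceed 1")
  structure(list(x50 = x50, sigma_g = sigma_g,
                 meanlog = log(x50), sdlog = log(sigma_g)),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("Log-normal mass distribution: x50 = %g um, sigma_g = %g\n",
              x$x50, x$sigma_g))
  invisible(x)
}

#' Mass probability density of droplet diameter
#' @param dist a \code{size_distribution}.
#' @param x droplet diameter(s), micrometres (> 0).
#' @return density per micrometre.
#' @export
mass_pdf <- function(dist, x) {
  if (any(x <= 0)) stop("diameter must be positive")
  1 / (sqrt(2 * pi) * x * dist$sdlog) *
    exp(-(log(x) - dist$meanlog)^2 / (2 * dist$sdlog^2))
}

#' Cumulative mass fraction below a diameter
#' @inheritParams mass_pdf
#' @return fraction of sprayed mass in droplets smaller than \code{x}.
#' @export
mass_cdf <- function(dist, x) {
  if (any(x <= 0)) stop("diameter must be positive")
  plnorm(x, meanlog = dist$meanlog, sdlog = dist$sdlog)
}

#' Mass fraction in a diameter interval
#'
#' Closed-form integral of the mass density between \code{a} and \code{b}
#' via the Gaussian error function of \eqn{\ln x}.
#'
#' @inheritParams mass_pdf
#' @param a,b interval limits, micrometres, \code{0 < a < b}.
#' @return fraction in \[0, 1\].
#' @export
mass_fraction <- function(dist, a, b) {
  if (any(a <= 0)) stop("interval limits must be positive")
  if (any(a >= b)) stop("need a < b")
  mass_cdf(dist, b) - mass_cdf(dist, a)
}

#' Droplet count density and absolute counts
#'
#' Converts the mass density to a number (count) density for spherical
#' droplets of constant formulation density: the count density is
#' proportional to \eqn{m(x)/x^3}, normalized over a stated interval
#' (the observed 1-24 um tracking window by default). For an absolute count
#' in a shot of known mass, each droplet of diameter \eqn{x} carries mass
#' \eqn{\rho_D \pi x^3 / 6}.
#'
#' @inheritParams mass_pdf
#' @param normalize_over interval (um) over which the relative density
#'   integrates to 1.
#' @return \code{count_density}: relative density per micrometre.
#' @export
count_density <- function(dist, x, normalize_over = c(1, 24)) {
  if (any(x <= 0)) stop("diameter must be positive")
  raw <- function(xx) mass_pdf(dist, xx) / xx^3
  norm <- integrate(raw, normalize_over[1], normalize_over[2],
                    rel.tol = 1e-10)$value
  raw(x) / norm
}

#' @rdname count_density
#' @param shot_mass_mg sprayed mass, mg.
#' @param interval diameter interval (um) to count droplets in.
#' @param density_kg_m3 formulation density.
#' @return \code{droplet_count}: expected number of droplets of the shot
#'   falling in \code{interval}.
#' @export
droplet_count <- function(dist, shot_mass_mg = 1, interval = c(1, 24),
                          density_kg_m3 = 1500) {
  # mass in [x, x+dx] is shot_mass * m(x) dx; droplet mass is rho * pi x^3/6
  # (x in um -> m^3 factor 1e-18); shot mass mg -> kg factor 1e-6
  per_um <- function(x) {
    droplet_mass_kg <- density_kg_m3 * pi * (x * 1e-6)^3 / 6
    shot_mass_mg * 1e-6 * mass_pdf(dist, x) / droplet_mass_kg
  }
  integrate(per_um, interval[1], interval[2], rel.tol = 1e-10)$value
}

#' Commercial spray product
#'
#' Bundles a size distribution with the per-pump shot mass and the API
#' (active pharmaceutical ingredient) concentration of a marketed product.
#'
#' @param name product name.
#' @param distribution a \code{size_distribution}.
#' @param shot_mass_mg formulation mass per pump, mg.
#' @param api_mcg_per_mg API concentration, mcg per mg of formulation.
#' @return object of class \code{spray_product}.
#' @export
spray_product <- function(name, distribution, shot_mass_mg, api_mcg_per_mg) {
  if (shot_mass_mg <= 0) stop("shot mass must be positive")
  if (api_mcg_per_mg < 0) stop("API concentration cannot be negative")
  structure(list(name = name, distribution = distribution,
                 shot_mass_mg = shot_mass_mg,
                 api_mcg_per_mg = api_mcg_per_mg),
            class = "spray_product")
}

#' @export
print.spray_product <- function(x, ...) {
  cat(sprintf("%s: x50 = %g um, sigma_g = %g, %g mg/pump, %g mcg API/mg\n",
              x$name, x$distribution$x50, x$distribution$sigma_g,
              x$shot_mass_mg, x$api_mcg_per_mg))
  invisible(x)
}

#' Built-in product registry
#'
#' The two measured over-the-counter products: Flonase (fluticasone
#' propionate; x50 = 37.16 um, sigma_g = 2.080, 104.51 mg per pump,
#' 50 mcg API per 100 mg formulation) and Nasacort (triamcinolone
#' acetonide; x50 = 43.81 um, sigma_g = 1.994, 97.64 mg per pump,
#' 55 mcg API per 110 mg formulation).
#'
#' @param name product name (case-insensitive); \code{NULL} lists the
#'   registry.
#' @param registry_file optional YAML file with entries
#'   \code{name, x50_um, sigma_g, shot_mass_mg, api_mcg_per_mg} replacing
#'   the built-ins.
#' @return a \code{spray_product}, or a data.frame when \code{name} is
#'   \code{NULL}.
#' @export
product_registry <- function(name = NULL, registry_file = NULL) {
  if (is.null(registry_file)) {
    reg <- data.frame(
      name = c("Flonase", "Nasacort"),
      x50_um = c(37.16, 43.81),
      sigma_g = c(2.080, 1.994),
      shot_mass_mg = c(104.51, 97.64),
      api_mcg_per_mg = c(50 / 100, 55 / 110))
  } else {
    raw <- yaml::read_yaml(registry_file)
    reg <- do.call(rbind, lapply(raw, as.data.frame))
  }
  if (is.null(name)) return(reg)
  hit <- which(tolower(reg$name) == tolower(name))
  if (length(hit) != 1L)
    stop("unknown spray product: ", name,
         " (registry has: ", paste(reg$name, collapse = ", "), ")")
  spray_product(reg$name[hit],
                size_distribution(reg$x50_um[hit], reg$sigma_g[hit]),
                reg$shot_mass_mg[hit], reg$api_mcg_per_mg[hit])
}
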