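run_config_schema <- list(
  airway = c("length_m", "elevation_profile", "radius_profile", "tilt_deg",
             "nasopharynx_start_s", "vestibule_end_s", "anterior_end_s",
             "side", "septum_frac"),
  flow = c("rate_lpm"),
  spray = c("cone_half_angle_deg", "speed_mps", "n_droplets", "insertion_mm",
            "density_kg_m3"),
  transport = c("dt_s", "t_max_s", "diameters_um"),
  analysis = c("cutoff", "products", "window_um"),
  sensitivity = c("enabled", "offset_mm", "phase_deg"),
  fixtures = c("enabled", "iu", "cu", "n_cases"),
  seeds = c("base"))

#' Default run configuration
#'
#' All defaults reproduce the study's stated protocol parameters: cone
#' half-angle 27.93 degrees, 10 m/s injection speed, 3,000 droplets per
#' release, 5 mm insertion, 1.5 g/mL formulation density, 1-24 um diameter
#' grid, 2 percent efficiency cutoff, 22.5 degree head tilt.
#'
#' @return nested list of configuration blocks.
#' @export
default_run_config <- function() {
  list(
    airway = list(length_m = 0.10,
                  elevation_profile = list(c(0, 45), c(0.12, 12), c(0.8, 5),
                                           c(1, -45)),
                  radius_profile = list(c(0, 7.0), c(0.12, 5.5), c(0.5, 6.5),
                                        c(0.85, 5.5), c(1, 6.0)),
                  tilt_deg = 22.5, nasopharynx_start_s = 0.85,
                  vestibule_end_s = 0.10, anterior_end_s = 0.45,
                  side = "left", septum_frac = 0.5),
    flow = list(rate_lpm = 15),
    spray = list(cone_half_angle_deg = 27.93, speed_mps = 10,
                 n_droplets = 3000, insertion_mm = 5, density_kg_m3 = 1500),
    transport = list(dt_s = 1e-4, t_max_s = 0.25, diameters_um = 1:24),
    analysis = list(cutoff = 0.02, products = c("Flonase", "Nasacort"),
                    window_um = c(1, 24)),
    sensitivity = list(enabled = FALSE, offset_mm = 5, phase_deg = 0),
    fixtures = list(enabled = FALSE,
                    iu = list(peak_efficiency = 0.465, peak_diameter_um = 13,
                              width_um = 4, noise_sd = 0),
                    cu = list(peak_efficiency = 0.0053, peak_diameter_um = 14,
                              width_um = 4, noise_sd = 0),
                    n_cases = 1),
    seeds = list(base = 1L))
}

check_config_keys <- function(config) {
  unknown_blocks <- setdiff(names(config), names(run_config_schema))
  if (length(unknown_blocks))
    stop("unknown configuration block(s): ",
         paste(unknown_blocks, collapse = ", "))
  for (blk in names(config)) {
    extra <- setdiff(names(config[[blk]]), run_config_schema[[blk]])
    if (length(extra))
      stop("unknown key(s) in '", blk, "' block: ",
           paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, and fills missing
#' values from \code{\link{default_run_config}}.
#'
#' @param path YAML file path, or \code{NULL} for the defaults.
#' @param overrides named list merged over the file values.
#' @return validated configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- if (is.null(path)) list() else yaml::read_yaml(path)
  check_config_keys(config)
  check_config_keys(overrides)
  config <- modifyList(default_run_config(), config)
  config <- modifyList(config, overrides)
  config
}

config_airway <- function(config) {
  a <- config$airway
  rp <- do.call(rbind, lapply(a$radius_profile, as.numeric))
  ep <- do.call(rbind, lapply(a$elevation_profile, as.numeric))
  airway_model(length_m = a$length_m, elevation_profile = ep,
               radius_profile = rp, tilt_deg = a$tilt_deg,
               nasopharynx_start_s = a$nasopharynx_start_s,
               vestibule_end_s = a$vestibule_end_s,
               anterior_end_s = a$anterior_end_s, side = a$side,
               septum_frac = a$septum_frac)
}

# stable FNV-1a hash of the deparsed configuration, for provenance stamps
# (arithmetic kept in doubles below 2^53 to avoid integer overflow)
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  h <- 2166136261
  prime <- 16777619
  for (b in utf8ToInt(txt)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (prime * lo + ((prime * hi) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline
#'
#' Executes the stages of the targeting analysis per the run configuration:
#' deposition curves for the CU and IU axes (simulated, or generated from
#' fixture templates when \code{fixtures$enabled}), ideal size ranges with
#' Stokes projection to the other inhalation rate, distribution-weighted
#' per-pump dose and API delivery per product, IU-over-CU improvement, and
#' (optionally) the perturbed-axis sensitivity analysis. Writes curve CSVs
#' and a JSON report stamped with the configuration hash and seeds; outputs
#' are byte-identical for identical configuration and seeds.
#'
#' @param config configuration list from \code{\link{read_run_config}}.
#' @param out_dir output directory (created if missing).
#' @return the report, invisibly.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir = ".") {
  check_config_keys(config)
  config <- modifyList(default_run_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seeds$base)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("nasodose %s | config %s | seed %d",
       as.character(utils::packageVersion("nasodose")),
       config_hash(config), seed)

  stage <- "configuration"
  report <- list(package_version = as.character(utils::packageVersion("nasodose")),
                 config_hash = config_hash(config), seed = seed)
  tryCatch({
    stage <- "curves"
    if (isTRUE(config$fixtures$enabled)) {
      logf("stage curves: fixture templates (no transport simulation)")
      iu_t <- do.call(curve_template, config$fixtures$iu)
      cu_t <- do.call(curve_template, config$fixtures$cu)
      iu_curve <- make_curve(iu_t, "IU", config$flow$rate_lpm,
                             diameters_um = config$transport$diameters_um,
                             seed = seed)
      cu_curve <- make_curve(cu_t, "CU", config$flow$rate_lpm,
                             diameters_um = config$transport$diameters_um,
                             seed = seed + 1)
      model <- NULL
    } else {
      logf("stage curves: Lagrangian simulation, %d droplets x %d diameters",
           config$spray$n_droplets, length(config$transport$diameters_um))
      model <- config_airway(config)
      flow <- flow_field(config$flow$rate_lpm)
      sim_curve <- function(axis, sd) deposition_curve(
        model, flow, axis, config$transport$diameters_um,
        n_droplets = config$spray$n_droplets, seed = sd,
        cone_half_angle = config$spray$cone_half_angle_deg,
        speed = config$spray$speed_mps,
        density_kg_m3 = config$spray$density_kg_m3,
        dt = config$transport$dt_s, t_max = config$transport$t_max_s)
      iu_curve <- sim_curve(iu_axis(model, insertion_mm = config$spray$insertion_mm), seed)
      cu_curve <- sim_curve(cu_axis(model, insertion_mm = config$spray$insertion_mm), seed + 5000)
    }
    write_deposition_curve(iu_curve, file.path(out_dir, "curve_iu.csv"))
    write_deposition_curve(cu_curve, file.path(out_dir, "curve_cu.csv"))

    stage <- "size ranges"
    r_iu <- ideal_size_range(iu_curve, config$analysis$cutoff)
    other_rate <- if (config$flow$rate_lpm == 15) 30 else 15
    report$ideal_range_iu <- list(
      D_min_um = r_iu$D_min, D_max_um = r_iu$D_max, empty = r_iu$empty,
      flow_lpm = config$flow$rate_lpm)
    if (!r_iu$empty) {
      pr <- project_range(r_iu, other_rate)
      report$projected_range <- list(D_min_um = round(pr$D_min, 2),
                                     D_max_um = round(pr$D_max, 2),
                                     flow_lpm = other_rate)
    }
    logf("stage size ranges: done")

    stage <- "dose"
    if (length(config$analysis$products) < 1)
      stop("configuration field analysis$products must name at least one spray product")
    report$dose <- lapply(config$analysis$products, function(pname) {
      prod <- product_registry(pname)
      iu <- delivery_estimate(prod, iu_curve, config$analysis$window_um)
      cu <- delivery_estimate(prod, cu_curve, config$analysis$window_um)
      list(product = prod$name,
           iu = list(deposited_mass_mg = iu$deposited_mass_mg,
                     api_mcg = round_api(iu$api_mcg)),
           cu = list(deposited_mass_mg = cu$deposited_mass_mg,
                     api_mcg = round_api(cu$api_mcg)),
           improvement_oom = improvement_oom(iu, cu))
    })
    logf("stage dose: done")

    if (isTRUE(config$sensitivity$enabled)) {
      stage <- "sensitivity"
      if (isTRUE(config$fixtures$enabled))
        stop("sensitivity analysis requires the transport simulator (disable fixtures)")
      sens <- sensitivity_analysis(model, flow_field(config$flow$rate_lpm),
                                   offset_mm = config$sensitivity$offset_mm,
                                   seed = seed,
                                   diameters_um = config$transport$diameters_um,
                                   n_droplets = config$spray$n_droplets,
                                   dt = config$transport$dt_s,
                                   t_max = config$transport$t_max_s,
                                   phase = config$sensitivity$phase_deg)
      write.csv(as.data.frame(sens$report),
                file.path(out_dir, "tolerance.csv"), row.names = FALSE,
                quote = FALSE)
      report$sensitivity <- list(median_r = stats::median(sens$report$r),
                                 n_robust = sum(sens$report$robust))
      logf("stage sensitivity: done")
    }
  }, error = function(e) {
    logf("ERROR in stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("pipeline complete")
  invisible(report)
}
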