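# shared fixtures built in code

default_model <- function() airway_model()

# deposition curve from raw efficiencies on the 1-24 um grid
curve_from <- function(eff, protocol = "IU", flow = 15) {
  as_deposition_curve(seq_along(eff), eff, protocol = protocol,
                      flow_lpm = flow)
}

# a single-droplet injection at a chosen point, for settling / decay checks
point_injection <- function(position, diameter_um, speed = 1e-6,
                            direction = c(1, 0, 0), seed = 1) {
  ax <- spray_axis("IU", position - 5e-3 * direction / sqrt(sum(direction^2)),
                   direction, insertion_mm = 5)
  spray_injection(ax, diameter_um, cone_half_angle = 1e-3, speed = speed,
                  n_droplets = 1, seed = seed)
}

# air properties used throughout
AIR_MU <- 1.825e-5
AIR_RHO <- 1.204
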