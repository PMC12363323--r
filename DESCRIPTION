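Package: nasodose
Title: Reduced-Order Modelling of Intranasal Spray Targeting of the Nasopharynx
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lagrangian droplet-deposition simulation and dose analysis for
    intranasal spray delivery to the nasopharynx. Provides an idealized
    curved-tube nasal passage with an analytic laminar inhalation flow field,
    a compiled Runge-Kutta tracker for sprayed droplet clouds under Stokes
    drag, gravity and Saffman lift with trap walls, Stokes-number scaling of
    ideal droplet size ranges across inhalation rates, log-normal spray
    product size distributions with mass/count conversion, distribution-
    weighted per-pump nasopharyngeal formulation and active-ingredient dose
    estimates, orders-of-magnitude comparison of spray orientation protocols,
    and spray-axis perturbation sensitivity analysis via Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
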