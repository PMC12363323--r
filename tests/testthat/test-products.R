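flonase_dist <- function() size_distribution(37.16, 2.080)
nasacort_dist <- function() size_distribution(43.81, 1.994)

test_that("mass density at the median matches hand evaluation (exponent zero)", {
  # 1 / (sqrt(2 pi) * x50 * ln sigma_g)
  expect_equal(mass_pdf(flonase_dist(), 37.16), 1.466e-2, tolerance = 1e-3)
  expect_equal(mass_pdf(flonase_dist(), 37.16),
               1 / (sqrt(2 * pi) * 37.16 * log(2.080)), tolerance = 1e-12)
  expect_error(mass_pdf(flonase_dist(), -1), "positive")
})

test_that("mass distribution is normalized with median at x50 for both products", {
  for (dist in list(flonase_dist(), nasacort_dist())) {
    total <- integrate(function(x) mass_pdf(dist, x), 0, Inf,
                       rel.tol = 1e-10)$value
    expect_lt(abs(total - 1), 1e-6)
    expect_lt(abs(mass_cdf(dist, dist$x50) - 0.5), 1e-9)
  }
})

test_that("closed-form mass fraction agrees with adaptive quadrature on random intervals", {
  set.seed(3)
  dist <- flonase_dist()
  for (i in 1:100) {
    ab <- sort(exp(runif(2, log(0.5), log(300))))
    if (ab[1] == ab[2]) next
    quad <- integrate(function(x) mass_pdf(dist, x), ab[1], ab[2],
                      rel.tol = 1e-12)$value
    expect_lt(abs(mass_fraction(dist, ab[1], ab[2]) - quad), 1e-8)
  }
})

test_that("one-geometric-sd band holds 68.27% of the mass, symmetrically in log space", {
  dist <- nasacort_dist()
  k <- 1
  band <- mass_fraction(dist, dist$x50 / dist$sigma_g^k,
                        dist$x50 * dist$sigma_g^k)
  expect_equal(band, 2 * pnorm(k) - 1, tolerance = 1e-12)
  for (r in c(1.3, 2, 5)) {
    expect_equal(mass_fraction(dist, dist$x50 / r, dist$x50),
                 mass_fraction(dist, dist$x50, dist$x50 * r),
                 tolerance = 1e-12)
  }
})

test_that("mass fraction in the tracked window matches Monte-Carlo sampling", {
  dist <- flonase_dist()
  set.seed(4)
  n <- 1e6
  x <- rlnorm(n, meanlog = log(37.16), sdlog = log(2.080))
  mc <- mean(x >= 1 & x <= 24)
  se <- sqrt(mc * (1 - mc) / n)
  expect_lt(abs(mass_fraction(dist, 1, 24) - mc), 3 * se)
})

test_that("count distribution shifts toward small sizes", {
  dist <- flonase_dist()
  # number-weighted log-normal has median x50 * exp(-3 ln^2 sigma_g)
  expected_median <- dist$x50 * exp(-3 * log(dist$sigma_g)^2)
  wide <- c(0.01, 2000)
  cdf <- function(m) integrate(function(x) count_density(dist, x, wide),
                               wide[1], m, rel.tol = 1e-10)$value
  med <- uniroot(function(m) cdf(m) - 0.5, c(0.1, 37), tol = 1e-8)$root
  expect_equal(med, expected_median, tolerance = 5e-3)
  expect_lt(med, dist$x50)
})

test_that("near-degenerate spread concentrates both densities at x50", {
  dist <- size_distribution(20, 1.0001)
  expect_gt(mass_fraction(dist, 19.99, 20.01), 0.999)
  narrow <- integrate(function(x) count_density(dist, x, c(19, 21)),
                      19.99, 20.01, rel.tol = 1e-9)$value
  expect_gt(narrow, 0.999)
})

test_that("absolute droplet count matches an independent discrete sum", {
  dist <- flonase_dist()
  got <- droplet_count(dist, shot_mass_mg = 1, interval = c(1, 24),
                       density_kg_m3 = 1500)
  x <- seq(1, 24, length.out = 100001)
  f <- 1e-6 * mass_pdf(dist, x) / (1500 * pi * (x * 1e-6)^3 / 6)
  riemann <- sum((f[-1] + f[-length(f)]) / 2 * diff(x))
  expect_equal(got, riemann, tolerance = 1e-3)
  expect_gt(got, 1e5) # a 1-mg shot carries a huge number of fine droplets
})

test_that("built-in registry stores the measured product parameters", {
  fl <- product_registry("Flonase")
  expect_equal(fl$distribution$x50, 37.16)
  expect_equal(fl$distribution$sigma_g, 2.080)
  expect_equal(fl$shot_mass_mg, 104.51)
  expect_equal(fl$api_mcg_per_mg, 0.5)
  na <- product_registry("nasacort") # case-insensitive
  expect_equal(na$distribution$x50, 43.81)
  expect_equal(na$distribution$sigma_g, 1.994)
  expect_equal(na$shot_mass_mg, 97.64)
  expect_equal(na$api_mcg_per_mg, 0.5)
  expect_error(product_registry("Afrin"), "unknown spray product")
})

test_that("a YAML registry file can replace the built-ins", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("- name: TestSpray", "  x50_um: 30", "  sigma_g: 1.8",
               "  shot_mass_mg: 100", "  api_mcg_per_mg: 0.4"), path)
  pr <- product_registry("TestSpray", registry_file = path)
  expect_equal(pr$distribution$x50, 30)
  expect_equal(pr$api_mcg_per_mg, 0.4)
})
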