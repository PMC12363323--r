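test_that("ideal size range thresholds the curve directly", {
  eff <- rep(0, 24); eff[12] <- 0.03; eff[13] <- 0.05
  r <- ideal_size_range(curve_from(eff))
  expect_equal(c(r$D_min, r$D_max), c(12, 13))
  expect_false(r$empty)

  none <- ideal_size_range(curve_from(rep(0.001, 24)))
  expect_true(none$empty)

  eff1 <- rep(0, 24); eff1[9] <- 0.2
  single <- ideal_size_range(curve_from(eff1))
  expect_equal(single$D_min, single$D_max)
})

test_that("ideal size range is monotone in the cutoff", {
  set.seed(5)
  eff <- pmin(1, abs(rnorm(24, 0.05, 0.05)))
  cv <- curve_from(eff)
  cuts <- c(0.01, 0.02, 0.05, 0.08)
  widths <- vapply(cuts, function(ct) {
    r <- ideal_size_range(cv, ct)
    if (r$empty) -1 else r$D_max - r$D_min
  }, numeric(1))
  ok <- widths >= 0
  expect_true(all(diff(widths[ok]) <= 0))
})

test_that("generic range averages the per-case extrema and ignores order", {
  r1 <- size_range(7, 16, 30); r2 <- size_range(8, 17, 15)
  g <- generic_range(list(r1, r2))
  expect_equal(c(g$D_min, g$D_max), c(7.5, 16.5))
  single <- generic_range(list(r1))
  expect_equal(c(single$D_min, single$D_max), c(7, 16))

  set.seed(6)
  ranges <- lapply(1:8, function(i) {
    lims <- sort(runif(2, 2, 24)); size_range(lims[1], lims[2], 15)
  })
  g8 <- generic_range(ranges)
  expect_equal(g8$D_min, mean(vapply(ranges, `[[`, 0, "D_min")))
  expect_equal(g8$D_max, mean(vapply(ranges, `[[`, 0, "D_max")))
  perm <- generic_range(ranges[sample(8)])
  expect_equal(c(perm$D_min, perm$D_max), c(g8$D_min, g8$D_max))
  expect_error(generic_range(list()), "at least one")
})

test_that("distribution weighting factorizes for constant efficiency", {
  prod <- product_registry("Flonase")
  eta <- 0.37
  dep <- weighted_deposition(curve_from(rep(eta, 24)), prod)
  expect_equal(dep,
               eta * prod$shot_mass_mg * mass_fraction(prod$distribution, 1, 24),
               tolerance = 1e-8)
  expect_equal(weighted_deposition(curve_from(rep(0, 24)), prod), 0,
               tolerance = 1e-12)
  # efficiency <= 1 bounds the deposit by the in-window shot mass
  expect_lt(weighted_deposition(curve_from(rep(1, 24)), prod),
            prod$shot_mass_mg * mass_fraction(prod$distribution, 1, 24) + 1e-9)
})

test_that("distribution weighting matches Monte-Carlo mass-weighted sampling", {
  prod <- product_registry("Nasacort")
  set.seed(7)
  eff <- pmin(1, pmax(0, 0.4 * exp(-(1:24 - 12)^2 / 32) + runif(24, 0, 0.05)))
  cv <- curve_from(eff)
  dep <- weighted_deposition(cv, prod)

  n <- 1e6
  x <- rlnorm(n, log(prod$distribution$x50), log(prod$distribution$sigma_g))
  eta_fun <- approxfun(1:24, eff, rule = 2)
  w <- ifelse(x >= 1 & x <= 24, eta_fun(x), 0)
  mc <- prod$shot_mass_mg * mean(w)
  se <- prod$shot_mass_mg * sd(w) / sqrt(n)
  expect_lt(abs(dep - mc), 3 * se)
})

test_that("curves that do not span the weighting window are rejected", {
  short <- as_deposition_curve(5:20, rep(0.1, 16))
  expect_error(weighted_deposition(short, product_registry("Flonase")),
               "cover")
})

test_that("API masses reproduce the printed product estimates at 2 significant figures", {
  # Flonase 50 mcg / 100 mg; Nasacort 55 mcg / 110 mg
  expect_equal(round_api(api_mass(1.9187, 0.5)), 0.96)
  expect_equal(round_api(api_mass(0.0495, 0.5)), 0.025)
  expect_equal(round_api(api_mass(1.8450, 0.5)), 0.92)
  expect_equal(round_api(api_mass(0.0482, 0.5)), 0.024)
  expect_equal(api_mass(0, product_registry("Flonase")), 0)
  expect_error(api_mass(-1, 0.5), "negative")
})

test_that("API mass is linear in the deposited mass", {
  prod <- product_registry("Nasacort")
  d <- c(0.3, 1.1, 2.7)
  expect_equal(api_mass(sum(d), prod), sum(api_mass(d, prod)),
               tolerance = 1e-12)
  expect_equal(api_mass(2 * d[1], prod), 2 * api_mass(d[1], prod),
               tolerance = 1e-12)
})

test_that("improvement in orders of magnitude matches direct logarithms", {
  expect_equal(improvement_oom(1.9187, 0.0495), log10(1.9187 / 0.0495),
               tolerance = 1e-12)
  expect_equal(improvement_oom(1.9187, 0.0495), 1.588, tolerance = 1e-3)
  expect_equal(improvement_oom(0.5, 0.5), 0)
  expect_equal(improvement_oom(5, 0.05), 2)
  expect_warning(inf_oom <- improvement_oom(1, 0), "unbounded")
  expect_identical(inf_oom, Inf)
})

test_that("case summary uses the sample standard deviation and flags zero-CU cases", {
  iu <- c(1.9187, 1.8450, 2.0)
  cu <- c(0.0495, 0.0482, 0.02)
  s <- summarize_improvement(iu, cu)
  oom <- log10(iu / cu)
  expect_equal(s$mean, mean(oom), tolerance = 1e-12)
  expect_equal(s$sd, sd(oom), tolerance = 1e-12)
  expect_equal(s$n, 3)
  expect_warning(s2 <- summarize_improvement(c(1, 2), c(0.1, 0)), "excluded")
  expect_equal(s2$n, 1)
})
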