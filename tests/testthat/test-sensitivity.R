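test_that("perturbed directions tilt by atan(radius/offset) and spread 72 degrees apart", {
  aw <- default_model()
  base <- iu_axis(aw)
  for (off in c(5, 10)) {
    ps <- perturbed_directions(base, aw, offset_mm = off)
    angs <- vapply(ps$axes, function(a)
      acos(sum(a$direction * base$direction)) * 180 / pi, numeric(1))
    expect_equal(angs, rep(atan(1 / off) * 180 / pi, 5), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  ps5 <- perturbed_directions(base, aw, 5)
  # azimuthal spacing about the base axis, in an orthonormal frame of the
  # plane perpendicular to it
  d <- base$direction
  u1 <- c(0, 1, 0) - d[2] * d; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- c(d[2] * u1[3] - d[3] * u1[2], d[3] * u1[1] - d[1] * u1[3],
          d[1] * u1[2] - d[2] * u1[1])
  azim <- vapply(ps5$axes, function(a) {
    w <- a$direction - sum(a$direction * d) * d
    atan2(sum(w * u2), sum(w * u1))
  }, numeric(1))
  gaps <- sort(diff(sort(azim))) * 180 / pi
  expect_equal(unname(gaps), rep(72, 4), tolerance = 1e-6)
  expect_error(perturbed_directions(base, aw, offset_mm = 7), "5 or 10")
})

test_that("perturbed direction construction is rotation-equivariant", {
  th <- 0.7
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  d <- c(0.9, -0.1, 0.42); d <- d / sqrt(sum(d^2))
  ref <- c(0, 1, 0)
  a <- perturb_axis_directions(d, 5, 1, phase = 30, ref = ref)
  b <- perturb_axis_directions(as.numeric(Rm %*% d), 5, 1, phase = 30,
                               ref = as.numeric(Rm %*% ref))
  expect_equal(b, t(Rm %*% t(a)), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("PD validity is reported per criterion rather than silently dropped", {
  aw <- default_model()
  base <- iu_axis(aw)
  for (off in c(5, 10)) {
    ps <- perturbed_directions(base, aw, offset_mm = off)
    expect_length(ps$axes, 5)
    expect_length(ps$validity, 5)
    for (v in ps$validity) {
      expect_named(v, c("valid", "intersects_nasopharynx", "avoids_septum",
                        "posterior_lateral_wall"))
      expect_type(v$valid, "logical")
    }
    # the base axis threads the passage, and at least one perturbed axis
    # does too; tilted axes that leave the slender idealized passage
    # anteriorly are reported with the failing criterion
    expect_true(validate_iu_axis(base, aw)$valid)
    expect_gte(sum(vapply(ps$validity, `[[`, TRUE, "valid")), 1)
  }
})

test_that("Pearson correlation matches the brute-force covariance formula", {
  a <- curve_from(c(1, 2, 3, 4) / 10)
  b <- curve_from(c(2, 4, 5, 9) / 10)
  pw <- pearson_with_p(a, b)
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pw$r, r_hand, tolerance = 1e-12)
  t_stat <- r_hand * sqrt((4 - 2) / (1 - r_hand^2))
  expect_equal(pw$p, 2 * pt(-abs(t_stat), df = 2), tolerance = 1e-12)
  expect_equal(pw$n, 4)
})

test_that("identical and mirrored curves give r = 1 and r = -1", {
  set.seed(8)
  eff <- runif(24, 0.2, 0.4) # keep the mirror inside [0, 1]
  cv <- curve_from(eff)
  expect_equal(pearson_with_p(cv, cv)$r, 1, tolerance = 1e-12)
  mirrored <- curve_from(2 * mean(eff) - eff)
  expect_equal(pearson_with_p(cv, mirrored)$r, -1, tolerance = 1e-12)
})

test_that("Pearson r is invariant under affine rescaling of either curve", {
  set.seed(9)
  eff <- runif(24, 0, 0.8)
  cv <- curve_from(eff)
  for (i in 1:10) {
    a <- runif(1, 0.1, 1); b <- runif(1, 0, 0.1)
    scaled <- curve_from(pmin(1, a * eff + b))
    expect_equal(pearson_with_p(cv, scaled)$r, 1, tolerance = 1e-9)
  }
})

test_that("permutation p-value broadly agrees with the t-based p-value", {
  set.seed(10)
  a <- curve_from(runif(24, 0, 0.4))
  b <- curve_from(pmin(1, pmax(0, a$efficiency + rnorm(24, 0, 0.1))))
  pt_ <- pearson_with_p(a, b, method = "t")
  pp_ <- pearson_with_p(a, b, method = "permutation", n_perm = 20000)
  expect_equal(pt_$r, pp_$r, tolerance = 1e-12)
  expect_lt(abs(log10(pp_$p) - log10(pt_$p)), 1)
})

test_that("tolerance report flags robust, non-robust and undefined directions", {
  iu <- curve_from(seq(0.02, 0.5, length.out = 24))
  pds <- list(PD1 = iu, PD2 = iu, PD3 = curve_from(rep(0.2, 24)),
              PD4 = curve_from(rev(iu$efficiency)), PD5 = iu)
  rep_ <- tolerance_report(iu, pds)
  expect_true(all(rep_$robust[c(1, 2, 5)]))
  expect_true(rep_$undefined[3])
  expect_false(rep_$robust[4]) # anti-correlated direction is not congruent
  expect_true(all(abs(rep_$r[!rep_$undefined]) <= 1))
  mismatched <- curve_from(rep(0.1, 24), flow = 30)
  expect_error(tolerance_report(iu, list(PD1 = mismatched)), "inhalation rate")
})
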