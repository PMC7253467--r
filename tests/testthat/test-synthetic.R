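test_that("control profiles hit their central and asymptotic anchors", {
  # sigmoid limits: t(0) = residual exactly, t(e -> Inf) -> rim
  grid <- c(0, 100, 200, 1e6)
  p <- make_control_profile(
    "INL", shape = list(residual_um = 0, rim_um = 40, centre_um = 450,
                        width_um = 150),
    grid = grid
  )
  expect_identical(p$samples$thickness_um[1], 0)
  expect_equal(p$samples$thickness_um[4], 40, tolerance = 1e-9)

  # IRL-type layer with an 8 um residual keeps exactly 8 um at FC
  p8 <- make_control_profile(
    "INL", shape = list(residual_um = 8, rim_um = 38, centre_um = 400,
                        width_um = 130)
  )
  expect_identical(p8$samples$thickness_um[1], 8)

  # default control: summed IRL thickness at FC is the 8 um anchor and
  # the FC stack stays near the 185 um total-thickness anchor
  at_fc <- vapply(c("GCL_IPL", "INL", "OPL", "HFL_ONL"),
                  function(l) make_control_profile(l)$samples$thickness_um[1],
                  numeric(1))
  expect_equal(unname(at_fc[["GCL_IPL"]] + at_fc[["INL"]]), 8)
  expect_equal(sum(at_fc), 185, tolerance = 0.05)

  expect_error(make_control_profile(
    "INL", shape = list(residual_um = 4, rim_um = 38, centre_um = 400,
                        width_um = 0)), "width")
  expect_error(make_control_profile("INL", grid = numeric(0)), "grid")
})

test_that("noisy generation is seed-deterministic", {
  a <- make_control_profile("OPL", noise_sd = 2, seed = 11)
  b <- make_control_profile("OPL", noise_sd = 2, seed = 11)
  c <- make_control_profile("OPL", noise_sd = 2, seed = 12)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples$thickness_um, c$samples$thickness_um))
})

test_that("identity warp returns the control unchanged with zero truth", {
  ctrl <- make_control_profile("GCL_IPL")
  out <- apply_retardation_warp(ctrl, warp_spec(0, 300))
  expect_equal(out$profile$samples$thickness_um,
               ctrl$samples$thickness_um, tolerance = 1e-12)
  expect_equal(out$retardation(c(0, 300, 900)), c(0, 0, 0))
})

test_that("linear_capped warp on constant thickness matches hand integration", {
  # psi(e) = (1 + alpha) e while e < lambda; t_PG = t (1 + alpha),
  # r(E) = E alpha / (1 + alpha)
  alpha <- 0.1
  w <- warp_spec(r_max = 200, lambda = 2000, form = "linear_capped")
  ctrl <- flat_profile(30)
  out <- apply_retardation_warp(ctrl, w)
  expect_equal(out$profile$samples$thickness_um,
               rep(30 * (1 + alpha), 49), tolerance = 1e-9)
  for (E in c(300, 500, 900)) {
    expect_equal(out$retardation(E), E * alpha / (1 + alpha),
                 tolerance = 1e-9)
  }
  # beyond the cap the shift is the constant r_max
  expect_equal(warp_psi_inverse(w, 2500), 2300)
})

test_that("warp inverse and ground truth are consistent with psi", {
  for (form in c("saturating_exponential", "linear_capped")) {
    w <- warp_spec(150, 300, form = form)
    for (E in c(1, 300, 900, 1200)) {
      x <- E - true_retardation(w, E)
      expect_equal(warp_psi(w, x), E, tolerance = 1e-6)
    }
  }
})

test_that("the warp conserves integrated layer mass", {
  ctrl <- make_control_profile("INL")
  f_c <- stats::splinefun(ctrl$samples$eccentricity_um,
                          ctrl$samples$thickness_um, method = "natural")
  for (w in list(warp_spec(60, 600), warp_spec(330, 35),
                 warp_spec(200, 400, form = "linear_capped"))) {
    E_max <- 1200
    lhs <- stats::integrate(
      function(e) f_c(pmin(warp_psi(w, e), E_max)) * warp_psi_deriv(w, e),
      0, warp_psi_inverse(w, E_max), rel.tol = 1e-9
    )$value
    rhs <- stats::integrate(f_c, 0, E_max, rel.tol = 1e-9)$value
    expect_equal(lhs, rhs, tolerance = 1e-6)
  }
})

test_that("synthetic A-scans honour their stored band geometry", {
  bands <- data.frame(layer = "OPL", inner_um = 140, outer_um = 160,
                      level = 0.7)
  # zero softness, zero noise: piecewise constant with exact boundaries
  a <- synthesize_ascan(bands, edge_softness = 0, noise_sd = 0,
                        baseline = 0.05)
  r <- a$samples$reflectivity
  d <- a$samples$depth_um
  expect_true(all(r[d >= 140 & d <= 160] == 0.75))
  expect_true(all(r[d < 140 | d > 160] == 0.05))
  expect_identical(a$bands, bands)

  # zero-width band with softness sigma is a Gaussian: FWHM = 2 sigma
  # sqrt(2 ln 2) ~ 11.77 um, measured by interpolated half-max crossings
  g <- synthesize_ascan(
    data.frame(layer = "OPL", inner_um = 150, outer_um = 150, level = 0.9),
    edge_softness = 5, baseline = 0
  )
  half <- 0.45
  above <- which(g$samples$reflectivity > half)
  lo <- approx(g$samples$reflectivity[c(min(above) - 1, min(above))],
               g$samples$depth_um[c(min(above) - 1, min(above))],
               xout = half)$y
  hi <- approx(g$samples$reflectivity[c(max(above), max(above) + 1)],
               g$samples$depth_um[c(max(above), max(above) + 1)],
               xout = half)$y
  expect_equal(hi - lo, 2 * 5 * sqrt(2 * log(2)), tolerance = 0.02)

  # seeded noise is reproducible
  n1 <- synthesize_ascan(bands, noise_sd = 0.02, seed = 3)
  n2 <- synthesize_ascan(bands, noise_sd = 0.02, seed = 3)
  expect_identical(n1$samples, n2$samples)

  expect_error(synthesize_ascan(
    data.frame(layer = c("A", "B"), inner_um = c(100, 110),
               outer_um = c(120, 130), level = 0.5)), "overlap")
})

test_that("cohort generation is seeded, labelled and truth-complete", {
  cfg <- cohort_config(seed = 3)
  ch <- generate_cohort(cfg)
  # truth covers warped layers x groups x eccentricities
  expect_equal(nrow(ch$truth), 3 * 3 * 4)
  expect_true(all(ch$truth$true_retardation_um >= 0))
  expect_false("HFL_ONL" %in% ch$truth$layer)

  # control-only config: empty ground-truth table
  empty <- generate_cohort(cohort_config(groups = list(), seed = 1))
  expect_equal(nrow(empty$truth), 0L)
  expect_equal(length(empty$profiles), 4L)

  # seed change alters noisy profiles but never the analytic truth
  noisy <- function(s) generate_cohort(cohort_config(
    groups = default_cohort_groups(noise_sd = 2), seed = s))
  c1 <- noisy(1); c2 <- noisy(2)
  expect_identical(c1$truth, c2$truth)
  expect_false(identical(c1$data$thickness_um, c2$data$thickness_um))

  dup <- list(list(label = "PG2", warp = warp_spec(10, 100)),
              list(label = "PG2", warp = warp_spec(20, 100)))
  expect_error(cohort_config(groups = dup), "duplicate")
})

test_that("ground-truth retardation is non-decreasing in r_max", {
  for (E in c(300, 900)) {
    r <- vapply(seq(0, 400, by = 50),
                function(rm) true_retardation(warp_spec(rm, 300), E),
                numeric(1))
    expect_true(all(r >= 0))
    expect_true(all(diff(r) >= -1e-9))
  }
})
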