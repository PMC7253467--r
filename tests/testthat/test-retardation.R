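test_that("interpolating spline reproduces polynomial profiles exactly", {
  e <- seq(0, 1200, by = 25)
  line <- layer_profile("INL", e, 5 + 0.02 * e)
  f <- fit_thickness_spline(line)
  xs <- seq(0, 1200, by = 7)
  expect_equal(f(xs), 5 + 0.02 * xs, tolerance = 1e-9)

  const <- flat_profile(17)
  g <- fit_thickness_spline(const)
  expect_equal(g(xs), rep(17, length(xs)), tolerance = 1e-9)

  expect_error(fit_thickness_spline(line, smoothing = -1), "smoothing")
})

test_that("smoothing recovers a noisy sigmoid to within the noise scale", {
  e <- seq(0, 990, by = 10)   # 100 samples
  truth <- sigmoid_truth(e)
  set.seed(101)
  noisy <- layer_profile("INL", e, pmax(0, truth + rnorm(length(e), sd = 2)))
  f <- fit_thickness_spline(noisy, smoothing = "gcv")
  expect_lte(sd(f(e) - truth), 2 * 1.5)
})

test_that("cumulative curves integrate simple profiles in closed form", {
  # constant t: Cum(E) = t E
  cc <- cumulative_curve(flat_profile(30), E_max = 900)
  expect_equal(eval_cumulative(cc, 900), 30 * 900, tolerance = 1e-6)
  expect_equal(eval_cumulative(cc, 0), 0)

  # linear t = a e: Cum(E) = a E^2 / 2
  e <- seq(0, 1200, by = 25)
  lin <- layer_profile("INL", e, 0.05 * e)
  cl <- cumulative_curve(lin, E_max = 1000)
  expect_equal(eval_cumulative(cl, 1000), 0.05 * 1000^2 / 2,
               tolerance = 1e-6)

  expect_error(cumulative_curve(flat_profile(30), E_max = 1300), "range")
})

test_that("cumulative curves are non-decreasing for noisy profiles", {
  set.seed(202)
  for (i in 1:5) {
    e <- seq(0, 1200, by = 25)
    t <- pmax(0, sigmoid_truth(e) + rnorm(length(e), sd = 4))
    cc <- cumulative_curve(layer_profile("INL", e, t), E_max = 1200)
    expect_equal(cc$values[1], 0)
    expect_true(all(diff(cc$values) >= 0))
  }
})

test_that("retardation identities hold exactly", {
  ctrl <- make_control_profile("INL")
  cum_c <- cumulative_curve(ctrl, 1200)
  # identical curves: zero retardation at every E
  for (E in c(100, 300, 500, 900)) {
    expect_equal(retardation_at(cum_c, cum_c, E)$retardation_um, 0,
                 tolerance = 1e-9)
  }
  # constant t vs 2t: the doubled curve reaches the control value at E/2
  c1 <- cumulative_curve(flat_profile(20, group = "C"), 1200)
  c2 <- cumulative_curve(flat_profile(40, group = "PG2"), 1200)
  est <- retardation_at(c1, c2, 600)
  expect_equal(est$retardation_um, 300, tolerance = 1e-6)
  expect_equal(est$residual_um, 300, tolerance = 1e-6)
})

test_that("retardation is invariant to a common thickness rescaling", {
  ctrl <- make_control_profile("GCL_IPL")
  pg <- apply_retardation_warp(ctrl, warp_spec(160, 85))$profile
  scale_p <- function(p, c) layer_profile(
    p$layer, p$samples$eccentricity_um, c * p$samples$thickness_um,
    group = p$group)
  r1 <- retardation_at(cumulative_curve(ctrl, 1200),
                       cumulative_curve(pg, 1200), 500)$retardation_um
  r2 <- retardation_at(cumulative_curve(scale_p(ctrl, 3.7), 1200),
                       cumulative_curve(scale_p(pg, 3.7), 1200),
                       500)$retardation_um
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("noise-free warp recovery matches the analytic ground truth", {
  ch <- generate_cohort(cohort_config(seed = 1))
  est <- cohort_retardation(ch)
  m <- merge(est, ch$truth, by = c("group", "layer", "eccentricity_um"))
  expect_equal(nrow(m), 36L)
  expect_true(all(m$status == "ok"))
  expect_lt(max(abs(m$retardation_um - m$true_retardation_um)), 2)
})

test_that("the estimator agrees with the brute-force crossing oracle", {
  ch <- generate_cohort(cohort_config(
    groups = default_cohort_groups(noise_sd = 2), control_noise_sd = 2,
    seed = 4))
  for (layer in c("GCL_IPL", "OPL")) {
    ctrl <- ch$profiles[[paste0("C.", layer)]]
    cum_c <- cumulative_curve(ctrl, 1200)
    for (g in c("PG1", "PG3")) {
      pg <- ch$profiles[[paste0(g, ".", layer)]]
      cum_g <- cumulative_curve(pg, 1200)
      for (E in c(300, 700)) {
        expect_equal(retardation_at(cum_c, cum_g, E)$retardation_um,
                     oracle_retardation(ctrl, pg, E), tolerance = 1)
      }
    }
  }
})

test_that("estimated retardation is monotone in the warp amplitude", {
  ctrl <- make_control_profile("INL")
  cum_c <- cumulative_curve(ctrl, 1200)
  est <- vapply(seq(0, 320, by = 80), function(rm) {
    pg <- apply_retardation_warp(ctrl, warp_spec(rm, 300))$profile
    retardation_at(cum_c, cumulative_curve(pg, 1200), 500)$retardation_um
  }, numeric(1))
  expect_true(all(diff(est) >= -1e-9))
})

test_that("unreachable cumulative targets are reported, not clipped", {
  thick <- cumulative_curve(flat_profile(40, group = "C"), 1200)
  thin <- cumulative_curve(flat_profile(10, group = "PG3"), 1200)
  expect_error(retardation_at(thick, thin, 900), "unreachable")
  prof <- retardation_profile(thick, thin, c(200, 900))
  expect_equal(prof$status[1], "ok")
  expect_match(prof$status[2], "unreachable")
  expect_true(is.na(prof$retardation_um[2]))

  other <- cumulative_curve(make_control_profile("OPL"), 1200)
  expect_error(retardation_at(thick, other, 300), "layer")
})

test_that("retardation profiles respect the requested eccentricity grid", {
  ctrl <- make_control_profile("INL")
  pg <- apply_retardation_warp(ctrl, warp_spec(160, 85), group = "PG2")
  cum_c <- cumulative_curve(ctrl, 1200)
  cum_p <- cumulative_curve(pg$profile, 1200)
  est <- retardation_profile(cum_c, cum_p)
  expect_equal(est$eccentricity_um, c(300, 500, 700, 900))
  expect_equal(nrow(retardation_profile(cum_c, cum_p, numeric(0))), 0L)
})

test_that("group summaries reproduce the published foveal-region means", {
  cells <- load_reference_table()$cells
  cells$retardation_um <- cells$retardation_um
  expected <- list(PG1 = c(46, 10, 72), PG2 = c(145, 50, 222),
                   PG3 = c(291, 199, 412))
  for (g in names(expected)) {
    s <- group_summary(cells[cells$group == g, ])
    expect_equal(s$mean_um_reported, expected[[g]][1])
    expect_equal(s$min_um, expected[[g]][2])
    expect_equal(s$max_um, expected[[g]][3])
    expect_equal(s$n_cells, 12L)
  }
  one <- data.frame(group = "PG2", layer = "INL", eccentricity_um = 500,
                    retardation_um = 88, residual_um = 412, status = "ok")
  s1 <- group_summary(one)
  expect_true(s1$mean_um == 88 && s1$min_um == 88 && s1$max_um == 88)
  expect_error(group_summary(one, window = c(600, 900)), "window")
})
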