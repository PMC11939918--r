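# synthetic two-overtone adsorption trace whose dD/dF ratio is an exact
# linear function of dF, with known zero-dissipation intercept phi
make_linear_ratio_trace <- function(phi = -113, x = c(0.2, 0.5),
                                    n_ad = 150, dt = 0.02) {
  tm <- seq(-1, 3, by = dt)
  theta <- pmin(pmax(tm, 0) / (n_ad * dt), 1)
  dF <- outer(theta * phi, 1 - x)           # per-overtone soft response
  dD <- matrix(0, length(tm), 2)
  for (j in 1:2) {
    s <- 0.001 / (1 - x[j])
    dD[, j] <- s * (phi - dF[, j]) * dF[, j]
  }
  baseline_correct(qcmd_trace(tm, dF, dD, overtones = c(3, 7),
                              annotations = c(lipid_start = 0)))
}

test_that("feature extraction on the calibrated single-lipid preset lands near the reference values", {
  for (tr in list(preset_clean("dopc_fig2"), preset_noisy("dopc_fig2"))) {
    fe <- extract_features(tr)
    expect_equal(fe$t_ads, 2.1, tolerance = 0.3 / 2.1)
    expect_equal(fe$dF_min, -56.5, tolerance = 3 / 56.5)
    expect_equal(fe$dF_asymp, -25.1, tolerance = 3 / 25.1)
    expect_true(fe$ruptured)
    expect_true(is.finite(fe$t_rup) && fe$t_rup > 0)
    expect_lt(fe$dD_asymp, 0.5)
  }
})

test_that("a monotone trace is reported unruptured with infinite rupture time", {
  fe <- extract_features(preset_clean("slv"))
  expect_false(fe$ruptured)
  expect_identical(fe$t_rup, Inf)
  expect_lt(abs(fe$dF_asymp - fe$dF_min), 2)
})

test_that("noise-free extraction recovers the generator ground truth", {
  for (nm in c("dopc_fig2", "slb", "partial")) {
    tr <- preset_clean(nm)
    tru <- attr(simulate_trace(nm, noise = FALSE), "truth")
    fe <- extract_features(tr)
    dt <- median(diff(tr$time))
    # minimum located within one sampling interval, value within the
    # one-sample increment of the underlying curve
    expect_lte(abs(fe$t_min - tru$t_min), dt + 1e-9)
    expect_lt(abs(fe$dF_min - tru$dF_min), 1)
    expect_lt(abs(fe$dF_asymp - tru$dF_asymp), 0.2)
  }
})

test_that("features are invariant to a constant pre-baseline offset", {
  tr <- simulate_trace("slb", noise = FALSE)
  shifted <- tr
  shifted$dF <- shifted$dF + 7.5
  shifted$dD <- shifted$dD + 0.3
  f1 <- extract_features(baseline_correct(tr))
  f2 <- extract_features(baseline_correct(shifted))
  expect_equal(f1[c("t_ads", "dF_min", "dD_max", "t_rup",
                    "dF_asymp", "dD_asymp")],
               f2[c("t_ads", "dF_min", "dD_max", "t_rup",
                    "dF_asymp", "dD_asymp")])
})

test_that("dissipation maximum dominates the asymptote whenever rupture occurred", {
  for (nm in c("dopc_fig2", "slb", "partial")) {
    fe <- extract_features(preset_clean(nm))
    expect_true(fe$ruptured)
    expect_gte(fe$dD_max, fe$dD_asymp)
  }
})

test_that("extraction preconditions are enforced", {
  raw <- simulate_trace("slb", noise = FALSE)  # not baseline-corrected
  expect_error(extract_features(raw), "baseline")
  tr <- preset_clean("slb")
  expect_error(extract_features(tr, overtone = 5), "overtone 5 not present")
  short <- baseline_correct(simulate_trace(
    simulation_config(kinetic_params(k_ads = 2, theta_crit = 0.5, k_rup = 0,
                                     t_flow_end = 2),
                      film_composition(2000, 450, 1e5, 4e5),
                      duration = 2.5), noise = FALSE))
  expect_error(extract_features(short), "no terminal plateau")
})

test_that("phase trajectories show adsorption everywhere but rupture only for SLB", {
  seg_counts <- function(tr) {
    pp <- phase_plot(tr, stride = 25)
    dF <- diff(pp$dF); dD <- diff(pp$dD)
    list(ads = sum(dF < -0.5 & dD > 0.02),    # mass and softness grow
         rup = sum(dF > 0.5 & dD < -0.02))    # mass loss and stiffening
  }
  slb <- seg_counts(preset_clean("slb"))
  expect_gt(slb$ads, 0)
  expect_gt(slb$rup, 0)
  slv <- seg_counts(preset_clean("slv"))
  expect_gt(slv$ads, 0)
  expect_equal(slv$rup, 0)
})

test_that("phase plot stride and ordering behave", {
  tr <- preset_clean("slb")
  pp1 <- phase_plot(tr, stride = 1)
  expect_equal(nrow(pp1), length(tr$time))
  expect_true(!is.unsorted(pp1$time))
  expect_error(phase_plot(tr, stride = 0), "stride")
})

test_that("multi-overtone extrapolation recovers the designed intercept exactly on a linear-ratio trace", {
  tr <- make_linear_ratio_trace(phi = -113)
  h <- deformed_height(tr)
  expect_equal(unname(h$intercepts_hz), c(-113, -113), tolerance = 1e-6)
  expect_equal(h$h_nm, 20.114, tolerance = 1e-6)
  expect_lt(h$spread_hz, 1e-4)
})

test_that("deformed height tracks the simulated layer mass within 10%", {
  for (nm in c("dopc_fig2", "partial", "slv")) {
    tr <- preset_clean(nm)
    tru <- attr(simulate_trace(nm, noise = FALSE), "truth")
    h <- deformed_height(tr)
    expect_lt(abs(h$h_nm - tru$h_true_nm) / tru$h_true_nm, 0.10)
  }
  # with default noise, still within 10%
  tr <- preset_noisy("dopc_fig2")
  tru <- attr(simulate_trace("dopc_fig2", noise = FALSE), "truth")
  expect_lt(abs(deformed_height(tr)$h_nm - tru$h_true_nm) / tru$h_true_nm,
            0.10)
})

test_that("height decreases with the mass carried per unit coverage", {
  cfg <- scenario_presets("slv")
  heavy <- simulate_trace(cfg, noise = FALSE)
  cfg$film$m_vesicle_sat <- cfg$film$m_vesicle_sat * 0.6
  light <- simulate_trace(cfg, noise = FALSE)
  h_heavy <- deformed_height(baseline_correct(heavy))$h_nm
  h_light <- deformed_height(baseline_correct(light))$h_nm
  expect_lt(h_light, h_heavy)
})

test_that("degenerate extrapolations fail loudly", {
  # constant dD/dF ratio: fitted slope ~0, intercept unstable
  tm <- seq(-1, 3, by = 0.02)
  theta <- pmin(pmax(tm, 0) / 2, 1)
  dF <- outer(-80 * theta, c(1, 1))
  dD <- 0.03 * abs(dF)
  flat <- baseline_correct(qcmd_trace(tm, dF, dD, overtones = c(3, 7),
                                      annotations = c(lipid_start = 0)))
  expect_error(deformed_height(flat), "slope is ~0")

  tr <- preset_clean("slb")
  expect_error(deformed_height(tr, overtones = 7), "at least two overtones")
  expect_error(deformed_height(tr, dF_floor = 1e5), "usable samples")
  expect_error(deformed_height(simulate_trace("slb", noise = FALSE)),
               "baseline")
})
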