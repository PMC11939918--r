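test_that("Sauerbrey mass and thickness reproduce the worked examples and are linear", {
  expect_equal(sauerbrey_mass(-30), 534)
  expect_equal(sauerbrey_mass(0), 0)
  expect_equal(sauerbrey_mass(-113), 2011.4)
  expect_equal(sauerbrey_thickness(-113, rho = 1), 20.114)
  expect_equal(sauerbrey_thickness(0), 0)
  expect_equal(sauerbrey_thickness(-25.1, rho = 1), 4.4678)
  # positive shift signals mass loss
  expect_lt(sauerbrey_mass(10), 0)

  set.seed(7)
  for (i in 1:25) {
    a <- runif(1, -5, 5); dF <- runif(1, -120, 20)
    expect_equal(sauerbrey_mass(a * dF), a * sauerbrey_mass(dF))
  }
  expect_error(sauerbrey_thickness(-30, rho = 0), "rho")
  expect_error(sauerbrey_thickness(-30, rho = -1), "rho")
})

test_that("hydration-corrected bilayer thickness matches the printed value and clamps at zero", {
  expect_equal(bilayer_thickness_corrected(-30), 4.32, tolerance = 1e-12)
  expect_equal(bilayer_thickness_corrected(-25), 3.43, tolerance = 1e-12)
  # boundary: Sauerbrey mass exactly equals the hydration mass
  expect_equal(bilayer_thickness_corrected(-102 / 17.8), 0)
  expect_warning(h <- bilayer_thickness_corrected(-1), "clamped")
  expect_equal(as.numeric(h), 0)
  expect_true(isTRUE(attr(h, "clamped")))
})

test_that("acoustic decay length has the right magnitude and overtone scaling", {
  expect_equal(decay_length(1, water25), 238.3897, tolerance = 1e-6)
  expect_equal(decay_length(3, water25) / decay_length(1, water25),
               1 / sqrt(3))
  # doubling the viscosity multiplies delta by sqrt(2)
  thick <- qcmd_constants(eta_l = 2 * water25$eta_l, rho_l = water25$rho_l)
  expect_equal(decay_length(5, thick) / decay_length(5, water25), sqrt(2))
  # n^(-1/2) law across the measured overtones
  n <- c(3, 7, 11)
  expect_equal(decay_length(n, water25) * sqrt(n),
               rep(decay_length(1, water25), 3))
  expect_error(decay_length(0), "integer")
  expect_error(decay_length(2.5), "integer")
})

test_that("rigid films follow Sauerbrey with zero dissipation at every overtone", {
  r <- rigid_film_response(534)
  expect_equal(r$dF, -30)
  expect_equal(r$dD, 0)
  expect_equal(rigid_film_response(0)$dF, 0)
  for (n in c(3, 7, 11))
    expect_identical(rigid_film_response(1234.5, n)$dF,
                     rigid_film_response(1234.5, 3)$dF)
  expect_error(rigid_film_response(-1), "m_f")
  # round trip through the thickness relation
  for (m in c(0, 10, 534, 2011.4))
    expect_equal(sauerbrey_thickness(rigid_film_response(m)$dF, rho = 1),
                 m * 1e-2)
})

test_that("viscoelastic response matches the frozen high-precision evaluation", {
  f <- viscoelastic_film(m_f = 2000, rho_f = 1, g_storage = 1e5, g_loss = 3e4)
  r <- viscoelastic_film_response(f, n = 3, constants = water25)
  # values frozen from an independent arbitrary-precision term-by-term oracle
  expect_equal(r$dF, -86.497613974, tolerance = 1e-9)
  expect_equal(r$dD, 34.482582117, tolerance = 1e-9)
  expect_equal(r$softness, 0.230171235631, tolerance = 1e-9)
})

test_that("viscoelastic response converges to the rigid response in the stiff limit", {
  stiff <- viscoelastic_film(m_f = 534, rho_f = 1,
                             g_storage = 1e12, g_loss = 1e6)
  r <- viscoelastic_film_response(stiff, n = c(3, 7, 11))
  rigid <- rigid_film_response(534)
  expect_true(all(abs(r$dF - rigid$dF) / abs(rigid$dF) < 1e-3))
  expect_true(all(r$dD * 1e-6 < 1e-8))  # dD dimensionless below 1e-8

  # soft film: strictly positive across-overtone spread, positive dissipation
  soft <- viscoelastic_film(m_f = 534, rho_f = 1,
                            g_storage = 1e5, g_loss = 1e5)
  rs <- viscoelastic_film_response(soft, n = c(3, 7, 11))
  expect_gt(diff(range(rs$dF)), 0)
  expect_true(all(rs$dD > 0))
})

test_that("film dissipation peaks at G' = G'' and declines beyond it", {
  gpp <- 3e4
  gp_grid <- seq(5e3, 5e5, by = 5e3)
  dD <- vapply(gp_grid, function(gp)
    viscoelastic_film_response(
      viscoelastic_film(2000, 1, gp, gpp), n = 3, constants = water25)$dD,
    numeric(1))
  expect_equal(gp_grid[which.max(dD)], gpp)
  past <- gp_grid >= gpp
  expect_true(all(diff(dD[past]) < 0))
})

test_that("film and constants constructors enforce their invariants", {
  expect_error(viscoelastic_film(-1, 1, 1e5, 1e4), "m_f")
  expect_error(viscoelastic_film(1, 0, 1e5, 1e4), "rho_f")
  expect_error(viscoelastic_film(1, 1, 0, 0), "g_storage")
  expect_error(viscoelastic_film(1, 1, 1e5, -1), "g_loss")
  expect_error(qcmd_constants(eta_l = 0), "eta_l")
  k <- qcmd_constants()
  expect_equal(k$m_q_g_cm2, k$sauerbrey_c * 1e-9 * k$f0_hz)
})

test_that("moduli-based dissipation matches the definition", {
  expect_equal(dissipation_from_moduli(1e5, 0), 0)
  expect_equal(dissipation_from_moduli(123, 2 * pi * 123), 1)
  expect_equal(dissipation_from_moduli(1e5, 3e4), 0.0477464829276,
               tolerance = 1e-9)
  expect_error(dissipation_from_moduli(0, 1), "g_storage")
})
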