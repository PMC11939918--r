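test_that("adsorption and rupture rates reproduce the printed reference rows", {
  expect_equal(adsorption_rate(-56.5, 2.1), 26.9, tolerance = 0.05 / 26.9)
  expect_equal(rupture_rate(-56.5, -25.1, 1.4), 22.4, tolerance = 0.05 / 22.4)
  expect_identical(rupture_rate(-56.6, -56.6, Inf), 0)
  expect_equal(rupture_rate(-45.1, -31.0, 1.95), 7.2, tolerance = 0.05 / 7.2)
  expect_equal(adsorption_rate(0, 5), 0)
  expect_equal(adsorption_rate(-60, 2), 30)
})

test_that("rate preconditions are enforced", {
  expect_error(adsorption_rate(-50, 0), "t_ads")
  expect_error(adsorption_rate(-50, -1), "t_ads")
  expect_error(rupture_rate(-50, -60, 1), "inconsistent")
  expect_error(rupture_rate(-50, -25, 0), "t_rup")
})

test_that("the boundary rule reproduces the narrative outcome for every reference row", {
  tab <- reference_features()
  expect_equal(nrow(tab), 17L)
  got <- classify_outcome(tab$dF_asymp_hz, tab$dD_asymp)
  want <- ifelse(tab$figure %in% c("6A", "7A", "7C", "8A", "8C"), "SLV",
          ifelse(tab$figure %in% c("9A", "10A"), "PARTIAL_SLB_SLV", "SLB"))
  expect_equal(got, unname(want))
})

test_that("classification boundaries are configurable and inputs validated", {
  expect_equal(classify_outcome(-25.1, 0.1), "SLB")
  expect_equal(classify_outcome(-94.4, 17.2), "SLV")
  expect_equal(classify_outcome(-42.8, 2.4), "PARTIAL_SLB_SLV")
  # tightening the SLV boundary reclassifies the partial row
  expect_equal(classify_outcome(-42.8, 2.4, slv_min_hz = 40), "SLV")
  expect_error(classify_outcome(NA, 1), "finite")
  expect_error(classify_outcome(-30, Inf), "finite")
})

test_that("osmolarity comparison matches the osmotic-stress experiment design", {
  # interior B2, exterior B5: the 150 mM NaCl hyperosmotic design
  o <- osmotic_condition("B2", "B5")
  expect_equal(o$label, "hyperosmotic")
  expect_lt(abs(o$nacl_equiv_mm - 150), 5)
  # interior B6, exterior B2: the 100 mM NaCl design (exact, no extra salts)
  o2 <- osmotic_condition("B6", "B2")
  expect_equal(o2$label, "hyperosmotic")
  expect_equal(o2$nacl_equiv_mm, 100)
  # identical buffers are isosmotic with zero difference
  o3 <- osmotic_condition("B1", "B1")
  expect_equal(o3$label, "isosmotic")
  expect_equal(o3$delta_mosm, 0)
  # B2 vs B4 differ only by 2.5 mM MgCl2: inside the isosmotic band
  expect_equal(osmotic_condition("B2", "B4")$label, "isosmotic")
})

test_that("osmotic labels are antisymmetric in the buffer pair", {
  bufs <- qcmd_buffers()
  flip <- c(hyperosmotic = "hypoosmotic", isosmotic = "isosmotic",
            hypoosmotic = "hyperosmotic")
  for (a in names(bufs)) for (b in names(bufs)) {
    ab <- osmotic_condition(bufs[[a]], bufs[[b]])
    ba <- osmotic_condition(bufs[[b]], bufs[[a]])
    expect_equal(ab$delta_mosm, -ba$delta_mosm)
    expect_equal(unname(flip[ab$label]), ba$label)
  }
})

test_that("unknown solutes error unless registered", {
  weird <- qcmd_buffer("X", c(sucrose = 100))
  expect_error(osmotic_condition(weird, qcmd_buffers()$B6), "unknown solute")
  o <- osmotic_condition(weird, qcmd_buffers()$B6,
                         registry = c(sucrose = 1))
  expect_equal(o$delta_mosm, 40 - 100)
})

test_that("experiment conditions validate their fields", {
  ok <- experiment_conditions(118, "B1", "B1", "B1",
                              flow = c(lipid_start = 0, lipid_end = 6.5))
  expect_s3_class(ok, "qcmd_conditions")
  expect_error(experiment_conditions(0, "B1", "B1", "B1"), "diameter")
  expect_error(experiment_conditions(80, "B1", "B1", "B1",
                                     flow = c(a = 5, b = 1)),
               "non-decreasing")
})

test_that("summarize_experiment produces a coherent record for each preset", {
  cond <- experiment_conditions(118, "B1", "B1", "B1",
                                flow = c(lipid_start = 0, lipid_end = 6.5))
  rec <- summarize_experiment(simulate_trace("dopc_fig2", noise = FALSE),
                              conditions = cond)
  expect_s3_class(rec, "qcmd_record")
  expect_equal(rec$outcome, "SLB")
  expect_equal(rec$R_ads, 26.9, tolerance = 3 / 26.9)
  expect_equal(rec$h_nm, 20.1, tolerance = 0.1)
  expect_false(is.na(rec$bilayer_thickness_nm))
  expect_equal(rec$osmotic_adsorption, "isosmotic")

  rec_slv <- summarize_experiment(simulate_trace("slv", noise = FALSE))
  expect_equal(rec_slv$outcome, "SLV")
  expect_identical(rec_slv$R_rup, 0)
  expect_true(is.na(rec_slv$bilayer_thickness_nm))

  rec_part <- summarize_experiment(simulate_trace("partial", noise = FALSE))
  expect_equal(rec_part$outcome, "PARTIAL_SLB_SLV")
  expect_gt(rec_part$R_rup, 0)
})

test_that("printed rates are recovered from the packaged features for self-consistent rows", {
  tab <- reference_features()
  rows <- tab[tab$figure %in% c("2A", "6A", "11A"), ]
  r_ads <- adsorption_rate(rows$dF_min_hz, rows$t_ads_min)
  r_rup <- rupture_rate(rows$dF_min_hz, rows$dF_asymp_hz, rows$t_rup_min)
  expect_equal(r_ads, rows$R_ads, tolerance = 0.05 / min(rows$R_ads))
  expect_equal(r_rup, rows$R_rup, tolerance = 0.05)
})

test_that("reference condition table aligns with the feature table", {
  cond <- reference_conditions()
  feat <- reference_features()
  expect_equal(nrow(cond), 12L)
  expect_true(all(c("2A", "6A", "11A") %in% cond$figure))
  expect_true(all(cond$hydration %in% names(qcmd_buffers())))
  # the successful-SLB runs applied hyperosmotic stress during adsorption
  for (fig in c("11A", "11C", "11D", "12A")) {
    row <- cond[cond$figure == fig, ]
    expect_equal(osmotic_condition(row$hydration, row$dilution)$label,
                 "hyperosmotic")
  }
})
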