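test_that("hydraulic permeability follows the Arrhenius law", {
  p <- membrane_params(lp0 = 2.8, dh_over_r = 3181, t_ref = 293.15)
  expect_equal(hydraulic_permeability(p, 293.15), 2.8)  # T = T0 collapses
  # frozen independent arithmetic: 2.8 * exp(-3181 * (1/303.15 - 1/293.15))
  expect_equal(hydraulic_permeability(p, 303.15), 4.005083114, tolerance = 1e-9)
  p0 <- membrane_params(lp0 = 2.8, dh_over_r = 0)
  expect_equal(hydraulic_permeability(p0, 350), 2.8)    # zero activation
  expect_error(hydraulic_permeability(p, -1), class = "skm_domain_error")
})

test_that("pure-water flux is linear in pressure", {
  p <- membrane_params(lp0 = 8.6, dh_over_r = 3428, t_ref = 293.15)
  # 8.6 * 9.5 at the reference temperature; the matching measured flux was
  # 87.0 +- 0.8, so the model-vs-data residual is a few units, not zero
  expect_equal(water_flux(p, 9.5, 293.15), 81.7)
  expect_equal(water_flux(p, 0, 293.15), 0)
  expect_equal(water_flux(p, 2 * 7.3, 298.15),
               2 * water_flux(p, 7.3, 298.15))
})

test_that("film-theory wall concentration behaves physically", {
  cf <- 1.47e-2; cp <- 7.03e-4
  expect_equal(wall_concentration(cf, cp, 0, 13), cf)       # no flux
  # frozen: 7.03e-4 + (1.47e-2 - 7.03e-4) * exp(4.7/13)
  expect_equal(wall_concentration(cf, cp, 4.7, 13), 2.07962007e-2,
               tolerance = 1e-8)
  expect_equal(wall_concentration(cf, cp, 4.7, Inf), cf)    # sentinel
  expect_error(wall_concentration(cf, cp, 800 * 13, 13),
               "larger", class = "skm_overflow_error")
  expect_error(wall_concentration(cf, 2 * cf, 4.7, 13),
               class = "skm_domain_error")
  # polarization can only enrich the wall
  set.seed(11)
  for (i in 1:50) {
    cfe <- runif(1, 1e-3, 3e-2); cpe <- runif(1, 0, cfe)
    expect_gte(wall_concentration(cfe, cpe, runif(1, 0, 60), runif(1, 5, 40)),
               cfe)
  }
})

test_that("van 't Hoff osmotic pressure difference", {
  expect_equal(osmotic_pressure_difference(5e-3, 5e-3, 298.15), 0)
  # frozen: 0.083145 * 293.15 * (2.081e-2 - 7.03e-4)
  expect_equal(osmotic_pressure_difference(2.081e-2, 7.03e-4, 293.15),
               0.49008715, tolerance = 1e-7)
  d1 <- osmotic_pressure_difference(1.2e-2, 2e-3, 293.15)
  d2 <- osmotic_pressure_difference(2.2e-2, 2e-3, 293.15)
  expect_equal(d2, 2 * d1)
  expect_error(osmotic_pressure_difference(1e-3, 2e-3, 293.15),
               class = "skm_domain_error")
})

test_that("implicit flux solver reduces to its closed-form limits", {
  cond <- list(tmp = 9.5, temperature = 298.15)
  cf <- 7.03e-3; cp <- 4.42e-4
  p0 <- membrane_params(lp0 = 2.5, dh_over_r = 4529, sigma = 0, k = 13)
  expect_identical(solve_flux(p0, 9.5, 298.15, cf, cp),
                   water_flux(p0, 9.5, 298.15))
  pI <- membrane_params(lp0 = 2.5, dh_over_r = 4529, sigma = 0.999, k = Inf)
  lpT <- hydraulic_permeability(pI, 298.15)
  expect_equal(solve_flux(pI, 9.5, 298.15, cf, cp),
               lpT * (9.5 - 0.999 * 0.083145 * 298.15 * (cf - cp)))
})

test_that("implicit flux solver agrees with the grid-scan oracle", {
  # reference condition: the fitted C2 parameter set at 9.5 bar / 298.15 K
  p <- membrane_params(lp0 = 2.5, dh_over_r = 4529, sigma = 0.999, k = 13)
  jv <- solve_flux(p, 9.5, 298.15, 7.03e-3, 4.42e-4)
  oracle <- grid_scan_flux(2.5, 4529, 0.999, 13, 9.5, 298.15,
                           7.03e-3, 4.42e-4)
  expect_equal(jv, oracle, tolerance = 1e-5)
  expect_lt(abs(jv - 26.8), 1.3)  # near the measured 26.8 +- 1.3

  set.seed(401)
  for (i in 1:20) {
    cs <- random_skm_case()
    cp <- runif(1, 0, 0.1) * cs$c_feed
    osm0 <- cs$sigma * 0.083145 * cs$temperature * (cs$c_feed - cp)
    if (osm0 >= cs$tmp) next
    jv <- solve_flux(membrane_params(cs$lp0, cs$dh_over_r, cs$sigma, cs$k),
                     cs$tmp, cs$temperature, cs$c_feed, cp)
    oracle <- grid_scan_flux(cs$lp0, cs$dh_over_r, cs$sigma, cs$k,
                             cs$tmp, cs$temperature, cs$c_feed, cp)
    expect_equal(jv, oracle, tolerance = 1e-5,
                 label = sprintf("random case %d", i))
  }
})

test_that("implicit flux is monotone in pressure and feed concentration", {
  p <- membrane_params(lp0 = 2.5, dh_over_r = 4529, sigma = 0.999, k = 13)
  tmps <- seq(3, 19, length.out = 5)
  cfs <- seq(2e-3, 2.5e-2, length.out = 5)
  jv <- outer(tmps, cfs, function(tt, cc)
    solve_flux(p, tt, 298.15, cc, 0.05 * cc))
  expect_true(all(diff(jv) > 0))        # increasing in pressure
  expect_true(all(t(diff(t(jv))) < 0))  # decreasing in feed concentration
  # osmotic opposition can only lower the flux below the pure-water line
  expect_true(all(jv <= water_flux(p, tmps, 298.15)))
})

test_that("infeasible driving pressure raises a no-solution error", {
  p <- membrane_params(lp0 = 2.5, sigma = 1, k = 13)
  # 0.2 bar applied vs ~0.36 bar bulk osmotic pressure
  expect_error(solve_flux(p, 0.2, 293.15, 1.5e-2, 0),
               "osmotic", class = "skm_no_solution_error")
  expect_true(is.na(solve_flux(p, 0.2, 293.15, 1.5e-2, 0,
                               on_no_root = "na")))
})

test_that("solute flux and its per-observation inverse are consistent", {
  perfect <- membrane_params(lp0 = 2.5, sigma = 1, k = 13, ps = 0)
  expect_equal(solute_flux(perfect, 2.081e-2, 7.03e-4, 4.7), 0)
  p1 <- membrane_params(lp0 = 2.5, sigma = 0.999, k = 13, ps = 1)
  # frozen: 1*(2.081e-2 - 7.03e-4) + 0.001 * 2.081e-2 * 4.7
  expect_equal(solute_flux(p1, 2.081e-2, 7.03e-4, 4.7), 2.0204807e-2,
               tolerance = 1e-8)
  noPs <- membrane_params(lp0 = 2.5, sigma = 0.999, k = 13)
  expect_error(solute_flux(noPs, 2.081e-2, 7.03e-4, 4.7),
               class = "skm_config_error")

  # inverse: with sigma = 1, Ps = Jv*Cp/(Cm - Cp)
  psig <- membrane_params(lp0 = 2.5, sigma = 1, k = 13)
  est <- estimate_solute_permeability(psig, 1.47e-2, 7.03e-4, 4.7)
  expect_equal(est, 0.1643, tolerance = 1e-2)
  expect_equal(estimate_solute_permeability(psig, 1.47e-2, 0, 4.7), 0)
  # round trip: the estimated Ps reproduces the mass balance Js = Jv*Cp
  p2 <- membrane_params(lp0 = 2.5, sigma = 0.999, k = 13, ps = est)
  est2 <- estimate_solute_permeability(p2, 1.47e-2, 7.03e-4, 4.7)
  cm <- wall_concentration(1.47e-2, 7.03e-4, 4.7, 13)
  pback <- membrane_params(lp0 = 2.5, sigma = 0.999, k = 13, ps = est2)
  expect_equal(solute_flux(pback, cm, 7.03e-4, 4.7), 4.7 * 7.03e-4,
               tolerance = 1e-12)
})

test_that("observed rejection is the bulk retained fraction", {
  # the strongest retention in the C1 campaign: 19.5 bar row
  expect_equal(observed_rejection(1.95e-2, 7.18e-4), 0.9632,
               tolerance = 1e-4)
  expect_equal(observed_rejection(1e-2, 0), 1)
  expect_equal(observed_rejection(1e-2, 1e-2), 0)
  expect_error(observed_rejection(0, 0), class = "skm_domain_error")
})

test_that("fouling index reproduces the measured irreversible fouling", {
  expect_equal(fouling_index(111.2, 32.4), 70.9, tolerance = 1e-3)
  expect_equal(fouling_index(57.3, 57.3), 0)
  expect_equal(fouling_index(156.3, 47.9), 69.4, tolerance = 1e-2)
  expect_error(fouling_index(0, 10), class = "skm_domain_error")
  # full 3x3 grid of matched water cells, against the published index table
  # (published values come from unrounded source fluxes, hence the band)
  fi <- fouling_index_table()
  published <- data.frame(
    tmp = rep(c(4.5, 9.5, 14.5), each = 3),
    temperature = rep(c(293.15, 298.15, 303.15), 3),
    fi = c(70.4, 70.2, 70.1, 67.3, 70.9, 66.8, 62.8, 69.4, 66.5))
  m <- merge(fi, published, by = c("tmp", "temperature"))
  expect_equal(nrow(m), 9L)
  expect_true(all(abs(m$fi_pct - m$fi) <= 0.15))
})
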