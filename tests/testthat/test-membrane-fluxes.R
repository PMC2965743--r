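test_that("LCC template: onset, closed-form peak time, post-pulse decay", {
  pr <- voltage_protocol()
  lp <- lcc_params(amplitude = 1)
  expect_equal(lcc_current_density(0, pr, lp), 0)
  # extremum of (1 - e^(-t/ta)) e^(-t/ti) at ta*log(1 + ti/ta)
  tpk <- lp$tau_act * log(1 + lp$tau_inact / lp$tau_act)
  expect_equal(tpk, 11.671, tolerance = 1e-3)
  tt <- seq(0, 70, by = 0.01)
  I <- lcc_current_density(tt, pr, lp)
  expect_equal(tt[which.min(I)], tpk, tolerance = 0.02)
  expect_true(all(I <= 0))  # inward
  # decayed to nothing ten deactivation constants after pulse end
  expect_lt(abs(lcc_current_density(70 + 10 * lp$tau_deact, pr, lp)),
            1e-4 * lp$amplitude)
})

test_that("LCC depth polynomial matches its printed coefficients", {
  w <- spatial_weight_params()
  expect_equal(lcc_spatial_weight(0, w), 0.4515 * 1.0033)
  expect_equal(lcc_spatial_weight(5.645, w) / lcc_spatial_weight(0, w),
               1.666, tolerance = 1e-3)
  # neutral polynomial is flat
  flat <- spatial_weight_params(C = 1, p1 = 0, p2 = 0, p3 = 0, p4 = 1)
  expect_equal(lcc_spatial_weight(c(0, 2, 5), flat), c(1, 1, 1))
  expect_error(lcc_spatial_weight(6, w), "outside")
})

test_that("NCX flux: resting efflux value, pulse entry mode, reversal", {
  expect_equal(ncx_flux(-50, 0.1), -1.69e-3, tolerance = 0.005)
  expect_gt(ncx_flux(10, 0.1), 0)   # entry mode during the pulse
  # reversal: flux crosses zero at the voltage where the numerator
  # vanishes; check sign change around it
  f <- function(V) ncx_flux(V, 0.1)
  Vrev <- stats::uniroot(f, c(-150, 150))$root
  expect_lt(f(Vrev - 1), 0)
  expect_gt(f(Vrev + 1), 0)
})

test_that("leak flux follows conductance times Nernst driving force", {
  k <- physical_constants()
  expect_equal(nernst_ca(0.1, 1000), 117.04, tolerance = 0.01)
  g <- 1e-5
  expect_equal(leak_flux(-50, 0.1, g_leak = g), g * (117.04 + 50),
               tolerance = 1e-3)
  # zero driving force
  expect_equal(leak_flux(0, 1000, g_leak = g), 0)
  expect_error(leak_flux(-50, 0, g_leak = g), "positive")
})

test_that("calibrated leak cancels NCX at rest; sign flips with Na_e", {
  pr <- voltage_protocol()
  g140 <- calibrate_rest_leak(ion_conditions(Na_e = 140))
  g0 <- calibrate_rest_leak(ion_conditions(Na_e = 0))
  expect_gt(g140, 0)
  expect_lt(g0, 0)
  # exact balance at machine precision
  tot <- ncx_flux(-50, 0.1, ion_conditions(Na_e = 140)) +
    leak_flux(-50, 0.1, ion_conditions(Na_e = 140), g140)
  expect_lt(abs(tot), 1e-18)
  tot0 <- ncx_flux(-50, 0.1, ion_conditions(Na_e = 0)) +
    leak_flux(-50, 0.1, ion_conditions(Na_e = 0), g0)
  expect_lt(abs(tot0), 1e-18)
})

test_that("current-to-flux conversion units and linearity", {
  expect_equal(current_density_to_flux(0), 0)
  expect_equal(current_density_to_flux(-1), 8.8 / (2 * 96.5))
  expect_equal(current_density_to_flux(-1), 0.0456, tolerance = 1e-3)
  expect_equal(current_density_to_flux(-3.7), 3.7 *
                 current_density_to_flux(-1))
})

test_that("boundary flux redistribution conserves totals at uniform Ca", {
  mesh <- fx_cyl_mesh()
  g <- calibrate_rest_leak()
  amp <- 5
  k <- physical_constants()
  V <- mesh$stats$compartment_volume
  memb <- mesh$facet_label %in% c("external_membrane", "ttubule_membrane")
  A <- mesh$facet_area[memb]
  tlab <- mesh$facet_label[memb] == "ttubule_membrane"
  Ca_u <- 0.12
  totals <- sapply(c("heterogeneous_polynomial", "uniform_6x_ttubule",
                     "homogeneous"), function(mode) {
    d <- build_boundary_flux(mesh, flux_scenario(mode), t = 20,
                             local_Ca = Ca_u,
                             lcc = lcc_params(amplitude = amp),
                             g_leak = g)
    c(lcc = sum(A * d$lcc), ncx = sum(A * d$ncx), leak = sum(A * d$leak))
  })
  # every component's area-weighted total equals the global model x volume
  J_lcc <- current_density_to_flux(
    lcc_current_density(20, voltage_protocol(), lcc_params(amplitude = amp)))
  J_ncx <- ncx_flux(10, Ca_u)
  J_leak <- leak_flux(10, Ca_u, g_leak = g)
  for (mode in colnames(totals)) {
    expect_equal(unname(totals["lcc", mode]), J_lcc * V, tolerance = 1e-12)
    expect_equal(unname(totals["ncx", mode]), J_ncx * V, tolerance = 1e-12)
    expect_equal(unname(totals["leak", mode]), J_leak * V,
                 tolerance = 1e-12)
  }
  # 6x mode: t-tubular facet density is 6x the external density
  d6 <- build_boundary_flux(mesh, flux_scenario("uniform_6x_ttubule"),
                            t = 20, local_Ca = Ca_u,
                            lcc = lcc_params(amplitude = amp), g_leak = g)
  expect_equal(unique(round(d6$lcc[tlab] / d6$lcc[!tlab][1], 9)), 6)
  # homogeneous mode: all facets identical
  dh <- build_boundary_flux(mesh, flux_scenario("homogeneous"), t = 20,
                            local_Ca = Ca_u,
                            lcc = lcc_params(amplitude = amp), g_leak = g)
  expect_lt(diff(range(dh$total)), 1e-12 * max(abs(dh$total)))
  # heterogeneous mode: within the tubule, density rises ~1.67-fold from
  # mouth to terminus
  dht <- build_boundary_flux(mesh, flux_scenario(), t = 20,
                             local_Ca = Ca_u,
                             lcc = lcc_params(amplitude = amp), g_leak = g)
  depth <- mesh$facet_centroid[memb, 3]
  shallow <- tlab & depth < 0.3
  deep <- tlab & depth > 5.2 & depth < 5.55
  ratio <- mean(dht$lcc[deep]) / mean(dht$lcc[shallow])
  wref <- spatial_weight_params()
  expected <- lcc_spatial_weight(mean(depth[deep]), wref) /
    lcc_spatial_weight(mean(depth[shallow]), wref)
  expect_equal(ratio, expected, tolerance = 0.05)
})

test_that("resting steady state: calibrated leak plus zero LCC holds Ca", {
  cfg <- simulation_config(lcc = lcc_params(amplitude = 0),
                           protocol = voltage_protocol(V_pulse = -50))
  g <- run_0d(cfg, times = seq(0, 400, by = 10))
  expect_lt(max(abs(g$Ca - 0.1)), 1e-6)
})
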