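# a synthetic solution with a prescribed per-vertex field, built on the
# shared cylinder mesh
synthetic_solution <- function(mesh, field_fun, times = c(0, 10, 20)) {
  cfg <- simulation_config(scenario = flux_scenario("homogeneous"))
  vals <- field_fun(mesh$vertices)
  fields <- list(Ca = matrix(rep(vals, length(times)), ncol = length(times)))
  structure(list(time = times, fields = fields,
                 global = structure(
                   data.frame(time = times,
                              Ca = rep(mean(vals), length(times)),
                              J_lcc = 0, J_ncx = 0, J_leak = 0),
                   class = c("global_transient", "data.frame")),
                 mass = data.frame(time = times, total_ca = 0, influx = 0),
                 mesh = mesh, config = cfg),
            class = "solution")
}

test_that("line-scan sampling is exact for uniform and linear fields", {
  mesh <- fx_cyl_mesh()
  sol_u <- synthetic_solution(mesh, function(v) rep(0.25, nrow(v)))
  img <- extract_linescan(sol_u)
  expect_lt(diff(range(img$values)), 1e-12)
  # linear-in-depth field a + b z is reproduced exactly by P1
  # interpolation
  a <- 0.1; b <- 0.05
  sol_l <- synthetic_solution(mesh, function(v) a + b * v[, 3])
  img_l <- extract_linescan(sol_l)
  expect_equal(img_l$values[, 1], a + b * img_l$positions,
               tolerance = 1e-9)
})

test_that("scan line placement respects the offset and stays cytosolic", {
  mesh <- fx_cyl_mesh()
  sol <- synthetic_solution(mesh, function(v) rep(1, nrow(v)))
  spec <- linescan_spec(offset_um = 0.2, angle_deg = 120)
  img <- extract_linescan(sol, spec)
  # radial distance from the tubule axis = cylinder radius + offset
  expect_equal(sqrt(sum((img$line_origin - c(1, 1))^2)), 0.2 + 0.2,
               tolerance = 1e-9)
  # an offset pointing into the lumen is rejected by point location
  expect_error(extract_linescan(sol, linescan_spec(offset_um = 1.5)),
               "outside|exits")
})

test_that("SCH arithmetic, bounds and scale invariance", {
  img <- structure(list(positions = c(0.17, 3.09, 5.45), times = c(0, 1),
                        values = cbind(c(0.2, 0.16, 0.1),
                                       c(0.3, 0.3, 0.3)),
                        species = "Ca",
                        spec = linescan_spec(spacing_um = 1)),
                   class = "linescan_image")
  expect_equal(compute_sch(img, t = 0), 0.5)
  expect_equal(compute_sch(img, t = 1), 0)
  # scale-free: multiplying the field by any constant leaves SCH fixed
  img2 <- img; img2$values <- img$values * 7.3
  expect_equal(compute_sch(img2, t = 0), compute_sch(img, t = 0))
  expect_error(compute_sch(img, spots = c(9), t = 0), "outside")
})

test_that("transient metrics recover a constructed maximum", {
  tt <- seq(0, 100, by = 0.5)
  vals <- 0.1 + 0.05 * sin(pi * tt / 100)^2   # max at t = 50
  m <- transient_metrics(vals, time = tt)
  expect_equal(m$t_peak, 50)
  expect_equal(m$peak, 0.15)
  expect_equal(m$value_at(25), vals[tt == 25])
  # constant trace: first index wins
  mc <- transient_metrics(rep(2, 5), time = 0:4)
  expect_equal(mc$t_peak, 0)
  expect_error(transient_metrics(numeric(0), time = numeric(0)), "empty")
})

test_that("front detection: traveling ramp speed and uniform-rise null", {
  positions <- seq(0, 5, by = 0.1)
  times <- seq(0, 160, by = 1)
  v_true <- 0.05  # um/ms
  ramp <- outer(positions, times, function(p, t)
    0.1 + 0.4 / (1 + exp(-(t - p / v_true - 10) / 1.5)))
  img <- structure(list(positions = positions, times = times,
                        values = ramp, species = "Ca",
                        spec = linescan_spec()),
                   class = "linescan_image")
  fr <- detect_front(img, threshold = 0.3)
  expect_true(fr$initiated)
  expect_equal(fr$speed_um_per_ms, v_true, tolerance = 0.05)
  expect_false(fr$faltered)   # front reaches the end of the line
  # simultaneous uniform rise: no propagating front
  flat <- outer(positions, times, function(p, t)
    0.1 + 0.4 * (t > 20))
  img_f <- img; img_f$values <- flat
  expect_false(detect_front(img_f, threshold = 0.3)$initiated)
  # threshold never crossed
  expect_false(detect_front(img, threshold = 10)$initiated)
})

test_that("heterogeneous-scenario image is hottest near the mouth at peak", {
  r <- fx_scenario("fig4_heterogeneous")
  img <- r$linescan
  tp <- transient_metrics(r$solution$global)$t_peak
  j <- which.min(abs(img$times - tp))
  prof <- img$values[, j]
  near <- mean(prof[img$positions <= 0.5])
  deep <- mean(prof[img$positions >= 5.0])
  expect_gt(near, deep)
})
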