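# Shared, lazily built fixtures. Expensive objects (meshes, scenario
# runs) are built once per test session and cached.

.fx <- new.env(parent = emptyenv())

fx_get <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# default calibrated compartment at the shipped resolution
fx_default_mesh <- function() {
  fx_get("default_mesh", function()
    generate_ttubule_mesh(ttubule_spec(), 0.07))
}

# thickened coarse branched variant used by the scenario property suite;
# larger radii allow a coarse grid (h = 0.14) that keeps 3-D runs fast
fx_test_spec <- function() {
  ttubule_spec(radius_min = 0.14, radius_max = 0.20, branch_radius = 0.16)
}

fx_test_mesh <- function() {
  fx_get("test_mesh", function()
    generate_ttubule_mesh(fx_test_spec(), 0.14))
}

# coarse idealized cylinder for 0-D/3-D cross-checks
fx_cyl_mesh <- function() {
  fx_get("cyl_mesh", function()
    generate_ttubule_mesh(
      ttubule_spec(variant = "cylindrical", radius_min = 0.2,
                   radius_max = 0.2), 0.18))
}

# LCC amplitude calibrated on the dye-present 0-D model
fx_amplitude <- function() {
  fx_get("amplitude", function()
    calibrate_lcc_amplitude(0.163, simulation_config()))
}

# scenario runs at property-suite resolution (dt = 1 ms, 250 ms)
fx_scenario <- function(preset) {
  fx_get(paste0("scen_", preset), function()
    run_scenario(preset,
                 overrides = list(dt = 1, output_every = 10,
                                  duration = 250,
                                  lcc_amplitude = fx_amplitude()),
                 mesh = fx_test_mesh()))
}

fx_sch_at_peak <- function(preset) {
  s <- fx_scenario(preset)$sch
  s$sch[s$epoch == "t_ca_peak"]
}

fx_spot_peak <- function(preset, position) {
  ls <- fx_scenario(preset)$linescan
  i <- which.min(abs(ls$positions - position))
  max(ls$values[i, ])
}
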