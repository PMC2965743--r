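#' Named scenario presets
#'
#' Returns the fully resolved configuration deltas for the standard
#' numerical experiments:
#' * `fig4_heterogeneous` -- 100 uM Fluo-3, LCC density following the
#'   depth polynomial, NCX 3x t-tubular, leak homogeneous;
#' * `fig4_uniform6x` -- as above but LCC uniform and 6x higher on the
#'   t-tubule membrane;
#' * `fig4_homogeneous` -- all fluxes uniform over the sarcolemma;
#' * `fig6_nodye` -- heterogeneous fluxes, Fluo-3 removed;
#' * `fig7_immobile` -- no dye, CaATP and CaCal immobilized;
#' * `fig8_zeroNa` -- no dye, extracellular Na+ removed (NCX forward
#'   mode inhibited; the leak recalibrates to a negative conductance).
#' @return named list of preset descriptions.
#' @export
scenario_presets <- function() {
  list(
    fig4_heterogeneous = list(fluo_total = 100,
                              lcc_mode = "heterogeneous_polynomial",
                              Na_e = 140, immobilize = character()),
    fig4_uniform6x = list(fluo_total = 100,
                          lcc_mode = "uniform_6x_ttubule",
                          Na_e = 140, immobilize = character()),
    fig4_homogeneous = list(fluo_total = 100, lcc_mode = "homogeneous",
                            Na_e = 140, immobilize = character()),
    fig6_nodye = list(fluo_total = 0,
                      lcc_mode = "heterogeneous_polynomial",
                      Na_e = 140, immobilize = character()),
    fig7_immobile = list(fluo_total = 0,
                         lcc_mode = "heterogeneous_polynomial",
                         Na_e = 140, immobilize = c("ATP", "Cal")),
    fig8_zeroNa = list(fluo_total = 0,
                       lcc_mode = "heterogeneous_polynomial",
                       Na_e = 0, immobilize = character()))
}

#' Build a simulation configuration from a preset
#'
#' @param preset a preset name (see [scenario_presets()]).
#' @param overrides named list overriding preset fields (`fluo_total`,
#'   `lcc_mode`, `Na_e`, `immobilize`) or numeric settings (`dt`,
#'   `duration`, `output_every`, `lcc_amplitude`).
#' @return a [simulation_config()].
#' @export
preset_config <- function(preset, overrides = list()) {
  presets <- scenario_presets()
  if (!preset %in% names(presets))
    stop("unknown preset: ", preset, "; available: ",
         paste(names(presets), collapse = ", "))
  p <- utils::modifyList(presets[[preset]], overrides)
  num <- function(nm, default) if (!is.null(p[[nm]])) p[[nm]] else default
  cfg <- simulation_config(
    buffers = buffer_set(fluo_total = p$fluo_total),
    scenario = flux_scenario(p$lcc_mode),
    ions = ion_conditions(Na_e = p$Na_e),
    dt = num("dt", 0.1), duration = num("duration", 400),
    output_every = num("output_every", 5),
    immobilize = p$immobilize)
  if (!is.null(p$lcc_amplitude)) cfg$lcc$amplitude <- p$lcc_amplitude
  cfg
}

#' Read a scenario configuration from a YAML file
#'
#' The file selects a `preset` and optionally overrides any of its
#' fields, plus mesh settings under `mesh:` (`target_edge_length`,
#' `seed`, `variant`, and any [ttubule_spec()] argument).
#' @param path YAML file path.
#' @return list with `config` (a `simulation_config`), `mesh_spec`
#'   (a `ttubule_spec`), `target_edge_length`, `preset`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  preset <- if (is.null(y$preset)) "fig4_heterogeneous" else y$preset
  overrides <- y[setdiff(names(y), c("preset", "mesh"))]
  cfg <- preset_config(preset, overrides)
  margs <- y$mesh
  h <- 0.12
  if (!is.null(margs)) {
    h <- if (!is.null(margs$target_edge_length))
      margs$target_edge_length else h
    margs$target_edge_length <- NULL
  }
  mesh_spec <- do.call(ttubule_spec, if (is.null(margs)) list() else margs)
  list(config = cfg, mesh_spec = mesh_spec, target_edge_length = h,
       preset = preset)
}

#' Run a complete scenario pipeline
#'
#' Executes the full chain for one preset: mesh generation, leak and LCC
#' amplitude calibration (the amplitude is always calibrated on the
#' dye-present 0-D model, since the dye does not affect Ca2+ entry),
#' the 0-D and 3-D runs, line-scan extraction and the SCH report, and
#' writes the artifacts (global transient and line-scan as tab-separated
#' text, mesh as MSH, manifest as YAML) to `out_dir`.
#'
#' @param preset preset name (see [scenario_presets()]).
#' @param overrides named list of preset overrides (see
#'   [preset_config()]).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param mesh optional pre-generated `labeled_mesh` (reused across
#'   scenario comparisons); generated from `mesh_spec` otherwise.
#' @param mesh_spec a [ttubule_spec()].
#' @param target_edge_length mesh resolution (um).
#' @param linescan a [linescan_spec()].
#' @param target_peak calibration target for the dye-present global peak
#'   (uM).
#' @return list with `config`, `mesh`, `global_0d`, `solution`,
#'   `linescan`, `sch`, `amplitude`, `manifest`.
#' @export
run_scenario <- function(preset, overrides = list(), out_dir = NULL,
                         mesh = NULL, mesh_spec = ttubule_spec(),
                         target_edge_length = 0.12,
                         linescan = linescan_spec(),
                         target_peak = 0.163) {
  cfg <- preset_config(preset, overrides)
  if (is.null(mesh))
    mesh <- generate_ttubule_mesh(mesh_spec, target_edge_length)
  # amplitude calibration on the dye-present well-mixed model
  if (is.null(overrides$lcc_amplitude)) {
    cal_cfg <- cfg
    cal_cfg$buffers <- buffer_set(fluo_total = 100)
    cal_cfg$immobilize <- character()
    amp <- calibrate_lcc_amplitude(target_peak, cal_cfg)
    cfg$lcc$amplitude <- amp
  } else amp <- overrides$lcc_amplitude
  g0 <- run_0d(cfg)
  sol <- run_3d(mesh, cfg)
  ls <- extract_linescan(sol, linescan)
  sch <- sch_report(ls, sol$global, cfg$lcc, cfg$protocol)
  manifest <- list(
    preset = preset, overrides = overrides,
    package_version = as.character(utils::packageVersion("ttcasim")),
    mesh = c(mesh$spec[c("variant", "seed")],
             list(target_edge_length = mesh$h,
                  vertices = nrow(mesh$vertices),
                  compartment_volume = mesh$stats$compartment_volume,
                  ttubule_fraction = mesh$stats$ttubule_fraction)),
    g_leak = cfg$g_leak, lcc_amplitude = amp,
    Na_e = cfg$ions$Na_e,
    fluo_total = if (is.null(cfg$buffers$buffers$Fluo3)) 0 else
      cfg$buffers$buffers$Fluo3$B_total,
    immobilize = cfg$immobilize,
    dt = cfg$dt, duration = cfg$duration,
    linescan = unclass(linescan))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(g0, file.path(out_dir, "global_0d.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(sol$global, file.path(out_dir, "global_3d.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    ls_tab <- cbind(position = ls$positions, as.data.frame(ls$values))
    names(ls_tab)[-1] <- sprintf("t%g", ls$times)
    utils::write.table(ls_tab, file.path(out_dir, "linescan.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(sch, file.path(out_dir, "sch.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_mesh_msh(mesh, file.path(out_dir, "mesh.msh"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  list(config = cfg, mesh = mesh, global_0d = g0, solution = sol,
       linescan = ls, sch = sch, amplitude = amp, manifest = manifest)
}
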