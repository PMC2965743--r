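#' Physical constants
#'
#' Faraday constant F = 96.5 C mmol^-1, gas constant
#' R = 8.314 J mol^-1 K^-1, temperature T = 295 K (room temperature,
#' matching the rate constants measured at 22 C).
#' @return list with `F_const` (C mmol^-1), `R_gas` (J mol^-1 K^-1), `T` (K).
#' @export
physical_constants <- function() {
  list(F_const = 96.5, R_gas = 8.314, T = 295)
}

#' Whole-cell geometric parameters
#'
#' Rat ventricular myocyte averages: cell volume 36.8 pL, membrane
#' capacitance 324 pF, capacitance-to-volume (surface-to-volume) ratio
#' 8.8 pF pL^-1, and the fraction of cytosolic volume rapidly accessible
#' to Ca2+ (0.35--0.37; myofilaments, mitochondria and nuclei exclude the
#' rest).
#' @param accessible_fraction fraction of cell volume accessible to Ca2+.
#' @return list of class `cell_params`.
#' @export
cell_params <- function(accessible_fraction = 0.37) {
  stopifnot(accessible_fraction >= 0.35, accessible_fraction <= 0.37)
  structure(list(V_cell_pL = 36.8, C_m_pF = 324, surface_to_volume = 8.8,
                 accessible_fraction = accessible_fraction,
                 accessible_volume_pL = 36.8 * accessible_fraction),
            class = "cell_params")
}

#' Ionic conditions
#'
#' @param Ca_e extracellular Ca2+ (uM), default 1000 (1 mM), constant.
#' @param Ca_rest resting cytosolic Ca2+ (uM), default 0.1.
#' @param Na_i cytosolic Na+ (mM), held constant at 10.
#' @param Na_e extracellular Na+ (mM); 140 normally, 0 for the
#'   NCX-forward-mode-inhibition scenario.
#' @return list of class `ion_conditions`.
#' @export
ion_conditions <- function(Ca_e = 1000, Ca_rest = 0.1, Na_i = 10, Na_e = 140) {
  stopifnot(Ca_e > 0, Ca_rest >= 0, Na_i > 0, Na_e >= 0)
  structure(list(Ca_e = Ca_e, Ca_rest = Ca_rest, Na_i = Na_i, Na_e = Na_e),
            class = "ion_conditions")
}

#' Na+/Ca2+ exchanger parameters (electrochemical formulation)
#' @param V_max pump rate (uM ms^-1), default 38.5.
#' @param eta voltage-partition parameter, default 0.35.
#' @param K_Na Na+ half-saturation (mM), default 87.5.
#' @param K_Ca Ca2+ half-saturation (uM), default 1380.
#' @param k_sat low-potential saturation factor, default 0.1.
#' @return list of class `ncx_params`.
#' @export
ncx_params <- function(V_max = 38.5, eta = 0.35, K_Na = 87.5,
                       K_Ca = 1380, k_sat = 0.1) {
  stopifnot(eta > 0, eta < 1, V_max > 0, K_Na > 0, K_Ca > 0, k_sat > 0)
  structure(list(V_max = V_max, eta = eta, K_Na = K_Na, K_Ca = K_Ca,
                 k_sat = k_sat), class = "ncx_params")
}

#' L-type Ca2+ current template parameters
#'
#' The whole-cell LCC current during the clamp pulse follows a
#' double-exponential activation/inactivation template
#' `-amplitude * (1 - exp(-t/tau_act)) * exp(-t/tau_inact)` with
#' tau_act = 4 ms and tau_inact = 70 ms, and decays with a fast
#' deactivation constant `tau_deact` after repolarization. `amplitude`
#' (pA/pF, positive number; the current itself is inward/negative) is a
#' calibrated free parameter, set so the dye-present global Ca2+ peak
#' matches the measured 163 nM (see [calibrate_lcc_amplitude()]).
#' @param amplitude peak-scale factor (pA pF^-1), positive.
#' @param tau_act activation time constant (ms).
#' @param tau_inact inactivation time constant (ms).
#' @param tau_deact post-pulse deactivation time constant (ms).
#' @param A_scale dimensionless scale constant, default 1.
#' @return list of class `lcc_params`.
#' @export
lcc_params <- function(amplitude = 1, tau_act = 4, tau_inact = 70,
                       tau_deact = 1, A_scale = 1) {
  stopifnot(tau_act > 0, tau_inact > 0, tau_deact > 0, amplitude >= 0)
  structure(list(amplitude = amplitude, tau_act = tau_act,
                 tau_inact = tau_inact, tau_deact = tau_deact,
                 A_scale = A_scale), class = "lcc_params")
}

#' Voltage-clamp protocol
#'
#' Holding potential -50 mV, depolarizing step (default to +10 mV, near
#' the LCC current maximum) for 70 ms, 400 ms total.
#' @param V_hold holding potential (mV).
#' @param V_pulse pulse potential (mV).
#' @param pulse_duration pulse length (ms).
#' @param total_duration simulated interval (ms).
#' @return list of class `voltage_protocol`.
#' @export
voltage_protocol <- function(V_hold = -50, V_pulse = 10,
                             pulse_duration = 70, total_duration = 400) {
  stopifnot(pulse_duration > 0, pulse_duration < total_duration)
  structure(list(V_hold = V_hold, V_pulse = V_pulse,
                 pulse_duration = pulse_duration,
                 total_duration = total_duration),
            class = "voltage_protocol")
}

#' Membrane voltage at time t under a clamp protocol
#' @param t time (ms), vectorized.
#' @param protocol a [voltage_protocol()].
#' @return voltage (mV).
#' @export
protocol_voltage <- function(t, protocol) {
  ifelse(t >= 0 & t < protocol$pulse_duration, protocol$V_pulse,
         protocol$V_hold)
}

#' Cubic polynomial weighting of LCC density along the tubule depth
#'
#' Immunolabeling indicates that LCC density increases toward the cell
#' interior. The fitted profile is `C * (p1*x^3 + p2*x^2 + p3*x + p4)`
#' with x the distance (um) from the external cell surface; the prefactor
#' C normalizes the redistribution so the total membrane Ca2+ flux is
#' unchanged.
#' @param C scale factor, default 0.4515.
#' @param p1,p2,p3,p4 cubic coefficients (defaults -4.1379e-4,
#'   -1.1722e-2, 1.978e-1, 1.0033).
#' @return list of class `spatial_weight_params`.
#' @export
spatial_weight_params <- function(C = 0.4515, p1 = -4.1379e-4,
                                  p2 = -1.1722e-2, p3 = 1.978e-1,
                                  p4 = 1.0033) {
  structure(list(C = C, p1 = p1, p2 = p2, p3 = p3, p4 = p4),
            class = "spatial_weight_params")
}

#' Evaluate the LCC depth-weight polynomial
#' @param x depth from the external surface (um), within
#'   `[0, max_depth]`; vectorized.
#' @param params a [spatial_weight_params()].
#' @param max_depth domain upper bound (um), default 5.645.
#' @return dimensionless weight.
#' @examples
#' w <- spatial_weight_params()
#' lcc_spatial_weight(5.645, w) / lcc_spatial_weight(0, w)  # ~1.67
#' @export
lcc_spatial_weight <- function(x, params = spatial_weight_params(),
                               max_depth = 5.645) {
  stopifnot(inherits(params, "spatial_weight_params"))
  if (any(x < -1e-9 | x > max_depth + 1e-9))
    stop("depth x outside [0, ", max_depth, "] um")
  params$C * (params$p1 * x^3 + params$p2 * x^2 + params$p3 * x + params$p4)
}

#' Whole-cell L-type Ca2+ current density
#'
#' During the pulse the current follows the activation/inactivation
#' template; at repolarization the channels deactivate quickly (time
#' constant `tau_deact`) from the value reached at pulse end. Negative
#' values are inward current.
#' @param t time since pulse onset (ms), vectorized.
#' @param protocol a [voltage_protocol()].
#' @param params an [lcc_params()].
#' @return current density (pA pF^-1); 0 before the pulse.
#' @export
lcc_current_density <- function(t, protocol, params) {
  stopifnot(inherits(protocol, "voltage_protocol"),
            inherits(params, "lcc_params"))
  tp <- protocol$pulse_duration
  shape <- function(u) (1 - exp(-u / params$tau_act)) * exp(-u / params$tau_inact)
  I <- numeric(length(t))
  during <- t >= 0 & t <= tp
  after <- t > tp
  I[during] <- -params$amplitude * params$A_scale * shape(t[during])
  I[after] <- -params$amplitude * params$A_scale * shape(tp) *
    exp(-(t[after] - tp) / params$tau_deact)
  I
}

#' Na+/Ca2+ exchange Ca2+ flux
#'
#' Electrochemical NCX formulation: with `phi = V*F/(R*T)` (V in volts),
#' `J = V_max * (exp(eta*phi) * Na_i^3 * Ca_e - exp((eta-1)*phi) * Na_e^3 * Ca_i) /
#'  ((K_Na^3 + Na_e^3) * (K_Ca + Ca_e) * (1 + k_sat * exp((eta-1)*phi)))`.
#' Positive values are Ca2+ entry into the cytosol (reverse mode);
#' at rest (-50 mV, 0.1 uM Ca_i, 140 mM Na_e) the exchanger extrudes
#' Ca2+ (J ~ -1.69e-3 uM/ms).
#' @param V membrane potential (mV).
#' @param Ca_i cytosolic Ca2+ (uM), > 0; vectorized.
#' @param ions an [ion_conditions()].
#' @param params an [ncx_params()].
#' @param k [physical_constants()].
#' @return Ca2+ flux (uM ms^-1), positive = entry.
#' @export
ncx_flux <- function(V, Ca_i, ions = ion_conditions(),
                     params = ncx_params(), k = physical_constants()) {
  stopifnot(inherits(ions, "ion_conditions"), inherits(params, "ncx_params"))
  phi <- (V / 1000) * (k$F_const * 1000) / (k$R_gas * k$T)  # F in C/mol
  ef <- exp(params$eta * phi)
  er <- exp((params$eta - 1) * phi)
  num <- params$V_max * (ef * ions$Na_i^3 * ions$Ca_e - er * ions$Na_e^3 * Ca_i)
  den <- (params$K_Na^3 + ions$Na_e^3) * (params$K_Ca + ions$Ca_e) *
    (1 + params$k_sat * er)
  num / den
}

#' Nernst potential for Ca2+ (mV)
#' @param Ca_i cytosolic Ca2+ (uM), > 0.
#' @param Ca_e extracellular Ca2+ (uM).
#' @param k [physical_constants()].
#' @return `(RT / 2F) * ln(Ca_e / Ca_i)` in mV.
#' @export
nernst_ca <- function(Ca_i, Ca_e = 1000, k = physical_constants()) {
  if (any(Ca_i <= 0)) stop("Ca_i must be positive (Nernst potential undefined)")
  1000 * (k$R_gas * k$T) / (2 * k$F_const * 1000) * log(Ca_e / Ca_i)
}

#' Background membrane Ca2+ leak flux
#'
#' A phenomenological conductance-style flux `g_leak * (E_Ca - V)` with
#' E_Ca the Ca2+ Nernst potential. It is not a specific transport protein;
#' its conductance is calibrated (see [calibrate_rest_leak()]) so the
#' resting membrane carries no net Ca2+ flux.
#' @param V membrane potential (mV).
#' @param Ca_i cytosolic Ca2+ (uM), > 0; vectorized.
#' @param ions an [ion_conditions()].
#' @param g_leak leak conductance (uM mV^-1 ms^-1).
#' @param k [physical_constants()].
#' @return Ca2+ flux (uM ms^-1), positive = entry when g_leak > 0.
#' @export
leak_flux <- function(V, Ca_i, ions = ion_conditions(), g_leak,
                      k = physical_constants()) {
  E_Ca <- nernst_ca(Ca_i, ions$Ca_e, k)
  g_leak * (E_Ca - V)
}

#' Calibrate the leak conductance for resting flux balance
#'
#' Solves `g_leak * (E_Ca - V_hold) = -J_NCX(V_hold, Ca_rest)` so that at
#' rest the leak exactly cancels the exchanger and no net Ca2+ crosses the
#' membrane. With 140 mM external Na+ the exchanger extrudes Ca2+ at rest
#' and g_leak is positive; with 0 mM external Na+ the exchanger runs in
#' pure entry mode and g_leak becomes negative (the leak then extrudes),
#' matching the signs of the two reference conductances (+3.4e-6 and
#' -6.8e-6 uM mV^-1 ms^-1).
#' @param ions an [ion_conditions()].
#' @param ncx an [ncx_params()].
#' @param protocol a [voltage_protocol()] (supplies the resting V_hold).
#' @param k [physical_constants()].
#' @return g_leak (uM mV^-1 ms^-1).
#' @export
calibrate_rest_leak <- function(ions = ion_conditions(), ncx = ncx_params(),
                                protocol = voltage_protocol(),
                                k = physical_constants()) {
  J_ncx <- ncx_flux(protocol$V_hold, ions$Ca_rest, ions, ncx, k)
  driving <- nernst_ca(ions$Ca_rest, ions$Ca_e, k) - protocol$V_hold
  if (abs(driving) < 1e-9) stop("zero leak driving force at rest")
  -J_ncx / driving
}

#' Convert a membrane current density to a cytosolic Ca2+ flux
#'
#' `J = -I * (surface-to-volume ratio) / (2F)`: with I in pA/pF, the
#' capacitance-to-volume ratio 8.8 pF/pL and F = 96.5 C/mmol the result
#' is in uM ms^-1 directly (pA/pL = mM/s per 2F coulomb per mmol Ca2+).
#' Inward (negative) current yields a positive cytosolic flux.
#' @param I current density (pA pF^-1), vectorized.
#' @param cell a [cell_params()].
#' @param k [physical_constants()].
#' @return Ca2+ flux (uM ms^-1).
#' @export
current_density_to_flux <- function(I, cell = cell_params(),
                                    k = physical_constants()) {
  -I * cell$surface_to_volume / (2 * k$F_const)
}

#' Membrane flux distribution scenario
#'
#' How LCC, NCX and leak densities are laid over the two membrane labels:
#' * `lcc_mode = "heterogeneous_polynomial"` -- LCC density follows the
#'   cubic depth polynomial ([lcc_spatial_weight()]);
#' * `"uniform_6x_ttubule"` -- uniform but six-fold higher on the t-tubule
#'   membrane than on the external membrane;
#' * `"homogeneous"` -- uniform everywhere.
#' NCX density is `ncx_ttubule_ratio` (3 or 1) times higher on the
#' t-tubule membrane; the leak is always homogeneous. Every redistribution
#' preserves the whole-compartment total of each flux component.
#' @param lcc_mode LCC distribution mode (see above).
#' @param ncx_ttubule_ratio 3 (default for the non-homogeneous LCC modes)
#'   or 1.
#' @return list of class `flux_scenario`.
#' @export
flux_scenario <- function(lcc_mode = c("heterogeneous_polynomial",
                                       "uniform_6x_ttubule", "homogeneous"),
                          ncx_ttubule_ratio = NULL) {
  lcc_mode <- match.arg(lcc_mode)
  if (is.null(ncx_ttubule_ratio))
    ncx_ttubule_ratio <- if (lcc_mode == "homogeneous") 1 else 3
  stopifnot(ncx_ttubule_ratio %in% c(1, 3))
  structure(list(lcc_mode = lcc_mode, ncx_ttubule_ratio = ncx_ttubule_ratio,
                 leak_mode = "homogeneous"), class = "flux_scenario")
}

# Per-facet dimensionless weights for one component on the membrane facets.
# mode: "poly" (depth polynomial), ratio (t-tubule:external density ratio).
facet_weights <- function(mesh, component = c("lcc", "ncx", "leak"),
                          scenario, weight_params = spatial_weight_params(),
                          tubule_depth = NULL) {
  component <- match.arg(component)
  memb <- mesh$facet_label %in% c("external_membrane", "ttubule_membrane")
  lab <- mesh$facet_label[memb]
  tt <- lab == "ttubule_membrane"
  w <- rep(1, sum(memb))
  if (component == "lcc") {
    if (scenario$lcc_mode == "heterogeneous_polynomial") {
      # the polynomial redistributes the t-tubular share of the LCC flux
      # along the tubule depth while keeping the t-tubular total -- and
      # hence the 6:1 tubule:external budget of the uniform-6x case --
      # unchanged
      if (is.null(tubule_depth))
        tubule_depth <- max(mesh$facet_centroid[memb, 3][tt])
      depth <- pmin(pmax(mesh$facet_centroid[memb, 3][tt], 0), tubule_depth)
      wp <- lcc_spatial_weight(depth, weight_params, max_depth = tubule_depth)
      A <- mesh$facet_area[memb]
      w[tt] <- wp * (6 * sum(A[tt])) / sum(A[tt] * wp)
    } else if (scenario$lcc_mode == "uniform_6x_ttubule") {
      w[tt] <- 6
    }
  } else if (component == "ncx") {
    w[tt] <- scenario$ncx_ttubule_ratio
  }
  w
}

#' Per-facet membrane Ca2+ flux densities
#'
#' Distributes the whole-compartment fluxes over the membrane facets of a
#' labeled mesh. For each component the facet density is
#' `V_comp * w_f * j(Ca_f) / sum_f(A_f * w_f)` where `w_f` is the
#' scenario weight, `j` the global flux model evaluated at the facet-local
#' Ca2+ and `V_comp` the compartment volume, so that at spatially uniform
#' Ca2+ the area-weighted total equals the whole-compartment flux
#' `j * V_comp` for every scenario (redistribution conserves the total).
#' @param mesh a `labeled_mesh` (see [generate_ttubule_mesh()]).
#' @param scenario a [flux_scenario()].
#' @param t time since pulse onset (ms).
#' @param local_Ca per-membrane-facet cytosolic Ca2+ (uM); a scalar is
#'   recycled.
#' @param lcc an [lcc_params()] (calibrated amplitude).
#' @param protocol a [voltage_protocol()].
#' @param ions an [ion_conditions()].
#' @param ncx an [ncx_params()].
#' @param g_leak leak conductance (uM mV^-1 ms^-1).
#' @param cell a [cell_params()].
#' @param weight_params a [spatial_weight_params()].
#' @param k [physical_constants()].
#' @return list with `facet_index` (indices of membrane facets within the
#'   mesh facet list), per-facet densities (uM um ms^-1) `lcc`, `ncx`,
#'   `leak`, and their sum `total`.
#' @export
build_boundary_flux <- function(mesh, scenario, t, local_Ca,
                                lcc = lcc_params(),
                                protocol = voltage_protocol(),
                                ions = ion_conditions(),
                                ncx = ncx_params(), g_leak,
                                cell = cell_params(),
                                weight_params = spatial_weight_params(),
                                k = physical_constants()) {
  stopifnot(inherits(scenario, "flux_scenario"))
  memb <- which(mesh$facet_label %in% c("external_membrane", "ttubule_membrane"))
  if (!length(memb)) stop("mesh has no membrane-labeled facets")
  A <- mesh$facet_area[memb]
  nCa <- length(local_Ca)
  if (nCa == 1L) local_Ca <- rep(local_Ca, length(memb))
  if (length(local_Ca) != length(memb))
    stop("local_Ca must have one value per membrane facet")
  V <- mesh$stats$compartment_volume
  Vnow <- protocol_voltage(t, protocol)

  dens_of <- function(component, j_local) {
    w <- facet_weights(mesh, component, scenario, weight_params)
    V * w * j_local / sum(A * w)
  }
  j_lcc <- current_density_to_flux(lcc_current_density(t, protocol, lcc),
                                   cell, k)
  out <- list(facet_index = memb,
              lcc = dens_of("lcc", j_lcc),
              ncx = dens_of("ncx", ncx_flux(Vnow, local_Ca, ions, ncx, k)),
              leak = dens_of("leak", leak_flux(Vnow, local_Ca, ions, g_leak, k)))
  out$total <- out$lcc + out$ncx + out$leak
  out
}
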