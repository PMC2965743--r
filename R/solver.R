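#' Simulation configuration
#'
#' Bundles everything one run needs: buffers, flux scenario, clamp
#' protocol, ionic conditions, flux-model parameters and numerical
#' settings. The leak conductance is calibrated at construction
#' ([calibrate_rest_leak()]) unless supplied explicitly.
#'
#' @param buffers a [buffer_set()].
#' @param scenario a [flux_scenario()].
#' @param protocol a [voltage_protocol()].
#' @param ions an [ion_conditions()].
#' @param lcc an [lcc_params()]; its amplitude is usually set by
#'   [calibrate_lcc_amplitude()].
#' @param ncx an [ncx_params()].
#' @param cell a [cell_params()].
#' @param weight_params a [spatial_weight_params()].
#' @param g_leak leak conductance (uM mV^-1 ms^-1) or `NULL` to calibrate.
#' @param dt time step (ms). Backward-Euler stepping; the default 0.1 ms
#'   resolves the fastest buffer relaxation (ATP, ~45 ms^-1).
#' @param duration simulated interval (ms).
#' @param output_every output sampling interval (ms) for 3-D fields.
#' @param immobilize character vector of buffer names whose Ca-bound
#'   complex is made stationary (D set to 0) without changing kinetics,
#'   e.g. `c("ATP", "Cal")` for the immobilization scenario.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(buffers = buffer_set(),
                              scenario = flux_scenario(),
                              protocol = voltage_protocol(),
                              ions = ion_conditions(),
                              lcc = lcc_params(),
                              ncx = ncx_params(),
                              cell = cell_params(),
                              weight_params = spatial_weight_params(),
                              g_leak = NULL,
                              dt = 0.1, duration = 400,
                              output_every = 5,
                              immobilize = character()) {
  stopifnot(dt > 0, duration > 0, output_every >= dt)
  if (is.null(g_leak))
    g_leak <- calibrate_rest_leak(ions, ncx, protocol)
  bad <- setdiff(immobilize, names(buffers$buffers))
  if (length(bad)) stop("unknown buffer(s) to immobilize: ",
                        paste(bad, collapse = ", "))
  structure(list(buffers = buffers, scenario = scenario,
                 protocol = protocol, ions = ions, lcc = lcc, ncx = ncx,
                 cell = cell, weight_params = weight_params,
                 g_leak = g_leak, dt = dt, duration = duration,
                 output_every = output_every, immobilize = immobilize),
            class = "simulation_config")
}

# effective complex diffusivity under the immobilization override
buffer_diffusivities <- function(config) {
  vapply(config$buffers$buffers, function(b)
    if (b$name %in% config$immobilize) 0 else b$D_complex, numeric(1))
}

# --- 0-D (well-mixed) reduction -------------------------------------------

#' Well-mixed (0-D) reduction of the compartment model
#'
#' Integrates the spatially averaged system
#' `dCa/dt = J_LCC + J_NCX + J_leak - sum(R_i)`,
#' `dCaB_i/dt = R_i` with a stiff solver (`deSolve::lsoda`), starting
#' from buffer equilibrium at the resting Ca2+. Because the global Ca2+
#' time course is insensitive to the spatial flux distribution, this
#' reduction serves for amplitude calibration and as a cross-check of
#' the 3-D solver.
#'
#' @param config a [simulation_config()].
#' @param times output times (ms); default `seq(0, duration, by = 1)`.
#' @return data frame of class `global_transient`: `time` (ms), `Ca`
#'   (uM), one column per buffer complex (uM), and the global fluxes
#'   `J_lcc`, `J_ncx`, `J_leak` (uM ms^-1).
#' @export
run_0d <- function(config, times = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(times)) times <- seq(0, config$duration, by = 1)
  bufs <- config$buffers$buffers
  nb <- length(bufs)
  eq <- equilibrium_state(config$ions$Ca_rest, config$buffers)
  y0 <- c(Ca = eq$Ca, eq$CaB)
  k <- physical_constants()
  B_tot <- vapply(bufs, `[[`, numeric(1), "B_total")
  k_on <- vapply(bufs, `[[`, numeric(1), "k_on")
  k_off <- vapply(bufs, `[[`, numeric(1), "k_off")

  rhs <- function(t, y, parms) {
    Ca <- y[1]; CaB <- y[-1]
    V <- protocol_voltage(t, config$protocol)
    J_lcc <- current_density_to_flux(
      lcc_current_density(t, config$protocol, config$lcc), config$cell, k)
    J_ncx <- ncx_flux(V, Ca, config$ions, config$ncx, k)
    J_leak <- leak_flux(V, Ca, config$ions, config$g_leak, k)
    R <- k_on * Ca * (B_tot - CaB) - k_off * CaB
    list(c(J_lcc + J_ncx + J_leak - sum(R), R),
         c(J_lcc = J_lcc, J_ncx = J_ncx, J_leak = J_leak))
  }
  # integrate across the repolarization kink piecewise
  tp <- config$protocol$pulse_duration
  t1 <- sort(unique(c(times[times <= tp], tp)))
  t2 <- sort(unique(c(tp, times[times >= tp])))
  s1 <- deSolve::lsoda(y0, t1, rhs, rtol = 1e-8, atol = 1e-10)
  s2 <- deSolve::lsoda(s1[nrow(s1), 2:(2 + nb)], t2, rhs,
                       rtol = 1e-8, atol = 1e-10)
  out <- rbind(s1[s1[, "time"] %in% times, , drop = FALSE],
               s2[s2[, "time"] %in% times & s2[, "time"] > tp, ,
                  drop = FALSE])
  out <- as.data.frame(out)
  names(out) <- c("time", "Ca", names(bufs), "J_lcc", "J_ncx", "J_leak")
  class(out) <- c("global_transient", "data.frame")
  out
}

#' Calibrate the LCC amplitude against a measured global Ca2+ peak
#'
#' Finds, by monotone bisection on the 0-D model, the LCC template
#' amplitude (pA/pF) whose global free-Ca2+ peak equals `target_peak`
#' within `tol`. The reference target is the measured peak of 163 nM in
#' dye-loaded myocytes with SR function blocked.
#'
#' @param target_peak target global Ca2+ peak (uM).
#' @param config a [simulation_config()] (the dye concentration in its
#'   buffer set is part of the calibration condition).
#' @param tol peak tolerance (uM), default 1e-3 (1 nM).
#' @param upper upper bracket for the amplitude (pA/pF).
#' @return calibrated amplitude (pA pF^-1).
#' @export
calibrate_lcc_amplitude <- function(target_peak, config, tol = 1e-3,
                                    upper = 40) {
  stopifnot(inherits(config, "simulation_config"),
            target_peak >= config$ions$Ca_rest)
  if (abs(target_peak - config$ions$Ca_rest) < tol / 2) return(0)
  peak_of <- function(a) {
    cfg <- config
    cfg$lcc$amplitude <- a
    max(run_0d(cfg, times = seq(0, config$duration, by = 1))$Ca)
  }
  lo <- 0; hi <- upper
  if (peak_of(hi) < target_peak)
    stop("target peak unreachable within amplitude bracket [0, ", upper, "]")
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    p <- peak_of(mid)
    if (abs(p - target_peak) < tol) return(mid)
    if (p < target_peak) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# --- P1 finite elements ----------------------------------------------------

# Lumped mass vector and stiffness matrix for P1 elements on a tet mesh.
fem_matrices <- function(mesh) {
  v <- mesh$vertices; tt <- mesh$tets
  m <- nrow(tt)
  a <- v[tt[, 1], , drop = FALSE]
  e1 <- v[tt[, 2], , drop = FALSE] - a
  e2 <- v[tt[, 3], , drop = FALSE] - a
  e3 <- v[tt[, 4], , drop = FALSE] - a
  # det and inverse-transpose rows -> gradients of barycentric functions
  cx <- e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
  cy <- e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]
  cz <- e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
  det <- e1[, 1] * cx + e1[, 2] * cy + e1[, 3] * cz   # 6 * volume
  vol <- det / 6
  # grad lambda_2 = (e2 x e3 resolved) etc., columns are xyz
  g2 <- cbind(cx, cy, cz) / det
  g3 <- cbind(e3[, 2] * e1[, 3] - e3[, 3] * e1[, 2],
              e3[, 3] * e1[, 1] - e3[, 1] * e1[, 3],
              e3[, 1] * e1[, 2] - e3[, 2] * e1[, 1]) / det
  g4 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / det
  g1 <- -(g2 + g3 + g4)
  G <- list(g1, g2, g3, g4)
  idx_i <- integer(16 * m); idx_j <- integer(16 * m); val <- numeric(16 * m)
  pos <- 1L
  for (i in 1:4) for (j in 1:4) {
    rng <- pos:(pos + m - 1L)
    idx_i[rng] <- tt[, i]
    idx_j[rng] <- tt[, j]
    val[rng] <- vol * rowSums(G[[i]] * G[[j]])
    pos <- pos + m
  }
  K <- Matrix::sparseMatrix(i = idx_i, j = idx_j, x = val,
                            dims = c(nrow(v), nrow(v)))
  Mlump <- as.numeric(Matrix::sparseMatrix(
    i = as.vector(tt), j = rep(1L, 4L * m), x = rep(vol / 4, 4),
    dims = c(nrow(v), 1)))
  list(K = Matrix::forceSymmetric(K), Mlump = Mlump, vol = vol)
}

# membrane facet -> vertex load operator (B: n_vert x n_memb, A_f/3 each)
# and vertex -> facet averaging operator (F: n_memb x n_vert, 1/3 each)
membrane_operators <- function(mesh) {
  memb <- which(mesh$facet_label %in% c("external_membrane",
                                        "ttubule_membrane"))
  f <- mesh$facets[memb, , drop = FALSE]
  nm <- length(memb)
  B <- Matrix::sparseMatrix(i = as.vector(f), j = rep(seq_len(nm), 3),
                            x = rep(mesh$facet_area[memb] / 3, 3),
                            dims = c(nrow(mesh$vertices), nm))
  Fop <- Matrix::sparseMatrix(i = rep(seq_len(nm), 3), j = as.vector(f),
                              x = rep(1 / 3, 3 * nm),
                              dims = c(nm, nrow(mesh$vertices)))
  list(index = memb, B = B, F = Fop)
}

# implicit reaction substep: per node, backward-Euler update of all
# buffers coupled through free Ca; reduces to a scalar monotone equation
# in Ca solved by vectorized Newton. Conserves Ca + sum(CaB) per node
# exactly.
reaction_step <- function(Ca, CaB, dt, B_tot, k_on, k_off) {
  nb <- length(k_on)
  total <- Ca
  for (b in seq_len(nb)) total <- total + CaB[[b]]
  x <- Ca
  for (it in 1:50) {
    fx <- x - total
    dfx <- rep(1, length(x))
    for (b in seq_len(nb)) {
      aa <- dt * k_on[b] * B_tot[[b]]
      bb <- dt * k_on[b]
      ee <- 1 + dt * k_off[b]
      den <- ee + bb * x
      cb <- (CaB[[b]] + aa * x) / den
      fx <- fx + cb
      dfx <- dfx + (aa * den - bb * (CaB[[b]] + aa * x)) / (den * den)
    }
    step <- fx / dfx
    x <- x - step
    x[x < 0] <- 0
    if (max(abs(step)) < 1e-13) break
  }
  out <- vector("list", nb)
  for (b in seq_len(nb)) {
    den <- 1 + dt * k_off[b] + dt * k_on[b] * x
    out[[b]] <- (CaB[[b]] + dt * k_on[b] * B_tot[[b]] * x) / den
  }
  # close the balance exactly
  xc <- total
  for (b in seq_len(nb)) xc <- xc - out[[b]]
  list(Ca = pmax(xc, 0), CaB = out)
}

#' Run the 3-D reaction-diffusion simulation
#'
#' Advances the coupled Ca2+/buffer system on a labeled mesh: free Ca2+
#' and mobile complexes diffuse (P1 finite elements, lumped mass),
#' membrane Ca2+ fluxes enter as Neumann conditions on the labeled
#' membrane facets ([build_boundary_flux()]), and binding kinetics are
#' integrated by an implicit (backward-Euler) reaction substep in a
#' first-order operator split. The stationary buffer troponin C is
#' removed from nodes within the sub-sarcolemmal exclusion depth of the
#' membrane. Deterministic for fixed inputs.
#'
#' @param mesh a `labeled_mesh`.
#' @param config a [simulation_config()].
#' @param record_fields logical; keep full per-node fields at the output
#'   times (memory permitting) or only global summaries.
#' @return object of class `solution`: list with `time` (output times,
#'   ms), `fields` (list of n_vertex x n_time matrices: `Ca` and one per
#'   buffer complex), `global` (a `global_transient` data frame),
#'   `mass` (data frame with volume-integrated total Ca and cumulative
#'   membrane influx, uM um^3), `mesh`, `config`.
#' @export
run_3d <- function(mesh, config, record_fields = TRUE) {
  stopifnot(inherits(mesh, "labeled_mesh"),
            inherits(config, "simulation_config"))
  bufs <- config$buffers$buffers
  nb <- length(bufs)
  nv <- nrow(mesh$vertices)
  dt <- config$dt
  k <- physical_constants()

  fem <- fem_matrices(mesh)
  ops <- membrane_operators(mesh)
  Db <- buffer_diffusivities(config)

  # per-node total TN (stationary buffers excluded near the membrane)
  dist <- mesh$membrane_distance
  if (is.null(dist)) dist <- distance_to_membrane_field(mesh)
  B_tot <- vector("list", nb)
  for (b in seq_len(nb)) {
    bt <- rep(bufs[[b]]$B_total, nv)
    if (!bufs[[b]]$mobile)
      bt[dist <= config$buffers$tn_exclusion_um + 1e-12] <- 0
    B_tot[[b]] <- bt
  }
  k_on <- vapply(bufs, `[[`, numeric(1), "k_on")
  k_off <- vapply(bufs, `[[`, numeric(1), "k_off")

  # initial equilibrium at resting Ca
  Ca <- rep(config$ions$Ca_rest, nv)
  CaB <- vector("list", nb)
  for (b in seq_len(nb))
    CaB[[b]] <- B_tot[[b]] * Ca / (bufs[[b]]$K_d + Ca)

  # pre-factorized backward-Euler diffusion operators
  Md <- Matrix::Diagonal(x = fem$Mlump)
  fac_ca <- Matrix::Cholesky(Md + dt * config$buffers$D_Ca * fem$K,
                             LDL = FALSE)
  fac_b <- vector("list", nb)
  for (b in seq_len(nb))
    if (Db[b] > 0)
      fac_b[[b]] <- Matrix::Cholesky(Md + dt * Db[b] * fem$K, LDL = FALSE)

  nsteps <- ceiling(config$duration / dt)
  out_stride <- max(1L, round(config$output_every / dt))
  out_idx <- unique(c(seq(0L, nsteps, by = out_stride), nsteps))
  nt <- length(out_idx)
  times <- out_idx * dt

  fields <- NULL
  if (record_fields) {
    fields <- c(list(Ca = matrix(NA_real_, nv, nt)),
                stats::setNames(replicate(nb, matrix(NA_real_, nv, nt),
                                          simplify = FALSE), names(bufs)))
  }
  glob <- matrix(NA_real_, nt, 5,
                 dimnames = list(NULL, c("time", "Ca", "J_lcc", "J_ncx",
                                         "J_leak")))
  mass <- matrix(NA_real_, nt, 3,
                 dimnames = list(NULL, c("time", "total_ca", "influx")))
  Vtot <- sum(fem$Mlump)
  Vcomp <- mesh$stats$compartment_volume
  influx_cum <- 0

  record <- function(slot, tnow, dens) {
    if (record_fields) {
      fields$Ca[, slot] <<- Ca
      for (b in seq_len(nb)) fields[[b + 1L]][, slot] <<- CaB[[b]]
    }
    total <- sum(fem$Mlump * Ca)
    for (b in seq_len(nb)) total <- total + sum(fem$Mlump * CaB[[b]])
    A <- mesh$facet_area[ops$index]
    glob[slot, ] <<- c(tnow, sum(fem$Mlump * Ca) / Vtot,
                       sum(A * dens$lcc) / Vcomp,
                       sum(A * dens$ncx) / Vcomp,
                       sum(A * dens$leak) / Vcomp)
    mass[slot, ] <<- c(tnow, total, influx_cum)
  }

  slot <- 1L
  dens0 <- build_boundary_flux(mesh, config$scenario, 0,
                               as.numeric(ops$F %*% Ca), config$lcc,
                               config$protocol, config$ions, config$ncx,
                               config$g_leak, config$cell,
                               config$weight_params, k)
  record(slot, 0, dens0); slot <- slot + 1L

  for (n in seq_len(nsteps)) {
    tn <- (n - 1L) * dt
    dens <- build_boundary_flux(mesh, config$scenario, tn,
                                as.numeric(ops$F %*% Ca), config$lcc,
                                config$protocol, config$ions, config$ncx,
                                config$g_leak, config$cell,
                                config$weight_params, k)
    load <- as.numeric(ops$B %*% dens$total)
    influx_cum <- influx_cum + dt * sum(load)
    # implicit diffusion
    Ca <- as.numeric(Matrix::solve(fac_ca, fem$Mlump * Ca + dt * load))
    for (b in seq_len(nb))
      if (Db[b] > 0)
        CaB[[b]] <- as.numeric(Matrix::solve(fac_b[[b]],
                                             fem$Mlump * CaB[[b]]))
    # implicit reaction
    rs <- reaction_step(Ca, CaB, dt, B_tot, k_on, k_off)
    Ca <- rs$Ca; CaB <- rs$CaB
    if (any(!is.finite(Ca)))
      stop("3-D solve diverged at t = ", tn, " ms; reduce dt")
    if (n %in% out_idx) {
      record(slot, n * dt, dens)
      slot <- slot + 1L
    }
  }

  global <- as.data.frame(glob)
  class(global) <- c("global_transient", "data.frame")
  structure(list(time = times, fields = fields, global = global,
                 mass = as.data.frame(mass), mesh = mesh, config = config),
            class = "solution")
}

#' @export
print.solution <- function(x, ...) {
  cat(sprintf("solution: %d output times over %g ms, %d nodes, %d species\n",
              length(x$time), max(x$time), nrow(x$mesh$vertices),
              1L + length(x$config$buffers$buffers)))
  m <- transient_metrics(x$global)
  cat(sprintf("global Ca: peak %.4f uM at %.1f ms\n", m$peak, m$t_peak))
  invisible(x)
}

#' Verify global Ca2+ mass conservation of a solution
#'
#' At every output time compares the change of the volume-integrated
#' total Ca2+ (free + all bound forms) against the time-integrated
#' membrane influx. The operator-split scheme conserves mass to solver
#' precision, so violations indicate a wiring defect.
#'
#' @param solution a [run_3d()] result.
#' @param tol relative tolerance, default 1e-6.
#' @return list with `ok`, `max_rel_error`, `worst_time` (ms).
#' @export
check_conservation <- function(solution, tol = 1e-6) {
  stopifnot(inherits(solution, "solution"))
  m <- solution$mass
  drift <- (m$total_ca - m$total_ca[1]) - m$influx
  rel <- abs(drift) / max(abs(m$total_ca))
  list(ok = all(rel <= tol), max_rel_error = max(rel),
       worst_time = m$time[which.max(rel)])
}
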