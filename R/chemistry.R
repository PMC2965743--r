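#' Ca2+ buffer parameters
#'
#' Bundles the kinetic and diffusive description of one cytosolic Ca2+
#' buffer: total concentration, on/off rate constants, diffusion coefficient
#' of the Ca-bound complex and a mobility flag. Ca2+ binds without
#' cooperativity, so a single site with dissociation constant
#' `K_d = k_off / k_on` describes each buffer.
#'
#' @param name buffer name (unique within a [buffer_set()]).
#' @param B_total total buffer concentration (uM).
#' @param k_on on-rate constant (uM^-1 ms^-1).
#' @param k_off off-rate constant (ms^-1).
#' @param D_complex diffusion coefficient of the Ca-bound complex
#'   (um^2 ms^-1); must be 0 for stationary buffers. The free and bound
#'   forms are assumed to diffuse equally fast, so the total buffer field
#'   stays spatially uniform (stationary buffers excepted).
#' @param mobile logical; `FALSE` for stationary buffers (troponin C).
#' @return an object of class `buffer_params`.
#' @examples
#' fluo <- buffer_params("Fluo3", 100, 0.23, 0.17, 0.1, TRUE)
#' fluo$K_d   # 0.739 uM
#' @export
buffer_params <- function(name, B_total, k_on, k_off, D_complex = 0,
                          mobile = D_complex > 0) {
  stopifnot(is.character(name), length(name) == 1L,
            B_total >= 0, k_on > 0, k_off >= 0, D_complex >= 0)
  if (!mobile && D_complex != 0)
    stop("stationary buffer must have D_complex = 0")
  structure(list(name = name, B_total = B_total, k_on = k_on, k_off = k_off,
                 K_d = k_off / k_on, D_complex = D_complex,
                 mobile = isTRUE(mobile)),
            class = "buffer_params")
}

#' Default cytosolic buffer set
#'
#' The four buffers of the compartment model: the indicator dye Fluo-3
#' (100 uM, K_d 0.739 uM, D 0.1 um^2/ms), ATP (260 uM, K_d 200 uM,
#' D 0.168), calmodulin (24 uM, K_d 2.38 uM, D 0.025) -- all mobile --
#' and stationary troponin C (70 uM, K_d 1 uM). Free Ca2+ diffuses at
#' `D_Ca` = 0.39 um^2/ms. Troponin C is absent from the sub-sarcolemmal
#' shell of depth `tn_exclusion_um` (45 nm, midpoint of the reported
#' 40--50 nm range).
#'
#' @param fluo_total total Fluo-3 concentration (uM); 0 removes the dye.
#' @param atp_total total ATP concentration (uM).
#' @param cal_total total calmodulin concentration (uM).
#' @param tn_total total troponin C concentration (uM).
#' @param D_Ca free Ca2+ diffusion coefficient (um^2 ms^-1).
#' @param tn_exclusion_um troponin-free sub-sarcolemmal depth (um).
#' @param extra optional list of additional [buffer_params()] (e.g. a
#'   stationary phospholipid buffer); appended after the defaults.
#' @return an object of class `buffer_set`: list with elements `buffers`
#'   (named list of `buffer_params`), `D_Ca`, `tn_exclusion_um`.
#' @export
buffer_set <- function(fluo_total = 100, atp_total = 260, cal_total = 24,
                       tn_total = 70, D_Ca = 0.39, tn_exclusion_um = 0.045,
                       extra = list()) {
  stopifnot(D_Ca > 0, tn_exclusion_um >= 0)
  buffers <- list()
  if (fluo_total > 0)
    buffers$Fluo3 <- buffer_params("Fluo3", fluo_total, 0.23, 0.17, 0.1, TRUE)
  if (atp_total > 0)
    buffers$ATP <- buffer_params("ATP", atp_total, 0.225, 45, 0.168, TRUE)
  if (cal_total > 0)
    buffers$Cal <- buffer_params("Cal", cal_total, 0.125, 0.2975, 0.025, TRUE)
  if (tn_total > 0)
    buffers$TN <- buffer_params("TN", tn_total, 0.04, 0.04, 0, FALSE)
  for (b in extra) {
    stopifnot(inherits(b, "buffer_params"))
    if (b$name %in% names(buffers)) stop("duplicate buffer name: ", b$name)
    buffers[[b$name]] <- b
  }
  structure(list(buffers = buffers, D_Ca = D_Ca,
                 tn_exclusion_um = tn_exclusion_um),
            class = "buffer_set")
}

#' Equilibrium species state at a given free Ca2+
#'
#' At equilibrium each buffer satisfies `CaB = B_total * Ca / (K_d + Ca)`,
#' which zeroes every reaction rate simultaneously. Used to initialize
#' simulations at the resting Ca2+ of 0.1 uM.
#'
#' @param Ca0 free Ca2+ concentration (uM), >= 0.
#' @param buffers a [buffer_set()].
#' @return list with `Ca` and named numeric vector `CaB` (uM per buffer).
#' @export
equilibrium_state <- function(Ca0, buffers) {
  stopifnot(inherits(buffers, "buffer_set"))
  if (!is.numeric(Ca0) || length(Ca0) != 1L || is.na(Ca0) || Ca0 < 0)
    stop("Ca0 must be a single non-negative number")
  CaB <- vapply(buffers$buffers,
                function(b) b$B_total * Ca0 / (b$K_d + Ca0), numeric(1))
  list(Ca = Ca0, CaB = CaB)
}

#' Net rate of Ca-buffer complex formation
#'
#' `R = k_on * Ca * (B_total - CaB) - k_off * CaB` (uM/ms); positive R
#' consumes free Ca2+. Vectorized over `Ca`/`CaB`.
#'
#' @param Ca free Ca2+ (uM).
#' @param CaB bound complex concentration (uM).
#' @param buffer a [buffer_params()].
#' @return rate of complex formation (uM ms^-1).
#' @export
reaction_rate <- function(Ca, CaB, buffer) {
  stopifnot(inherits(buffer, "buffer_params"))
  buffer$k_on * Ca * (buffer$B_total - CaB) - buffer$k_off * CaB
}

#' Effective Ca2+ diffusion coefficient under rapid buffering
#'
#' Rapid-buffer approximation in the low-Ca2+ linearization: with binding
#' ratios `beta_i = B_total_i / K_d_i`,
#' `D_eff = (D_Ca + sum_mobile D_i * beta_i) / (1 + sum_all beta_i)`.
#' Stationary buffers contribute to the denominator only. Inputs and the
#' returned value are in um^2 s^-1 to match the conventional reporting
#' scale (the internal dynamics use um^2 ms^-1).
#'
#' @param D_Ca free Ca2+ diffusion coefficient (um^2 s^-1, e.g. 390).
#' @param buffers a [buffer_set()]; its per-ms `D_complex` values are
#'   converted to um^2 s^-1 internally.
#' @return effective diffusion coefficient (um^2 s^-1).
#' @examples
#' # calmodulin + troponin C only, D_Ca = 390 um^2/s -> ~8 um^2/s
#' effective_diffusion(390, buffer_set(fluo_total = 0, atp_total = 0))
#' @export
effective_diffusion <- function(D_Ca, buffers) {
  stopifnot(inherits(buffers, "buffer_set"), D_Ca > 0)
  num <- D_Ca
  den <- 1
  for (b in buffers$buffers) {
    if (b$K_d <= 0) stop("K_d must be positive for buffer ", b$name)
    beta <- b$B_total / b$K_d
    den <- den + beta
    if (b$mobile) num <- num + 1000 * b$D_complex * beta
  }
  num / den
}
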