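# Assembly of the 18-equation steady-state system.
#
# Unknown ordering (natural units): C_1..7^c (mM), C_1..7^p (mM), C_X (mM),
# Q (m^3/s), V^c (mV), V^p (mV).
#
# The fast dissociation step of the buffer is eliminated by replacing the
# HCO3-/H+/H2CO3 balances of each compartment with:
#   (i)  T_HCO3 - T_H = 0                  (difference of the two balances
#                                           sharing the fast-reaction term)
#   (ii) T_HCO3 + T_CO2 + T_H2CO3 = 0      (total carbon conservation)
#   (iii) T_HCO3 + T_H2CO3 - rho_d = 0     (slow step kinetics)
#   (iv) C_H2CO3 = K_eq * C_H * C_HCO3     (fast-step equilibrium)
# where T_i is the net transport (minus advective export, in the PC) of
# species i into the compartment and rho_d = vol * (k_d C_H2CO3 - k_h C_CO2)
# is the slow-step net rate in mol/s. Rows (i)-(iii) replace three solute
# balances; (iv) closes the compartment. Exactly one of (ii)/(iii) carries
# the reaction term, which keeps the system well-scaled when CA makes the
# slow step effectively instantaneous.

# Per-row scale factors for nondimensionalization.
.residual_scales <- function(p) {
  J_ref <- p$P_pump * p$A_mem          # mol/s
  vol_c <- p$A_mem * p$L
  vol_p <- p$A_pc * p$H
  # reference magnitude of the slow reaction terms (C_H2CO3 ~ 5e-3 mM,
  # C_CO2 ~ 1.7 mM at physiological conditions)
  s_rxn_c <- J_ref + vol_c * (p$k_d * 5e-3 + p$k_h * 1.7)
  s_rxn_p <- J_ref + vol_p * (p$k_d * 5e-3 + p$k_h * 1.7)
  list(J_ref = J_ref, vol_c = vol_c, vol_p = vol_p,
       s_rxn_c = s_rxn_c, s_rxn_p = s_rxn_p,
       C_ref = 100, Q_ref = 1e-11)
}

# Build the residual as a closure over precomputed parameter combinations,
# operating directly on the solver variables x = (log C, Q/Qref, V/rtf).
# This is the hot path: every transporter log quotient is linear in x and
# every area*permeability product is folded in once.
.make_residual_fn <- function(p, cs, Vs) {
  sc <- .residual_scales(p)
  rtf <- .rtf_mV(p$T_abs)
  RT <- .GAS_R * p$T_abs
  ls <- log(cs)
  vs <- Vs / rtf                                  # stromal potential, units RT/F
  # area * intensity / permeability products
  PAnkcc <- p$A_mem * p$P_nkcc;  PAaes <- p$A_mem * p$P_aes
  PAnhe <- p$A_mem * p$P_nhe;    PAnbcs <- p$A_mem * p$P_nbcs
  PAKs <- p$A_mem * p$P_K_s
  PAco2s <- p$A_mem * p$P_co2_s; PAh2co3s <- p$A_mem * p$P_h2co3_s
  PApump <- p$A_mem * p$P_pump;  PAaep <- p$A_mem * p$P_aep
  PAnbcp <- p$A_mem * p$P_nbcp;  PAKp <- p$A_mem * p$P_K_p
  PAClp <- p$A_mem * p$P_Cl_p
  PAco2p <- p$A_mem * p$P_co2_p; PAh2co3p <- p$A_mem * p$P_h2co3_p
  PAtj <- p$A_tj * p$P_tj
  PAco2tj <- p$A_tj * p$P_co2_tj; PAh2co3tj <- p$A_tj * p$P_h2co3_tj
  W_sc <- p$A_mem * p$K_s * p$sigma * RT
  W_cp <- p$A_mem * p$K_p * p$sigma * RT
  W_sp <- p$A_tj * p$K_tj * p$sigma * RT
  lnkcc_s <- ls[1] + ls[2] + 2 * ls[3]
  lnbcs_s <- ls[1] + 2 * ls[4]
  osm_s <- sum(cs)
  kNa0 <- p$pump_K_Na0; kNas <- p$pump_K_Na_slope
  kK0 <- p$pump_K_K0; kKs <- p$pump_K_K_slope
  kd <- p$k_d; kh <- p$k_h; lKeq <- log(p$K_eq)
  zX <- p$z_X
  iJ <- 1 / sc$J_ref; iRc <- 1 / sc$s_rxn_c; iRp <- 1 / sc$s_rxn_p
  iC <- 1 / sc$C_ref; iQ <- 1 / sc$Q_ref
  vol_c <- sc$vol_c; vol_p <- sc$vol_p
  Qref <- sc$Q_ref
  ghk <- function(cm, ck, xi) {
    if (abs(xi) < 1e-6) (cm - ck) + 0.5 * xi * (cm + ck)
    else { e <- exp(-xi); xi * (cm - ck * e) / (1 - e) }
  }

  function(x) {
    cc <- exp(x[1:7]); cp <- exp(x[8:14]); CX <- exp(x[15])
    Q <- x[16] * Qref; vc <- x[17]; vp <- x[18]

    # stromal membrane (stroma -> cell)
    v_nkcc <- PAnkcc * (lnkcc_s - x[1] - x[2] - 2 * x[3])
    aes_Cl <- PAaes * (ls[3] + x[4] - x[3] - ls[4])
    nhe_Na <- PAnhe * (ls[1] + x[5] - x[1] - ls[5])
    nbcs_Na <- PAnbcs * (lnbcs_s - x[1] - 2 * x[4] - (vs - vc))
    K_s <- PAKs * ghk(cs[2], cc[2], vs - vc)
    co2_s <- PAco2s * (cs[6] - cc[6])
    h2co3_s <- PAh2co3s * (cs[7] - cc[7])

    # PC membrane (cell -> PC)
    v_pump <- PApump * (cc[1] / (cc[1] + kNa0 * (1 + cc[2] / kNas)))^3 *
      (cp[2] / (cp[2] + kK0 * (1 + cp[1] / kKs)))^2
    aep_HCO3 <- PAaep * (x[10] + x[4] - x[3] - x[11])
    nbcp_Na <- PAnbcp * (x[1] + 2 * x[4] - x[8] - 2 * x[11] - (vc - vp))
    K_p <- PAKp * ghk(cc[2], cp[2], vc - vp)
    Cl_p <- PAClp * ghk(cc[3], cp[3], vp - vc)
    co2_p <- PAco2p * (cc[6] - cp[6])
    h2co3_p <- PAh2co3p * (cc[7] - cp[7])

    # tight junction (stroma -> PC)
    xi_tj <- vs - vp
    tj1 <- PAtj * ghk(cs[1], cp[1], xi_tj)
    tj2 <- PAtj * ghk(cs[2], cp[2], xi_tj)
    tj3 <- PAtj * ghk(cs[3], cp[3], -xi_tj)
    tj4 <- PAtj * ghk(cs[4], cp[4], -xi_tj)
    tj6 <- PAco2tj * (cs[6] - cp[6])
    tj7 <- PAh2co3tj * (cs[7] - cp[7])

    J_sc1 <- v_nkcc + nhe_Na + nbcs_Na
    J_sc2 <- v_nkcc + K_s
    J_sc3 <- 2 * v_nkcc + aes_Cl
    J_sc4 <- 2 * nbcs_Na - aes_Cl
    J_cp1 <- 3 * v_pump + nbcp_Na
    J_cp2 <- -2 * v_pump + K_p
    J_cp3 <- Cl_p - aep_HCO3
    J_cp4 <- aep_HCO3 + 2 * nbcp_Na

    rho_c <- vol_c * (kd * cc[7] - kh * cc[6])
    rho_p <- vol_p * (kd * cp[7] - kh * cp[6])

    osm_c <- sum(cc) + CX
    osm_p <- sum(cp)
    Q_sc <- -W_sc * (osm_s - osm_c)
    Q_cp <- -W_cp * (osm_c - osm_p)
    Q_sp <- -W_sp * (osm_s - osm_p)

    T4p <- J_cp4 + tj4 - Q * cp[4]
    T5p <- -Q * cp[5]
    T6p <- co2_p + tj6 - Q * cp[6]
    T7p <- h2co3_p + tj7 - Q * cp[7]

    c((J_sc1 - J_cp1) * iJ,
      (J_sc2 - J_cp2) * iJ,
      (J_sc3 - J_cp3) * iJ,
      (J_sc4 - J_cp4 - (-nhe_Na)) * iJ,
      (J_sc4 - J_cp4 + co2_s - co2_p + h2co3_s - h2co3_p) * iJ,
      (J_sc4 - J_cp4 + h2co3_s - h2co3_p - rho_c) * iRc,
      x[7] - lKeq - x[5] - x[4],
      (J_cp1 + tj1 - Q * cp[1]) * iJ,
      (J_cp2 + tj2 - Q * cp[2]) * iJ,
      (J_cp3 + tj3 - Q * cp[3]) * iJ,
      (T4p - T5p) * iJ,
      (T4p + T6p + T7p) * iJ,
      (T4p + T7p - rho_p) * iRp,
      x[14] - lKeq - x[12] - x[11],
      (cc[1] + cc[2] - cc[3] - cc[4] + cc[5] + zX * CX) * iC,
      (cp[1] + cp[2] - cp[3] - cp[4] + cp[5]) * iC,
      (Q_sc - Q_cp) * iQ,
      (Q_cp + Q_sp - Q) * iQ)
  }
}

# Core residual: u is the 18-vector in natural units; concentrations must be
# strictly positive (the solver guarantees this by working in log space).
.residual_raw <- function(u, p, cs, Vs, fn = .make_residual_fn(p, cs, Vs)) {
  fn(.u_to_x(u, .rtf_mV(p$T_abs)))
}

#' Residuals of the 18-equation steady-state system
#'
#' Evaluates the nondimensionalized residuals of the coupled solute, water
#' and charge balances at a trial point. The system comprises, for each of
#' the cell and the posterior chamber: the Na+, K+ and Cl- balances, the
#' fast-buffer reductions (HCO3- minus H+ balance, total carbon balance,
#' slow-step kinetics) and the fast-equilibrium constraint
#' `C_H2CO3 = K_eq * C_H * C_HCO3`; plus both electroneutrality conditions
#' and the two water balances `Q_sc - Q_cp = 0`,
#' `Q_cp + Q_sp - Q = 0`. PC solute export is purely advective (`Q C_i^p`).
#'
#' @param unknowns Numeric 18-vector: `C_1..7^c` (mM), `C_1..7^p` (mM),
#'   `C_X` (mM), `Q` (m^3/s), `V^c` (mV), `V^p` (mV).
#' @param params An `ah_parameters` object.
#' @param stroma Stromal `ah_state` (the fixed boundary condition).
#' @return Numeric 18-vector of dimensionless residuals; zero (to solver
#'   tolerance) at a steady state. Non-positive trial concentrations are
#'   clamped at 1e-12 mM with a warning.
#' @export
residual_system <- function(unknowns, params, stroma) {
  if (length(unknowns) != 18L) stop("`unknowns` must have length 18")
  u <- as.numeric(unknowns)
  if (any(u[1:15] <= 0)) {
    warning("non-positive concentration(s) clamped at 1e-12 mM",
            call. = FALSE)
    u[1:15] <- pmax(u[1:15], 1e-12)
  }
  r <- .residual_raw(u, params, stroma$conc, stroma$V)
  if (any(!is.finite(r)))
    stop("non-finite residual component(s) at equation(s): ",
         paste(which(!is.finite(r)), collapse = ", "))
  r
}

# Physiological initial guess (from typical measured composition).
.initial_guess <- function(p, stroma) {
  cs <- stroma$conc
  Hc <- 10^(3 - 7.45)
  cc <- c(Na = 15, K = 160, Cl = 46, HCO3 = 26, H = Hc,
          CO2 = cs[["CO2"]], H2CO3 = p$K_eq * Hc * 26)
  CX <- sum(.VALENCE * cc) / (-p$z_X)
  Hp <- 10^(3 - 7.45)
  cp <- c(Na = 152, K = 4, Cl = 131, HCO3 = 25, H = Hp,
          CO2 = cs[["CO2"]], H2CO3 = p$K_eq * Hp * 25)
  cp[["Na"]] <- cp[["Na"]] - sum(.VALENCE * cp)   # make the guess neutral
  c(cc, cp, CX, 3e-11, -70, -1)
}
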