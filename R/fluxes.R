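# Flux laws for every pathway on the stromal membrane, the posterior-chamber
# membrane and the tight junction. Sign convention: fluxes are positive in
# the stroma -> cell -> PC (and stroma -> PC) direction; antisymmetry under
# swapping the two sides holds for every law.

# thermal voltage RT/F in mV
.rtf_mV <- function(T_abs) 1000 * .GAS_R * T_abs / .FARADAY

# Clamp concentrations entering log quotients. Never silent.
.clamp_conc <- function(x, floor = 1e-12) {
  if (any(x < floor)) {
    warning("concentration(s) below ", floor,
            " mM clamped inside a log quotient", call. = FALSE)
    x <- pmax(x, floor)
  }
  x
}

# GHK constant-field "driving concentration" phi such that J = A * P * phi.
# xi = z*F*dV/(R*T) (dimensionless); removable singularity at xi = 0 handled
# by a first-order expansion.
.ghk_phi <- function(cm, ck, xi) {
  if (abs(xi) < 1e-6) {
    (cm - ck) + 0.5 * xi * (cm + ck)
  } else {
    e <- exp(-xi)
    xi * (cm - ck * e) / (1 - e)
  }
}

.check_PA <- function(permeability, area) {
  if (permeability < 0) stop("permeability must be non-negative")
  if (area < 0) stop("area must be non-negative")
}

#' Electrodiffusive (GHK) flux of an ion through a channel
#'
#' Goldman-Hodgkin-Katz constant-field flux of a charged species across a
#' membrane: `J = A * P * xi * (C_m - C_k * exp(-xi)) / (1 - exp(-xi))`
#' with `xi = z * F * (V_m - V_k) / (R * T)`. For an uncharged species this
#' reduces to Fick's law; as the potential difference vanishes the flux
#' tends to the Fickian limit `A * P * (C_m - C_k)`.
#'
#' @param species Species name (one of `ah_species()$species`) or index 1-7.
#' @param permeability Membrane permeability P in m/s.
#' @param area Membrane area in m^2.
#' @param from_state,to_state `ah_state` objects on side m and k.
#' @param T_abs Absolute temperature in K.
#' @return Flux in mol/s, positive from `from_state` to `to_state`.
#' @export
#' @examples
#' s <- compartment_state(c(Na = 150, K = 5, Cl = 130, HCO3 = 25,
#'                          H = 4e-5, CO2 = 1.7, H2CO3 = 5e-3), V = 0)
#' c2 <- compartment_state(c(Na = 15, K = 160, Cl = 45, HCO3 = 27,
#'                           H = 3.5e-5, CO2 = 1.7, H2CO3 = 5e-3), V = -70)
#' electrodiffusive_flux("K", 5e-8, 6e-4, s, c2)
electrodiffusive_flux <- function(species, permeability, area,
                                  from_state, to_state, T_abs = 310) {
  .check_PA(permeability, area)
  i <- if (is.character(species)) match(species, .SPECIES) else as.integer(species)
  if (is.na(i) || i < 1L || i > 7L) stop("unknown species: ", species)
  z <- .VALENCE[[i]]
  xi <- z * (from_state$V - to_state$V) / .rtf_mV(T_abs)
  area * permeability * .ghk_phi(from_state$conc[[i]], to_state$conc[[i]], xi)
}

#' Diffusive flux of an uncharged species (CO2, H2CO3)
#'
#' Fickian membrane flux `J = A * P * (C_m - C_k)`.
#'
#' @inheritParams electrodiffusive_flux
#' @return Flux in mol/s, positive from `from_state` to `to_state`.
#' @export
uncharged_diffusive_flux <- function(species, permeability, area,
                                     from_state, to_state) {
  if (is.character(species) && !species %in% c("CO2", "H2CO3"))
    stop("`species` must be CO2 or H2CO3")
  .check_PA(permeability, area)
  i <- if (is.character(species)) match(species, .SPECIES) else as.integer(species)
  area * permeability * (from_state$conc[[i]] - to_state$conc[[i]])
}

#' Na+-K+ ATPase flux
#'
#' Active extrusion of 3 Na+ from the cell into the posterior chamber and
#' import of 2 K+ per cycle. The turnover saturates in intracellular Na+
#' and PC-side K+ with Michaelis constants that depend weakly on the
#' trans-side ion (a standard formulation for epithelial Na+-K+ ATPase):
#' `v = A * P_pump * (Na_c/(Na_c+K_Na))^3 * (K_p/(K_p+K_K))^2`.
#'
#' @param P_pump Pump intensity, mol/m^2/s.
#' @param area PC membrane area, m^2.
#' @param cell,pc Cell and posterior-chamber `ah_state`s.
#' @param K_Na0,K_Na_slope,K_K0,K_K_slope Saturation constants (mM), see
#'   [model_parameters()].
#' @return Named vector `c(J_Na, J_K)` in mol/s, positive cell -> PC
#'   (so `J_Na = 3v > 0` and `J_K = -2v < 0`).
#' @export
pump_flux <- function(P_pump, area, cell, pc,
                      K_Na0 = 0.2, K_Na_slope = 8.33,
                      K_K0 = 0.1, K_K_slope = 18.5) {
  if (P_pump < 0) stop("`P_pump` must be non-negative")
  .check_PA(P_pump, area)
  v <- .pump_rate(P_pump, area, cell$conc[["Na"]], cell$conc[["K"]],
                  pc$conc[["Na"]], pc$conc[["K"]],
                  K_Na0, K_Na_slope, K_K0, K_K_slope)
  c(J_Na = 3 * v, J_K = -2 * v)
}

.pump_rate <- function(P_pump, area, Na_c, K_c, Na_p, K_p,
                       K_Na0, K_Na_slope, K_K0, K_K_slope) {
  K_Na <- K_Na0 * (1 + K_c / K_Na_slope)
  K_K <- K_K0 * (1 + Na_p / K_K_slope)
  area * P_pump * (Na_c / (Na_c + K_Na))^3 * (K_p / (K_p + K_K))^2
}

#' Na+/K+/2Cl- cotransporter (nkcc) flux
#'
#' Electroneutral coupled transport with stoichiometry 1:1:2, driven by the
#' thermodynamic mass-action quotient
#' `f = ln[(Na_s K_s Cl_s^2) / (Na_c K_c Cl_c^2)]` (no voltage dependence,
#' net carrier charge 0). Located on the stromal membrane.
#'
#' @param P_nkcc Transporter intensity, mol/m^2/s.
#' @param area Stromal membrane area, m^2.
#' @param stroma,cell `ah_state`s.
#' @return Named vector `c(J_Na, J_K, J_Cl)` in mol/s, positive
#'   stroma -> cell; `J_Cl = 2 J_Na = 2 J_K`.
#' @export
nkcc_flux <- function(P_nkcc, area, stroma, cell) {
  .check_PA(P_nkcc, area)
  s <- .clamp_conc(stroma$conc); cc <- .clamp_conc(cell$conc)
  v <- area * P_nkcc *
    log((s[["Na"]] * s[["K"]] * s[["Cl"]]^2) /
        (cc[["Na"]] * cc[["K"]] * cc[["Cl"]]^2))
  c(J_Na = v, J_K = v, J_Cl = 2 * v)
}

#' Cl-/HCO3- anion exchanger (aes, aep) flux
#'
#' Electroneutral 1:1 countertransport: Cl- moves from side a to side b
#' while HCO3- moves b to a, driven by
#' `f = ln[(Cl_a HCO3_b) / (Cl_b HCO3_a)]`. Instantiated as `aes` with
#' (a, b) = (stroma, cell) and as `aep` with (a, b) = (PC, cell), so that
#' the physiological direction is Cl- entering the cell and HCO3- leaving.
#'
#' @param P_ae Exchanger intensity, mol/m^2/s.
#' @param area Membrane area, m^2.
#' @param side_a,side_b `ah_state`s.
#' @return Named vector `c(J_Cl, J_HCO3)` in mol/s; `J_Cl` positive a -> b,
#'   and `J_HCO3 = -J_Cl` (positive flux of HCO3- is also a -> b, hence the
#'   minus sign encodes the countertransport).
#' @export
anion_exchanger_flux <- function(P_ae, area, side_a, side_b) {
  .check_PA(P_ae, area)
  a <- .clamp_conc(side_a$conc); b <- .clamp_conc(side_b$conc)
  JCl <- area * P_ae *
    log((a[["Cl"]] * b[["HCO3"]]) / (b[["Cl"]] * a[["HCO3"]]))
  c(J_Cl = JCl, J_HCO3 = -JCl)
}

#' Na+/H+ exchanger (nhe) flux
#'
#' Electroneutral 1:1 exchange on the stromal membrane: Na+ enters the cell
#' and H+ is extruded, driven by `f = ln[(Na_s H_c) / (Na_c H_s)]`.
#'
#' @param P_nhe Exchanger intensity, mol/m^2/s.
#' @param area Stromal membrane area, m^2.
#' @param stroma,cell `ah_state`s.
#' @return Named vector `c(J_Na, J_H)` in mol/s, positive stroma -> cell;
#'   `J_H = -J_Na`.
#' @export
nhe_flux <- function(P_nhe, area, stroma, cell) {
  .check_PA(P_nhe, area)
  s <- .clamp_conc(stroma$conc); cc <- .clamp_conc(cell$conc)
  JNa <- area * P_nhe *
    log((s[["Na"]] * cc[["H"]]) / (cc[["Na"]] * s[["H"]]))
  c(J_Na = JNa, J_H = -JNa)
}

#' Na+/HCO3- cotransporter (nbcs, nbcp) flux
#'
#' Coupled cotransport of 1 Na+ with 2 HCO3- (presumed stoichiometry); the
#' carrier has net charge -1, so the driving force is the electrochemical
#' quotient `f = ln[(Na_a HCO3_a^2) / (Na_b HCO3_b^2)] - F (V_a - V_b)/(RT)`.
#' Instantiated as `nbcs` with (a, b) = (stroma, cell) and `nbcp` with
#' (a, b) = (cell, PC).
#'
#' @param P_nbc Transporter intensity, mol/m^2/s.
#' @param area Membrane area, m^2.
#' @param side_a,side_b `ah_state`s.
#' @param T_abs Absolute temperature in K.
#' @return Named vector `c(J_Na, J_HCO3)` in mol/s, positive a -> b;
#'   `J_HCO3 = 2 J_Na`.
#' @export
nbc_flux <- function(P_nbc, area, side_a, side_b, T_abs = 310) {
  .check_PA(P_nbc, area)
  a <- .clamp_conc(side_a$conc); b <- .clamp_conc(side_b$conc)
  f <- log((a[["Na"]] * a[["HCO3"]]^2) / (b[["Na"]] * b[["HCO3"]]^2)) -
    (side_a$V - side_b$V) / .rtf_mV(T_abs)
  JNa <- area * P_nbc * f
  c(J_Na = JNa, J_HCO3 = 2 * JNa)
}

#' Osmotic water flux across a membrane
#'
#' `Q = -A K sigma R T (osm_from - osm_to)` where the osmolarity sums all
#' seven species plus the fixed charge `CX` where the cell is involved.
#' Positive when the destination compartment is hyperosmotic.
#'
#' @param K Hydraulic conductivity, m/s/Pa.
#' @param sigma Reflection coefficient, dimensionless in (0, 1].
#' @param area Membrane area, m^2.
#' @param from_state,to_state `ah_state`s.
#' @param T_abs Absolute temperature in K.
#' @return Water flux in m^3/s, positive from `from_state` to `to_state`.
#' @export
water_flux <- function(K, sigma, area, from_state, to_state, T_abs = 310) {
  if (K < 0) stop("`K` must be non-negative")
  if (area < 0) stop("`area` must be non-negative")
  -area * K * sigma * .GAS_R * T_abs *
    (.osmolarity(from_state) - .osmolarity(to_state))
}

# ---------------------------------------------------------------------------
# Internal fast core used by the residual system and the transient solver.
# Plain numeric vectors, species order .SPECIES, potentials in mV.
# Returns per-species totals J_sc, J_cp, J_sp (mol/s) and, if detail = TRUE,
# per-pathway matrices.
.flux_core <- function(p, cs, Vs, cc, Vc, cp, Vp, detail = FALSE) {
  rtf <- 1000 * .GAS_R * p$T_abs / .FARADAY

  # --- stromal membrane (stroma -> cell) ---
  v_nkcc <- p$A_mem * p$P_nkcc *
    log((cs[1] * cs[2] * cs[3]^2) / (cc[1] * cc[2] * cc[3]^2))
  aes_Cl <- p$A_mem * p$P_aes * log((cs[3] * cc[4]) / (cc[3] * cs[4]))
  nhe_Na <- p$A_mem * p$P_nhe * log((cs[1] * cc[5]) / (cc[1] * cs[5]))
  nbcs_Na <- p$A_mem * p$P_nbcs *
    (log((cs[1] * cs[4]^2) / (cc[1] * cc[4]^2)) - (Vs - Vc) / rtf)
  K_s <- p$A_mem * p$P_K_s * .ghk_phi(cs[2], cc[2], (Vs - Vc) / rtf)
  co2_s <- p$A_mem * p$P_co2_s * (cs[6] - cc[6])
  h2co3_s <- p$A_mem * p$P_h2co3_s * (cs[7] - cc[7])

  J_sc <- c(v_nkcc + nhe_Na + nbcs_Na,          # Na
            v_nkcc + K_s,                       # K
            2 * v_nkcc + aes_Cl,                # Cl
            2 * nbcs_Na - aes_Cl,               # HCO3
            -nhe_Na,                            # H
            co2_s, h2co3_s)

  # --- PC membrane (cell -> PC) ---
  v_pump <- .pump_rate(p$P_pump, p$A_mem, cc[1], cc[2], cp[1], cp[2],
                       p$pump_K_Na0, p$pump_K_Na_slope,
                       p$pump_K_K0, p$pump_K_K_slope)
  aep_HCO3 <- p$A_mem * p$P_aep * log((cp[3] * cc[4]) / (cc[3] * cp[4]))
  nbcp_Na <- p$A_mem * p$P_nbcp *
    (log((cc[1] * cc[4]^2) / (cp[1] * cp[4]^2)) - (Vc - Vp) / rtf)
  K_p <- p$A_mem * p$P_K_p * .ghk_phi(cc[2], cp[2], (Vc - Vp) / rtf)
  Cl_p <- p$A_mem * p$P_Cl_p * .ghk_phi(cc[3], cp[3], -(Vc - Vp) / rtf)
  co2_p <- p$A_mem * p$P_co2_p * (cc[6] - cp[6])
  h2co3_p <- p$A_mem * p$P_h2co3_p * (cc[7] - cp[7])

  J_cp <- c(3 * v_pump + nbcp_Na,               # Na
            -2 * v_pump + K_p,                  # K
            Cl_p - aep_HCO3,                    # Cl
            aep_HCO3 + 2 * nbcp_Na,             # HCO3
            0,                                  # H (no pathway on p~)
            co2_p, h2co3_p)

  # --- tight junction (stroma -> PC) ---
  xi_tj <- (Vs - Vp) / rtf
  J_sp <- c(p$A_tj * p$P_tj * .ghk_phi(cs[1], cp[1], xi_tj),
            p$A_tj * p$P_tj * .ghk_phi(cs[2], cp[2], xi_tj),
            p$A_tj * p$P_tj * .ghk_phi(cs[3], cp[3], -xi_tj),
            p$A_tj * p$P_tj * .ghk_phi(cs[4], cp[4], -xi_tj),
            0,                                  # H not carried by tj
            p$A_tj * p$P_co2_tj * (cs[6] - cp[6]),
            p$A_tj * p$P_h2co3_tj * (cs[7] - cp[7]))

  out <- list(J_sc = J_sc, J_cp = J_cp, J_sp = J_sp)
  if (detail) {
    m7 <- function(...) {
      cols <- list(...)
      m <- do.call(cbind, cols)
      rownames(m) <- .SPECIES
      m
    }
    out$pathways <- list(
      stromal = m7(
        nkcc = c(v_nkcc, v_nkcc, 2 * v_nkcc, 0, 0, 0, 0),
        aes = c(0, 0, aes_Cl, -aes_Cl, 0, 0, 0),
        nhe = c(nhe_Na, 0, 0, 0, -nhe_Na, 0, 0),
        nbcs = c(nbcs_Na, 0, 0, 2 * nbcs_Na, 0, 0, 0),
        K_channel = c(0, K_s, 0, 0, 0, 0, 0),
        gas = c(0, 0, 0, 0, 0, co2_s, h2co3_s)),
      pc = m7(
        pump = c(3 * v_pump, -2 * v_pump, 0, 0, 0, 0, 0),
        aep = c(0, 0, -aep_HCO3, aep_HCO3, 0, 0, 0),
        nbcp = c(nbcp_Na, 0, 0, 2 * nbcp_Na, 0, 0, 0),
        K_channel = c(0, K_p, 0, 0, 0, 0, 0),
        Cl_channel = c(0, 0, Cl_p, 0, 0, 0, 0),
        gas = c(0, 0, 0, 0, 0, co2_p, h2co3_p)),
      tj = m7(
        electrodiffusion = c(J_sp[1:4], 0, 0, 0),
        gas = c(0, 0, 0, 0, 0, J_sp[6], J_sp[7])))
  }
  out
}

#' Assemble all membrane fluxes for a set of compartment states
#'
#' Evaluates every pathway on the stromal membrane (nkcc, aes, nhe, nbcs,
#' K+ channel, CO2/H2CO3 diffusion), the PC membrane (pump, aep, nbcp, K+
#' and Cl- channels, CO2/H2CO3 diffusion) and the tight junction
#' (electrodiffusion of Na+, K+, Cl-, HCO3- plus CO2/H2CO3 diffusion), and
#' returns per-species totals together with the per-pathway breakdown.
#'
#' @param params An `ah_parameters` object.
#' @param stroma,cell,pc `ah_state`s for the three compartments.
#' @return An object of class `ah_fluxes`: list with `totals` (7 x 3 matrix,
#'   columns `sc`, `cp`, `sp`, mol/s, positive stroma -> cell -> PC) and
#'   `pathways` (per-membrane species x pathway matrices).
#' @export
assemble_membrane_fluxes <- function(params, stroma, cell, pc) {
  fx <- .flux_core(params,
                   .clamp_conc(stroma$conc), stroma$V,
                   .clamp_conc(cell$conc), cell$V,
                   .clamp_conc(pc$conc), pc$V, detail = TRUE)
  totals <- cbind(sc = fx$J_sc, cp = fx$J_cp, sp = fx$J_sp)
  rownames(totals) <- .SPECIES
  structure(list(totals = totals, pathways = fx$pathways),
            class = "ah_fluxes")
}

#' @export
print.ah_fluxes <- function(x, ...) {
  cat("<ah_fluxes> per-species totals (mol/s), positive stroma->cell->PC\n")
  print(signif(x$totals, 4))
  invisible(x)
}
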