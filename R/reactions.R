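#' Bicarbonate buffer reaction rates (slow step, mass action)
#'
#' The solutes interact through `HCO3- + H+ <-> H2CO3 <-> CO2 + H2O`. The
#' first (dissociation) step is effectively instantaneous and is therefore
#' never evaluated kinetically: the steady-state system imposes it as the
#' equilibrium constraint `C_H2CO3 = K_eq * C_H * C_HCO3` (see
#' [residual_system()]). This function evaluates the slow second step with
#' the mass action law, per unit compartment volume:
#' `R_CO2 = k_d * C_H2CO3 - k_h * C_CO2` (mM/s), with the opposite
#' contribution on H2CO3. Carbonic anhydrase catalyzes the slow step; when
#' `ca_active = FALSE` both `k_d` and `k_h` are divided by `ca_factor`
#' (default 1e6), representing full CA inhibition.
#'
#' @param state An `ah_state`.
#' @param k_d,k_h Dehydration / hydration rate constants, 1/s (water
#'   activity absorbed into `k_h`).
#' @param ca_active Logical; `FALSE` models carbonic anhydrase inhibition.
#' @param ca_factor Catalysis factor removed under inhibition.
#' @return Named numeric vector of length 7: net production rate of each
#'   species in mM/s. Only CO2 and H2CO3 carry the slow step, so charge
#'   (`sum(z_i R_i) = 0`) and carbon (`R_HCO3 + R_CO2 + R_H2CO3 = 0`) are
#'   conserved identically.
#' @export
#' @examples
#' s <- compartment_state(c(Na = 150, K = 5, Cl = 130, HCO3 = 25,
#'                          H = 3.8e-5, CO2 = 1.7, H2CO3 = 5e-3))
#' reaction_rates(s, k_d = 4.96e5, k_h = 1.45e3)
reaction_rates <- function(state, k_d, k_h, ca_active = TRUE,
                           ca_factor = 1e6) {
  if (k_d < 0 || k_h < 0) stop("rate constants must be non-negative")
  if (!ca_active) {
    k_d <- k_d / ca_factor
    k_h <- k_h / ca_factor
  }
  R_co2 <- k_d * state$conc[["H2CO3"]] - k_h * state$conc[["CO2"]]
  setNames(c(0, 0, 0, 0, 0, R_co2, -R_co2), .SPECIES)
}
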