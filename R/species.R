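#' Species handled by the model
#'
#' The model tracks seven solutes in every compartment, in a fixed order:
#' Na+, K+, Cl-, HCO3-, H+, CO2 and H2CO3. All concentration vectors in the
#' package use this order and these names.
#'
#' @return A data frame with columns `species` and `valence`.
#' @export
#' @examples
#' ah_species()
ah_species <- function() {
  data.frame(species = .SPECIES, valence = unname(.VALENCE),
             stringsAsFactors = FALSE)
}

.SPECIES <- c("Na", "K", "Cl", "HCO3", "H", "CO2", "H2CO3")
.VALENCE <- c(Na = 1, K = 1, Cl = -1, HCO3 = -1, H = 1, CO2 = 0, H2CO3 = 0)

#' Construct a compartment state
#'
#' A compartment state bundles the seven solute concentrations (mM, which is
#' numerically identical to mol/m^3), the electric potential (mV, stroma
#' grounded at 0), and, for the cellular compartment only, the concentration
#' of fixed non-diffusible charge `CX` (mM, valence `z_X` from the model
#' parameters).
#'
#' @param conc Named numeric vector of length 7 with names
#'   Na, K, Cl, HCO3, H, CO2, H2CO3, in mM. Must be non-negative.
#' @param V Electric potential of the compartment in mV.
#' @param CX Fixed-charge concentration in mM (cell only), or `NULL`.
#' @return An object of class `ah_state`.
#' @export
compartment_state <- function(conc, V = 0, CX = NULL) {
  if (length(conc) != 7L)
    stop("`conc` must have exactly 7 entries (one per species)")
  if (is.null(names(conc))) names(conc) <- .SPECIES
  if (!all(.SPECIES %in% names(conc)))
    stop("`conc` must be named with: ", paste(.SPECIES, collapse = ", "))
  conc <- conc[.SPECIES]
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative")
  if (!is.null(CX) && (!is.finite(CX) || CX < 0))
    stop("`CX` must be a non-negative concentration")
  structure(list(conc = conc, V = as.numeric(V),
                 CX = if (is.null(CX)) NULL else as.numeric(CX)),
            class = "ah_state")
}

#' @export
print.ah_state <- function(x, ...) {
  cat("<ah_state>  V =", format(x$V, digits = 4), "mV")
  if (!is.null(x$CX)) cat("  CX =", format(x$CX, digits = 4), "mM")
  cat("\n")
  print(round(x$conc, 4))
  invisible(x)
}

#' Build the stromal boundary condition
#'
#' The stroma is the model's fixed boundary: the four major ions and the pH
#' are imposed, and the minor carbonate species are completed so that the
#' imposed state is consistent with the buffer reactions. H+ follows from
#' the pH, H2CO3 from the fast dissociation equilibrium
#' `C_H2CO3 = K_eq * C_H * C_HCO3`, and CO2 from the slow-step equilibrium
#' `C_CO2 = (k_d / k_h) * C_H2CO3`.
#'
#' @param params Model parameters (for `K_eq`, `k_d`, `k_h`), see
#'   [model_parameters()].
#' @param Na,K,Cl,HCO3 Imposed concentrations in mM.
#' @param pH Imposed stromal pH.
#' @param V Stromal potential in mV (reference, normally 0).
#' @param tol Tolerance on the stromal charge imbalance, mM of charge. The
#'   major-ion row must balance; the H+ derived from the pH contributes a
#'   physically negligible ~4e-5 mM.
#' @return An `ah_state` for the stroma.
#' @export
#' @examples
#' p <- default_parameters()
#' stroma_state(p, Na = 150, K = 5, Cl = 130, HCO3 = 25, pH = 7.42)
stroma_state <- function(params, Na = 150, K = 5, Cl = 130, HCO3 = 25,
                         pH = 7.42, V = 0, tol = 1e-3) {
  H <- 10^(3 - pH)                       # mM
  H2CO3 <- params$K_eq * H * HCO3
  CO2 <- (params$k_d / params$k_h) * H2CO3
  conc <- c(Na = Na, K = K, Cl = Cl, HCO3 = HCO3, H = H,
            CO2 = CO2, H2CO3 = H2CO3)
  imbalance <- sum(.VALENCE * conc)
  if (abs(imbalance) > tol)
    stop("stroma violates electroneutrality: sum(z_i * C_i) = ",
         format(imbalance), " mM; adjust the imposed concentrations")
  compartment_state(conc, V = V)
}

# Osmolarity of a state in mM, counting the fixed charge if present.
.osmolarity <- function(state) {
  sum(state$conc) + if (is.null(state$CX)) 0 else state$CX
}

#' pH of a compartment state
#' @param state An `ah_state`.
#' @return pH computed as `-log10` of the H+ concentration in mol/L.
#' @export
state_pH <- function(state) 3 - log10(state$conc[["H"]])
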