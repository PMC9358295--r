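#' Model parameters for the ciliary-epithelium transport model
#'
#' Bundles the geometry, hydraulic conductivities, gas permeabilities,
#' buffer reaction constants, and the intensities/permeabilities of every
#' ion pathway. Defaults are the baseline values of the model; transporter
#' intensities are given in mol/m^2/s and channel permeabilities in m/s
#' (i.e. with the 1e-6 / 1e-8 table scalings already applied).
#'
#' Parameter groups:
#' \describe{
#'   \item{geometry}{`L` cell-layer thickness (m), `H` posterior-chamber
#'     length (m), `A_mem` area of the stromal and PC membranes (m^2),
#'     `A_tj` tight-junction area (m^2), `A_pc` PC cross-section (m^2).}
#'   \item{hydraulic}{`K_s`, `K_tj`, `K_p` hydraulic conductivities
#'     (m/s/Pa) of the stromal membrane, tight junction and PC membrane.}
#'   \item{gas permeabilities}{`P_co2_*`, `P_h2co3_*` (m/s) per membrane.}
#'   \item{reactions}{`k_d`, `k_h` (1/s) dehydration/hydration rates of the
#'     slow step H2CO3 <-> CO2 + H2O (catalyzed by carbonic anhydrase);
#'     `K_eq` (1/mM) association constant of the fast step
#'     HCO3- + H+ <-> H2CO3.}
#'   \item{other}{`T_abs` temperature (K), `sigma` reflection coefficient,
#'     `z_X` valence of the intracellular fixed charge.}
#'   \item{transporter intensities}{`P_pump`, `P_nkcc`, `P_aes`, `P_aep`,
#'     `P_nbcp`, `P_nbcs`, `P_nhe` (mol/m^2/s). The nbc intensities are not
#'     fixed by independent measurements; the defaults are calibrated so
#'     that the baseline solve reproduces the reference composition and
#'     fluxes (see the package vignette).}
#'   \item{channel permeabilities}{`P_K_s`, `P_K_p`, `P_Cl_p`, `P_tj` (m/s).}
#'   \item{pump kinetics}{`pump_K_Na0`, `pump_K_Na_slope`, `pump_K_K0`,
#'     `pump_K_K_slope` (mM): Michaelis constants of the Na+-K+ ATPase,
#'     `K_Na = pump_K_Na0 * (1 + K_c / pump_K_Na_slope)` and
#'     `K_K = pump_K_K0 * (1 + Na_p / pump_K_K_slope)`.}
#' }
#'
#' @param ... Named overrides of any default parameter.
#' @return An object of class `ah_parameters` (a validated named list).
#' @export
#' @examples
#' p <- model_parameters(P_nkcc = 2e-6)
#' p$P_nkcc
model_parameters <- function(...) {
  p <- .default_parameter_list()
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- dots
  }
  validate_parameters(structure(p, class = "ah_parameters"))
}

#' @rdname model_parameters
#' @export
default_parameters <- function() model_parameters()

.default_parameter_list <- function() {
  list(
    # geometry
    L = 1e-5, H = 6e-3, A_mem = 6e-4, A_tj = 6e-7, A_pc = 2.6e-5,
    # hydraulic conductivities
    K_s = 2e-11, K_tj = 2e-11, K_p = 2e-10,
    # CO2 / H2CO3 permeabilities
    P_co2_s = 1.5e-3, P_co2_tj = 1.5e-3, P_co2_p = 1.5e-2,
    P_h2co3_s = 1.28e-5, P_h2co3_tj = 1.28e-5, P_h2co3_p = 1.28e-4,
    # buffer reaction constants
    k_d = 4.96e5, k_h = 1.45e3, K_eq = 5.3,
    # other
    T_abs = 310, sigma = 1, z_X = -1.5,
    # transporter intensities, mol/m^2/s (table scaling 1e-6 applied)
    P_pump = 6e-6, P_nkcc = 1e-6, P_aes = 4e-6, P_aep = 0.4e-6,
    P_nbcp = .NBC_DEFAULTS[["P_nbcp"]], P_nbcs = .NBC_DEFAULTS[["P_nbcs"]],
    P_nhe = 3.4e-6,
    # channel permeabilities, m/s (table scaling 1e-8 applied)
    P_K_s = 5e-8, P_K_p = 30e-8, P_Cl_p = 6e-8, P_tj = 600e-8,
    # Na+-K+ ATPase saturation constants (mM); the two leading constants
    # are co-calibrated with the nbc intensities (see vignette) and stay
    # close to their conventional literature values (0.2 and 0.1 mM)
    pump_K_Na0 = 0.2071, pump_K_Na_slope = 8.33,
    pump_K_K0 = 0.1156, pump_K_K_slope = 18.5
  )
}

#' Validate model parameters
#'
#' Checks positivity (all parameters except `z_X`, which must be negative)
#' and that the reflection coefficient lies in (0, 1].
#'
#' @param params An `ah_parameters` object or plain named list.
#' @return The validated `ah_parameters` object, invisibly usable.
#' @export
validate_parameters <- function(params) {
  p <- unclass(params)
  ref <- .default_parameter_list()
  missing <- setdiff(names(ref), names(p))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  num <- vapply(p[names(ref)], function(x) is.numeric(x) && length(x) == 1L &&
                  is.finite(x), logical(1))
  if (!all(num))
    stop("non-scalar or non-finite parameter(s): ",
         paste(names(ref)[!num], collapse = ", "))
  pos <- setdiff(names(ref), "z_X")
  bad <- pos[vapply(p[pos], function(x) x <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ", paste(bad, collapse = ", "))
  if (p$z_X >= 0) stop("`z_X` must be negative (fixed charge is anionic)")
  if (p$sigma > 1) stop("`sigma` must lie in (0, 1]")
  structure(p[names(ref)], class = "ah_parameters")
}

#' @export
print.ah_parameters <- function(x, ...) {
  cat("<ah_parameters> ciliary epithelium transport model\n")
  cat("  transporters (mol/m2/s): pump", format(x$P_pump),
      " nkcc", format(x$P_nkcc), " aes", format(x$P_aes),
      " aep", format(x$P_aep), "\n    nbcp", format(x$P_nbcp),
      " nbcs", format(x$P_nbcs), " nhe", format(x$P_nhe), "\n")
  cat("  channels (m/s): K_s", format(x$P_K_s), " K_p", format(x$P_K_p),
      " Cl_p", format(x$P_Cl_p), " tj", format(x$P_tj), "\n")
  cat("  reactions: k_d", format(x$k_d), " k_h", format(x$k_h),
      " K_eq", format(x$K_eq), "\n")
  invisible(x)
}

#' Describe a model perturbation
#'
#' A perturbation either rescales named parameters by a multiplicative
#' factor, inhibits carbonic anhydrase (dividing both `k_d` and `k_h` by
#' `ca_factor`, default 1e6), or both.
#'
#' @param param Character vector of parameter names to rescale (or `NULL`).
#' @param factor Multiplicative factor, strictly positive.
#' @param ca If `TRUE`, inhibit carbonic anhydrase.
#' @param ca_factor Catalysis factor removed under CA inhibition.
#' @return An object of class `ah_perturbation`.
#' @export
#' @examples
#' perturbation("P_pump", factor = 0.5)
#' perturbation(ca = TRUE)
perturbation <- function(param = NULL, factor = 1, ca = FALSE,
                         ca_factor = 1e6) {
  if (!is.null(param) && !is.character(param))
    stop("`param` must be a character vector of parameter names")
  if (!is.numeric(factor) || any(factor <= 0))
    stop("`factor` must be strictly positive")
  if (!is.null(param) && length(factor) != 1L &&
      length(factor) != length(param))
    stop("`factor` must be scalar or one per parameter")
  structure(list(param = param, factor = factor, ca = isTRUE(ca),
                 ca_factor = ca_factor),
            class = "ah_perturbation")
}

#' Apply a perturbation to a parameter set
#'
#' @param params An `ah_parameters` object.
#' @param spec An [perturbation()] object.
#' @return The perturbed, re-validated `ah_parameters`.
#' @export
apply_perturbation <- function(params, spec) {
  stopifnot(inherits(spec, "ah_perturbation"))
  p <- unclass(params)
  if (!is.null(spec$param)) {
    unknown <- setdiff(spec$param, names(p))
    if (length(unknown))
      stop("unknown parameter(s) in perturbation: ",
           paste(unknown, collapse = ", "))
    f <- rep_len(spec$factor, length(spec$param))
    for (i in seq_along(spec$param))
      p[[spec$param[i]]] <- p[[spec$param[i]]] * f[i]
  }
  if (spec$ca) {
    p$k_d <- p$k_d / spec$ca_factor
    p$k_h <- p$k_h / spec$ca_factor
  }
  validate_parameters(structure(p, class = "ah_parameters"))
}
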