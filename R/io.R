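# Configuration loading/validation and report tables.

.CONFIG_SCHEMA <- list(
  geometry = c("L", "H", "A_mem", "A_tj", "A_pc"),
  hydraulic = c("K_s", "K_tj", "K_p"),
  gas_permeability = c("P_co2_s", "P_co2_tj", "P_co2_p",
                       "P_h2co3_s", "P_h2co3_tj", "P_h2co3_p"),
  reactions = c("k_d", "k_h", "K_eq"),
  other = c("T", "sigma", "z_X"),
  transporters = c("P_pump", "P_nkcc", "P_aes", "P_aep", "P_nbcp",
                   "P_nbcs", "P_nhe"),
  channels = c("P_K_s", "P_K_p", "P_Cl_p", "P_tj"),
  stroma = c("Na", "K", "Cl", "HCO3", "pH")
)

#' Path to the shipped default configuration
#' @return File path of the packaged baseline YAML configuration.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "aquahumor",
              mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration mirroring the model's parameter groups
#' (geometry, hydraulic conductivities, gas permeabilities, reaction
#' constants, other, transporter intensities, channel permeabilities) plus
#' a `stroma` block and optional `pump_kinetics`, `solver` and
#' `sensitivity` blocks. Transporter intensities are given in units of
#' 1e-6 mol/m^2/s and channel permeabilities in 1e-8 m/s (the conventional
#' table scalings); the scalings are applied here, so the returned
#' parameters are plain SI.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A list with `params` (`ah_parameters`), `stroma` (`ah_state`),
#'   `solver` (`ah_solver_config`) and `sensitivity`
#'   (`ah_sensitivity_config`).
#' @export
#' @examples
#' cfg <- load_config(default_config_path())
#' cfg$params$P_nkcc
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)

  for (grp in names(.CONFIG_SCHEMA)) {
    if (is.null(raw[[grp]]))
      stop("config is missing the `", grp, "` block")
    missing <- setdiff(.CONFIG_SCHEMA[[grp]], names(raw[[grp]]))
    if (length(missing))
      stop("config block `", grp, "` is missing field(s): ",
           paste(missing, collapse = ", "))
  }

  pl <- c(raw$geometry, raw$hydraulic, raw$gas_permeability, raw$reactions,
          list(T_abs = raw$other$T, sigma = raw$other$sigma,
               z_X = raw$other$z_X),
          lapply(raw$transporters, function(x) x * 1e-6),
          lapply(raw$channels, function(x) x * 1e-8),
          raw$pump_kinetics)
  params <- do.call(model_parameters, pl)

  sb <- raw$stroma
  stroma <- stroma_state(params, Na = sb$Na, K = sb$K, Cl = sb$Cl,
                         HCO3 = sb$HCO3, pH = sb$pH,
                         V = if (is.null(sb$V)) 0 else sb$V)

  solver <- do.call(solver_config, if (is.null(raw$solver)) list()
                    else raw$solver)
  sens <- do.call(sensitivity_config, if (is.null(raw$sensitivity)) list()
                  else raw$sensitivity)
  list(params = params, stroma = stroma, solver = solver,
       sensitivity = sens)
}

#' Render composition and flux tables for one or more solutions
#'
#' Produces the two standard report tables: compartment composition (ion
#' concentrations in mM, pH, potential in mV, for stroma / cell / PC) and
#' transepithelial fluxes (ions in umol/m^2/s per unit membrane area, water
#' in m^3/s).
#'
#' @param solutions A named list of `ah_solution`s (e.g.
#'   `list(baseline = sol)`).
#' @param out_dir Optional directory; if given, writes `composition.csv`
#'   and `fluxes.csv` there.
#' @return List with data frames `composition` and `fluxes`.
#' @export
render_tables <- function(solutions, out_dir = NULL) {
  if (inherits(solutions, "ah_solution")) solutions <- list(model = solutions)
  comp <- do.call(rbind, lapply(names(solutions), function(nm) {
    sol <- solutions[[nm]]
    row <- function(label, st) data.frame(
      case = nm, compartment = label,
      Na = st$conc[["Na"]], K = st$conc[["K"]], Cl = st$conc[["Cl"]],
      HCO3 = st$conc[["HCO3"]], pH = unname(state_pH(st)), V_mV = st$V,
      stringsAsFactors = FALSE)
    rbind(row("stroma", sol$stroma), row("cell", sol$cell),
          row("pc", sol$pc))
  }))
  flux <- do.call(rbind, lapply(names(solutions), function(nm) {
    f <- transepithelial_fluxes(solutions[[nm]])
    data.frame(case = nm, Na = f[["Na"]], K = f[["K"]], Cl = f[["Cl"]],
               HCO3 = f[["HCO3"]], H2O = f[["H2O"]],
               stringsAsFactors = FALSE)
  }))
  rownames(comp) <- rownames(flux) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(comp, file.path(out_dir, "composition.csv"), row.names = FALSE)
    write.csv(flux, file.path(out_dir, "fluxes.csv"), row.names = FALSE)
  }
  list(composition = comp, fluxes = flux)
}

#' Run manifest for reproducible outputs
#'
#' @param config_path Path of the configuration used.
#' @param seed Seed(s) in effect.
#' @param command Free-form description of the invoked command.
#' @return A list with the package version, timestamp, config checksum,
#'   seed and command; suitable for [jsonlite::write_json()].
#' @export
run_manifest <- function(config_path = NULL, seed = NULL, command = "") {
  list(package = "aquahumor",
       version = as.character(utils::packageVersion("aquahumor")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = if (is.null(config_path)) NULL else
         list(path = config_path,
              md5 = unname(tools::md5sum(config_path))),
       seed = seed, command = command)
}
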