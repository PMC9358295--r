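# Shared fixtures: reference composition/flux values the model is expected
# to reproduce, and cached solves so expensive steady states are computed
# once per test run.

REF_STROMA <- c(Na = 150, K = 5, Cl = 130, HCO3 = 25)
REF_CELL <- c(Na = 17.8, K = 154.4, Cl = 45, HCO3 = 26.9)
REF_CELL_PH <- 7.46
REF_CELL_V <- -75.6
REF_PC <- c(Na = 151.8, K = 4.3, Cl = 126.9, HCO3 = 28.6)
REF_PC_PH <- 7.49
REF_PC_V <- -1.56
REF_Q <- 2.91e-11                       # m^3/s
REF_FLUX <- c(Na = 7.34, K = 0.21, Cl = 6.16, HCO3 = 1.38)  # umol/m2/s

REF_NOCA_CELL <- c(Na = 5.35, K = 165.3, Cl = 59.7, HCO3 = 18.3)
REF_NOCA_PC <- c(Na = 135, K = 20.3, Cl = 145, HCO3 = 10)
REF_NOCA_PC_PH <- 7.04
REF_NOCA_PC_V <- -22
REF_NOCA_Q <- 1.6e-11

.fixture_cache <- new.env(parent = emptyenv())

baseline_params <- function() default_parameters()

baseline_stroma <- function(p = baseline_params()) stroma_state(p)

baseline_solution <- function() {
  if (is.null(.fixture_cache$sol)) {
    p <- baseline_params()
    .fixture_cache$sol <- solve_steady_state(p, baseline_stroma(p))
  }
  .fixture_cache$sol
}

ca_experiment <- function() {
  if (is.null(.fixture_cache$ca)) {
    p <- baseline_params()
    .fixture_cache$ca <- inhibit_ca(p, baseline_stroma(p))
  }
  .fixture_cache$ca
}

# a generic non-equilibrium pair of states for flux-law property tests
random_state_pair <- function(seed) {
  set.seed(seed)
  mk <- function() {
    conc <- c(Na = runif(1, 5, 180), K = runif(1, 2, 170),
              Cl = runif(1, 20, 150), HCO3 = runif(1, 5, 40),
              H = 10^runif(1, -5, -4), CO2 = runif(1, 0.5, 3),
              H2CO3 = runif(1, 1e-3, 1e-2))
    compartment_state(conc, V = runif(1, -90, 10))
  }
  list(a = mk(), b = mk())
}
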