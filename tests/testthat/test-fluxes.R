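# Properties of the individual flux laws: equilibrium zeros, stoichiometric
# coupling, antisymmetry under swapping the two sides, and agreement of the
# GHK channel flux with an independent Nernst-Planck boundary-value oracle.

# Steady 1-D Nernst-Planck flux across a unit-thickness membrane with a
# linear potential profile, by shooting on the constant flux density:
# c'(x) = xi * c - j / D with c(0) = cm, c(1) = ck, D = P.
np_oracle_flux <- function(z, P, cm, ck, dV_mV, T_abs = 310) {
  rtf <- 1000 * 8.314462618 * T_abs / 96485.33212
  xi <- z * dV_mV / rtf
  endc <- function(j) {
    rhs <- function(x, y, parms) list(xi * y[1] - j / P)
    out <- deSolve::ode(y = c(c = cm), times = c(0, 1), func = rhs,
                        parms = NULL, rtol = 1e-12, atol = 1e-14)
    out[nrow(out), "c"] - ck
  }
  lim <- 10 * P * (cm + ck + 1) * (1 + abs(xi))
  uniroot(endc, interval = c(-lim, lim), tol = 1e-16)$root
}

mk_state <- function(conc7, V = 0) compartment_state(conc7, V = V)

flat <- function(Na = 100, K = 100, Cl = 100, HCO3 = 10, H = 4e-5,
                 CO2 = 1.7, H2CO3 = 5e-3, V = 0)
  compartment_state(c(Na = Na, K = K, Cl = Cl, HCO3 = HCO3, H = H,
                      CO2 = CO2, H2CO3 = H2CO3), V = V)

test_that("GHK electrodiffusive flux matches the Nernst-Planck oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    z_sp <- sample(c("Na", "K", "Cl", "HCO3"), 1)
    z <- c(Na = 1, K = 1, Cl = -1, HCO3 = -1)[[z_sp]]
    P <- 10^runif(1, -9, -6)
    cm <- runif(1, 1, 200); ck <- runif(1, 1, 200)
    dV <- runif(1, -80, 80)
    from <- flat(V = dV); to <- flat(V = 0)
    from$conc[[z_sp]] <- cm; to$conc[[z_sp]] <- ck
    got <- electrodiffusive_flux(z_sp, P, area = 1, from, to)
    want <- np_oracle_flux(z, P, cm, ck, dV)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("GHK flux tends to the Fickian limit as the potential vanishes", {
  from <- flat(V = 1e-9); to <- flat(V = 0)
  from$conc[["Na"]] <- 2; to$conc[["Na"]] <- 1
  got <- electrodiffusive_flux("Na", 1e-8, 1, from, to)
  expect_equal(got, 1e-8 * (2 - 1), tolerance = 1e-6)
  # exact equilibrium: equal concentrations, no potential
  expect_equal(electrodiffusive_flux("K", 1e-8, 1, flat(), flat()), 0)
  # zero permeability kills any flux
  expect_equal(electrodiffusive_flux("Cl", 0, 1, from, to), 0)
})

test_that("uncharged diffusion is Fickian and linear", {
  a <- flat(CO2 = 2.7); b <- flat(CO2 = 1.7)
  # P_co2 on the PC membrane with a 1 mM difference (mM = mol/m^3)
  expect_equal(uncharged_diffusive_flux("CO2", 1.5e-2, 6e-4, a, b),
               1.5e-2 * 6e-4 * 1)
  expect_equal(uncharged_diffusive_flux("CO2", 1.5e-2, 6e-4, a, a), 0)
  a2 <- flat(CO2 = 3.7)   # doubled difference, doubled flux
  expect_equal(uncharged_diffusive_flux("CO2", 1.5e-2, 6e-4, a2, b),
               2 * uncharged_diffusive_flux("CO2", 1.5e-2, 6e-4, a, b))
  expect_error(uncharged_diffusive_flux("Na", 1e-8, 1, a, b), "CO2 or H2CO3")
})

test_that("pump flux obeys 3:2 stoichiometry and saturating kinetics", {
  st <- random_state_pair(1)
  J <- pump_flux(6e-6, 6e-4, st$a, st$b)
  expect_equal(J[["J_Na"]] / J[["J_K"]], -3 / 2)
  expect_true(J[["J_Na"]] > 0)          # always extrudes Na+ from the cell
  expect_equal(unname(pump_flux(0, 6e-4, st$a, st$b)), c(0, 0))
  # monotone in intracellular Na+
  lo <- st$a; lo$conc[["Na"]] <- 5
  hi <- st$a; hi$conc[["Na"]] <- 50
  expect_lt(pump_flux(6e-6, 6e-4, lo, st$b)[["J_Na"]],
            pump_flux(6e-6, 6e-4, hi, st$b)[["J_Na"]])
  expect_error(pump_flux(-1e-6, 6e-4, st$a, st$b), "non-negative")
})

test_that("nkcc flux: 1:1:2 coupling, equilibrium zero, antisymmetry", {
  st <- random_state_pair(2)
  J <- nkcc_flux(1e-6, 6e-4, st$a, st$b)
  expect_equal(J[["J_Cl"]], 2 * J[["J_Na"]])
  expect_equal(J[["J_Na"]], J[["J_K"]])
  Jr <- nkcc_flux(1e-6, 6e-4, st$b, st$a)
  expect_equal(unname(J), -unname(Jr))
  # transporter equilibrium: identical compositions
  expect_equal(unname(nkcc_flux(1e-6, 6e-4, st$a, st$a)), c(0, 0, 0))
})

test_that("anion exchanger: electroneutral 1:1 exchange, linear in intensity", {
  st <- random_state_pair(3)
  J <- anion_exchanger_flux(4e-6, 6e-4, st$a, st$b)
  expect_equal(J[["J_Cl"]] + J[["J_HCO3"]], 0)
  expect_equal(unname(anion_exchanger_flux(8e-6, 6e-4, st$a, st$b)),
               2 * unname(J))
  expect_equal(unname(anion_exchanger_flux(4e-6, 6e-4, st$a, st$a)), c(0, 0))
  # swap antisymmetry
  expect_equal(unname(anion_exchanger_flux(4e-6, 6e-4, st$b, st$a)),
               -unname(J))
})

test_that("nhe flux: Na+ in, H+ out, 1:1", {
  st <- random_state_pair(4)
  J <- nhe_flux(3.4e-6, 6e-4, st$a, st$b)
  expect_equal(J[["J_Na"]], -J[["J_H"]])
  expect_equal(unname(nhe_flux(3.4e-6, 6e-4, st$a, st$a)), c(0, 0))
})

test_that("nbc flux: 1:2 coupling and electrochemical equilibrium zero", {
  st <- random_state_pair(5)
  J <- nbc_flux(1e-6, 6e-4, st$a, st$b)
  expect_equal(J[["J_HCO3"]], 2 * J[["J_Na"]])
  # set the potential difference to the Nernst-type equilibrium value of
  # the charge -1 carrier: flux must vanish
  rtf <- 1000 * 8.314462618 * 310 / 96485.33212
  lnq <- log((st$a$conc[["Na"]] * st$a$conc[["HCO3"]]^2) /
             (st$b$conc[["Na"]] * st$b$conc[["HCO3"]]^2))
  a_eq <- st$a; a_eq$V <- st$b$V + rtf * lnq
  J0 <- nbc_flux(1e-6, 6e-4, a_eq, st$b)
  expect_equal(unname(J0), c(0, 0), tolerance = 1e-12)
})

test_that("osmotic water flux: zero at equal osmolarity, linear in K", {
  a <- flat(); b <- flat()
  expect_equal(water_flux(2e-11, 1, 6e-4, a, b), 0)
  b2 <- flat(Na = 110)   # destination hyperosmotic by 10 mM
  Q1 <- water_flux(2e-11, 1, 6e-4, a, b2)
  expect_gt(Q1, 0)
  expect_equal(water_flux(4e-11, 1, 6e-4, a, b2), 2 * Q1)
  # the fixed charge counts towards cell osmolarity
  cellish <- compartment_state(a$conc, V = 0, CX = 10)
  expect_equal(water_flux(2e-11, 1, 6e-4, cellish, b2), 0)
})

test_that("zero concentrations entering log quotients are clamped loudly", {
  a <- flat(); b <- flat()
  b$conc[["Na"]] <- 0
  expect_warning(nkcc_flux(1e-6, 6e-4, a, b), "clamped")
})

test_that("per-species totals equal the sum of pathway contributions", {
  sol <- baseline_solution()
  fx <- sol$fluxes
  expect_equal(rowSums(fx$pathways$stromal), fx$totals[, "sc"],
               ignore_attr = TRUE)
  expect_equal(rowSums(fx$pathways$pc), fx$totals[, "cp"],
               ignore_attr = TRUE)
  expect_equal(rowSums(fx$pathways$tj), fx$totals[, "sp"],
               ignore_attr = TRUE)
})

test_that("all-zero intensities and permeabilities give all-zero fluxes", {
  p <- baseline_params()
  eps <- 1e-300   # parameters must be strictly positive; use denormal-small
  for (nm in c("P_pump", "P_nkcc", "P_aes", "P_aep", "P_nbcp", "P_nbcs",
               "P_nhe", "P_K_s", "P_K_p", "P_Cl_p", "P_tj", "P_co2_s",
               "P_co2_tj", "P_co2_p", "P_h2co3_s", "P_h2co3_tj",
               "P_h2co3_p"))
    p[[nm]] <- eps
  s <- baseline_stroma()
  cell <- compartment_state(s$conc, V = -70, CX = 0)
  pc <- compartment_state(s$conc, V = -1)
  fx <- assemble_membrane_fluxes(p, s, cell, pc)
  expect_true(all(abs(fx$totals) < 1e-290))
})
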