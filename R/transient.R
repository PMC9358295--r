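# Time-dependent relaxation of the same balances, used to verify that the
# algebraic steady state is a stable equilibrium.
#
# Dynamic variables (per compartment): Na, K, Cl, CO2, and the two
# invariants of the fast buffer step, B = HCO3 + H2CO3 and W = H + H2CO3.
# At every instant the fast equilibrium C_H2CO3 = K_eq * C_H * C_HCO3
# splits B and W back into (HCO3, H, H2CO3); the potentials V^c, V^p are
# algebraic unknowns enforcing zero net electric current into the cell and
# the PC (which preserves electroneutrality exactly, since the reactions
# conserve charge and advection removes no net charge from a neutral PC);
# the water flux is the instantaneous osmotic value Q = Q_cp + Q_sp. The
# fixed-charge concentration C_X is a constant (no volume dynamics).

# Split (B, W) into (HCO3, H, H2CO3) via the fast equilibrium.
.split_buffer <- function(B, W, K_eq) {
  b <- K_eq * (B + W) + 1
  disc <- b * b - 4 * K_eq^2 * B * W
  h2 <- (b - sqrt(max(disc, 0))) / (2 * K_eq)
  h2 <- min(h2, 0.999999 * min(B, W))
  c(HCO3 = B - h2, H = W - h2, H2CO3 = h2)
}

# y: c(Na,K,Cl,CO2,B,W) for cell then PC. Returns full 7-species vectors.
.expand_dynamic <- function(y, K_eq) {
  y <- unname(y)
  bc <- .split_buffer(y[5], y[6], K_eq)
  bp <- .split_buffer(y[11], y[12], K_eq)
  list(cc = c(y[1], y[2], y[3], bc[["HCO3"]], bc[["H"]], y[4], bc[["H2CO3"]]),
       cp = c(y[7], y[8], y[9], bp[["HCO3"]], bp[["H"]], y[10], bp[["H2CO3"]]))
}

.dynamic_from_states <- function(cell, pc) {
  c(cell$conc[["Na"]], cell$conc[["K"]], cell$conc[["Cl"]],
    cell$conc[["CO2"]], cell$conc[["HCO3"]] + cell$conc[["H2CO3"]],
    cell$conc[["H"]] + cell$conc[["H2CO3"]],
    pc$conc[["Na"]], pc$conc[["K"]], pc$conc[["Cl"]],
    pc$conc[["CO2"]], pc$conc[["HCO3"]] + pc$conc[["H2CO3"]],
    pc$conc[["H"]] + pc$conc[["H2CO3"]])
}

# Solve the two zero-net-current equations for (Vc, Vp), warm-started.
.solve_potentials <- function(p, cs, Vs, cc, cp, V0) {
  z <- .VALENCE
  fn <- function(v) {
    fx <- .flux_core(p, cs, Vs, cc, v[1], cp, v[2])
    c(sum(z * (fx$J_sc - fx$J_cp)), sum(z * (fx$J_cp + fx$J_sp))) /
      (p$P_pump * p$A_mem)
  }
  v <- V0
  f <- fn(v)
  for (it in 1:30) {
    if (max(abs(f)) < 1e-11) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- 1e-6 * max(1, abs(v[j]))
      vh <- v; vh[j] <- vh[j] + h
      J[, j] <- (fn(vh) - f) / h
    }
    dv <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(dv)) break
    mx <- max(abs(dv)); if (mx > 30) dv <- dv * (30 / mx)
    t <- 1
    repeat {
      ft <- fn(v + t * dv)
      if (all(is.finite(ft)) && max(abs(ft)) < max(abs(f))) break
      t <- t / 2
      if (t < 1e-5) break
    }
    v <- v + t * dv
    f <- fn(v)
  }
  v
}

#' Integrate the time-dependent relaxation of the transport model
#'
#' Adds storage terms to the solute balances (with cell volume
#' `A_mem * L` and PC volume `A_pc * H`) and integrates them as a
#' differential-algebraic system: concentrations evolve in time while the
#' potentials enforce zero net current into each compartment and the water
#' flux takes its instantaneous osmotic value. Used to verify stability of
#' the algebraic steady state, to which a stable trajectory relaxes.
#'
#' @param params An `ah_parameters` object.
#' @param stroma Stromal `ah_state`.
#' @param initial_state An `ah_solution`, or a list with `ah_state`
#'   elements `cell` (carrying `CX`) and `pc`.
#' @param horizon Integration horizon in seconds.
#' @param n_out Number of output times.
#' @param rtol,atol Integrator tolerances (passed to [deSolve::ode()]).
#' @return An object of class `ah_trajectory`: `times`, matrix `y` of the
#'   twelve dynamic concentrations, matrices of recovered full states, the
#'   potentials and water flux along the trajectory, and the final
#'   `cell`/`pc` states.
#' @export
integrate_transient <- function(params, stroma, initial_state,
                                horizon = 6e4, n_out = 200,
                                rtol = 1e-8, atol = 1e-12) {
  p <- validate_parameters(params)
  if (inherits(initial_state, "ah_solution"))
    initial_state <- list(cell = initial_state$cell, pc = initial_state$pc)
  cell0 <- initial_state$cell; pc0 <- initial_state$pc
  if (is.null(cell0$CX)) stop("initial cell state must carry `CX`")
  CX <- cell0$CX
  vol_c <- p$A_mem * p$L
  vol_p <- p$A_pc * p$H
  cs <- stroma$conc; Vs <- stroma$V
  RT <- .GAS_R * p$T_abs
  env <- new.env()
  env$V <- c(cell0$V, pc0$V)

  rhs <- function(t, y, parms) {
    st <- .expand_dynamic(y, p$K_eq)
    cc <- st$cc; cp <- st$cp
    V <- .solve_potentials(p, cs, Vs, cc, cp, env$V)
    env$V <- V
    fx <- .flux_core(p, cs, Vs, cc, V[1], cp, V[2])
    osm_c <- sum(cc) + CX
    Q_cp <- -p$A_mem * p$K_p * p$sigma * RT * (osm_c - sum(cp))
    Q_sp <- -p$A_tj * p$K_tj * p$sigma * RT * (sum(cs) - sum(cp))
    Q <- Q_cp + Q_sp
    Tc <- fx$J_sc - fx$J_cp
    Tp <- fx$J_cp + fx$J_sp - Q * cp
    rho_c <- vol_c * (p$k_d * cc[7] - p$k_h * cc[6])
    rho_p <- vol_p * (p$k_d * cp[7] - p$k_h * cp[6])
    dy <- c(Tc[1], Tc[2], Tc[3], Tc[6] + rho_c,
            Tc[4] + Tc[7] - rho_c, Tc[5] + Tc[7] - rho_c) / vol_c
    dy <- c(dy, c(Tp[1], Tp[2], Tp[3], Tp[6] + rho_p,
                  Tp[4] + Tp[7] - rho_p, Tp[5] + Tp[7] - rho_p) / vol_p)
    list(dy, V_c = V[1], V_p = V[2], Q = Q)
  }

  y0 <- .dynamic_from_states(cell0, pc0)
  names(y0) <- c(paste0(c("Na", "K", "Cl", "CO2", "B", "W"), "_c"),
                 paste0(c("Na", "K", "Cl", "CO2", "B", "W"), "_p"))
  times <- seq(0, horizon, length.out = n_out)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = rtol,
                      atol = atol + 1e-9 * abs(y0))
  if (attr(out, "istate")[1] < 0)
    stop("transient integration failed at t = ", max(out[, "time"]), " s")

  yT <- out[nrow(out), ]
  stT <- .expand_dynamic(unname(yT[2:13]), p$K_eq)
  cellT <- compartment_state(setNames(stT$cc, .SPECIES),
                             V = unname(yT[["V_c"]]), CX = CX)
  pcT <- compartment_state(setNames(stT$cp, .SPECIES),
                           V = unname(yT[["V_p"]]))
  structure(list(times = out[, "time"], y = out[, 2:13, drop = FALSE],
                 V_c = out[, "V_c"], V_p = out[, "V_p"], Q = out[, "Q"],
                 cell = cellT, pc = pcT, CX = CX),
            class = "ah_trajectory")
}

#' @export
print.ah_trajectory <- function(x, ...) {
  cat("<ah_trajectory>", length(x$times), "time points over",
      format(max(x$times)), "s;  final Q =",
      format(x$Q[length(x$Q)], digits = 4), "m^3/s\n")
  invisible(x)
}

# Relative distance between a trajectory endpoint and a steady solution,
# on the dynamic variables.
.trajectory_distance <- function(traj, solution) {
  a <- .dynamic_from_states(traj$cell, traj$pc)
  b <- .dynamic_from_states(solution$cell, solution$pc)
  max(abs(a - b) / pmax(abs(b), 1e-6))
}

# Zero the net charge of a state by adjusting Cl- (constraint projection
# after a perturbation).
.project_neutral <- function(conc, extra_charge = 0) {
  conc[["Cl"]] <- conc[["Cl"]] + sum(.VALENCE * conc) + extra_charge
  conc
}

#' Verify stability of a steady state by perturb-and-relax
#'
#' Perturbs every dynamic concentration of a converged solution by random
#' factors of magnitude `magnitude`, projects the perturbed state back onto
#' the electroneutrality constraints (adjusting Cl-), integrates the
#' transient model, and reports the distance of each endpoint from the
#' algebraic root. The verdict is `stable` iff every run returns within
#' `tol` (relative, max-norm over the dynamic variables).
#'
#' @param params,stroma As for [solve_steady_state()].
#' @param solution A converged `ah_solution`.
#' @param n_perturbations Number of random perturbations.
#' @param magnitude Relative perturbation magnitude (default 5%).
#' @param seed RNG seed; the verdict is deterministic given the seed.
#' @param horizon Integration horizon in seconds.
#' @param tol Return-to-root tolerance (relative).
#' @return List with `stable` (logical), `distances` per run, and the
#'   settings used.
#' @export
assess_stability <- function(params, stroma, solution, n_perturbations = 3,
                             magnitude = 0.05, seed = 1, horizon = 2e5,
                             tol = 1e-3) {
  stopifnot(inherits(solution, "ah_solution"))
  draws <- .with_seed(seed, {
    lapply(seq_len(n_perturbations), function(i)
      runif(12, -magnitude, magnitude))
  })
  distances <- vapply(draws, function(d) {
    y <- .dynamic_from_states(solution$cell, solution$pc) * (1 + d)
    st <- .expand_dynamic(y, params$K_eq)
    cc <- .project_neutral(setNames(st$cc, .SPECIES),
                           extra_charge = params$z_X * solution$cell$CX)
    cp <- .project_neutral(setNames(st$cp, .SPECIES))
    init <- list(cell = compartment_state(cc, V = solution$cell$V,
                                          CX = solution$cell$CX),
                 pc = compartment_state(cp, V = solution$pc$V))
    traj <- integrate_transient(params, stroma, init, horizon = horizon,
                                n_out = 50)
    .trajectory_distance(traj, solution)
  }, numeric(1))
  list(stable = all(distances < tol), distances = distances,
       magnitude = magnitude, horizon = horizon, tol = tol, seed = seed)
}
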