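#' Solver settings for the steady-state solve
#'
#' @param tol Convergence tolerance on the max-norm of the
#'   nondimensionalized residual.
#' @param max_iter Maximum Newton iterations per start.
#' @param multistart Number of randomized restarts around the physiological
#'   initial guess if the first solve fails.
#' @param seed Seed for the multistart perturbations.
#' @param guess Optional initial guess: an `ah_solution`, or a numeric
#'   18-vector in the [residual_system()] ordering. Default: physiological
#'   composition.
#' @return An object of class `ah_solver_config`.
#' @export
solver_config <- function(tol = 1e-10, max_iter = 60, multistart = 20,
                          seed = 1234, guess = NULL) {
  if (tol <= 0) stop("`tol` must be positive")
  if (max_iter < 1) stop("`max_iter` must be at least 1")
  structure(list(tol = tol, max_iter = max_iter, multistart = multistart,
                 seed = seed, guess = guess),
            class = "ah_solver_config")
}

# transform between natural unknowns u and solver variables x
.u_to_x <- function(u, rtf) {
  u <- unname(u)
  c(log(u[1:15]), u[16] / 1e-11, u[17:18] / rtf)
}
.x_to_u <- function(x, rtf) {
  x <- unname(x)
  c(exp(x[1:15]), x[16] * 1e-11, x[17:18] * rtf)
}

# Damped quasi-Newton iteration in log-concentration space: full
# finite-difference Jacobian on the first step (and whenever progress
# stalls), Broyden rank-1 updates in between.
.fd_jacobian <- function(fn, x, f) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- 1e-7 * max(1, abs(x[j]))
    xh <- x; xh[j] <- xh[j] + h
    J[, j] <- (fn(xh) - f) / h
  }
  J
}

.newton <- function(x0, fn, tol, max_iter) {
  x <- x0
  f <- fn(x)
  if (any(!is.finite(f))) return(list(x = x, norm = Inf, converged = FALSE,
                                      iterations = 0L))
  J <- NULL
  fresh <- FALSE
  age <- 0L
  for (it in seq_len(max_iter)) {
    nrm <- max(abs(f))
    if (nrm < tol)
      return(list(x = x, norm = nrm, converged = TRUE, iterations = it - 1L))
    if (is.null(J) || age > 8L) {
      J <- .fd_jacobian(fn, x, f)
      fresh <- TRUE
      age <- 0L
    }
    lu <- tryCatch(.lu_solver(J), error = function(e) NULL)
    if (is.null(lu)) {
      if (!fresh) { J <- NULL; next }
      return(list(x = x, norm = nrm, converged = FALSE, iterations = it))
    }
    dx <- lu(-f)
    if (any(!is.finite(dx))) {
      if (!fresh) { J <- NULL; next }
      return(list(x = x, norm = nrm, converged = FALSE, iterations = it))
    }
    # cap the log-space step to stay in a trust region
    mx <- max(abs(dx))
    if (mx > 5) dx <- dx * (5 / mx)
    ndx <- sqrt(sum(dx * dx))
    # natural-level (affine-invariant) monotonicity test: accept when the
    # simplified Newton correction ||J^-1 f|| shrinks — robust where the
    # raw residual norm forms a narrow valley (stiff water/charge rows)
    t <- 1
    accepted <- FALSE
    ft <- NULL
    while (t >= 1e-4) {
      ft <- fn(x + t * dx)
      if (all(is.finite(ft))) {
        dxbar <- lu(-ft)
        if (all(is.finite(dxbar)) &&
            (sqrt(sum(dxbar * dxbar)) <= (1 - t / 4) * ndx ||
             max(abs(ft)) < 0.9 * nrm)) {
          accepted <- TRUE
          break
        }
      }
      t <- t / 2
    }
    if (!accepted) {
      if (!fresh) { J <- NULL; next }
      return(list(x = x, norm = nrm, converged = FALSE, iterations = it))
    }
    s <- t * dx
    if (!fresh && t < 0.99) {
      J <- NULL          # stale secant model: rebuild next iteration
    } else {
      J <- J + tcrossprod((ft - f) - J %*% s, s) / sum(s * s)
      fresh <- FALSE
      age <- age + 1L
    }
    x <- x + s
    f <- ft
  }
  list(x = x, norm = max(abs(f)), converged = max(abs(f)) < tol,
       iterations = max_iter)
}

# LU-factor a matrix once and return a solve function.
.lu_solver <- function(J) {
  qrJ <- qr(J)
  if (qrJ$rank < ncol(J)) stop("singular Jacobian")
  function(b) qr.coef(qrJ, b)
}

#' Solve the steady-state transport system
#'
#' Finds the root of [residual_system()] — the 18 unknowns: cell and PC
#' concentrations, fixed-charge concentration, water production rate and
#' both potentials — by a damped Newton iteration in log-concentration
#' space (which keeps every concentration strictly positive). If the
#' physiological initial guess fails, randomized restarts around it are
#' attempted.
#'
#' @param params An `ah_parameters` object.
#' @param stroma Stromal `ah_state` boundary condition.
#' @param config An [solver_config()].
#' @return An object of class `ah_solution`: `cell` and `pc` states (`cell`
#'   carries `CX`), water flux `Q` (m^3/s), `fluxes` (an `ah_fluxes`
#'   breakdown), `residual_norm`, `iterations`, `converged`, and the inputs.
#' @export
#' @examples
#' p <- default_parameters()
#' s <- stroma_state(p)
#' sol <- solve_steady_state(p, s)
#' sol$Q
solve_steady_state <- function(params, stroma, config = solver_config()) {
  p <- validate_parameters(params)
  rtf <- .rtf_mV(p$T_abs)
  cs <- stroma$conc; Vs <- stroma$V
  fn <- .make_residual_fn(p, cs, Vs)

  u0 <- config$guess
  if (inherits(u0, "ah_solution")) u0 <- .solution_to_vector(u0)
  if (is.null(u0)) u0 <- .initial_guess(p, stroma)
  if (length(u0) != 18L) stop("initial guess must have length 18")

  res <- .newton(.u_to_x(u0, rtf), fn, config$tol, config$max_iter)
  if (!res$converged && config$multistart > 0) {
    rng <- .with_seed(config$seed, {
      lapply(seq_len(config$multistart), function(i)
        c(rnorm(15, 0, 0.25), rnorm(1, 0, 0.5), rnorm(2, 0, 0.3)))
    })
    base <- .u_to_x(.initial_guess(p, stroma), rtf)
    best <- res
    for (d in rng) {
      cand <- .newton(base + d, fn, config$tol, config$max_iter)
      if (cand$converged) { best <- cand; break }
      if (cand$norm < best$norm) best <- cand
    }
    res <- best
  }
  if (!res$converged)
    stop("steady-state solve did not converge; best residual max-norm = ",
         format(res$norm, digits = 4))

  u <- .x_to_u(res$x, rtf)
  cell <- compartment_state(setNames(u[1:7], .SPECIES), V = u[17], CX = u[15])
  pc <- compartment_state(setNames(u[8:14], .SPECIES), V = u[18])
  structure(list(cell = cell, pc = pc, Q = u[16],
                 fluxes = assemble_membrane_fluxes(p, stroma, cell, pc),
                 residual_norm = res$norm, iterations = res$iterations,
                 converged = TRUE, params = p, stroma = stroma),
            class = "ah_solution")
}

.solution_to_vector <- function(sol) {
  c(sol$cell$conc, sol$pc$conc, sol$cell$CX, sol$Q, sol$cell$V, sol$pc$V)
}

# Lean solve used in ensembles: plain parameter list in, 18-vector out.
.solve_u <- function(p, cs, Vs, u0, tol = 1e-8, max_iter = 40) {
  rtf <- .rtf_mV(p$T_abs)
  fn <- .make_residual_fn(p, cs, Vs)
  res <- .newton(.u_to_x(u0, rtf), fn, tol, max_iter)
  list(u = .x_to_u(res$x, rtf), converged = res$converged,
       norm = res$norm, iterations = res$iterations)
}

# run code with a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.ah_solution <- function(x, ...) {
  cat("<ah_solution>  converged in", x$iterations, "iterations,",
      "residual", format(x$residual_norm, digits = 3), "\n")
  tab <- rbind(cell = c(x$cell$conc[1:4], pH = unname(state_pH(x$cell)),
                        V = x$cell$V),
               pc = c(x$pc$conc[1:4], pH = unname(state_pH(x$pc)),
                      V = x$pc$V))
  print(round(tab, 2))
  cat("Q =", format(x$Q, digits = 4), "m^3/s   CX =",
      format(x$cell$CX, digits = 4), "mM\n")
  invisible(x)
}
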