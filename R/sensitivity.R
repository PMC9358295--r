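# Extended Fourier Amplitude Sensitivity Test (eFAST) over the channel
# intensities and permeabilities, plus the ensemble experiments built on
# the same design (paired CA inhibition, pump knockdown).

.EFAST_PARAMS <- c("P_nkcc", "P_aes", "P_aep", "P_nbcp", "P_nbcs", "P_nhe",
                   "P_K_s", "P_K_p", "P_Cl_p", "P_tj")

#' Settings for the eFAST sensitivity analysis
#'
#' @param parameters Character vector of parameter names to vary. Default:
#'   the ten channel intensities/permeabilities (the pump is held fixed).
#' @param range_fraction Half-width of the variation range as a fraction of
#'   the baseline value (default 0.5, i.e. +/-50%). Zero gives a degenerate
#'   (constant) ensemble, useful as a consistency check.
#' @param runs_per_parameter Model runs per varied parameter; must be
#'   divisible by `resamples`. 257 is a practical reduced scale; 5973
#'   (3 resample curves of 1991 points) matches the full-scale study.
#' @param M Interference factor of the frequency design.
#' @param resamples Number of random-phase resample curves per parameter.
#' @param seed RNG seed for the phases.
#' @param outputs Names of the model outputs of interest.
#' @return An object of class `ah_sensitivity_config`.
#' @export
sensitivity_config <- function(parameters = .EFAST_PARAMS,
                               range_fraction = 0.5,
                               runs_per_parameter = 257,
                               M = 4, resamples = 1, seed = 1,
                               outputs = c("Q", "Na_p", "K_p", "Cl_p",
                                           "HCO3_p")) {
  if (range_fraction < 0 || range_fraction >= 1)
    stop("`range_fraction` must lie in [0, 1)")
  if (runs_per_parameter %% resamples != 0)
    stop("`runs_per_parameter` must be divisible by `resamples`")
  Ns <- runs_per_parameter / resamples
  if (Ns < 4 * M^2 + 1)
    stop("runs per curve (", Ns, ") below the Nyquist bound ",
         4 * M^2 + 1, " for interference factor M = ", M)
  structure(list(parameters = parameters, range_fraction = range_fraction,
                 runs_per_parameter = runs_per_parameter, M = M,
                 resamples = resamples, Ns = Ns, seed = seed,
                 outputs = outputs),
            class = "ah_sensitivity_config")
}

#' Generate the eFAST sample matrix
#'
#' Each varied parameter is assigned, in turn, the highest interference-free
#' frequency `omega_max = floor((Ns - 1) / (2 M))` while the remaining
#' parameters oscillate at low complementary frequencies
#' (at most `floor(omega_max / (2 M))`); the search curve
#' `x = 1/2 + asin(sin(omega s + phi)) / pi` sweeps each parameter across
#' its range. Random phases `phi` (seeded) decorrelate resample curves.
#'
#' @param config An [sensitivity_config()].
#' @param baseline Named numeric vector of baseline values for
#'   `config$parameters`.
#' @param lower,upper Optional explicit bounds (named as `baseline`);
#'   default `baseline * (1 -/+ range_fraction)`.
#' @return An object of class `ah_efast_design`: sample matrix `X`
#'   (`runs_per_parameter * length(parameters)` rows), row metadata
#'   (`target`, `curve`, `point`), and the frequency layout.
#' @export
efast_design <- function(config, baseline, lower = NULL, upper = NULL) {
  np <- length(config$parameters)
  if (np < 2) stop("need at least two parameters for eFAST")
  baseline <- baseline[config$parameters]
  if (any(is.na(baseline))) stop("baseline values missing for some parameters")
  if (is.null(lower)) lower <- baseline * (1 - config$range_fraction)
  if (is.null(upper)) upper <- baseline * (1 + config$range_fraction)
  lower <- lower[config$parameters]; upper <- upper[config$parameters]

  Ns <- config$Ns; M <- config$M; Nr <- config$resamples
  omega_max <- floor((Ns - 1) / (2 * M))
  omega_c <- rep_len(seq_len(max(1, floor(omega_max / (2 * M)))), np - 1)
  s <- pi * (2 * seq_len(Ns) - Ns - 1) / Ns

  phases <- .with_seed(config$seed, {
    array(runif(np * Nr * np, 0, 2 * pi), dim = c(np, Nr, np))
  })

  X <- matrix(NA_real_, np * Nr * Ns, np,
              dimnames = list(NULL, config$parameters))
  target <- integer(np * Nr * Ns); curve <- integer(np * Nr * Ns)
  point <- integer(np * Nr * Ns)
  row <- 0L
  for (i in seq_len(np)) {
    omega <- numeric(np)
    omega[i] <- omega_max
    omega[-i] <- omega_c
    for (l in seq_len(Nr)) {
      phi <- phases[i, l, ]
      idx <- row + seq_len(Ns)
      for (j in seq_len(np)) {
        x <- 0.5 + asin(sin(omega[j] * s + phi[j])) / pi
        X[idx, j] <- lower[j] + x * (upper[j] - lower[j])
      }
      target[idx] <- i; curve[idx] <- l; point[idx] <- seq_len(Ns)
      row <- row + Ns
    }
  }
  structure(list(X = X, target = target, curve = curve, point = point,
                 omega_max = omega_max, omega_c = omega_c, Ns = Ns,
                 M = M, resamples = Nr, parameters = config$parameters,
                 baseline = baseline, lower = lower, upper = upper),
            class = "ah_efast_design")
}

#' Total-order sensitivity indices from an evaluated eFAST design
#'
#' For each varied parameter, the output variance at frequencies up to
#' `floor(omega_max / 2)` estimates the variance due to everything except
#' that parameter; the total index is one minus its share of the total
#' variance, averaged over resample curves. The effect direction is the
#' sign of the Spearman rank correlation between the parameter and the
#' output across the whole ensemble (`+`, `-`, or `0` when |rho| < 0.1).
#'
#' @param y Numeric vector of model outputs, one per design row (`NA` for
#'   failed runs; curves containing failures are excluded from the
#'   spectral estimate).
#' @param design An `ah_efast_design`.
#' @return A data frame with one row per parameter: `parameter`, `S_T`
#'   (total-order index in `[0, 1]`), `direction`, `curves_used`.
#' @export
efast_total_index <- function(y, design) {
  stopifnot(inherits(design, "ah_efast_design"))
  if (length(y) != nrow(design$X))
    stop("`y` must have one value per design row")
  Ns <- design$Ns
  cutoff <- max(1, floor(design$omega_max / 2))
  np <- length(design$parameters)
  S_T <- numeric(np); used <- integer(np); dir <- character(np)
  for (i in seq_len(np)) {
    st <- c()
    for (l in seq_len(design$resamples)) {
      sel <- design$target == i & design$curve == l
      yk <- y[sel][order(design$point[sel])]
      if (anyNA(yk)) next
      f <- stats::fft(yk - mean(yk))
      power <- (Mod(f[2:((Ns + 1) %/% 2)])^2) * 2 / Ns^2
      D <- sum(power)
      if (D <= 0) { st <- c(st, 0); next }
      Dc <- sum(power[seq_len(min(cutoff, length(power)))])
      st <- c(st, min(max(1 - Dc / D, 0), 1))
    }
    used[i] <- length(st)
    S_T[i] <- if (length(st)) mean(st) else NA_real_
    ok <- !is.na(y)
    rho <- if (sum(ok) > 2)
      suppressWarnings(cor(design$X[ok, i], y[ok], method = "spearman"))
    else NA_real_
    dir[i] <- if (is.na(rho) || abs(rho) < 0.1) "0"
              else if (rho > 0) "+" else "-"
  }
  data.frame(parameter = design$parameters, S_T = S_T, direction = dir,
             curves_used = used, stringsAsFactors = FALSE)
}

# Evaluate the model over the rows of a design. Returns the output matrix,
# the solution vectors (for warm starts of derived arms) and a success mask.
# `transform` maps a baseline parameter set + design row to the parameter
# set actually solved (used for the CA-off and pump-knockdown arms).
.evaluate_ensemble <- function(params, stroma, design,
                               transform = NULL, guesses = NULL,
                               tol = 1e-9, max_iter = 40) {
  n <- nrow(design$X)
  pn <- design$parameters
  Y <- matrix(NA_real_, n, 5,
              dimnames = list(NULL, c("Q", "Na_p", "K_p", "Cl_p", "HCO3_p")))
  U <- matrix(NA_real_, n, 18)
  cs <- stroma$conc; Vs <- stroma$V
  base_guess <- .initial_guess(params, stroma)
  prev <- NULL
  for (r in seq_len(n)) {
    p <- unclass(params)
    p[pn] <- design$X[r, ]
    if (!is.null(transform)) p <- transform(p)
    g <- if (!is.null(guesses) && !anyNA(guesses[r, ])) guesses[r, ]
         else if (!is.null(prev)) prev else base_guess
    res <- .solve_u(p, cs, Vs, g, tol = tol, max_iter = max_iter)
    if (!res$converged && !is.null(prev))
      res <- .solve_u(p, cs, Vs, base_guess, tol = tol, max_iter = max_iter)
    if (!res$converged) {
      # deterministic multistart fallback around the physiological guess
      draws <- .with_seed(971210 + r, {
        lapply(1:6, function(i) rnorm(18, 0, c(rep(0.25, 15), 0.5, 5, 5)))
      })
      for (d in draws) {
        u0 <- base_guess
        u0[1:16] <- u0[1:16] * exp(d[1:16])
        u0[17:18] <- u0[17:18] + d[17:18]
        res <- .solve_u(p, cs, Vs, u0, tol = tol, max_iter = 80)
        if (res$converged) break
      }
    }
    if (res$converged) {
      U[r, ] <- res$u
      Y[r, ] <- c(res$u[16], res$u[8], res$u[9], res$u[10], res$u[11])
      prev <- res$u
    }
  }
  list(Y = Y, U = U, ok = !is.na(Y[, 1]))
}

.check_failures <- function(ok, what) {
  frac <- mean(!ok)
  if (frac > 0.25)
    stop(sprintf("%.0f%% of %s solves failed", 100 * frac, what))
  if (frac > 0.05)
    warning(sprintf("%.0f%% of %s solves failed", 100 * frac, what),
            call. = FALSE)
}

#' Run the eFAST global sensitivity analysis on the transport model
#'
#' Builds the eFAST design over the configured parameters (by default the
#' ten channel intensities/permeabilities within +/-50% of baseline),
#' solves the steady state for every sample, and returns total-order
#' indices and effect directions for the water production rate and the PC
#' concentrations.
#'
#' @param params,stroma Model baseline and boundary condition.
#' @param config An [sensitivity_config()].
#' @return An object of class `ah_sensitivity_result`: `indices` (long data
#'   frame parameter x output), `design`, the output matrix `Y`, solution
#'   matrix `U`, and `failed` (count).
#' @export
run_efast <- function(params, stroma, config = sensitivity_config()) {
  params <- validate_parameters(params)
  design <- efast_design(config, unlist(unclass(params)[config$parameters]))
  ev <- .evaluate_ensemble(params, stroma, design)
  .check_failures(ev$ok, "ensemble")
  idx <- do.call(rbind, lapply(config$outputs, function(out) {
    d <- efast_total_index(ev$Y[, out], design)
    d$output <- out
    d
  }))
  structure(list(indices = idx[, c("parameter", "output", "S_T",
                                   "direction", "curves_used")],
                 design = design, Y = ev$Y, U = ev$U,
                 failed = sum(!ev$ok), params = params, stroma = stroma,
                 config = config),
            class = "ah_sensitivity_result")
}

#' @export
print.ah_sensitivity_result <- function(x, ...) {
  cat("<ah_sensitivity_result>", nrow(x$design$X), "runs,",
      x$failed, "failed\n")
  q <- x$indices[x$indices$output == "Q", ]
  q <- q[order(-q$S_T), ]
  cat("total-order indices for Q:\n")
  print(data.frame(parameter = q$parameter, S_T = round(q$S_T, 3),
                   direction = q$direction), row.names = FALSE)
  invisible(x)
}

#' Paired normal / CA-inhibited ensemble comparison
#'
#' Runs the identical parameter-variation design twice — once with
#' carbonic anhydrase active and once inhibited (`k_d`, `k_h` divided by
#' 1e6) — and summarizes the mean and SD of the water production rate and
#' PC concentrations in both arms, together with the member-wise mean
#' relative reduction of Q.
#'
#' @param params,stroma Model baseline and boundary condition.
#' @param config An [sensitivity_config()].
#' @param reference Optionally, an `ah_sensitivity_result` from
#'   [run_efast()] at the same config, whose runs are reused as the
#'   normal arm.
#' @param ca_factor Catalysis factor removed in the inhibited arm.
#' @return List with `summary` (data frame of mean/SD per output per arm),
#'   `mean_Q_reduction_percent`, per-member reductions, and failure counts.
#' @export
paired_ca_comparison <- function(params, stroma,
                                 config = sensitivity_config(),
                                 reference = NULL, ca_factor = 1e6) {
  params <- validate_parameters(params)
  if (is.null(reference)) reference <- run_efast(params, stroma, config)
  design <- reference$design
  off <- .evaluate_ensemble(
    params, stroma, design,
    transform = function(p) {
      p$k_d <- p$k_d / ca_factor; p$k_h <- p$k_h / ca_factor; p
    },
    guesses = reference$U)
  .check_failures(off$ok, "CA-inhibited ensemble")
  both <- reference$Y[, 1] > 0 & !is.na(reference$Y[, 1]) & off$ok
  red <- 100 * (1 - off$Y[both, "Q"] / reference$Y[both, "Q"])
  outs <- colnames(reference$Y)
  summary <- do.call(rbind, lapply(outs, function(o) {
    data.frame(output = o,
               mean_normal = mean(reference$Y[both, o]),
               sd_normal = sd(reference$Y[both, o]),
               mean_no_ca = mean(off$Y[both, o]),
               sd_no_ca = sd(off$Y[both, o]))
  }))
  list(summary = summary,
       mean_Q_reduction_percent = mean(red),
       Q_reduction_percent = red,
       n_members = sum(both),
       failed = c(normal = reference$failed, no_ca = sum(!off$ok)))
}

#' Pump-knockdown ensemble
#'
#' For every member of the parameter-variation ensemble, solves the model
#' with the pump intensity at its value and at `factor` times that value,
#' and reports the mean relative decrease of the water production rate.
#'
#' @param params,stroma Model baseline and boundary condition.
#' @param config An [sensitivity_config()].
#' @param factor Multiplicative knockdown factor for `param` (default 0.5).
#' @param param Parameter knocked down (default `P_pump`).
#' @param reference Optional [run_efast()] result to reuse as the
#'   reference arm.
#' @return List with `mean_Q_decrease_percent`, the member-wise decreases,
#'   and failure counts.
#' @export
knockdown_ensemble <- function(params, stroma,
                               config = sensitivity_config(),
                               factor = 0.5, param = "P_pump",
                               reference = NULL) {
  params <- validate_parameters(params)
  if (is.null(reference)) reference <- run_efast(params, stroma, config)
  design <- reference$design
  kd <- .evaluate_ensemble(
    params, stroma, design,
    transform = function(p) { p[[param]] <- p[[param]] * factor; p },
    guesses = reference$U)
  .check_failures(kd$ok, "knockdown ensemble")
  both <- reference$Y[, 1] > 0 & !is.na(reference$Y[, 1]) & kd$ok
  dec <- 100 * (1 - kd$Y[both, "Q"] / reference$Y[both, "Q"])
  list(mean_Q_decrease_percent = mean(dec),
       Q_decrease_percent = dec,
       n_members = sum(both),
       failed = c(reference = reference$failed, knockdown = sum(!kd$ok)))
}
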