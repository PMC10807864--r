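# Reduced description of one isolated area: with the rate variables slaved to
# their transfer functions (tau_r << tau_N), the local circuit is a 3D system
# in the gating variables (S_A, S_B, S_C).

# Resolve effective local inhibitory weights, allowing explicit overrides.
resolve_local_weights <- function(params, PV, g_EI = NULL, g_II = NULL) {
  lw <- local_inhibitory_weights(PV, params)
  list(g_EI = if (is.null(g_EI)) lw$g_EI else g_EI,
       g_II = if (is.null(g_II)) lw$g_II else g_II)
}

local_currents <- function(S, params, g_EI, g_II, I_ext = c(0, 0, 0)) {
  c(params$g_E_self * S[1] + params$g_E_cross * S[2] - g_EI * S[3] +
      params$I0_A + I_ext[1],
    params$g_E_self * S[2] + params$g_E_cross * S[1] - g_EI * S[3] +
      params$I0_B + I_ext[2],
    params$g_IE * (S[1] + S[2]) - g_II * S[3] + params$I0_C + I_ext[3])
}

local_F <- function(S, params, g_EI, g_II, I_ext = c(0, 0, 0)) {
  I <- local_currents(S, params, g_EI, g_II, I_ext)
  c(-S[1] / params$tau_N + params$gamma * (1 - S[1]) * phi_E(I[1], params),
    -S[2] / params$tau_N + params$gamma * (1 - S[2]) * phi_E(I[2], params),
    -S[3] / params$tau_G + params$gamma_I * phi_I(I[3], params))
}

#' Analytic Jacobian of the reduced local circuit
#'
#' Partial derivatives of the gating derivatives with respect to
#' `(S_A, S_B, S_C)`, with the rates adiabatically eliminated. The
#' inhibitory transfer-function derivative is `c1/g_I` on its active branch
#' and 0 below the rectification threshold.
#'
#' @param S gating triple.
#' @param params a [model_params()] object.
#' @param PV normalized PV fraction of the area (sets the local inhibitory
#'   weights unless overridden).
#' @param g_EI,g_II optional explicit local inhibitory weights (nA).
#' @param I_ext external current triple (nA).
#' @return 3 x 3 numeric matrix (units 1/s).
#' @export
local_jacobian <- function(S, params, PV = 0, g_EI = NULL, g_II = NULL,
                           I_ext = c(0, 0, 0)) {
  w <- resolve_local_weights(params, PV, g_EI, g_II)
  I <- local_currents(S, params, w$g_EI, w$g_II, I_ext)
  dphiA <- phi_E_deriv(I[1], params)
  dphiB <- phi_E_deriv(I[2], params)
  dphiC <- phi_I_deriv(I[3], params)
  g <- params$gamma; gI <- params$gamma_I
  J <- matrix(0, 3, 3)
  J[1, 1] <- -1 / params$tau_N - g * phi_E(I[1], params) +
    g * (1 - S[1]) * dphiA * params$g_E_self
  J[1, 2] <- g * (1 - S[1]) * dphiA * params$g_E_cross
  J[1, 3] <- -g * (1 - S[1]) * dphiA * w$g_EI
  J[2, 1] <- g * (1 - S[2]) * dphiB * params$g_E_cross
  J[2, 2] <- -1 / params$tau_N - g * phi_E(I[2], params) +
    g * (1 - S[2]) * dphiB * params$g_E_self
  J[2, 3] <- -g * (1 - S[2]) * dphiB * w$g_EI
  J[3, 1] <- gI * dphiC * params$g_IE
  J[3, 2] <- gI * dphiC * params$g_IE
  J[3, 3] <- -1 / params$tau_G - gI * dphiC * w$g_II
  J
}

#' Fixed point of an isolated local circuit
#'
#' Solves the reduced gating equations by damped Newton iteration with the
#' analytic Jacobian, starting from a low-activity (`S ~ 0`) or
#' high-activity (`S_A ~ 0.7`, memory-like) initial guess. Converged roots
#' have residual below `1e-10`; non-convergence raises an error carrying the
#' last iterate and residual.
#'
#' @param params a [model_params()] object.
#' @param PV normalized PV fraction of the area.
#' @param branch `"low"` or `"high"` initial guess (ignored when `S0` given).
#' @param g_EI,g_II optional explicit local inhibitory weights (nA).
#' @param S0 optional explicit initial guess.
#' @param I_ext external current triple (nA).
#' @param tol residual tolerance.
#' @return list with `S` (gating triple), `rates` (Hz, via the transfer
#'   functions), `I` (currents), `residual` and `branch`.
#' @export
fixed_point <- function(params, PV = 0, branch = c("low", "high"),
                        g_EI = NULL, g_II = NULL, S0 = NULL,
                        I_ext = c(0, 0, 0), tol = 1e-10) {
  branch <- match.arg(branch)
  w <- resolve_local_weights(params, PV, g_EI, g_II)
  if (is.null(S0))
    S0 <- if (branch == "low") c(0.01, 0.01, 0.01) else c(0.7, 0.02, 0.2)
  S <- S0
  f <- local_F(S, params, w$g_EI, w$g_II, I_ext)
  for (it in seq_len(200)) {
    if (max(abs(f)) < tol) break
    J <- local_jacobian(S, params, PV, w$g_EI, w$g_II, I_ext)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian during Newton iteration at S = ",
                            paste(signif(S, 4), collapse = ", "))
    lambda <- 1
    repeat {
      S_new <- S - lambda * step
      S_new[1:2] <- pmin(pmax(S_new[1:2], 0), 1)  # keep NMDA gating feasible
      S_new[3] <- max(S_new[3], 0)
      f_new <- local_F(S_new, params, w$g_EI, w$g_II, I_ext)
      if (max(abs(f_new)) < max(abs(f)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    S <- S_new; f <- f_new
  }
  if (max(abs(f)) >= tol)
    stop(sprintf(
      "fixed-point iteration did not converge (branch %s): residual %.3g at S = %s",
      branch, max(abs(f)), paste(signif(S, 5), collapse = ", ")))
  I <- local_currents(S, params, w$g_EI, w$g_II, I_ext)
  list(S = S,
       rates = c(phi_E(I[1], params), phi_E(I[2], params), phi_I(I[3], params)),
       I = I, residual = max(abs(f)), branch = branch)
}

#' Relax the reduced local circuit by forward integration
#'
#' Noise-free forward Euler of the 3D gating system; the independent check
#' that a Newton root is the state the dynamics actually settle into.
#'
#' @inheritParams fixed_point
#' @param S0 initial gating triple.
#' @param t_max integration time (s).
#' @param dt step (s).
#' @return final gating triple.
#' @export
relax_local <- function(params, PV = 0, g_EI = NULL, g_II = NULL,
                        S0 = c(0, 0, 0), I_ext = c(0, 0, 0),
                        t_max = 5, dt = 1e-4) {
  w <- resolve_local_weights(params, PV, g_EI, g_II)
  S <- S0
  for (k in seq_len(round(t_max / dt)))
    S <- S + dt * local_F(S, params, w$g_EI, w$g_II, I_ext)
  S
}

#' Jacobian eigenvalues at a local fixed point
#'
#' Eigenvalues of the analytic 3 x 3 Jacobian, sorted by real part in
#' descending order. The baseline is stable iff all real parts are
#' negative. Fixed points whose inhibitory input lies within `1e-6` nA of
#' the rectification kink are rejected as non-differentiable.
#'
#' @param fp a fixed point from [fixed_point()] (or a gating triple).
#' @inheritParams fixed_point
#' @return complex vector of length 3 (1/s), attribute `stable`.
#' @export
jacobian_eigs <- function(fp, params, PV = 0, g_EI = NULL, g_II = NULL,
                          I_ext = c(0, 0, 0)) {
  S <- if (is.list(fp)) fp$S else fp
  w <- resolve_local_weights(params, PV, g_EI, g_II)
  I_C <- local_currents(S, params, w$g_EI, w$g_II, I_ext)[3]
  if (abs(I_C - phi_I_threshold(params)) < 1e-6)
    stop("fixed point sits at the inhibitory transfer-function kink; ",
         "perturb the parameters away from the non-differentiable point")
  J <- local_jacobian(S, params, PV, w$g_EI, w$g_II, I_ext)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(Re(ev), decreasing = TRUE)]
  attr(ev, "stable") <- all(Re(ev) < 0)
  ev
}

#' Baseline-stability scenario battery
#'
#' The five standard settings probing local vs long-range stabilization:
#' (1) no long-range coupling; (2) no long-range coupling and local
#' inhibition onto excitatory cells removed (`g_EI = 0`); (3) intact
#' network; (4) long-range projections onto inhibitory cells removed
#' (`mu_IE = 0`); (5) local `g_EI = 0` with long-range coupling intact.
#' Scenarios 1-2 are evaluated analytically per isolated area (fixed point +
#' eigenvalues); 3-5 by noise-free simulation with no stimulus, where an
#' area counts as having left baseline if its delay rate exceeds `theta`.
#' Numerical divergence is reported as unstable, not as an error.
#'
#' @param conn a `connectome`.
#' @param params a [model_params()] object.
#' @param scenarios integer subset of 1:5.
#' @param theta rate threshold (Hz) for leaving baseline.
#' @param T_trial simulation length (s) for scenarios 3-5.
#' @return list of per-scenario reports: each with `scenario`, `table`
#'   (data frame of per-area rates and verdicts), `stable` (scalar), and
#'   for 1-2 a matrix `eigenvalues` (areas x 3, real parts).
#' @export
scenario_battery <- function(conn, params, scenarios = 1:5, theta = 5,
                             T_trial = params$T_trial) {
  out <- list()
  areas <- conn$atlas$name
  for (sc in scenarios) {
    if (sc %in% c(1, 2)) {
      p <- params
      if (sc == 2) p$g_EI_0 <- 0
      p$mu_EE <- 0; p$mu_IE <- 0   # isolated areas
      ev <- matrix(NA_real_, length(areas), 3,
                   dimnames = list(areas, paste0("lambda", 1:3)))
      rate <- numeric(length(areas)); stab <- logical(length(areas))
      for (i in seq_along(areas)) {
        fp <- fixed_point(p, PV = conn$PV[[i]], branch = "low")
        e <- jacobian_eigs(fp, p, PV = conn$PV[[i]])
        ev[i, ] <- Re(e)
        rate[i] <- fp$rates[1]
        stab[i] <- attr(e, "stable")
      }
      out[[paste0("scenario", sc)]] <- list(
        scenario = sc,
        table = data.frame(area = areas, rate = rate, stable = stab),
        eigenvalues = ev, stable = all(stab))
    } else {
      p <- params
      if (sc == 4) p$mu_IE <- 0
      if (sc == 5) p$g_EI_0 <- 0
      proto <- wm_protocol(character(), params = p, T_trial = T_trial)
      tr <- tryCatch(
        simulate_network(conn, p, proto, deterministic = TRUE),
        error = function(e) NULL)
      if (is.null(tr)) {
        out[[paste0("scenario", sc)]] <- list(
          scenario = sc,
          table = data.frame(area = areas, rate = NA_real_, high = TRUE),
          stable = FALSE, diverged = TRUE)
      } else {
        dr <- delay_rates(tr)
        out[[paste0("scenario", sc)]] <- list(
          scenario = sc,
          table = data.frame(area = areas, rate = unname(dr),
                             high = unname(dr > theta)),
          stable = all(dr <= theta), diverged = FALSE)
      }
    }
  }
  out
}

#' Does an isolated area sustain stimulus-triggered persistent activity?
#'
#' Integrates a single uncoupled area (noise-free) through the standard
#' trial: burn-in, stimulus to population A during `[T_on, T_off)`, then
#' delay. The area is flagged persistent if the delay-window mean of `r_A`
#' exceeds `theta`.
#'
#' @param params a [model_params()] object.
#' @param PV normalized PV fraction of the area.
#' @param theta persistence threshold (Hz).
#' @param dt integration step (s).
#' @return list with `persistent` (flag) and `delay_rate` (Hz).
#' @export
isolated_persistence <- function(params, PV = 0, theta = 5, dt = 2e-4) {
  w <- resolve_local_weights(params, PV)
  S <- c(0, 0, 0)
  t_grid <- seq(0, params$T_trial, by = dt)
  win <- t_grid >= params$T_trial - 2 & t_grid <= params$T_trial - 0.5
  acc <- 0; n_acc <- 0
  for (k in seq_along(t_grid)) {
    t <- t_grid[k]
    I_ext <- c(if (t >= params$T_on && t < params$T_off) params$I_stim else 0,
               0, 0)
    if (win[k]) {
      I <- local_currents(S, params, w$g_EI, w$g_II, I_ext)
      acc <- acc + phi_E(I[1], params); n_acc <- n_acc + 1
    }
    S <- S + dt * local_F(S, params, w$g_EI, w$g_II, I_ext)
  }
  rate <- acc / n_acc
  list(persistent = rate > theta, delay_rate = rate)
}

#' Sweep the local-inhibition parameter plane
#'
#' For every grid cell `(g_EI_0, g_EI_scaling)` runs a no-stimulus trial
#' (baseline stable iff no area leaves baseline) and a stimulated trial
#' (persistent-area count at `theta`), noise-free. `condition` selects the
#' gradient-removal controls: `"pv_mean"` replaces the PV gradient by its
#' mean, `"cib_mean"` replaces the CIB coefficient by 0.5.
#'
#' @param conn a `connectome`.
#' @param g_EI0_grid,scaling_grid numeric grids (nA / unitless).
#' @param condition `"default"`, `"pv_mean"` or `"cib_mean"`.
#' @param params a [model_params()] object.
#' @param stim_area stimulated area (default: lowest-hierarchy area, the
#'   primary-sensory analogue).
#' @param theta persistence threshold (Hz).
#' @param T_trial trial length (s); shorter values speed up coarse scans.
#' @return list of matrices `count` (persistent areas) and `baseline_stable`
#'   (logical), rows `g_EI0_grid` x cols `scaling_grid`.
#' @export
gradient_sweep <- function(conn, g_EI0_grid, scaling_grid,
                           condition = c("default", "pv_mean", "cib_mean"),
                           params = model_params(),
                           stim_area = NULL, theta = 5,
                           T_trial = params$T_trial) {
  condition <- match.arg(condition)
  stopifnot(length(g_EI0_grid) > 0, length(scaling_grid) > 0)
  if (is.null(stim_area)) stim_area <- conn$atlas$name[which.min(conn$h)]
  count <- matrix(NA_integer_, length(g_EI0_grid), length(scaling_grid),
                  dimnames = list(g_EI0_grid, scaling_grid))
  stable <- matrix(NA, length(g_EI0_grid), length(scaling_grid),
                   dimnames = list(g_EI0_grid, scaling_grid))
  sim_cond <- if (condition == "default") "default" else condition
  for (i in seq_along(g_EI0_grid)) for (j in seq_along(scaling_grid)) {
    p <- params
    p$g_EI_0 <- g_EI0_grid[i]
    p$g_EI_scaling <- scaling_grid[j]
    base <- tryCatch(simulate_network(
      conn, p, wm_protocol(character(), params = p, T_trial = T_trial),
      deterministic = TRUE, condition = sim_cond), error = function(e) NULL)
    stable[i, j] <- !is.null(base) && all(delay_rates(base) <= theta)
    stim <- tryCatch(simulate_network(
      conn, p, wm_protocol(stim_area, params = p, T_trial = T_trial),
      deterministic = TRUE, condition = sim_cond), error = function(e) NULL)
    count[i, j] <- if (is.null(stim)) NA_integer_
                   else sum(persistent_areas(delay_rates(stim), theta))
  }
  list(count = count, baseline_stable = stable,
       condition = condition, stim_area = stim_area)
}

#' Saddle-node scan of the low-activity fixed point
#'
#' Scans `g_EI_0` downward and reports the largest value at which the
#' low-activity fixed point ceases to exist: the Newton solve from the low
#' guess fails (or lands on a high-rate state) *and* relaxation from the
#' origin escapes above `theta`. The boundary is refined by bisection to
#' `tol` nA. Returns `NA` when no bifurcation occurs in the range.
#'
#' @param params a [model_params()] object.
#' @param PV normalized PV fraction of the area.
#' @param g_EI0_range numeric length-2 range to scan (nA).
#' @param theta rate threshold (Hz) distinguishing low from high states.
#' @param tol bisection tolerance (nA).
#' @return critical `g_EI_0` (nA) or `NA`.
#' @export
bifurcation_scan <- function(params, PV = 0, g_EI0_range = c(0, 0.5),
                             theta = 5, tol = 1e-4) {
  low_exists <- function(gEI0) {
    p <- params
    p$g_EI_0 <- gEI0
    fp <- tryCatch(fixed_point(p, PV = PV, branch = "low"),
                   error = function(e) NULL)
    if (is.null(fp) || fp$rates[1] > theta) return(FALSE)
    S_end <- relax_local(p, PV = PV, t_max = 3)
    w <- resolve_local_weights(p, PV)
    r_end <- phi_E(local_currents(S_end, p, w$g_EI, w$g_II)[1], p)
    r_end <= theta
  }
  hi <- max(g_EI0_range); lo <- min(g_EI0_range)
  if (!low_exists(hi))
    return(hi)   # already gone at the top of the range
  if (low_exists(lo))
    return(NA_real_)  # low state survives the whole range: no saddle-node
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    if (low_exists(mid)) hi <- mid else lo <- mid
  }
  (hi + lo) / 2
}
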