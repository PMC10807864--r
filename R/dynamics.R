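#' Excitatory transfer function
#'
#' Steady-state firing rate of an excitatory population given its total input
#' current: `phi(I) = (a I - b) / (1 - exp(-d (a I - b)))`. The removable
#' singularity at `a I = b` evaluates to `1/d`; the function is smooth,
#' strictly increasing and positive for all finite input. Vectorized over `I`.
#'
#' @param I input current (nA), any length.
#' @param params a [model_params()] object.
#' @return firing rate (Hz).
#' @export
phi_E <- function(I, params) {
  u <- params$a * I - params$b
  x <- params$d * u
  out <- u / (1 - exp(-x))
  small <- abs(x) < 1e-7
  if (any(small)) out[small] <- 1 / params$d + u[small] / 2
  out
}

# dphi_E/dI, analytic; smooth limit a/2 at the singularity.
phi_E_deriv <- function(I, params) {
  u <- params$a * I - params$b
  x <- params$d * u
  ex <- exp(-x)
  denom <- (1 - ex)
  out <- params$a * (denom - u * params$d * ex) / denom^2
  small <- abs(x) < 1e-6
  if (any(small)) out[small] <- params$a * (0.5 + x[small] / 6)
  out
}

#' Inhibitory transfer function
#'
#' Rectified-linear steady-state rate of the inhibitory population:
#' `phi(I) = max(0, (c1 I - c0)/g_I + r0_I)`, slope `c1/g_I` above the
#' rectification threshold. Vectorized over `I`.
#'
#' @inheritParams phi_E
#' @return firing rate (Hz).
#' @export
phi_I <- function(I, params) {
  pmax(0, (params$c1 * I - params$c0) / params$g_I + params$r0_I)
}

# dphi_I/dI: c1/g_I on the active branch, 0 below threshold.
phi_I_deriv <- function(I, params) {
  active <- (params$c1 * I - params$c0) / params$g_I + params$r0_I > 0
  ifelse(active, params$c1 / params$g_I, 0)
}

# Input current at which phi_I leaves rectification.
phi_I_threshold <- function(params) {
  (params$c0 - params$g_I * params$r0_I) / params$c1
}

#' PV-scaled local inhibitory weights
#'
#' Local inhibition onto excitatory (`g_EI`) and inhibitory (`g_II`) cells
#' grows linearly with the normalized PV fraction of the area:
#' `g_EI_i = g_EI_0 (1 + g_EI_scaling PV_i)` and likewise for `g_II`.
#' `mode = "mean"` replaces every area's PV value by the cortical mean, the
#' gradient-removal control.
#'
#' @param PV normalized PV fraction per area, in `[0, 1]`.
#' @param params a [model_params()] object.
#' @param mode `"gradient"` (default) or `"mean"`.
#' @return list with numeric vectors `g_EI` and `g_II` (nA).
#' @export
local_inhibitory_weights <- function(PV, params,
                                     mode = c("gradient", "mean")) {
  mode <- match.arg(mode)
  if (any(PV < -1e-12 | PV > 1 + 1e-12)) stop("PV must lie in [0, 1]")
  if (mode == "mean") PV <- rep(mean(PV), length(PV))
  list(g_EI = params$g_EI_0 * (1 + params$g_EI_scaling * PV),
       g_II = params$g_II_0 * (1 + params$g_II_scaling * PV))
}

#' Total input currents of the three local populations
#'
#' Sums recurrent, background, long-range, noise and external currents for
#' the two excitatory populations (A, B) and the inhibitory population (C)
#' of each area. Inhibitory gating enters subtractively. All arguments are
#' vectors over areas (or scalars); returns per-population current vectors.
#'
#' @param S_A,S_B,S_C synaptic gating vectors.
#' @param g_EI,g_II PV-scaled local inhibitory weights (vectors, nA).
#' @param params a [model_params()] object.
#' @param I_LR list with long-range currents `I_A`, `I_B`, `I_C` (default 0).
#' @param I_ext list with external currents `I_A`, `I_B`, `I_C` (default 0).
#' @param x list with noise currents `x_A`, `x_B`, `x_C` (default 0).
#' @return list with current vectors `I_A`, `I_B`, `I_C` (nA).
#' @export
total_currents <- function(S_A, S_B, S_C, g_EI, g_II, params,
                           I_LR = list(I_A = 0, I_B = 0, I_C = 0),
                           I_ext = list(I_A = 0, I_B = 0, I_C = 0),
                           x = list(x_A = 0, x_B = 0, x_C = 0)) {
  list(
    I_A = params$g_E_self * S_A + params$g_E_cross * S_B - g_EI * S_C +
      params$I0_A + I_LR$I_A + x$x_A + I_ext$I_A,
    I_B = params$g_E_self * S_B + params$g_E_cross * S_A - g_EI * S_C +
      params$I0_B + I_LR$I_B + x$x_B + I_ext$I_B,
    I_C = params$g_IE * (S_A + S_B) - g_II * S_C +
      params$I0_C + I_LR$I_C + x$x_C + I_ext$I_C
  )
}

#' Synaptic gating derivatives
#'
#' NMDA gating of the excitatory populations saturates at 1
#' (`dS = -S/tau_N + gamma (1 - S) r`); GABA gating of the inhibitory
#' population integrates linearly (`dS = -S/tau_G + gamma_I r`).
#'
#' @param S_A,S_B,S_C gating vectors.
#' @param r_A,r_B,r_C rate vectors (Hz), nonnegative.
#' @param params a [model_params()] object.
#' @return list of derivatives (per second).
#' @export
synapse_derivatives <- function(S_A, S_B, S_C, r_A, r_B, r_C, params) {
  list(
    dS_A = -S_A / params$tau_N + params$gamma * (1 - S_A) * r_A,
    dS_B = -S_B / params$tau_N + params$gamma * (1 - S_B) * r_B,
    dS_C = -S_C / params$tau_G + params$gamma_I * r_C
  )
}

#' Firing-rate relaxation derivatives
#'
#' Rates relax toward the transfer function of the instantaneous current
#' with time constant `tau_r`: `dr = (-r + phi(I)) / tau_r`.
#'
#' @param r_A,r_B,r_C rate vectors (Hz).
#' @param I list of currents from [total_currents()].
#' @param params a [model_params()] object.
#' @return list of derivatives (Hz per second).
#' @export
rate_relaxation <- function(r_A, r_B, r_C, I, params) {
  list(
    dr_A = (-r_A + phi_E(I$I_A, params)) / params$tau_r,
    dr_B = (-r_B + phi_E(I$I_B, params)) / params$tau_r,
    dr_C = (-r_C + phi_I(I$I_C, params)) / params$tau_r
  )
}

#' One Euler-Maruyama step of the Ornstein-Uhlenbeck noise current
#'
#' `x <- x + (-x / tau_noise) dt + sigma sqrt(dt) N(0, 1)`. With
#' `sigma = 0` the current decays deterministically as `exp(-t/tau_noise)`.
#' The stationary standard deviation is `sigma * sqrt(tau_noise / 2)`.
#' Draws come from the session RNG; seed the caller for reproducibility.
#'
#' @param x current noise value(s) (nA).
#' @param dt time step (s), must be smaller than `tau_noise`.
#' @param sigma noise amplitude (nA), scalar or vector like `x`.
#' @param params a [model_params()] object (supplies `tau_noise`).
#' @return updated noise value(s).
#' @export
ou_step <- function(x, dt, sigma, params) {
  stopifnot(dt < params$tau_noise)
  x + (-x / params$tau_noise) * dt +
    sigma * sqrt(dt) * stats::rnorm(length(x))
}

#' Simulate an Ornstein-Uhlenbeck path
#'
#' Convenience wrapper iterating [ou_step()] from `x0`; used for calibration
#' checks of the stationary noise statistics.
#'
#' @param n_steps number of steps.
#' @param dt time step (s).
#' @param sigma noise amplitude (nA).
#' @param params a [model_params()] object.
#' @param x0 initial value.
#' @return numeric vector of length `n_steps + 1`.
#' @export
ou_path <- function(n_steps, dt, sigma, params, x0 = 0) {
  stopifnot(dt < params$tau_noise)
  # AR(1) recursion of the Euler-Maruyama scheme, identical draws to ou_step
  eps <- sigma * sqrt(dt) * stats::rnorm(n_steps)
  a <- 1 - dt / params$tau_noise
  x <- numeric(n_steps + 1)
  x[1] <- x0
  for (k in seq_len(n_steps)) x[k + 1] <- a * x[k] + eps[k]
  x
}
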