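#' Model parameters for the multiregional working-memory network
#'
#' Builds the full parameter set of the mean-field model in internal units
#' (seconds, nA, Hz). Source tables quote some values in ms and pA; they
#' are converted here once so the dynamics code never mixes units. The
#' excitatory transfer-function time parameter `d` enters as 0.308 s for
#' dimensional consistency with `a * I` in Hz.
#'
#' Three named regimes are provided:
#' \describe{
#'   \item{`reference`}{no isolated area sustains persistent activity;
#'     distributed memory relies on long-range loops
#'     (`g_E_self = 0.4`, `g_EI_0 = 0.192`, `mu_EE = 0.1`, `mu_IE = 0.167` nA).}
#'   \item{`alternative`}{stronger local recurrence balanced by stronger local
#'     inhibition, so a subset of areas is bistable in isolation
#'     (`g_E_self = 0.6`, `g_EI_0 = 0.5`, `mu_EE = 0.19` nA).}
#'   \item{`thalamocortical`}{cortical long-range coupling weakened tenfold and
#'     thalamocortical conductances enabled (`mu_EE = 0.01`, `mu_IE = 0.0167`,
#'     `g_ct = 0.32`, `g_E_tc = 0.6`, `g_I_tc = 1.38` nA).}
#' }
#'
#' @param regime character; one of `"reference"`, `"alternative"`,
#'   `"thalamocortical"`.
#' @param ... named overrides of individual parameters (internal units).
#' @return an object of class `distwm_params` (a named list).
#' @examples
#' p <- model_params()
#' p$g_EI_0
#' model_params("alternative", mu_EE = 0.02)$mu_EE
#' @export
model_params <- function(regime = c("reference", "alternative", "thalamocortical"),
                         ...) {
  regime <- match.arg(regime)
  p <- list(
    # time constants (s)
    tau_N = 0.060, tau_G = 0.005, tau_A = 0.002, tau_r = 0.002,
    tau_noise = 0.002,
    # excitatory transfer function (Hz/nA, Hz, s)
    a = 140, b = 54, d = 0.308,
    # inhibitory transfer function
    g_I = 4, c1 = 615, c0 = 177, r0_I = 5.5,
    r0_E = 5,                      # documentation-only; state starts at zero
    # synaptic scaling
    gamma = 1.282, gamma_I = 2, gamma_A = 2,
    # local conductance-like weights (nA)
    g_E_self = 0.4, g_E_cross = 0.0107, g_IE = 0.2656,
    g_EI_0 = 0.192, g_EI_scaling = 0.83,
    g_II_0 = 0.105, g_II_scaling = 0.714,
    # background currents (nA)
    I0_A = 0.305, I0_B = 0.305, I0_C = 0.26,
    # noise amplitudes (nA)
    sigma_A = 0.005, sigma_B = 0.005, sigma_C = 0,
    # long-range coupling (nA)
    mu_EE = 0.1, mu_IE = 0.167,
    # connectivity shaping
    beta = 2.42, k_scale = 0.3, alpha_h = 1.33, beta_h = -0.22,
    # protocol defaults
    I_stim = 0.5, I_inh = 5,
    T_on = 2, T_off = 2.5, T_trial = 10, dt = 5e-4,
    # thalamocortical block (nA); I_th_0 calibrated so the isolated thalamic
    # baseline rate stays below 5 Hz (the reticular-nucleus current is folded
    # into this constant)
    g_ct = 0.32, g_E_tc = 0.6, g_I_tc = 1.38, I_th_0 = 0.3,
    regime = regime
  )
  if (regime == "alternative") {
    p$g_E_self <- 0.6
    p$g_EI_0 <- 0.5
    p$mu_EE <- 0.19
  } else if (regime == "thalamocortical") {
    p$mu_EE <- 0.01
    p$mu_IE <- 0.0167
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  stopifnot(p$tau_N > 0, p$tau_G > 0, p$tau_r > 0, p$tau_noise > 0,
            p$dt > 0, p$dt < min(p$tau_N, p$tau_G, p$tau_r, p$tau_noise))
  class(p) <- "distwm_params"
  p
}

#' @export
print.distwm_params <- function(x, ...) {
  cat("<distwm_params> regime:", x$regime, "\n")
  cat(sprintf("  g_E_self=%g g_EI_0=%g g_EI_scaling=%g mu_EE=%g mu_IE=%g nA\n",
              x$g_E_self, x$g_EI_0, x$g_EI_scaling, x$mu_EE, x$mu_IE))
  cat(sprintf("  dt=%g s, T_trial=%g s, stimulus [%g, %g) s at %g nA\n",
              x$dt, x$T_trial, x$T_on, x$T_off, x$I_stim))
  invisible(x)
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
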