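#' Stimulation / inhibition protocol
#'
#' Describes one trial: which excitatory populations receive the sensory
#' stimulus during `[T_on, T_off)`, any simulated-optogenetics inhibition
#' events, trial length, step size and RNG seed. Inhibition events are lists
#' with fields `areas` (names), `phase` (`"stimulus"` or `"delay"`),
#' `current` (nA) and `pop` (`"C"` for the cortical inhibitory population;
#' thalamic events target both excitatory populations, see
#' [simulate_tc()]). Delay-phase inhibition starts 2 s after stimulus offset
#' and lasts to the end of the trial.
#'
#' @param stim_areas character vector of stimulated areas (may be empty).
#' @param stim_pop stimulated population, `"A"` (default) or `"B"`.
#' @param params a [model_params()] supplying the timing defaults.
#' @param I_stim,T_on,T_off,T_trial,dt protocol scalars (nA / s).
#' @param inhibition list of inhibition events (see above).
#' @param seed integer RNG seed for the noise process.
#' @return an object of class `wm_protocol`.
#' @export
wm_protocol <- function(stim_areas = character(), stim_pop = "A",
                        params = model_params(),
                        I_stim = params$I_stim, T_on = params$T_on,
                        T_off = params$T_off, T_trial = params$T_trial,
                        dt = params$dt, inhibition = list(), seed = 1L) {
  stopifnot(T_on >= 0, T_on < T_off, T_off <= T_trial, dt > 0,
            stim_pop %in% c("A", "B"))
  structure(list(stim_areas = stim_areas, stim_pop = stim_pop,
                 I_stim = I_stim, T_on = T_on, T_off = T_off,
                 T_trial = T_trial, dt = dt, inhibition = inhibition,
                 seed = as.integer(seed)),
            class = "wm_protocol")
}

#' Long-range currents from the network state
#'
#' Selectivity-preserving excitation onto the matching excitatory population
#' (`I_A_i = mu_EE sum_j W_E[i, j] S_A_j`, likewise B) and pooled drive onto
#' the inhibitory population
#' (`I_C_i = mu_IE sum_j W_I[i, j] (S_A_j + S_B_j)`).
#'
#' @param S_A,S_B gating vectors of all source areas.
#' @param W_E,W_I CIB-split connectivity (target-by-source).
#' @param mu_EE,mu_IE long-range coupling strengths (nA).
#' @return list with current vectors `I_A`, `I_B`, `I_C`.
#' @export
long_range_currents <- function(S_A, S_B, W_E, W_I, mu_EE, mu_IE) {
  stopifnot(ncol(W_E) == length(S_A), ncol(W_I) == length(S_A))
  list(I_A = as.vector(mu_EE * (W_E %*% S_A)),
       I_B = as.vector(mu_EE * (W_E %*% S_B)),
       I_C = as.vector(mu_IE * (W_I %*% (S_A + S_B))))
}

# Resolve a zeroed state list for n areas (all gating, rates, noise at 0).
blank_state <- function(n) {
  z <- numeric(n)
  list(S_A = z, S_B = z, S_C = z, r_A = z, r_B = z, r_C = z,
       x_A = z, x_B = z, x_C = z)
}

# Per-event time window [start, end): stimulus phase shares the stimulus
# window; delay phase starts 2 s after stimulus offset.
inhibition_window <- function(event, protocol) {
  if (!is.null(event$window)) return(event$window)
  phase <- match.arg(event$phase, c("stimulus", "delay"))
  if (phase == "stimulus") c(protocol$T_on, protocol$T_off)
  else c(protocol$T_off + 2, protocol$T_trial)
}

#' Simulate the multiregional cortical network
#'
#' Forward Euler-Maruyama integration of the coupled mean-field equations:
#' NMDA/GABA gating, rate relaxation through the population transfer
#' functions, Ornstein-Uhlenbeck noise currents, PV-scaled local inhibition
#' and CIB-split long-range coupling. All state variables start at zero
#' (the pre-stimulus interval serves as burn-in to the baseline state)
#' unless `init` resumes a previous final state.
#'
#' @param conn a `connectome`.
#' @param params a [model_params()] object.
#' @param protocol a [wm_protocol()].
#' @param deterministic if `TRUE`, noise amplitudes are forced to zero.
#' @param condition `"default"`, `"pv_mean"` (PV gradient replaced by its
#'   cortical mean) or `"cib_mean"` (CIB coefficient replaced by 0.5).
#' @param init optional state list (as in `$final_state` of a trajectory).
#' @param record `"rates"` (default) or `"none"` (final state only; sweeps).
#' @return an object of class `wm_trajectory`: `time`, rate matrices
#'   `r_A`, `r_B`, `r_C` (time x areas), `final_state`, `areas`, resolved
#'   `params` and `protocol`, and the observed gating range
#'   `gating_range`.
#' @export
simulate_network <- function(conn, params, protocol,
                             deterministic = FALSE,
                             condition = c("default", "pv_mean", "cib_mean"),
                             init = NULL, record = c("rates", "none")) {
  condition <- match.arg(condition)
  record <- match.arg(record)
  n <- n_areas(conn)
  areas <- conn$atlas$name
  dt <- protocol$dt
  n_steps <- as.integer(round(protocol$T_trial / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1)

  lw <- local_inhibitory_weights(
    conn$PV, params, mode = if (condition == "pv_mean") "mean" else "gradient")
  if (condition == "cib_mean") {
    W_E <- 0.5 * conn$W
    W_I <- 0.5 * conn$W
  } else {
    W_E <- conn$W_E
    W_I <- conn$W_I
  }

  sA <- if (deterministic) 0 else params$sigma_A
  sB <- if (deterministic) 0 else params$sigma_B
  sC <- if (deterministic) 0 else params$sigma_C

  # external current masks
  stim_idx <- match(protocol$stim_areas, areas)
  if (anyNA(stim_idx)) stop("unknown stimulated area(s): ",
                            paste(protocol$stim_areas[is.na(stim_idx)],
                                  collapse = ", "))
  inh <- lapply(protocol$inhibition, function(ev) {
    idx <- match(ev$areas, areas)
    if (anyNA(idx)) stop("unknown inhibited area(s): ",
                         paste(ev$areas[is.na(idx)], collapse = ", "))
    list(idx = idx, window = inhibition_window(ev, protocol),
         current = if (is.null(ev$current)) params$I_inh else ev$current,
         pop = if (is.null(ev$pop)) "C" else ev$pop)
  })

  st <- if (is.null(init)) blank_state(n) else init
  keep <- record == "rates"
  if (keep) {
    R_A <- matrix(NA_real_, n_steps + 1, n, dimnames = list(NULL, areas))
    R_B <- R_A; R_C <- R_A
    R_A[1, ] <- st$r_A; R_B[1, ] <- st$r_B; R_C[1, ] <- st$r_C
  }
  g_lo <- Inf; g_hi <- -Inf

  seeded <- !deterministic
  if (seeded) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
    set.seed(protocol$seed)
    on.exit({
      if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
  }
  decay <- 1 - dt / params$tau_noise
  for (k in seq_len(n_steps)) {
    t <- times[k]
    I_ext_A <- numeric(n); I_ext_B <- numeric(n); I_ext_C <- numeric(n)
    if (length(stim_idx) && t >= protocol$T_on && t < protocol$T_off) {
      if (protocol$stim_pop == "A") I_ext_A[stim_idx] <- protocol$I_stim
      else I_ext_B[stim_idx] <- protocol$I_stim
    }
    for (ev in inh) {
      if (t >= ev$window[1] && t < ev$window[2]) {
        if (ev$pop == "C") I_ext_C[ev$idx] <- I_ext_C[ev$idx] + ev$current
        else if (ev$pop == "A") I_ext_A[ev$idx] <- I_ext_A[ev$idx] + ev$current
        else I_ext_B[ev$idx] <- I_ext_B[ev$idx] + ev$current
      }
    }
    I_LR <- long_range_currents(st$S_A, st$S_B, W_E, W_I,
                                params$mu_EE, params$mu_IE)
    I <- total_currents(st$S_A, st$S_B, st$S_C, lw$g_EI, lw$g_II, params,
                        I_LR = I_LR,
                        I_ext = list(I_A = I_ext_A, I_B = I_ext_B,
                                     I_C = I_ext_C),
                        x = list(x_A = st$x_A, x_B = st$x_B, x_C = st$x_C))
    dr <- rate_relaxation(st$r_A, st$r_B, st$r_C, I, params)
    dS <- synapse_derivatives(st$S_A, st$S_B, st$S_C,
                              st$r_A, st$r_B, st$r_C, params)
    st$S_A <- st$S_A + dt * dS$dS_A
    st$S_B <- st$S_B + dt * dS$dS_B
    st$S_C <- st$S_C + dt * dS$dS_C
    st$r_A <- st$r_A + dt * dr$dr_A
    st$r_B <- st$r_B + dt * dr$dr_B
    st$r_C <- st$r_C + dt * dr$dr_C
    if (deterministic) {
      st$x_A <- st$x_A * decay
      st$x_B <- st$x_B * decay
      st$x_C <- st$x_C * decay
    } else {
      st$x_A <- ou_step(st$x_A, dt, sA, params)
      st$x_B <- ou_step(st$x_B, dt, sB, params)
      st$x_C <- ou_step(st$x_C, dt, sC, params)
    }
    g_lo <- min(g_lo, st$S_A, st$S_B)
    g_hi <- max(g_hi, st$S_A, st$S_B)
    if (!all(is.finite(st$r_A)) || !all(is.finite(st$S_A)))
      stop("non-finite state at step ", k, " (t = ", times[k + 1], " s)")
    if (keep) {
      R_A[k + 1, ] <- st$r_A
      R_B[k + 1, ] <- st$r_B
      R_C[k + 1, ] <- st$r_C
    }
  }

  structure(list(
    time = times,
    r_A = if (keep) R_A else NULL,
    r_B = if (keep) R_B else NULL,
    r_C = if (keep) R_C else NULL,
    areas = areas, final_state = st,
    gating_range = c(min = g_lo, max = g_hi),
    params = params, protocol = protocol, condition = condition
  ), class = "wm_trajectory")
}

#' @export
print.wm_trajectory <- function(x, ...) {
  cat("<wm_trajectory>", length(x$areas), "areas,",
      length(x$time) - 1, "steps of", x$protocol$dt, "s\n")
  if (!is.null(x$r_A)) {
    dr <- delay_rates(x)
    cat("  persistent areas (A > 5 Hz):", sum(dr > 5), "\n")
  }
  invisible(x)
}

#' Mean delay-period firing rate per area
#'
#' Time-average of the chosen population's rate over the window from 2 s
#' before trial end to 0.5 s before trial end, the interval on which every
#' persistence measure in the package is computed.
#'
#' @param traj a `wm_trajectory` with recorded rates.
#' @param population `"A"` (default, the stimulated selectivity), `"B"` or
#'   `"C"`.
#' @return named numeric vector of rates (Hz).
#' @export
delay_rates <- function(traj, population = c("A", "B", "C")) {
  population <- match.arg(population)
  R <- traj[[paste0("r_", population)]]
  if (is.null(R)) stop("trajectory was run with record = 'none'")
  Tt <- traj$protocol$T_trial
  if (Tt - traj$protocol$T_off < 2)
    stop("delay window [T_trial - 2, T_trial - 0.5] lies outside the delay")
  sel <- traj$time >= Tt - 2 - 1e-9 & traj$time <= Tt - 0.5 + 1e-9
  colMeans(R[sel, , drop = FALSE])
}

#' Flag areas with persistent delay activity
#'
#' An area is persistent iff its delay rate strictly exceeds the threshold
#' (default 5 Hz, the census threshold used throughout).
#'
#' @param rates named vector of delay rates (Hz).
#' @param theta threshold (Hz), must be positive.
#' @return logical vector.
#' @export
persistent_areas <- function(rates, theta = 5) {
  stopifnot(theta > 0)
  rates > theta
}

#' Pearson correlation between delay rates and a structural covariate
#'
#' Restricted to an optional subset (typically the persistent areas);
#' reports the coefficient and the two-sided p-value.
#'
#' @param rates numeric vector.
#' @param covariate numeric vector, same length.
#' @param subset optional logical vector selecting the points used.
#' @return list with elements `r`, `p`, `n`.
#' @export
correlate_measure <- function(rates, covariate, subset = NULL) {
  stopifnot(length(rates) == length(covariate))
  if (is.null(subset)) subset <- rep(TRUE, length(rates))
  x <- rates[subset]; y <- covariate[subset]
  if (length(x) < 3) stop("need at least 3 points in the subset")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in rates or covariate over the subset")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
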