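#' Thalamocortical connectivity matrices
#'
#' Builds the corticothalamic (cortex -> thalamus) and thalamocortical
#' (thalamus -> cortex) weight blocks: each raw block is power-rescaled and
#' max-normalized like the cortical matrix (but without the volume/density
#' normalization, which is skipped for thalamic data), then split by the CIB
#' coefficient computed from the hierarchy difference between target and
#' source. Thalamic hierarchy scores must already be normalized with the
#' *cortical* bounds, so they are comparable to `h` (and may lie outside
#' `[0, 1]`). The inhibitory-targeting part of the corticothalamic block,
#' `W_ct_I`, is computed for completeness but unused by the dynamics: the
#' modelled thalamus has no inhibitory population.
#'
#' @param W_ct_raw raw cortex-to-thalamus weights (thalamic targets x
#'   cortical sources).
#' @param W_tc_raw raw thalamus-to-cortex weights (cortical targets x
#'   thalamic sources).
#' @param h normalized cortical hierarchy vector.
#' @param h_th thalamic hierarchy vector on the cortical scale.
#' @param beta CIB sigmoid steepness.
#' @param k_scale rescaling exponent.
#' @return list with `W_ct`, `W_ct_E`, `W_ct_I`, `W_tc`, `W_tc_E`,
#'   `W_tc_I`, `m_ct`, `m_tc`, `h_th`.
#' @export
tc_matrices <- function(W_ct_raw, W_tc_raw, h, h_th, beta = 2.42,
                        k_scale = 0.3) {
  stopifnot(nrow(W_ct_raw) == length(h_th), ncol(W_ct_raw) == length(h),
            nrow(W_tc_raw) == length(h), ncol(W_tc_raw) == length(h_th))
  if (length(W_ct_raw) == 0 || length(W_tc_raw) == 0)
    stop("empty thalamocortical matrices")
  rescale <- function(Wr) {
    W <- Wr^k_scale
    m <- max(W)
    if (m <= 0) stop("all-zero thalamocortical block")
    W / m
  }
  W_ct <- rescale(W_ct_raw)
  W_tc <- rescale(W_tc_raw)
  m_ct <- 1 / (1 + exp(-beta * outer(h_th, h, `-`)))
  m_tc <- 1 / (1 + exp(-beta * outer(h, h_th, `-`)))
  list(W_ct = W_ct, W_ct_E = m_ct * W_ct, W_ct_I = (1 - m_ct) * W_ct,
       W_tc = W_tc, W_tc_E = m_tc * W_tc, W_tc_I = (1 - m_tc) * W_tc,
       m_ct = m_ct, m_tc = m_tc, h_th = h_th)
}

#' One forward-Euler step of the thalamic populations
#'
#' The thalamus is purely excitatory and non-recurrent: each area holds two
#' selective populations with AMPA gating. Rates relax to the excitatory
#' transfer function of the corticothalamic input plus background; gating
#' integrates `dS = -S/tau_A + gamma_A r` (unbounded in `r`, unlike NMDA).
#'
#' @param state list with vectors `S_A`, `S_B`, `r_A`, `r_B`.
#' @param I_A,I_B total input currents per thalamic area (nA).
#' @param params a [model_params()] object.
#' @param dt step (s).
#' @return updated state list.
#' @export
thalamic_step <- function(state, I_A, I_B, params, dt) {
  r_A <- state$r_A + dt * (-state$r_A + phi_E(I_A, params)) / params$tau_r
  r_B <- state$r_B + dt * (-state$r_B + phi_E(I_B, params)) / params$tau_r
  S_A <- state$S_A + dt * (-state$S_A / params$tau_A +
                             params$gamma_A * state$r_A)
  S_B <- state$S_B + dt * (-state$S_B / params$tau_A +
                             params$gamma_A * state$r_B)
  list(S_A = S_A, S_B = S_B, r_A = r_A, r_B = r_B)
}

#' Simulate the thalamocortical network
#'
#' Extends [simulate_network()] with thalamic areas: cortical populations
#' additionally receive `I_tc_A_i = g_E_tc sum_j W_tc_E[i, j] S_th_A_j`
#' (selectivity-preserving, likewise B) and
#' `I_tc_C_i = g_I_tc sum_j W_tc_I[i, j] (S_th_A_j + S_th_B_j)`; thalamic
#' populations receive `g_ct sum_j W_ct_E[i, j] S_pop_j` from the cortex
#' plus the constant background `I_th_0` (the reticular-nucleus inhibition
#' folded in). There are no thalamo-thalamic connections and no thalamic
#' noise. Inhibition events whose areas are thalamic inject a
#' *hyperpolarizing* (negative) current into both thalamic excitatory
#' populations.
#'
#' @param conn a `connectome` (cortical part).
#' @param tc thalamocortical matrices from [tc_matrices()].
#' @param params a [model_params()] object (typically regime
#'   `"thalamocortical"`).
#' @param protocol a [wm_protocol()]; stimulus targets are cortical.
#' @param thalamic_areas character names of the thalamic areas (defaults to
#'   rownames of `tc$W_ct`).
#' @param deterministic noise off.
#' @return a `wm_trajectory` with extra elements `r_th_A`, `r_th_B`
#'   (time x thalamic areas) and `thalamic_areas`.
#' @export
simulate_tc <- function(conn, tc, params, protocol,
                        thalamic_areas = NULL, deterministic = FALSE) {
  n <- n_areas(conn)
  nt <- nrow(tc$W_ct)
  areas <- conn$atlas$name
  if (is.null(thalamic_areas))
    thalamic_areas <- rownames(tc$W_ct) %||% sprintf("T%02d", seq_len(nt))
  dt <- protocol$dt
  n_steps <- as.integer(round(protocol$T_trial / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1)
  lw <- local_inhibitory_weights(conn$PV, params)

  stim_idx <- match(protocol$stim_areas, areas)
  if (anyNA(stim_idx)) stop("unknown stimulated area(s)")
  inh <- lapply(protocol$inhibition, function(ev) {
    th <- all(ev$areas %in% thalamic_areas)
    idx <- if (th) match(ev$areas, thalamic_areas) else match(ev$areas, areas)
    if (anyNA(idx)) stop("unknown inhibited area(s): ",
                         paste(ev$areas, collapse = ", "))
    list(idx = idx, thalamic = th,
         window = inhibition_window(ev, protocol),
         current = if (is.null(ev$current)) params$I_inh else ev$current,
         pop = if (is.null(ev$pop)) "C" else ev$pop)
  })

  st <- blank_state(n)
  th <- list(S_A = numeric(nt), S_B = numeric(nt),
             r_A = numeric(nt), r_B = numeric(nt))
  R_A <- matrix(NA_real_, n_steps + 1, n, dimnames = list(NULL, areas))
  R_B <- R_A; R_C <- R_A
  Rth_A <- matrix(NA_real_, n_steps + 1, nt,
                  dimnames = list(NULL, thalamic_areas))
  Rth_B <- Rth_A
  R_A[1, ] <- 0; R_B[1, ] <- 0; R_C[1, ] <- 0
  Rth_A[1, ] <- 0; Rth_B[1, ] <- 0
  g_lo <- Inf; g_hi <- -Inf

  sA <- if (deterministic) 0 else params$sigma_A
  sB <- if (deterministic) 0 else params$sigma_B
  sC <- if (deterministic) 0 else params$sigma_C
  if (!deterministic) {
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
    I_ext_th_A <- numeric(nt); I_ext_th_B <- numeric(nt)
    if (length(stim_idx) && t >= protocol$T_on && t < protocol$T_off) {
      if (protocol$stim_pop == "A") I_ext_A[stim_idx] <- protocol$I_stim
      else I_ext_B[stim_idx] <- protocol$I_stim
    }
    for (ev in inh) {
      if (t >= ev$window[1] && t < ev$window[2]) {
        if (ev$thalamic) {
          # hyperpolarize both excitatory thalamic populations
          I_ext_th_A[ev$idx] <- I_ext_th_A[ev$idx] - ev$current
          I_ext_th_B[ev$idx] <- I_ext_th_B[ev$idx] - ev$current
        } else if (ev$pop == "C") {
          I_ext_C[ev$idx] <- I_ext_C[ev$idx] + ev$current
        } else if (ev$pop == "A") {
          I_ext_A[ev$idx] <- I_ext_A[ev$idx] + ev$current
        } else {
          I_ext_B[ev$idx] <- I_ext_B[ev$idx] + ev$current
        }
      }
    }
    I_LR <- long_range_currents(st$S_A, st$S_B, conn$W_E, conn$W_I,
                                params$mu_EE, params$mu_IE)
    I_tc <- list(
      I_A = as.vector(params$g_E_tc * (tc$W_tc_E %*% th$S_A)),
      I_B = as.vector(params$g_E_tc * (tc$W_tc_E %*% th$S_B)),
      I_C = as.vector(params$g_I_tc * (tc$W_tc_I %*% (th$S_A + th$S_B))))
    I <- total_currents(st$S_A, st$S_B, st$S_C, lw$g_EI, lw$g_II, params,
                        I_LR = list(I_A = I_LR$I_A + I_tc$I_A,
                                    I_B = I_LR$I_B + I_tc$I_B,
                                    I_C = I_LR$I_C + I_tc$I_C),
                        I_ext = list(I_A = I_ext_A, I_B = I_ext_B,
                                     I_C = I_ext_C),
                        x = list(x_A = st$x_A, x_B = st$x_B, x_C = st$x_C))
    I_th_A <- as.vector(params$g_ct * (tc$W_ct_E %*% st$S_A)) +
      params$I_th_0 + I_ext_th_A
    I_th_B <- as.vector(params$g_ct * (tc$W_ct_E %*% st$S_B)) +
      params$I_th_0 + I_ext_th_B

    dr <- rate_relaxation(st$r_A, st$r_B, st$r_C, I, params)
    dS <- synapse_derivatives(st$S_A, st$S_B, st$S_C,
                              st$r_A, st$r_B, st$r_C, params)
    th <- thalamic_step(th, I_th_A, I_th_B, params, dt)
    st$S_A <- st$S_A + dt * dS$dS_A
    st$S_B <- st$S_B + dt * dS$dS_B
    st$S_C <- st$S_C + dt * dS$dS_C
    st$r_A <- st$r_A + dt * dr$dr_A
    st$r_B <- st$r_B + dt * dr$dr_B
    st$r_C <- st$r_C + dt * dr$dr_C
    if (deterministic) {
      st$x_A <- st$x_A * decay; st$x_B <- st$x_B * decay
      st$x_C <- st$x_C * decay
    } else {
      st$x_A <- ou_step(st$x_A, dt, sA, params)
      st$x_B <- ou_step(st$x_B, dt, sB, params)
      st$x_C <- ou_step(st$x_C, dt, sC, params)
    }
    g_lo <- min(g_lo, st$S_A, st$S_B)
    g_hi <- max(g_hi, st$S_A, st$S_B)
    if (!all(is.finite(st$r_A)) || !all(is.finite(th$r_A)))
      stop("non-finite state at step ", k)
    R_A[k + 1, ] <- st$r_A; R_B[k + 1, ] <- st$r_B; R_C[k + 1, ] <- st$r_C
    Rth_A[k + 1, ] <- th$r_A; Rth_B[k + 1, ] <- th$r_B
  }

  structure(list(
    time = times, r_A = R_A, r_B = R_B, r_C = R_C,
    r_th_A = Rth_A, r_th_B = Rth_B,
    areas = areas, thalamic_areas = thalamic_areas,
    final_state = c(st, list(th = th)),
    gating_range = c(min = g_lo, max = g_hi),
    params = params, protocol = protocol, condition = "default"
  ), class = "wm_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
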