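# Independent oracles and shared micro-fixtures for the test suite.
# Oracles are deliberately naive (loops, recursion, power iteration) and
# share no code with the implementation paths they check.

# Elementwise volume/density normalization by explicit double loop.
brute_normalize <- function(W_raw, vol, dens) {
  n <- nrow(W_raw)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- W_raw[i, j] * vol[j] / dens[i]
  out
}

# Simple-cycle enumeration by recursion with the minimum vertex first
# (rotations identified; the two orientations of an L >= 3 cycle are
# distinct sequences). W[i, j] is the weight of the edge j -> i.
brute_loop_strength <- function(W, L) {
  n <- nrow(W)
  score <- numeric(n)
  recurse <- function(path, prod) {
    last <- path[length(path)]
    if (length(path) == L) {
      w <- W[path[1], last]          # closing edge last -> start
      if (w != 0) score[path] <<- score[path] + prod * w
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (v > path[1] && !(v %in% path)) {
        w <- W[v, last]              # edge last -> v
        if (w != 0) recurse(c(path, v), prod * w)
      }
    }
  }
  for (s in seq_len(n)) recurse(s, 1)
  score
}

# Power iteration for the Perron vector of a positive matrix.
power_iteration <- function(W, iters = 10000, tol = 1e-14) {
  v <- rep(1, nrow(W))
  for (k in seq_len(iters)) {
    v_new <- as.vector(W %*% v)
    v_new <- v_new / sum(v_new)
    if (max(abs(v_new - v)) < tol) break
    v <- v_new
  }
  v
}

# Finite-difference Jacobian of the reduced local circuit.
fd_local_jacobian <- function(S, params, PV, g_EI = NULL, g_II = NULL,
                              h = 1e-7) {
  lw <- local_inhibitory_weights(PV, params)
  gEI <- if (is.null(g_EI)) lw$g_EI else g_EI
  gII <- if (is.null(g_II)) lw$g_II else g_II
  f <- function(S) {
    I_A <- params$g_E_self * S[1] + params$g_E_cross * S[2] - gEI * S[3] +
      params$I0_A
    I_B <- params$g_E_self * S[2] + params$g_E_cross * S[1] - gEI * S[3] +
      params$I0_B
    I_C <- params$g_IE * (S[1] + S[2]) - gII * S[3] + params$I0_C
    c(-S[1] / params$tau_N + params$gamma * (1 - S[1]) * phi_E(I_A, params),
      -S[2] / params$tau_N + params$gamma * (1 - S[2]) * phi_E(I_B, params),
      -S[3] / params$tau_G + params$gamma_I * phi_I(I_C, params))
  }
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    e <- rep(0, 3); e[j] <- h
    J[, j] <- (f(S + e) - f(S - e)) / (2 * h)
  }
  J
}

# Small synthetic connectome shared by several files (cheap to build).
small_connectome <- function(n = 6, seed = 7) {
  synthetic_connectome(fixture_spec(n_areas = n, seed = seed))
}

# Short protocol for fast simulations: 6 s trial keeps the 1.5 s delay
# averaging window valid (T_off = 2.5 s).
short_protocol <- function(stim, params, ...) {
  wm_protocol(stim, params = params, T_trial = 6, ...)
}

# Four-area functional-role fixture: a sensory input area driving a
# mutually coupled association pair, which in turn drives a readout area
# that projects back only weakly; a reference-regime network where the pair
# sustains activity only jointly.
role_fixture <- function() {
  atlas <- area_atlas(c("IN", "X1", "X2", "RO"), 1, 1,
                      pv_density = c(1, 0, 0.02, 0.1),
                      hierarchy_raw = c(0, 0.8, 0.9, 1))
  W <- matrix(0, 4, 4, dimnames = list(atlas$name, atlas$name))
  W["X1", "IN"] <- 1          # input -> core pair
  W["X2", "IN"] <- 0.8
  W["X1", "X2"] <- 1          # strong mutual core loop
  W["X2", "X1"] <- 1
  W["RO", "X1"] <- 1          # core -> readout
  W["RO", "X2"] <- 1
  W["X1", "RO"] <- 0.005      # negligible feedback from readout
  W["X2", "RO"] <- 0.005
  W[W == 0] <- 1e-4
  diag(W) <- 0
  build_connectome(atlas, W)
}
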