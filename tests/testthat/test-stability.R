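p_ref <- model_params()
p_alt <- model_params("alternative")

test_that("Newton fixed points agree with forward-integration relaxation", {
  # reference regime, inhibition intact: the low branch is the baseline state
  fp <- fixed_point(p_ref, PV = 0, branch = "low")
  expect_lt(fp$residual, 1e-10)
  S_relax <- relax_local(p_ref, PV = 0, S0 = c(0, 0, 0), t_max = 6)
  expect_lt(max(abs(fp$S - S_relax)), 1e-6)
  # without local inhibition onto E
  fp0 <- fixed_point(p_ref, PV = 0, g_EI = 0)
  S_relax0 <- relax_local(p_ref, PV = 0, g_EI = 0, t_max = 6)
  expect_lt(max(abs(fp0$S - S_relax0)), 1e-6)
})

test_that("a linear one-population caricature recovers its closed form", {
  # with gamma * r constant the NMDA steady state is gamma r tau / (1 + ...)
  r <- 8
  S_star <- p_ref$gamma * r * p_ref$tau_N / (1 + p_ref$gamma * r * p_ref$tau_N)
  d <- synapse_derivatives(S_star, 0, 0, r, 0, 0, p_ref)
  expect_equal(d$dS_A, 0, tolerance = 1e-12)
})

test_that("reference baseline eigenvalues are reproduced to one decimal", {
  fp <- fixed_point(p_ref, PV = 0, branch = "low")
  ev <- as.vector(Re(jacobian_eigs(fp, p_ref, PV = 0)))
  expect_equal(round(ev, 1), c(-10.4, -12.5, -229.8))
  fp0 <- fixed_point(p_ref, PV = 0, g_EI = 0)
  ev0 <- as.vector(Re(jacobian_eigs(fp0, p_ref, PV = 0, g_EI = 0)))
  expect_equal(round(ev0, 1), c(-7.4, -7.9, -232.3))
  # the inhibitory eigenvalue identity on the active branch
  expect_equal(ev0[3],
               -1 / p_ref$tau_G -
                 p_ref$gamma_I * (p_ref$c1 / p_ref$g_I) * p_ref$g_II_0,
               tolerance = 1e-9)
})

test_that("with g_EI = 0 the excitatory block decouples from inhibition", {
  # leading two eigenvalues must not depend on g_II or PV
  base <- Re(jacobian_eigs(fixed_point(p_ref, PV = 0, g_EI = 0),
                           p_ref, PV = 0, g_EI = 0))[1:2]
  for (gII in c(0.05, 0.105, 0.3)) for (pv in c(0, 0.5, 1)) {
    ev <- Re(jacobian_eigs(
      fixed_point(p_ref, PV = pv, g_EI = 0, g_II = gII),
      p_ref, PV = pv, g_EI = 0, g_II = gII))[1:2]
    expect_equal(ev, base, tolerance = 1e-8)
  }
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(17)
  for (k in 1:25) {
    pv <- runif(1)
    p <- model_params(g_E_self = runif(1, 0.3, 0.5),
                      g_EI_0 = runif(1, 0.1, 0.4))
    fp <- tryCatch(fixed_point(p, PV = pv, branch = "low"),
                   error = function(e) NULL)
    if (is.null(fp)) next
    J <- local_jacobian(fp$S, p, PV = pv)
    J_fd <- fd_local_jacobian(fp$S, p, pv)
    expect_lt(max(abs(J - J_fd)) / max(abs(J_fd)), 1e-4)
  }
})

test_that("eigenvalue verdicts agree with perturbed forward integration", {
  set.seed(29)
  checked <- 0
  while (checked < 20) {
    p <- model_params(g_E_self = runif(1, 0.3, 0.6),
                      g_EI_0 = runif(1, 0.1, 0.5))
    pv <- runif(1)
    fp <- tryCatch(fixed_point(p, PV = pv, branch = "low"),
                   error = function(e) NULL)
    if (is.null(fp)) next
    ev <- jacobian_eigs(fp, p, PV = pv)
    S_end <- relax_local(p, PV = pv, S0 = fp$S + 1e-3, t_max = 2)
    returned <- max(abs(S_end - fp$S)) < 1e-4
    expect_equal(returned, attr(ev, "stable"))
    checked <- checked + 1
  }
})

test_that("the scenario battery reproduces the stability verdicts", {
  conn <- synthetic_connectome(fixture_spec(n_areas = 43, seed = 1))
  sb <- scenario_battery(conn, p_ref, scenarios = 1:5, T_trial = 6)
  # isolated areas are stable with and without local inhibition
  expect_true(sb$scenario1$stable)
  expect_true(sb$scenario2$stable)
  # intact network holds its baseline
  expect_true(sb$scenario3$stable)
  expect_equal(sum(sb$scenario3$table$high), 0)
  # removing long-range E->I or local I->E destabilizes the coupled network
  expect_false(sb$scenario4$stable)
  expect_gt(sum(sb$scenario4$table$high), 0)
  expect_false(sb$scenario5$stable)
  expect_gt(sum(sb$scenario5$table$high), 0)
  # scenario-1/2 eigenvalues for a PV = 0 area match the reference values
  i0 <- which.min(conn$PV)
  expect_equal(round(sb$scenario1$eigenvalues[i0, ], 1),
               c(lambda1 = -10.4, lambda2 = -12.5, lambda3 = -229.8))
  expect_equal(round(sb$scenario2$eigenvalues[i0, ], 1),
               c(lambda1 = -7.4, lambda2 = -7.9, lambda3 = -232.3))
})

test_that("isolated persistence depends on regime and inhibition strength", {
  expect_true(isolated_persistence(p_alt, PV = 0)$persistent)
  expect_false(isolated_persistence(p_ref, PV = 0)$persistent)
  # overwhelming local inhibition always suppresses persistence
  p_heavy <- model_params("alternative", g_EI_0 = 5)
  expect_false(isolated_persistence(p_heavy, PV = 0)$persistent)
})

test_that("persistence counts fall as local inhibition rises", {
  fix <- census_fixture()
  p <- model_params(g_E_self = 0.44)
  sw <- gradient_sweep(fix$conn, g_EI0_grid = c(0.192, 0.35),
                       scaling_grid = 0.83, params = p,
                       stim_area = fix$candidates[1], T_trial = 6)
  expect_true(all(diff(sw$count[, 1]) <= 0))
  expect_true(all(sw$baseline_stable))
})

test_that("pv_mean weights equal default weights when PV is constant", {
  pv <- rep(0.4, 7)
  a <- local_inhibitory_weights(pv, p_ref, "gradient")
  b <- local_inhibitory_weights(pv, p_ref, "mean")
  expect_identical(a, b)
})

test_that("saddle-node scan finds the loss of the low state", {
  # alternative regime: low state disappears below a critical g_EI_0
  crit <- bifurcation_scan(p_alt, PV = 0, g_EI0_range = c(0, 0.5))
  expect_true(is.finite(crit))
  expect_gt(crit, 0)
  expect_lt(crit, 0.5)
  # reference regime: the low state exists even at g_EI_0 = 0
  expect_true(is.na(bifurcation_scan(p_ref, PV = 0,
                                     g_EI0_range = c(0, 0.192))))
  # the critical inhibition grows with local excitation
  p_more <- model_params("alternative", g_E_self = 0.65)
  crit2 <- bifurcation_scan(p_more, PV = 0, g_EI0_range = c(0, 0.7))
  expect_gt(crit2, crit)
})
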