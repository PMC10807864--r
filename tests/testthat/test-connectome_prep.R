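test_that("volume/density normalization matches the elementwise definition", {
  at <- area_atlas(c("a", "b"), volume_mm3 = c(1, 2), neuron_density = c(1, 1),
                   pv_density = c(0, 0), hierarchy_raw = c(0, 1))
  W <- matrix(c(0, 3, 2, 0), 2, 2)
  expect_equal(normalize_connectivity(W, at), matrix(c(0, 3, 4, 0), 2, 2))

  # unit volumes and densities leave the matrix unchanged
  at1 <- area_atlas(c("a", "b"), 1, 1, 0, hierarchy_raw = c(0, 1))
  expect_equal(normalize_connectivity(W, at1), W)

  # random instance against the brute-force double loop
  set.seed(11)
  n <- 5
  vol <- runif(n, 0.5, 3); dens <- runif(n, 0.5, 2)
  at5 <- area_atlas(letters[1:n], vol, dens, 0, hierarchy_raw = seq(0, 1, length.out = n))
  Wr <- matrix(runif(n * n), n, n); diag(Wr) <- 0
  expect_equal(normalize_connectivity(Wr, at5), brute_normalize(Wr, vol, dens))
  expect_true(all(diag(normalize_connectivity(Wr, at5)) == 0))
})

test_that("normalization rejects degenerate atlases by name", {
  at <- area_atlas(c("a", "b"), c(1, 1), c(1, 1), 0, hierarchy_raw = c(0, 1))
  at$neuron_density[2] <- 0
  expect_error(normalize_connectivity(diag(0, 2), at), "b")
})

test_that("min-max normalization maps to [0,1], passes gaps, honours bounds", {
  expect_equal(minmax_normalize(c(1, 3, 5)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(0.2, NA, 0.8)), c(0, NA, 1))
  # thalamic values normalized with cortical bounds may leave [0,1]
  expect_equal(minmax_normalize(c(-0.1, 0.5, 1.2), bounds = c(0, 1)),
               c(-0.1, 0.5, 1.2))
  expect_error(minmax_normalize(c(2, 2, 2)), "range")
  expect_error(minmax_normalize(c(1, NA)), "two")
})

test_that("hierarchy imputation is the affine weighted mean of known areas", {
  # one unknown area fed only by a known area at h = 0.6
  W <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  h <- c(NA, 0.6)
  expect_equal(impute_hierarchy(W, h, alpha_h = 1.33, beta_h = -0.22)[1],
               1.33 * 0.6 - 0.22)

  # identity coefficients + constant known values -> that constant
  W6 <- matrix(runif(36), 6, 6); diag(W6) <- 0
  hc <- c(NA, rep(0.4, 5))
  expect_equal(impute_hierarchy(W6, hc, alpha_h = 1, beta_h = 0)[1], 0.4)

  # random instance against a direct weighted-mean computation
  set.seed(21)
  W6 <- matrix(runif(36), 6, 6); diag(W6) <- 0
  h6 <- c(runif(4), NA, NA)
  out <- impute_hierarchy(W6, h6, alpha_h = 1.33, beta_h = -0.22)
  for (i in 5:6) {
    wm <- sum(W6[i, 1:4] * h6[1:4]) / sum(W6[i, 1:4])
    expect_equal(out[i], 1.33 * wm - 0.22)
  }
  expect_equal(out[1:4], h6[1:4])  # known entries untouched

  # a gap with zero input weight from known areas is an error
  Wz <- matrix(0, 2, 2); Wz[2, 1] <- 1
  expect_error(impute_hierarchy(Wz, c(NA, 0.5)), "zero weight")
})

test_that("nearest-neighbour thalamic gap fill uses the declared order", {
  expect_equal(fill_thalamic_hierarchy(c(0.2, NA, NA, 0.8)),
               c(0.2, 0.2, 0.8, 0.8))
  expect_equal(fill_thalamic_hierarchy(c(NA, 0.5)), c(0.5, 0.5))
})

test_that("power-law rescaling is max-normalized, monotone, range-compressing", {
  W <- matrix(c(0, 4, 16, 0), 2, 2)
  out <- rescale_connectivity(W, 0.5)
  expect_equal(max(out), 1)
  expect_equal(out[1, 2], sqrt(16) / sqrt(16))
  expect_equal(out[2, 1], sqrt(4) / sqrt(16))   # 2/4 = 0.5

  expect_equal(rescale_connectivity(W, 1), W / 16)

  # five decades compressed to 10^(5 * 0.3)
  W5 <- matrix(c(0, 1e-5, 1, 0), 2, 2)
  out5 <- rescale_connectivity(W5, 0.3)
  nz <- out5[out5 > 0]
  expect_equal(log10(max(nz) / min(nz)), 5 * 0.3, tolerance = 1e-12)

  # rank preservation on a random matrix
  set.seed(5)
  Wr <- matrix(10^runif(49, -5, 0), 7, 7); diag(Wr) <- 0
  expect_equal(order(Wr), order(rescale_connectivity(Wr, 0.3)))

  expect_error(rescale_connectivity(matrix(0, 2, 2)), "all-zero")
})

test_that("CIB coefficients are a complementary sigmoid of hierarchy difference", {
  m <- cib_matrix(c(0, 1), beta = 2.42)
  expect_equal(diag(m), c(0.5, 0.5))
  expect_equal(m[2, 1], 1 / (1 + exp(-2.42)), tolerance = 1e-12)
  expect_equal(m[2, 1], 0.9184, tolerance = 1e-4)
  expect_equal(m[1, 2], 1 - 1 / (1 + exp(-2.42)), tolerance = 1e-12)
  expect_equal(m + t(m), matrix(1, 2, 2))

  # shift invariance and boundedness
  h <- runif(5)
  expect_equal(cib_matrix(h), cib_matrix(h + 3.7))
  expect_true(all(cib_matrix(h) > 0 & cib_matrix(h) < 1))
})

test_that("CIB split conserves total connectivity exactly", {
  set.seed(9)
  W <- matrix(runif(25), 5, 5); diag(W) <- 0
  m <- cib_matrix(runif(5))
  sp <- split_by_target(W, m)
  expect_equal(sp$W_E + sp$W_I, W, tolerance = 1e-14)
  # removing CIB gives equal halves
  sp2 <- split_by_target(W, matrix(0.5, 5, 5))
  expect_equal(sp2$W_E, W / 2)
  expect_equal(sp2$W_I, W / 2)
  # the worked single-entry value
  expect_equal(split_by_target(matrix(1), matrix(0.9184))$W_E[1, 1], 0.9184)
})

test_that("cell type-specific variants follow their definitions", {
  set.seed(13)
  W <- matrix(runif(16), 4, 4); diag(W) <- 0
  PV <- c(0, 0.3, 0.7, 1)

  # pure feedforward limit: k_cell = 1 recovers W (up to max-normalization,
  # which is a no-op because max(W_cell) = max(W) after dividing by max)
  m1 <- matrix(1, 4, 4)
  expect_equal(celltype_matrix(W, m1, PV, "celltype"), W / max(W))

  # m = 0.5: k_cell = 0.5 - 0.5 PV_i; the PV = 1 row vanishes
  mh <- matrix(0.5, 4, 4)
  ct <- celltype_matrix(W, mh, PV, "celltype")
  expect_equal(unname(ct[4, ]), rep(0, 4))
  raw <- (0.5 - 0.5 * PV) * W
  expect_equal(ct, raw / max(raw))

  # sign flip for feedback entries
  mfb <- matrix(0.4, 4, 4)
  expect_equal(celltype_matrix(W, mfb, PV, "sign_only"), -W)
  # noPV keeps the magnitude of the bias
  expect_equal(celltype_matrix(W, mfb, PV, "noPV"), (2 * 0.4 - 1) * W)

  # with PV == 1 the projection coefficient collapses to 2m - 1, so the
  # celltype variant equals noPV up to the max-normalization factor
  m <- cib_matrix(runif(4))
  ct1 <- celltype_matrix(W, m, rep(1, 4), "celltype")
  np <- celltype_matrix(W, m, rep(1, 4), "noPV")
  expect_equal(ct1, np / max(np))

  expect_error(celltype_matrix(W, matrix(0, 4, 4), PV, "celltype"),
               "degenerate")
})

test_that("the assembled connectome satisfies its invariants", {
  conn <- small_connectome(8)
  expect_equal(max(conn$W), 1)
  expect_true(all(conn$W >= 0))
  expect_true(all(diag(conn$W) == 0 & diag(conn$W_raw) == 0 &
                    diag(conn$W_norm) == 0))
  expect_equal(conn$W_E + conn$W_I, conn$W, tolerance = 1e-14)
  expect_equal(conn$m + t(conn$m), matrix(1, 8, 8,
                                          dimnames = dimnames(conn$m)))
  expect_equal(unname(range(conn$PV)), c(0, 1))
  expect_equal(unname(range(conn$h)), c(0, 1))
  expect_equal(max(conn$W_variant$celltype), 1)
})

test_that("area table and weight matrix CSV round-trips are exact", {
  dir <- withr::local_tempdir()
  toy <- toy_two_area_fixture()
  write_area_table(toy$atlas, file.path(dir, "areas.csv"))
  back <- read_area_table(file.path(dir, "areas.csv"))
  expect_equal(as.data.frame(back), as.data.frame(toy$atlas))

  write_weight_matrix(toy$W_raw, file.path(dir, "W.csv"), stage = "raw")
  Wb <- read_weight_matrix(file.path(dir, "W.csv"))
  expect_equal(Wb, toy$W_raw)
  meta <- jsonlite::read_json(file.path(dir, "W.csv.meta.json"))
  expect_match(meta$orientation, "target")

  conn <- build_connectome(toy$atlas, toy$W_raw)
  export_connectome(conn, file.path(dir, "conn"))
  expect_true(file.exists(file.path(dir, "conn", "W_celltype.csv")))
  expect_equal(read_weight_matrix(file.path(dir, "conn", "W.csv")), conn$W)
})
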