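test_that("input strength is the incoming row sum", {
  W <- matrix(c(0, 2, 1, 0), 2, 2)
  expect_equal(unname(input_strength(W)), c(1, 2))
  # invariant to permuting source columns
  set.seed(2)
  Wr <- matrix(runif(36), 6, 6); diag(Wr) <- 0
  expect_equal(input_strength(Wr), input_strength(Wr[, sample(6)]))
  # brute-force double loop on a signed variant
  conn <- small_connectome(6)
  Wt <- conn$W_variant$celltype
  manual <- vapply(1:6, function(i) sum(Wt[i, ]), numeric(1))
  expect_equal(unname(input_strength(Wt)), manual)
})

test_that("eigenvector centrality matches symmetry and power iteration", {
  expect_equal(unname(eigenvector_centrality(matrix(1, 3, 3))), rep(1 / 3, 3))
  W2 <- matrix(c(0, 1, 1, 0), 2, 2)
  ec2 <- eigenvector_centrality(W2)
  expect_equal(unname(ec2), c(0.5, 0.5))
  # positive random matrix against naive power iteration
  set.seed(31)
  Wp <- matrix(runif(36, 0.1, 1), 6, 6)
  expect_equal(unname(eigenvector_centrality(Wp)), power_iteration(Wp),
               tolerance = 1e-8)
  # signed variant: deterministic sign, unit Euclidean norm
  conn <- small_connectome(6)
  v <- eigenvector_centrality(conn$W_variant$celltype)
  expect_equal(sum(v^2), 1)
  expect_gt(v[which.max(abs(v))], 0)
  expect_error(eigenvector_centrality(matrix(0, 3, 3)), "all-zero")
  # ambiguous leading eigenvalue is refused
  expect_error(eigenvector_centrality(diag(c(1, 1, 0.5))), "ambiguous")
})

test_that("loop strength equals brute-force cycle enumeration", {
  toy <- toy_two_area_fixture()
  expect_equal(unname(loop_strength(toy$W_raw, 2)), c(0.1, 0.1))
  # all-ones 4x4 with zero diagonal: every area sits in three 2-cycles
  W4 <- matrix(1, 4, 4); diag(W4) <- 0
  expect_equal(unname(loop_strength(W4, 2)), rep(3, 4))
  # L = 3 on the same graph: cycles through i choose 2 partners, both
  # orientations -> 3 * 2 = 6
  expect_equal(unname(loop_strength(W4, 3)), rep(6, 4))
  # random matrices, all supported lengths, against the recursive oracle
  set.seed(41)
  for (k in 1:12) {
    n <- sample(4:7, 1)
    W <- matrix(runif(n * n) * (runif(n * n) < 0.7), n, n)
    diag(W) <- 0
    for (L in 2:4)
      expect_equal(unname(loop_strength(W, L)), brute_loop_strength(W, L),
                   tolerance = 1e-12)
  }
  # rows of zeros contribute nothing through their dead edges
  Wz <- matrix(1, 4, 4); diag(Wz) <- 0; Wz[2, ] <- 0
  expect_equal(loop_strength(Wz, 2)[2], 0)
  expect_error(loop_strength(matrix(0, 3, 3), 5), "2, 3 and 4")
  expect_error(loop_strength(matrix(0, 2, 2), 3), "exceeds")
})

test_that("restricted loop strength works on the induced subgraph", {
  set.seed(43)
  W <- matrix(runif(49), 7, 7); diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("a", 1:7)
  sub <- c("a2", "a4", "a5", "a7")
  expect_equal(unname(loop_strength(W, 2, restrict = sub)),
               brute_loop_strength(W[sub, sub], 2))
})

test_that("L2 and L3 cell type-specific rankings agree on dense fixtures", {
  conn <- synthetic_connectome(fixture_spec(n_areas = 25, seed = 6,
                                            weight_decades = 2))
  Wc <- conn$W_variant$celltype
  rho <- cor(loop_strength(Wc, 2), loop_strength(Wc, 3), method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("celltype measures reduce to raw ones in the degenerate limit", {
  set.seed(47)
  W <- matrix(runif(25), 5, 5); diag(W) <- 0
  m1 <- matrix(1, 5, 5)
  Wc <- celltype_matrix(W, m1, rep(0, 5), "celltype")
  expect_equal(Wc, W / max(W))
  expect_equal(input_strength(Wc) * max(W), input_strength(W))
  expect_equal(unname(loop_strength(Wc, 2)) * max(W)^2,
               unname(loop_strength(W, 2)))
})

test_that("logistic prediction handles separation, noise and degeneracy", {
  # perfectly separated measure
  out <- predict_binary(c(1:5, 11:15), rep(c(FALSE, TRUE), each = 5))
  expect_equal(out$accuracy, 1)
  expect_true(out$separated)
  # labels independent of the measure: near-chance accuracy
  set.seed(53)
  accs <- replicate(20, {
    predict_binary(rnorm(40), rep(c(TRUE, FALSE), 20))$accuracy
  })
  expect_lt(abs(mean(accs) - 0.55), 0.15)
  # constant measure falls back to the majority class
  out3 <- predict_binary(rep(1, 10), c(rep(TRUE, 7), rep(FALSE, 3)))
  expect_equal(out3$accuracy, 0.7)
  expect_error(predict_binary(1:4, rep(TRUE, 4)), "both classes")
})

test_that("predict_rate is the subsetted Pearson correlation", {
  set.seed(59)
  rates <- runif(12, 0, 30)
  measure <- 3 * rates + rnorm(12, sd = 1e-8)
  sub <- rates > 10
  expect_equal(predict_rate(measure, rates, sub)$r, 1, tolerance = 1e-6)
})

test_that("graph measure tables cover every requested variant", {
  conn <- small_connectome(6)
  tab <- graph_measure_table(conn, loop_lengths = 2)
  expect_setequal(unique(tab$variant),
                  c("raw", "celltype", "sign_only", "noPV"))
  got <- subset(tab, variant == "raw" & measure == "input_strength")$value
  expect_equal(got, unname(input_strength(conn$W)))
})
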