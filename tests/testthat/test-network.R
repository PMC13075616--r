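test_that("clustering coefficient matches hand-computable graphs", {
  # complete graph with equal weights: every normalized triangle is 1
  W <- matrix(0.6, 4, 4); diag(W) <- NA
  cc <- clustering_coefficient(W)
  expect_equal(unname(cc$clustering), rep(1, 4))
  expect_equal(cc$mean_clustering, 1)
  # star graph: no triangles anywhere
  S <- matrix(0, 4, 4); S[1, 2:4] <- S[2:4, 1] <- 0.8; diag(S) <- NA
  expect_equal(unname(clustering_coefficient(S)$clustering), rep(0, 4))
  # triangle (1.0, 0.5, 0.5): node opposite the 1.0 edge
  Tm <- matrix(0, 3, 3)
  Tm[1, 2] <- Tm[2, 1] <- 1.0
  Tm[1, 3] <- Tm[3, 1] <- 0.5
  Tm[2, 3] <- Tm[3, 2] <- 0.5
  cc3 <- clustering_coefficient(Tm)
  expect_equal(unname(cc3$clustering), brute_onnela(Tm))
  expect_equal(unname(cc3$clustering[3]), (1.0 * 0.5 * 0.5)^(1 / 3) / 1)
  expect_error(clustering_coefficient(matrix(c(0, 1, 0.5, 0), 2, 2)),
               "symmetric")
  expect_error(clustering_coefficient(matrix(2, 2, 2)), "\\[0, 1\\]")
})

test_that("efficiency matches hand evaluation of inverse shortest paths", {
  # complete unit graph
  W <- matrix(1, 3, 3); diag(W) <- NA
  ef <- efficiency(W)
  expect_equal(unname(ef$nodal_efficiency), rep(1, 3))
  expect_equal(ef$global_efficiency, 1)
  # two nodes, w = 0.5: d = 2
  W2 <- matrix(c(NA, 0.5, 0.5, NA), 2, 2)
  ef2 <- efficiency(W2)
  expect_equal(unname(ef2$nodal_efficiency), c(0.5, 0.5))
  # 3-node path with unit weights
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  ef3 <- efficiency(P)
  expect_equal(unname(ef3$nodal_efficiency), c(0.75, 1, 0.75))
  expect_equal(ef3$global_efficiency, 5 / 6)
})

test_that("metrics agree with exhaustive oracles on random small graphs", {
  set.seed(31)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    w <- runif(sum(ut))
    w[runif(length(w)) < 0.3] <- 0       # some absent edges
    W[ut] <- w
    W <- W + t(W)
    diag(W) <- NA
    if (max(W, na.rm = TRUE) == 0) next
    expect_equal(unname(clustering_coefficient(W)$clustering),
                 brute_onnela(W), tolerance = 1e-12)
    D <- brute_distances(W)
    inv <- 1 / D; diag(inv) <- 0
    expect_equal(unname(efficiency(W)$nodal_efficiency),
                 unname(rowSums(inv) / (n - 1)), tolerance = 1e-12)
  }
})

test_that("scaling behaviour: NE scales with weights, Onnela C does not", {
  set.seed(32)
  W <- matrix(runif(25), 5, 5); W <- (W + t(W)) / 2; diag(W) <- NA
  for (c in c(0.2, 0.7)) {
    expect_equal(efficiency(W * c)$nodal_efficiency,
                 efficiency(W)$nodal_efficiency * c, tolerance = 1e-12)
    expect_equal(clustering_coefficient(W * c)$clustering,
                 clustering_coefficient(W)$clustering, tolerance = 1e-12)
  }
})

test_that("strengthening an edge never lowers any nodal efficiency", {
  set.seed(33)
  W <- matrix(runif(36, 0, 0.8), 6, 6); W <- (W + t(W)) / 2; diag(W) <- NA
  base <- efficiency(W)$nodal_efficiency
  for (rep in 1:10) {
    i <- sample(6, 1); j <- sample(setdiff(1:6, i), 1)
    W2 <- W
    W2[i, j] <- W2[j, i] <- min(1, W[i, j] + runif(1, 0, 1 - W[i, j]))
    expect_true(all(efficiency(W2)$nodal_efficiency >= base - 1e-12))
  }
})

test_that("network_metrics ties the summaries to their per-node means", {
  set.seed(34)
  W <- matrix(runif(49), 7, 7); W <- (W + t(W)) / 2; diag(W) <- NA
  nm <- network_metrics(W)
  expect_equal(nm$mean_clustering, mean(nm$clustering))
  expect_equal(nm$global_efficiency, mean(nm$nodal_efficiency))
  expect_true(all(nm$clustering >= 0 & nm$clustering <= 1))
  expect_true(all(nm$nodal_efficiency >= 0 & nm$nodal_efficiency <= 1))
})
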