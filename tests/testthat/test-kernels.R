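# Relationship matrices, generic kernels, fusion and cross-kernels.

test_that("VanRaden G matches the hand-evaluated formula", {
  g <- make_geno(matrix(c(2, 0), 2, 1))
  G <- vanraden_g(g)
  # Z = [1, -1], denom = 2 * 0.5 * 0.5 -> G = [[2,-2],[-2,2]]
  expect_equal(unname(as.matrix(G)), matrix(c(2, -2, -2, 2), 2, 2))
  # all heterozygotes with supplied p = 0.5: Z = 0 -> G = 0
  gh <- make_geno(matrix(1, 3, 1))
  expect_equal(unname(as.matrix(vanraden_g(gh, freq = 0.5))),
               matrix(0, 3, 3))
  # all monomorphic -> zero denominator
  gm <- make_geno(matrix(2, 3, 2))
  expect_error(vanraden_g(gm), "zero denominator")
})

test_that("VanRaden G from data frequencies has zero row sums and unit-scale diagonal", {
  g <- simulate_genotypes(50, 200, seed = 21)
  G <- as.matrix(vanraden_g(g))
  expect_lt(max(abs(rowSums(G))), 1e-8)
  expect_gt(mean(diag(G)), 0.9)
  expect_lt(mean(diag(G)), 1.1)
  expect_lt(max(abs(G - t(G))), 1e-10)
})

test_that("expression E matches hand evaluation and scaling expectations", {
  e <- expr_matrix(matrix(c(1, 3), 2, 1), individual_ids = c("a", "b"),
                   state = "log2p1")
  E <- expression_e(e)
  expect_equal(unname(as.matrix(E)),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  # duplicate individuals give identical E rows
  ed <- expr_matrix(matrix(c(1, 1, 3, 4, 4, 1), 3, 2,
                           dimnames = list(c("a", "b", "c"), NULL)),
                    state = "log2p1")
  Ed <- as.matrix(expression_e(ed))
  expect_equal(Ed["a", ], Ed["b", ], ignore_attr = TRUE)
  # iid-normal expression: mean diagonal near (n-1)/n
  set.seed(31)
  en <- expr_matrix(matrix(rnorm(100 * 2000), 100, 2000) + 5,
                    state = "log2p1")
  En <- as.matrix(expression_e(en))
  expect_gt(mean(diag(En)), 0.95)
  expect_lt(mean(diag(En)), 1.05)
  # zero-variance genes are dropped, and all-constant input errors
  ec <- expr_matrix(matrix(c(1, 1, 2, 3), 2, 2), state = "log2p1")
  expect_equal(expression_e(ec)$params$n_dropped, 1)
  eall <- expr_matrix(matrix(1, 2, 2), state = "log2p1")
  expect_error(expression_e(eall), "no genes")
})

test_that("linear and Gaussian kernels evaluate the printed formulas", {
  X <- matrix(c(1, 3, 2, 4), 2, 2)  # rows [1,2], [3,4]
  expect_equal(unname(as.matrix(linear_kernel(X))),
               matrix(c(5, 11, 11, 25), 2, 2))
  # gaussian: x_i=[0,0], x_j=[1,1], theta=0.5 -> exp(-1)
  Xg <- rbind(c(0, 0), c(1, 1))
  Kg <- as.matrix(gaussian_kernel(Xg, theta = 0.5))
  expect_equal(Kg[1, 2], exp(-1), tolerance = 1e-12)
  expect_equal(diag(Kg), c(1, 1), ignore_attr = TRUE)
  expect_error(gaussian_kernel(Xg, theta = 0), "positive")
  expect_error(gaussian_kernel(Xg, theta = -1), "positive")
  # product form = squared-distance form
  set.seed(5)
  Xr <- matrix(rnorm(15), 5, 3)
  Kr <- as.matrix(gaussian_kernel(Xr, theta = 0.7))
  prod_form <- exp(-0.7 * (Xr[2, 1] - Xr[4, 1])^2) *
    exp(-0.7 * (Xr[2, 2] - Xr[4, 2])^2) *
    exp(-0.7 * (Xr[2, 3] - Xr[4, 3])^2)
  expect_equal(Kr[2, 4], prod_form, tolerance = 1e-12)
  # entries in (0, 1]; theta -> 0 gives the all-ones matrix
  expect_true(all(Kr > 0 & Kr <= 1))
  K0 <- as.matrix(gaussian_kernel(Xr, theta = 1e-12))
  expect_lt(max(abs(K0 - 1)), 1e-6)
})

test_that("gaussian kernel agrees with an independent RBF implementation", {
  skip_if_not_installed("kernlab")
  set.seed(6)
  X <- matrix(rnorm(40), 8, 5)
  theta <- 0.3
  K <- as.matrix(gaussian_kernel(X, theta))
  Kref <- kernlab::kernelMatrix(kernlab::rbfdot(sigma = theta), X)
  expect_equal(K, unname(Kref@.Data), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("kernel fusion is the convex combination it claims to be", {
  Ka <- kernel_matrix(diag(2), individual_ids = c("a", "b"),
                      kind = "linear")
  Kb <- kernel_matrix(2 * diag(2), individual_ids = c("a", "b"),
                      kind = "linear")
  expect_equal(as.matrix(combine_kernels(Ka, Kb, 1)), as.matrix(Ka))
  K1 <- kernel_matrix(matrix(1), individual_ids = "a", kind = "linear")
  K3 <- kernel_matrix(matrix(3), individual_ids = "a", kind = "linear")
  expect_equal(as.matrix(combine_kernels(K1, K3, 0.5))[1, 1], 2)
  expect_equal(unname(as.matrix(combine_kernels(Ka, Kb, 0.25))),
               1.75 * diag(2))
  # linearity in w1: K(w1) - K(0) = w1 (Ka - Kb)
  for (w1 in c(0.1, 0.4, 0.9)) {
    lhs <- as.matrix(combine_kernels(Ka, Kb, w1)) -
      as.matrix(combine_kernels(Ka, Kb, 0))
    expect_equal(lhs, w1 * (as.matrix(Ka) - as.matrix(Kb)))
  }
  Kc <- kernel_matrix(diag(2), individual_ids = c("a", "x"),
                      kind = "linear")
  expect_error(combine_kernels(Ka, Kc, 0.5), "mismatch at position 2")
  expect_error(combine_kernels(Ka, Kb, 1.5), "w1")
})

test_that("cross-kernel rows use the training kernel's formula", {
  Xtr <- rbind(c(1, 0), c(0, 1))
  expect_equal(unname(cross_kernel(Xtr, rbind(c(1, 0)), "linear")),
               matrix(c(1, 0), 1, 2))
  expect_equal(unname(cross_kernel(Xtr, rbind(c(0, 0)), "linear")),
               matrix(0, 1, 2))
  # test sample identical to a training sample -> gaussian entry 1
  kg <- cross_kernel(Xtr, rbind(c(0, 1)), "gaussian", theta = 2)
  expect_equal(kg[1, 2], 1)
  expect_lt(kg[1, 1], 1)
  expect_error(cross_kernel(Xtr, rbind(c(1, 0, 0)), "linear"),
               "feature-dimension mismatch")
})

test_that("train-learned feature scaling is reused for test rows", {
  set.seed(7)
  Xtr <- matrix(rnorm(50, mean = 3, sd = 2), 10, 5)
  sf <- standardize_features(Xtr)
  Ztr <- apply_standardization(Xtr, sf)
  expect_lt(max(abs(colMeans(Ztr))), 1e-12)
  expect_equal(unname(apply(Ztr, 2, sd)), rep(1, 5))
  Xte <- matrix(rnorm(10, mean = 3, sd = 2), 2, 5)
  Zte <- apply_standardization(Xte, sf)
  expect_equal(Zte, sweep(sweep(Xte, 2, sf$center), 2, sf$scale, "/"))
})
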