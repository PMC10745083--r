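test_that("objective value matches an independently coded evaluation", {
  set.seed(40)
  C <- matrix(rgamma(6 * 8, 1), 6, 8)
  M <- matrix(runif(48) > 0.2, 6, 8)
  W0 <- matrix(runif(6 * 2), 6, 2)
  H0 <- matrix(runif(2 * 8), 2, 8)
  lam <- 0.002
  # plain-loop oracle
  acc <- 0
  R <- C - W0 %*% H0
  for (i in 1:6) for (j in 1:8) if (M[i, j]) acc <- acc + R[i, j]^2
  oracle <- 0.5 * acc + lam * (sum(H0) + sum(W0))
  expect_equal(nmf_objective(C, M, W0, H0, lam), oracle, tolerance = 1e-12)
})

test_that("an exact rank-1 matrix is reconstructed almost perfectly", {
  set.seed(41)
  u <- rgamma(12, 2); v <- rgamma(15, 2)
  C <- u %*% t(v)
  fit <- masked_sparse_nmf(C, q = 1, lambda = 0, seed = 1, max_iter = 5000)
  rel <- norm(C - fit$W %*% fit$H, "F") / norm(C, "F")
  expect_lt(rel, 1e-6)
})

test_that("the objective trace is non-increasing for every fit", {
  set.seed(42)
  for (seed in 1:5) {
    p <- planted_connectivity(S = 15, T_ = 20, q = 3, noise_sd = 0.05, seed = seed)
    fit <- masked_sparse_nmf(p$C, p$M, q = 3, lambda = 0.002, seed = seed,
                             max_iter = 300)
    expect_true(all(diff(fit$objective_trace) <= 1e-10))
  }
})

test_that("masked entries of the input have zero influence", {
  p <- planted_connectivity(S = 12, T_ = 14, q = 2, noise_sd = 0.02, seed = 3)
  fit1 <- masked_sparse_nmf(p$C, p$M, q = 2, seed = 5, max_iter = 200)
  C2 <- p$C
  C2[!p$M] <- C2[!p$M] + 100  # perturb only masked entries
  fit2 <- masked_sparse_nmf(C2, p$M, q = 2, seed = 5, max_iter = 200)
  expect_identical(fit1$W, fit2$W)
  expect_identical(fit1$H, fit2$H)
  # NAs on masked entries are equally inert
  C3 <- p$C; C3[!p$M] <- NA
  fit3 <- masked_sparse_nmf(C3, p$M, q = 2, seed = 5, max_iter = 200)
  expect_identical(fit1$H, fit3$H)
})

test_that("factors are nonnegative with unit-norm hidden units", {
  p <- planted_connectivity(seed = 4)
  fit <- masked_sparse_nmf(p$C, p$M, q = 3, seed = 2, max_iter = 300)
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
  expect_equal(unname(rowSums(fit$H^2)), rep(1, 3), tolerance = 1e-9)
})

test_that("the sparsity penalty cannot improve the unpenalized fit error", {
  p <- planted_connectivity(S = 15, T_ = 18, q = 2, noise_sd = 0.05,
                            masked_fraction = 0, seed = 6)
  f0 <- masked_sparse_nmf(p$C, q = 2, lambda = 0, seed = 9,
                          max_iter = 10000, tol = 1e-10)
  f1 <- masked_sparse_nmf(p$C, q = 2, lambda = 0.002, seed = 9,
                          max_iter = 10000, tol = 1e-10)
  err <- function(f) norm(p$C - f$W %*% f$H, "F")
  expect_lte(err(f0), err(f1) + 1e-6)
})

test_that("degenerate factorization requests are rejected", {
  C <- matrix(1, 3, 4)
  expect_error(masked_sparse_nmf(C, q = 5), "q must be")
  C[1, 1] <- Inf
  expect_error(masked_sparse_nmf(C, q = 2), "non-finite")
})

test_that("rank selection recovers a planted rank and respects ties", {
  expect_equal(as.numeric(select_rank(planted_connectivity(seed = 2)$C,
                                      q_grid = 4)), 4)
  p <- planted_connectivity(S = 30, T_ = 40, q = 3, noise_sd = 0.01, seed = 5)
  picks <- vapply(1:10, function(r) {
    as.numeric(select_rank(p$C, p$M, q_grid = 1:6, n_repeats = 1, seed = r))
  }, numeric(1))
  expect_equal(as.numeric(names(which.max(table(picks)))), 3)
  # pure noise: the smallest rank wins in the majority of seeds
  noise_picks <- vapply(1:10, function(r) {
    set.seed(100 + r)
    Cn <- matrix(abs(rnorm(30 * 40)), 30, 40)
    as.numeric(select_rank(Cn, q_grid = 1:4, n_repeats = 2, seed = r))
  }, numeric(1))
  expect_gt(sum(noise_picks == 1), 5)
})

test_that("replicate fits are deterministic under a fixed seed", {
  p <- planted_connectivity(seed = 7)
  f1 <- masked_sparse_nmf(p$C, p$M, q = 3, seed = 11, max_iter = 150)
  f2 <- masked_sparse_nmf(p$C, p$M, q = 3, seed = 11, max_iter = 150)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  s1 <- stability_archetypes(p$C, p$M, q = 3, n_replicates = 3, seed = 5,
                             max_iter = 150)
  s2 <- stability_archetypes(p$C, p$M, q = 3, n_replicates = 3, seed = 5,
                             max_iter = 150)
  expect_identical(s1$archetypes, s2$archetypes)
})

test_that("noiseless planted factors appear in every stability replicate", {
  p <- planted_connectivity(S = 25, T_ = 30, q = 3, noise_sd = 0,
                            masked_fraction = 0, seed = 8)
  st <- stability_archetypes(p$C, q = 3, n_replicates = 5, top_k = 3, seed = 2,
                             max_iter = 1500)
  expect_equal(unname(st$frequency), rep(5L, 3))
  mm <- match_archetypes(st$archetypes, p$H)
  expect_gte(mm$mean_cosine, 0.95)
})

test_that("median archetypes recover planted patterns under light noise", {
  p <- planted_connectivity(S = 25, T_ = 30, q = 3, noise_sd = 0.01,
                            masked_fraction = 0.1, seed = 9)
  st <- stability_archetypes(p$C, p$M, q = 3, n_replicates = 8, top_k = 3,
                             seed = 3, max_iter = 1000)
  mm <- match_archetypes(st$archetypes, p$H)
  expect_gte(mm$mean_cosine, 0.9)
})
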