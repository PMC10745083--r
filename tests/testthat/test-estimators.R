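make_support <- function(ont, n, leaf = ont$sources$leaf_id[1], seed = 1,
                         classes = "wt") {
  set.seed(seed)
  cents <- random_leaf_points(ont, leaf, n)
  y <- random_y(n, nrow(ont$targets))
  manual_dataset(ont, rep_len(classes, n), cents, y)
}

test_that("class space distances match brute-force cosine computation", {
  ont <- toy_brain()
  Tn <- nrow(ont$targets)
  set.seed(4)
  cents <- random_leaf_points(ont, 1001, 12)
  y <- random_y(12, Tn)
  y[5:8, ] <- y[1:4, ]  # classes a and b identical
  d <- manual_dataset(ont, rep(c("a", "b", "c"), each = 4), cents, y)
  cs <- build_class_space(d)
  expect_equal(class_distance(cs, "a", "b"), 0, tolerance = 1e-12)
  expect_equal(class_distance(cs, "a", "a"), 0)
  # brute-force pairwise re-evaluation on unit-sum rows
  yn <- y / rowSums(y)
  for (pair in list(c("a", "c"), c("b", "c"))) {
    i1 <- which(rep(c("a", "b", "c"), each = 4) == pair[1])
    i2 <- which(rep(c("a", "b", "c"), each = 4) == pair[2])
    expect_equal(class_distance(cs, pair[1], pair[2]),
                 oracle_cosine_dist(colMeans(yn[i1, ]), colMeans(yn[i2, ])),
                 tolerance = 1e-12)
  }
})

test_that("orthogonal class embeddings are at cosine distance 1", {
  ont <- toy_brain()
  Tn <- nrow(ont$targets)
  y <- matrix(0, 2, Tn)
  y[1, 1] <- 1; y[2, 2] <- 1
  cents <- rbind(c(150, 150, 150), c(250, 250, 250))
  d <- manual_dataset(ont, c("a", "b"), cents, y)
  cs <- build_class_space(d)
  expect_equal(class_distance(cs, "a", "b"), 1)
})

test_that("nw_predict equals the brute-force kernel average", {
  ont <- toy_brain()
  d <- make_support(ont, 10, seed = 7)
  cents <- as.matrix(d$experiments[, c("cx", "cy", "cz")])
  loc <- c(180, 220, 140)
  for (sigma in c(50, 300, 2000)) {
    expect_equal(nw_predict(loc, cents, d$y, sigma),
                 setNames(oracle_nw(loc, cents, d$y, sigma), colnames(d$y)),
                 tolerance = 1e-12)
  }
  # single support experiment: its projection exactly, any bandwidth
  expect_equal(nw_predict(loc, cents[1, , drop = FALSE],
                          d$y[1, , drop = FALSE], 123),
               d$y[1, ], tolerance = 1e-14)
  # equidistant pair: componentwise mean
  c2 <- rbind(c(100, 200, 200), c(300, 200, 200))
  expect_equal(nw_predict(c(200, 200, 200), c2, d$y[1:2, ], 77),
               colMeans(d$y[1:2, ]), tolerance = 1e-12)
  expect_null(nw_predict(loc, cents[0, , drop = FALSE], d$y[0, , drop = FALSE], 100))
})

test_that("kernel predictions stay within the support's componentwise hull", {
  ont <- toy_brain()
  d <- make_support(ont, 8, seed = 9)
  cents <- as.matrix(d$experiments[, c("cx", "cy", "cz")])
  set.seed(10)
  for (r in 1:20) {
    loc <- runif(3, 0, 400)
    p <- nw_predict(loc, cents, d$y, runif(1, 10, 5000))
    expect_true(all(p >= apply(d$y, 2, min) - 1e-12))
    expect_true(all(p <= apply(d$y, 2, max) + 1e-12))
  }
})

test_that("infinite bandwidth gives the unweighted support mean", {
  ont <- toy_brain()
  d <- make_support(ont, 9, seed = 12)
  cents <- as.matrix(d$experiments[, c("cx", "cy", "cz")])
  expect_equal(nw_predict(c(10, 20, 30), cents, d$y, 1e12),
               colMeans(d$y), tolerance = 1e-9)
})

test_that("vanishing bandwidth converges on the nearest experiment", {
  ont <- toy_brain()
  d <- make_support(ont, 6, seed = 13)
  cents <- as.matrix(d$experiments[, c("cx", "cy", "cz")])
  expect_equal(nw_predict(cents[3, ], cents, d$y, 1e-3), d$y[3, ],
               tolerance = 1e-9)
})

test_that("cre_nw_predict filters the support to the class and leaf", {
  ont <- toy_brain()
  set.seed(14)
  cents <- rbind(random_leaf_points(ont, 1001, 6), random_leaf_points(ont, 1002, 2))
  y <- random_y(8, nrow(ont$targets))
  cls <- c("a", "a", "a", "b", "b", "b", "b", "a")
  d <- manual_dataset(ont, cls, cents, y)
  loc <- c(150, 150, 150)
  # equals class-agnostic smoothing on the manually filtered support
  idx <- 1:3
  expect_equal(cre_nw_predict(loc, "a", d, 250),
               setNames(oracle_nw(loc, cents[idx, ], y[idx, , drop = FALSE], 250),
                        colnames(d$y)),
               tolerance = 1e-12)
  # leaf holding one experiment of the class: that experiment exactly
  expect_equal(cre_nw_predict(c(550, 150, 150), "b", d, 99), d$y[7, ],
               tolerance = 1e-12)
  # class with no centroid in the leaf: missing, not an error
  expect_null(cre_nw_predict(c(550, 150, 150), "c", d, 99))
})

test_that("el_predict blends the class mean with the product-kernel term", {
  ont <- toy_brain()
  set.seed(15)
  cents <- random_leaf_points(ont, 1001, 6)
  y <- random_y(6, nrow(ont$targets))
  cls <- c("a", "a", "b", "b", "c", "c")
  d <- manual_dataset(ont, cls, cents, y)
  loc <- c(170, 210, 190)
  sx <- 240; sc <- 0.4
  # alpha = 1: exactly the class-leaf mean
  expect_equal(unname(el_predict(loc, "a", d, sx, sc, alpha = 1)),
               colMeans(y[1:2, ]), tolerance = 1e-12)
  # alpha = 0, sigma_c -> Inf: class-agnostic smoothing over the leaf
  expect_equal(el_predict(loc, "a", d, sx, 1e12, alpha = 0),
               setNames(oracle_nw(loc, cents, y, sx), colnames(d$y)),
               tolerance = 1e-9)
  # alpha = 0.5: hand-composed blend of the two oracle terms
  yn <- y / rowSums(y)
  dv <- vapply(cls, function(v) {
    if (v == "a") 0 else oracle_cosine_dist(colMeans(yn[cls == "a", , drop = FALSE]),
                                            colMeans(yn[cls == v, , drop = FALSE]))
  }, numeric(1))
  w <- exp(-colSums((t(cents) - loc)^2) / (2 * sx^2) - dv^2 / (2 * sc^2))
  g <- drop(crossprod(w / sum(w), y))
  m <- colMeans(y[1:2, ])
  expect_equal(el_predict(loc, "a", d, sx, sc, alpha = 0.5),
               setNames(0.5 * m + 0.5 * g, colnames(d$y)), tolerance = 1e-10)
})

test_that("small class bandwidth concentrates the kernel on the same class", {
  ont <- toy_brain()
  set.seed(16)
  cents <- random_leaf_points(ont, 1001, 6)
  y <- random_y(6, nrow(ont$targets))
  cls <- c("a", "a", "b", "b", "c", "c")
  d <- manual_dataset(ont, cls, cents, y)
  loc <- c(150, 150, 150)
  expect_equal(el_predict(loc, "a", d, 300, 1e-8, alpha = 0),
               cre_nw_predict(loc, "a", d, 300), tolerance = 1e-12)
})

test_that("el_predict falls back through class then leaf means", {
  ont <- toy_brain()
  set.seed(17)
  cents <- rbind(random_leaf_points(ont, 1001, 2), random_leaf_points(ont, 1002, 2))
  y <- random_y(4, nrow(ont$targets))
  d <- manual_dataset(ont, c("a", "a", "b", "b"), cents, y)
  # class b has no centroid in leaf 1001: m falls back to b's global mean
  p <- el_predict(c(150, 150, 150), "b", d, 200, 0.5, alpha = 1)
  expect_equal(unname(p), colMeans(y[3:4, ]), tolerance = 1e-12)
  # empty leaf: missing
  expect_null(el_predict(c(150, 550, 150), "a", d, 200, 0.5, alpha = 0.5))
})

test_that("nnls recovers exact and planted solutions", {
  X <- diag(3)
  Y <- matrix(c(1, 0, 2, 3, 1, 0), 3, 2)
  expect_equal(unname(nnls_fit(X, Y)), Y, tolerance = 1e-10)
  set.seed(18)
  X <- matrix(runif(40 * 6), 40, 6)
  W_true <- matrix(rgamma(6 * 4, 1), 6, 4)
  Y <- X %*% W_true
  expect_equal(unname(nnls_fit(X, Y)), W_true, tolerance = 1e-8)
  expect_error(nnls_fit(X, -Y), "nonnegative")
  X0 <- X; X0[, 2] <- 0
  expect_warning(W0 <- nnls_fit(X0, Y), "all-zero")
  expect_equal(unname(W0[2, ]), rep(0, 4))
})
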