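test_that("structure-level rows are |s| times the leaf prediction", {
  ont <- toy_brain()  # 64-voxel leafs
  set.seed(30)
  cent <- random_leaf_points(ont, 1001, 1)
  y <- random_y(1, nrow(ont$targets))
  d <- manual_dataset(ont, "a", cent, y)
  m <- estimator_model("cre_nw", sigma_x = 500)
  C <- build_connectivity(m, d, v = "a")
  # the single support experiment makes the prediction constant = y
  expect_equal(unname(C["M1L1", ]), 64 * y[1, ], tolerance = 1e-10)
  # leafs without a class-a centroid are missing rows, not zeros
  expect_true(all(is.na(C["M1L2", ])))
  expect_true(all(is.na(C["M2L1", ])))
})

test_that("voxel mode equals the explicit per-voxel summation oracle", {
  ont <- make_brain(1, 2, c(2, 2, 2))
  set.seed(31)
  cents <- rbind(random_leaf_points(ont, 1001, 3), random_leaf_points(ont, 1002, 2))
  y <- random_y(5, nrow(ont$targets))
  d <- manual_dataset(ont, rep("a", 5), cents, y)
  m <- estimator_model("nw", sigma_x = 180)
  C <- build_connectivity(m, d, v = "a", mode = "voxel")
  for (leaf in c("1001", "1002")) {
    vox <- ont$voxels[[paste0(leaf, ":L")]]
    acc <- rep(0, nrow(ont$targets))
    for (j in seq_len(nrow(vox))) {
      ctr <- (vox[j, ] - 0.5) * 100
      sup <- as.matrix(d$experiments[, c("cx", "cy", "cz")])
      acc <- acc + oracle_nw(ctr, sup, y, 180)
    }
    expect_equal(unname(C[ont$acronym_of[[leaf]], ]), acc, tolerance = 1e-10)
  }
})

test_that("connectivity variants follow the voxel-count normalizations", {
  ont <- make_brain(1, 1, c(4, 1, 1))  # |s| = 4, ipsi/contra targets of 4, 4
  set.seed(32)
  cent <- random_leaf_points(ont, 1001, 1)
  y <- matrix(1, 1, nrow(ont$targets))
  d <- manual_dataset(ont, "a", cent, y)
  C <- build_connectivity(estimator_model("cre_nw", sigma_x = 100), d, v = "a")
  expect_equal(unname(C[1, ]), c(4, 4))        # strength: |s| * 1
  CN <- normalize_connectivity(C, ont, "normalized")
  expect_equal(unname(CN[1, ]), c(1, 1))       # / |s|
  CD <- normalize_connectivity(C, ont, "density")
  expect_equal(unname(CD[1, ]), c(0.25, 0.25)) # / (|s| |t|)
  expect_identical(normalize_connectivity(C, ont, "strength"), C)
})

test_that("normalization round-trips reconstruct strength exactly", {
  ont <- toy_brain()
  set.seed(33)
  C <- matrix(rgamma(nrow(ont$sources) * nrow(ont$targets), 1),
              nrow(ont$sources), nrow(ont$targets),
              dimnames = list(ont$sources$acronym, ont$targets$key))
  C[2, ] <- NA  # missing row must stay missing
  CN <- normalize_connectivity(C, ont, "normalized")
  CD <- normalize_connectivity(C, ont, "density")
  expect_equal(CN * ont$sources$n_voxels, C, tolerance = 1e-12)
  expect_equal(sweep(CD * ont$sources$n_voxels, 2, ont$targets$n_voxels, "*"),
               C, tolerance = 1e-12)
  expect_true(all(is.na(CN[2, ])))
})

test_that("class-averaged matrix ignores missing rows", {
  d <- synthetic_study("class_dominated", seed = 6)
  m <- estimator_model("cre_nw", sigma_x = 500)
  tens <- connectivity_tensor(m, d)
  # one class: that class's matrix
  t1 <- tens; t1$values <- tens$values["wt", , , drop = FALSE]
  expect_equal(cre_average_matrix(t1), tens$values["wt", , ])
  # mask-aware mean oracle over 3 classes
  avg <- cre_average_matrix(tens)
  for (s in sample(nrow(avg), 2)) {
    for (t in sample(ncol(avg), 3)) {
      vals <- tens$values[, s, t]
      expect_equal(avg[s, t],
                   if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE))
    }
  }
  # two classes, one missing row: the present one
  v2 <- tens$values[1:2, , ]
  v2[2, 1, ] <- NA
  t2 <- tens; t2$values <- v2
  expect_equal(cre_average_matrix(t2)[1, ],
               colMeans(rbind(v2[1, 1, ]), na.rm = TRUE))
})

test_that("provenance counts equal the evaluation-set tallies", {
  d <- synthetic_study("class_dominated", seed = 7)
  tens <- connectivity_tensor(estimator_model("cre_nw", sigma_x = 500), d)
  es <- eval_set(d)
  for (k in seq_len(nrow(es))) {
    acr <- d$ontology$acronym_of[[as.character(es$leaf_id[k])]]
    expect_equal(unname(tens$provenance[es$cell_class[k], acr]), es$n[k])
  }
  # missing exactly where the class has no centroid in the source leaf
  expect_identical(is.na(tens$values[, , 1]), tens$provenance == 0L)
})

test_that("top-percentile targets include ties at the cut", {
  row <- setNames(as.numeric(1:10), paste0("t", 1:10))
  expect_identical(top_targets(row, 90), "t10")
  expect_identical(top_targets(row, 0), names(row))
  row2 <- setNames(c(1, 5, 5, 2), paste0("t", 1:4))
  expect_setequal(top_targets(row2, 75), c("t2", "t3"))
  # sort-based oracle on a random vector
  set.seed(34)
  r <- setNames(runif(100), paste0("t", 1:100))
  cut <- quantile(r, 0.75)
  expect_setequal(top_targets(r, 75), names(r)[r >= cut])
  expect_error(top_targets(setNames(rep(NA_real_, 3), letters[1:3]), 50), "empty")
})

test_that("distal mask keeps pairs at or beyond the threshold", {
  ont <- make_brain(1, 3, c(2, 2, 2))
  M <- distal_mask(ont, threshold_um = 200)
  # a source is at distance 0 from its own ipsilateral target
  for (i in seq_len(nrow(ont$sources))) {
    expect_false(M[ont$sources$acronym[i], paste0(ont$sources$acronym[i], "_ipsi")])
  }
  # boundary is inclusive ("less than" is masked strictly)
  expect_true(all(M == (outer(ont$sources$acronym, ont$targets$key,
                              Vectorize(function(s, t) region_distance(ont, s, t))) >= 200)))
  M2 <- distal_mask(ont, threshold_um = region_distance(ont, "M1L1", "M1L2_ipsi"))
  expect_true(M2["M1L1", "M1L2_ipsi"])
})

test_that("connectivity writer emits wide and long formats with empty missings", {
  d <- synthetic_study("class_dominated", seed = 8)
  tens <- connectivity_tensor(estimator_model("cre_nw", sigma_x = 500), d)
  dir <- tempfile()
  write_connectivity(tens, dir)
  expect_true(file.exists(file.path(dir, "connectivity_wt.csv")))
  long <- read.delim(file.path(dir, "connectivity_long.tsv"))
  expect_equal(nrow(long), prod(dim(tens$values)))
  wide <- as.matrix(read.csv(file.path(dir, "connectivity_wt.csv"), row.names = 1,
                             check.names = FALSE))
  expect_equal(unname(wide), unname(tens$values["wt", , ]), tolerance = 1e-12)
})
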