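#' Build a synthetic block-parcellated brain
#'
#' Axis-aligned block parcellation with two mirrored hemispheres: each major
#' division is a row of `leafs_per_major` rectangular leafs, mirrored across
#' the lattice midline along the third axis. Deterministic given its
#' arguments; the seed is recorded for provenance.
#'
#' @param n_major number of major divisions.
#' @param leafs_per_major leafs per major division.
#' @param leaf_shape_voxels integer triple: voxels per leaf block (the third
#'   entry is the per-hemisphere depth).
#' @param spacing_um voxel spacing (default 100 um).
#' @param seed recorded seed (construction is deterministic).
#' @return a [region_ontology] over a matching [voxel_lattice].
#' @export
make_brain <- function(n_major = 4, leafs_per_major = 3,
                       leaf_shape_voxels = c(4, 4, 4), spacing_um = 100,
                       seed = 1) {
  ls <- as.integer(leaf_shape_voxels)
  if (any(c(n_major, leafs_per_major, ls) < 1)) stop_mesoconn("sizes must be positive")
  shape <- c(ls[1] * leafs_per_major, ls[2] * n_major, 2L * ls[3])
  lattice <- voxel_lattice(shape, spacing_um = spacing_um)
  ann <- array(0L, dim = shape)
  nodes <- data.frame(id = 997L, acronym = "brain",
                      parent_structure_id = NA_integer_,
                      stringsAsFactors = FALSE)
  for (m in seq_len(n_major)) {
    nodes <- rbind(nodes, data.frame(id = m * 1000L, acronym = paste0("M", m),
                                     parent_structure_id = 997L))
    for (j in seq_len(leafs_per_major)) {
      id <- m * 1000L + j
      nodes <- rbind(nodes, data.frame(id = id,
                                       acronym = paste0("M", m, "L", j),
                                       parent_structure_id = m * 1000L))
      xs <- ((j - 1) * ls[1] + 1):(j * ls[1])
      ys <- ((m - 1) * ls[2] + 1):(m * ls[2])
      ann[xs, ys, 1:ls[3]] <- id                      # left (source) hemisphere
      ann[xs, ys, (ls[3] + 1):(2 * ls[3])] <- id      # mirrored right hemisphere
    }
  }
  ont <- region_ontology(nodes, ann, lattice)
  attr(ont, "seed") <- seed
  ont
}

#' Sample a ground-truth connectivity function
#'
#' Emulates the structural assumptions behind kernel connectome estimation:
#' each (class, leaf) pair has a sparse nonnegative target pattern that can
#' change sharply across leafs and classes, while within a leaf the
#' projection varies smoothly with source position through a positive scalar
#' modulation field.
#'
#' Patterns: a base pattern per leaf (gamma draws on a Bernoulli support of
#' expected density `1 - pattern_sparsity`, unit-sum) is perturbed per class
#' by entrywise log-normal factors of scale `class_effect`; `class_effect =
#' 0` makes all classes share the leaf pattern. Modulation: per leaf, a
#' sinusoid of a random direction with amplitude `1/smoothness_scale` on the
#' log scale, so `smoothness_scale -> Inf` gives a constant field.
#'
#' @param ontology a [region_ontology].
#' @param n_classes number of cell classes (class 1 is the wild type,
#'   labelled `"wt"`).
#' @param pattern_sparsity expected fraction of zero targets per pattern.
#' @param class_effect scale of between-class pattern divergence (>= 0).
#' @param smoothness_scale inverse amplitude of within-leaf spatial
#'   modulation.
#' @param seed RNG seed.
#' @return object of class `ground_truth`.
#' @export
sample_ground_truth <- function(ontology, n_classes = 3, pattern_sparsity = 0.5,
                                class_effect = 1, smoothness_scale = 10,
                                seed = 1) {
  stopifnot(n_classes >= 1, pattern_sparsity >= 0, pattern_sparsity < 1,
            class_effect >= 0, smoothness_scale > 0)
  tgt <- ontology$targets
  src <- ontology$sources
  Tn <- nrow(tgt)
  classes <- c("wt", if (n_classes > 1) paste0("class", 2:n_classes))
  gt <- with_seed(seed, {
    P <- array(0, dim = c(n_classes, nrow(src), Tn),
               dimnames = list(classes, src$acronym, tgt$key))
    for (s in seq_len(nrow(src))) {
      support <- runif(Tn) >= pattern_sparsity
      if (!any(support)) support[sample.int(Tn, 1)] <- TRUE
      base <- rgamma(Tn, shape = 2, rate = 1) * support
      base <- base / sum(base)
      for (vi in seq_len(n_classes)) {
        p <- base * exp(class_effect * rnorm(Tn))
        P[vi, s, ] <- p / sum(p)
      }
    }
    mod <- do.call(rbind, lapply(seq_len(nrow(src)), function(s) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      data.frame(leaf_id = src$leaf_id[s], ux = u[1], uy = u[2], uz = u[3],
                 phase = runif(1, 0, 2 * pi))
    }))
    list(P = P, mod = mod)
  })
  sp <- ontology$lattice$spacing_um
  gt$mod$wavelength_um <- vapply(gt$mod$leaf_id, function(l) {
    vox <- ontology$voxels[[paste0(l, ":L")]]
    2 * max(apply(vox, 2, function(z) diff(range(z)) + 1)) * sp
  }, numeric(1))
  structure(list(ontology = ontology, classes = classes, patterns = gt$P,
                 modulation = gt$mod, pattern_sparsity = pattern_sparsity,
                 class_effect = class_effect, smoothness_scale = smoothness_scale,
                 seed = seed),
            class = "ground_truth")
}

# smooth positive within-leaf modulation field at micrometre positions
modulation_field <- function(gt, leaf_id, pos_um) {
  m <- gt$modulation[gt$modulation$leaf_id == leaf_id, ]
  if (nrow(m) == 0) stop_mesoconn("no modulation for leaf ", leaf_id)
  pos_um <- matrix(pos_um, ncol = 3)
  s <- sin(2 * pi * (pos_um %*% c(m$ux, m$uy, m$uz)) / m$wavelength_um + m$phase)
  drop(exp(s / gt$smoothness_scale))
}

#' True regionalized projection at a source location
#'
#' @param gt a [sample_ground_truth()] result.
#' @param v class label.
#' @param loc 3-vector, micrometres (inside a source leaf).
#' @return named T-vector
#'   `pattern(v, leaf(loc)) * modulation(leaf(loc), loc)`.
#' @export
true_projection <- function(gt, v, loc) {
  l <- leaf_at(gt$ontology, loc)
  if (l == 0) stop_mesoconn("location outside the annotated brain")
  acr <- gt$ontology$acronym_of[[as.character(l)]]
  gt$patterns[v, acr, ] * modulation_field(gt, l, loc)
}

#' True regionalized connectivity tensor
#'
#' \eqn{\mathcal{C}(v, s, t) = \sum_{voxels\ of\ s} f(v, voxel, t)}, computed
#' by exact summation of the modulation field over voxel centres.
#'
#' @param gt a [sample_ground_truth()] result.
#' @return class x S x T array of strengths.
#' @export
true_connectivity <- function(gt) {
  ont <- gt$ontology
  src <- ont$sources
  out <- array(NA_real_, dim = dim(gt$patterns), dimnames = dimnames(gt$patterns))
  sp <- ont$lattice$spacing_um
  for (s in seq_len(nrow(src))) {
    vox <- ont$voxels[[paste0(src$leaf_id[s], ":L")]]
    fs <- sum(modulation_field(gt, src$leaf_id[s], voxel_centers_um(vox, sp)))
    for (vi in seq_along(gt$classes)) {
      out[vi, s, ] <- gt$patterns[vi, s, ] * fs
    }
  }
  out
}

#' Simulate tracer experiments from a ground truth
#'
#' For each designed experiment an injection centroid is drawn uniformly in
#' the leaf interior; the injection is a Gaussian blob (sd 1.5 voxels)
#' truncated at the leaf boundary and normalized to unit mass, so centroids
#' are unambiguous and the blob mass does not confound the projection scale.
#' The regionalized projection is the true projection at the centroid under
#' entrywise multiplicative log-normal noise, matching the multiplicative
#' variability of fluorescence intensities.
#'
#' @param gt a [sample_ground_truth()] result.
#' @param design data.frame with columns `cell_class`, `leaf_id`, `n`;
#'   default: `n_per_cell` experiments for every (class, source leaf) pair.
#' @param n_per_cell experiments per (class, leaf) cell for the default
#'   design.
#' @param noise_sd standard deviation of the log-normal noise (log scale).
#' @param seed RNG seed.
#' @param normalization normalization applied to the emitted dataset.
#' @param keep_volumes attach injection voxel fields (needed by the NNLS
#'   baseline's regionalized injections; disable to save memory).
#' @return a [tracer_dataset()] with the ground truth attached as attribute
#'   `"ground_truth"`.
#' @export
simulate_experiments <- function(gt, design = NULL, n_per_cell = 2,
                                 noise_sd = 0.2, seed = 1,
                                 normalization = "none", keep_volumes = TRUE) {
  ont <- gt$ontology
  src <- ont$sources
  if (is.null(design)) {
    design <- expand.grid(cell_class = gt$classes, leaf_id = src$leaf_id,
                          n = n_per_cell, stringsAsFactors = FALSE)
  }
  if (!all(design$cell_class %in% gt$classes)) {
    stop_mesoconn("design references unknown class(es): ",
                  paste(setdiff(design$cell_class, gt$classes), collapse = ", "))
  }
  if (!all(design$leaf_id %in% src$leaf_id)) {
    stop_mesoconn("design references unknown leaf id(s): ",
                  paste(setdiff(design$leaf_id, src$leaf_id), collapse = ", "))
  }
  design <- design[design$n > 0, , drop = FALSE]
  sp <- ont$lattice$spacing_um
  Tn <- nrow(ont$targets)
  with_seed(seed, {
    rows <- list()
    ys <- list()
    injections <- if (keep_volumes) list() else NULL
    x_rows <- if (keep_volumes) list() else NULL
    eid <- 0L
    for (r in seq_len(nrow(design))) {
      l <- design$leaf_id[r]
      v <- design$cell_class[r]
      vox <- ont$voxels[[paste0(l, ":L")]]
      lo <- apply(vox, 2, min)
      hi <- apply(vox, 2, max)
      for (k in seq_len(design$n[r])) {
        eid <- eid + 1L
        # uniform over the span of voxel centres (half-voxel interior margin)
        cent <- (lo - 0.5 + runif(3) * (hi - lo)) * sp
        y <- true_projection(gt, v, cent) * exp(rnorm(Tn, 0, noise_sd))
        rows[[eid]] <- data.frame(id = sprintf("exp%04d", eid), cell_class = v,
                                  cx = cent[1], cy = cent[2], cz = cent[3],
                                  stringsAsFactors = FALSE)
        ys[[eid]] <- y
        if (keep_volumes) {
          blob <- array(0, dim = ont$lattice$shape)
          centers <- voxel_centers_um(vox, sp)
          dens <- exp(-colSums((t(centers) - cent)^2) / (2 * (1.5 * sp)^2))
          blob[vox] <- dens / sum(dens)
          injections[[eid]] <- blob
          x_rows[[eid]] <- regionalize_injection(blob, ont)
        }
      }
    }
    experiments <- do.call(rbind, rows)
    y <- do.call(rbind, ys)
    colnames(y) <- ont$targets$key
    x_S <- if (keep_volumes) do.call(rbind, x_rows) else NULL
    d <- tracer_dataset(experiments, y, ont, x_S = x_S,
                        injections = injections)
    if (normalization != "none") d <- normalize_dataset(d, normalization)
    attr(d, "ground_truth") <- gt
    d
  })
}

#' Canned synthetic study conditions
#'
#' Three fixed scenarios used for estimator validation, with the generator
#' parameters that define them (rationale in the methods vignette):
#' \describe{
#'   \item{`class_dominated`}{2 majors x 2 leafs (4^3 voxels), 3 strongly
#'     divergent classes (`class_effect = 3`), near-flat within-leaf
#'     modulation (`smoothness_scale = 1000`), log-normal noise sd 0.2,
#'     3 experiments per (class, leaf).}
#'   \item{`space_dominated`}{4 majors x 1 leaf, identical class patterns
#'     (`class_effect = 0`), strong smooth modulation
#'     (`smoothness_scale = 2`), noise sd 0.1, 2 experiments per cell.}
#'   \item{`recovery`}{2 majors x 2 leafs, 3 classes, gentle modulation
#'     (`smoothness_scale = 100`), noiseless, 6 experiments per cell.}
#' }
#'
#' @param scenario one of `"class_dominated"`, `"space_dominated"`,
#'   `"recovery"`.
#' @param seed RNG seed for patterns, centroids and noise.
#' @return a [tracer_dataset()] with attached ground truth.
#' @export
synthetic_study <- function(scenario = c("class_dominated", "space_dominated",
                                         "recovery"), seed = 1) {
  scenario <- match.arg(scenario)
  cfg <- switch(scenario,
    class_dominated = list(n_major = 2, lpm = 2, n_classes = 3, class_effect = 3,
                           smooth = 1000, noise = 0.2, n_per_cell = 3),
    space_dominated = list(n_major = 4, lpm = 1, n_classes = 3, class_effect = 0,
                           smooth = 2, noise = 0.1, n_per_cell = 2),
    recovery = list(n_major = 2, lpm = 2, n_classes = 3, class_effect = 1,
                    smooth = 100, noise = 0, n_per_cell = 6))
  ont <- make_brain(n_major = cfg$n_major, leafs_per_major = cfg$lpm,
                    leaf_shape_voxels = c(4, 4, 4), seed = seed)
  gt <- sample_ground_truth(ont, n_classes = cfg$n_classes,
                            pattern_sparsity = 0.5,
                            class_effect = cfg$class_effect,
                            smoothness_scale = cfg$smooth, seed = seed)
  simulate_experiments(gt, n_per_cell = cfg$n_per_cell, noise_sd = cfg$noise,
                       seed = seed + 1, keep_volumes = FALSE)
}

#' Planted low-rank connectivity matrix for factorization tests
#'
#' Generates `C = W H + noise` with sparse nonnegative factors and an
#' optional random mask, the standard planted-model benchmark for NMF rank
#' selection and stability checks.
#'
#' @param S,T_ matrix dimensions.
#' @param q planted rank.
#' @param noise_sd additive Gaussian noise sd (clipped at 0).
#' @param masked_fraction fraction of entries masked out.
#' @param seed RNG seed.
#' @return list with `C`, `M`, and the planted `W`, `H` (H rows unit-L2).
#' @export
planted_connectivity <- function(S = 30, T_ = 40, q = 3, noise_sd = 0.01,
                                 masked_fraction = 0.1, seed = 1) {
  with_seed(seed, {
    H <- matrix(rgamma(q * T_, shape = 0.5), q, T_)
    H <- H / sqrt(rowSums(H^2))
    W <- matrix(rgamma(S * q, shape = 1, rate = 1), S, q)
    C <- W %*% H + matrix(rnorm(S * T_, 0, noise_sd), S, T_)
    C[C < 0] <- 0
    M <- matrix(runif(S * T_) >= masked_fraction, S, T_)
    list(C = C, M = M, W = W, H = H)
  })
}
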