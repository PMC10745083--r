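#' Build a class-specific connectivity matrix
#'
#' Assembles the S x T regionalized connectivity estimate for one cell class
#' by summing model predictions over the voxels of each source leaf. In
#' `"structure"` mode the model is evaluated once at the leaf centroid and
#' replicated: row = `|s| * fhat(s)`; in `"voxel"` mode predictions are summed
#' voxel by voxel. The NNLS baseline's row is its indicator-injection
#' response `fhat(1_s)` directly. Rows of source leafs in which the class has
#' no injection centroid are missing (`NA`), distinguishing "not estimated for
#' lack of data" from zero connectivity.
#'
#' @param model a fitted [estimator_model()].
#' @param d a [tracer_dataset()].
#' @param ontology a [region_ontology] (defaults to the dataset's).
#' @param v cell class label.
#' @param mode `"structure"` or `"voxel"` evaluation.
#' @return S x T matrix (rows = source acronyms, cols = target keys) with
#'   `NA` rows where the class lacks a centroid.
#' @export
build_connectivity <- function(model, d, ontology = d$ontology, v,
                               mode = c("structure", "voxel")) {
  mode <- match.arg(mode)
  src <- ontology$sources
  keys <- ontology$targets$key
  C <- matrix(NA_real_, nrow(src), length(keys),
              dimnames = list(src$acronym, keys))
  sp <- ontology$lattice$spacing_um
  cs <- if (model$kind == "el") build_class_space(d) else NULL
  for (r in seq_len(nrow(src))) {
    l <- src$leaf_id[r]
    has_class <- length(intersect(d$I_leaf[[as.character(l)]],
                                  d$I_class[[v]])) > 0
    if (!has_class) next
    vox <- ontology$voxels[[paste0(l, ":L")]]
    centers <- voxel_centers_um(vox, sp)
    if (model$kind == "nnls") {
      m_id <- unname(ontology$major_of[as.character(l)])
      W <- model$W[[as.character(m_id)]]
      if (!is.null(W) && src$acronym[r] %in% rownames(W)) {
        C[r, ] <- W[src$acronym[r], ]
      }
      next
    }
    if (mode == "structure") {
      p <- predict_projection(model, d, colMeans(centers), v = v, class_space = cs)
      if (!is.null(p)) C[r, ] <- nrow(vox) * p
    } else {
      acc <- rep(0, length(keys))
      ok <- TRUE
      for (j in seq_len(nrow(centers))) {
        p <- predict_projection(model, d, centers[j, ], v = v, class_space = cs)
        if (is.null(p)) { ok <- FALSE; break }
        acc <- acc + p
      }
      if (ok) C[r, ] <- acc
    }
  }
  C
}

#' Assemble a class x source x target connectivity tensor
#'
#' @param model a fitted [estimator_model()].
#' @param d a [tracer_dataset()].
#' @param classes class labels to include (default: all observed).
#' @param mode passed to [build_connectivity()].
#' @return object of class `connectivity_tensor`: a 3D array (`values`) with
#'   missing-entry semantics, the `variant` tag (`"strength"`), and a
#'   provenance matrix counting the experiments behind each (class, source)
#'   row.
#' @export
connectivity_tensor <- function(model, d, classes = names(d$I_class),
                                mode = c("structure", "voxel")) {
  mode <- match.arg(mode)
  ont <- d$ontology
  src <- ont$sources
  values <- array(NA_real_, dim = c(length(classes), nrow(src), nrow(ont$targets)),
                  dimnames = list(classes, src$acronym, ont$targets$key))
  prov <- matrix(0L, length(classes), nrow(src),
                 dimnames = list(classes, src$acronym))
  for (vi in seq_along(classes)) {
    values[vi, , ] <- build_connectivity(model, d, ont, classes[vi], mode = mode)
    prov[vi, ] <- vapply(src$leaf_id, function(l) {
      length(intersect(d$I_leaf[[as.character(l)]], d$I_class[[classes[vi]]]))
    }, integer(1))
  }
  structure(list(values = values, variant = "strength", provenance = prov,
                 ontology = ont, model_kind = model$kind),
            class = "connectivity_tensor")
}

#' Convert between connectivity variants
#'
#' Strength \eqn{\mathcal{C}}, normalized strength
#' \eqn{\mathcal{C}_N = \mathcal{C} / |s|}, and density
#' \eqn{\mathcal{C}_D = \mathcal{C} / (|s| |t|)}, where `|s|` and `|t|` are
#' source and target voxel counts. Missing entries stay missing.
#'
#' @param C an S x T strength matrix (rows/cols named as produced by
#'   [build_connectivity()]) or a `connectivity_tensor`.
#' @param ontology a [region_ontology]; taken from the tensor when omitted.
#' @param variant `"strength"`, `"normalized"`, or `"density"`.
#' @return the rescaled matrix or tensor.
#' @export
normalize_connectivity <- function(C, ontology = NULL,
                                   variant = c("strength", "normalized", "density")) {
  variant <- match.arg(variant)
  if (inherits(C, "connectivity_tensor")) {
    ontology <- ontology %||% C$ontology
    for (vi in seq_len(dim(C$values)[1])) {
      C$values[vi, , ] <- normalize_connectivity(C$values[vi, , ], ontology, variant)
    }
    C$variant <- variant
    return(C)
  }
  if (variant == "strength") return(C)
  ns <- ontology$sources$n_voxels
  out <- C / ns
  if (variant == "density") out <- sweep(out, 2, ontology$targets$n_voxels, "/")
  out
}

#' Average connectivity matrix over cell classes
#'
#' Entrywise mean over the class dimension, ignoring missing entries; rows
#' missing in every class stay missing.
#'
#' @param tensor a `connectivity_tensor`.
#' @return S x T matrix.
#' @export
cre_average_matrix <- function(tensor) {
  vals <- tensor$values
  out <- apply(vals, c(2, 3), function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  })
  out
}

#' Targets in the top percentile of a connectivity row
#'
#' Returns the targets whose weight is at or above the `p`-th percentile of
#' the row's non-missing weights; ties at the cut are all included.
#'
#' @param row named T-vector (may contain `NA`).
#' @param percentile p in \[0, 100).
#' @return character vector of target names.
#' @export
top_targets <- function(row, percentile) {
  if (percentile < 0 || percentile >= 100) stop_mesoconn("percentile must be in [0, 100)")
  w <- row[!is.na(row)]
  if (length(w) == 0) stop_mesoconn("empty connectivity row")
  cut <- unname(quantile(w, percentile / 100))
  names(w)[w >= cut]
}

#' Distal source-target mask
#'
#' Marks source-target pairs to keep for distal analyses: `TRUE` when the
#' region distance is at least `threshold_um`; pairs strictly closer are
#' masked out, removing injection-site and traveling-fiber artifacts.
#'
#' @param ontology a [region_ontology].
#' @param threshold_um distance threshold (default 1500 um).
#' @param mode distance mode, see [region_distance()].
#' @return logical S x T matrix (`TRUE` = kept).
#' @export
distal_mask <- function(ontology, threshold_um = 1500,
                        mode = c("min_voxel", "centroid")) {
  mode <- match.arg(mode)
  if (threshold_um < 0) stop_mesoconn("threshold_um must be >= 0")
  src <- ontology$sources
  tgt <- ontology$targets
  M <- matrix(NA, nrow(src), nrow(tgt), dimnames = list(src$acronym, tgt$key))
  for (i in seq_len(nrow(src))) {
    for (j in seq_len(nrow(tgt))) {
      M[i, j] <- region_distance(ontology, src$acronym[i], tgt$key[j],
                                 mode = mode) >= threshold_um
    }
  }
  M
}

#' Write a connectivity tensor
#'
#' Wide CSV per class (rows = source acronyms, cols = target keys; missing
#' entries are empty fields, never 0) and one long TSV with columns class,
#' source, target, variant, value, n_experiments.
#'
#' @param tensor a `connectivity_tensor`.
#' @param dir output directory.
#' @param log10_display write an additional log10-transformed display copy of
#'   each wide CSV (stored values are never transformed).
#' @return `dir`, invisibly.
#' @export
write_connectivity <- function(tensor, dir, log10_display = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- tensor$values
  classes <- dimnames(vals)[[1]]
  long <- list()
  for (vi in seq_along(classes)) {
    M <- vals[vi, , ]
    utils::write.csv(M, file.path(dir, paste0("connectivity_", classes[vi], ".csv")),
                     na = "")
    if (log10_display) {
      utils::write.csv(log10(M), file.path(dir, paste0("connectivity_",
                                                       classes[vi], "_log10.csv")), na = "")
    }
    df <- expand.grid(source = rownames(M), target = colnames(M),
                      stringsAsFactors = FALSE)
    df$class <- classes[vi]
    df$variant <- tensor$variant
    df$value <- as.vector(M)
    df$n_experiments <- tensor$provenance[vi, df$source]
    df$missing <- is.na(df$value)
    long[[vi]] <- df[, c("class", "source", "target", "variant", "value",
                         "n_experiments", "missing")]
  }
  long <- do.call(rbind, long)
  long <- long[order(long$class, long$source, long$target), ]
  write.table(long, file.path(dir, "connectivity_long.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}

#' @export
print.connectivity_tensor <- function(x, ...) {
  dd <- dim(x$values)
  cat("connectivity_tensor (", x$variant, "): ", dd[1], " classes x ", dd[2],
      " sources x ", dd[3], " targets; ",
      sum(is.na(x$values[, , 1])), " missing (class, source) rows\n", sep = "")
  invisible(x)
}
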