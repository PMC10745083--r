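#' Injection centroid of a voxel field
#'
#' Signal-weighted mean of voxel-centre positions. Pass a binarized field
#' (`field > 0`) for an unweighted centroid.
#'
#' @param field nonnegative numeric 3D array of injection signal.
#' @param lattice a [voxel_lattice] the field is aligned to.
#' @return 3-vector of micrometre coordinates.
#' @export
compute_centroid <- function(field, lattice) {
  if (!identical(dim(field), lattice$shape)) stop_mesoconn("field not aligned to lattice")
  if (any(field < 0)) stop_mesoconn("injection field must be nonnegative")
  tot <- sum(field)
  if (tot <= 0) stop_mesoconn("cannot compute centroid of an all-zero injection field")
  idx <- which(field > 0, arr.ind = TRUE)
  w <- field[idx] / tot
  unname(drop(crossprod(w, voxel_centers_um(idx, lattice$spacing_um))))
}

#' Regionalize a projection field over the target set
#'
#' Sums the field over the voxels of each target leaf instance (ipsilateral
#' and contralateral leafs are separate targets).
#'
#' @param field numeric 3D array aligned to the ontology's lattice.
#' @param ontology a [region_ontology].
#' @return named T-vector (names = target keys).
#' @export
regionalize <- function(field, ontology) {
  if (!identical(dim(field), ontology$lattice$shape)) {
    stop_mesoconn("field not aligned to lattice")
  }
  tgt <- ontology$targets
  hemi <- ifelse(tgt$hemisphere == "ipsi", "L", "R")
  out <- vapply(seq_len(nrow(tgt)), function(i) {
    v <- ontology$voxels[[paste0(tgt$leaf_id[i], ":", hemi[i])]]
    sum(field[v])
  }, numeric(1))
  setNames(out, tgt$key)
}

# regionalized injection over the source leaf set (S-vector)
regionalize_injection <- function(field, ontology) {
  src <- ontology$sources
  out <- vapply(seq_len(nrow(src)), function(i) {
    sum(field[ontology$voxels[[paste0(src$leaf_id[i], ":L")]]])
  }, numeric(1))
  setNames(out, src$acronym)
}

# spread a regionalized target vector uniformly over each target's voxels,
# so that regionalize() recovers it exactly
project_to_volume <- function(y, ontology) {
  out <- array(0, dim = ontology$lattice$shape)
  tgt <- ontology$targets
  hemi <- ifelse(tgt$hemisphere == "ipsi", "L", "R")
  for (i in seq_len(nrow(tgt))) {
    v <- ontology$voxels[[paste0(tgt$leaf_id[i], ":", hemi[i])]]
    out[v] <- out[v] + y[[tgt$key[i]]] / nrow(v)
  }
  out
}

#' Normalize an experiment's regionalized projection
#'
#' `total_projection` rescales so the entries sum to 1 (comparability across
#' cell classes with different tracer efficiency); `injection_volume` divides
#' by the number of positive injection voxels; `none` is the identity.
#'
#' @param e an experiment as returned by [experiment()]: a list with at least
#'   `y_T` and, for `injection_volume`, `n_injection_voxels`.
#' @param mode normalization mode.
#' @return the experiment with rescaled `y_T`.
#' @export
normalize_experiment <- function(e, mode = c("total_projection", "injection_volume", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(e)
  denom <- switch(mode,
                  total_projection = sum(e$y_T),
                  injection_volume = e$n_injection_voxels %||% 0)
  if (is.na(denom) || denom <= 0) {
    stop_mesoconn("zero normalizer (", mode, ") for experiment ", e$id %||% "<unnamed>")
  }
  e$y_T <- e$y_T / denom
  e
}

#' Apply a lower limit of detection
#'
#' Entries strictly below `epsilon` are set to zero; the operation is
#' idempotent.
#'
#' @param y numeric vector or matrix of regionalized projections.
#' @param epsilon nonnegative detection threshold.
#' @return `y` with sub-threshold entries zeroed.
#' @export
apply_detection_limit <- function(y, epsilon) {
  if (epsilon < 0) stop_mesoconn("epsilon must be >= 0")
  y[y < epsilon] <- 0
  y
}

#' Fit a detection limit from a dataset
#'
#' Default detection threshold: the 5th percentile of the positive entries of
#' the (normalized) regionalized projections.
#'
#' @param d a [tracer_dataset()].
#' @param prob quantile of positive entries to use.
#' @return scalar threshold.
#' @export
fit_detection_limit <- function(d, prob = 0.05) {
  pos <- d$y[d$y > 0]
  if (length(pos) == 0) return(0)
  unname(quantile(pos, prob))
}

#' Construct a tracer experiment dataset
#'
#' The central data container: an experiment table with injection centroids
#' and class labels, the n x T matrix of regionalized projections, and index
#' sets by leaf, major structure and cell class recomputed deterministically
#' from centroids and labels. Experiments whose centroid falls in an
#' unannotated voxel are excluded with a warning.
#'
#' @param experiments data.frame with columns `id`, `cell_class`, `cx`, `cy`,
#'   `cz` (centroid, micrometres).
#' @param y numeric matrix (experiments x targets), columns named by the
#'   ontology's target keys.
#' @param ontology a [region_ontology].
#' @param x_S optional matrix of regionalized injections (experiments x
#'   source leafs), used by the NNLS baseline.
#' @param injections optional list of injection voxel fields.
#' @param normalization normalization mode already applied to `y`.
#' @return object of class `tracer_dataset`.
#' @export
tracer_dataset <- function(experiments, y, ontology, x_S = NULL,
                           injections = NULL, normalization = "none") {
  stopifnot(is.data.frame(experiments), is.matrix(y))
  if (nrow(experiments) != nrow(y)) stop_mesoconn("experiments and y row count mismatch")
  if (any(y < 0)) stop_mesoconn("regionalized projections must be nonnegative")
  if (is.null(colnames(y)) || !identical(colnames(y), ontology$targets$key)) {
    stop_mesoconn("columns of y must be the ontology target keys, in order")
  }
  sp <- ontology$lattice$spacing_um
  shape <- ontology$lattice$shape
  vox <- cbind(pmin(pmax(floor(experiments$cx / sp) + 1, 1), shape[1]),
               pmin(pmax(floor(experiments$cy / sp) + 1, 1), shape[2]),
               pmin(pmax(floor(experiments$cz / sp) + 1, 1), shape[3]))
  leaf <- ontology$annotation[vox]
  bad <- leaf == 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " experiment(s) with centroid in unannotated voxels: ",
            paste(experiments$id[bad], collapse = ", "))
    experiments <- experiments[!bad, , drop = FALSE]
    y <- y[!bad, , drop = FALSE]
    if (!is.null(x_S)) x_S <- x_S[!bad, , drop = FALSE]
    if (!is.null(injections)) injections <- injections[!bad]
    leaf <- leaf[!bad]
  }
  experiments$leaf_id <- leaf
  experiments$major_id <- unname(ontology$major_of[as.character(leaf)])
  if (is.null(experiments$n_injection_voxels)) {
    experiments$n_injection_voxels <- if (!is.null(injections)) {
      vapply(injections, function(f) sum(f > 0), numeric(1))
    } else NA_real_
  }
  rownames(y) <- experiments$id
  d <- structure(list(
    experiments = experiments, y = y, x_S = x_S, injections = injections,
    ontology = ontology, normalization = normalization
  ), class = "tracer_dataset")
  rebuild_index_sets(d)
}

rebuild_index_sets <- function(d) {
  e <- d$experiments
  idx <- seq_len(nrow(e))
  d$I_leaf <- split(idx, e$leaf_id)
  d$I_major <- split(idx, e$major_id)
  d$I_class <- split(idx, e$cell_class)
  d
}

#' Extract one experiment from a dataset
#'
#' @param d a [tracer_dataset()].
#' @param i row index or experiment id.
#' @return list with `id`, `cell_class`, `centroid_um`, `y_T`,
#'   `n_injection_voxels`, `leaf_id`, `major_id`.
#' @export
experiment <- function(d, i) {
  if (is.character(i)) i <- match(i, d$experiments$id)
  e <- d$experiments[i, ]
  list(id = e$id, cell_class = e$cell_class,
       centroid_um = c(e$cx, e$cy, e$cz),
       y_T = d$y[i, ], n_injection_voxels = e$n_injection_voxels,
       leaf_id = e$leaf_id, major_id = e$major_id)
}

#' Normalize all experiments in a dataset
#'
#' @param d a [tracer_dataset()].
#' @param mode normalization mode; see [normalize_experiment()].
#' @return the dataset with rescaled projections.
#' @export
normalize_dataset <- function(d, mode = c("total_projection", "injection_volume", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(d)
  denom <- switch(mode,
                  total_projection = rowSums(d$y),
                  injection_volume = d$experiments$n_injection_voxels)
  if (any(is.na(denom) | denom <= 0)) {
    stop_mesoconn("zero normalizer (", mode, ") for experiment(s): ",
                  paste(d$experiments$id[is.na(denom) | denom <= 0], collapse = ", "))
  }
  d$y <- d$y / denom
  d$normalization <- mode
  d
}

# subset a dataset to experiment indices, rebuilding index sets
dataset_subset <- function(d, idx) {
  d$experiments <- d$experiments[idx, , drop = FALSE]
  d$y <- d$y[idx, , drop = FALSE]
  if (!is.null(d$x_S)) d$x_S <- d$x_S[idx, , drop = FALSE]
  if (!is.null(d$injections)) d$injections <- d$injections[idx]
  rebuild_index_sets(d)
}

#' @export
print.tracer_dataset <- function(x, ...) {
  cat("tracer_dataset:", nrow(x$experiments), "experiments,",
      length(x$I_class), "cell classes,",
      length(x$I_leaf), "occupied leafs; normalization:", x$normalization, "\n")
  invisible(x)
}

# --- manifest / volume IO --------------------------------------------------

#' Write a dataset to a directory
#'
#' Emits a tab-separated manifest (`manifest.tsv` with id, cell_class,
#' centroid coordinates and volume paths), a regionalized projection table
#' (`regionalized.tsv`, experiments x target keys), and per-experiment
#' injection/projection volumes as text-encoded NRRD. Projection volumes are
#' synthesized from the regionalized vectors (uniform within each target) when
#' no voxel data are attached.
#'
#' @param d a [tracer_dataset()].
#' @param dir output directory.
#' @param volumes write NRRD volumes (set `FALSE` for table-only output).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(d, dir, volumes = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- d$experiments
  man <- data.frame(id = e$id, cell_class = e$cell_class,
                    centroid_x_um = e$cx, centroid_y_um = e$cy, centroid_z_um = e$cz,
                    injection_path = NA_character_, projection_path = NA_character_,
                    stringsAsFactors = FALSE)
  if (volumes) {
    sp <- d$ontology$lattice$spacing_um
    for (i in seq_len(nrow(e))) {
      pp <- file.path("volumes", paste0(e$id[i], "_projection.nrrd"))
      dir.create(file.path(dir, "volumes"), showWarnings = FALSE)
      write_nrrd(project_to_volume(d$y[i, ], d$ontology), file.path(dir, pp), sp)
      man$projection_path[i] <- pp
      if (!is.null(d$injections)) {
        ip <- file.path("volumes", paste0(e$id[i], "_injection.nrrd"))
        write_nrrd(d$injections[[i]], file.path(dir, ip), sp)
        man$injection_path[i] <- ip
      }
    }
  }
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  reg <- data.frame(id = e$id, d$y, check.names = FALSE)
  write.table(reg, file.path(dir, "regionalized.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a dataset from a directory
#'
#' Reads `manifest.tsv`; regionalized projections come from projection NRRD
#' volumes when present, otherwise from `regionalized.tsv`.
#'
#' @param dir directory written by [write_dataset()].
#' @param ontology a [region_ontology].
#' @param normalization normalization mode recorded for the data.
#' @return a [tracer_dataset()].
#' @export
read_dataset <- function(dir, ontology, normalization = "none") {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop_mesoconn("manifest not found: ", mpath)
  man <- read.delim(mpath, stringsAsFactors = FALSE)
  n <- nrow(man)
  keys <- ontology$targets$key
  injections <- NULL
  if (all(!is.na(man$projection_path))) {
    y <- t(vapply(seq_len(n), function(i) {
      vol <- read_nrrd(file.path(dir, man$projection_path[i]))
      regionalize(vol, ontology)
    }, numeric(length(keys))))
  } else {
    reg <- read.delim(file.path(dir, "regionalized.tsv"), check.names = FALSE,
                      stringsAsFactors = FALSE)
    y <- as.matrix(reg[match(man$id, reg$id), keys, drop = FALSE])
  }
  colnames(y) <- keys
  if (any(!is.na(man$injection_path))) {
    injections <- lapply(seq_len(n), function(i) {
      if (is.na(man$injection_path[i])) NULL
      else read_nrrd(file.path(dir, man$injection_path[i]))
    })
  }
  experiments <- data.frame(id = as.character(man$id), cell_class = man$cell_class,
                            cx = man$centroid_x_um, cy = man$centroid_y_um,
                            cz = man$centroid_z_um, stringsAsFactors = FALSE)
  x_S <- NULL
  if (!is.null(injections) && all(!vapply(injections, is.null, logical(1)))) {
    x_S <- t(vapply(injections, regionalize_injection, ontology = ontology,
                    numeric(nrow(ontology$sources))))
    colnames(x_S) <- ontology$sources$acronym
  }
  tracer_dataset(experiments, y, ontology, x_S = x_S, injections = injections,
                 normalization = normalization)
}
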