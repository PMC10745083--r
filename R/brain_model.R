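#' Voxel lattice
#'
#' A regular 3D grid of cubic voxels at fixed spacing (default 100 um, the
#' resolution at which tracer fluorescence is quantified). Voxel indices are
#' 1-based in R; the physical centre of voxel (i, j, k) is
#' `(c(i, j, k) - 0.5) * spacing_um`.
#'
#' @param shape integer triple (nx, ny, nz).
#' @param spacing_um positive voxel edge length in micrometres.
#' @param brain_mask optional logical array marking in-brain voxels; defaults
#'   to all `TRUE`.
#' @return an object of class `voxel_lattice`.
#' @export
voxel_lattice <- function(shape, spacing_um = 100, brain_mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1)) stop_mesoconn("shape must be 3 positive integers")
  if (!is.numeric(spacing_um) || spacing_um <= 0) stop_mesoconn("spacing_um must be > 0")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = shape)
  if (!identical(dim(brain_mask), shape)) stop_mesoconn("brain_mask dimensions must equal shape")
  structure(list(shape = shape, spacing_um = spacing_um, brain_mask = brain_mask),
            class = "voxel_lattice")
}

# physical centres (um) of voxel index rows (n x 3 matrix, 1-based indices)
voxel_centers_um <- function(idx, spacing_um) {
  (idx - 0.5) * spacing_um
}

# --- structure graph -------------------------------------------------------

# Normalize an Allen-dialect structure graph into a data.frame
# (id, acronym, parent_structure_id). Accepts a flat record list, a
# {"msg": [...]} wrapper, or a nested tree with "children".
flatten_structure_graph <- function(x) {
  if (is.list(x) && !is.null(x$msg)) x <- x$msg
  rows <- list()
  visit <- function(node) {
    rows[[length(rows) + 1]] <<- data.frame(
      id = as.integer(node$id),
      acronym = as.character(node$acronym %||% paste0("id", node$id)),
      parent_structure_id = as.integer(node$parent_structure_id %||% NA_integer_),
      stringsAsFactors = FALSE
    )
    for (ch in node$children %||% list()) visit(ch)
  }
  if (!is.null(x$id)) visit(x) else for (node in x) visit(node)
  do.call(rbind, rows)
}

validate_structure_graph <- function(nodes) {
  if (anyDuplicated(nodes$id)) stop_mesoconn("duplicate structure ids in ontology")
  known <- nodes$id
  bad <- !is.na(nodes$parent_structure_id) & !(nodes$parent_structure_id %in% known)
  if (any(bad)) {
    stop_mesoconn("orphan ontology node(s): ",
                  paste0(nodes$id[bad], " (unknown parent ",
                         nodes$parent_structure_id[bad], ")", collapse = ", "))
  }
  roots <- nodes$id[is.na(nodes$parent_structure_id)]
  if (length(roots) != 1) stop_mesoconn("ontology must have exactly one root, found ", length(roots))
  # cycle check: every node must reach the root
  parent <- setNames(nodes$parent_structure_id, nodes$id)
  for (id in nodes$id) {
    seen <- integer(0)
    cur <- id
    while (!is.na(parent[[as.character(cur)]])) {
      if (cur %in% seen) stop_mesoconn("cyclic parent links in ontology at id ", id)
      seen <- c(seen, cur)
      cur <- parent[[as.character(cur)]]
    }
  }
  invisible(nodes)
}

#' Region ontology from a structure graph and annotation volume
#'
#' Builds the hierarchical region bookkeeping used throughout the package:
#' leaf structures (annotated nodes with no annotated descendants), their
#' assignment to major brain divisions, hemisphere-split voxel sets, the
#' source set (leafs of the designated hemisphere) and the target set
#' (ipsilateral plus contralateral leaf instances).
#'
#' Hemispheres are split at the lattice midline along the third axis; the
#' designated source hemisphere is the lower half ("L"). A leaf whose voxels
#' lie entirely on the source side (e.g., a midline structure) contributes an
#' ipsilateral target only, which is why the contralateral target count can be
#' smaller than the source count.
#'
#' @param nodes data.frame with columns `id`, `acronym`, `parent_structure_id`
#'   (NA for the root).
#' @param annotation integer 3D array of structure ids (0 = unannotated).
#' @param lattice a [voxel_lattice].
#' @return object of class `region_ontology` with elements `nodes`, `lattice`,
#'   `annotation`, `sources` (data.frame leaf_id/acronym/n_voxels),
#'   `targets` (data.frame key/leaf_id/acronym/hemisphere/n_voxels), and
#'   per-region voxel index sets.
#' @export
region_ontology <- function(nodes, annotation, lattice) {
  validate_structure_graph(nodes)
  if (!identical(dim(annotation), lattice$shape)) {
    stop_mesoconn("annotation dimensions must equal lattice shape")
  }
  ann_ids <- sort(unique(as.vector(annotation)))
  ann_ids <- ann_ids[ann_ids != 0]
  unknown <- ann_ids[!(ann_ids %in% nodes$id)]
  if (length(unknown) > 0) {
    stop_mesoconn("annotation labels absent from structure graph: ",
                  paste(unknown, collapse = ", "))
  }
  # leafs: annotated nodes with no annotated descendants
  has_ann_desc <- vapply(nodes$id, function(id) {
    desc <- descendants(nodes, id)
    any(desc %in% ann_ids)
  }, logical(1))
  leaf_ids <- ann_ids[!has_ann_desc[match(ann_ids, nodes$id)]]
  non_leaf_ann <- setdiff(ann_ids, leaf_ids)
  if (length(non_leaf_ann) > 0) {
    warning("annotated structures with annotated descendants are not leafs: ",
            paste(non_leaf_ann, collapse = ", "))
  }
  root_id <- nodes$id[is.na(nodes$parent_structure_id)]
  parent <- setNames(nodes$parent_structure_id, nodes$id)
  major_of <- vapply(leaf_ids, function(id) {
    cur <- id
    repeat {
      p <- parent[[as.character(cur)]]
      if (is.na(p) || p == root_id) return(cur)
      cur <- p
    }
  }, numeric(1))
  names(major_of) <- leaf_ids
  acronym_of <- setNames(nodes$acronym, nodes$id)

  nz <- lattice$shape[3]
  left_max <- ceiling(nz / 2)  # source hemisphere: z index <= midline
  vox <- which(annotation != 0, arr.ind = TRUE)
  vox_id <- annotation[vox]
  hemi <- ifelse(vox[, 3] <= left_max, "L", "R")
  keykey <- paste0(vox_id, ":", hemi)
  voxels <- split(seq_len(nrow(vox)), keykey)
  voxels <- lapply(voxels, function(i) vox[i, , drop = FALSE])

  src <- data.frame(leaf_id = leaf_ids,
                    acronym = unname(acronym_of[as.character(leaf_ids)]),
                    stringsAsFactors = FALSE)
  src$n_voxels <- vapply(src$leaf_id, function(id) {
    v <- voxels[[paste0(id, ":L")]]
    if (is.null(v)) 0L else nrow(v)
  }, integer(1))
  src <- src[src$n_voxels >= 1, , drop = FALSE]
  rownames(src) <- NULL

  tgt <- do.call(rbind, lapply(leaf_ids, function(id) {
    acr <- acronym_of[[as.character(id)]]
    out <- list()
    vL <- voxels[[paste0(id, ":L")]]
    vR <- voxels[[paste0(id, ":R")]]
    if (!is.null(vL)) {
      out[[length(out) + 1]] <- data.frame(
        key = paste0(acr, "_ipsi"), leaf_id = id, acronym = acr,
        hemisphere = "ipsi", n_voxels = nrow(vL), stringsAsFactors = FALSE)
    }
    if (!is.null(vR)) {
      out[[length(out) + 1]] <- data.frame(
        key = paste0(acr, "_contra"), leaf_id = id, acronym = acr,
        hemisphere = "contra", n_voxels = nrow(vR), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }))
  tgt <- tgt[order(tgt$hemisphere == "contra", tgt$leaf_id), , drop = FALSE]
  rownames(tgt) <- NULL

  structure(list(
    nodes = nodes, lattice = lattice, annotation = annotation,
    root_id = root_id, leaf_ids = leaf_ids, major_of = major_of,
    acronym_of = acronym_of, sources = src, targets = tgt, voxels = voxels
  ), class = "region_ontology")
}

descendants <- function(nodes, id) {
  out <- integer(0)
  frontier <- id
  repeat {
    ch <- nodes$id[!is.na(nodes$parent_structure_id) &
                     nodes$parent_structure_id %in% frontier]
    if (length(ch) == 0) break
    out <- c(out, ch)
    frontier <- ch
  }
  out
}

#' Load a region ontology from files
#'
#' Reads a structure graph in the Allen structure-graph JSON dialect (fields
#' `id`, `acronym`, `parent_structure_id`; flat list, `msg`-wrapped list, or
#' nested `children` tree) together with an annotation volume aligned to the
#' lattice.
#'
#' @param json_path path to the structure-graph JSON.
#' @param annotation integer 3D array of structure ids, or a path to a
#'   text-encoded NRRD volume of ids.
#' @param lattice a [voxel_lattice]; defaults to one matching the annotation
#'   at 100 um spacing.
#' @return a [region_ontology].
#' @export
load_ontology <- function(json_path, annotation, lattice = NULL) {
  if (!file.exists(json_path)) stop_mesoconn("ontology file not found: ", json_path)
  x <- jsonlite::read_json(json_path)
  nodes <- flatten_structure_graph(x)
  if (is.character(annotation)) {
    vol <- read_nrrd(annotation)
    sp <- attr(vol, "spacing_um") %||% 100
    annotation <- array(as.integer(round(vol)), dim = dim(vol))
    if (is.null(lattice)) lattice <- voxel_lattice(dim(annotation), spacing_um = sp)
  }
  if (is.null(lattice)) lattice <- voxel_lattice(dim(annotation))
  region_ontology(nodes, annotation, lattice)
}

#' Write an ontology's structure graph and annotation volume
#'
#' @param ontology a [region_ontology].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly. Writes `structure_graph.json` and
#'   `annotation.nrrd`.
#' @export
write_ontology <- function(ontology, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  msg <- lapply(seq_len(nrow(ontology$nodes)), function(i) {
    r <- ontology$nodes[i, ]
    list(id = r$id, acronym = r$acronym,
         parent_structure_id = if (is.na(r$parent_structure_id)) NULL else r$parent_structure_id)
  })
  jsonlite::write_json(list(msg = msg), file.path(dir, "structure_graph.json"),
                       auto_unbox = TRUE, null = "null")
  write_nrrd(ontology$annotation, file.path(dir, "annotation.nrrd"),
             spacing_um = ontology$lattice$spacing_um)
  invisible(dir)
}

# resolve a region argument to a voxel index matrix.
# Accepts a target key ("ACR_ipsi"/"ACR_contra"), a source acronym or leaf id
# (interpreted in the source hemisphere).
region_voxels <- function(ontology, region) {
  if (is.character(region) && region %in% ontology$targets$key) {
    row <- ontology$targets[ontology$targets$key == region, ]
    hemi <- if (row$hemisphere == "ipsi") "L" else "R"
    return(ontology$voxels[[paste0(row$leaf_id, ":", hemi)]])
  }
  if (is.character(region)) {
    id <- ontology$leaf_ids[ontology$acronym_of[as.character(ontology$leaf_ids)] == region]
    if (length(id) != 1) stop_mesoconn("unknown region: ", region)
    region <- id
  }
  ontology$voxels[[paste0(region, ":L")]]
}

#' Distance between two regions
#'
#' Either the Euclidean distance between the voxel-centre means of the two
#' regions (`centroid`), or the minimum pairwise voxel-centre distance
#' (`min_voxel`). The default is `min_voxel`: the short-range artifacts the
#' distal mask removes arise at region borders, not centroids.
#'
#' @param ontology a [region_ontology].
#' @param a,b regions: a target key (`"ACR_ipsi"`/`"ACR_contra"`), a source
#'   acronym, or a leaf id (interpreted in the source hemisphere).
#' @param mode `"min_voxel"` or `"centroid"`.
#' @return nonnegative distance in micrometres.
#' @export
region_distance <- function(ontology, a, b, mode = c("min_voxel", "centroid")) {
  mode <- match.arg(mode)
  va <- region_voxels(ontology, a)
  vb <- region_voxels(ontology, b)
  if (is.null(va) || nrow(va) == 0) stop_mesoconn("region has no voxels: ", a)
  if (is.null(vb) || nrow(vb) == 0) stop_mesoconn("region has no voxels: ", b)
  sp <- ontology$lattice$spacing_um
  pa <- voxel_centers_um(va, sp)
  pb <- voxel_centers_um(vb, sp)
  if (mode == "centroid") {
    sqrt(sum((colMeans(pa) - colMeans(pb))^2))
  } else {
    d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
    sqrt(max(0, min(d2)))
  }
}

#' Implied contralateral target count
#'
#' In a parcellation with one designated source hemisphere, the target set is
#' the union of ipsilateral leaf instances (one per source leaf) and
#' contralateral instances, so the contralateral count implied by printed
#' source and target totals is `n_targets - n_sources`.
#'
#' @param n_sources number of source leafs (one hemisphere).
#' @param n_targets total number of targets (ipsilateral + contralateral).
#' @return the implied number of contralateral targets.
#' @export
implied_contralateral_count <- function(n_sources, n_targets) {
  if (n_targets < n_sources) stop_mesoconn("n_targets must be >= n_sources")
  n_targets - n_sources
}

#' @export
print.region_ontology <- function(x, ...) {
  cat("region_ontology:", nrow(x$nodes), "nodes,",
      length(x$leaf_ids), "leafs,",
      nrow(x$sources), "source leafs,",
      nrow(x$targets), "targets (",
      sum(x$targets$hemisphere == "ipsi"), "ipsi +",
      sum(x$targets$hemisphere == "contra"), "contra )\n")
  invisible(x)
}
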