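# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles deliberately re-derive quantities with plain loops so they
# share no code with the implementation paths they check.

oracle_nw <- function(loc, centroids, Y, sigma) {
  w <- numeric(nrow(centroids))
  for (i in seq_len(nrow(centroids))) {
    w[i] <- exp(-sum((loc - centroids[i, ])^2) / (2 * sigma^2))
  }
  out <- numeric(ncol(Y))
  for (i in seq_len(nrow(centroids))) out <- out + w[i] * Y[i, ]
  out / sum(w)
}

oracle_cosine_dist <- function(a, b) {
  1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

oracle_l2 <- function(y, yhat) {
  s <- 0
  for (t in seq_along(y)) s <- s + (y[t] - yhat[t])^2
  s
}

# small two-major, two-leaf-per-major brain shared by many tests
toy_brain <- function() make_brain(2, 2, c(4, 4, 4))

# dataset from explicit centroids (um) and projection rows
manual_dataset <- function(ont, cell_class, centroids, y, x_S = NULL) {
  stopifnot(nrow(centroids) == length(cell_class), nrow(y) == length(cell_class))
  colnames(y) <- ont$targets$key
  experiments <- data.frame(id = sprintf("e%02d", seq_along(cell_class)),
                            cell_class = cell_class,
                            cx = centroids[, 1], cy = centroids[, 2],
                            cz = centroids[, 3], stringsAsFactors = FALSE)
  tracer_dataset(experiments, y, ont, x_S = x_S)
}

# random in-leaf centroids (um) for a leaf of a toy brain
random_leaf_points <- function(ont, leaf_id, n) {
  vox <- ont$voxels[[paste0(leaf_id, ":L")]]
  lo <- apply(vox, 2, min); hi <- apply(vox, 2, max)
  sp <- ont$lattice$spacing_um
  t(replicate(n, (lo - 0.5 + runif(3) * (hi - lo)) * sp))
}

random_y <- function(n, Tn) matrix(rgamma(n * Tn, 1.5), n, Tn)

# structure-graph JSON written to a temp file
write_tree_json <- function(records) {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(msg = records), path, auto_unbox = TRUE, null = "null")
  path
}
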