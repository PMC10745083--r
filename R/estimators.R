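#' Build the cell-class space
#'
#' Embeds every cell class by its averaged regionalized projection pattern
#' and equips the set of classes with a distance. Projection rows are
#' unit-sum normalized before averaging regardless of the dataset's
#' normalization, so the space reflects projection *shape*, not tracer
#' magnitude. The default distance is one minus cosine similarity of the
#' global class embeddings.
#'
#' @param d a [tracer_dataset()].
#' @param metric `"cosine"` (1 - cosine similarity) or `"euclidean"`.
#' @param exclude experiment indices to leave out (used during
#'   cross-validation refits).
#' @return object of class `class_space`: global embeddings (class x T),
#'   per-(class, leaf) mean projections, and the class distance matrix.
#' @export
build_class_space <- function(d, metric = c("cosine", "euclidean"),
                              exclude = integer(0)) {
  metric <- match.arg(metric)
  keep <- setdiff(seq_len(nrow(d$y)), exclude)
  if (length(keep) == 0) stop_mesoconn("class space needs at least one experiment")
  y <- d$y[keep, , drop = FALSE]
  rs <- rowSums(y)
  ok <- rs > 0
  yn <- y[ok, , drop = FALSE] / rs[ok]
  cls <- d$experiments$cell_class[keep][ok]
  leaf <- d$experiments$leaf_id[keep][ok]
  classes <- sort(unique(d$experiments$cell_class))
  present <- classes[classes %in% cls]
  if (length(present) == 0) stop_mesoconn("no class has a usable experiment")
  global <- t(vapply(present, function(v) colMeans(yn[cls == v, , drop = FALSE]),
                     numeric(ncol(yn))))
  rownames(global) <- present
  leaf_means <- tapply(seq_along(cls), list(cls, leaf), function(i) {
    colMeans(yn[i, , drop = FALSE])
  })
  D <- matrix(0, length(present), length(present),
              dimnames = list(present, present))
  if (length(present) > 1) {
    for (i in seq_along(present)) {
      for (j in seq_along(present)) {
        if (i < j) {
          D[i, j] <- D[j, i] <- class_embedding_distance(global[i, ], global[j, ], metric)
        }
      }
    }
  }
  structure(list(classes = present, global = global, leaf_means = leaf_means,
                 distance = D, metric = metric),
            class = "class_space")
}

class_embedding_distance <- function(a, b, metric) {
  if (metric == "euclidean") return(sqrt(sum((a - b)^2)))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(1)
  1 - sum(a * b) / (na * nb)
}

#' Distance between two classes in class space
#'
#' Classes absent from the space (possible after exclusions) are assigned the
#' largest observed distance, a conservative "maximally dissimilar" default.
#'
#' @param cs a `class_space`.
#' @param v,vp class labels.
#' @return nonnegative scalar, 0 when `v == vp`.
#' @export
class_distance <- function(cs, v, vp) {
  if (identical(v, vp)) return(0)
  if (v %in% cs$classes && vp %in% cs$classes) return(cs$distance[v, vp])
  if (length(cs$classes) < 2) return(1)
  max(cs$distance)
}

# Gaussian kernel log-weights, normalized stably via max-shift
kernel_weights <- function(log_w) {
  w <- exp(log_w - max(log_w))
  w / sum(w)
}

#' Nadaraya-Watson projection prediction
#'
#' Kernel-weighted average of the support experiments' regionalized
#' projections with a Gaussian spatial kernel:
#' \eqn{\hat f(x) = \sum_i K(\|x - c_i\|/\sigma_x) y_i / \sum_i K(\cdot)}.
#' The result is a convex combination of the support rows.
#'
#' @param loc 3-vector, micrometres.
#' @param centroids support centroid matrix (n x 3, micrometres).
#' @param Y support projection matrix (n x T).
#' @param sigma_x spatial bandwidth, micrometres.
#' @return named T-vector, or `NULL` (missing) for empty support.
#' @export
nw_predict <- function(loc, centroids, Y, sigma_x) {
  if (is.null(centroids) || nrow(centroids) == 0) return(NULL)
  if (sigma_x <= 0) stop_mesoconn("sigma_x must be > 0")
  d2 <- colSums((t(centroids) - loc)^2)
  w <- kernel_weights(-d2 / (2 * sigma_x^2))
  drop(crossprod(w, Y))
}

# leaf (annotation id) containing a micrometre location, 0 if unannotated
leaf_at <- function(ontology, loc) {
  sp <- ontology$lattice$spacing_um
  shape <- ontology$lattice$shape
  v <- pmin(pmax(floor(loc / sp) + 1, 1), shape)
  ontology$annotation[matrix(v, nrow = 1)]
}

#' Class-restricted Nadaraya-Watson prediction
#'
#' Nadaraya-Watson smoothing using only same-class experiments with centroids
#' in the leaf containing `loc` (support \eqn{I_l \cap I_v}).
#'
#' @param loc 3-vector, micrometres; must fall in an annotated leaf.
#' @param v cell class label.
#' @param d a [tracer_dataset()].
#' @param sigma_x spatial bandwidth, micrometres.
#' @param exclude experiment indices excluded from the support.
#' @return named T-vector, or `NULL` when the leaf holds no class-`v`
#'   centroid.
#' @export
cre_nw_predict <- function(loc, v, d, sigma_x, exclude = integer(0)) {
  l <- leaf_at(d$ontology, loc)
  sup <- intersect(d$I_leaf[[as.character(l)]], d$I_class[[v]])
  sup <- setdiff(sup, exclude)
  if (length(sup) == 0) return(NULL)
  nw_predict(loc, as.matrix(d$experiments[sup, c("cx", "cy", "cz")]),
             d$y[sup, , drop = FALSE], sigma_x)
}

# class-leaf / class / leaf mean projections with exclusions (fallback chain)
class_leaf_mean <- function(d, v, l, exclude = integer(0)) {
  sup <- setdiff(intersect(d$I_leaf[[as.character(l)]], d$I_class[[v]]), exclude)
  if (length(sup) == 0) return(NULL)
  colMeans(d$y[sup, , drop = FALSE])
}
class_mean <- function(d, v, exclude = integer(0)) {
  sup <- setdiff(d$I_class[[v]], exclude)
  if (length(sup) == 0) return(NULL)
  colMeans(d$y[sup, , drop = FALSE])
}
leaf_mean <- function(d, l, exclude = integer(0)) {
  sup <- setdiff(d$I_leaf[[as.character(l)]], exclude)
  if (length(sup) == 0) return(NULL)
  colMeans(d$y[sup, , drop = FALSE])
}

# m(v, l): class-leaf mean with documented fallback chain
el_class_term <- function(d, v, l, exclude = integer(0)) {
  class_leaf_mean(d, v, l, exclude) %||%
    class_mean(d, v, exclude) %||%
    leaf_mean(d, l, exclude)
}

#' Expected-loss (EL) projection prediction
#'
#' Blends the regionally averaged class projection with a product-kernel
#' regression over all experiments in the leaf, regardless of class:
#' \deqn{\hat f = \alpha\, m(v, l) + (1-\alpha)\, g(x, v, l),}
#' where \eqn{m(v, l)} is the class-leaf mean projection (falling back to the
#' global class mean, then to the all-class leaf mean, when the class has no
#' centroid in the leaf) and \eqn{g} is a Nadaraya-Watson regression over
#' \eqn{I_l} with weights
#' \eqn{K(\|x - c_i\|/\sigma_x)\, K(d_V(v, v_i)/\sigma_c)}. Large
#' \eqn{\sigma_c} recovers class-agnostic spatial smoothing; small
#' \eqn{\sigma_c} concentrates on same-class experiments.
#'
#' @param loc 3-vector, micrometres; must fall in a leaf with experiments.
#' @param v cell class label.
#' @param d a [tracer_dataset()].
#' @param sigma_x spatial bandwidth, micrometres.
#' @param sigma_c class-space bandwidth.
#' @param alpha blend weight in \[0, 1\] on the class-mean term.
#' @param class_space optional precomputed [build_class_space()] result
#'   consistent with `exclude`.
#' @param exclude experiment indices excluded from all data-dependent terms.
#' @return named T-vector, or `NULL` when the leaf holds no experiments.
#' @export
el_predict <- function(loc, v, d, sigma_x, sigma_c, alpha,
                       class_space = NULL, exclude = integer(0)) {
  if (alpha < 0 || alpha > 1) stop_mesoconn("alpha must be in [0, 1]")
  if (sigma_x <= 0 || sigma_c <= 0) stop_mesoconn("bandwidths must be > 0")
  l <- leaf_at(d$ontology, loc)
  sup <- setdiff(d$I_leaf[[as.character(l)]], exclude)
  if (length(sup) == 0) return(NULL)
  m <- el_class_term(d, v, l, exclude)
  if (alpha == 1) return(m)
  if (is.null(class_space)) class_space <- build_class_space(d, exclude = exclude)
  cent <- as.matrix(d$experiments[sup, c("cx", "cy", "cz")])
  d2 <- colSums((t(cent) - loc)^2)
  dv <- vapply(d$experiments$cell_class[sup], class_distance, numeric(1),
               cs = class_space, v = v)
  w <- kernel_weights(-d2 / (2 * sigma_x^2) - dv^2 / (2 * sigma_c^2))
  g <- drop(crossprod(w, d$y[sup, , drop = FALSE]))
  alpha * m + (1 - alpha) * g
}

#' Nonnegative least-squares connectivity fit
#'
#' Baseline linear model predicting regionalized projections from
#' regionalized injections: minimizes \eqn{\|XW - Y\|_2^2} subject to
#' \eqn{W \ge 0}, solved per target column. The prediction for a source
#' region `s` is row `s` of `W` (the response to the indicator injection).
#'
#' @param X regionalized injection matrix (experiments x sources).
#' @param Y regionalized projection matrix (experiments x targets),
#'   nonnegative.
#' @return nonnegative S x T matrix `W`; rows for all-zero injection columns
#'   are zero, with a warning.
#' @export
nnls_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_mesoconn("X and Y must have the same number of rows")
  if (any(Y < 0)) stop_mesoconn("Y must be nonnegative")
  dead <- colSums(abs(X)) == 0
  if (any(dead)) {
    warning("all-zero injection column(s); corresponding rows set to 0: ",
            paste(colnames(X)[dead] %||% which(dead), collapse = ", "))
  }
  W <- matrix(0, ncol(X), ncol(Y), dimnames = list(colnames(X), colnames(Y)))
  Xr <- X[, !dead, drop = FALSE]
  for (t in seq_len(ncol(Y))) {
    W[!dead, t] <- pracma::lsqnonneg(Xr, Y[, t])$x
  }
  W
}

# --- estimator model -------------------------------------------------------

#' Construct an estimator model specification
#'
#' The four predictor families and their training/prediction index-set
#' policies: `nnls` (linear NNLS, trained and predicting within the major
#' structure), `nw` (class-agnostic spatial smoothing over the major
#' structure), `cre_nw` (spatial smoothing over same-class experiments in the
#' leaf), and `el` (class-mean / product-kernel blend over the leaf).
#'
#' @param kind one of `"nnls"`, `"nw"`, `"cre_nw"`, `"el"`.
#' @param sigma_x spatial bandwidth (um); required for kernel kinds.
#' @param sigma_c class-space bandwidth; `el` only.
#' @param alpha blend weight in \[0, 1\]; `el` only.
#' @param normalization normalization mode the model expects its data in.
#' @return object of class `estimator_model` with a hyperparameter table
#'   (one global row; [select_hyperparameters()] installs per-major rows).
#' @export
estimator_model <- function(kind = c("el", "nw", "cre_nw", "nnls"),
                            sigma_x = NULL, sigma_c = NULL, alpha = NULL,
                            normalization = "none") {
  kind <- match.arg(kind)
  if (kind %in% c("nw", "cre_nw", "el")) {
    if (is.null(sigma_x) || sigma_x <= 0) stop_mesoconn("sigma_x must be > 0 for ", kind)
  }
  if (kind == "el") {
    if (is.null(sigma_c) || sigma_c <= 0) stop_mesoconn("sigma_c must be > 0 for el")
    if (is.null(alpha) || alpha < 0 || alpha > 1) stop_mesoconn("alpha must be in [0, 1] for el")
  }
  hp <- data.frame(major_id = NA_real_,
                   sigma_x = sigma_x %||% NA_real_,
                   sigma_c = sigma_c %||% NA_real_,
                   alpha = alpha %||% NA_real_)
  structure(list(kind = kind, hp = hp, normalization = normalization, W = NULL),
            class = "estimator_model")
}

get_hp <- function(model, major_id) {
  hp <- model$hp
  row <- hp[!is.na(hp$major_id) & hp$major_id == major_id, ]
  if (nrow(row) == 0) row <- hp[is.na(hp$major_id), ]
  if (nrow(row) == 0) row <- hp[1, ]
  row[1, ]
}

#' Fit an estimator on a dataset
#'
#' Kernel models are lazy (all work happens at prediction); the NNLS baseline
#' fits and caches one weight matrix per major structure, using the sources
#' of that major as predictors.
#'
#' @param model an [estimator_model()].
#' @param d a [tracer_dataset()] with `x_S` present for `nnls`.
#' @return the fitted model.
#' @export
fit_estimator <- function(model, d) {
  if (model$kind == "nnls") {
    if (is.null(d$x_S)) stop_mesoconn("nnls requires regionalized injections (x_S)")
    model$W <- lapply(names(d$I_major), function(m) {
      idx <- d$I_major[[m]]
      cols <- major_source_columns(d, as.numeric(m))
      nnls_fit(d$x_S[idx, cols, drop = FALSE], d$y[idx, , drop = FALSE])
    })
    names(model$W) <- names(d$I_major)
  }
  model
}

major_source_columns <- function(d, major_id) {
  src <- d$ontology$sources
  src$acronym[d$ontology$major_of[as.character(src$leaf_id)] == major_id]
}

#' Predict a regionalized projection vector
#'
#' Dispatches on the model kind, applying its index-set policy (see
#' [estimator_model()]); `exclude` removes experiments from every
#' data-dependent quantity, which is how leave-one-out refitting is realized.
#'
#' @param model a (fitted) [estimator_model()].
#' @param d a [tracer_dataset()].
#' @param loc 3-vector, micrometres.
#' @param v cell class label (used by `cre_nw` and `el`).
#' @param exclude experiment indices to exclude.
#' @param x_s regionalized injection vector of the experiment being predicted
#'   (`nnls` only; named by source acronym).
#' @param class_space optional precomputed class space consistent with
#'   `exclude` (`el` only).
#' @return named T-vector or `NULL` when the model's support is empty.
#' @export
predict_projection <- function(model, d, loc, v = NULL, exclude = integer(0),
                               x_s = NULL, class_space = NULL) {
  l <- leaf_at(d$ontology, loc)
  if (l == 0) return(NULL)
  m_id <- unname(d$ontology$major_of[as.character(l)])
  hp <- get_hp(model, m_id)
  switch(model$kind,
    nw = {
      sup <- setdiff(d$I_major[[as.character(m_id)]], exclude)
      if (length(sup) == 0) return(NULL)
      nw_predict(loc, as.matrix(d$experiments[sup, c("cx", "cy", "cz")]),
                 d$y[sup, , drop = FALSE], hp$sigma_x)
    },
    cre_nw = cre_nw_predict(loc, v, d, hp$sigma_x, exclude = exclude),
    el = el_predict(loc, v, d, hp$sigma_x, hp$sigma_c, hp$alpha,
                    class_space = class_space, exclude = exclude),
    nnls = {
      if (is.null(x_s)) stop_mesoconn("nnls prediction requires x_s")
      cols <- major_source_columns(d, m_id)
      W <- if (length(exclude) == 0 && !is.null(model$W)) {
        model$W[[as.character(m_id)]]
      } else {
        idx <- setdiff(d$I_major[[as.character(m_id)]], exclude)
        if (length(idx) == 0) return(NULL)
        suppressWarnings(nnls_fit(d$x_S[idx, cols, drop = FALSE],
                                  d$y[idx, , drop = FALSE]))
      }
      drop(x_s[cols] %*% W)
    })
}

#' @export
print.estimator_model <- function(x, ...) {
  cat("estimator_model:", x$kind, "\n")
  print(x$hp, row.names = FALSE)
  invisible(x)
}
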