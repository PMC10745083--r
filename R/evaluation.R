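#' Squared-error (l2) loss between projection vectors
#'
#' @param y,yhat equal-length numeric vectors.
#' @return \eqn{\sum_t (y_t - \hat y_t)^2}.
#' @export
l2_loss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop_mesoconn("l2_loss: length mismatch")
  sum((y - yhat)^2)
}

#' Evaluation set: (leaf, class) cells present at least twice
#'
#' Restricting evaluation to leaf/class combinations with two or more
#' experiments makes leave-one-out prediction well defined for every model,
#' including the class-restricted ones.
#'
#' @param d a [tracer_dataset()].
#' @return data.frame with `leaf_id`, `major_id`, `cell_class`, `n`
#'   (`n >= 2`); zero rows when no cell qualifies.
#' @export
eval_set <- function(d) {
  e <- d$experiments
  tab <- as.data.frame(table(leaf_id = e$leaf_id, cell_class = e$cell_class),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq >= 2, , drop = FALSE]
  out <- data.frame(leaf_id = as.numeric(tab$leaf_id),
                    cell_class = tab$cell_class, n = tab$Freq,
                    stringsAsFactors = FALSE)
  out$major_id <- unname(d$ontology$major_of[as.character(out$leaf_id)])
  out <- out[order(out$leaf_id, out$cell_class), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("major_id", "leaf_id", "cell_class", "n")]
}

#' Weighted l2-loss under leave-one-out cross-validation
#'
#' For every experiment `i` in every evaluation cell (leaf `s`, class `v`
#' with \eqn{|I_s \cap I_v| \ge 2}), all data-dependent quantities (class
#' space, class means, NNLS fits) are recomputed on the dataset without `i`,
#' the model predicts at `(c(i), v_i)`, and the squared error against
#' \eqn{y_T(i)} is accumulated. The overall loss weights rare cells up:
#' \deqn{\mathcal{L} = \frac{1}{|\mathcal{SV}|} \sum_{(s,v)}
#'   \frac{1}{|I_s \cap I_v|} \sum_{i} \ell_i.}
#'
#' A missing held-out prediction falls back to the class-mean chain (class-
#' leaf mean, global class mean, leaf mean, all without `i`); if even that is
#' empty the prediction is the detection-limit-floored zero vector. Fallbacks
#' are counted, never silently dropped.
#'
#' @param model an [estimator_model()].
#' @param d a [tracer_dataset()].
#' @param detection_limit threshold applied to observed and predicted vectors
#'   before scoring (0 disables).
#' @param cells evaluation cells, default [eval_set()].
#' @param class_spaces optional list (indexed by experiment) of precomputed
#'   leave-one-out class spaces, for grid searches.
#' @return object of class `evaluation_report`: per-cell mean losses,
#'   per-major aggregates, the overall weighted loss, and fallback counts.
#' @export
loocv_weighted_loss <- function(model, d, detection_limit = 0,
                                cells = eval_set(d), class_spaces = NULL) {
  if (nrow(cells) == 0) stop_mesoconn("evaluation set is empty")
  n_fallback <- 0L
  n_zero <- 0L
  losses_by_cell <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    l <- cells$leaf_id[k]; v <- cells$cell_class[k]
    idx <- intersect(d$I_leaf[[as.character(l)]], d$I_class[[v]])
    losses <- vapply(idx, function(i) {
      cs <- if (model$kind == "el") {
        if (!is.null(class_spaces)) class_spaces[[i]] else build_class_space(d, exclude = i)
      } else NULL
      pred <- predict_projection(model, d,
                                 loc = c(d$experiments$cx[i], d$experiments$cy[i],
                                         d$experiments$cz[i]),
                                 v = v, exclude = i,
                                 x_s = if (!is.null(d$x_S)) d$x_S[i, ] else NULL,
                                 class_space = cs)
      if (is.null(pred)) {
        pred <- el_class_term(d, v, l, exclude = i)
        if (is.null(pred)) {
          pred <- rep(0, ncol(d$y))
          n_zero <<- n_zero + 1L
        } else {
          n_fallback <<- n_fallback + 1L
        }
      }
      yi <- d$y[i, ]
      if (detection_limit > 0) {
        yi <- apply_detection_limit(yi, detection_limit)
        pred <- apply_detection_limit(pred, detection_limit)
      }
      l2_loss(yi, pred)
    }, numeric(1))
    losses_by_cell[[k]] <- losses
  }
  cells$mean_loss <- vapply(losses_by_cell, mean, numeric(1))
  per_major <- aggregate(mean_loss ~ major_id, data = cells, FUN = mean)
  structure(list(cells = cells, per_major = per_major,
                 overall = weighted_loss_from_cells(losses_by_cell),
                 n_fallback = n_fallback, n_zero = n_zero,
                 model = model),
            class = "evaluation_report")
}

# the weighted double sum: mean over cells of within-cell mean losses,
# L = (1/|SV|) sum_(s,v) (1/|I_s n I_v|) sum_i l_i.
# Up-weights rare (leaf, class) cells; a cell's contribution is invariant to
# duplicating its loss contents.
weighted_loss_from_cells <- function(losses_by_cell) {
  mean(vapply(losses_by_cell, mean, numeric(1)))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report (", x$model$kind, "): overall weighted loss ",
      format(x$overall, digits = 6), " over ", nrow(x$cells), " cells",
      if (x$n_fallback + x$n_zero > 0)
        paste0(" (", x$n_fallback, " fallback, ", x$n_zero, " zero predictions)"),
      "\n", sep = "")
  invisible(x)
}

#' Default hyperparameter grid for an estimator kind
#'
#' Spatial bandwidths log-spaced over 100 um - 1 cm (7 points), class-space
#' bandwidths log-spaced over 0.01 - 10 (7 points; cosine distances live in
#' \[0, 2\]), and blend weights on a 0.1-step grid.
#'
#' @param kind estimator kind.
#' @return data.frame of grid points.
#' @export
default_grid <- function(kind) {
  sigma_x <- 10^seq(2, 4, length.out = 7)
  sigma_c <- 10^seq(-2, 1, length.out = 7)
  alpha <- seq(0, 1, by = 0.1)
  switch(kind,
         nnls = data.frame(sigma_x = NA_real_),
         nw = data.frame(sigma_x = sigma_x),
         cre_nw = data.frame(sigma_x = sigma_x),
         el = expand.grid(sigma_x = sigma_x, sigma_c = sigma_c, alpha = alpha))
}

# choose the best grid row: minimal loss, ties toward the smoother model
# (larger sigma_x, then larger sigma_c, then larger alpha)
pick_best_row <- function(grid, losses) {
  best <- min(losses)
  cand <- which(losses <= best)
  key <- function(col) if (col %in% names(grid)) {
    x <- grid[[col]][cand]
    ifelse(is.na(x), -Inf, x)
  } else rep(0, length(cand))
  ord <- order(key("sigma_x"), key("sigma_c"), key("alpha"), decreasing = TRUE)
  cand[ord[1]]
}

#' Select estimator hyperparameters by leave-one-out cross-validation
#'
#' Minimizes [loocv_weighted_loss()] over a grid, independently for each
#' major structure (the training policy is major-structure-wide). Ties are
#' broken toward the smoother model: larger spatial bandwidth first, then
#' larger class bandwidth, then larger blend weight.
#'
#' @param kind estimator kind to tune.
#' @param d a [tracer_dataset()].
#' @param grid data.frame of candidate hyperparameters (see
#'   [default_grid()]).
#' @param per_major select separately per major structure (default) or one
#'   global setting.
#' @param detection_limit passed to [loocv_weighted_loss()].
#' @param normalization normalization tag stored on the returned model.
#' @return a fitted [estimator_model()] whose hyperparameter table holds the
#'   selected row(s); the full selection trace is attached as attribute
#'   `"selection"`.
#' @export
select_hyperparameters <- function(kind, d, grid = default_grid(kind),
                                   per_major = TRUE, detection_limit = 0,
                                   normalization = d$normalization) {
  if (nrow(grid) == 0) stop_mesoconn("hyperparameter grid is empty")
  all_cells <- eval_set(d)
  cs_list <- NULL
  if (kind == "el") {
    # leave-one-out class spaces are shared across grid points and majors
    cs_list <- vector("list", nrow(d$y))
    held <- unique(unlist(lapply(seq_len(nrow(all_cells)), function(k) {
      intersect(d$I_leaf[[as.character(all_cells$leaf_id[k])]],
                d$I_class[[all_cells$cell_class[k]]])
    })))
    for (i in held) cs_list[[i]] <- build_class_space(d, exclude = i)
  }
  scopes <- if (per_major) names(d$I_major) else list(NULL)
  hp_rows <- list()
  trace <- list()
  for (m in scopes) {
    cells <- if (is.null(m)) all_cells else
      all_cells[all_cells$major_id == as.numeric(m), , drop = FALSE]
    if (nrow(cells) == 0) next
    losses <- vapply(seq_len(nrow(grid)), function(g) {
      mod <- make_grid_model(kind, grid[g, , drop = FALSE], normalization)
      loocv_weighted_loss(mod, d, detection_limit = detection_limit,
                          cells = cells, class_spaces = cs_list)$overall
    }, numeric(1))
    best <- pick_best_row(grid, losses)
    row <- grid[best, , drop = FALSE]
    row$major_id <- if (is.null(m)) NA_real_ else as.numeric(m)
    hp_rows[[length(hp_rows) + 1]] <- row
    trace[[length(trace) + 1]] <- cbind(major_id = row$major_id, grid, loss = losses)
  }
  if (length(hp_rows) == 0) stop_mesoconn("no major structure has an evaluation cell")
  hp <- do.call(rbind, lapply(hp_rows, function(r) {
    data.frame(major_id = r$major_id,
               sigma_x = r$sigma_x %||% NA_real_,
               sigma_c = if ("sigma_c" %in% names(r)) r$sigma_c else NA_real_,
               alpha = if ("alpha" %in% names(r)) r$alpha else NA_real_)
  }))
  model <- structure(list(kind = kind, hp = hp, normalization = normalization,
                          W = NULL), class = "estimator_model")
  model <- fit_estimator_if_possible(model, d)
  attr(model, "selection") <- do.call(rbind, trace)
  model
}

make_grid_model <- function(kind, row, normalization) {
  structure(list(kind = kind,
                 hp = data.frame(major_id = NA_real_,
                                 sigma_x = row$sigma_x %||% NA_real_,
                                 sigma_c = if ("sigma_c" %in% names(row)) row$sigma_c else NA_real_,
                                 alpha = if ("alpha" %in% names(row)) row$alpha else NA_real_),
                 normalization = normalization, W = NULL),
            class = "estimator_model")
}

fit_estimator_if_possible <- function(model, d) {
  if (model$kind == "nnls" && !is.null(d$x_S)) fit_estimator(model, d) else model
}

#' Write an evaluation report
#'
#' @param report an `evaluation_report`.
#' @param path_tsv per-cell TSV output path (major_structure, leaf, class, n,
#'   mean_loss).
#' @param path_json optional JSON summary path.
#' @return `path_tsv`, invisibly.
#' @export
write_evaluation_report <- function(report, path_tsv, path_json = NULL) {
  write.table(report$cells, path_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(path_json)) {
    jsonlite::write_json(list(kind = report$model$kind,
                              overall_weighted_loss = report$overall,
                              n_cells = nrow(report$cells),
                              n_fallback = report$n_fallback,
                              n_zero = report$n_zero),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(path_tsv)
}
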