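#' Masked sparse NMF objective
#'
#' \deqn{\tfrac12 \|M \odot (C - WH)\|_2^2 + \lambda (\|H\|_1 + \|W\|_1).}
#' The mask is applied to the residual, so masked entries of `C` have no
#' influence on the fit.
#'
#' @param C S x T matrix.
#' @param M logical/0-1 mask (TRUE = fitted entry).
#' @param W S x q nonnegative weights.
#' @param H q x T nonnegative hidden units.
#' @param lambda L1 penalty.
#' @return scalar objective value.
#' @export
nmf_objective <- function(C, M, W, H, lambda) {
  R <- M * (C - W %*% H)
  0.5 * sum(R^2) + lambda * (sum(H) + sum(W))
}

#' Masked, L1-penalized nonnegative matrix factorization
#'
#' Finds a local minimizer of [nmf_objective()] by mask-aware multiplicative
#' updates. The L1 penalty enters the update denominators
#' (majorization-minimization form), which keeps the penalized objective
#' non-increasing at every iteration; the trace is recorded and checked in
#' the test suite. Masked entries of `C` (including `NA`s there) have zero
#' influence on the result. On return the rows of `H` are unit-L2-normalized
#' with the scale absorbed into `W`.
#'
#' @param C S x T matrix, nonnegative on unmasked entries.
#' @param M logical mask (TRUE = fitted); default all TRUE.
#' @param q factorization rank, `1 <= q <= min(S, T)`.
#' @param lambda L1 penalty (default 0.002, favouring sparse, interpretable
#'   components).
#' @param seed RNG seed for the uniform initialization.
#' @param max_iter maximum multiplicative updates.
#' @param tol relative objective-change stopping tolerance.
#' @return object of class `archetype_decomposition` with `W`, `H`,
#'   `lambda`, `mask`, `objective_trace`, `replicate_seed`.
#' @export
masked_sparse_nmf <- function(C, M = NULL, q, lambda = 0.002, seed = 1,
                              max_iter = 2000, tol = 1e-6) {
  C <- as.matrix(C)
  if (is.null(M)) M <- matrix(TRUE, nrow(C), ncol(C))
  M <- (M & !is.na(C)) * 1
  C[is.na(C)] <- 0
  C <- C * M  # masked entries have zero influence
  if (q < 1 || q > min(dim(C))) stop_mesoconn("q must be in [1, min(S, T)]")
  if (any(!is.finite(C))) stop_mesoconn("non-finite unmasked entries in C")
  if (any(C < 0)) stop_mesoconn("C must be nonnegative on unmasked entries")
  if (lambda < 0) stop_mesoconn("lambda must be >= 0")
  if (sum(M) == 0) stop_mesoconn("mask leaves no entries to fit")
  S <- nrow(C); T_ <- ncol(C)
  eps <- 1e-12
  scale0 <- sqrt(mean(C[M == 1]) / max(q, 1) + eps)
  init <- with_seed(seed, list(W = matrix(runif(S * q, 0.1, 1), S, q) * scale0,
                               H = matrix(runif(q * T_, 0.1, 1), q, T_) * scale0))
  W <- init$W; H <- init$H
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    W <- W * ((C %*% t(H)) / ((M * WH) %*% t(H) + lambda + eps))
    WH <- W %*% H
    H <- H * ((t(W) %*% C) / (t(W) %*% (M * WH) + lambda + eps))
    cur <- nmf_objective(C, M, W, H, lambda)
    obj <- c(obj, cur)
    if (is.finite(prev) && abs(prev - cur) <= tol * max(prev, eps)) break
    prev <- cur
  }
  # unit-L2 rows of H, scale absorbed into W
  nrm <- sqrt(rowSums(H^2))
  pos <- nrm > 0
  H[pos, ] <- H[pos, , drop = FALSE] / nrm[pos]
  W[, pos] <- sweep(W[, pos, drop = FALSE], 2, nrm[pos], "*")
  dimnames(W) <- list(rownames(C), paste0("A", seq_len(q)))
  dimnames(H) <- list(paste0("A", seq_len(q)), colnames(C))
  structure(list(W = W, H = H, lambda = lambda, mask = M == 1,
                 objective_trace = obj, replicate_seed = seed,
                 converged = length(obj) < max_iter),
            class = "archetype_decomposition")
}

#' @export
print.archetype_decomposition <- function(x, ...) {
  cat("archetype_decomposition: q =", ncol(x$W), ", lambda =", x$lambda,
      ",", length(x$objective_trace), "iterations, final objective",
      format(utils::tail(x$objective_trace, 1), digits = 6), "\n")
  invisible(x)
}

#' Select the NMF rank by unsupervised cross-validation
#'
#' For each candidate rank, repeatedly hides a random subset of the unmasked
#' entries (adding them to the mask during fitting), fits, and scores the
#' squared reconstruction error on the held-out entries. Returns the rank
#' minimizing the mean held-out error; ties go to the smaller rank.
#'
#' @param C,M matrix and mask as in [masked_sparse_nmf()].
#' @param q_grid candidate ranks.
#' @param holdout_fraction fraction of unmasked entries hidden per repeat,
#'   in (0, 0.5).
#' @param n_repeats holdout repeats per rank.
#' @param seed RNG seed.
#' @param lambda L1 penalty used during the fits.
#' @param ... further arguments to [masked_sparse_nmf()].
#' @return the selected rank; the per-rank mean held-out errors are attached
#'   as attribute `"errors"`.
#' @export
select_rank <- function(C, M = NULL, q_grid, holdout_fraction = 0.2,
                        n_repeats = 5, seed = 1, lambda = 0.002, ...) {
  if (length(q_grid) == 0) stop_mesoconn("q_grid is empty")
  if (holdout_fraction <= 0 || holdout_fraction >= 0.5) {
    stop_mesoconn("holdout_fraction must be in (0, 0.5)")
  }
  C <- as.matrix(C)
  if (is.null(M)) M <- matrix(TRUE, nrow(C), ncol(C))
  M <- M & !is.na(C)
  q_grid <- sort(q_grid)
  unmasked <- which(M)
  err <- matrix(NA_real_, length(q_grid), n_repeats)
  for (r in seq_len(n_repeats)) {
    hide <- with_seed(seed * 1000 + r, {
      sample(unmasked, size = max(1, round(holdout_fraction * length(unmasked))))
    })
    M_fit <- M
    M_fit[hide] <- FALSE
    for (qi in seq_along(q_grid)) {
      fit <- masked_sparse_nmf(C, M_fit, q = q_grid[qi], lambda = lambda,
                               seed = seed * 1000 + r, ...)
      R <- C - fit$W %*% fit$H
      err[qi, r] <- mean(R[hide]^2)
    }
  }
  mean_err <- rowMeans(err)
  q_sel <- q_grid[which.min(mean_err)]  # ties: first = smallest q
  attr(q_sel, "errors") <- setNames(mean_err, q_grid)
  q_sel
}

cosine_distance_matrix <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  Xn <- X / pmax(nrm, 1e-300)
  D <- 1 - Xn %*% t(Xn)
  D[D < 0] <- 0
  D
}

#' Stability clustering of NMF archetypes
#'
#' Runs [masked_sparse_nmf()] from `n_replicates` random initializations,
#' pools all unit-normalized `H` rows, clusters them by average-linkage
#' agglomeration under cosine distance cut at `match_threshold`, and ranks
#' clusters by the number of distinct replicates represented. The element-
#' wise median of each cluster's members is its archetype; the top `top_k`
#' clusters are returned.
#'
#' @param C,M matrix and mask as in [masked_sparse_nmf()].
#' @param q factorization rank.
#' @param lambda L1 penalty.
#' @param n_replicates number of random restarts (>= 2).
#' @param match_threshold cosine-distance cut for clustering.
#' @param top_k number of stable components to return (default 15).
#' @param seed base seed; replicate r uses `seed * 1000 + r`.
#' @param ... further arguments to [masked_sparse_nmf()].
#' @return object of class `stability_result`: `archetypes` (k x T matrix of
#'   cluster medians), `frequency` (distinct replicates per cluster),
#'   `clusters` (member assignment table), and the replicate fits' seeds.
#' @export
stability_archetypes <- function(C, M = NULL, q, lambda = 0.002,
                                 n_replicates = 30, match_threshold = 0.3,
                                 top_k = 15, seed = 1, ...) {
  if (n_replicates < 2) stop_mesoconn("n_replicates must be >= 2")
  rows <- list()
  meta <- list()
  for (r in seq_len(n_replicates)) {
    fit <- masked_sparse_nmf(C, M, q = q, lambda = lambda,
                             seed = seed * 1000 + r, ...)
    H <- fit$H
    keep <- rowSums(H^2) > 0
    H <- H[keep, , drop = FALSE]
    rows[[r]] <- H
    meta[[r]] <- data.frame(replicate = r, component = which(keep))
  }
  pool <- do.call(rbind, rows)
  meta <- do.call(rbind, meta)
  if (nrow(pool) < 2) stop_mesoconn("too few nonzero components to cluster")
  D <- cosine_distance_matrix(pool)
  hc <- hclust(as.dist(D), method = "average")
  cl <- cutree(hc, h = match_threshold)
  meta$cluster <- cl
  k_all <- sort(unique(cl))
  freq <- vapply(k_all, function(k) length(unique(meta$replicate[cl == k])), integer(1))
  size <- vapply(k_all, function(k) sum(cl == k), integer(1))
  ord <- order(-freq, -size, k_all)
  k_sel <- k_all[ord][seq_len(min(top_k, length(k_all)))]
  arch <- t(vapply(k_sel, function(k) {
    apply(pool[cl == k, , drop = FALSE], 2, median)
  }, numeric(ncol(pool))))
  rownames(arch) <- paste0("S", seq_along(k_sel))
  colnames(arch) <- colnames(pool)
  structure(list(archetypes = arch,
                 frequency = setNames(freq[ord][seq_along(k_sel)], rownames(arch)),
                 cluster_size = setNames(size[ord][seq_along(k_sel)], rownames(arch)),
                 clusters = meta, n_replicates = n_replicates,
                 match_threshold = match_threshold, seed = seed),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat("stability_result:", nrow(x$archetypes), "stable archetypes from",
      x$n_replicates, "replicates; frequencies:",
      paste(x$frequency, collapse = " "), "\n")
  invisible(x)
}

#' Optimal matching of estimated archetypes to references
#'
#' Matches rows of `H_est` to rows of `H_ref` one-to-one so as to maximize
#' the mean cosine similarity (exhaustive over assignments; intended for the
#' small ranks used in recovery checks). Factorization identifiability is
#' only up to permutation and scale, so recovery is always assessed after
#' this matching.
#'
#' @param H_est,H_ref matrices with the same number of columns; `H_est` must
#'   have at least as many rows as `H_ref`.
#' @return list with `assignment` (row of `H_est` matched to each row of
#'   `H_ref`) and `mean_cosine`.
#' @export
match_archetypes <- function(H_est, H_ref) {
  k <- nrow(H_ref)
  if (nrow(H_est) < k) stop_mesoconn("H_est must have at least nrow(H_ref) rows")
  if (k > 8) stop_mesoconn("exhaustive matching supports at most 8 reference rows")
  sim <- (H_ref / pmax(sqrt(rowSums(H_ref^2)), 1e-300)) %*%
    t(H_est / pmax(sqrt(rowSums(H_est^2)), 1e-300))
  perms <- all_injections(seq_len(nrow(H_est)), k)
  best <- -Inf
  best_p <- NULL
  for (p in perms) {
    s <- mean(sim[cbind(seq_len(k), p)])
    if (s > best) { best <- s; best_p <- p }
  }
  list(assignment = best_p, mean_cosine = best)
}

# all ordered selections of k elements from x (k-permutations)
all_injections <- function(x, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_injections(x[-i], k - 1)) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}
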