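# Two-block partial least squares between the neurocranial and
# splanchnocranial blocks of the size-scaled shape matrix: SVD of the 3x3
# between-block association matrix (cross-correlations by default).

block_columns <- function(m) {
  bm <- attr(m, "block_map")
  if (is.null(bm)) bm <- cranio_blocks()
  list(neuro = unclass(m)[, bm$neurocranium, drop = FALSE],
       splanchno = unclass(m)[, bm$splanchnocranium, drop = FALSE])
}

#' Fit a two-block partial least squares model
#'
#' Computes the singular value decomposition of the between-block association
#' matrix (cross-correlations in `"correlation"` mode, cross-covariances in
#' `"covariance"` mode) over all specimens jointly (non-pooled). Block scores
#' are the centered (and, in correlation mode, column-standardized) block
#' data projected on the unit-norm singular vectors. Each dimension is
#' oriented so the neurocranial loadings sum to a positive value; the
#' splanchnocranial sign is then data-driven.
#'
#' @param shape A `cranio_shapematrix` (see [shape_matrix()]).
#' @param mode Association matrix: `"correlation"` (default) or
#'   `"covariance"`.
#' @return Object of class `cranio_pls` with elements `neuro_loadings`,
#'   `splanchno_loadings` (3 x 3, unit-norm columns), `singular_values`,
#'   `pct_covariation` (100 * d_i^2 / sum d^2), `neuro_scores`,
#'   `splanchno_scores`, `score_correlation`, `mode`, and the training
#'   centering/scaling statistics used by [project_pls()].
#' @export
fit_pls <- function(shape, mode = c("correlation", "covariance")) {
  mode <- match.arg(mode)
  blocks <- block_columns(shape)
  n <- nrow(blocks$neuro)
  if (n < 4L) stop("at least 4 specimens are required, got ", n)
  for (b in names(blocks)) {
    sds <- apply(blocks[[b]], 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant column in ", b, " block: ",
           paste(colnames(blocks[[b]])[sds == 0], collapse = ", "))
    }
  }
  center <- lapply(blocks, colMeans)
  scale_ <- lapply(blocks, function(x) {
    if (mode == "correlation") apply(x, 2, stats::sd) else rep(1, ncol(x))
  })
  std <- mapply(function(x, mu, s) sweep(sweep(x, 2, mu), 2, s, "/"),
                blocks, center, scale_, SIMPLIFY = FALSE)
  # association matrix: cross-products of standardized (or centered) blocks
  assoc <- crossprod(std$neuro, std$splanchno) / (n - 1)
  dec <- svd(assoc)
  u <- dec$u
  v <- dec$v
  # orientation: neurocranial loadings sum positive; flip u and v as a pair
  for (k in seq_len(ncol(u))) {
    if (sum(u[, k]) < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  rownames(u) <- colnames(blocks$neuro)
  rownames(v) <- colnames(blocks$splanchno)
  colnames(u) <- colnames(v) <- paste0("D", seq_len(ncol(u)))
  ns <- std$neuro %*% u
  ss <- std$splanchno %*% v
  d2 <- dec$d^2
  res <- structure(list(
    neuro_loadings = u,
    splanchno_loadings = v,
    singular_values = dec$d,
    pct_covariation = 100 * d2 / sum(d2),
    neuro_scores = ns,
    splanchno_scores = ss,
    score_correlation = vapply(seq_len(ncol(ns)),
                               function(k) stats::cor(ns[, k], ss[, k]), 0),
    mode = mode,
    center = center,
    scale = scale_,
    n = n
  ), class = "cranio_pls")
  res
}

#' Project specimens into a fitted PLS space
#'
#' New specimens are centered (and scaled, in correlation mode) with the
#' TRAINING statistics, then projected on the stored loading vectors, so
#' fossils or perturbed replicates can be placed in a space fitted on
#' another subset.
#'
#' @param model A `cranio_pls`.
#' @param shape A `cranio_shapematrix` with the same variable order.
#' @return List with `neuro_scores` and `splanchno_scores` (n x 3).
#' @export
project_pls <- function(model, shape) {
  stopifnot(inherits(model, "cranio_pls"))
  blocks <- block_columns(shape)
  if (!identical(colnames(blocks$neuro), rownames(model$neuro_loadings)) ||
      !identical(colnames(blocks$splanchno), rownames(model$splanchno_loadings))) {
    stop("variable order does not match the fitted model")
  }
  std <- mapply(function(x, mu, s) sweep(sweep(x, 2, mu), 2, s, "/"),
                blocks, model$center, model$scale, SIMPLIFY = FALSE)
  list(neuro_scores = std$neuro %*% model$neuro_loadings,
       splanchno_scores = std$splanchno %*% model$splanchno_loadings)
}

#' @export
print.cranio_pls <- function(x, ...) {
  cat("Two-block PLS (", x$mode, " mode), n = ", x$n, "\n", sep = "")
  cat("singular values:", format(x$singular_values, digits = 4), "\n")
  cat("% covariation:  ", format(x$pct_covariation, digits = 4), "\n")
  cat("score correlation:", format(x$score_correlation, digits = 3), "\n")
  invisible(x)
}

#' Tidy export of PLS loadings and scores
#'
#' @param model A `cranio_pls`.
#' @return List of two data frames: `loadings` (variable, block, dimension,
#'   loading) and `scores` (specimen_id, dimension, neuro_score,
#'   splanchno_score).
#' @export
pls_tables <- function(model) {
  stopifnot(inherits(model, "cranio_pls"))
  long <- function(L, block) {
    data.frame(variable = rep(rownames(L), ncol(L)),
               block = block,
               dimension = rep(seq_len(ncol(L)), each = nrow(L)),
               loading = as.vector(L))
  }
  loadings <- rbind(long(model$neuro_loadings, "neurocranium"),
                    long(model$splanchno_loadings, "splanchnocranium"))
  ids <- rownames(model$neuro_scores)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(model$neuro_scores)))
  scores <- do.call(rbind, lapply(seq_len(ncol(model$neuro_scores)), function(k) {
    data.frame(specimen_id = ids, dimension = k,
               neuro_score = model$neuro_scores[, k],
               splanchno_score = model$splanchno_scores[, k],
               row.names = NULL)
  }))
  list(loadings = loadings, scores = scores)
}
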