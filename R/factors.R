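# Factor model: principal component analysis of the 6x6 Pearson correlation
# matrix of the log-raw measurements, with eigenvectors rescaled by the
# square root of their eigenvalues so loadings are variable-factor
# correlations, plus the isometric-vector angle diagnostic that separates
# the size factor from the shape factor.

#' Fit the correlation-matrix factor model
#'
#' Eigen-decomposition of the Pearson correlation matrix of the log10
#' measurements. Loadings are eigenvectors times the square root of their
#' eigenvalues; factor scores are standardized to unit variance, so each
#' loading equals the correlation between its variable and the factor.
#' Orientation: factor 1 is signed so the neurocranial variables load
#' positively (relatively large neurocranium scores high); every other
#' factor is signed so its loadings sum positive (for factor 2 this makes
#' all six loadings positive: overall size increases with the score).
#'
#' @param logm A `cranio_logmatrix` (see [log_matrix()]).
#' @param k Number of retained factors (default 2).
#' @return Object of class `cranio_factors` with `eigenvalues` (all 6),
#'   `pct_variance` (100 * eigenvalue / 6), `loadings` (6 x k),
#'   `communalities` (h^2, row sums of squared retained loadings), `scores`
#'   (n x k, unit variance), `scoring` (the 6 x k scoring-coefficient
#'   matrix applied to standardized variables), and the training
#'   means/standard deviations.
#' @export
fit_factors <- function(logm, k = 2) {
  x <- unclass(logm)
  n <- nrow(x)
  p <- ncol(x)
  if (n < p + 1L) stop("need more specimens (", n, ") than variables (", p, ")")
  if (k > p) stop("k must be at most ", p)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column: ", paste(colnames(x)[sds == 0], collapse = ", "))
  }
  mu <- colMeans(x)
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  lambda <- eig$values
  V <- eig$vectors
  rownames(V) <- colnames(x)
  bm <- attr(logm, "block_map")
  neuro <- if (is.null(bm)) cranio_blocks()$neurocranium else bm$neurocranium
  for (j in seq_len(p)) {
    s <- if (j == 1L) sum(V[neuro, j]) else sum(V[, j])
    if (s < 0) V[, j] <- -V[, j]
  }
  keep <- seq_len(k)
  loadings <- V[, keep, drop = FALSE] %*% diag(sqrt(lambda[keep]), k)
  colnames(loadings) <- paste0("F", keep)
  # standardized scores: z V Lambda^{-1/2}; sample variance exactly 1
  scoring <- V[, keep, drop = FALSE] %*% diag(1 / sqrt(lambda[keep]), k)
  colnames(scoring) <- paste0("F", keep)
  z <- sweep(sweep(x, 2, mu), 2, sds, "/")
  scores <- z %*% scoring
  structure(list(
    eigenvalues = lambda,
    pct_variance = 100 * lambda / p,
    loadings = loadings,
    communalities = rowSums(loadings^2),
    scores = scores,
    scoring = scoring,
    center = mu,
    sd = sds,
    k = k,
    n = n
  ), class = "cranio_factors")
}

#' Score new specimens in a fitted factor space
#'
#' Standardizes with the TRAINING means and standard deviations, then applies
#' the stored scoring coefficients, so fossils or perturbed replicates are
#' placed in the fixed factor space.
#'
#' @param model A `cranio_factors`.
#' @param logm A `cranio_logmatrix` with the same variable order.
#' @return n x k matrix of factor scores.
#' @export
score_factors <- function(model, logm) {
  stopifnot(inherits(model, "cranio_factors"))
  x <- unclass(logm)
  if (!identical(colnames(x), names(model$center))) {
    stop("variable order does not match the fitted model")
  }
  z <- sweep(sweep(x, 2, model$center), 2, model$sd, "/")
  z %*% model$scoring
}

#' Angle of the isometric vector with the first two factors
#'
#' The isometric direction — equal proportional change of every measurement,
#' `(1, ..., 1)/sqrt(6)` in log-variable space — is mapped into score space
#' by the factor-scoring transformation (standardization by the training
#' SDs followed by the scoring coefficients). The angles between its image
#' and the two factor axes, folded to `[0, 90]` degrees, diagnose which
#' factor carries size: a small angle to factor 2 identifies it as the size
#' vector and factor 1 as the shape vector.
#'
#' @param model A `cranio_factors` with `k = 2`.
#' @return List with `angle_to_factor1` and `angle_to_factor2` (degrees).
#' @export
isometry_angles <- function(model) {
  stopifnot(inherits(model, "cranio_factors"))
  if (model$k != 2L) stop("isometry angles are defined for k = 2 retained factors")
  iso <- rep(1 / sqrt(length(model$sd)), length(model$sd))
  image <- as.vector((iso / model$sd) %*% model$scoring)
  len <- sqrt(sum(image^2))
  if (len < .Machine$double.eps^0.5) stop("degenerate isometric image")
  fold <- function(cosv) {
    a <- acos(max(-1, min(1, abs(cosv)))) * 180 / pi
    a
  }
  list(angle_to_factor1 = fold(image[1] / len),
       angle_to_factor2 = fold(image[2] / len))
}

#' @export
print.cranio_factors <- function(x, ...) {
  cat("Correlation-matrix factor model, k = ", x$k, ", n = ", x$n, "\n", sep = "")
  cat("eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  cat("% variance: ", format(x$pct_variance, digits = 4), "\n")
  print(round(cbind(x$loadings, h2 = x$communalities), 3))
  invisible(x)
}

#' Factor-analysis summary tables
#'
#' @param model A `cranio_factors`.
#' @return List of data frames: `loadings` (variable, one column per factor,
#'   h2) and `variance` (factor, eigenvalue, pct_variance), mirroring the
#'   usual published layout.
#' @export
factor_tables <- function(model) {
  stopifnot(inherits(model, "cranio_factors"))
  loadings <- data.frame(variable = rownames(model$loadings),
                         model$loadings,
                         h2 = model$communalities,
                         row.names = NULL, check.names = FALSE)
  keep <- seq_len(model$k)
  variance <- data.frame(factor = paste0("F", keep),
                         eigenvalue = model$eigenvalues[keep],
                         pct_variance = model$pct_variance[keep])
  list(loadings = loadings, variance = variance)
}
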