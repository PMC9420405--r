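# Operational heterochrony model: decompose a between-group difference in
# the size-shape plane into a displacement ALONG a reference ontogenetic
# trajectory (ontogenetic scaling: paedomorphic when truncated, peramorphic
# when extended) and an orthogonal OFFSET from it (lateral transposition),
# plus the encephalization association statistics.

#' Decompose a centroid difference into scaling and transposition
#'
#' The reference trajectory is an RMA fit (typically the ancestral group's
#' ontogenetic line in the factor plane) with an ontogenetic polarity: the
#' juvenile-to-adult direction along the line. The target centroid's
#' displacement from the reference centroid is orthogonally projected onto
#' the line direction (`along`, signed by the polarity) and its normal
#' (`offset`). `along > dead_band` labels the target peramorphic (beyond the
#' reference adult state), `along < -dead_band` paedomorphic. `offset` is
#' compared with the reference line's prediction-band half-width at the
#' target's along-coordinate: a larger |offset| labels the target laterally
#' transposed.
#'
#' @param reference A `cranio_rma` fitted on the reference group's scores.
#' @param target Numeric length-2 centroid (axis 1, axis 2) of the target.
#' @param polarity Length-2 vector giving the juvenile-to-adult direction;
#'   it is projected onto the reference line and normalized.
#' @param dead_band Half-width (score units) of the `none` zone for the
#'   scaling label. Default 0.1.
#' @param conf Prediction-band level for the transposition threshold.
#' @return List of class `cranio_decomp`: `along`, `offset`,
#'   `scaling_label`, `transposition_label`, `threshold`, `reference_centroid`,
#'   `direction` (unit along-vector), `normal` (unit offset-vector).
#' @export
decompose_trajectory <- function(reference, target, polarity,
                                 dead_band = 0.1, conf = 0.95) {
  stopifnot(inherits(reference, "cranio_rma"), length(target) == 2L,
            length(polarity) == 2L)
  if (sqrt(sum(polarity^2)) < .Machine$double.eps^0.5) {
    stop("polarity must be a non-zero vector")
  }
  # unit direction of the reference line, signed by the polarity
  u <- c(1, reference$slope)
  u <- u / sqrt(sum(u^2))
  if (sum(u * polarity) < 0) u <- -u
  nrm <- c(-u[2], u[1])
  centroid <- c(mean(reference$x), mean(reference$y))
  d <- as.numeric(target) - centroid
  along <- sum(d * u)
  offset <- sum(d * nrm)

  # prediction band: perpendicular residuals of the reference specimens,
  # widened for leverage at the target's along-coordinate
  ref_d <- cbind(reference$x - centroid[1], reference$y - centroid[2])
  ref_along <- ref_d %*% u
  ref_off <- ref_d %*% nrm
  n <- reference$n
  s <- sqrt(sum(ref_off^2) / (n - 2))
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 2) *
    s * sqrt(1 + 1 / n + along^2 / sum(ref_along^2))

  scaling <- if (along > dead_band) "peramorphic"
  else if (along < -dead_band) "paedomorphic"
  else "none"
  # small absolute guard so an exactly-on-line target on a noise-free
  # reference (threshold 0) is not flagged by floating-point dust
  transposition <- if (abs(offset) > half + 1e-12) "transposed" else "on-trajectory"
  structure(list(along = along, offset = offset,
                 scaling_label = scaling, transposition_label = transposition,
                 threshold = half, reference_centroid = centroid,
                 direction = u, normal = nrm),
            class = "cranio_decomp")
}

#' @export
print.cranio_decomp <- function(x, ...) {
  cat(sprintf("trajectory decomposition: along %.4f (%s), offset %.4f (%s, threshold %.4f)\n",
              x$along, x$scaling_label, x$offset, x$transposition_label, x$threshold))
  invisible(x)
}

#' Encephalization quotient
#'
#' `EQ = ECV / (a * BM^b)`: observed endocranial volume over the volume
#' expected from body mass under a power-law scaling with constants `a`
#' and `b`. The constants materially affect downstream associations and are
#' always carried in the result.
#'
#' @param bm_kg Body mass in kg (> 0).
#' @param ecv_cm3 Endocranial volume in cm^3 (> 0).
#' @param a,b Scaling constants (defaults 1.77 and 0.76, a widely used
#'   primate scaling).
#' @return Data frame: `bm_kg`, `ecv_cm3`, `log_bm`, `log_ecv`, `eq`, with
#'   the constants as attributes `eq_a`, `eq_b`.
#' @export
compute_eq <- function(bm_kg, ecv_cm3, a = 1.77, b = 0.76) {
  if (any(!is.finite(bm_kg) | bm_kg <= 0) || any(!is.finite(ecv_cm3) | ecv_cm3 <= 0)) {
    stop("bm_kg and ecv_cm3 must be positive and finite")
  }
  out <- data.frame(bm_kg = bm_kg, ecv_cm3 = ecv_cm3,
                    log_bm = log10(bm_kg), log_ecv = log10(ecv_cm3),
                    eq = ecv_cm3 / (a * bm_kg^b))
  attr(out, "eq_a") <- a
  attr(out, "eq_b") <- b
  out
}

#' Pairwise correlations among factor scores and encephalization variables
#'
#' Pearson correlations (with two-sided p-values) among Factor I, Factor II,
#' log body mass, log endocranial volume and EQ, computed on complete cases,
#' optionally split by group (e.g. australopithecines vs fossil Homo).
#'
#' @param data Data frame with columns `factor1`, `factor2`, `log_bm`,
#'   `log_ecv`, `eq`; extra numeric columns (e.g. `geo_age`) are included.
#' @param group Optional grouping vector; one result per level.
#' @return For ungrouped input, a list of class `cranio_assoc` with `r`
#'   (correlation matrix), `p` (p-value matrix) and `n`; for grouped input,
#'   a named list of such results.
#' @export
cranial_associations <- function(data, group = NULL) {
  if (!is.null(group)) {
    idx <- split(seq_len(nrow(data)), group)
    return(lapply(idx, function(i) cranial_associations(data[i, , drop = FALSE])))
  }
  num <- data[, vapply(data, is.numeric, TRUE), drop = FALSE]
  num <- num[stats::complete.cases(num), , drop = FALSE]
  n <- nrow(num)
  if (n < 4L) stop("need at least 4 complete cases, got ", n)
  p <- ncol(num)
  r <- stats::cor(num)
  pv <- matrix(NA_real_, p, p, dimnames = dimnames(r))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i != j) pv[i, j] <- stats::cor.test(num[[i]], num[[j]])$p.value
    else pv[i, j] <- 0
  }
  structure(list(r = r, p = pv, n = n), class = "cranio_assoc")
}

#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, tested
#' with a t statistic on `df = n - 3`.
#'
#' @param x,y,z Numeric vectors (complete cases used; n >= 5).
#' @return List: `r`, `df`, `p` (two-sided).
#' @export
partial_correlation <- function(x, y, z) {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 5L) stop("partial correlation needs n >= 5, got ", n)
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) {
    stop("control variable is collinear with x or y")
  }
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  df <- n - 3
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, p = 2 * stats::pt(-abs(tstat), df = df))
}
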