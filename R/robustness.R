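# Measurement-error robustness: perturb a specimen's six measurements with
# bounded multiplicative error, re-apply the model's preprocessing, and
# re-project into the FIXED ordination (the model is never refitted), then
# summarize positional stability of the replicate cloud.

# score a raw mm matrix (n x 6, canonical column order) in an existing model,
# returning the 2-D plane used for plots: factors 1-2, or PLS dimension 1 of
# each block
score_plane <- function(model, mm) {
  stopifnot(is.matrix(mm), identical(colnames(mm), cranio_vars()))
  lg <- log10(mm)
  if (inherits(model, "cranio_factors")) {
    sc <- score_factors(model, lg)
    sc[, 1:2, drop = FALSE]
  } else if (inherits(model, "cranio_pls")) {
    shp <- lg - rowMeans(lg)
    attr(shp, "block_map") <- cranio_blocks()
    pr <- project_pls(model, shp)
    cbind(pr$neuro_scores[, 1], pr$splanchno_scores[, 1])
  } else {
    stop("model must be a cranio_factors or cranio_pls object")
  }
}

#' Perturb a specimen and re-project it into a fixed ordination
#'
#' Each replicate multiplies every measurement by an independent draw from
#' `Uniform(1 - e, 1 + e)` (the most direct encoding of "inaccuracies of up
#' to e"), or from a Gaussian with SD `e/2` truncated at `1 +/- e`. The
#' perturbed specimen goes through the model's own preprocessing and is
#' scored in the fixed model space; the ordination is never refitted.
#'
#' @param ds A `cranio_dataset` containing the specimen.
#' @param specimen_id Id of the specimen to perturb.
#' @param model A fitted `cranio_factors` or `cranio_pls`.
#' @param error_level Maximum relative error `e` (fraction; e.g. 0.05).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed; recorded in the result.
#' @param dist `"uniform"` (default) or `"truncnorm"`.
#' @return List of class `cranio_perturb`: `specimen_id`, `original`
#'   (length-2 score), `score_cloud` (n_reps x 2), `centroid_shift`
#'   (distance of the cloud centroid from the original score), `dispersion`
#'   (RMS radius of the cloud about its centroid), `error_level`, `n_reps`,
#'   `seed`.
#' @export
perturb_and_project <- function(ds, specimen_id, model, error_level = 0.05,
                                n_reps = 500, seed = 1L,
                                dist = c("uniform", "truncnorm")) {
  dist <- match.arg(dist)
  stopifnot(inherits(ds, "cranio_dataset"))
  if (error_level < 0) stop("error_level must be >= 0")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  row <- which(ds$specimen_id == specimen_id)
  if (length(row) != 1L) stop("specimen '", specimen_id, "' not found")
  meas <- measurement_matrix(ds)[row, ]

  factors <- with_local_seed(seed, {
    if (error_level == 0) {
      matrix(1, n_reps, 6L)
    } else if (dist == "uniform") {
      matrix(stats::runif(n_reps * 6L, 1 - error_level, 1 + error_level),
             n_reps, 6L)
    } else {
      draw_trunc <- function(n) {
        out <- stats::rnorm(n, 1, error_level / 2)
        bad <- abs(out - 1) > error_level
        while (any(bad)) {
          out[bad] <- stats::rnorm(sum(bad), 1, error_level / 2)
          bad <- abs(out - 1) > error_level
        }
        out
      }
      matrix(draw_trunc(n_reps * 6L), n_reps, 6L)
    }
  })
  mm <- sweep(factors, 2, meas, "*")
  colnames(mm) <- cranio_vars()
  cloud <- score_plane(model, mm)
  orig <- drop(score_plane(model, matrix(meas, 1, 6,
                                         dimnames = list(NULL, cranio_vars()))))
  ctr <- colMeans(cloud)
  structure(list(
    specimen_id = specimen_id,
    original = orig,
    score_cloud = cloud,
    centroid_shift = sqrt(sum((ctr - orig)^2)),
    dispersion = sqrt(mean(rowSums(sweep(cloud, 2, ctr)^2))),
    error_level = error_level,
    n_reps = n_reps,
    seed = seed
  ), class = "cranio_perturb")
}

#' @export
print.cranio_perturb <- function(x, ...) {
  cat(sprintf("perturbation of %s: %d reps at +/-%.1f%%, centroid shift %.4g, dispersion %.4g (seed %d)\n",
              x$specimen_id, x$n_reps, 100 * x$error_level,
              x$centroid_shift, x$dispersion, x$seed))
  invisible(x)
}

#' Robustness summary over several specimens
#'
#' Because the scoring maps are linear in the log measurements, a given set
#' of multiplicative perturbation draws displaces every specimen's score by
#' the same amounts; each specimen therefore gets its own seed
#' (`seed + position - 1`) so the summaries are independent draws.
#'
#' @param ds A `cranio_dataset`.
#' @param specimen_ids Specimens to perturb.
#' @param model Fixed ordination model.
#' @param seed Base seed; specimen `i` uses `seed + i - 1`.
#' @param ... Passed to [perturb_and_project()].
#' @return Data frame: specimen_id, centroid_shift, dispersion.
#' @export
robustness_summary <- function(ds, specimen_ids, model, seed = 1L, ...) {
  rows <- lapply(seq_along(specimen_ids), function(i) {
    p <- perturb_and_project(ds, specimen_ids[i], model,
                             seed = seed + i - 1L, ...)
    data.frame(specimen_id = specimen_ids[i],
               centroid_shift = p$centroid_shift,
               dispersion = p$dispersion)
  })
  do.call(rbind, rows)
}
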