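# End-to-end driver reproducing the study-style analysis on any validated
# craniometric dataset: ordinations, allometric fits and contrasts,
# trajectory angles, heterochrony decomposition inputs and encephalization
# associations, in one pass.

#' Run the full cranial allometry-heterochrony analysis
#'
#' Chains preprocessing, 2B-PLS, the factor model with its isometry
#' diagnostic, per-group RMA fits of Factor II on Factor I, ontogenetic
#' centroid angles, the PLS-plane RMA contrast between two clades (slope
#' test and intercept-CI comparison), and — where body mass and endocranial
#' volume are present — the correlation/partial-correlation analysis.
#'
#' @param ds A `cranio_dataset`.
#' @param ape_groups,hominin_groups Group labels forming the two clades for
#'   the PLS-plane contrast; `NULL` skips the contrast.
#' @param rma_groups Group labels for the per-group factor-plane RMA table;
#'   defaults to groups having at least 4 specimens.
#' @param assoc_groups Group labels entering the encephalization analysis
#'   (complete BM/ECV cases only); `NULL` uses all groups with data.
#' @param eq_a,eq_b Encephalization-quotient constants (see [compute_eq()]).
#' @param pls_mode Association mode for [fit_pls()].
#' @param seed Seed for bootstrap confidence intervals.
#' @return List of class `cranio_analysis`: `pls`, `factors`, `isometry`,
#'   `rma` (table + fits), `angles`, `clade_contrast` (fits, slope test,
#'   intercept comparison) and `assoc` (per-group correlation matrices and
#'   the two partial correlations of Factor I with log ECV and EQ).
#' @export
run_full_analysis <- function(ds, ape_groups = NULL, hominin_groups = NULL,
                              rma_groups = NULL, assoc_groups = NULL,
                              eq_a = 1.77, eq_b = 0.76,
                              pls_mode = "correlation", seed = 1L) {
  stopifnot(inherits(ds, "cranio_dataset"))
  logm <- log_matrix(ds)
  shape <- shape_matrix(ds)
  pls <- fit_pls(shape, mode = pls_mode)
  fm <- fit_factors(logm, k = 2)
  iso <- isometry_angles(fm)

  if (is.null(rma_groups)) {
    tab <- table(ds$group)
    rma_groups <- names(tab)[tab >= 4L]
  }
  keep <- ds$group %in% rma_groups
  rma <- rma_by_group(fm$scores[keep, 1:2, drop = FALSE], ds$group[keep],
                      seed = seed)

  both_stages <- intersect(unique(ds$group[ds$age_class == "adult"]),
                           unique(ds$group[ds$age_class == "juvenile"]))
  angles <- if (length(both_stages) > 0L) {
    sel <- ds$group %in% both_stages
    centroid_angles(fm$scores[sel, 1:2, drop = FALSE],
                    ds$group[sel], ds$age_class[sel])
  } else NULL

  clade_contrast <- NULL
  if (!is.null(ape_groups) && !is.null(hominin_groups)) {
    pls_xy <- cbind(pls$neuro_scores[, 1], pls$splanchno_scores[, 1])
    fit_clade <- function(groups, label) {
      sel <- ds$group %in% groups
      fit_rma(pls_xy[sel, 1], pls_xy[sel, 2], seed = seed,
              x_label = "neuro D1", y_label = "splanchno D1")
    }
    fa <- fit_clade(ape_groups, "apes")
    fh <- fit_clade(hominin_groups, "hominins")
    clade_contrast <- list(
      apes = fa, hominins = fh,
      slope_test = clarke_test(fa, fh),
      intercepts = compare_intercepts(fa, fh))
  }

  assoc <- NULL
  has_bm <- is.finite(ds$bm_kg) & is.finite(ds$ecv_cm3)
  if (is.null(assoc_groups)) assoc_groups <- unique(ds$group[has_bm])
  sel <- has_bm & ds$group %in% assoc_groups
  if (sum(sel) >= 4L) {
    eq <- compute_eq(ds$bm_kg[sel], ds$ecv_cm3[sel], a = eq_a, b = eq_b)
    tab <- data.frame(factor1 = fm$scores[sel, 1], factor2 = fm$scores[sel, 2],
                      log_bm = eq$log_bm, log_ecv = eq$log_ecv, eq = eq$eq)
    grp <- ds$group[sel]
    per_group <- tryCatch(cranial_associations(tab, group = grp),
                          error = function(e) NULL)
    partials <- lapply(split(tab, grp), function(d) {
      if (nrow(d) < 5L) return(NULL)
      list(f1_ecv_given_eq = partial_correlation(d$factor1, d$log_ecv, d$eq),
           f1_eq_given_ecv = partial_correlation(d$factor1, d$eq, d$log_ecv))
    })
    assoc <- list(table = tab, group = grp, correlations = per_group,
                  partials = partials, eq_a = eq_a, eq_b = eq_b)
  }

  structure(list(pls = pls, factors = fm, isometry = iso, rma = rma,
                 angles = angles, clade_contrast = clade_contrast,
                 assoc = assoc),
            class = "cranio_analysis")
}

#' @export
print.cranio_analysis <- function(x, ...) {
  cat("== 2B-PLS ==\n"); print(x$pls)
  cat("== Factor model ==\n"); print(x$factors)
  cat(sprintf("isometric vector: %.2f deg to factor I, %.2f deg to factor II\n",
              x$isometry$angle_to_factor1, x$isometry$angle_to_factor2))
  cat("== RMA (factor II ~ factor I) ==\n"); print(x$rma$table, digits = 4)
  if (!is.null(x$angles)) {
    cat("== Ontogenetic centroid angles ==\n")
    print(x$angles[, c("group", "angle_deg")], digits = 4)
  }
  if (!is.null(x$clade_contrast)) {
    cat("== Clade contrast (PLS plane) ==\n")
    print(x$clade_contrast$apes); print(x$clade_contrast$hominins)
    print(x$clade_contrast$slope_test)
    cat("intercept CIs overlap:", x$clade_contrast$intercepts$overlap, "\n")
  }
  invisible(x)
}
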