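# Log transform and Mosimann geometric-mean size standardization.
# Both matrices keep specimens in dataset order and variables in the fixed
# analysis order GOL, BBH, XCB, NPH, BPL, ZYB.

measurement_matrix <- function(ds) {
  stopifnot(inherits(ds, "cranio_dataset"))
  m <- as.matrix(as.data.frame(ds)[, cranio_vars(), drop = FALSE])
  rownames(m) <- ds$specimen_id
  storage.mode(m) <- "double"
  m
}

#' Base-10 log matrix of the six measurements
#'
#' @param ds A `cranio_dataset`.
#' @return n x 6 matrix of `log10(mm)` values, class `cranio_logmatrix`, with
#'   specimen ids as row names and the block map carried as an attribute.
#' @export
log_matrix <- function(ds) {
  m <- measurement_matrix(ds)
  if (any(!is.finite(m)) || any(m <= 0)) stop("measurements must be positive and finite")
  out <- log10(m)
  structure(out, block_map = attr(ds, "block_map"),
            class = c("cranio_logmatrix", class(out)))
}

#' Size-scaled (Mosimann) shape matrix
#'
#' Each specimen's six measurements are divided by their joint geometric mean
#' before the base-10 log, so each specimen has geometric mean 1 and carries
#' only shape information. Implemented equivalently as log10 followed by
#' row-centering, so every row sums to zero.
#'
#' @param ds A `cranio_dataset`.
#' @return n x 6 matrix (class `cranio_shapematrix`): `log10(x / gm(x))`.
#' @export
shape_matrix <- function(ds) {
  lm <- log_matrix(ds)
  out <- lm - rowMeans(lm)
  structure(unclass(out), block_map = attr(ds, "block_map"),
            class = c("cranio_shapematrix", "matrix", "array"))
}

#' Export an analysis matrix as CSV
#'
#' @param m A matrix from [log_matrix()] or [shape_matrix()].
#' @param path Output path; the specimen id becomes the first column.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(specimen_id = rownames(m), unclass(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
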