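#' @keywords internal
"_PACKAGE"

# Canonical analysis order of the six craniometric variables: neurocranial
# block first (GOL, BBH, XCB), then splanchnocranial (NPH, BPL, ZYB).
# This ordering fixes loading signs/order across the whole pipeline.

#' Craniometric variable names in analysis order
#'
#' `GOL` (glabella-opisthocranion length), `BBH` (basion-bregma height) and
#' `XCB` (maximum biparietal breadth) proxy the neurocranium; `NPH`
#' (nasion-prosthion height), `BPL` (basion-prosthion length) and `ZYB`
#' (bizygomatic breadth) proxy the splanchnocranium. All in mm.
#'
#' @return Character vector of the six variable names.
#' @export
cranio_vars <- function() c("GOL", "BBH", "XCB", "NPH", "BPL", "ZYB")

#' Default block map: which variables form each cranial module
#'
#' @return Named list with elements `neurocranium` and `splanchnocranium`,
#'   each a character vector of three variable names.
#' @export
cranio_blocks <- function() {
  list(neurocranium = c("GOL", "BBH", "XCB"),
       splanchnocranium = c("NPH", "BPL", "ZYB"))
}

.age_classes <- c("adult", "juvenile")
.optional_cols <- c("bm_kg", "ecv_cm3", "geo_age")

#' Construct a validated craniometric dataset
#'
#' A `cranio_dataset` is a data frame of specimens carrying the six
#' craniometric measurements (mm) plus identification columns, with the block
#' assignment and free-form metadata stored as attributes.
#'
#' @param df Data frame with columns `specimen_id`, `taxon`, `group`,
#'   `age_class`, the six measurements, and optionally `bm_kg`, `ecv_cm3`,
#'   `geo_age`.
#' @param block_map Named list assigning the six variables to the two blocks;
#'   defaults to [cranio_blocks()].
#' @param metadata Free-form provenance list.
#' @return Object of class `cranio_dataset` (a data frame).
#' @export
cranio_dataset <- function(df, block_map = cranio_blocks(), metadata = list()) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("specimen_id", "taxon", "group", "age_class", cranio_vars())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in .optional_cols) if (!col %in% names(df)) df[[col]] <- NA_real_
  df <- df[, c(required, .optional_cols)]
  df$specimen_id <- as.character(df$specimen_id)
  df$taxon <- as.character(df$taxon)
  df$group <- as.character(df$group)
  df$age_class <- as.character(df$age_class)
  for (v in c(cranio_vars(), .optional_cols)) df[[v]] <- as.numeric(df[[v]])
  validate_block_map(block_map)
  structure(df,
            block_map = block_map,
            metadata = metadata,
            class = c("cranio_dataset", "data.frame")) |>
    validate_dataset()
}

validate_block_map <- function(block_map) {
  if (!is.list(block_map) ||
      !setequal(names(block_map), c("neurocranium", "splanchnocranium"))) {
    stop("block_map must name exactly the blocks 'neurocranium' and 'splanchnocranium'")
  }
  vars <- unlist(block_map, use.names = FALSE)
  if (length(block_map$neurocranium) != 3L || length(block_map$splanchnocranium) != 3L ||
      !setequal(vars, cranio_vars()) || anyDuplicated(vars) > 0L) {
    stop("block_map must partition the six variables, three per block")
  }
  invisible(block_map)
}

#' Validate a craniometric dataset
#'
#' Checks the specimen-level invariants: all six measurements strictly
#' positive and finite, age classes drawn from `adult`/`juvenile`, and unique
#' specimen ids. Fails with an error naming the offending specimen/variable.
#'
#' @param ds A `cranio_dataset`.
#' @return `ds`, invisibly usable downstream.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "cranio_dataset"))
  if (nrow(ds) == 0L) stop("dataset is empty")
  dup <- ds$specimen_id[duplicated(ds$specimen_id)]
  if (length(dup) > 0L) {
    stop("duplicated specimen_id: ", paste(unique(dup), collapse = ", "))
  }
  bad_age <- !ds$age_class %in% .age_classes
  if (any(bad_age)) {
    stop("invalid age_class for specimen ",
         paste(ds$specimen_id[bad_age], collapse = ", "),
         " (allowed: ", paste(.age_classes, collapse = ", "), ")")
  }
  for (v in cranio_vars()) {
    x <- ds[[v]]
    bad <- !is.finite(x) | x <= 0
    if (any(bad)) {
      stop("non-positive or non-numeric measurement ", v, " for specimen ",
           paste(ds$specimen_id[bad], collapse = ", "))
    }
  }
  ds
}

#' Read a craniometric CSV table
#'
#' Expects a header row; default column names are the standard abbreviations
#' (see [cranio_vars()]). Differently named columns can be mapped through
#' `schema`. Decimal separator is `.`; delimiter is `,` unless `sep = "\t"`.
#'
#' @param path Path to an existing CSV/TSV file.
#' @param schema Named character vector mapping canonical column names to the
#'   file's column names, e.g. `c(GOL = "glabella_opisthocranion")`. Columns
#'   not mentioned keep their canonical names.
#' @param sep Field delimiter, `","` (default) or `"\t"`.
#' @param block_map,metadata Passed to [cranio_dataset()].
#' @return A validated `cranio_dataset`, rows in file order.
#' @export
read_craniometric_csv <- function(path, schema = character(),
                                  sep = ",", block_map = cranio_blocks(),
                                  metadata = list(source = path)) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path) || !file.exists(path)) {
    stop("craniometric table not found: '", path, "'")
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = ".",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  for (canonical in names(schema)) {
    src <- schema[[canonical]]
    if (!src %in% names(raw)) {
      stop("schema column '", src, "' (mapped to ", canonical, ") not present in ", path)
    }
    names(raw)[names(raw) == src] <- canonical
  }
  required <- c("specimen_id", "taxon", "group", "age_class", cranio_vars())
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  cranio_dataset(raw, block_map = block_map, metadata = metadata)
}

#' Write a craniometric dataset to CSV
#'
#' Measurements are written with full precision (at least 3 decimals
#' preserved); missing optional fields become empty cells.
#'
#' @param ds A `cranio_dataset`.
#' @param path Output file path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_craniometric_csv <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "cranio_dataset"))
  out <- as.data.frame(ds)
  utils::write.table(out, path, sep = sep, dec = ".", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Filter specimens by taxon, group, age class or arbitrary predicate
#'
#' Row order and the block map are preserved. An empty result is allowed but
#' flagged with a warning.
#'
#' @param ds A `cranio_dataset`.
#' @param taxon,group,age_class Optional character vectors of levels to keep.
#' @param predicate Optional function taking the dataset's data frame and
#'   returning a logical vector.
#' @return Filtered `cranio_dataset`.
#' @export
filter_specimens <- function(ds, taxon = NULL, group = NULL, age_class = NULL,
                             predicate = NULL) {
  stopifnot(inherits(ds, "cranio_dataset"))
  keep <- rep(TRUE, nrow(ds))
  if (!is.null(taxon)) keep <- keep & ds$taxon %in% taxon
  if (!is.null(group)) keep <- keep & ds$group %in% group
  if (!is.null(age_class)) keep <- keep & ds$age_class %in% age_class
  if (!is.null(predicate)) keep <- keep & as.logical(predicate(as.data.frame(ds)))
  out <- ds[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("filter produced an empty dataset")
  attr(out, "block_map") <- attr(ds, "block_map")
  attr(out, "metadata") <- attr(ds, "metadata")
  class(out) <- class(ds)
  out
}

#' Path of the study measurement table, if installed
#'
#' The original study's specimen measurement table (and the body-mass /
#' endocranial-volume subset) are distributed as supplementary material of
#' the source article and are not bundled here. If a user transcribes them to
#' `inst/extdata/hominid_craniometrics.csv` (and
#' `inst/extdata/hominid_bm_ecv.csv`) before installation, this helper
#' locates them; otherwise it returns `""`.
#'
#' @param which `"measurements"` or `"bm_ecv"`.
#' @return File path, or `""` when the table is not installed.
#' @export
study_data_path <- function(which = c("measurements", "bm_ecv")) {
  which <- match.arg(which)
  fname <- switch(which,
                  measurements = "hominid_craniometrics.csv",
                  bm_ecv = "hominid_bm_ecv.csv")
  system.file("extdata", fname, package = "craniomod")
}

#' @export
print.cranio_dataset <- function(x, ...) {
  cat("<cranio_dataset> ", nrow(x), " specimens, ",
      length(unique(x$group)), " groups (",
      sum(x$age_class == "adult"), " adults, ",
      sum(x$age_class == "juvenile"), " juveniles)\n", sep = "")
  NextMethod()
}
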