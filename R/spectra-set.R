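# Metadata columns a spectra_set may carry, in canonical order. Any column of
# the tibble not in this list is treated as a spectral (wavenumber) column.
META_COLS <- c("spectrum_id", "sample_id", "genet_id", "species", "population",
               "temperature", "nutrient", "replicate")

#' Spectra set: a tibble of FTIR spectra with sample metadata
#'
#' A `spectra_set` is a tibble with one row per measured spectrum. Metadata
#' columns (`spectrum_id`, `sample_id`, `genet_id`, `species`, `population`,
#' `temperature`, `nutrient`, `replicate` — whichever apply) come first,
#' followed by one numeric column per wavenumber, named by the wavenumber
#' value. Because it is a plain tibble, all dplyr verbs apply; the class is
#' re-attached by the accessors below.
#'
#' @param meta A data frame of per-spectrum metadata (columns from the set
#'   above; must include `spectrum_id`).
#' @param mat Numeric matrix of absorbances, rows matching `meta` rows.
#' @param wn Wavenumber axis, length `ncol(mat)`.
#'
#' @return A tibble with class `spectra_set`.
#' @seealso [spectra_matrix()], [spectra_meta()], [wavenumbers()],
#'   [read_spectra()], [write_spectra()]
#' @export
spectra_set <- function(meta, mat, wn) {
  meta <- as_tibble(meta)
  if (!"spectrum_id" %in% names(meta)) abort("`meta` must have `spectrum_id`.")
  extra <- setdiff(names(meta), META_COLS)
  if (length(extra)) {
    abort(paste0("Unknown metadata column(s): ", paste(extra, collapse = ", ")))
  }
  mat <- as.matrix(mat)
  check_axis(wn)
  if (nrow(mat) != nrow(meta)) abort("Row count of `mat` must match `meta`.")
  if (ncol(mat) != length(wn)) abort("`mat` must have one column per wavenumber.")
  if (!all(is.finite(mat))) abort("All absorbances must be finite.")
  if (anyDuplicated(meta$spectrum_id)) abort("`spectrum_id` must be unique.")
  colnames(mat) <- format_wn(wn)
  out <- bind_cols(meta[intersect(META_COLS, names(meta))], as_tibble(mat))
  new_spectra_set(out)
}

new_spectra_set <- function(x) {
  class(x) <- unique(c("spectra_set", class(as_tibble(x))))
  x
}

format_wn <- function(wn) sprintf("%.3f", wn)

spectral_cols <- function(x) setdiff(names(x), META_COLS)

#' Extract the absorbance matrix of a spectra set
#'
#' @param x A [spectra_set()] (or any data frame with wavenumber-named
#'   columns).
#' @return Numeric matrix, spectra in rows, wavenumbers in columns.
#' @export
spectra_matrix <- function(x) {
  sc <- spectral_cols(x)
  m <- as.matrix(as_tibble(x)[sc])
  storage.mode(m) <- "double"
  rownames(m) <- if ("spectrum_id" %in% names(x)) x$spectrum_id else NULL
  m
}

#' Extract the metadata columns of a spectra set
#' @inheritParams spectra_matrix
#' @return A tibble of the metadata columns only.
#' @export
spectra_meta <- function(x) {
  tib <- as_tibble(x)
  class(tib) <- setdiff(class(tib), "spectra_set")
  tib[intersect(META_COLS, names(tib))]
}

#' Extract the wavenumber axis of a spectra set
#' @inheritParams spectra_matrix
#' @return Numeric vector of wavenumbers (cm^-1), parsed from column names.
#' @export
wavenumbers <- function(x) {
  wn <- suppressWarnings(as.numeric(spectral_cols(x)))
  if (anyNA(wn)) abort("Non-numeric spectral column names; not a spectra set?")
  wn
}

# Rebuild a spectra_set from existing metadata and a replacement matrix.
set_spectra_matrix <- function(x, mat, wn = wavenumbers(x)) {
  spectra_set(spectra_meta(x), mat, wn)
}

#' @export
print.spectra_set <- function(x, ...) {
  wn <- wavenumbers(x)
  cat(sprintf("<spectra_set: %d spectra x %d wavenumbers (%.1f-%.1f cm^-1)>\n",
              nrow(x), length(wn), max(wn), min(wn)))
  print(spectra_meta(x), ...)
  invisible(x)
}

#' Write a spectra set as CSV matrix + metadata files
#'
#' The spectral matrix goes to one CSV (first column `spectrum_id`, remaining
#' columns headed by wavenumber values); the metadata table to a second CSV.
#' Absorbances are written with full `%.17g` precision so a write/read
#' round-trip is bit-exact.
#'
#' @param x A [spectra_set()].
#' @param matrix_path,metadata_path Output CSV paths.
#' @return `x`, invisibly.
#' @export
write_spectra <- function(x, matrix_path, metadata_path) {
  mat <- spectra_matrix(x)
  chr <- matrix(sprintf("%.17g", mat), nrow = nrow(mat),
                dimnames = dimnames(mat))
  tab <- bind_cols(tibble(spectrum_id = spectra_meta(x)$spectrum_id),
                   as_tibble(chr))
  readr::write_csv(tab, matrix_path)
  readr::write_csv(spectra_meta(x), metadata_path)
  invisible(x)
}

#' Read a spectra set from CSV matrix + metadata files
#'
#' Inverse of [write_spectra()]. The matrix file must have a `spectrum_id`
#' first column and wavenumber-headed numeric columns; every spectrum id must
#' appear exactly once in the metadata file.
#'
#' @param matrix_path,metadata_path CSV paths as written by [write_spectra()].
#' @return A [spectra_set()].
#' @export
read_spectra <- function(matrix_path, metadata_path) {
  # base strtod parsing is correctly rounded, so %.17g output round-trips
  # bit-exactly (readr's fast float path can be 1 ulp off)
  tab <- as_tibble(utils::read.csv(matrix_path, check.names = FALSE,
                                   colClasses = c(spectrum_id = "character")))
  if (names(tab)[1] != "spectrum_id") {
    abort("Matrix file must have `spectrum_id` as its first column.")
  }
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE)
  if ("replicate" %in% names(meta)) meta$replicate <- as.integer(meta$replicate)
  missing_ids <- setdiff(tab$spectrum_id, meta$spectrum_id)
  if (length(missing_ids)) {
    abort(paste0("Metadata missing spectrum id(s): ",
                 paste(head(missing_ids, 5), collapse = ", ")))
  }
  extra_ids <- setdiff(meta$spectrum_id, tab$spectrum_id)
  if (length(extra_ids)) {
    abort(paste0("Matrix missing spectrum id(s): ",
                 paste(head(extra_ids, 5), collapse = ", ")))
  }
  meta <- meta[match(tab$spectrum_id, meta$spectrum_id), ]
  wn <- suppressWarnings(as.numeric(names(tab)[-1]))
  if (anyNA(wn)) abort("Matrix columns must be headed by wavenumber values.")
  mat <- as.matrix(tab[-1])
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-numeric/missing absorbance at row %d, column %s.",
                  bad[1], names(tab)[-1][bad[2]]))
  }
  spectra_set(meta, mat, wn)
}
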