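#' Savitzky-Golay second derivative of spectra
#'
#' Applies the Savitzky-Golay derivative filter to every spectrum: a local
#' least-squares polynomial of degree `polyorder` over a sliding window of
#' `window` points, evaluated as its second derivative. Defaults (degree 2,
#' window 7) are the standard choice for FTIR fingerprinting. The derivative
#' is taken in index units (the uniform grid step is the unit); at the edges
#' the window polynomial is fitted one-sidedly and evaluated at the shifted
#' point, so the output length equals the input length.
#'
#' @param x A [spectra_set()].
#' @param window Odd window size in points (> `polyorder`).
#' @param polyorder Polynomial degree (>= 2, the derivative order).
#' @return A [spectra_set()] of the same shape.
#' @export
sg_second_derivative <- function(x, window = 7, polyorder = 2) {
  wn <- wavenumbers(x)
  check_axis(wn)
  if (window %% 2 != 1) abort("`window` must be odd.")
  if (window <= polyorder) abort("`window` must exceed `polyorder`.")
  if (polyorder < 2) abort("`polyorder` must be at least 2 (derivative order).")
  mat <- spectra_matrix(x)
  if (ncol(mat) < window) abort("Spectrum shorter than the filter window.")
  out <- t(apply(mat, 1, function(z) {
    signal::sgolayfilt(z, p = polyorder, n = window, m = 2, ts = 1)
  }))
  set_spectra_matrix(x, out)
}

#' Extended multiplicative signal correction (EMSC)
#'
#' Fits each spectrum \eqn{z} by ordinary least squares to the model
#' \deqn{z \approx a + b\,m + c\tilde\nu + d\tilde\nu^2}
#' where \eqn{m} is a reference spectrum and \eqn{\tilde\nu} the wavenumber
#' axis rescaled to \[-1, 1\], then returns the corrected spectrum
#' \eqn{(z - a - c\tilde\nu - d\tilde\nu^2)/b}. This removes multiplicative
#' scatter and any baseline in the span of \{1, \eqn{\tilde\nu},
#' \eqn{\tilde\nu^2}\} exactly. Spectra whose fitted scale \eqn{|b|} falls
#' below `tol` cannot be corrected; they are dropped with a warning.
#'
#' @param x A [spectra_set()].
#' @param reference Reference spectrum \eqn{m}: `"mean"` (column mean of `x`,
#'   the default) or a numeric vector on the same axis.
#' @param tol Degeneracy tolerance for the multiplicative coefficient.
#' @return A [spectra_set()] with attribute `"emsc_params"`: a tibble
#'   (`spectrum_id`, `a`, `b`, `c`, `d`) of the fitted parameters, and
#'   attribute `"emsc_reference"` holding \eqn{m}.
#' @export
emsc_correct <- function(x, reference = "mean", tol = 1e-8) {
  wn <- wavenumbers(x)
  mat <- spectra_matrix(x)
  m <- if (identical(reference, "mean")) colMeans(mat) else as.numeric(reference)
  if (length(m) != length(wn)) abort("Reference length must match the axis.")
  if (all(m == 0)) abort("Reference spectrum is identically zero.")
  lam <- axis_unit_scale(wn)
  design <- cbind(`1` = 1, m = m, lam = lam, lam2 = lam^2)
  qrd <- qr(design)
  coef <- qr.coef(qrd, t(mat))          # 4 x n_spectra
  b <- coef[2, ]
  degen <- abs(b) < tol
  if (any(degen)) {
    warn(sprintf("Dropping %d spectrum/spectra with degenerate EMSC fit: %s",
                 sum(degen),
                 paste(head(rownames(mat)[degen], 5), collapse = ", ")))
  }
  keep <- which(!degen)
  corrected <- (mat[keep, , drop = FALSE] -
                  tcrossprod(t(coef[c(1, 3, 4), keep, drop = FALSE]),
                             design[, c(1, 3, 4)])) / b[keep]
  out <- set_spectra_matrix(
    as_tibble(x)[keep, , drop = FALSE], corrected, wn)
  params <- tibble(spectrum_id = spectra_meta(x)$spectrum_id,
                   a = coef[1, ], b = coef[2, ], c = coef[3, ], d = coef[4, ])
  attr(out, "emsc_params") <- params
  attr(out, "emsc_reference") <- m
  out
}

#' Average technical replicates
#'
#' Collapses the spectra of each sample (grouped by `sample_id` by default) to
#' their arithmetic mean. The replicate column is dropped; metadata fields
#' constant within a group are kept; sample order follows first occurrence.
#'
#' @param x A [spectra_set()].
#' @param group Metadata column to average within (default `"sample_id"`).
#' @return A [spectra_set()] with one spectrum per group.
#' @export
average_replicates <- function(x, group = "sample_id") {
  meta <- spectra_meta(x)
  if (!group %in% names(meta)) {
    abort(sprintf("Grouping column `%s` not present.", group))
  }
  mat <- spectra_matrix(x)
  ids <- factor(meta[[group]], levels = unique(meta[[group]]))
  avg <- rowsum(mat, ids, reorder = FALSE) / as.vector(table(ids)[levels(ids)])
  keep_meta <- meta[!duplicated(ids), setdiff(names(meta), "replicate"),
                    drop = FALSE]
  # a collapsed sample is identified by its group id
  keep_meta$spectrum_id <- as.character(unique(ids))
  spectra_set(keep_meta, avg, wavenumbers(x))
}

#' Pearson-correlation spectral variability
#'
#' Summarises how variable a set of spectra is over a spectral region as the
#' mean over all unordered spectrum pairs of \eqn{(1 - r) \times 10^4}, with
#' \eqn{r} the Pearson correlation of the two spectra restricted to the
#' region. The default region, 1,700-1,600 cm^-1, covers the amide I band
#' where biological variation concentrates. Pairs involving a spectrum with
#' zero variance in the region are skipped with a warning.
#'
#' @param x A [spectra_set()] with at least two spectra.
#' @param region Numeric length-2 wavenumber bounds (order-free), cm^-1.
#' @return A single number: mean pairwise (1 - PCC) x 10^4.
#' @export
pcc_variability <- function(x, region = c(1600, 1700)) {
  wn <- wavenumbers(x)
  lo <- min(region); hi <- max(region)
  sel <- wn >= lo & wn <= hi
  if (!any(sel)) abort("No axis points fall inside `region`.")
  mat <- spectra_matrix(x)[, sel, drop = FALSE]
  if (nrow(mat) < 2) abort("Need at least two spectra.")
  sds <- apply(mat, 1, sd)
  flat <- sds == 0
  if (any(flat)) {
    warn(sprintf("Skipping %d zero-variance spectrum/spectra in the region.",
                 sum(flat)))
    mat <- mat[!flat, , drop = FALSE]
    if (nrow(mat) < 2) abort("Fewer than two usable spectra in the region.")
  }
  r <- cor(t(mat))
  mean((1 - r[upper.tri(r)]) * 1e4)
}

#' Standard preprocessing pipeline
#'
#' The analysis-ready representation, in the canonical order: Savitzky-Golay
#' second derivative, EMSC against the dataset mean (computed once, before
#' any modelling), then technical-replicate averaging.
#'
#' @param x A raw [spectra_set()].
#' @param window,polyorder Savitzky-Golay settings, see
#'   [sg_second_derivative()].
#' @param reference EMSC reference, see [emsc_correct()].
#' @param average Average technical replicates afterwards? (default TRUE; set
#'   FALSE for replicate-level variability analyses).
#' @return A preprocessed [spectra_set()].
#' @export
preprocess_spectra <- function(x, window = 7, polyorder = 2,
                               reference = "mean", average = TRUE) {
  out <- sg_second_derivative(x, window = window, polyorder = polyorder)
  out <- emsc_correct(out, reference = reference)
  if (average && "sample_id" %in% names(spectra_meta(out))) {
    out <- average_replicates(out)
  }
  out
}
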