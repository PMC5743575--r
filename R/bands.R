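#' Constituent band library for grass pollen spectra
#'
#' Catalogue of Gaussian absorption bands used by the synthetic spectrum
#' generator, grouped by biochemical constituent. Band centres follow the
#' assignments established for grass pollen FTIR spectra: amide I/II protein
#' bands near 1,650 and 1,540 cm^-1; lipid carbonyl and acyl-chain bands
#' (1,745, 1,712, 1,470, 1,170, 2,923 cm^-1); carbohydrate C-O/C-C stretches
#' in the 1,200-900 cm^-1 window (amylose, cellulose and arabinoxylan
#' signals); phenylpropanoid sporopollenin bands (1,668, 1,658, 1,625, 1,512,
#' 850, 835, 815 cm^-1); and the ubiquitous CH-stretch envelope at 3,050 and
#' 2,960-2,830 cm^-1. Widths (Gaussian sigma) and relative amplitudes are
#' generator defaults: sharp condensed-phase bands get sigma near 10-15 cm^-1,
#' the broad CH-stretch envelope 40 cm^-1.
#'
#' @return A tibble with columns `constituent`, `center` (cm^-1), `width`
#'   (Gaussian sigma, cm^-1) and `amplitude` (relative absorbance).
#' @examples
#' band_library()
#' @export
band_library <- function() {
  bands <- tibble::tribble(
    ~constituent,    ~center, ~width, ~amplitude,
    "protein",        1650,     25,    1.00,  # amide I (C=O stretch)
    "protein",        1540,     22,    0.75,  # amide II (NH def / C-N stretch)
    "lipid",          2923,     25,    0.45,  # acyl C-H stretch
    "lipid",          1745,     14,    0.55,  # ester C=O stretch
    "lipid",          1712,     12,    0.20,
    "lipid",          1470,     12,    0.30,  # CH2 deformation
    "lipid",          1170,     14,    0.30,  # C-C stretch
    "carbohydrate",   1164,     12,    0.30,  # arabinoxylan
    "carbohydrate",   1083,     14,    0.55,
    "carbohydrate",   1076,     14,    0.65,  # amylose
    "carbohydrate",   1052,     15,    0.80,  # amylose
    "carbohydrate",   1023,     13,    0.60,
    "carbohydrate",    995,     15,    0.35,
    "carbohydrate",    930,     16,    0.20,
    "sporopollenin",  1668,     11,    0.28,
    "sporopollenin",  1658,     11,    0.28,
    "sporopollenin",  1625,     13,    0.35,
    "sporopollenin",  1512,     11,    0.50,
    "sporopollenin",   850,     10,    0.25,
    "sporopollenin",   835,     10,    0.25,
    "sporopollenin",   815,     10,    0.18,
    "CH-stretch",     3050,     40,    0.15,  # =C-H stretch
    "CH-stretch",     2960,     40,    0.35,  # CH3 stretch envelope
    "CH-stretch",     2870,     40,    0.28,
    "CH-stretch",     2850,     40,    0.22
  )
  bands
}

# Pure (noise/scatter free) constituent profiles evaluated on an axis:
# matrix with one column per constituent, rows = axis points.
constituent_profiles <- function(wn, bands = band_library()) {
  cons <- unique(bands$constituent)
  out <- matrix(0, nrow = length(wn), ncol = length(cons),
                dimnames = list(NULL, cons))
  for (i in seq_len(nrow(bands))) {
    b <- bands[i, ]
    out[, b$constituent] <- out[, b$constituent] +
      b$amplitude * exp(-0.5 * ((wn - b$center) / b$width)^2)
  }
  out
}

#' Synthesize a single FTIR spectrum from constituent weights
#'
#' Forward model for one measured spectrum: a non-negative mixture of the
#' Gaussian constituent bands, distorted by a multiplicative scatter factor
#' and a quadratic baseline, plus i.i.d. Gaussian detector noise:
#' \deqn{z(\nu) = b\, m(\nu) + a + c\tilde\nu + d\tilde\nu^2 + \varepsilon}
#' where \eqn{m} is the weighted band mixture and \eqn{\tilde\nu} is the axis
#' rescaled to \[-1, 1\]. These are exactly the artifact classes that EMSC
#' with linear and quadratic components removes.
#'
#' @param weights Named non-negative numeric vector of constituent weights
#'   (names must appear in [band_library()]'s `constituent` column; missing
#'   constituents count as 0).
#' @param wn Wavenumber axis (see [wavenumber_axis()]).
#' @param scatter Numeric vector `c(b, a, c, d)`: multiplicative scale,
#'   additive offset, linear and quadratic baseline coefficients. Defaults to
#'   the undistorted `c(1, 0, 0, 0)`.
#' @param noise_sd Standard deviation of additive Gaussian noise (absorbance
#'   units).
#' @param bands Band library tibble; defaults to [band_library()].
#'
#' @return Numeric vector of absorbances, one per axis point.
#' @examples
#' wn <- wavenumber_axis(1800, 900, 2)
#' z <- synthesize_spectrum(c(protein = 1, carbohydrate = 0.5), wn)
#' @export
synthesize_spectrum <- function(weights, wn, scatter = c(1, 0, 0, 0),
                                noise_sd = 0, bands = band_library()) {
  if (any(weights < 0)) abort("Constituent weights must be non-negative.")
  if (length(scatter) != 4L) abort("`scatter` must be c(b, a, c, d).")
  prof <- constituent_profiles(wn, bands)
  w <- setNames(numeric(ncol(prof)), colnames(prof))
  known <- intersect(names(weights), names(w))
  if (length(known) < length(weights)) {
    abort(paste0("Unknown constituent(s): ",
                 paste(setdiff(names(weights), names(w)), collapse = ", ")))
  }
  w[known] <- weights[known]
  m <- drop(prof %*% w)
  lam <- axis_unit_scale(wn)
  z <- scatter[1] * m + scatter[2] + scatter[3] * lam + scatter[4] * lam^2
  if (noise_sd > 0) z <- z + rnorm(length(wn), sd = noise_sd)
  z
}
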