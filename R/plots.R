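#' Plot spectra
#'
#' Line plot of (a subset of) the spectra, wavenumber axis reversed as is
#' conventional for infrared spectra, coloured by a metadata column.
#'
#' @param object A [spectra_set()].
#' @param colour Metadata column to colour by (default `species` if present).
#' @param max_spectra Cap on the number of spectra drawn (sampled evenly).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectra_set <- function(object, colour = NULL, max_spectra = 30,
                                 ...) {
  meta <- spectra_meta(object)
  colour <- colour %||% (if ("species" %in% names(meta)) "species" else NULL)
  idx <- if (nrow(object) > max_spectra) {
    unique(round(seq(1, nrow(object), length.out = max_spectra)))
  } else seq_len(nrow(object))
  tib <- as_tibble(object)[idx, , drop = FALSE]
  long <- tidyr::pivot_longer(tib, cols = all_of(spectral_cols(object)),
                              names_to = "wavenumber",
                              values_to = "absorbance") %>%
    mutate(wavenumber = as.numeric(.data$wavenumber))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                          group = .data$spectrum_id)) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = expression(Wavenumber ~ (cm^-1)), y = "Absorbance")
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data[[colour]]),
                                linewidth = 0.3)
  } else {
    p <- p + ggplot2::geom_line(linewidth = 0.3)
  }
  p
}

#' Plot a cross-validation grid
#'
#' Misclassification rate against degree of sparsity, one line per component
#' count, with the selected setting marked.
#'
#' @param object A [select_sparsity_cv()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splsr_cv <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data$sparsity, .data$mcr,
                               colour = factor(.data$ncomp))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = glance(object), colour = "black", size = 2) +
    ggplot2::labs(x = "Degree of sparsity", y = "CV misclassification rate",
                  colour = "Components")
}

#' Plot a permutation-test null distribution
#'
#' Histogram of permuted success rates with the observed SR marked.
#'
#' @param object A [permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$sr)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_sr, colour = "red") +
    ggplot2::labs(x = "Success rate (%)", y = "Permutations",
                  subtitle = sprintf("observed SR %.1f%%, p = %.4g",
                                     object$observed_sr, object$p_value))
}
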