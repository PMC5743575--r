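#' Permutation test of a cross-validated classification model
#'
#' Assesses whether a classification model captures real class structure: the
#' observed statistic is the cross-validated success rate (SR) of the full
#' model-selection procedure ([select_sparsity_cv()], including the sparsity
#' search) on the true labels; each permutation shuffles the labels and
#' reruns the *identical* procedure, so selection optimism cannot leak into
#' the null distribution. The p-value uses the add-one estimator
#' \deqn{p = (1 + \#\{SR_{perm} \ge SR_{obs}\}) / (1 + n_{perm})}
#' which is valid by exchangeability and can never be zero (its floor is
#' \eqn{1/(1+n_{perm})}).
#'
#' @inheritParams select_sparsity_cv
#' @param n_perm Number of label permutations (>= 19; default 999).
#' @param seed Integer seed controlling folds and permutations.
#' @return An object of class `permutation_result`: list with `observed_sr`,
#'   `permuted_sr` (length `n_perm`), `p_value`, `n_perm`, `seed`.
#' @export
permutation_test <- function(data, response,
                             sparsity_grid = seq(0.90, 0.99, by = 0.01),
                             ncomp_grid = 1:15, folds = 3,
                             n_perm = 999, seed = 1) {
  labels <- as.character(pull_response(data, {{ response }}))
  if (length(unique(labels)) < 2) abort("Labels are constant.")
  if (n_perm < 19) abort("Use at least 19 permutations.")
  run_cv <- function(lab, cv_seed) {
    cv_with_labels(data, lab, sparsity_grid, ncomp_grid, folds, cv_seed)$sr
  }
  observed <- run_cv(labels, derive_seed(seed, "cv", 0))
  permuted <- vapply(seq_len(n_perm), function(i) {
    perm <- withr::with_seed(derive_seed(seed, "perm", i), sample(labels))
    run_cv(perm, derive_seed(seed, "cv", i))
  }, numeric(1))
  p <- (1 + sum(permuted >= observed)) / (1 + n_perm)
  structure(list(observed_sr = observed, permuted_sr = permuted,
                 p_value = p, n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result: observed SR %.1f%%, p = %.4g (%d permutations)>\n",
              x$observed_sr, x$p_value, x$n_perm))
  invisible(x)
}

#' Per-population environmental-factor models
#'
#' For a single population's samples, fits the cross-validated classification
#' model separating one environmental factor: `"temperature"` (14 vs 20 C,
#' binary), `"nutrients"` (+NU vs -NU, binary) or `"interaction"` (the four
#' temperature x nutrient groups; by convention fitted with the component
#' count fixed at 10). Optionally attaches a permutation test of the model.
#'
#' @param data A preprocessed, averaged [spectra_set()] restricted to one
#'   population.
#' @param factor One of `"temperature"`, `"nutrients"`, `"interaction"`.
#' @param sparsity_grid,folds CV settings, see [select_sparsity_cv()].
#' @param ncomp_grid Component-count candidates for the binary factors; the
#'   interaction model always uses 10 components.
#' @param n_perm Number of permutations; 0 skips the permutation test.
#' @param seed Integer seed.
#' @return A list with the `cv` result ([select_sparsity_cv()]) and, when
#'   `n_perm > 0`, the `permutation` ([permutation_test()]) result.
#' @export
factor_models <- function(data, factor = c("temperature", "nutrients",
                                           "interaction"),
                          sparsity_grid = seq(0.90, 0.99, by = 0.01),
                          ncomp_grid = 1:15, folds = 3, n_perm = 999,
                          seed = 1) {
  factor <- match.arg(factor)
  meta <- spectra_meta(data)
  if (length(unique(meta$population)) > 1 ||
      length(unique(meta$species)) > 1) {
    abort("`data` must be restricted to a single population.")
  }
  labels <- switch(factor,
                   temperature = meta$temperature,
                   nutrients = meta$nutrient,
                   interaction = paste(meta$temperature, meta$nutrient,
                                       sep = "/"))
  if (length(unique(labels)) < 2) {
    abort(sprintf("Factor `%s` has a single level in this subset.", factor))
  }
  if (factor == "interaction") ncomp_grid <- 10
  cv <- cv_with_labels(data, labels, sparsity_grid, ncomp_grid, folds,
                       derive_seed(seed, "factor", factor))
  out <- list(factor = factor, cv = cv)
  if (n_perm > 0) {
    tib <- as_tibble(data)
    tib$species <- labels # response slot convention of cv_with_labels
    out$permutation <- permutation_test(
      new_spectra_set(tib), species, sparsity_grid = sparsity_grid,
      ncomp_grid = ncomp_grid, folds = folds, n_perm = n_perm,
      seed = derive_seed(seed, "permfactor", factor))
  }
  out
}
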