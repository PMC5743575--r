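#' Tidy a sparse PLS discriminant model
#'
#' One row per (wavenumber, component) with a nonzero loading weight, plus
#' the regression coefficients per class.
#'
#' @param x An [fit_splsr()] model.
#' @param ... Unused.
#' @return A tibble: `wavenumber`, `component`, `weight`, one
#'   `coef_<class>` column per class.
#' @export
tidy.splsr <- function(x, ...) {
  wn <- suppressWarnings(as.numeric(x$variables))
  coefs <- as_tibble(x$B)
  names(coefs) <- paste0("coef_", x$levels)
  purrr::map_dfr(seq_len(x$ncomp), function(k) {
    nz <- which(x$W[, k] != 0)
    tibble(wavenumber = wn[nz], component = k, weight = x$W[nz, k])
  }) %>%
    left_join(bind_cols(tibble(wavenumber = wn), coefs), by = "wavenumber")
}

#' @export
glance.splsr <- function(x, ...) {
  tibble(ncomp = x$ncomp, n_classes = length(x$levels),
         n_variables = nrow(x$W),
         n_selected = sum(rowSums(x$W != 0) > 0),
         sparsity = paste(format(x$sparsity), collapse = "/"))
}

#' Tidy a cross-validation result
#'
#' @param x A [select_sparsity_cv()] result.
#' @param ... Unused.
#' @return The CV grid tibble (`sparsity`, `ncomp`, `mcr`, `sr`).
#' @export
tidy.splsr_cv <- function(x, ...) x$grid

#' @export
glance.splsr_cv <- function(x, ...) {
  tibble(sparsity = x$sparsity, ncomp = x$ncomp, mcr = x$mcr, sr = x$sr)
}

#' Tidy a permutation test result
#'
#' @param x A [permutation_test()] result.
#' @param ... Unused.
#' @return A tibble with one row per permutation (`permutation`, `sr`).
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(permutation = seq_len(x$n_perm), sr = x$permuted_sr)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed_sr = x$observed_sr, p_value = x$p_value,
         n_perm = x$n_perm,
         permuted_sr_mean = mean(x$permuted_sr))
}

#' Tidy a Fisher scatter result
#'
#' @param x A [fisher_scatter()] result.
#' @param ... Unused.
#' @return A tibble with one row per group: `group`, `n`, and the group
#'   mean's distance from the global mean.
#' @export
tidy.fisher_result <- function(x, ...) {
  tibble(group = names(x$group_sizes),
         n = as.integer(x$group_sizes),
         dist_from_global = vapply(x$group_means, function(m) {
           sqrt(sum((m - x$global_mean)^2))
         }, numeric(1)))
}

#' @export
glance.fisher_result <- function(x, ...) {
  tibble(fcc = x$fcc, trace_sb = sum(diag(x$Sb)), trace_sw = sum(diag(x$Sw)),
         n_groups = length(x$group_sizes), n_dims = x$n_dims)
}

#' Tidy a hierarchy model
#'
#' @param x A [train_hierarchy()] model.
#' @param ... Unused.
#' @return A tibble with one row per tree node: level, path, node type and,
#'   for fitted nodes, the chosen sparsity / component count and CV success
#'   rate.
#' @export
tidy.hierarchy_model <- function(x, ...) {
  node_row <- function(node, level, path) {
    if (node$type == "passthrough") {
      tibble(level = level, path = path, type = "passthrough",
             sparsity = NA_real_, ncomp = NA_integer_, cv_sr = NA_real_)
    } else {
      tibble(level = level, path = path, type = "model",
             sparsity = node$cv$sparsity, ncomp = as.integer(node$cv$ncomp),
             cv_sr = node$cv$sr)
    }
  }
  bind_rows(
    node_row(x$root, "species", "(root)"),
    purrr::imap_dfr(x$pop_nodes, ~ node_row(.x, "population", .y)),
    purrr::imap_dfr(x$cond_nodes, ~ node_row(.x, "condition",
                                             gsub("\\|\\|", " / ", .y))))
}

#' @export
glance.hierarchy_model <- function(x, ...) {
  tibble(n_models = x$n_models, n_train = length(x$train_ids), seed = x$seed)
}
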