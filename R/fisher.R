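#' PCA scores of a spectra set
#'
#' Column-centered principal component scores via singular value
#' decomposition, with a deterministic sign convention (the largest-magnitude
#' loading of each component is made positive) so repeated runs are
#' bit-identical.
#'
#' @param data A [spectra_set()] (>= 2 spectra).
#' @param ncomp Number of components; `NULL` keeps the smallest number
#'   explaining at least `var_explained` of variance, capped at `max_comp`.
#' @param var_explained Variance-explained threshold for automatic `ncomp`.
#' @param max_comp Cap on the automatic component count.
#' @return A numeric scores matrix (samples x components) with attribute
#'   `"var_explained"` (cumulative fraction per component).
#' @export
pca_scores <- function(data, ncomp = NULL, var_explained = 0.99,
                       max_comp = 10) {
  X <- spectra_matrix(data)
  if (nrow(X) < 2) abort("Need at least two spectra.")
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d[1], 1e-300) * 1e-12
  rank <- sum(pos)
  cumvar <- cumsum(sv$d^2) / sum(sv$d^2)
  if (is.null(ncomp)) {
    ncomp <- min(which(cumvar[seq_len(rank)] >= var_explained), max_comp)
  } else if (ncomp > rank) {
    warn(sprintf("Truncating `ncomp` from %d to rank %d.", ncomp, rank))
    ncomp <- rank
  }
  keep <- seq_len(ncomp)
  # sign convention: largest |loading| entry positive
  flip <- vapply(keep, function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u[, keep, drop = FALSE] %*%
                    diag(sv$d[keep], ncomp), 2, flip, `*`)
  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", keep)
  attr(scores, "var_explained") <- cumvar[keep]
  scores
}

#' Fisher scatter analysis of genotype-based clustering
#'
#' Quantifies phenotypic rigidity: how strongly samples cluster by genotype
#' (genet) when the same genotype has been grown under different
#' environmental conditions. On a score matrix (typically PCA scores of
#' preprocessed spectra for one population), computes the between-group and
#' within-group scatter matrices
#' \deqn{S_b = \sum_i n_i (\mu - \bar x_i)(\mu - \bar x_i)^T, \qquad
#'       S_w = \sum_i \sum_j (\bar x_i - x_{ij})(\bar x_i - x_{ij})^T}
#' (\eqn{\mu} the global mean, \eqn{\bar x_i} the mean of group \eqn{i},
#' \eqn{n_i} its size) and the Fisher clustering coefficient
#' \deqn{FCC = \mathrm{tr}(S_b)/\mathrm{tr}(S_w),} the rotation-invariant
#' scalar reduction of the matrix ratio. High FCC = tight genotype clusters
#' relative to environmental spread (rigidity); low FCC = plasticity or
#' random variation. Singleton groups contribute nothing to \eqn{S_w}; if
#' \eqn{S_w} is identically zero the FCC is flagged infinite.
#'
#' @param scores Numeric matrix (samples x dimensions), e.g. from
#'   [pca_scores()].
#' @param groups Group (genotype) label per row.
#' @return An object of class `fisher_result`: list with `Sb`, `Sw`, `fcc`,
#'   `global_mean`, `group_means`, `group_sizes`, `n_dims`.
#' @examples
#' s <- matrix(c(-1.5, -0.5, 0.5, 1.5), ncol = 1)
#' fisher_scatter(s, c("A", "A", "B", "B"))$fcc # 4
#' @export
fisher_scatter <- function(scores, groups) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(groups)) abort("One group label per row needed.")
  mu <- colMeans(scores)
  d <- ncol(scores)
  Sb <- matrix(0, d, d); Sw <- matrix(0, d, d)
  means <- list(); sizes <- integer(0)
  for (g in unique(groups)) {
    xi <- scores[groups == g, , drop = FALSE]
    ni <- nrow(xi)
    xbar <- colMeans(xi)
    Sb <- Sb + ni * tcrossprod(mu - xbar)
    dev <- sweep(xi, 2, xbar)
    Sw <- Sw + crossprod(dev)
    means[[g]] <- xbar; sizes[g] <- ni
  }
  tw <- sum(diag(Sw))
  fcc <- if (tw == 0) Inf else sum(diag(Sb)) / tw
  structure(list(Sb = Sb, Sw = Sw, fcc = fcc, global_mean = mu,
                 group_means = means, group_sizes = sizes, n_dims = d),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("<fisher_result: FCC = %s over %d group(s) in %d dimension(s)>\n",
              format(x$fcc, digits = 4), length(x$group_sizes), x$n_dims))
  invisible(x)
}

#' Genotype clustering coefficient per population
#'
#' Convenience wrapper running [pca_scores()] + [fisher_scatter()] for each
#' (species, population) subset of a preprocessed, averaged spectra set, with
#' genets as groups.
#'
#' @param data A preprocessed, averaged [spectra_set()] carrying `genet_id`.
#' @param ncomp,var_explained,max_comp Passed to [pca_scores()].
#' @return A tibble: `species`, `population`, `n_samples`, `n_pcs`, `fcc`.
#' @export
fisher_clustering <- function(data, ncomp = NULL, var_explained = 0.99,
                              max_comp = 10) {
  meta <- spectra_meta(data)
  if (!"genet_id" %in% names(meta)) abort("`data` must carry `genet_id`.")
  tib <- as_tibble(data)
  combos <- distinct(meta, .data$species, .data$population)
  purrr::pmap_dfr(combos, function(species, population) {
    idx <- meta$species == species & meta$population == population
    sub <- new_spectra_set(tib[idx, , drop = FALSE])
    sc <- pca_scores(sub, ncomp = ncomp, var_explained = var_explained,
                     max_comp = max_comp)
    fr <- fisher_scatter(sc, spectra_meta(sub)$genet_id)
    tibble(species = species, population = population,
           n_samples = sum(idx), n_pcs = ncol(sc), fcc = fr$fcc)
  })
}
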