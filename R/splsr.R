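# ---- low-level NIPALS sparse PLS2 --------------------------------------
#
# X, Y are already column-centered. Sequential component extraction: for each
# component the dense PLS2 loading weight is found by the NIPALS inner
# iteration, then hard-thresholded — the floor(s * p) entries smallest in
# absolute value are zeroed and the survivors renormalized to unit norm —
# and extraction continues with the sparsified weight (scores and deflation
# use it). With s = 0 this is exactly dense NIPALS PLS2 with X-deflation.
nipals_splsr <- function(X, Y, ncomp, sparsity = 0, tol = 1e-10,
                         max_iter = 500) {
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (any(sparsity < 0 | sparsity > 0.99)) {
    abort("`sparsity` must lie in [0, 0.99].")
  }
  sparsity <- rep_len(sparsity, ncomp)
  max_rank <- min(n - 1L, p)
  if (ncomp > max_rank) {
    warn(sprintf("Truncating `ncomp` from %d to %d (rank limit).",
                 ncomp, max_rank))
    ncomp <- max_rank
    sparsity <- sparsity[seq_len(ncomp)]
  }
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, q, ncomp); Tm <- matrix(0, n, ncomp)
  Xk <- X
  actual <- 0L
  for (k in seq_len(ncomp)) {
    u <- Y[, which.max(colSums(Y^2))]
    t_old <- NULL
    w <- numeric(p); tt <- numeric(n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xk, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- Xk %*% w
      tsq <- sum(tt^2)
      if (tsq < 1e-14) break
      qv <- crossprod(Y, tt) / tsq
      u <- drop(Y %*% qv) / sum(qv^2)
      if (!is.null(t_old) &&
          sum((tt - t_old)^2) <= tol^2 * max(tsq, 1e-300)) break
      t_old <- tt
    }
    if (sqrt(sum(w^2)) < 1e-14 || sum(tt^2) < 1e-14) {
      warn(sprintf("Rank exhausted after %d component(s).", actual))
      break
    }
    n_zero <- floor(sparsity[k] * p)
    if (n_zero >= p) abort("Sparsity degree would zero all loading weights.")
    if (n_zero > 0) {
      ord <- order(abs(w))
      w[ord[seq_len(n_zero)]] <- 0
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) abort("All surviving loading weights are zero.")
      w <- w / nw
      tt <- Xk %*% w
    }
    tsq <- sum(tt^2)
    if (tsq < 1e-14) {
      warn(sprintf("Rank exhausted after %d component(s).", actual))
      break
    }
    pv <- crossprod(Xk, tt) / tsq
    qv <- crossprod(Y, tt) / tsq
    Xk <- Xk - tcrossprod(tt, pv)
    W[, k] <- w; P[, k] <- pv; Q[, k] <- qv; Tm[, k] <- tt
    actual <- k
  }
  if (actual == 0L) abort("No PLS component could be extracted (zero-variance X?).")
  list(W = W[, seq_len(actual), drop = FALSE],
       P = P[, seq_len(actual), drop = FALSE],
       Q = Q[, seq_len(actual), drop = FALSE],
       scores = Tm[, seq_len(actual), drop = FALSE],
       ncomp = actual, sparsity = sparsity[seq_len(actual)])
}

# Regression coefficient matrix for the first k components:
# B_k = W_k (P_k' W_k)^{-1} Q_k'
pls_coefficients <- function(fit, k = fit$ncomp) {
  W <- fit$W[, seq_len(k), drop = FALSE]
  P <- fit$P[, seq_len(k), drop = FALSE]
  Q <- fit$Q[, seq_len(k), drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

one_hot <- function(labels, levels = sort(unique(labels))) {
  Y <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  Y[cbind(seq_along(labels), match(labels, levels))] <- 1
  Y
}

# ---- user-facing fit ----------------------------------------------------

#' Fit a (sparse) PLS discriminant model
#'
#' Classification by partial least-squares regression onto a one-hot class
#' indicator matrix (both blocks column-centered at fit time), with optional
#' per-component hard-threshold sparsity: a degree of sparsity `s` zeroes the
#' `floor(s * p)` loading-weight entries smallest in absolute value and
#' renormalizes the survivors, so only a small, interpretable subset of
#' wavenumbers drives each latent component. Prediction decodes the dummy
#' regression by argmax.
#'
#' @param data A [spectra_set()] (or data frame whose non-metadata columns
#'   are the predictors).
#' @param response Metadata column holding the class label (tidy-eval, e.g.
#'   `species`).
#' @param ncomp Number of latent components.
#' @param sparsity Degree of sparsity in \[0, 0.99\]; scalar (shared by all
#'   components) or one value per component. 0 = dense PLSR.
#' @return An object of class `splsr` with elements `W`, `P`, `Q`, `B`,
#'   `scores`, `x_mean`, `y_mean`, `levels`, `ncomp`, `sparsity`.
#' @examples
#' cfg <- design_config(
#'   populations = tibble::tibble(species = c("P. alpina", "F. ovina"),
#'                                population = c("Norway", "Italy"),
#'                                n_samples = c(8, 8)),
#'   axis = wavenumber_axis(1800, 900, 4), replicates = 1)
#' spectra <- preprocess_spectra(simulate_pollen_spectra(cfg))
#' fit <- fit_splsr(spectra, species, ncomp = 2, sparsity = 0.9)
#' predict(fit, spectra)
#' @export
fit_splsr <- function(data, response, ncomp = 2, sparsity = 0) {
  labels <- as.character(pull_response(data, {{ response }}))
  X <- spectra_matrix(data)
  if (all(apply(X, 2, sd) == 0)) {
    abort("Predictor matrix has zero variance.")
  }
  levels <- sort(unique(labels))
  if (length(levels) < 2) abort("Need at least two classes.")
  Y <- one_hot(labels, levels)
  x_mean <- colMeans(X)
  y_mean <- colMeans(Y)
  fit <- nipals_splsr(sweep(X, 2, x_mean), sweep(Y, 2, y_mean),
                      ncomp = ncomp, sparsity = sparsity)
  B <- pls_coefficients(fit)
  dimnames(B) <- list(colnames(X), levels)
  structure(
    c(fit, list(B = B, x_mean = x_mean, y_mean = y_mean,
                levels = levels, variables = colnames(X))),
    class = "splsr")
}

pull_response <- function(data, response) {
  tib <- as_tibble(data)
  dplyr::pull(tib, {{ response }})
}

#' @export
print.splsr <- function(x, ...) {
  cat(sprintf("<splsr: %d component(s), %d variables, classes: %s>\n",
              x$ncomp, nrow(x$W), paste(x$levels, collapse = ", ")))
  cat(sprintf("  sparsity per component: %s\n",
              paste(format(x$sparsity), collapse = ", ")))
  invisible(x)
}

#' Predict classes from a (sparse) PLS discriminant model
#'
#' @param object An [fit_splsr()] model.
#' @param newdata A [spectra_set()] on the same wavenumber axis/variables.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return A tibble with one `.pred_<class>` score column per class and the
#'   argmax-decoded `.pred_class` (ties broken toward the first class in
#'   sorted order).
#' @export
predict.splsr <- function(object, newdata, ncomp = object$ncomp, ...) {
  X <- spectra_matrix(newdata)
  if (ncol(X) != nrow(object$W) ||
      !identical(colnames(X), object$variables)) {
    abort("`newdata` variables do not match the training variables.")
  }
  if (ncomp < 1 || ncomp > object$ncomp) {
    abort(sprintf("`ncomp` must be in 1..%d.", object$ncomp))
  }
  B <- if (ncomp == object$ncomp) object$B else pls_coefficients(object, ncomp)
  scores <- sweep(X, 2, object$x_mean) %*% B
  scores <- sweep(scores, 2, object$y_mean, `+`)
  colnames(scores) <- object$levels
  pred <- object$levels[apply(scores, 1, which.max)]
  out <- as_tibble(scores)
  names(out) <- paste0(".pred_", names(out))
  out$.pred_class <- pred
  out
}

#' Confusion matrix and misclassification metrics
#'
#' @param truth,estimate Character/factor vectors of true and predicted
#'   labels.
#' @return A list with the `table` (true x predicted counts, on the union of
#'   levels), `mcr` (misclassification rate) and `sr` (success rate,
#'   `(1 - MCR) * 100`).
#' @export
confusion_matrix <- function(truth, estimate) {
  lev <- sort(union(unique(truth), unique(estimate)))
  tab <- table(factor(truth, lev), factor(estimate, lev),
               dnn = c("truth", "predicted"))
  mcr <- 1 - sum(diag(tab)) / sum(tab)
  list(table = tab, mcr = mcr, sr = (1 - mcr) * 100)
}

# ---- cross-validated sparsity selection --------------------------------

stratified_folds <- function(labels, folds, seed) {
  assign_once <- function() {
    fold <- integer(length(labels))
    for (lev in unique(labels)) {
      idx <- sample(which(labels == lev))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  }
  withr::with_seed(seed, {
    fold <- assign_once()
    ok <- all(vapply(seq_len(folds), function(f) {
      length(unique(labels[fold != f])) == length(unique(labels))
    }, logical(1)))
    if (!ok) {
      fold <- assign_once()
      ok <- all(vapply(seq_len(folds), function(f) {
        length(unique(labels[fold != f])) == length(unique(labels))
      }, logical(1)))
      if (!ok) abort("A class is absent from a training fold; too few samples.")
    }
    fold
  })
}

#' Select the degree of sparsity (and component count) by cross-validation
#'
#' Runs stratified k-fold cross-validation (3 blocks by default, matching
#' standard chemometric practice) over a grid of sparsity degrees — 90% to
#' 99% of variables removed by default — and candidate component counts, and
#' picks the setting with minimum held-out misclassification rate (MCR).
#' Ties are broken toward higher sparsity, then fewer components (parsimony).
#' The chosen model is refitted on all rows.
#'
#' @inheritParams fit_splsr
#' @param sparsity_grid Candidate degrees of sparsity.
#' @param ncomp_grid Candidate component counts.
#' @param folds Number of CV blocks.
#' @param seed Integer seed controlling the random fold split.
#' @return An object of class `splsr_cv`: a list with the full results `grid`
#'   (tibble: sparsity, ncomp, mcr, sr), the chosen row, the refitted `model`
#'   and the fold assignment.
#' @export
select_sparsity_cv <- function(data, response,
                               sparsity_grid = seq(0.90, 0.99, by = 0.01),
                               ncomp_grid = 1:15, folds = 3, seed = 1) {
  labels <- as.character(pull_response(data, {{ response }}))
  X <- spectra_matrix(data)
  if (length(unique(labels)) < 2) abort("Need at least two classes.")
  if (min(table(labels)) < folds) {
    warn("A class has fewer members than folds; training folds may be thin.")
  }
  fold <- stratified_folds(labels, folds, seed)
  levels <- sort(unique(labels))
  ncomp_max <- max(ncomp_grid)
  err <- array(0, dim = c(length(sparsity_grid), length(ncomp_grid)))
  for (f in seq_len(folds)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    ytr <- labels[tr]; yte <- labels[!tr]
    if (nrow(Xte) == 0) next
    x_mean <- colMeans(Xtr)
    Ytr <- one_hot(ytr, levels)
    y_mean <- colMeans(Ytr)
    Xc <- sweep(Xtr, 2, x_mean); Yc <- sweep(Ytr, 2, y_mean)
    Xte_c <- sweep(Xte, 2, x_mean)
    for (si in seq_along(sparsity_grid)) {
      fit <- nipals_splsr(Xc, Yc, ncomp = ncomp_max,
                          sparsity = sparsity_grid[si])
      for (ai in seq_along(ncomp_grid)) {
        k <- min(ncomp_grid[ai], fit$ncomp)
        B <- pls_coefficients(fit, k)
        sc <- sweep(Xte_c %*% B, 2, y_mean, `+`)
        pred <- levels[apply(sc, 1, which.max)]
        err[si, ai] <- err[si, ai] + sum(pred != yte)
      }
    }
  }
  grid <- tidyr::expand_grid(ncomp = ncomp_grid, sparsity = sparsity_grid) %>%
    arrange(.data$sparsity, .data$ncomp)
  grid$mcr <- as.vector(err[cbind(match(grid$sparsity, sparsity_grid),
                                  match(grid$ncomp, ncomp_grid))]) /
    length(labels)
  grid$sr <- (1 - grid$mcr) * 100
  best <- grid %>%
    filter(.data$mcr == min(.data$mcr)) %>%
    arrange(dplyr::desc(.data$sparsity), .data$ncomp) %>%
    slice(1)
  model <- suppressWarnings(
    fit_splsr(data, {{ response }}, ncomp = best$ncomp,
              sparsity = best$sparsity))
  structure(list(grid = grid, sparsity = best$sparsity, ncomp = best$ncomp,
                 mcr = best$mcr, sr = best$sr, model = model, fold = fold,
                 seed = seed),
            class = "splsr_cv")
}

#' @export
print.splsr_cv <- function(x, ...) {
  cat(sprintf(
    "<splsr_cv: chosen sparsity %.2f, %d component(s), CV MCR %.3f (SR %.1f%%)>\n",
    x$sparsity, x$ncomp, x$mcr, x$sr))
  invisible(x)
}
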