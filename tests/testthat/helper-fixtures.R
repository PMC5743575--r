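# Shared fixtures: small axes and designs keep the suite fast while
# exercising the same code paths as the full 4,000-500 cm^-1 grid.

small_axis <- function() wavenumber_axis(1800, 900, 4)

# A compact balanced design: 2 species x 2 populations x 4 conditions.
tiny_design <- function(n_samples = 16, replicates = 2, seed = 1, ...) {
  design_config(
    populations = tibble::tibble(
      species = rep(c("A. odoratum", "P. alpina"), each = 2),
      population = c("France", "Greece", "Sweden", "Norway"),
      n_samples = n_samples),
    replicates = replicates, axis = small_axis(), seed = seed, ...)
}

# spectra_set wrapper around a bare matrix with minimal metadata and an
# arbitrary class label column (stored as `species`).
matrix_spectra <- function(X, labels = NULL, wn = NULL) {
  n <- nrow(X)
  wn <- wn %||% seq(2000, by = -1, length.out = ncol(X))
  meta <- tibble::tibble(spectrum_id = sprintf("s%03d", seq_len(n)),
                         sample_id = sprintf("s%03d", seq_len(n)))
  if (!is.null(labels)) meta$species <- as.character(labels)
  spectra_set(meta, X, wn)
}

# Gaussian two-class data with a given mean separation on the first
# `n_informative` variables.
two_class_data <- function(n_per_class = 20, p = 30, delta = 0,
                           n_informative = 1) {
  X <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  labels <- rep(c("a", "b"), each = n_per_class)
  X[labels == "b", seq_len(n_informative)] <-
    X[labels == "b", seq_len(n_informative)] + delta
  matrix_spectra(X, labels)
}

# Independent textbook NIPALS PLS2 reference (deflates both X and Y, as in
# the classical algorithm; regression predictions coincide with the
# X-deflation-only variant). Used as the oracle for the package's fits.
ref_nipals_pls2 <- function(X, Y, ncomp, tol = 1e-13, max_iter = 2000) {
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  E <- sweep(X, 2, x_mean); F_ <- sweep(Y, 2, y_mean)
  p <- ncol(X); q <- ncol(Y); n <- nrow(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); Q <- matrix(0, q, ncomp)
  for (a in seq_len(ncomp)) {
    u <- F_[, which.max(apply(F_, 2, var))]
    repeat {
      w <- t(E) %*% u / drop(crossprod(u))
      w <- w / sqrt(drop(crossprod(w)))
      tt <- E %*% w
      q_ <- t(F_) %*% tt / drop(crossprod(tt))
      u_new <- F_ %*% q_ / drop(crossprod(q_))
      if (sum((u_new - u)^2) < tol^2 * max(sum(u^2), 1e-300)) {
        u <- u_new
        break
      }
      u <- u_new
    }
    p_ <- t(E) %*% tt / drop(crossprod(tt))
    E <- E - tt %*% t(p_)
    F_ <- F_ - tt %*% t(q_)
    W[, a] <- w; P[, a] <- p_; Q[, a] <- q_
  }
  B <- W %*% solve(t(P) %*% W) %*% t(Q)
  list(B = B, x_mean = x_mean, y_mean = y_mean,
       predict = function(Xnew) {
         sweep(sweep(Xnew, 2, x_mean) %*% B, 2, y_mean, `+`)
       })
}

ref_one_hot <- function(labels) {
  lev <- sort(unique(labels))
  Y <- matrix(0, length(labels), length(lev), dimnames = list(NULL, lev))
  Y[cbind(seq_along(labels), match(labels, lev))] <- 1
  Y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
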