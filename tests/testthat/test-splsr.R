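test_that("dense NIPALS reproduces an exactly linear response", {
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  b <- c(2, -1)
  y <- X %*% b # one latent direction suffices... up to 2 components
  fit <- pollenftir:::nipals_splsr(scale(X, scale = FALSE),
                                   scale(y, scale = FALSE), ncomp = 2)
  B <- pollenftir:::pls_coefficients(fit)
  pred <- scale(X, scale = FALSE) %*% B
  expect_equal(as.vector(pred), as.vector(scale(y, scale = FALSE)),
               tolerance = 1e-8)
})

test_that("dense fits match an independent textbook NIPALS and mixOmics", {
  skip_if_not_installed("mixOmics")
  set.seed(2)
  for (rep in 1:3) {
    n <- 25; p <- 12
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
    labels <- sample(rep(c("a", "b", "c"), length.out = n))
    Y <- ref_one_hot(labels)
    k <- 4
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    fit <- pollenftir:::nipals_splsr(Xc, Yc, ncomp = k)
    mine <- Xc %*% pollenftir:::pls_coefficients(fit)
    # oracle 1: textbook NIPALS (helper)
    ref <- ref_nipals_pls2(X, Y, ncomp = k)
    expect_equal(mine, ref$predict(X) - rep(1, n) %o% ref$y_mean,
                 tolerance = 1e-6, ignore_attr = TRUE)
    # oracle 2: mixOmics dense PLS
    mo <- mixOmics::pls(X, Y, ncomp = k, mode = "regression", scale = FALSE)
    mo_pred <- predict(mo, X)$predict[, , k]
    expect_equal(mine + rep(1, n) %o% colMeans(Y), mo_pred,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("latent scores are mutually orthogonal", {
  set.seed(3)
  X <- matrix(rnorm(300), 30, 10)
  Y <- ref_one_hot(sample(rep(c("a", "b", "c"), 10)))
  fit <- pollenftir:::nipals_splsr(scale(X, scale = FALSE),
                                   scale(Y, scale = FALSE), ncomp = 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("hard thresholding zeroes exactly floor(s * p) loading weights", {
  set.seed(4)
  d <- two_class_data(n_per_class = 15, p = 100, delta = 1.5,
                      n_informative = 10)
  for (s in c(0.5, 0.73, 0.9, 0.99)) {
    fit <- fit_splsr(d, species, ncomp = 2, sparsity = s)
    nz <- colSums(fit$W != 0)
    expect_equal(unname(nz), rep(100 - floor(s * 100), 2))
    # survivors renormalized to unit norm
    expect_equal(unname(colSums(fit$W^2)), c(1, 1), tolerance = 1e-12)
  }
  # p = 100, s = 0.99 -> a single survivor
  fit <- fit_splsr(d, species, ncomp = 1, sparsity = 0.99)
  expect_equal(sum(fit$W != 0), 1)
  expect_error(pollenftir:::nipals_splsr(matrix(rnorm(40), 20, 2),
                                         matrix(rnorm(20), 20, 1),
                                         ncomp = 1, sparsity = 1.2),
               "0, 0.99")
})

test_that("sparsity 0 equals the dense fit and a 10-sigma variable survives", {
  set.seed(5)
  d <- two_class_data(n_per_class = 20, p = 50, delta = 3)
  dense <- fit_splsr(d, species, ncomp = 3, sparsity = 0)
  ref <- ref_nipals_pls2(spectra_matrix(d), ref_one_hot(d$species), 3)
  mine <- as.matrix(predict(dense, d)[, c(".pred_a", ".pred_b")])
  expect_equal(mine, ref$predict(spectra_matrix(d)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # one informative variable among 99 noise ones at 10 sigma separation:
  # its loading weight dominates component 1, so it survives s = 0.99
  set.seed(6)
  d2 <- two_class_data(n_per_class = 20, p = 100, delta = 10)
  fit <- fit_splsr(d2, species, ncomp = 1, sparsity = 0.99)
  expect_equal(which(fit$W[, 1] != 0), 1)
})

test_that("predictions are equivariant under variable permutation", {
  set.seed(7)
  d <- two_class_data(n_per_class = 12, p = 20, delta = 2)
  fit <- fit_splsr(d, species, ncomp = 2, sparsity = 0.5)
  # shuffle variables, relabelling them on a fresh descending axis
  perm <- sample(20)
  X <- spectra_matrix(d)
  dp <- matrix_spectra(X[, perm], labels = d$species, wn = wavenumbers(d))
  fitp <- fit_splsr(dp, species, ncomp = 2, sparsity = 0.5)
  expect_equal(fitp$W, fit$W[perm, ], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(predict(fitp, dp)$.pred_class, predict(fit, d)$.pred_class)
})

test_that("argmax decoding and confusion metrics follow the SR definition", {
  # hand-computed: 5 errors in 20 samples -> MCR 0.25, SR 75
  truth <- rep(c("x", "y"), each = 10)
  est <- c(rep("x", 8), rep("y", 2), rep("x", 3), rep("y", 7))
  cm <- confusion_matrix(truth, est)
  expect_equal(unname(as.vector(cm$table)), c(8, 3, 2, 7))
  expect_equal(cm$mcr, 0.25)
  expect_equal(cm$sr, 75.0)
  # resubstitution on separable data is error-free
  set.seed(8)
  d <- two_class_data(n_per_class = 15, p = 25, delta = 8)
  fit <- fit_splsr(d, species, ncomp = 2)
  expect_equal(predict(fit, d)$.pred_class, d$species)
  # variable mismatch raises
  d2 <- two_class_data(n_per_class = 5, p = 10)
  expect_error(predict(fit, d2), "variables")
})

test_that("CV selects by minimum MCR with ties toward higher sparsity", {
  set.seed(9)
  d <- two_class_data(n_per_class = 12, p = 40, delta = 10,
                      n_informative = 5)
  cv <- select_sparsity_cv(d, species, sparsity_grid = seq(0.9, 0.99, 0.01),
                           ncomp_grid = 1:2, folds = 3, seed = 1)
  expect_equal(cv$mcr, 0)
  expect_equal(cv$sr, 100)
  expect_true(all(cv$grid$sr == 100))
  expect_equal(cv$sparsity, 0.99) # tie-break: parsimony
  expect_equal(cv$ncomp, 1)
  # default grid spans exactly 0.90 ... 0.99
  expect_equal(unique(tidy(cv)$sparsity), seq(0.90, 0.99, by = 0.01))
})

test_that("CV is reproducible for a fixed seed", {
  set.seed(10)
  d <- two_class_data(n_per_class = 10, p = 30, delta = 1)
  a <- select_sparsity_cv(d, species, sparsity_grid = c(0.9, 0.95),
                          ncomp_grid = 1:3, seed = 99)
  b <- select_sparsity_cv(d, species, sparsity_grid = c(0.9, 0.95),
                          ncomp_grid = 1:3, seed = 99)
  expect_identical(a$grid, b$grid)
  expect_identical(a$fold, b$fold)
  c2 <- select_sparsity_cv(d, species, sparsity_grid = c(0.9, 0.95),
                           ncomp_grid = 1:3, seed = 100)
  expect_false(identical(a$fold, c2$fold))
})

test_that("chance-level data yields chance-level CV success rates", {
  # labels independent of X, 2 balanced classes: mean SR across seeds ~ 50%
  srs <- vapply(1:25, function(s) {
    set.seed(s)
    d <- two_class_data(n_per_class = 20, p = 30, delta = 0)
    suppressWarnings(select_sparsity_cv(
      d, species, sparsity_grid = c(0.9, 0.99), ncomp_grid = 1:2,
      folds = 3, seed = s)$sr)
  }, numeric(1))
  expect_gt(mean(srs), 45)
  expect_lt(mean(srs), 62) # selection optimism keeps this near chance
})
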