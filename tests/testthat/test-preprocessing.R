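test_that("SG second derivative reproduces polynomial derivatives exactly", {
  n <- 60
  wn <- seq(2000, by = -2, length.out = n)
  # constant -> zero
  const <- matrix_spectra(matrix(5, 2, n), wn = wn)
  expect_equal(max(abs(spectra_matrix(sg_second_derivative(const)))), 0)
  # quadratic y_i = i^2 -> second derivative 2 everywhere, edges included
  # (the window polynomial of degree 2 fits a quadratic exactly)
  quad <- matrix_spectra(matrix((1:n)^2, 1, n), wn = wn)
  d <- spectra_matrix(sg_second_derivative(quad, window = 7, polyorder = 2))
  expect_equal(as.vector(d), rep(2, n), tolerance = 1e-10)
})

test_that("SG filtering is linear in its input", {
  set.seed(1)
  n <- 80
  x <- rnorm(n); y <- rnorm(n)
  D <- function(v) spectra_matrix(sg_second_derivative(
    matrix_spectra(matrix(v, 1, n))))
  expect_lt(max(abs(D(2.5 * x - 0.7 * y) - (2.5 * D(x) - 0.7 * D(y)))),
            1e-12)
})

test_that("SG validates its configuration", {
  s <- matrix_spectra(matrix(rnorm(50), 1, 50))
  expect_error(sg_second_derivative(s, window = 6), "odd")
  expect_error(sg_second_derivative(s, window = 3, polyorder = 3), "exceed")
  bad_axis <- tibble::tibble(spectrum_id = "a", sample_id = "a")
  bad <- dplyr::bind_cols(bad_axis,
                          stats::setNames(as.data.frame(t(rnorm(10))),
                                          sprintf("%.3f", c(100:95, 80:77))))
  expect_error(sg_second_derivative(pollenftir:::new_spectra_set(bad)),
               "uniformly spaced")
})

test_that("EMSC recovers known artifact parameters to 1e-10", {
  wn <- small_axis()
  lam <- pollenftir:::axis_unit_scale(wn)
  m <- synthesize_spectrum(c(protein = 1, carbohydrate = 0.5), wn)
  # identity case
  s0 <- matrix_spectra(matrix(m, 1), wn = wn)
  out0 <- emsc_correct(s0, reference = m)
  p0 <- attr(out0, "emsc_params")
  expect_equal(c(p0$a, p0$b, p0$c, p0$d), c(0, 1, 0, 0), tolerance = 1e-10)
  expect_equal(as.vector(spectra_matrix(out0)), m, tolerance = 1e-10)
  # known (a, b, c, d); oracle = solving the normal equations directly
  z <- 0.5 + 2 * m + 0.1 * lam + 0.05 * lam^2
  out <- emsc_correct(matrix_spectra(matrix(z, 1), wn = wn), reference = m)
  pp <- attr(out, "emsc_params")
  G <- cbind(1, m, lam, lam^2)
  oracle <- solve(crossprod(G), crossprod(G, z))
  expect_equal(c(pp$a, pp$b, pp$c, pp$d), as.vector(oracle),
               tolerance = 1e-10)
  expect_equal(c(pp$a, pp$b, pp$c, pp$d), c(0.5, 2, 0.1, 0.05),
               tolerance = 1e-10)
  expect_equal(as.vector(spectra_matrix(out)), m, tolerance = 1e-10)
})

test_that("EMSC correction is scale invariant and idempotent", {
  wn <- small_axis()
  m <- synthesize_spectrum(c(protein = 1, lipid = 0.7), wn)
  x <- matrix_spectra(rbind(m, 3 * m), wn = wn)
  out <- emsc_correct(x, reference = m)
  mat <- spectra_matrix(out)
  expect_equal(mat[1, ], mat[2, ], tolerance = 1e-10, ignore_attr = TRUE)
  # idempotence against the same reference
  again <- emsc_correct(out, reference = m)
  expect_equal(spectra_matrix(again), spectra_matrix(out), tolerance = 1e-10)
})

test_that("EMSC removes any artifact in the polynomial + scale span", {
  wn <- small_axis()
  lam <- pollenftir:::axis_unit_scale(wn)
  m <- synthesize_spectrum(c(protein = 1, carbohydrate = 1, lipid = 0.5), wn)
  set.seed(7)
  for (i in 1:20) {
    b <- runif(1, 0.2, 5)
    abc <- rnorm(3, sd = c(1, 0.5, 0.5))
    z <- b * m + abc[1] + abc[2] * lam + abc[3] * lam^2
    out <- emsc_correct(matrix_spectra(matrix(z, 1), wn = wn), reference = m)
    expect_lt(max(abs(spectra_matrix(out) - rbind(m))), 1e-9)
  }
})

test_that("degenerate EMSC fits are excluded with a warning", {
  wn <- small_axis()
  m <- synthesize_spectrum(c(protein = 1), wn)
  lam <- pollenftir:::axis_unit_scale(wn)
  # second spectrum orthogonal to m's span contribution: pure baseline
  z <- 0.3 + 0.2 * lam
  x <- matrix_spectra(rbind(m, z), wn = wn)
  expect_warning(out <- emsc_correct(x, reference = m), "degenerate")
  expect_equal(nrow(out), 1)
})

test_that("replicate averaging collapses the matrix correctly", {
  cfg <- tiny_design(seed = 9, replicates = 3)
  raw <- simulate_pollen_spectra(cfg)
  avg <- average_replicates(raw)
  expect_equal(nrow(avg), nrow(raw) / 3)
  expect_false("replicate" %in% names(spectra_meta(avg)))
  # arithmetic mean at every wavenumber
  sid <- spectra_meta(raw)$sample_id[1]
  man <- colMeans(spectra_matrix(raw)[spectra_meta(raw)$sample_id == sid, ])
  expect_equal(spectra_matrix(avg)[1, ], man, ignore_attr = TRUE)
  # single replicate: unchanged spectra
  one <- pollenftir:::new_spectra_set(
    tibble::as_tibble(raw)[raw$replicate == 1, ])
  avg1 <- average_replicates(one)
  expect_equal(spectra_matrix(avg1), spectra_matrix(one),
               ignore_attr = TRUE)
})

test_that("main design averages 1,140 replicate spectra to 380", {
  cfg <- main_study_design(axis = small_axis(), seed = 1)
  raw <- simulate_pollen_spectra(cfg)
  expect_equal(nrow(average_replicates(raw)), 380)
})

test_that("pcc_variability matches the (1 - r) x 1e4 definition", {
  n <- 120
  wn <- seq(1700, 1600, length.out = n) # all points inside the region
  x <- sin(seq(0, 6, length.out = n))
  # construct a partner with Pearson correlation exactly 0.9998
  xc <- (x - mean(x)) / sqrt(sum((x - mean(x))^2))
  set.seed(2)
  zr <- rnorm(n); zr <- zr - mean(zr)
  zr <- zr - sum(zr * xc) * xc; zr <- zr / sqrt(sum(zr^2))
  r <- 0.9998
  y <- r * xc + sqrt(1 - r^2) * zr
  s <- matrix_spectra(rbind(xc, y), wn = wn)
  expect_equal(pcc_variability(s, region = c(1600, 1700)), 2.0,
               tolerance = 1e-6)
  # identical spectra -> 0
  s2 <- matrix_spectra(rbind(x, x), wn = wn)
  expect_equal(pcc_variability(s2), 0)
  # default region is 1,700-1,600 cm^-1: points outside must not matter
  wn2 <- seq(1800, by = -1, length.out = 300)
  base <- sin(seq(0, 7, length.out = 300))
  a <- base; b <- base
  a[wn2 > 1700] <- rnorm(sum(wn2 > 1700)) # differ only outside the region
  sa <- matrix_spectra(rbind(a, b), wn = wn2)
  expect_lt(abs(pcc_variability(sa)), 1e-9)
})

test_that("pcc_variability is invariant to affine rescaling", {
  set.seed(4)
  n <- 150
  wn <- seq(1750, by = -1, length.out = n)
  x <- rnorm(n); y <- rnorm(n)
  v1 <- pcc_variability(matrix_spectra(rbind(x, y), wn = wn))
  v2 <- pcc_variability(matrix_spectra(rbind(5 * x - 2, 0.1 * y + 7),
                                       wn = wn))
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("zero-variance spectra in the region are skipped with a warning", {
  n <- 120
  wn <- seq(1700, by = -1, length.out = n)
  x <- rnorm(n)
  flat <- rep(1, n)
  s <- matrix_spectra(rbind(x, x + rnorm(n, sd = 0.01), flat), wn = wn)
  expect_warning(v <- pcc_variability(s), "zero-variance")
  expect_true(is.finite(v))
})

test_that("preprocess_spectra applies derivative, EMSC, then averaging", {
  cfg <- tiny_design(seed = 6)
  raw <- simulate_pollen_spectra(cfg)
  proc <- preprocess_spectra(raw)
  expect_equal(nrow(proc), nrow(raw) / cfg$replicates)
  # equivalent to the explicit chain
  manual <- average_replicates(emsc_correct(sg_second_derivative(raw)))
  expect_equal(spectra_matrix(proc), spectra_matrix(manual))
})
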