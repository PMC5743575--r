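Package: pollenftir
Title: FTIR Chemotyping of Pollen by Sparse PLS Hierarchical Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biochemical phenotyping of pollen from Fourier transform
    infrared (FTIR) absorbance spectra. Implements the full chemometric chain:
    Savitzky-Golay second-derivative filtering, extended multiplicative signal
    correction (EMSC) with linear and quadratic baseline components, technical
    replicate averaging, a Pearson-correlation spectral variability statistic,
    sparse partial least-squares discriminant analysis (NIPALS with hard
    thresholding of loading weights), hierarchical species/population/growth
    condition classification trees, permutation-test model validation, and a
    Fisher between-to-within scatter ratio quantifying genotype-based
    clustering (phenotypic rigidity). A synthetic spectrum generator emulates
    the sampling design and band structure of grass pollen FTIR studies so the
    whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
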