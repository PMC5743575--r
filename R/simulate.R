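CONSTITUENTS <- c("protein", "lipid", "carbohydrate", "sporopollenin",
                  "CH-stretch")

#' Specify a factor-level effect on constituent composition
#'
#' An effect multiplies the constituent weights of every sample carrying the
#' given factor level. Constituents not named keep multiplier 1; the neutral
#' level of a factor is simply absent from the effect table.
#'
#' @param factor One of `"population"`, `"temperature"`, `"nutrient"`.
#' @param level Factor level label the effect applies to.
#' @param ... Named positive multipliers, e.g. `protein = 1.2`.
#' @return A tibble with columns `factor`, `level`, `constituent`,
#'   `multiplier`.
#' @export
effect_spec <- function(factor, level, ...) {
  mult <- c(...)
  if (length(mult) == 0) abort("Supply at least one constituent multiplier.")
  if (any(mult <= 0)) abort("Effect multipliers must be positive.")
  bad <- setdiff(names(mult), CONSTITUENTS)
  if (length(bad)) {
    abort(paste0("Unknown constituent(s): ", paste(bad, collapse = ", ")))
  }
  tibble(factor = factor, level = level,
         constituent = names(mult), multiplier = unname(mult))
}

#' Default factor effects of the synthetic design
#'
#' Encodes the qualitative effect directions seen in grass pollen FTIR
#' studies: warm growth raises the protein (amide) signal relative to
#' carbohydrates; added nutrients raise the protein-to-carbohydrate ratio and
#' shift lipid/sporopollenin signals; populations differ in
#' protein/lipid/carbohydrate balance, most strongly for the alpine species.
#' Magnitudes are generator surrogates (the source studies quantify none):
#' population effects (~8-12%) are sized well above the condition effects
#' (~2-4%) and around the genet-to-genet spread, so that species
#' classification is near-perfect, population classification good but
#' imperfect, and growth-condition classification clearly above chance yet
#' noisy — the qualitative accuracy gradient such studies report.
#'
#' @return A tibble as produced by binding [effect_spec()] rows.
#' @export
default_effects <- function() {
  bind_rows(
    # populations (~10% shifts)
    effect_spec("population", "France",  protein = 1.10, lipid = 0.92),
    effect_spec("population", "Greece",  carbohydrate = 1.10,
                sporopollenin = 0.92),
    effect_spec("population", "Finland", protein = 0.90, lipid = 1.08),
    effect_spec("population", "Sweden",  carbohydrate = 0.92, lipid = 1.10),
    effect_spec("population", "Italy",   protein = 1.08, sporopollenin = 1.10),
    effect_spec("population", "Norway",  carbohydrate = 1.12, lipid = 0.90),
    # warm growth: higher protein-to-carbohydrate ratio
    effect_spec("temperature", "20C", protein = 1.06, carbohydrate = 0.94),
    # added nutrients: higher protein-to-carbohydrate ratio, lipid shift
    effect_spec("nutrient", "+NU", protein = 1.045, carbohydrate = 0.965,
                lipid = 1.03, sporopollenin = 0.97)
  )
}

default_species_weights <- function() {
  list(
    "A. odoratum" = c(protein = 0.85, lipid = 1.15, carbohydrate = 1.30,
                      sporopollenin = 1.00, "CH-stretch" = 1.00),
    "F. ovina"    = c(protein = 0.95, lipid = 0.85, carbohydrate = 1.10,
                      sporopollenin = 1.20, "CH-stretch" = 1.00),
    "P. alpina"   = c(protein = 1.35, lipid = 1.00, carbohydrate = 0.85,
                      sporopollenin = 0.90, "CH-stretch" = 1.00)
  )
}

#' Configure a synthetic pollen FTIR experiment
#'
#' Describes a growth experiment in which each genetic individual (genet) is
#' split into clones (ramets), one per growth condition, and every pollen
#' sample is measured in technical replicates. Sample counts per population
#' must therefore be divisible by the number of conditions.
#'
#' @param populations Tibble with columns `species`, `population`,
#'   `n_samples`.
#' @param temperatures,nutrients Condition levels; their crossing defines the
#'   growth conditions (default 2 x 2 = 4).
#' @param replicates Technical replicates per sample (default 3).
#' @param species_weights Named list: species -> named constituent weight
#'   vector (the species' baseline composition).
#' @param effects Effect table, see [effect_spec()] / [default_effects()].
#' @param scatter List with `mult_sd`, `add_sd`, `lin_sd`, `quad_sd`: spreads
#'   of the per-replicate multiplicative scale (log scale), additive offset,
#'   and linear/quadratic baseline coefficients.
#' @param noise_sd Additive Gaussian noise sd (absorbance units).
#' @param individual_effect_sd Log-scale sd of the per-genet constituent
#'   multipliers, shared by all clones of a genet.
#' @param axis Wavenumber axis (default full 4,000-500 cm^-1 grid).
#' @param seed Integer seed; all randomness derives from it.
#' @return A list with class `design_config`.
#' @export
design_config <- function(populations,
                          temperatures = c("14C", "20C"),
                          nutrients = c("+NU", "-NU"),
                          replicates = 3,
                          species_weights = default_species_weights(),
                          effects = default_effects(),
                          scatter = list(mult_sd = 0.08, add_sd = 0.02,
                                         lin_sd = 0.01, quad_sd = 0.01),
                          noise_sd = 1e-4,
                          individual_effect_sd = 0.05,
                          axis = wavenumber_axis(),
                          seed = 1) {
  populations <- as_tibble(populations)
  stopifnot(all(c("species", "population", "n_samples") %in% names(populations)))
  if (any(populations$n_samples <= 0)) abort("Sample counts must be positive.")
  if (replicates < 1) abort("`replicates` must be at least 1.")
  n_cond <- length(temperatures) * length(nutrients)
  if (any(populations$n_samples %% n_cond != 0)) {
    abort(sprintf(
      "Each population's `n_samples` must be divisible by %d (conditions).",
      n_cond))
  }
  miss <- setdiff(unique(populations$species), names(species_weights))
  if (length(miss)) {
    abort(paste0("No baseline weights for species: ",
                 paste(miss, collapse = ", ")))
  }
  check_axis(axis)
  structure(list(populations = populations, temperatures = temperatures,
                 nutrients = nutrients, replicates = as.integer(replicates),
                 species_weights = species_weights, effects = effects,
                 scatter = scatter, noise_sd = noise_sd,
                 individual_effect_sd = individual_effect_sd,
                 axis = axis, seed = as.integer(seed)),
            class = "design_config")
}

#' The main-study sampling design
#'
#' 380 pollen samples across three grass species and nine populations:
#' 140 *A. odoratum* (France 44, Greece 48, Finland 48), 96 *F. ovina*
#' (Sweden 48, Finland 32, Italy 16) and 144 *P. alpina* (Sweden, Italy,
#' Norway: 48 each), uniformly spread over the four growth conditions
#' (95 samples per condition) and measured in three technical replicates
#' (1,140 spectra).
#'
#' @param ... Passed on to [design_config()] (e.g. a reduced `axis` or a
#'   different `seed`).
#' @return A `design_config`.
#' @export
main_study_design <- function(...) {
  pops <- tibble::tribble(
    ~species,       ~population, ~n_samples,
    "A. odoratum",  "France",     44,
    "A. odoratum",  "Greece",     48,
    "A. odoratum",  "Finland",    48,
    "F. ovina",     "Sweden",     48,
    "F. ovina",     "Finland",    32,
    "F. ovina",     "Italy",      16,
    "P. alpina",    "Sweden",     48,
    "P. alpina",    "Italy",      48,
    "P. alpina",    "Norway",     48
  )
  design_config(populations = pops, ...)
}

# Deterministic 31-bit stream seed derived from the global seed and a key.
derive_seed <- function(seed, ...) {
  key <- paste(seed, ..., sep = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

effect_multipliers <- function(effects, fac, lev) {
  m <- setNames(rep(1, length(CONSTITUENTS)), CONSTITUENTS)
  if (is.null(effects) || nrow(effects) == 0) return(m)
  sel <- effects$factor == fac & effects$level == lev
  m[effects$constituent[sel]] <- effects$multiplier[sel]
  m
}

#' Generate a synthetic labelled spectra set
#'
#' Runs the forward model over the whole design: each genet draws one set of
#' log-normal constituent multipliers (shared across its clones), each clone
#' sits in one growth condition, and each technical replicate of a sample
#' differs only in scatter artifacts and noise. All randomness flows through
#' per-genet / per-sample streams derived from the config seed, so generation
#' is fully reproducible and subsetting or extending the design (e.g. more
#' replicates) never changes previously generated spectra.
#'
#' @param config A [design_config()].
#' @param seed Optional override of `config$seed`.
#' @return A [spectra_set()] with `nrow = sum(n_samples) * replicates`.
#' @examples
#' cfg <- design_config(
#'   populations = tibble::tibble(species = "P. alpina",
#'                                population = "Norway", n_samples = 8),
#'   axis = wavenumber_axis(1800, 800, 4), replicates = 2)
#' simulate_pollen_spectra(cfg)
#' @export
simulate_pollen_spectra <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "design_config"))
  wn <- config$axis
  prof <- constituent_profiles(wn)
  lam <- axis_unit_scale(wn)
  conds <- expand.grid(nutrient = config$nutrients,
                       temperature = config$temperatures,
                       stringsAsFactors = FALSE)[, c("temperature", "nutrient")]
  n_cond <- nrow(conds)
  sp_code <- function(s) {
    parts <- strsplit(gsub("[^A-Za-z ]", "", s), " +")[[1]]
    paste0(toupper(substr(parts, 1, 1)), collapse = "")
  }

  meta_rows <- list()
  spec_rows <- list()
  idx <- 0L
  for (pi in seq_len(nrow(config$populations))) {
    sp <- config$populations$species[pi]
    pop <- config$populations$population[pi]
    n_genets <- config$populations$n_samples[pi] %/% n_cond
    base_w <- config$species_weights[[sp]][CONSTITUENTS]
    base_w[is.na(base_w)] <- 0
    names(base_w) <- CONSTITUENTS
    pop_mult <- effect_multipliers(config$effects, "population", pop)
    for (gi in seq_len(n_genets)) {
      genet_id <- sprintf("%s_%s_g%02d", sp_code(sp), pop, gi)
      genet_mult <- withr::with_seed(
        derive_seed(seed, "genet", genet_id),
        exp(rnorm(length(CONSTITUENTS), sd = config$individual_effect_sd)))
      names(genet_mult) <- CONSTITUENTS
      for (ci in seq_len(n_cond)) {
        temp <- conds$temperature[ci]
        nut <- conds$nutrient[ci]
        w <- base_w * pop_mult * genet_mult *
          effect_multipliers(config$effects, "temperature", temp) *
          effect_multipliers(config$effects, "nutrient", nut)
        m <- drop(prof %*% w)
        sample_id <- sprintf("%s_%s%s", genet_id, temp, nut)
        reps <- withr::with_seed(
          derive_seed(seed, "sample", sample_id),
          lapply(seq_len(config$replicates), function(r) {
            b <- exp(rnorm(1, sd = config$scatter$mult_sd))
            a <- rnorm(1, sd = config$scatter$add_sd)
            cc <- rnorm(1, sd = config$scatter$lin_sd)
            d <- rnorm(1, sd = config$scatter$quad_sd)
            z <- b * m + a + cc * lam + d * lam^2
            if (config$noise_sd > 0) {
              z <- z + rnorm(length(z), sd = config$noise_sd)
            }
            z
          }))
        for (r in seq_len(config$replicates)) {
          idx <- idx + 1L
          meta_rows[[idx]] <- tibble(
            spectrum_id = sprintf("%s_r%d", sample_id, r),
            sample_id = sample_id, genet_id = genet_id,
            species = sp, population = pop,
            temperature = temp, nutrient = nut, replicate = r)
          spec_rows[[idx]] <- reps[[r]]
        }
      }
    }
  }
  meta <- bind_rows(meta_rows)
  mat <- do.call(rbind, spec_rows)
  spectra_set(meta, mat, wn)
}

#' Growth-condition label of a spectra set
#'
#' Combines temperature and nutrient levels into the single growth-condition
#' label used by the third classification level.
#'
#' @param x A [spectra_set()] (or its metadata tibble).
#' @return Character vector, e.g. `"14C/+NU"`.
#' @export
condition_label <- function(x) {
  paste(x$temperature, x$nutrient, sep = "/")
}
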