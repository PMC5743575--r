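#' Configure a full analysis run
#'
#' Collects every setting of the end-to-end analysis. Input spectra may be
#' given as CSV paths (matrix + metadata as read by [read_spectra()]) or the
#' pipeline can simulate them from a [design_config()].
#'
#' @param spectra_path,metadata_path CSV input paths (both or neither).
#' @param design A [design_config()] used to simulate input when no paths are
#'   given.
#' @param out_dir Output directory for report tables (`NULL`: nothing
#'   written).
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param train_size,train_fraction Hierarchy split settings (see
#'   [split_train_validation()]).
#' @param sparsity_grid,ncomp_grid,folds Node/factor model CV settings.
#' @param n_perm Permutations per factor model (0 disables the tests).
#' @param fisher_max_comp PCA component cap for the rigidity analysis.
#' @param seed Global seed; every stage derives its stream from it.
#' @return A list with class `run_config`.
#' @export
run_config <- function(spectra_path = NULL, metadata_path = NULL,
                       design = main_study_design(), out_dir = NULL,
                       sg_window = 7, sg_polyorder = 2,
                       train_size = NULL, train_fraction = 0.6,
                       sparsity_grid = seq(0.90, 0.99, by = 0.01),
                       ncomp_grid = 1:15, folds = 3, n_perm = 999,
                       fisher_max_comp = 10, seed = 1) {
  if (xor(is.null(spectra_path), is.null(metadata_path))) {
    abort("Give both `spectra_path` and `metadata_path`, or neither.")
  }
  structure(list(spectra_path = spectra_path, metadata_path = metadata_path,
                 design = design, out_dir = out_dir, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, train_size = train_size,
                 train_fraction = train_fraction,
                 sparsity_grid = sparsity_grid, ncomp_grid = ncomp_grid,
                 folds = folds, n_perm = n_perm,
                 fisher_max_comp = fisher_max_comp, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  rlang::hash(unclass(config)[setdiff(names(config), "out_dir")])
}

stamp <- function(tab, config) {
  mutate(tab, seed = config$seed, config_hash = config_hash(config))
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the end-to-end pollen chemotyping analysis
#'
#' Executes the full chain on one dataset: preprocessing (second derivative,
#' EMSC, replicate averaging), stratified train/validation split,
#' hierarchical species/population/condition classification, per-population
#' temperature / nutrient / interaction models with permutation tests, and
#' the per-population Fisher clustering coefficient. Every output table
#' carries the seed and a hash of the configuration, so two runs differing
#' only in output path produce identical tables.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list of tibbles: `counts`, `level_sr` (per-level
#'   success rates), `predictions`, `factor_table` (per population x factor:
#'   SR and p-value), `fcc_table`, plus the fitted `hierarchy`. Tables are
#'   also written as CSV under `config$out_dir` when set.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  raw <- if (!is.null(config$spectra_path)) {
    stage_msg("input", "reading %s", config$spectra_path)
    read_spectra(config$spectra_path, config$metadata_path)
  } else {
    stage_msg("input", "simulating design (seed %d)", config$seed)
    simulate_pollen_spectra(config$design, seed = config$seed)
  }
  stage_msg("input", "%d spectra, %d samples", nrow(raw),
            length(unique(raw$sample_id)))

  stage_msg("preprocess", "second derivative + EMSC + replicate averaging")
  proc <- preprocess_spectra(raw, window = config$sg_window,
                             polyorder = config$sg_polyorder)
  counts <- tibble(
    n_spectra = nrow(raw),
    n_samples = length(unique(raw$sample_id)),
    n_averaged = nrow(proc),
    samples_per_condition = nrow(raw) /
      length(unique(raw$replicate)) /
      length(unique(condition_label(raw))))

  stage_msg("split", "stratified train/validation split")
  split <- split_train_validation(proc, train_size = config$train_size,
                                  train_fraction = config$train_fraction,
                                  seed = derive_seed(config$seed, "split"))
  if (nrow(split$validation) == 0) {
    warn("Empty validation set: hierarchy evaluation tables will be empty.")
  }

  stage_msg("hierarchy", "training node models (%d train samples)",
            nrow(split$train))
  hier <- train_hierarchy(split$train, sparsity_grid = config$sparsity_grid,
                          ncomp_grid = config$ncomp_grid,
                          folds = config$folds,
                          seed = derive_seed(config$seed, "hier"))
  counts$n_hierarchy_models <- hier$n_models
  if (nrow(split$validation) > 0) {
    preds <- predict(hier, split$validation)
    level_sr <- hierarchy_success_rates(preds)
  } else {
    preds <- tibble(); level_sr <- tibble()
  }

  stage_msg("factors", "per-population environmental models (n_perm = %d)",
            config$n_perm)
  meta <- spectra_meta(proc)
  combos <- distinct(meta, .data$species, .data$population)
  tib <- as_tibble(proc)
  factor_table <- purrr::pmap_dfr(combos, function(species, population) {
    idx <- meta$species == species & meta$population == population
    sub <- new_spectra_set(tib[idx, , drop = FALSE])
    purrr::map_dfr(c("temperature", "nutrients", "interaction"), function(f) {
      fm <- factor_models(sub, f, sparsity_grid = config$sparsity_grid,
                          ncomp_grid = config$ncomp_grid,
                          folds = config$folds, n_perm = config$n_perm,
                          seed = derive_seed(config$seed, "factor",
                                             species, population))
      tibble(species = species, population = population, factor = f,
             sr = fm$cv$sr,
             p_value = if (is.null(fm$permutation)) NA_real_
                       else fm$permutation$p_value)
    })
  })

  stage_msg("fisher", "genotype clustering coefficients")
  fcc_table <- fisher_clustering(proc, max_comp = config$fisher_max_comp)

  out <- list(counts = stamp(counts, config),
              level_sr = if (nrow(level_sr)) stamp(level_sr, config)
                         else level_sr,
              predictions = preds,
              factor_table = stamp(factor_table, config),
              fcc_table = stamp(fcc_table, config),
              hierarchy = hier)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("counts", "level_sr", "predictions", "factor_table",
                 "fcc_table")) {
      if (nrow(as_tibble(out[[nm]])) == 0) next
      readr::write_csv(as_tibble(out[[nm]]),
                       file.path(config$out_dir, paste0(nm, ".csv")))
    }
    jsonlite::write_json(
      list(seed = config$seed, config_hash = config_hash(config)),
      file.path(config$out_dir, "run_info.json"), auto_unbox = TRUE)
  }
  invisible(out)
}
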