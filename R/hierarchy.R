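#' Stratified train/validation split
#'
#' Splits an averaged spectra set (one row per sample) into disjoint training
#' and validation sets, stratified by species x population x growth
#' condition. Either a fraction or an explicit training-set size can be
#' given; per-stratum training counts are allocated proportionally
#' (largest-remainder rounding) so the total is hit exactly. Strata with
#' fewer than 2 samples are kept whole in training with a warning.
#'
#' @param data An averaged [spectra_set()].
#' @param train_size Number of training samples; overrides `train_fraction`
#'   when given. The 380-sample main design with `train_size = 218` yields
#'   the canonical 218/162 split.
#' @param train_fraction Fraction of samples for training.
#' @param seed Integer seed for the random within-stratum draw.
#' @return A list with `train` and `validation` spectra sets.
#' @export
split_train_validation <- function(data, train_size = NULL,
                                   train_fraction = 0.6, seed = 1) {
  meta <- spectra_meta(data)
  strata_cols <- intersect(c("species", "population", "temperature",
                             "nutrient"), names(meta))
  stratum <- interaction(meta[strata_cols], drop = TRUE)
  n <- nrow(meta)
  n_train <- if (!is.null(train_size)) as.integer(train_size)
             else round(train_fraction * n)
  if (n_train < 0 || n_train > n) abort("Training size out of range.")
  sizes <- as.vector(table(stratum))
  small <- sizes < 2
  if (any(small)) {
    warn(sprintf("%d stratum/strata with < 2 samples kept whole in training.",
                 sum(small)))
  }
  # proportional allocation with largest-remainder rounding
  exact <- sizes * n_train / n
  alloc <- floor(exact)
  alloc[small] <- sizes[small]
  rem <- n_train - sum(alloc)
  if (rem > 0) {
    frac <- exact - floor(exact)
    frac[small] <- -Inf
    order_idx <- order(frac, decreasing = TRUE)
    take <- head(order_idx[alloc[order_idx] < sizes[order_idx]], rem)
    alloc[take] <- alloc[take] + 1
  } else if (rem < 0) {
    order_idx <- order(exact - floor(exact))
    order_idx <- order_idx[!small[order_idx] & alloc[order_idx] > 0]
    take <- head(order_idx, -rem)
    alloc[take] <- alloc[take] - 1
  }
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(seq_along(levels(stratum)), function(i) {
      idx <- which(stratum == levels(stratum)[i])
      sample(idx, min(alloc[i], length(idx)))
    }))
  })
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_len(n), train_idx)
  if (length(val_idx) == 0) {
    warn("Validation set is empty (train fraction 1).")
  }
  tib <- as_tibble(data)
  list(train = new_spectra_set(tib[train_idx, , drop = FALSE]),
       validation = new_spectra_set(tib[val_idx, , drop = FALSE]))
}

level_truth <- function(meta, level) {
  switch(level,
         species = meta$species,
         population = meta$population,
         condition = paste(meta$temperature, meta$nutrient, sep = "/"),
         abort("Unknown hierarchy level."))
}

#' Train the three-level hierarchical classification tree
#'
#' Builds one classifier per tree node: a single species model at the root,
#' one population model per species with at least two populations, and one
#' growth-condition model per (species, population) with at least two
#' conditions — 13 models for the full 3 x 3 x 4 design. Each node model is a
#' sparse PLS discriminant model tuned by [select_sparsity_cv()] on exactly
#' the training rows matching the node's path. Nodes with a single child
#' class need no classifier and pass the label through.
#'
#' @param train A preprocessed, averaged [spectra_set()] with at least two
#'   species.
#' @param sparsity_grid,ncomp_grid,folds CV settings per node, see
#'   [select_sparsity_cv()].
#' @param seed Integer seed; each node derives its own fold seed from it.
#' @return An object of class `hierarchy_model`.
#' @export
train_hierarchy <- function(train,
                            sparsity_grid = seq(0.90, 0.99, by = 0.01),
                            ncomp_grid = 1:15, folds = 3, seed = 1) {
  meta <- spectra_meta(train)
  tib <- as_tibble(train)
  fit_node <- function(rows, level, key) {
    sub <- new_spectra_set(tib[rows, , drop = FALSE])
    labels <- level_truth(spectra_meta(sub), level)
    classes <- sort(unique(labels))
    if (length(classes) < 2) {
      return(list(type = "passthrough", label = classes))
    }
    cv <- cv_with_labels(sub, labels, sparsity_grid, ncomp_grid, folds,
                         derive_seed(seed, "node", key))
    list(type = "model", cv = cv, classes = classes)
  }

  root <- fit_node(seq_len(nrow(tib)), "species", "root")
  species_levels <- sort(unique(meta$species))
  pop_nodes <- lapply(species_levels, function(sp) {
    fit_node(which(meta$species == sp), "population", paste0("pop:", sp))
  })
  names(pop_nodes) <- species_levels
  cond_nodes <- list()
  for (sp in species_levels) {
    for (pop in sort(unique(meta$population[meta$species == sp]))) {
      key <- paste(sp, pop, sep = "||")
      cond_nodes[[key]] <- fit_node(
        which(meta$species == sp & meta$population == pop),
        "condition", paste0("cond:", key))
    }
  }
  n_models <- sum(root$type == "model",
                  vapply(pop_nodes, function(x) x$type == "model", logical(1)),
                  vapply(cond_nodes, function(x) x$type == "model", logical(1)))
  structure(list(root = root, pop_nodes = pop_nodes, cond_nodes = cond_nodes,
                 n_models = n_models, seed = seed,
                 train_ids = meta$spectrum_id),
            class = "hierarchy_model")
}

# select_sparsity_cv over an explicit label vector (internal).
cv_with_labels <- function(sub, labels, sparsity_grid, ncomp_grid, folds,
                           seed) {
  sub2 <- as_tibble(sub)
  # reuse the sample_id slot? no — attach labels via a closure-friendly trick:
  # temporarily overwrite the species column (metadata is copied, not shared).
  sub2$species <- labels
  sub2 <- new_spectra_set(sub2)
  select_sparsity_cv(sub2, species, sparsity_grid = sparsity_grid,
                     ncomp_grid = ncomp_grid, folds = folds, seed = seed)
}

#' @export
print.hierarchy_model <- function(x, ...) {
  cat(sprintf("<hierarchy_model: %d node model(s); species -> population -> condition>\n",
              x$n_models))
  invisible(x)
}

node_predict <- function(node, sub) {
  if (node$type == "passthrough") return(rep(node$label, nrow(sub)))
  predict(node$cv$model, sub)$.pred_class
}

#' Route samples through a fitted hierarchy
#'
#' Each sample is classified at the species level, then routed to the
#' predicted species' population model, then to the predicted (species,
#' population) condition model — so an error at an upper level propagates
#' downward, exactly as hierarchical success rates are scored in validation.
#'
#' @param object A [train_hierarchy()] model.
#' @param newdata A preprocessed, averaged [spectra_set()] on the training
#'   axis.
#' @param ... Unused.
#' @return A tibble with true and predicted labels per level plus
#'   hierarchical correctness flags (`correct_species`, `correct_population`,
#'   `correct_condition`; lower levels require all ancestors correct).
#' @export
predict.hierarchy_model <- function(object, newdata, ...) {
  meta <- spectra_meta(newdata)
  tib <- as_tibble(newdata)
  n <- nrow(tib)
  pred_sp <- node_predict(object$root, newdata)
  pred_pop <- character(n)
  pred_cond <- character(n)
  for (sp in unique(pred_sp)) {
    idx <- which(pred_sp == sp)
    sub <- new_spectra_set(tib[idx, , drop = FALSE])
    node <- object$pop_nodes[[sp]]
    if (is.null(node)) {
      pred_pop[idx] <- NA_character_
      next
    }
    pred_pop[idx] <- node_predict(node, sub)
  }
  for (key in unique(paste(pred_sp, pred_pop, sep = "||"))) {
    idx <- which(paste(pred_sp, pred_pop, sep = "||") == key)
    node <- object$cond_nodes[[key]]
    sub <- new_spectra_set(tib[idx, , drop = FALSE])
    pred_cond[idx] <- if (is.null(node)) NA_character_
                      else node_predict(node, sub)
  }
  truth_sp <- meta$species
  truth_pop <- meta$population
  truth_cond <- paste(meta$temperature, meta$nutrient, sep = "/")
  ok_sp <- pred_sp == truth_sp
  ok_pop <- ok_sp & !is.na(pred_pop) & pred_pop == truth_pop
  ok_cond <- ok_pop & !is.na(pred_cond) & pred_cond == truth_cond
  tibble(spectrum_id = meta$spectrum_id,
         species = truth_sp, pred_species = pred_sp,
         population = truth_pop, pred_population = pred_pop,
         condition = truth_cond, pred_condition = pred_cond,
         correct_species = ok_sp, correct_population = ok_pop,
         correct_condition = ok_cond)
}

#' Per-level success rates of a hierarchical classification
#'
#' @param predictions Output of [predict.hierarchy_model()].
#' @return A tibble with one row per level: `level`, `n`, `sr` (percent,
#'   hierarchical scoring: a sample counts as correct at a level only if all
#'   levels above it are also correct).
#' @export
hierarchy_success_rates <- function(predictions) {
  tibble(level = c("species", "population", "condition"),
         n = nrow(predictions),
         sr = c(mean(predictions$correct_species),
                mean(predictions$correct_population),
                mean(predictions$correct_condition)) * 100)
}
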