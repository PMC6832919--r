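# End-to-end orchestration: prepare -> feature selection -> ordinal
# evaluation -> importance -> item grouping -> Bayesian networks ->
# severe/mild combination analysis, with an artifact manifest.

#' Run the full analysis pipeline
#'
#' Executes every stage on a cohort's raw tables and returns all results;
#' when `out_dir` is given, per-stage CSV/JSON/DOT/Newick artifacts and a
#' manifest (parameters, seeds, file checksums) are written.
#'
#' @param cohort An `als_cohort`, or a named list of raw tables.
#' @param items ALSFRS items to analyse (default all ten).
#' @param settings Semi-temporal settings to evaluate (default all three).
#' @param models Model names passed to [default_models()].
#' @param featsel_K Maximal feature-subset size for lab selection.
#' @param cv_folds Evaluation folds (default 10).
#' @param bn_max_vars Cap on the number of variables entering the network
#'   search (top by importance), keeping structure learning tractable.
#' @param bn_max_parents,rf_trees Stage parameters.
#' @param stages Which stages to run (prepare always runs).
#' @param drop_threshold Variable-drop missingness threshold.
#' @param seed Master seed; stage seeds derive from it.
#' @param out_dir Optional output directory.
#' @return A list of class `als_pipeline_result`.
#' @export
run_pipeline <- function(cohort,
                         items = alsfrs_items(),
                         settings = c("last", "both", "first"),
                         models = c("clm", "odt", "cpt", "rf", "prior"),
                         featsel_K = 10L,
                         cv_folds = 10L,
                         bn_max_vars = 10L,
                         bn_max_parents = 4L,
                         rf_trees = 200L,
                         stages = c("featsel", "ordinal", "importance",
                                    "grouping", "bnet", "combos"),
                         drop_threshold = 0.4,
                         seed = 1L,
                         out_dir = NULL) {
  items <- validate_items(items)
  settings <- match.arg(settings, several.ok = TRUE)
  res <- list(params = list(items = items, settings = settings,
                            models = models, featsel_K = featsel_K,
                            cv_folds = cv_folds, bn_max_vars = bn_max_vars,
                            bn_max_parents = bn_max_parents,
                            rf_trees = rf_trees, seed = seed,
                            drop_threshold = drop_threshold))

  res$dataset <- build_patient_dataset(cohort, drop_threshold = drop_threshold)
  tabs <- lapply(stats::setNames(settings, settings), function(s) {
    lapply(stats::setNames(items, items), function(it) {
      assemble_setting(res$dataset, s, it)
    })
  })

  if ("featsel" %in% stages) {
    base_setting <- if ("last" %in% settings) "last" else settings[1]
    res$selection <- lapply(stats::setNames(items, items), function(it) {
      mt <- tabs[[base_setting]][[it]]
      labs <- grep("^lab_", table_features(mt), value = TRUE)
      select_features(mt, features = labs, K = featsel_K, seed = seed)
    })
    res$selection_counts <- count_feature_selections(res$selection)
  }

  if ("ordinal" %in% stages) {
    model_set <- default_models(seed = seed, rf_trees = rf_trees,
                                models = models)
    res$evals <- purrr::imap(tabs, function(by_item, s) {
      purrr::imap(by_item, function(mt, it) {
        cv_evaluate(mt, model_set, k = cv_folds, seed = seed)
      })
    })
    res$eval_summary <- purrr::imap_dfr(res$evals, function(by_item, s) {
      purrr::imap_dfr(by_item, function(ev, it) {
        dplyr::mutate(glance(ev), setting = s, item = it)
      })
    })
  }

  imp_setting <- if ("both" %in% settings) "both" else settings[1]
  if ("importance" %in% stages || "combos" %in% stages) {
    res$importance <- lapply(stats::setNames(items, items), function(it) {
      rank_importance(tabs[[imp_setting]][[it]])
    })
    res$importance_avg <- average_importance(res$importance)
  }

  if ("grouping" %in% stages) {
    res$grouping <- cluster_items(res$dataset$data)
  }

  bn_setting <- if ("last" %in% settings) "last" else settings[1]
  if ("bnet" %in% stages || "combos" %in% stages) {
    res$bn <- lapply(stats::setNames(items, items), function(it) {
      mt <- tabs[[bn_setting]][[it]]
      feats <- table_features(mt)
      if (length(feats) > bn_max_vars && !is.null(res$importance)) {
        imp <- res$importance[[it]]
        base_rank <- stats::setNames(imp$vli,
                                     sub("_(first|last)$", "", imp$predictor))
        sc <- vapply(sub("_(first|last)$", "", feats), function(b) {
          s <- base_rank[names(base_rank) == b]
          if (length(s) == 0) 0 else max(s)
        }, numeric(1))
        feats <- feats[order(-sc)][seq_len(bn_max_vars)]
      }
      disc <- discretize_table(mt, columns = feats)
      disc$data$target <- as.character(mt$target)
      model <- rmcv_learn(disc$data, "target",
                          max_parents = bn_max_parents, seed = seed)
      list(model = model, mb = markov_blanket(model), discretization = disc)
    })
  }

  if ("combos" %in% stages) {
    res$combos <- lapply(stats::setNames(items, items), function(it) {
      bn <- res$bn[[it]]
      mb <- bn$mb
      if (length(mb) == 0) return(NULL)
      four <- select_four_variables(mb, res$importance[[it]])
      dd <- bn$discretization$data
      # FVC displayed on four labelled quartile levels when the MDL scheme
      # is coarser
      mt <- tabs[[bn_setting]][[it]]
      for (v in four) {
        if (grepl("^fvc_percent", v) && length(unique(dd[[v]])) < 4) {
          dd[[v]] <- fvc_quartile_levels(mt[[v]])
        }
      }
      groups <- split_severity(mt)
      combination_frequencies(dd, four, groups)
    })
  }

  if (!is.null(out_dir)) {
    res$manifest <- write_pipeline_outputs(res, out_dir)
  }
  class(res) <- "als_pipeline_result"
  res
}

#' @export
print.als_pipeline_result <- function(x, ...) {
  cat("<als_pipeline_result> ", nrow(x$dataset$data), " patients; stages: ",
      paste(intersect(c("featsel", "ordinal", "importance", "grouping",
                        "bnet", "combos"),
                      c(if (!is.null(x$selection)) "featsel",
                        if (!is.null(x$evals)) "ordinal",
                        if (!is.null(x$importance)) "importance",
                        if (!is.null(x$grouping)) "grouping",
                        if (!is.null(x$bn)) "bnet",
                        if (!is.null(x$combos)) "combos")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(as.data.frame(x), p, row.names = FALSE)
    p
  }
  paths <- character(0)
  paths <- c(paths, wcsv(res$dataset$data, "uniform_dataset.csv"))
  paths <- c(paths, wcsv(res$dataset$log$dropped_patients, "dropped_patients.csv"))
  if (!is.null(res$selection)) {
    sel <- lapply(res$selection, selected_features)
    p <- file.path(out_dir, "selected_features.json")
    jsonlite::write_json(sel, p)
    paths <- c(paths, p, wcsv(res$selection_counts[, c("feature", "n_selected")],
                              "selection_counts.csv"))
  }
  if (!is.null(res$eval_summary)) {
    paths <- c(paths, wcsv(res$eval_summary, "eval_summary.csv"))
    folds <- purrr::imap_dfr(res$evals, function(by_item, s) {
      purrr::imap_dfr(by_item, function(ev, it) {
        dplyr::mutate(tidy(ev), setting = s, item = it)
      })
    })
    paths <- c(paths, wcsv(folds, "eval_folds.csv"))
  }
  if (!is.null(res$importance)) {
    per <- purrr::imap_dfr(res$importance, function(imp, it) {
      dplyr::mutate(tibble::as_tibble(imp), item = it)
    })
    paths <- c(paths, wcsv(per, "importance_per_item.csv"),
               wcsv(res$importance_avg, "importance_averaged.csv"))
  }
  if (!is.null(res$grouping)) {
    p <- file.path(out_dir, "item_groups.json")
    jsonlite::write_json(res$grouping$groups, p)
    paths <- c(paths, p)
    if (!is.null(res$grouping$linkage)) {
      pn <- file.path(out_dir, "item_dendrogram.nwk")
      grouping_newick(res$grouping, pn)
      paths <- c(paths, pn)
    }
  }
  if (!is.null(res$bn)) {
    for (it in names(res$bn)) {
      pd <- file.path(out_dir, paste0("bn_", it, ".dot"))
      bn_to_dot(res$bn[[it]]$model, file = pd)
      pm <- file.path(out_dir, paste0("bn_", it, "_mb.dot"))
      bn_to_dot(res$bn[[it]]$model, mb_only = TRUE, file = pm)
      paths <- c(paths, pd, pm)
    }
    pj <- file.path(out_dir, "markov_blankets.json")
    jsonlite::write_json(lapply(res$bn, `[[`, "mb"), pj)
    paths <- c(paths, pj)
  }
  if (!is.null(res$combos)) {
    for (it in names(res$combos)) {
      if (is.null(res$combos[[it]])) next
      paths <- c(paths, wcsv(res$combos[[it]],
                             paste0("combinations_", it, ".csv")))
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("alsord")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    params = res$params,
    files = lapply(stats::setNames(paths, basename(paths)), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  pm <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, pm, auto_unbox = TRUE)
  manifest
}
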