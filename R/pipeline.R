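# End-to-end orchestration: preprocess -> select with 1-3 algorithms ->
# combine -> evaluate -> rates -> comparison statistics, with every
# intermediate artifact written to disk and a manifest that allows an exact
# re-run.

#' Pipeline configuration
#'
#' Accepts either a named list or a YAML file path with the same fields.
#'
#' @param data path to a delimited matrix, a [feature_matrix()], or a
#'   [synth_spec()] (in YAML: a `synth:` block of [synth_spec()] arguments).
#' @param algorithms 1 to 3 of `c("sma", "pfa", "hgso", "pso")`.
#' @param outdir output directory.
#' @param seed global seed; per-algorithm run seeds are derived as
#'   `seed + 1000 * index`.
#' @param orientation,label_source,delimiter passed to [read_matrix()] when
#'   `data` is a path.
#' @param fitness list of [fitness_config()] arguments.
#' @param optimizer list of [optimizer_config()] arguments shared by all
#'   algorithms (`pop_size`, `max_iter`, ...).
#' @param classifiers classifiers for the evaluation stage, default
#'   `c("KNN")`.
#' @param cv evaluation CV spec, default `list(type = "kfold", k = 5, seed =
#'   seed + 7)`.
#' @param positive optional positive class label.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(data, algorithms = c("sma", "pfa", "hgso"),
                            outdir = "swarmfs_out", seed = 1,
                            orientation = "samples_in_columns",
                            label_source = "label", delimiter = "\t",
                            fitness = list(), optimizer = list(),
                            classifiers = "KNN", cv = NULL,
                            positive = NULL) {
  algorithms <- match.arg(algorithms, c("sma", "pfa", "hgso", "pso"),
                          several.ok = TRUE)
  if (length(algorithms) < 1 || length(algorithms) > 3)
    stop_validation("pipeline takes 1 to 3 algorithms, got %d",
                    length(algorithms))
  structure(list(data = data, algorithms = algorithms, outdir = outdir,
                 seed = as.integer(seed), orientation = orientation,
                 label_source = label_source, delimiter = delimiter,
                 fitness = fitness, optimizer = optimizer,
                 classifiers = classifiers,
                 cv = cv %||% list(type = "kfold", k = 5, seed = seed + 7),
                 positive = positive),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror [pipeline_config()] arguments, with an
#'   optional `synth:` block in place of a `data:` path.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) {
    y$data <- do.call(synth_spec, y$synth)
    y$synth <- NULL
  }
  do.call(pipeline_config, y)
}

#' Run the full selection pipeline
#'
#' Stages, in order: load or generate the matrix; remove features with
#' missing values; run each configured algorithm; combine the selected
#' subsets by intersection and union (when 2 or 3 algorithms are
#' configured); evaluate every subset with the configured classifiers;
#' tabulate selection rates; compare the solo algorithms with Wilcoxon
#' signed-rank (pairwise) and Friedman tests on per-fold accuracies. All
#' artifacts are written under `cfg$outdir`, together with a JSON manifest
#' recording seeds and configuration for exact re-runs.
#'
#' @param cfg a [pipeline_config()] (or path to a YAML config).
#' @return result bundle, invisibly: list with `matrix`, `runs`, `combos`,
#'   `evaluation`, `rates`, `stats`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[swarmFS] ", sprintf(...))

  # --- stage 1: data -------------------------------------------------------
  m <- if (inherits(cfg$data, "FeatureMatrix")) {
    cfg$data
  } else if (inherits(cfg$data, "SynthSpec")) {
    log_msg("generating synthetic data (%s model, %d x %d)",
            cfg$data$value_model, cfg$data$n_per_class * cfg$data$n_classes,
            cfg$data$n_features)
    synth_generate(cfg$data)$matrix
  } else {
    log_msg("reading %s", cfg$data)
    read_matrix(cfg$data, orientation = cfg$orientation,
                label_source = cfg$label_source, delimiter = cfg$delimiter)
  }

  # --- stage 2: preprocessing ---------------------------------------------
  m <- drop_missing_features(m)

  fit_cfg <- do.call(fitness_config,
                     utils::modifyList(list(fold_seed = cfg$seed), cfg$fitness))

  # --- stage 3: feature selection -----------------------------------------
  runs <- list()
  for (i in seq_along(cfg$algorithms)) {
    algo <- cfg$algorithms[i]
    opt_cfg <- do.call(optimizer_config, utils::modifyList(
      list(algorithm = algo, seed = cfg$seed + 1000L * i), cfg$optimizer))
    log_msg("selecting with %s (pop %d, %d iterations, seed %d)",
            algo, opt_cfg$pop_size, opt_cfg$max_iter, opt_cfg$seed)
    run <- swarm_optimize(m, fit_cfg, opt_cfg)
    runs[[toupper(algo)]] <- run
    write_feature_list(run$best_mask, m$feature_ids,
                       file.path(cfg$outdir, paste0("subset_", algo, ".txt")))
    write_trace(run, file.path(cfg$outdir, paste0("trace_", algo, ".tsv")))
  }

  # --- stage 4: combination ------------------------------------------------
  combos <- NULL
  all_masks <- lapply(runs, `[[`, "best_mask")
  if (length(runs) >= 2) {
    combos <- combine_masks(all_masks)
    for (nm in names(combos$combos)) {
      fn <- chartr("&|", "ix", nm)  # '&' -> i(ntersection), '|' -> x (union)
      write_feature_list(combos$combos[[nm]], m$feature_ids,
                         file.path(cfg$outdir, paste0("combo_", fn, ".txt")))
    }
  }

  # --- stage 5: evaluation -------------------------------------------------
  subsets <- all_masks
  if (!is.null(combos)) subsets <- c(subsets, combos$combos)
  eval_rows <- list()
  reports <- list()
  for (nm in names(subsets)) {
    mask <- subsets[[nm]]
    if (!any(mask)) {
      # empty combination: no classifier can run, reported as missing
      eval_rows[[nm]] <- data.frame(subset = nm, classifier = cfg$classifiers,
                                    n_selected = 0, accuracy = NA_real_)
      next
    }
    rep_nm <- evaluate_classifiers(mask, m, classifiers = cfg$classifiers,
                                   cv = cfg$cv, positive = cfg$positive)
    reports[[nm]] <- rep_nm
    eval_rows[[nm]] <- data.frame(
      subset = nm, classifier = names(rep_nm),
      n_selected = sum(mask),
      accuracy = vapply(rep_nm, `[[`, numeric(1), "accuracy"))
  }
  evaluation <- do.call(rbind, c(eval_rows, list(make.row.names = FALSE)))
  utils::write.table(evaluation, file.path(cfg$outdir, "evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 6: rates and statistics --------------------------------------
  rates <- NULL
  if (length(runs) >= 2) {
    rates <- rate_table(stats::setNames(list(all_masks), "dataset"))
    utils::write.table(cbind(row = rownames(rates), format_rate_table(rates)),
                       file.path(cfg$outdir, "rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stat_results <- NULL
  if (length(runs) >= 2) {
    fold_acc <- lapply(names(runs), function(nm) {
      r <- reports[[nm]]
      r[[cfg$classifiers[1]]]$per_fold_accuracy
    })
    names(fold_acc) <- names(runs)
    acc_mat <- do.call(cbind, fold_acc)
    pair_tests <- list()
    prs <- utils::combn(names(runs), 2, simplify = FALSE)
    for (pr in prs) {
      pair_tests[[paste(pr, collapse = " vs ")]] <-
        wilcoxon_signed_rank(fold_acc[[pr[1]]], fold_acc[[pr[2]]])
    }
    stat_results <- list(wilcoxon = pair_tests,
                         friedman = if (length(runs) >= 2) friedman(acc_mat))
    stat_lines <- c(
      vapply(names(pair_tests), function(nm) {
        w <- pair_tests[[nm]]
        sprintf("wilcoxon\t%s\tR+=%g\tR-=%g\tp=%.6g", nm, w$r_plus, w$r_minus,
                w$p_value)
      }, character(1)),
      sprintf("friedman\tall\tchisq=%.6g\tdf=%d\tp=%.6g",
              stat_results$friedman$statistic, stat_results$friedman$df,
              stat_results$friedman$p_value))
    writeLines(stat_lines, file.path(cfg$outdir, "stats.tsv"))
  }

  # --- manifest ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("swarmFS")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    algorithms = cfg$algorithms,
    run_seeds = vapply(runs, `[[`, integer(1), "seed"),
    fitness = unclass(fit_cfg),
    optimizer = cfg$optimizer,
    classifiers = cfg$classifiers,
    cv = cfg$cv,
    n_samples = n_samples(m),
    n_features = n_features(m)
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(matrix = m, runs = runs, combos = combos,
                 evaluation = evaluation, rates = rates,
                 stats = stat_results, manifest = manifest))
}
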