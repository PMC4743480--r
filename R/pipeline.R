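#' Pipeline configuration
#'
#' Validated bundle of every knob the end-to-end run uses. Thresholds are
#' checked against their documented ranges at construction; the seed is
#' mandatory so every run is reproducible.
#'
#' @param input Either a [synthetic_spec()] or a list
#'   `list(compounds = <csv path>, quantum = <csv path or NULL>)`.
#' @param task Tag describing the binary task, e.g. `"inhibitor"` or
#'   `"substrate"`; the positive class is the tag itself for CSV input.
#' @param mw_limit Curation molecular-weight ceiling in Da (default 1000).
#' @param cor_cutoff Collinearity cutoff on |r| in (0, 1] (default 0.7).
#' @param train_fraction Training share of the split (default 0.85).
#' @param k_folds Cross-validation folds (default 10).
#' @param learners Character subset of `c("tree", "mlp", "svm")`.
#' @param seed Integer seed (required).
#' @param out_dir Output directory for stage artifacts, or `NULL` to skip
#'   writing.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, task = "inhibitor", mw_limit = 1000,
                            cor_cutoff = 0.7, train_fraction = 0.85,
                            k_folds = 10, learners = "tree", seed,
                            out_dir = NULL) {
  if (missing(seed) || !is.finite(seed)) {
    stop("pipeline_config: seed is mandatory")
  }
  if (!(cor_cutoff > 0 && cor_cutoff <= 1)) {
    stop("pipeline_config: cor_cutoff must lie in (0, 1]")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("pipeline_config: train_fraction must lie in (0, 1)")
  }
  if (mw_limit <= 0) stop("pipeline_config: mw_limit must be positive")
  if (k_folds < 2) stop("pipeline_config: k_folds must be at least 2")
  bad <- setdiff(learners, c("tree", "mlp", "svm"))
  if (length(bad)) {
    stop("pipeline_config: unknown learner(s): ", paste(bad, collapse = ", "))
  }
  structure(list(input = input, task = task, mw_limit = mw_limit,
                 cor_cutoff = cor_cutoff, train_fraction = train_fraction,
                 k_folds = k_folds, learners = learners,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full classification pipeline
#'
#' Executes the four stages in order — (1) dataset preparation,
#' (2) descriptor computation and feature selection, (3) imbalance
#' correction by FCM cluster selection, (4) model building and
#' validation — and assembles a run report. Balancing is skipped (and
#' noted) when the positive class does not outnumber the negative class.
#' Reruns with the same config and seed produce identical reports.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `run_report`: list with `census`, `selection`
#'   (kept/removed/cutoff), `balancing` (cluster evaluation table or a
#'   skip note), `metrics` (per learner: training / cross-validation /
#'   external rows), `rules` (rendered decision-tree rules), `provenance`
#'   (config echo, config hash, seed). Artifacts are written under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  report <- list()
  tryCatch({
    # stage 1-2: dataset preparation + descriptors
    if (inherits(config$input, "synthetic_spec")) {
      gen <- generate_feature_table(config$input)
      ft <- gen$table
      report$census <- census_counts_generic(ft$labels)
    } else {
      stage <- "curation"
      records <- utils::read.csv(config$input$compounds,
                                 stringsAsFactors = FALSE)
      cur <- curate(molecule_records(records$smiles, records$label,
                                     ids = records$id),
                    mw_limit = config$mw_limit)
      report$census <- as.list(cur$census)
      stage <- "descriptors"
      ft <- build_feature_table(cur, positive = config$task)
      if (!is.null(config$input$quantum)) {
        ft <- attach_quantum_block(ft, config$input$quantum)
      }
    }
    stage <- "feature_selection"
    sel <- select_features(ft, cutoff = config$cor_cutoff)
    ft <- sel$table
    report$selection <- list(kept = sel$report$kept,
                             removed = sel$report$removed,
                             cutoff = sel$report$cutoff)

    stage <- "balancing"
    pos_label <- ft$positive
    is_pos <- as.character(ft$labels) == pos_label
    if (sum(is_pos) > sum(!is_pos)) {
      bal <- select_representative_cluster(
        ft_rows(ft, which(is_pos)), ft_rows(ft, which(!is_pos)),
        fcm_config(seed = config$seed))
      ft <- bal$balanced
      report$balancing <- list(skipped = FALSE,
                               evaluations = bal$evaluations,
                               selected_cluster = bal$selected_id)
    } else {
      report$balancing <- list(
        skipped = TRUE,
        note = "positive class does not outnumber negative class")
    }

    stage <- "split"
    plan <- pca_random_split(ft, config$train_fraction, seed = config$seed)
    train <- ft_rows(ft, plan$train_ids)
    test <- ft_rows(ft, plan$test_ids)
    report$split <- list(n_train = length(plan$train_ids),
                         n_test = length(plan$test_ids),
                         method = as.list(plan$method))

    stage <- "model_building"
    report$metrics <- list()
    for (alg in config$learners) {
      cfg <- learner_config(alg, seed = config$seed)
      model <- train_learner(train, cfg, seed = config$seed)
      m_tr <- metrics(confusion(predict_learner(model, train$x),
                                as.character(train$labels), pos_label))
      m_cv <- suppressWarnings(
        kfold_cv(train, cfg, k = config$k_folds, seed = config$seed))
      m_ext <- metrics(confusion(predict_learner(model, test$x),
                                 as.character(test$labels), pos_label))
      report$metrics[[alg]] <- list(
        training = as.list(unclass(m_tr)),
        cross_validation = as.list(unclass(m_cv)),
        external = as.list(unclass(m_ext)),
        chosen = as.list(model$chosen))
      if (alg == "tree") {
        report$rules <- render_rules(model$fit)
      }
    }
    report$provenance <- list(task = config$task, seed = config$seed,
                              config_hash = config_hash(config))
    report <- structure(report, class = "run_report")
    if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
    report
  }, error = function(e) {
    stop("run_pipeline: stage '", stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
}

census_counts_generic <- function(labels) {
  tab <- table(labels)
  out <- as.list(as.integer(tab))
  names(out) <- names(tab)
  out$total <- sum(tab)
  out
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  if (inherits(cfg$input, "synthetic_spec")) cfg$input <- unclass(cfg$input)
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Write run-report artifacts
#'
#' Emits the report JSON plus publication-style tables: per-learner metric
#' tables (rows training / 10-fold CV / external; accuracy, sensitivity
#' and specificity rendered with three decimals), the cluster evaluation
#' table and the rendered rule tree.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  for (alg in names(report$metrics)) {
    m <- report$metrics[[alg]]
    tab <- do.call(rbind, lapply(
      c("training", "cross_validation", "external"), function(set) {
        v <- m[[set]]
        data.frame(set = set,
                   accuracy = sprintf("%.3f", v$accuracy),
                   sensitivity = sprintf("%.3f", v$sensitivity),
                   specificity = sprintf("%.3f", v$specificity),
                   mcc = sprintf("%.3f", v$mcc),
                   stringsAsFactors = FALSE)
      }))
    utils::write.csv(tab, file.path(dir, paste0("metrics_", alg, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(report$balancing$evaluations)) {
    utils::write.csv(report$balancing$evaluations,
                     file.path(dir, "cluster_evaluations.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$rules)) {
    writeLines(report$rules, file.path(dir, "rules.txt"))
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (seed", x$provenance$seed, ")\n")
  cat("census:", paste(names(x$census), unlist(x$census), sep = "=",
                       collapse = ", "), "\n")
  cat("kept features:", paste(x$selection$kept, collapse = ", "), "\n")
  if (isTRUE(x$balancing$skipped)) {
    cat("balancing: skipped (", x$balancing$note, ")\n")
  } else {
    cat("balancing: cluster", x$balancing$selected_cluster, "selected\n")
  }
  for (alg in names(x$metrics)) {
    v <- x$metrics[[alg]]$cross_validation
    cat(sprintf("%s 10-fold CV: accuracy %.3f %%, MCC %.3f\n",
                alg, v$accuracy, v$mcc))
  }
  if (!is.null(x$rules)) cat("rules:\n", x$rules, sep = "")
  invisible(x)
}
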