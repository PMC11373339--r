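# End-to-end drivers: simulate, impute, benchmark, evaluate. One mask plan
# is shared by every method in a benchmark run (required for the paired
# signed-rank comparison) and serialized for audit. All outputs are plain
# text and byte-reproducible under a fixed seed.

#' Validate and normalize a benchmark run configuration
#'
#' @param config named list (typically from a YAML file): `dataset` (either
#'   `list(preset = ...)` or `list(table = path, embeddings = path,
#'   groups = path)`), `methods` (character vector; `"GNN"` selects the
#'   graph attention imputer, other names come from [imputer_registry()]),
#'   `test_frac`, `val_frac`, `model` (overrides for [model_config()]),
#'   `evaluation` (`bins`, `bootstrap_reps`, `alpha`, `fdr_mark`),
#'   `out_dir`, `seed`, `verbose`. Unknown keys are rejected.
#' @return The completed configuration list.
#' @export
validate_run_config <- function(config) {
  known <- c("dataset", "methods", "test_frac", "val_frac", "model",
             "evaluation", "out_dir", "seed", "verbose")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  defaults <- list(methods = c("GNN", "Median", "KNN"), test_frac = 0.10,
                   val_frac = 0.10, model = list(),
                   evaluation = list(bins = c(0, 0.25, 0.5, 0.75, 1),
                                     bootstrap_reps = 1000L, alpha = 0.05,
                                     fdr_mark = 0.05),
                   out_dir = NULL, seed = 1L, verbose = FALSE)
  config <- modifyList(defaults, config)
  if (is.null(config$dataset)) stop("config needs a 'dataset' entry")
  eval_known <- c("bins", "bootstrap_reps", "alpha", "fdr_mark")
  extra <- setdiff(names(config$evaluation), eval_known)
  if (length(extra)) stop("unknown evaluation key(s): ",
                          paste(extra, collapse = ", "))
  bad <- setdiff(config$methods,
                 c("GNN", names(imputer_registry())))
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  config
}

resolve_dataset <- function(dataset_cfg) {
  if (!is.null(dataset_cfg$preset)) {
    fix <- make_benchmark_fixture(dataset_cfg$preset)
    list(dataset = fix$dataset, embeddings = fix$embeddings,
         de_labels = fix$truth$de_labels, truth = fix$truth)
  } else if (!is.null(dataset_cfg$table)) {
    ds <- load_peptide_table(dataset_cfg$table)
    emb <- if (!is.null(dataset_cfg$embeddings))
      load_embedding_table(dataset_cfg$embeddings, ds$peptide_ids) else NULL
    if (!is.null(dataset_cfg$groups)) {
      gr <- read_sample_groups(dataset_cfg$groups)
      ds <- peptide_dataset(ds$abundance, ds$peptide_ids, ds$protein_groups,
                            ds$sample_ids, gr)
    }
    de <- if (!is.null(dataset_cfg$de_labels)) {
      df <- read.delim(dataset_cfg$de_labels)
      as.logical(df[[2L]][match(ds$peptide_ids, df[[1L]])])
    } else NULL
    list(dataset = ds, embeddings = emb, de_labels = de, truth = NULL)
  } else stop("dataset config needs 'preset' or 'table'")
}

#' Run the full imputation benchmark on one shared mask plan
#'
#' Generates or loads a dataset, draws one evaluation mask plan, runs every
#' configured method on the identical training view, and assembles the
#' complete evaluation report: per-sample RMSE with bootstrap confidence
#' intervals, dataset MAE, the pairwise signed-rank matrix with win counts,
#' missingness-stratified RMSE, uncertainty diagnostics (when the GNN method
#' runs) and differential-expression ROC analysis (when sample groups and
#' ground-truth labels are available).
#'
#' @param config a configuration list (see [validate_run_config()]).
#' @return The report as a nested list; when `config$out_dir` is set the
#'   report is also written as JSON + TSV tables.
#' @export
run_benchmark <- function(config) {
  config <- validate_run_config(config)
  res <- resolve_dataset(config$dataset)
  ds <- res$dataset
  plan <- make_masked_split(ds, config$test_frac, config$val_frac,
                            seed = config$seed)
  std <- log_standardize(ds)
  trainZ <- apply_mask_plan(std$matrix, plan)
  tables <- list()
  extras <- list()
  gnn_result <- NULL
  for (m in config$methods) {
    if (config$verbose) message("running method ", m)
    if (m == "GNN") {
      cfg <- do.call(model_config,
                     modifyList(list(seed = config$seed), config$model))
      fit <- train_gnn_imputer(ds, plan, embeddings = res$embeddings,
                               cfg = cfg, verbose = config$verbose)
      gnn_result <- impute_gnn(ds, fit, embeddings = res$embeddings,
                               plan = plan)
      tables[[m]] <- error_table(plan, gnn_result$mu, m, ds,
                                 sigma = sqrt(gnn_result$sigma2))
      extras$gnn_history <- fit$history
    } else {
      completed <- impute_matrix(trainZ, m, seed = config$seed)
      tables[[m]] <- error_table(plan, completed, m, ds)
    }
  }
  evalc <- config$evaluation
  per_sample <- lapply(tables, samplewise_rmse)
  report <- list(
    config = config[c("methods", "test_frac", "val_frac", "seed")],
    n_peptides = nrow(ds$abundance), n_samples = ncol(ds$abundance),
    n_test = nrow(plan$test_idx), n_val = nrow(plan$val_idx),
    rmse = lapply(tables, dataset_rmse),
    mae = lapply(tables, dataset_mae),
    samplewise_rmse = per_sample,
    rmse_ci = lapply(per_sample, function(v)
      bootstrap_ci(v, reps = evalc$bootstrap_reps, seed = config$seed)))
  if (length(tables) >= 2L) {
    pw <- pairwise_wilcoxon_matrix(tables, alpha = evalc$alpha)
    report$wilcoxon_p <- pw$p_matrix
    report$win_counts <- as.list(pw$win_counts)
  }
  report$stratified_rmse <- lapply(tables, stratified_rmse, bins = evalc$bins)
  if (!is.null(gnn_result)) {
    tab <- tables[["GNN"]]
    if (!is.null(tab)) {
      report$uncertainty <- list(
        spearman = cor(tab$sigma, tab$abs_error, method = "spearman"),
        quantile_rmse = uncertainty_quantile_rmse(tab))
    }
  }
  if (!is.null(ds$sample_groups) && !is.null(res$de_labels) &&
      length(unique(ds$sample_groups)) == 2L) {
    report$de <- lapply(tables, function(tab) {
      m <- tab$method[1L]
      completed <- if (m == "GNN") {
        M <- gnn_result$mu
        M[!is.na(trainZ)] <- trainZ[!is.na(trainZ)]
        M
      } else impute_matrix(trainZ, m, seed = config$seed)
      de <- welch_de(completed, ds$sample_groups)
      roc <- roc_pr(res$de_labels[de$table$row], de$table$q,
                    fdr_mark = evalc$fdr_mark)
      list(auc = roc$auc, pr_auc = roc$pr_auc,
           operating_point = as.list(roc$operating_point),
           n_tested = nrow(de$table))
    })
  }
  if (!is.null(config$out_dir))
    write_benchmark_report(report, tables, plan, config$out_dir)
  invisible(report)
}

write_benchmark_report <- function(report, tables, plan, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null",
    matrix = "rowmajor", dataframe = "columns")
  write_mask_plan(plan, file.path(out_dir, "maskplan.tsv"))
  per_sample <- do.call(rbind, lapply(names(tables), function(m) {
    v <- samplewise_rmse(tables[[m]])
    data.frame(method = m, sample_id = names(v), rmse = unname(v))
  }))
  write.table(format(per_sample, digits = 10, trim = TRUE),
              file.path(out_dir, "rmse_per_sample.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  errs <- do.call(rbind, tables)
  write.table(format(errs, digits = 10, trim = TRUE),
              file.path(out_dir, "errors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$wilcoxon_p)) {
    pm <- as.data.frame(report$wilcoxon_p)
    pm <- cbind(method = rownames(report$wilcoxon_p), pm)
    write.table(format(pm, digits = 10, trim = TRUE),
                file.path(out_dir, "wilcoxon_p.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Simulate a synthetic dataset to disk
#'
#' @param preset a [make_benchmark_fixture()] preset name, or `NULL` when a
#'   `spec` is given.
#' @param out_dir output directory.
#' @param spec optional [synthetic_spec()] used instead of a preset.
#' @return Invisibly, the written file paths.
#' @export
run_simulate <- function(preset = NULL, out_dir, spec = NULL) {
  gen <- if (!is.null(spec)) generate_dataset(spec)
    else make_benchmark_fixture(preset)
  write_synthetic_dataset(gen, out_dir)
}

#' Impute a dataset with one method and write the completed table
#'
#' Writes the completed wide peptide table (raw measurement scale) and, for
#' the GNN method, a per-entry sigma table alongside.
#'
#' @param dataset_cfg dataset part of the run configuration (see
#'   [validate_run_config()]).
#' @param method `"GNN"` or a name from [imputer_registry()].
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param model optional [model_config()] overrides for the GNN method.
#' @return Invisibly, the output directory.
#' @export
run_impute <- function(dataset_cfg, method, out_dir, seed = 1L,
                       model = list()) {
  res <- resolve_dataset(dataset_cfg)
  ds <- res$dataset
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  std <- log_standardize(ds)
  if (method == "GNN") {
    # an internal split still provides the validation set for early stopping
    plan <- make_masked_split(ds, 0.01, 0.10, seed = seed)
    cfg <- do.call(model_config, modifyList(list(seed = seed), model))
    fit <- train_gnn_imputer(ds, plan, embeddings = res$embeddings, cfg = cfg)
    result <- impute_gnn(ds, fit, embeddings = res$embeddings)
    completed <- result$completed
    sig <- result$uncertainty
    sig_df <- data.frame(peptide_id = rep(ds$peptide_ids, ncol(sig)),
                         sample_id = rep(ds$sample_ids, each = nrow(sig)),
                         sigma = as.vector(sig))
    sig_df <- sig_df[!is.na(sig_df$sigma), ]
    write.table(sig_df, file.path(out_dir, "uncertainty.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    if (!method %in% names(imputer_registry()))
      stop("unknown imputation method '", method, "'")
    filled <- impute_matrix(std$matrix, method, seed = seed)
    completed <- inverse_transform(filled, std$state)
    completed[!is.na(ds$abundance)] <- ds$abundance[!is.na(ds$abundance)]
  }
  out <- peptide_dataset(completed, ds$peptide_ids, ds$protein_groups,
                         ds$sample_ids, ds$sample_groups)
  write_peptide_table(out, file.path(out_dir, "completed.tsv"))
  invisible(out_dir)
}

#' Re-score a completed table against a saved mask plan
#'
#' @param completed_path completed wide peptide table written by
#'   [run_impute()] or [run_benchmark()].
#' @param maskplan_path mask plan TSV written by [write_mask_plan()].
#' @return list with `rmse` and `mae` over the plan's test positions.
#' @export
run_evaluate <- function(completed_path, maskplan_path) {
  ds <- load_peptide_table(completed_path)
  plan <- read_mask_plan(maskplan_path)
  z <- (log(ds$abundance) - plan$state$mean) / plan$state$sd
  pred <- z[plan$test_idx]
  err <- pred - plan$truth_test
  list(rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       n_test = length(err))
}

#' Read a mask plan serialized by [write_mask_plan()]
#' @param path TSV path.
#' @return A [mask_plan].
#' @export
read_mask_plan <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- regmatches(header, gregexpr("[a-z]+=[^ ]+", header))[[1L]]
  meta <- setNames(sub("^[a-z]+=", "", kv), sub("=.*$", "", kv))
  df <- read.delim(path, skip = 1L)
  state <- structure(list(mean = as.numeric(meta["mean"]),
                          sd = as.numeric(meta["sd"]), per_sample = FALSE),
                     class = "transform_state")
  test <- df[df$set == "test", ]
  val <- df[df$set == "val", ]
  new_mask_plan(cbind(test$row, test$col), cbind(val$row, val$col),
                test$truth, val$truth, meta[["mechanism"]], state,
                c(as.integer(meta["nrow"]), as.integer(meta["ncol"])))
}
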