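#' Run the repeated-split evaluation protocol
#'
#' For each repeat r in `0..repeats-1`: reseed the split with
#' `base_seed + r`, build (or reuse) the neighborhood graphs, train the
#' model on the training pairs with early stopping on the validation set,
#' score the test pairs, and compute AUROC and AUPRC. Results are aggregated
#' into a metrics report (mean and standard deviation across repeats).
#'
#' Graph construction is transductive by default: similarities come from the
#' encodings of *all* entities (encodings are computed from sequences alone
#' and involve no interaction labels, so test entities in the graph leak no
#' labels), while the training loss only ever sees training pairs. With
#' `graph_scope = "inductive"`, training-time graphs are restricted to
#' train/validation entities and test entities attach to the full graph only
#' at inference.
#'
#' @param proteins,drugs [encoding_matrix()] objects for all entities.
#' @param interactions an [interaction_set()] of positives.
#' @param mode,balance,fractions split protocol, see [make_split()].
#' @param config a [gat_config()] (its seed is re-derived per repeat).
#' @param repeats number of reseeded repetitions.
#' @param base_seed first split seed.
#' @param graph_quantile similarity quantile used as binarization threshold.
#' @param self_connections keep self-edges in the adjacency.
#' @param graph_scope `"transductive"` or `"inductive"`.
#' @param n_leak if nonzero, apply [leak_samples()] with this count to each
#'   cold-drug split before training.
#' @return an object of class `metrics_report`: data.frame `per_run`
#'   (seed, auroc, auprc) plus aggregate fields and the scenario descriptor.
#' @export
run_experiment <- function(proteins, drugs, interactions,
                           mode = "warm", balance = "balanced_1_1",
                           fractions = c(0.79, 0.01, 0.20),
                           config = gat_config(), repeats = 10L,
                           base_seed = 0L, graph_quantile = 0.95,
                           self_connections = TRUE,
                           graph_scope = c("transductive", "inductive"),
                           n_leak = 0L) {
  graph_scope <- match.arg(graph_scope)
  X <- proteins; Y <- drugs
  sim_x <- pearson_similarity(X)
  sim_y <- pearson_similarity(Y)
  per <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    seed <- base_seed + r - 1L
    res <- tryCatch(
      run_once(X, Y, sim_x, sim_y, interactions, mode, balance, fractions,
               config, seed, graph_quantile, self_connections, graph_scope,
               n_leak),
      error = function(e)
        stop(sprintf("repeat with seed %d failed: %s", seed,
                     conditionMessage(e)), call. = FALSE))
    per[[r]] <- data.frame(seed = seed, auroc = res$auroc, auprc = res$auprc)
  }
  per_run <- do.call(rbind, per)
  structure(list(per_run = per_run,
                 mean_auroc = mean(per_run$auroc),
                 mean_auprc = mean(per_run$auprc),
                 sd_auroc = stats::sd(per_run$auroc),
                 sd_auprc = stats::sd(per_run$auprc),
                 scenario = list(mode = mode, balance = balance,
                                 n_leak = n_leak, graph_scope = graph_scope,
                                 use_gat = config$use_gat)),
            class = "metrics_report")
}

run_once <- function(X, Y, sim_x, sim_y, interactions, mode, balance,
                     fractions, config, seed, graph_quantile,
                     self_connections, graph_scope, n_leak) {
  sp <- make_split(interactions, mode, balance, fractions, seed = seed)
  if (n_leak > 0) sp <- leak_samples(sp, n_leak, seed = seed)
  cfg <- config
  cfg$seed <- derive_seed(seed, "model")
  if (graph_scope == "transductive" || !cfg$use_gat) {
    gx <- neighborhood_graph(sim_x, quantile = graph_quantile,
                             self_connections = self_connections,
                             basis = "pearson_encoding")
    gy <- neighborhood_graph(sim_y, quantile = graph_quantile,
                             self_connections = self_connections,
                             basis = "pearson_encoding")
    fit <- suppressWarnings(
      dtigat(X, Y, sp$train, gx, gy, config = cfg, val_pairs = sp$val))
    scores <- predict(fit, sp$test)
  } else {
    vis_p <- sort(unique(c(sp$train$protein_id, sp$val$protein_id)))
    vis_d <- sort(unique(c(sp$train$drug_id, sp$val$drug_id)))
    Xv <- encoding_matrix(unclass(X)[vis_p, , drop = FALSE], source = "synthetic")
    Yv <- encoding_matrix(unclass(Y)[vis_d, , drop = FALSE], source = "synthetic")
    gx <- neighborhood_graph(sim_x[vis_p, vis_p], quantile = graph_quantile,
                             self_connections = self_connections,
                             basis = "pearson_encoding")
    gy <- neighborhood_graph(sim_y[vis_d, vis_d], quantile = graph_quantile,
                             self_connections = self_connections,
                             basis = "pearson_encoding")
    fit <- suppressWarnings(
      dtigat(Xv, Yv, sp$train, gx, gy, config = cfg, val_pairs = sp$val))
    gx_full <- neighborhood_graph(sim_x, quantile = graph_quantile,
                                  self_connections = self_connections,
                                  basis = "pearson_encoding")
    gy_full <- neighborhood_graph(sim_y, quantile = graph_quantile,
                                  self_connections = self_connections,
                                  basis = "pearson_encoding")
    scores <- suppressWarnings(
      predict(fit, sp$test,
              newdata = list(proteins = X, drugs = Y,
                             protein_graph = gx_full, drug_graph = gy_full)))
  }
  list(auroc = auroc(scores, sp$test$label),
       auprc = auprc(scores, sp$test$label))
}

#' @export
print.metrics_report <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf("<metrics_report> mode %s, balance %s%s (%s, %s)\n",
              sc$mode, sc$balance,
              if (sc$n_leak > 0) sprintf(", leak %d", sc$n_leak) else "",
              sc$graph_scope,
              if (sc$use_gat) "full model" else "encoder-only ablation"))
  cat(sprintf("  %d repeats: AUROC %.4f +/- %.4f, AUPRC %.4f +/- %.4f\n",
              nrow(x$per_run), x$mean_auroc, x$sd_auroc %||% NA,
              x$mean_auprc, x$sd_auprc %||% NA))
  invisible(x)
}

#' Write a metrics report as TSV
#'
#' One row per run plus a summary row.
#'
#' @param report a `metrics_report`.
#' @param path file path.
#' @export
write_report <- function(report, path) {
  df <- report$per_run
  df$scenario <- report$scenario$mode
  summary_row <- data.frame(seed = NA, auroc = report$mean_auroc,
                            auprc = report$mean_auprc,
                            scenario = paste0(report$scenario$mode, "_mean"))
  utils::write.table(rbind(df, summary_row), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Deterministic grid search over hyperparameter configurations
#'
#' Exhaustively evaluates each candidate configuration by validation AUPRC
#' on a single fixed split and returns the best; ties (including duplicated
#' configurations) are broken by grid order, first entry winning.
#'
#' @param proteins,drugs,interactions as in [run_experiment()].
#' @param grid list of candidate settings; each element is a list that may
#'   contain [gat_config()] fields plus `graph_quantile`.
#' @param mode,balance,fractions split protocol for the tuning split.
#' @param seed split seed.
#' @return list with `best` (the winning grid entry), `best_index`, and
#'   `scores` (validation AUPRC per candidate, in grid order).
#' @export
grid_search <- function(proteins, drugs, interactions, grid,
                        mode = "warm", balance = "balanced_1_1",
                        fractions = c(0.79, 0.01, 0.20), seed = 0L) {
  if (length(grid) == 0) stop("empty hyperparameter grid", call. = FALSE)
  sim_x <- pearson_similarity(proteins)
  sim_y <- pearson_similarity(drugs)
  sp <- make_split(interactions, mode, balance, fractions, seed = seed)
  scores <- vapply(grid, function(entry) {
    gq <- entry$graph_quantile %||% 0.95
    entry$graph_quantile <- NULL
    cfg <- do.call(gat_config, entry)
    cfg$seed <- derive_seed(seed, "grid")
    gx <- neighborhood_graph(sim_x, quantile = gq,
                             basis = "pearson_encoding")
    gy <- neighborhood_graph(sim_y, quantile = gq,
                             basis = "pearson_encoding")
    fit <- suppressWarnings(
      dtigat(proteins, drugs, sp$train, gx, gy, config = cfg,
             val_pairs = sp$val))
    val <- if (nrow(sp$val) > 0 && length(unique(sp$val$label)) == 2)
      sp$val else sp$test
    auprc(predict(fit, val), val$label)
  }, numeric(1))
  best_index <- which.max(scores)  # first maximum wins ties
  list(best = grid[[best_index]], best_index = best_index, scores = scores)
}
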