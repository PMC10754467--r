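# End-to-end pipeline: preprocess -> DEG -> fit -> drivers -> evaluate,
# with a resolved-config record written alongside every run.

#' Run the full inference pipeline
#'
#' Sequences the stages on one expression matrix and writes each stage's
#' output files plus a fully resolved JSON configuration record sufficient
#' to reproduce the run. Stages can be skipped; a stage whose upstream
#' artifact was skipped and not supplied raises an error naming the stage.
#'
#' Outputs in `out_dir`:
#' \describe{
#'   \item{deg_table.tsv}{gene, emd_score, p_value, q_value, selected}
#'   \item{labels.tsv}{cell_id, subtype, one loss column per subtype}
#'   \item{lambda.tsv}{gene, one weight column per subtype}
#'   \item{loss_trace.tsv}{epoch, loss}
#'   \item{drivers_subtypeK.tsv}{ranked gene, weight per subtype}
#'   \item{shared_drivers.txt}{genes in every subtype's driver set}
#'   \item{run_config.json}{resolved configuration + matrix digest}
#' }
#'
#' @param x An [expression_matrix()] (or a path to a dense TSV read with
#'   [read_dense_matrix()] defaults).
#' @param out_dir Output directory (created if needed).
#' @param n_subtypes Number of subtypes for the model stage.
#' @param groups Optional [cell_annotation()] (tumor/non-tumor), required
#'   for the `deg` stage.
#' @param stages Character vector drawn from
#'   `c("preprocess", "deg", "fit", "drivers", "evaluate")`.
#' @param preprocess A [preprocess_config()].
#' @param model A [model_config()] (built from `n_subtypes` when missing).
#' @param fraction Driver fraction for the drivers stage (default 0.05).
#' @param true_labels Optional labels for the evaluate stage (ARI of the
#'   fitted assignment against them).
#' @param verbose Log stage progress and durations to stderr.
#' @return Invisibly, a list with the stage results (`matrix`, `deg`,
#'   `fit`, `rankings`, `shared`, `evaluation`, `out_dir`).
#' @export
run_pipeline <- function(x, out_dir, n_subtypes = 2, groups = NULL,
                         stages = c("preprocess", "deg", "fit", "drivers",
                                    "evaluate"),
                         preprocess = preprocess_config(),
                         model = NULL, fraction = 0.05, true_labels = NULL,
                         verbose = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.character(x) && length(x) == 1L) x <- read_dense_matrix(x)
  validate_expression_matrix(x)
  if (is.null(model)) model <- model_config(n_subtypes = n_subtypes)
  if ("drivers" %in% stages && !("fit" %in% stages)) {
    stop_scdrivers("stage 'drivers' requires stage 'fit' in the same run")
  }
  if ("deg" %in% stages && is.null(groups)) {
    stop_scdrivers("stage 'deg' requires a tumor/non-tumor annotation")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message("[scdrivers] ", ...)
  timings <- list()
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    log_msg(stage, " done in ", timings[[stage]], "s")
    out
  }
  result <- list(out_dir = out_dir)

  if ("preprocess" %in% stages) {
    x <- timed("preprocess", {
      out <- filter_genes_by_prevalence(x, preprocess$prevalence_t)
      select_variable_genes(out, preprocess$variable_top_pct)
    })
  }
  if ("deg" %in% stages) {
    deg <- timed("deg", deg_test(x, groups, preprocess))
    write_gene_table(deg, file.path(out_dir, "deg_table.tsv"))
    result$deg <- deg
    keep <- deg$gene[deg$selected]
    if (length(keep) >= 2L) {
      x <- x[, keep]
      log_msg("restricting to ", length(keep), " selected DEGs")
    } else {
      log_msg("fewer than 2 DEGs selected; keeping all ", ncol(x), " genes")
    }
  }
  result$matrix <- x
  if ("fit" %in% stages) {
    fit <- timed("fit", csdgi_fit(x, model))
    labels_tab <- data.frame(cell_id = rownames(x),
                             subtype = fit$assignment$labels)
    loss_cols <- as.data.frame(fit$assignment$losses)
    names(loss_cols) <- paste0("loss_subtype", seq_len(ncol(loss_cols)))
    utils::write.table(cbind(labels_tab, loss_cols),
                       file.path(out_dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gene_table(data.frame(gene = fit$gene_names, fit$gene_weights),
                     file.path(out_dir, "lambda.tsv"))
    utils::write.table(
      data.frame(epoch = seq_along(fit$loss_trace), loss = fit$loss_trace),
      file.path(out_dir, "loss_trace.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    result$fit <- fit
  }
  if ("drivers" %in% stages) {
    rankings <- timed("drivers", driver_rankings(result$fit, fraction))
    for (k in seq_along(rankings)) {
      write_gene_table(rankings[[k]]$ranked,
                       file.path(out_dir, sprintf("drivers_subtype%d.tsv", k)))
    }
    shared <- if (length(rankings) >= 2L) shared_drivers(rankings) else
      character(0)
    writeLines(shared, file.path(out_dir, "shared_drivers.txt"))
    result$rankings <- rankings
    result$shared <- shared
  }
  if ("evaluate" %in% stages) {
    evaluation <- timed("evaluate", {
      out <- list()
      if (!is.null(result$fit) && !is.null(true_labels)) {
        out$ari <- adjusted_rand_index(true_labels, result$fit$assignment$labels)
      }
      if (!is.null(result$fit)) {
        out$cells_per_subtype <- as.integer(
          tabulate(result$fit$assignment$labels, model$n_subtypes))
        out$final_loss <- result$fit$final_loss
      }
      out
    })
    result$evaluation <- evaluation
  }

  run_config <- list(
    package_version = as.character(utils::packageVersion("scdrivers")),
    stages = stages,
    matrix_digest = list(n_cells = nrow(x), n_genes = ncol(x),
                         value_sum = sum(unclass(x))),
    preprocess = unclass(preprocess),
    model = unclass(model),
    fraction = fraction,
    timings_sec = timings,
    evaluation = result$evaluation)
  jsonlite::write_json(run_config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(result)
}
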