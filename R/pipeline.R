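#' Resolved configuration for a full biomarker-discovery run
#'
#' Bundles every tunable of the pipeline with a default, so a run is fully
#' described by one object: the expression transform, discretization
#' parameters, mRMR list length, classifier and cross-validation settings,
#' IFS depth, and the overlap-test universe. One master `seed` drives the
#' synthetic generator and the CV fold shuffle through independently
#' derived streams, so changing the CV behaviour never changes the data.
#'
#' @param n_select Length of the mRMR ranked list (top-K genes).
#' @param K IFS curve depth (defaults to `n_select`).
#' @param log1p_transform Apply `log1p` to counts before discretization and
#'   classification.
#' @param scheme,alpha,n_bins Discretization parameters ([discretize()]).
#' @param classifier A [classifier_spec()].
#' @param cv_kind,cv_k Cross-validation plan ([cv_scheme()]); the CV seed
#'   is derived from `seed`.
#' @param universe_size Overlap-test universe; `NULL` means "number of
#'   genes in the matrix at run time".
#' @param min_cells_expressed Optional mRMR pre-filter (see [mrmr_rank()]).
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n_select = 100L, K = n_select,
                       log1p_transform = TRUE,
                       scheme = "mean_sigma", alpha = 0.5, n_bins = 3L,
                       classifier = classifier_spec(),
                       cv_kind = "loocv", cv_k = 5L,
                       universe_size = NULL,
                       min_cells_expressed = 0L,
                       seed = 1L) {
  structure(list(n_select = as.integer(n_select), K = as.integer(K),
                 log1p_transform = isTRUE(log1p_transform),
                 scheme = scheme, alpha = alpha, n_bins = as.integer(n_bins),
                 classifier = classifier,
                 cv = cv_scheme(cv_kind, k = cv_k, seed = as.integer(seed) + 1L),
                 universe_size = universe_size,
                 min_cells_expressed = as.integer(min_cells_expressed),
                 seed = as.integer(seed)),
            class = "run_config")
}

config_snapshot <- function(config) {
  list(n_select = config$n_select, K = config$K,
       log1p_transform = config$log1p_transform,
       scheme = config$scheme, alpha = config$alpha, n_bins = config$n_bins,
       classifier = unclass(config$classifier),
       cv = unclass(config$cv),
       universe_size = config$universe_size,
       min_cells_expressed = config$min_cells_expressed,
       seed = config$seed)
}

#' Run the full biomarker-discovery pipeline
#'
#' Orchestrates rank -> IFS -> peak selection -> panel evaluation (and an
#' optional gene-set overlap test) on a labelled expression matrix, with
#' every stage's parameters taken from one [run_config()]. If `output_dir`
#' is given, the ranked list, IFS curve, panel, metrics report, resolved
#' config (YAML) and a log are written there; an IFS plot is attempted but
#' plotting failure never fails the run.
#'
#' The reported confusion matrix and metrics replay the IFS curve's stored
#' point at the selected k — the panel is never refit — so the report is
#' internally consistent by construction: the reported MCC equals
#' `mcc(reported confusion matrix)` exactly.
#'
#' @param m Genes x cells count/expression matrix (untransformed; the
#'   config's `log1p_transform` is applied here).
#' @param labels Per-cell binary labels.
#' @param config A [run_config()].
#' @param reference_gmt Optional GMT file of reference gene sets for the
#'   overlap test.
#' @param output_dir Optional directory for stage outputs.
#' @param verbose Log progress to stderr.
#' @return List with `ranking`, `curve`, `peak`, `panel`, `metrics`
#'   (confusion matrix + mcc/sensitivity/specificity/accuracy),
#'   `overlap` (or `NULL`), and `config`.
#' @export
run_pipeline <- function(m, labels, config = run_config(),
                         reference_gmt = NULL, output_dir = NULL,
                         verbose = FALSE) {
  say <- function(stage, fmt, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  validate_expression_matrix(m)
  say("input", "matrix %d genes x %d cells; classes: %s",
      nrow(m), ncol(m), paste(names(table(labels)), table(labels),
                              sep = "=", collapse = ", "))
  positive <- as_positive(labels)
  m_cls <- if (config$log1p_transform) log1p(m) else m

  ranking <- stage("rank", mrmr_rank(
    m, labels, n_select = config$n_select, scheme = config$scheme,
    alpha = config$alpha, n_bins = config$n_bins,
    log1p_transform = config$log1p_transform,
    min_cells_expressed = config$min_cells_expressed))
  say("rank", "ranked %d of %d genes; top gene %s",
      nrow(ranking), attr(ranking, "n_total_genes"), ranking$gene_id[1L])

  curve <- stage("ifs", ifs_curve(
    m_cls, labels, ranking, K = config$K, spec = config$classifier,
    cv = config$cv, positive = positive))
  peak <- select_peak(curve)
  say("ifs", "peak MCC %.4f at k = %d", peak$peak_mcc, peak$k)

  point <- curve[curve$k == peak$k, , drop = FALSE]
  panel <- build_panel(ranking, peak$k, curve_point = point,
                       seed = config$seed, config = config_snapshot(config))
  cm <- confusion_counts(TP = point$TP, FP = point$FP, TN = point$TN,
                         FN = point$FN, positive = positive)
  metrics <- list(confusion = cm, mcc = mcc(cm),
                  sensitivity = sensitivity(cm),
                  specificity = specificity(cm),
                  accuracy = accuracy(cm))

  overlap <- NULL
  if (!is.null(reference_gmt)) {
    universe <- if (is.null(config$universe_size)) nrow(m) else config$universe_size
    overlap <- stage("overlap", overlap_report(
      gene_set("panel", panel$gene_ids), reference_gmt, universe))
    say("overlap", "%d reference sets tested against universe %d",
        nrow(overlap), universe)
  }

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- config_snapshot(config)
    write_ranked_list(ranking, file.path(output_dir, "ranked_genes.tsv"),
                      seed = config$seed, config = NULL)
    curve_df <- as.data.frame(curve)
    utils::write.table(curve_df, file.path(output_dir, "ifs_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_panel(panel, file.path(output_dir, "panel.tsv"))
    metr_df <- data.frame(
      metric = c("k", "TP", "FP", "TN", "FN", "mcc", "sensitivity",
                 "specificity", "accuracy"),
      value = c(peak$k, cm$TP, cm$FP, cm$TN, cm$FN, metrics$mcc,
                metrics$sensitivity, metrics$specificity, metrics$accuracy))
    utils::write.table(metr_df, file.path(output_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(cfg, file.path(output_dir, "config.yaml"))
    if (!is.null(overlap)) {
      utils::write.table(overlap, file.path(output_dir, "overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    tryCatch({
      grDevices::png(file.path(output_dir, "ifs_curve.png"),
                     width = 900, height = 600, res = 120)
      plot_ifs_curve(curve)
      grDevices::dev.off()
    }, error = function(e) {
      say("plot", "skipped (%s)", conditionMessage(e))
    })
  }

  list(ranking = ranking, curve = curve, peak = peak, panel = panel,
       metrics = metrics, overlap = overlap, config = config)
}
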