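#' Incremental feature selection curve over nested top-k gene sets
#'
#' Evaluates the top-k prefixes of an mRMR ranking, for k = 1..K, each with
#' a freshly cross-validated classifier, and records the confusion matrix
#' and Matthews correlation coefficient at every k. The gene set at point k
#' is exactly the set at k - 1 plus the rank-k gene (nested prefixes), and
#' evaluations are independent across k — no model state is carried between
#' prefixes.
#'
#' @param m Genes x cells expression matrix (classifier-ready values).
#' @param labels Per-cell binary labels.
#' @param ranking A `mrmr_ranking` from [mrmr_rank()] (or read back with
#'   [read_ranked_list()]).
#' @param K Largest prefix size to evaluate (default 100).
#' @param spec A [classifier_spec()].
#' @param cv A [cv_scheme()].
#' @param positive Name of the positive class.
#' @param verbose Print one line per k.
#' @return An `ifs_curve` data frame with columns `k`, `mcc`, `TP`, `FP`,
#'   `TN`, `FN` and attributes `cv`, `classifier`, `positive`,
#'   `gene_ids` (the rank-ordered genes the prefixes are drawn from).
#' @export
ifs_curve <- function(m, labels, ranking, K = 100L,
                      spec = classifier_spec(), cv = cv_scheme("loocv"),
                      positive = as_positive(labels), verbose = FALSE) {
  K <- as.integer(K)
  if (K > nrow(ranking)) {
    stop(sprintf("K (%d) exceeds the ranked list length (%d)",
                 K, nrow(ranking)), call. = FALSE)
  }
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  genes <- ranking$gene_id[seq_len(K)]
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    pred <- cross_validated_predictions(
      m, labels, genes = genes[seq_len(k)], spec = spec, cv = cv,
      positive = positive)
    cm <- confusion(pred, labels, positive = positive)
    rows[[k]] <- data.frame(k = k, mcc = mcc(cm), TP = cm$TP, FP = cm$FP,
                            TN = cm$TN, FN = cm$FN)
    if (verbose) message(sprintf("IFS k=%d MCC=%.4f", k, rows[[k]]$mcc))
  }
  structure(do.call(rbind, rows),
            cv = cv, classifier = spec, positive = positive,
            gene_ids = genes,
            class = c("ifs_curve", "data.frame"))
}

#' Locate the MCC-optimal point of an IFS curve
#'
#' Returns the smallest k attaining the maximum MCC (parsimony tie-break:
#' among equally good panels, prefer the smaller one).
#'
#' @param curve An `ifs_curve`.
#' @return List with `k` and `peak_mcc`.
#' @examples
#' curve <- data.frame(k = 1:3, mcc = c(0.5, 0.9, 0.9))
#' select_peak(curve)  # k = 2, peak 0.9
#' @export
select_peak <- function(curve) {
  if (!nrow(curve)) stop("IFS curve is empty", call. = FALSE)
  peak <- max(curve$mcc)
  k_star <- curve$k[which(curve$mcc == peak)[1L]]
  list(k = k_star, peak_mcc = peak)
}

#' Assemble a biomarker panel from a ranking and a panel size
#'
#' The panel is the top-k prefix of the mRMR ranking, in rank order, with
#' provenance (peak MCC, confusion matrix at k, seed, config snapshot)
#' attached.
#'
#' @param ranking A `mrmr_ranking`.
#' @param k Panel size (positive, at most the ranking length).
#' @param curve_point Optional single-row slice of an `ifs_curve` at this k,
#'   stored as the panel's evaluation record.
#' @param seed,config Optional provenance.
#' @return A `biomarker_panel` list: `gene_ids`, `k`, `peak_mcc`,
#'   `curve_point`, `provenance`.
#' @export
build_panel <- function(ranking, k, curve_point = NULL, seed = NA,
                        config = NULL) {
  k <- as.integer(k)
  if (k <= 0L) stop("panel size k must be positive", call. = FALSE)
  if (k > nrow(ranking)) {
    stop(sprintf("k (%d) exceeds the ranked list length (%d)", k, nrow(ranking)),
         call. = FALSE)
  }
  structure(list(
    gene_ids = ranking$gene_id[seq_len(k)],
    k = k,
    peak_mcc = if (is.null(curve_point)) NA_real_ else curve_point$mcc,
    curve_point = curve_point,
    provenance = list(seed = seed, config = config)),
    class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker panel: %d genes, peak MCC %.4f\n", x$k, x$peak_mcc))
  cat(paste(strwrap(paste(x$gene_ids, collapse = ", "), 70), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Plot an IFS curve (panel size vs cross-validated MCC)
#'
#' Draws k against MCC and marks the selected peak. Intended as an optional
#' diagnostic output; failures to open a graphics device should be caught
#' by the caller and never fail a run.
#'
#' @param curve An `ifs_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_ifs_curve <- function(curve, ...) {
  peak <- select_peak(curve)
  graphics::plot(curve$k, curve$mcc, type = "b", pch = 16, cex = 0.6,
                 xlab = "number of top-ranked genes (k)",
                 ylab = "cross-validated MCC", ...)
  graphics::abline(v = peak$k, lty = 2, col = "grey40")
  graphics::points(peak$k, peak$peak_mcc, col = "red", pch = 19)
  graphics::mtext(sprintf("peak MCC %.3f at k = %d", peak$peak_mcc, peak$k),
                  side = 3, line = 0.2, cex = 0.8)
  invisible(curve)
}
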