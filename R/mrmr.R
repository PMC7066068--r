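# Binary tissue labels: two levels, first = negative, second = positive.
as_binary_labels <- function(labels, positive = "tumor") {
  lv <- unique(as.character(labels))
  if (length(lv) < 2L) {
    stop("labels contain a single class ('", lv,
         "'); both classes are required", call. = FALSE)
  }
  if (length(lv) > 2L) {
    stop("labels must be binary; found levels: ", paste(lv, collapse = ", "),
         call. = FALSE)
  }
  if (!positive %in% lv) {
    stop("positive class '", positive, "' not found among labels (",
         paste(lv, collapse = ", "), ")", call. = FALSE)
  }
  factor(as.character(labels), levels = c(setdiff(lv, positive), positive))
}

#' Per-gene relevance to the tissue label
#'
#' Relevance of a gene is the plug-in mutual information between its
#' discretized expression and the binary tissue label (the label is already
#' categorical and bypasses discretization). A constant gene has zero
#' mutual information with everything by construction.
#'
#' @param m Genes x cells expression matrix.
#' @param labels Per-cell binary labels (length = `ncol(m)`).
#' @param scheme,alpha,n_bins Discretization parameters, see [discretize()].
#' @param log1p_transform Apply `log1p` to expression before binning.
#' @return Named numeric vector of relevance values (nats), one per gene.
#' @export
relevance_scores <- function(m, labels, scheme = "mean_sigma", alpha = 0.5,
                             n_bins = 3L, log1p_transform = FALSE) {
  y <- as_binary_labels(labels, positive = as_positive(labels))
  codes <- discretize_matrix(m, scheme, alpha, n_bins, log1p_transform)
  yc <- as.integer(y)
  nb <- attr(codes, "n_bins")
  d <- vapply(seq_len(nrow(m)), function(i) {
    mi_from_codes(codes[i, ], yc, nb, 2L)
  }, numeric(1))
  stats::setNames(d, rownames(m))
}

# Pick a positive-class name without forcing callers to say it: prefer
# "tumor" if present, else the lexicographically larger level (the choice
# does not affect mutual information, only confusion-matrix orientation).
as_positive <- function(labels) {
  lv <- unique(as.character(labels))
  if ("tumor" %in% lv) "tumor" else sort(lv)[length(lv)]
}

#' Symmetric pairwise mutual-information table for a gene subset
#'
#' Computes the gene x gene plug-in MI matrix over discretized expression.
#' The diagonal holds per-gene plug-in entropies (MI of a gene with itself).
#'
#' @inheritParams relevance_scores
#' @param genes Gene identifiers (subset of `rownames(m)`).
#' @return Symmetric numeric matrix with `genes` as dimnames.
#' @export
pairwise_mi <- function(m, genes = rownames(m), scheme = "mean_sigma",
                        alpha = 0.5, n_bins = 3L, log1p_transform = FALSE) {
  if (!length(genes)) stop("gene subset must be non-empty", call. = FALSE)
  stopifnot(all(genes %in% rownames(m)))
  codes <- discretize_matrix(m[genes, , drop = FALSE], scheme, alpha, n_bins,
                             log1p_transform)
  nb <- attr(codes, "n_bins")
  k <- length(genes)
  out <- matrix(0, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- mi_from_codes(codes[i, ], codes[j, ], nb, nb)
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Greedy mRMR ranking of genes
#'
#' Ranks genes by the minimum-redundancy maximum-relevance criterion in its
#' difference (MID) form. Writing \eqn{D(g) = I(g, t)} for the relevance of
#' gene \eqn{g} to the tissue label \eqn{t} and
#' \eqn{R(g) = \frac{1}{m}\sum_{g_i \in \Omega_s} I(g, g_i)} for its mean
#' mutual information with the \eqn{m} already-selected genes
#' \eqn{\Omega_s}, each greedy step moves the candidate maximizing
#' \eqn{D(g) - R(g)} into the selected set. The first pick has no selected
#' genes, so its redundancy is defined as 0 and the step reduces to pure
#' maximum relevance.
#'
#' Ties at any step are broken by higher relevance, then lexicographically
#' smaller gene identifier, making the ranking deterministic across
#' platforms. Scores are compared at 12 significant digits so that
#' mathematically equal scores reached through different summation orders
#' are treated as the ties they are. Pairwise MI is computed lazily
#' against selected genes only
#' (`n_select * n_genes` evaluations), never as a full gene x gene table.
#'
#' @inheritParams relevance_scores
#' @param n_select Number of genes to rank (default 100).
#' @param min_cells_expressed Optional pre-filter: drop genes expressed
#'   (value > 0) in fewer than this many cells before ranking (default 0,
#'   i.e. off).
#' @return A `mrmr_ranking` data frame with columns `rank`, `gene_id`,
#'   `relevance`, `redundancy`, `mrmr_score` and attribute `n_total_genes`.
#' @export
mrmr_rank <- function(m, labels, n_select = 100L, scheme = "mean_sigma",
                      alpha = 0.5, n_bins = 3L, log1p_transform = FALSE,
                      min_cells_expressed = 0L) {
  y <- as_binary_labels(labels, positive = as_positive(labels))
  if (min_cells_expressed > 0L) {
    keep <- rowSums(m > 0) >= min_cells_expressed
    m <- m[keep, , drop = FALSE]
  }
  n_genes <- nrow(m)
  n_select <- as.integer(n_select)
  if (n_select < 1L) stop("n_select must be >= 1", call. = FALSE)
  if (n_select > n_genes) {
    stop(sprintf("n_select (%d) exceeds the number of genes (%d)",
                 n_select, n_genes), call. = FALSE)
  }
  codes <- discretize_matrix(m, scheme, alpha, n_bins, log1p_transform)
  nb <- attr(codes, "n_bins")
  yc <- as.integer(y)
  ids <- rownames(m)
  D <- vapply(seq_len(n_genes),
              function(i) mi_from_codes(codes[i, ], yc, nb, 2L), numeric(1))

  selected <- integer(0)
  remaining <- seq_len(n_genes)
  red_sum <- numeric(n_genes)   # running sum of MI with selected genes
  out_rank <- integer(n_select)
  out_rel <- numeric(n_select)
  out_red <- numeric(n_select)

  for (step in seq_len(n_select)) {
    m_sel <- length(selected)
    red <- if (m_sel == 0L) numeric(length(remaining)) else
      red_sum[remaining] / m_sel
    score <- D[remaining] - red
    # max score; ties -> max relevance; ties -> lexicographic gene id.
    # 12-significant-digit comparison so equal scores computed in different
    # summation orders still tie deterministically.
    best <- remaining[order(-signif(score, 12), -signif(D[remaining], 12),
                            ids[remaining])[1L]]
    bi <- match(best, remaining)
    out_rank[step] <- best
    out_rel[step] <- D[best]
    out_red[step] <- red[bi]
    selected <- c(selected, best)
    remaining <- remaining[-bi]
    if (length(remaining) && step < n_select) {
      bc <- codes[best, ]
      for (g in remaining) {
        red_sum[g] <- red_sum[g] + mi_from_codes(codes[g, ], bc, nb, nb)
      }
    }
  }

  structure(
    data.frame(rank = seq_len(n_select),
               gene_id = ids[out_rank],
               relevance = out_rel,
               redundancy = out_red,
               mrmr_score = out_rel - out_red,
               stringsAsFactors = FALSE),
    n_total_genes = n_genes,
    class = c("mrmr_ranking", "data.frame"))
}
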