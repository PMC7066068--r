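#' Specification for a synthetic labelled scRNA-seq data set
#'
#' Describes a two-class (tumor vs periphery) count matrix with known
#' ground truth: a minority of class-informative genes, groups of mutually
#' redundant genes (jittered copies of informative templates), bulk noise
#' genes, negative-binomial overdispersion, and dropout zeros. The class
#' imbalance default mirrors a roughly 2:1 tumor-to-periphery design,
#' scaled down to desktop size.
#'
#' Informative genes have class-dependent means `base_mean * 2^(+lfc/2)`
#' and `base_mean * 2^(-lfc/2)` (direction alternating across genes so both
#' up- and down-regulated markers occur); noise genes have mean `base_mean`
#' in both classes. `dispersion` is the negative-binomial overdispersion
#' \eqn{\alpha} in \eqn{Var = \mu + \alpha \mu^2} (i.e. `size = 1/alpha`).
#'
#' @param n_pos,n_neg Cells in the positive (tumor) / negative (periphery)
#'   class.
#' @param n_genes Total genes.
#' @param n_informative Class-informative genes.
#' @param n_redundant_groups Number of informative templates that get
#'   redundant copies.
#' @param group_size Copies per template.
#' @param log2_fold_change Effect size between class means (log2 units).
#' @param base_mean Baseline negative-binomial mean.
#' @param dispersion Overdispersion alpha (>= 0; 0 degenerates to Poisson).
#' @param dropout_prob Independent Bernoulli zeroing probability in \[0, 1\].
#' @param seed Integer RNG seed; generation is fully reproducible from it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_pos = 200L, n_neg = 120L, n_genes = 500L,
                           n_informative = 20L, n_redundant_groups = 5L,
                           group_size = 3L, log2_fold_change = 2,
                           base_mean = 5, dispersion = 0.5,
                           dropout_prob = 0.3, seed = 20200305L) {
  spec <- list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
               n_genes = as.integer(n_genes),
               n_informative = as.integer(n_informative),
               n_redundant_groups = as.integer(n_redundant_groups),
               group_size = as.integer(group_size),
               log2_fold_change = log2_fold_change,
               base_mean = base_mean, dispersion = dispersion,
               dropout_prob = dropout_prob, seed = as.integer(seed))
  with(spec, {
    if (n_pos < 1L || n_neg < 1L || n_genes < 1L)
      stop("cell and gene counts must be positive", call. = FALSE)
    if (n_informative < 0L || n_redundant_groups < 0L || group_size < 0L)
      stop("gene group counts must be non-negative", call. = FALSE)
    if (n_informative + n_redundant_groups * group_size > n_genes)
      stop("n_informative + n_redundant_groups * group_size exceeds n_genes",
           call. = FALSE)
    if (n_redundant_groups > n_informative)
      stop("more redundant groups than informative templates", call. = FALSE)
    if (dropout_prob < 0 || dropout_prob > 1)
      stop("dropout_prob must be in [0, 1]", call. = FALSE)
    if (base_mean <= 0 || dispersion < 0)
      stop("base_mean must be > 0 and dispersion >= 0", call. = FALSE)
  })
  structure(spec, class = "synthetic_spec")
}

#' The frozen parameter-recovery scenario
#'
#' Returns the fixed synthetic scenario used by the package's end-to-end
#' validation: 200 tumor + 120 periphery cells, 500 genes of which 20 are
#' informative (log2 fold change 2), 5 redundant groups of 3 jittered
#' copies, base mean 5, overdispersion 0.5, dropout 0.3, seed 20200305.
#' Frozen so downstream recovery checks are stable.
#'
#' @return A [synthetic_spec()].
#' @export
default_recovery_scenario <- function() synthetic_spec()

#' Generate a labelled synthetic expression matrix with known ground truth
#'
#' Counts are drawn per gene and cell from a negative binomial with the
#' class-dependent means described in [synthetic_spec()]. Each redundant
#' copy resamples its template's (pre-dropout) counts through a Poisson
#' jitter — `rpois(lambda = template count)` — so copies are highly but not
#' perfectly correlated with their template after discretization. Dropout
#' is applied last as independent Bernoulli zeroing of every entry.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (genes x cells counts), `labels` (named
#'   character vector, `"tumor"`/`"periphery"`), and `truth` — a list with
#'   `informative_gene_ids`, `redundant_group_map` (template id -> copy
#'   ids), `noise_gene_ids`, and `expected_class_means` (per informative
#'   gene, pre-dropout class means).
#' @export
generate_synthetic <- function(spec = default_recovery_scenario()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  n_cells <- spec$n_pos + spec$n_neg
  labels <- c(rep("tumor", spec$n_pos), rep("periphery", spec$n_neg))
  cell_ids <- sprintf("CELL_%04d", seq_len(n_cells))
  names(labels) <- cell_ids
  is_pos <- labels == "tumor"

  n_copies <- spec$n_redundant_groups * spec$group_size
  n_noise <- spec$n_genes - spec$n_informative - n_copies
  info_ids <- if (spec$n_informative) sprintf("INFO_%03d", seq_len(spec$n_informative)) else character(0)
  noise_ids <- if (n_noise) sprintf("NOISE_%03d", seq_len(n_noise)) else character(0)

  size <- if (spec$dispersion > 0) 1 / spec$dispersion else Inf
  draw_nb <- function(n, mu) {
    if (is.finite(size)) stats::rnbinom(n, mu = mu, size = size)
    else stats::rpois(n, lambda = mu)
  }

  fc <- 2^(spec$log2_fold_change / 2)
  mat <- matrix(0, nrow = spec$n_genes, ncol = n_cells)
  ids <- character(spec$n_genes)
  expected <- list()
  row <- 0L

  for (i in seq_len(spec$n_informative)) {
    up_in_tumor <- i %% 2L == 1L   # alternate direction
    mu_pos <- if (up_in_tumor) spec$base_mean * fc else spec$base_mean / fc
    mu_neg <- if (up_in_tumor) spec$base_mean / fc else spec$base_mean * fc
    row <- row + 1L
    mat[row, is_pos] <- draw_nb(spec$n_pos, mu_pos)
    mat[row, !is_pos] <- draw_nb(spec$n_neg, mu_neg)
    ids[row] <- info_ids[i]
    expected[[info_ids[i]]] <- c(tumor = mu_pos, periphery = mu_neg)
  }

  group_map <- list()
  if (spec$n_redundant_groups > 0L) {
    templates <- info_ids[seq_len(spec$n_redundant_groups)]
    for (g in seq_len(spec$n_redundant_groups)) {
      tmpl_row <- match(templates[g], ids)
      copies <- sprintf("RED_%s_COPY%d", templates[g], seq_len(spec$group_size))
      for (c_id in copies) {
        row <- row + 1L
        mat[row, ] <- stats::rpois(n_cells, lambda = mat[tmpl_row, ])
        ids[row] <- c_id
      }
      group_map[[templates[g]]] <- copies
    }
  }

  for (j in seq_len(n_noise)) {
    row <- row + 1L
    mat[row, ] <- draw_nb(n_cells, spec$base_mean)
    ids[row] <- noise_ids[j]
  }

  if (spec$dropout_prob > 0) {
    keep <- stats::rbinom(length(mat), 1L, 1 - spec$dropout_prob)
    mat <- mat * keep
  }
  dimnames(mat) <- list(ids, cell_ids)

  list(matrix = mat,
       labels = labels,
       truth = list(informative_gene_ids = info_ids,
                    redundant_group_map = group_map,
                    noise_gene_ids = noise_ids,
                    expected_class_means = expected))
}
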