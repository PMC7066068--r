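#' Discretize a continuous expression vector
#'
#' mRMR scores are mutual informations between discrete variables, so each
#' gene's continuous expression is binned first. Two schemes are offered:
#'
#' * `mean_sigma` (default, 3 bins): the convention of the original mRMR
#'   literature. Values below `mean - alpha * sd` go to bin 0, values above
#'   `mean + alpha * sd` to bin 2, the rest to bin 1. `sd` is the sample
#'   (n - 1) standard deviation. A constant vector has `sd = 0` and maps
#'   entirely to the middle bin.
#' * `equal_frequency`: near-equal bin occupancy (sizes differ by at most
#'   one), ties resolved by value order then original index. A constant
#'   vector collapses to a single bin with a warning.
#'
#' @param values Finite numeric vector.
#' @param scheme `"mean_sigma"` or `"equal_frequency"`.
#' @param alpha Positive band half-width in sd units (`mean_sigma` only).
#' @param n_bins Number of bins; must be 3 for `mean_sigma`, >= 2 otherwise.
#' @return Integer vector of bin indices in `[0, n_bins)`, with attributes
#'   `n_bins` and `scheme`, class `"discretized"`.
#' @examples
#' discretize(c(0, 0, 0, 10))           # 10 lands in the top bin
#' discretize(1:10, "equal_frequency", n_bins = 2)  # median split
#' @export
discretize <- function(values,
                       scheme = c("mean_sigma", "equal_frequency"),
                       alpha = 0.5, n_bins = 3L) {
  scheme <- match.arg(scheme)
  if (!length(values) || !all(is.finite(values))) {
    stop("values must be a non-empty finite numeric vector", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  n <- length(values)
  if (scheme == "mean_sigma") {
    if (n_bins != 3L) {
      stop("mean_sigma discretization is defined for n_bins = 3", call. = FALSE)
    }
    if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0", call. = FALSE)
    mu <- mean(values)
    s <- if (n > 1L) stats::sd(values) else 0
    bins <- integer(n) + 1L
    bins[values < mu - alpha * s] <- 0L
    bins[values > mu + alpha * s] <- 2L
  } else {
    if (length(unique(values)) == 1L) {
      warning("constant vector under equal_frequency: single-bin output",
              call. = FALSE)
      bins <- integer(n)
    } else {
      # stable order: by value, ties by original index
      ord <- order(values, seq_len(n))
      sizes <- rep(n %/% n_bins, n_bins)
      extra <- n %% n_bins
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      bins <- integer(n)
      bins[ord] <- rep(seq_len(n_bins) - 1L, times = sizes)
    }
  }
  structure(bins, n_bins = n_bins, scheme = scheme, class = "discretized")
}

# Internal fast path: MI in nats from 1-based integer bin codes with known
# alphabet sizes. Plug-in estimator; 0 * log(0) := 0 by construction.
mi_from_codes <- function(xc, yc, nx, ny) {
  n <- length(xc)
  joint <- tabulate((xc - 1L) * ny + yc, nbins = nx * ny) / n
  px <- tabulate(xc, nbins = nx) / n
  py <- tabulate(yc, nbins = ny) / n
  pxy_ind <- rep(px, each = ny) * rep.int(py, nx)
  nz <- joint > 0
  max(0, sum(joint[nz] * log(joint[nz] / pxy_ind[nz])))
}

as_codes <- function(x) {
  if (inherits(x, "discretized")) {
    list(codes = as.integer(unclass(x)) + 1L, n = attr(x, "n_bins"))
  } else {
    f <- as.integer(factor(x))
    list(codes = f, n = max(f))
  }
}

#' Plug-in mutual information between two discrete vectors
#'
#' Estimates \eqn{I(X;Y) = \sum_{a,b} p(a,b) \ln[p(a,b) / (p(a) p(b))]}
#' in nats from the empirical joint distribution of two equal-length
#' categorical vectors (bin indices, factors, or labels), with the usual
#' convention \eqn{0 \ln 0 = 0}. The estimate is non-negative and symmetric
#' in its arguments; `mutual_information(x, x)` equals the plug-in entropy
#' of `x`.
#'
#' @param x,y Equal-length discrete vectors ([discretize()] output, factors,
#'   integer codes, or character labels).
#' @return Mutual information in nats (scalar, >= 0).
#' @examples
#' mutual_information(c(0, 1, 0, 1), c(0, 1, 0, 1))  # = log(2)
#' mutual_information(c(0, 0, 1, 1), c(0, 1, 0, 1))  # exactly independent: 0
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: x has %d elements, y has %d",
                 length(x), length(y)), call. = FALSE)
  }
  if (!length(x)) stop("at least one sample is required", call. = FALSE)
  cx <- as_codes(x)
  cy <- as_codes(y)
  mi_from_codes(cx$codes, cy$codes, cx$n, cy$n)
}

#' Plug-in Shannon entropy of a discrete vector (nats)
#'
#' @param x Discrete vector as in [mutual_information()].
#' @return Entropy in nats.
#' @export
plugin_entropy <- function(x) {
  cx <- as_codes(x)
  p <- tabulate(cx$codes, nbins = cx$n) / length(cx$codes)
  p <- p[p > 0]
  -sum(p * log(p))
}

# Discretize every gene (row) of an expression matrix into a genes x cells
# integer code matrix (1-based), applying the optional log1p transform first.
discretize_matrix <- function(m, scheme = "mean_sigma", alpha = 0.5,
                              n_bins = 3L, log1p_transform = FALSE) {
  if (log1p_transform) m <- log1p(m)
  codes <- matrix(1L, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    b <- suppressWarnings(
      discretize(m[i, ], scheme = scheme, alpha = alpha, n_bins = n_bins))
    codes[i, ] <- as.integer(unclass(b)) + 1L
  }
  attr(codes, "n_bins") <- as.integer(n_bins)
  codes
}
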