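# Independent brute-force oracles. These deliberately share no code with the
# package: MI by an explicit triple loop over bin-value pairs, mRMR by a
# greedy re-scan that recomputes every term from scratch, hypergeometric
# tails by exhaustive enumeration of combinations.

brute_mi <- function(x, y) {
  x <- as.vector(unclass(x)); y <- as.vector(unclass(y))
  n <- length(x)
  vx <- unique(x); vy <- unique(y)
  total <- 0
  for (a in vx) {
    for (b in vy) {
      pab <- sum(x == a & y == b) / n
      if (pab > 0) {
        pa <- sum(x == a) / n
        pb <- sum(y == b) / n
        total <- total + pab * log(pab / (pa * pb))
      }
    }
  }
  total
}

brute_entropy <- function(x) brute_mi(x, x)

# Greedy mRMR re-scanning all candidates each step, recomputing every MI
# with brute_mi. Tie rule (as documented for mrmr_rank): scores compared at
# 12 significant digits; ties -> max relevance (same comparison) -> smaller
# gene id. bins: genes x cells integer matrix (already discretized);
# ylab: label codes.
brute_mrmr <- function(bins, ylab, n_select = nrow(bins)) {
  ids <- rownames(bins)
  D <- sapply(seq_len(nrow(bins)), function(i) brute_mi(bins[i, ], ylab))
  selected <- character(0)
  remaining <- ids
  out <- character(n_select)
  for (step in seq_len(n_select)) {
    best <- NA; best_key <- NULL
    for (g in remaining) {
      gi <- match(g, ids)
      red <- if (!length(selected)) 0 else
        mean(sapply(selected, function(s) brute_mi(bins[gi, ], bins[match(s, ids), ])))
      key <- list(score = signif(D[gi] - red, 12), rel = signif(D[gi], 12), id = g)
      better <- is.null(best_key) ||
        key$score > best_key$score ||
        (key$score == best_key$score &&
           (key$rel > best_key$rel ||
              (key$rel == best_key$rel && key$id < best_key$id)))
      if (better) { best <- g; best_key <- key }
    }
    out[step] <- best
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  out
}

# P(X >= obs) for the overlap of a size-k panel and a size-m reference in a
# size-N universe, by enumerating all choose(N, k) panels.
brute_hyper_tail <- function(obs, m, N, k) {
  panels <- utils::combn(N, k)
  ref <- seq_len(m)
  hits <- apply(panels, 2, function(p) sum(p %in% ref) >= obs)
  mean(hits)
}

rand_discrete <- function(n, n_vals = 3L) sample.int(n_vals, n, replace = TRUE) - 1L
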