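# Shared fixtures. The frozen recovery scenario is expensive (LOOCV over
# hundreds of cells), so its artifacts are computed once per test session
# and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

recovery_data <- function() memo("recovery_data", {
  generate_synthetic(default_recovery_scenario())
})

recovery_ranking <- function() memo("recovery_ranking", {
  d <- recovery_data()
  mrmr_rank(d$matrix, d$labels, n_select = 100, log1p_transform = TRUE)
})

recovery_curve <- function() memo("recovery_curve", {
  d <- recovery_data()
  ifs_curve(log1p(d$matrix), d$labels, recovery_ranking(), K = 40,
            spec = classifier_spec(), cv = cv_scheme("loocv"))
})

# Two well-separated Gaussian classes: 2 informative features, n per class,
# class means +/- delta/2 on both features, unit sd.
separated_gaussians <- function(n_per_class = 20, delta = 6, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  m <- rbind(
    f1 = c(rnorm(n_per_class, delta / 2), rnorm(n_per_class, -delta / 2)),
    f2 = c(rnorm(n_per_class, delta / 2), rnorm(n_per_class, -delta / 2)))
  colnames(m) <- sprintf("c%02d", seq_len(n))
  labels <- stats::setNames(rep(c("tumor", "periphery"), each = n_per_class),
                            colnames(m))
  list(matrix = m, labels = labels)
}

# Tiny labelled count matrix for IO round-trips.
tiny_matrix <- function() {
  m <- matrix(c(0, 2, 5, 1, 0, 3), nrow = 3,
              dimnames = list(c("GENE_A", "GENE_B", "GENE_C"), c("c1", "c2")))
  storage.mode(m) <- "double"
  m
}
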