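make_matrix <- function(values, genes, cells = NULL) {
  m <- do.call(rbind, values)
  rownames(m) <- genes
  colnames(m) <- if (is.null(cells)) sprintf("c%02d", seq_len(ncol(m))) else cells
  storage.mode(m) <- "double"
  m
}

test_that("relevance equals per-gene MI with the label; perfect marker gets label entropy", {
  n <- 20
  labels <- rep(c("tumor", "periphery"), each = n / 2)
  # a marker whose discretized vector separates the classes exactly
  marker <- c(rep(100, n / 2), rep(0, n / 2))
  flat <- rep(4, n)
  set.seed(11)
  noise <- replicate(3, rpois(n, 4), simplify = FALSE)
  m <- make_matrix(c(list(marker, flat), noise),
                   c("MARK", "FLAT", "N1", "N2", "N3"))
  d <- relevance_scores(m, labels)
  expect_equal(unname(d["MARK"]), plugin_entropy(labels), tolerance = 1e-12)
  expect_identical(unname(d["FLAT"]), 0)
  # element-wise agreement with direct MI calls
  for (g in rownames(m)) {
    expect_equal(unname(d[g]),
                 brute_mi(discretize(m[g, ]), as.integer(factor(labels))),
                 tolerance = 1e-12)
  }
  expect_error(relevance_scores(m, rep("tumor", n)), "single class")
})

test_that("pairwise MI table is symmetric with entropies on the diagonal", {
  set.seed(12)
  m <- make_matrix(replicate(3, rpois(30, 5), simplify = FALSE),
                   c("A", "B", "C"))
  m <- rbind(m, DUP = m["A", ])
  tab <- pairwise_mi(m)
  expect_equal(tab, t(tab))
  expect_true(all(tab >= 0))
  for (g in rownames(m)) {
    expect_equal(tab[g, g], plugin_entropy(discretize(m[g, ])),
                 tolerance = 1e-12)
  }
  # identical genes share their entropy as off-diagonal MI
  expect_equal(tab["A", "DUP"], tab["A", "A"], tolerance = 1e-12)
  # values identical to direct calls
  expect_equal(tab["B", "C"],
               mutual_information(discretize(m["B", ]), discretize(m["C", ])),
               tolerance = 1e-14)
})

test_that("a dominant marker ranks first and n_select is validated", {
  n <- 24
  labels <- rep(c("tumor", "periphery"), each = n / 2)
  set.seed(13)
  m <- make_matrix(c(list(c(rep(50, n / 2), rep(0, n / 2))),
                     replicate(6, rpois(n, 5), simplify = FALSE)),
                   c("MARK", sprintf("N%d", 1:6)))
  r <- mrmr_rank(m, labels, n_select = 7)
  expect_identical(r$gene_id[1], "MARK")
  expect_identical(r$redundancy[1], 0)
  expect_equal(r$mrmr_score, r$relevance - r$redundancy, tolerance = 1e-12)
  expect_error(mrmr_rank(m, labels, n_select = 8), "8.*7|exceeds")
})

test_that("an exact duplicate of the top marker is pushed below a weaker marker", {
  # A and B are identical strong-but-imperfect markers (14/16 cells agree
  # with the label); C is a weaker marker only partially redundant with A.
  # After A is picked, the duplicate scores D(B) - MI(B, A) = D(A) - H(A)
  # (deeply negative), so C wins step 2 whenever its penalized score beats
  # that - the redundancy penalty in action.
  labels <- rep(c("tumor", "periphery"), each = 8)
  a <- c(rep(60, 8), 60, 60, rep(0, 6))
  cc <- c(rep(60, 6), 0, 0, rep(0, 5), 60, 60, 60)  # 11/16 agreement
  m <- make_matrix(list(a, a, cc), c("A", "B", "C"))
  r <- mrmr_rank(m, labels, n_select = 3)
  expect_identical(r$gene_id, c("A", "C", "B"))
  # hand-evaluate the step-2 comparison with the module's own MI values
  dA <- discretize(m["A", ]); dCc <- discretize(m["C", ])
  D <- relevance_scores(m, labels)
  miBA <- mutual_information(dA, dA)   # B duplicates A
  miCA <- mutual_information(dCc, dA)
  expect_gt(D[["C"]] - miCA, D[["B"]] - miBA)
  # recorded redundancy for the duplicate equals its mean MI to {A, C}
  miBC <- mutual_information(dA, dCc)
  expect_equal(r$redundancy[3], (miBA + miBC) / 2, tolerance = 1e-12)
})

test_that("greedy ranking equals the brute-force oracle on random instances", {
  set.seed(14)
  for (rep in 1:50) {
    n_genes <- sample(3:10, 1)
    n_cells <- sample(12:60, 1)
    m <- matrix(rpois(n_genes * n_cells, sample(2:6, 1)), nrow = n_genes,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("c%02d", seq_len(n_cells))))
    labels <- sample(c("tumor", "periphery"), n_cells, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c("tumor", "periphery")
    r <- mrmr_rank(m, labels, n_select = n_genes)
    bins <- do.call(rbind, lapply(seq_len(n_genes),
                                  function(i) as.integer(unclass(discretize(m[i, ])))))
    rownames(bins) <- rownames(m)
    oracle <- brute_mrmr(bins, as.integer(factor(labels)))
    expect_identical(r$gene_id, oracle)
  }
})

test_that("ranking is deterministic and the pre-filter drops rare genes", {
  d <- recovery_data()
  sub <- d$matrix[1:60, ]
  r1 <- mrmr_rank(sub, d$labels, n_select = 20, log1p_transform = TRUE)
  r2 <- mrmr_rank(sub, d$labels, n_select = 20, log1p_transform = TRUE)
  expect_identical(r1, r2)
  m <- rbind(sub, RARE = c(1, rep(0, ncol(sub) - 1)))
  rf <- mrmr_rank(m, d$labels, n_select = 20, log1p_transform = TRUE,
                  min_cells_expressed = 5)
  expect_false("RARE" %in% rf$gene_id)
  expect_identical(attr(rf, "n_total_genes"), 60L)
})

test_that("mRMR recovers planted informative genes in the top 30", {
  d <- recovery_data()
  r <- recovery_ranking()
  top30 <- r$gene_id[1:30]
  recall <- mean(d$truth$informative_gene_ids %in% top30)
  expect_gte(recall, 0.8)
})
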