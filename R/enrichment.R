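#' Construct a named gene set
#'
#' Gene identifiers are upper-cased before storage so that overlap tests
#' compare case-insensitively; duplicates within a set are collapsed with
#' a warning.
#'
#' @param name Set name.
#' @param gene_ids Character vector of gene identifiers.
#' @return A `gene_set` list with fields `name` and `gene_ids`.
#' @export
gene_set <- function(name, gene_ids) {
  gene_ids <- toupper(as.character(gene_ids))
  if (!length(gene_ids)) stop("gene set '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(gene_ids)) {
    warning("gene set '", name, "': duplicate identifiers collapsed",
            call. = FALSE)
    gene_ids <- unique(gene_ids)
  }
  structure(list(name = name, gene_ids = gene_ids), class = "gene_set")
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail hypergeometric test of the overlap between a biomarker panel
#' and a reference gene set drawn from a common identifier universe:
#' the p-value is \eqn{P(X \ge o)} for \eqn{X} hypergeometric with
#' population `universe_size`, `|reference|` successes and `|panel|` draws,
#' where \eqn{o} is the observed overlap. The tail is computed by exact
#' summation of hypergeometric probabilities (no normal approximation).
#' Zero overlap gives p = 1. Identifiers are compared case-insensitively.
#'
#' The universe size is a deliberate explicit parameter: published overlap
#' p-values are irreproducible when the universe is left implicit, so this
#' function refuses to guess one (a sensible choice is the number of genes
#' in the expression matrix the panel came from).
#'
#' @param panel A [gene_set()] (or character vector) — the drawn set.
#' @param reference A [gene_set()] (or character vector) — the success set.
#' @param universe_size Number of genes in the common universe; must be at
#'   least the size of the union of the two sets.
#' @return List with `overlap` (count), `overlap_genes`, `p_value`,
#'   `panel_size`, `reference_size`, `universe_size`.
#' @examples
#' hypergeometric_overlap_test(c("a", "b", "c"), c("a", "b", "d", "e"),
#'                             universe_size = 10)
#' @export
hypergeometric_overlap_test <- function(panel, reference, universe_size) {
  if (!inherits(panel, "gene_set")) panel <- gene_set("panel", panel)
  if (!inherits(reference, "gene_set")) reference <- gene_set("reference", reference)
  universe_size <- as.integer(universe_size)
  union_n <- length(union(panel$gene_ids, reference$gene_ids))
  if (universe_size < union_n) {
    stop(sprintf("universe_size (%d) is smaller than the union of the sets (%d)",
                 universe_size, union_n), call. = FALSE)
  }
  ov <- intersect(panel$gene_ids, reference$gene_ids)
  if (!length(ov)) {
    warning("panel and reference share no identifiers; check that both use ",
            "the same gene namespace", call. = FALSE)
  }
  # P(X >= o): exact upper tail of the hypergeometric distribution
  p <- stats::phyper(length(ov) - 1L,
                     m = length(reference$gene_ids),
                     n = universe_size - length(reference$gene_ids),
                     k = length(panel$gene_ids),
                     lower.tail = FALSE)
  list(overlap = length(ov), overlap_genes = ov, p_value = p,
       panel_size = length(panel$gene_ids),
       reference_size = length(reference$gene_ids),
       universe_size = universe_size)
}

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set exchange format: one set per line with
#' fields `name`, `description`, then one gene per field. Lines with fewer
#' than three fields are malformed.
#'
#' @param path GMT file path.
#' @return List of [gene_set()] objects, in file order.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    gene_set(fields[1L], fields[-(1:2)])
  })
}

#' Overlap-test a panel against every set in a GMT file
#'
#' @param panel A [gene_set()] or character vector.
#' @param gmt_path Path to a GMT file of reference sets.
#' @param universe_size Common universe size (see
#'   [hypergeometric_overlap_test()]).
#' @param bonferroni Also report Bonferroni-adjusted p-values over the sets
#'   in the file.
#' @return Data frame with one row per reference set: `set`, `set_size`,
#'   `overlap`, `p_value` (and `p_bonferroni` if requested).
#' @export
overlap_report <- function(panel, gmt_path, universe_size,
                           bonferroni = TRUE) {
  sets <- read_gene_set(gmt_path)
  rows <- lapply(sets, function(s) {
    r <- suppressWarnings(hypergeometric_overlap_test(panel, s, universe_size))
    data.frame(set = s$name, set_size = r$reference_size,
               overlap = r$overlap, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni) {
    out$p_bonferroni <- stats::p.adjust(out$p_value, method = "bonferroni")
  }
  out
}
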