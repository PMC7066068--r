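#' Read a labelled expression matrix from disk
#'
#' Loads a genes x cells expression matrix from a dense delimited file or a
#' Matrix Market (MTX) coordinate triplet with gene/cell sidecar files.
#' Whatever the on-disk orientation, the returned matrix always has genes in
#' rows and cells in columns, with identifiers as dimnames.
#'
#' The dense dialect follows the common GEO supplementary-matrix layout:
#' first column holds gene (or cell) identifiers, the header row holds the
#' identifiers of the other axis. For `mtx_triplet`, `path` names the `.mtx`
#' file and one-identifier-per-line sidecars must be supplied (defaults:
#' `<path>.genes.txt` and `<path>.cells.txt` next to the matrix).
#'
#' @param path Path to the matrix file.
#' @param format One of `"dense_tsv"`, `"dense_csv"`, `"mtx_triplet"`.
#' @param genes_in_rows Logical; `TRUE` (default) if the on-disk rows are
#'   genes. Ignored for `mtx_triplet`, where the sidecars disambiguate.
#' @param gene_file,cell_file Sidecar paths for `mtx_triplet`.
#' @param sep Field separator override for the dense formats.
#' @return A numeric matrix (genes x cells) with unique rownames (gene ids)
#'   and colnames (cell ids). No `NA` entries are permitted.
#' @export
read_expression_matrix <- function(path,
                                   format = c("dense_tsv", "dense_csv", "mtx_triplet"),
                                   genes_in_rows = TRUE,
                                   gene_file = NULL,
                                   cell_file = NULL,
                                   sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("expression matrix file does not exist: ", path, call. = FALSE)
  }
  if (format == "mtx_triplet") {
    if (is.null(gene_file)) gene_file <- paste0(path, ".genes.txt")
    if (is.null(cell_file)) cell_file <- paste0(path, ".cells.txt")
    if (!file.exists(gene_file) || !file.exists(cell_file)) {
      stop("mtx_triplet requires gene and cell sidecar files; missing: ",
           paste(c(gene_file, cell_file)[!file.exists(c(gene_file, cell_file))],
                 collapse = ", "), call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    genes <- genes[nzchar(genes)]
    cells <- cells[nzchar(cells)]
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop(sprintf(
        "dimension mismatch: matrix is %d x %d but sidecars list %d genes and %d cells",
        nrow(m), ncol(m), length(genes), length(cells)), call. = FALSE)
    }
    dimnames(m) <- list(genes, cells)
  } else {
    if (is.null(sep)) sep <- if (format == "dense_tsv") "\t" else ","
    dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
    row_ids <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- row_ids
    if (!genes_in_rows) m <- t(m)
  }
  validate_expression_matrix(m)
  m
}

validate_expression_matrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must carry gene rownames and cell colnames",
         call. = FALSE)
  }
  dup_g <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_g)) {
    stop("duplicate gene identifiers: ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_c <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_c)) {
    stop("duplicate cell identifiers: ", paste(dup_c, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-finite expression value at gene '%s', cell '%s'",
                 rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]),
         call. = FALSE)
  }
  invisible(m)
}

#' Write an expression matrix as a dense delimited file
#'
#' Inverse of [read_expression_matrix()] for the dense dialects: first column
#' `gene_id`, header row of cell identifiers.
#'
#' @param m Genes x cells matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator (tab by default).
#' @export
write_expression_matrix <- function(m, path, sep = "\t") {
  validate_expression_matrix(m)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Read and write per-cell tissue labels
#'
#' Labels are stored as a two-column TSV (`cell_id`, `label`). On reading,
#' the vector is ordered to match `cell_ids` when given.
#'
#' @param path Label TSV path.
#' @param cell_ids Optional cell ordering to enforce.
#' @return Named character vector of labels, names are cell ids.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  labels <- stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  if (!is.null(cell_ids)) {
    missing <- setdiff(cell_ids, names(labels))
    if (length(missing)) {
      stop("labels missing for cells: ", paste(utils::head(missing, 5L), collapse = ", "),
           call. = FALSE)
    }
    labels <- labels[cell_ids]
  }
  labels
}

#' @rdname read_labels
#' @param labels Named character vector (names = cell ids).
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(cell_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Count expressed genes per cell
#'
#' A gene counts as expressed in a cell when its value is strictly greater
#' than `threshold` (default 0, i.e. any mapped reads). Single-cell matrices
#' are sparse, so this per-cell count is a standard depth/quality summary.
#'
#' @param m Genes x cells expression matrix.
#' @param threshold Expression cutoff; strictly-greater comparison.
#' @return List with `per_cell` (named integer vector) and `mean` (scalar).
#' @examples
#' m <- matrix(c(0, 0, 5, 1, 0, 0, 0, 0), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), c("c1", "c2")))
#' count_expressed_genes(m)$per_cell  # c1 = 2, c2 = 0
#' @export
count_expressed_genes <- function(m, threshold = 0) {
  per_cell <- colSums(m > threshold)
  list(per_cell = stats::setNames(as.integer(per_cell), colnames(m)),
       mean = mean(per_cell))
}

output_header <- function(kind, seed = NA, config = NULL) {
  cfg <- if (is.null(config)) "" else
    paste0(" config=", gsub("\n", " ", yaml::as.yaml(config)))
  c(sprintf("# %s written by mrmrIFS %s", kind,
            as.character(utils::packageVersion("mrmrIFS"))),
    sprintf("# seed=%s%s", as.character(seed), cfg))
}

#' Write and read a ranked gene list
#'
#' Serializes a ranking produced by [mrmr_rank()] as a tab-separated file
#' with columns `rank`, `gene_id`, `relevance`, `redundancy`, `mrmr_score`,
#' preceded by `#`-commented header lines recording the package version,
#' seed and configuration. [read_ranked_list()] round-trips the file.
#'
#' @param ranking A `mrmr_ranking` data frame from [mrmr_rank()].
#' @param path Output path.
#' @param seed,config Optional provenance recorded in the header.
#' @param digits Decimal digits written for the score columns.
#' @export
write_ranked_list <- function(ranking, path, seed = NA, config = NULL,
                              digits = 10) {
  if (!nrow(ranking)) stop("refusing to write an empty ranking", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("ranked gene list", seed, config), con)
  df <- data.frame(
    rank = ranking$rank,
    gene_id = ranking$gene_id,
    relevance = formatC(ranking$relevance, digits = digits, format = "f"),
    redundancy = formatC(ranking$redundancy, digits = digits, format = "f"),
    mrmr_score = formatC(ranking$mrmr_score, digits = digits, format = "f"))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  df$gene_id <- as.character(df$gene_id)
  structure(df, class = c("mrmr_ranking", "data.frame"))
}

#' Write a biomarker panel to a tab-separated file
#'
#' @param panel A `biomarker_panel` from [build_panel()].
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  if (!length(panel$gene_ids)) stop("refusing to write an empty panel", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header("biomarker panel", panel$provenance$seed,
                           panel$provenance$config), con)
  writeLines(sprintf("# k=%d peak_mcc=%.10f", panel$k, panel$peak_mcc), con)
  utils::write.table(
    data.frame(rank = seq_along(panel$gene_ids), gene_id = panel$gene_ids),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
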