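#' Declared level-1 cell-type vocabulary
#'
#' Lineage labels used throughout the package: T follicular helper (Tfh),
#' non-Tfh non-naive CD4 T (nnCD4), light/dark-zone germinal center B cells
#' (LZ_GCB, DZ_GCB), naive B, follicular dendritic cells (FDC), epithelium,
#' and a catch-all Other.
#'
#' @export
GC_TYPE_L1 <- c("Tfh", "nnCD4", "LZ_GCB", "DZ_GCB", "NaiveB", "FDC",
                "Epithelium", "Other")

REQUIRED_CELL_COLUMNS <- c("cell_id", "x", "y", "sample_id", "type_l1")

#' Validate a segmented-cell table
#'
#' A cell table has one row per segmented cell with columns `cell_id`
#' (unique), `x`/`y` (finite centroid coordinates in micrometres, image
#' convention: origin top-left, y increasing downward), `sample_id`, and a
#' level-1 type label `type_l1` from a declared vocabulary. Optional columns
#' (`type_l2`, `cn_id`, ...) are preserved.
#'
#' @param cells data.frame to validate.
#' @param vocabulary allowed `type_l1` labels.
#' @return the validated data.frame, invisibly classed `cell_table`.
#' @export
validate_cell_table <- function(cells, vocabulary = GC_TYPE_L1) {
  stopifnot(is.data.frame(cells))
  missing_cols <- setdiff(REQUIRED_CELL_COLUMNS, names(cells))
  if (length(missing_cols)) {
    stop("cell table format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cells$cell_id <- as.character(cells$cell_id)
  dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
  if (length(dup)) {
    stop("cell table validation error: duplicated cell_id(s): ",
         paste(head(dup, 10), collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y))) {
    stop("cell table validation error: non-finite x/y coordinates",
         call. = FALSE)
  }
  bad <- setdiff(unique(as.character(cells$type_l1)), vocabulary)
  if (length(bad)) {
    stop("cell table validation error: type_l1 label(s) outside vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(cells) <- unique(c("cell_table", class(cells)))
  cells
}

#' Read a segmented-cell table from delimited text
#'
#' @param path tab-delimited file with a header naming at least
#'   `cell_id, x, y, sample_id, type_l1`.
#' @param vocabulary allowed `type_l1` labels.
#' @return a validated cell table (`data.frame`); extra columns preserved.
#' @export
read_cell_table <- function(path, vocabulary = GC_TYPE_L1) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cell_table(df, vocabulary = vocabulary)
}

#' Write a cell table as tab-delimited text
#' @param cells cell table.
#' @param path output path.
#' @export
write_cell_table <- function(cells, path) {
  write.table(cells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sparse gene-by-cell count matrix
#'
#' Matrix Market coordinate format with plain-text sidecar files listing the
#' gene symbols (rows) and cell identifiers (columns), one per line — the
#' prevailing single-cell interchange convention.
#'
#' @param matrix_path `.mtx` file.
#' @param genes_path,cells_path sidecar identifier files.
#' @return a `dgCMatrix` with genes as rownames and cells as colnames.
#' @export
read_count_matrix <- function(matrix_path, genes_path, cells_path) {
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop(sprintf(paste0("count matrix format error: header declares %d x %d ",
                        "but sidecars list %d genes and %d cells"),
                 nrow(m), ncol(m), length(genes), length(cells)),
         call. = FALSE)
  }
  if (any(m@x < 0)) {
    stop("count matrix validation error: negative entries present",
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("count matrix validation error: duplicated gene symbols",
         call. = FALSE)
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(genes, cells)
  m
}

#' Write a sparse count matrix with identifier sidecars
#'
#' @param counts gene-by-cell sparse matrix with dimnames.
#' @param matrix_path,genes_path,cells_path output paths.
#' @export
write_count_matrix <- function(counts, matrix_path, genes_path, cells_path) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), matrix_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), cells_path)
  invisible(matrix_path)
}

#' Check that a cell table and a count matrix describe the same cells
#'
#' @param cells cell table.
#' @param counts gene-by-cell matrix with cell ids as colnames.
#' @return invisibly TRUE; errors with the symmetric difference otherwise.
#' @export
validate_pairing <- function(cells, counts) {
  a <- cells$cell_id
  b <- colnames(counts)
  only_table <- setdiff(a, b)
  only_matrix <- setdiff(b, a)
  if (length(only_table) || length(only_matrix)) {
    stop("paired data validation error: cell sets differ; ",
         length(only_table), " only in cell table (e.g. ",
         paste(head(only_table, 5), collapse = ", "), "); ",
         length(only_matrix), " only in count matrix (e.g. ",
         paste(head(only_matrix, 5), collapse = ", "), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Analysis configuration
#'
#' One structured object holding every tunable numeric of the positional
#' analysis, echoed into all output artifacts for provenance.
#'
#' @param k neighborhood window size (nearest neighbours, self included).
#' @param n_cn number of cellular neighborhoods to resolve.
#' @param bin_um raster bin size for the GC mask, micrometres.
#' @param closing_radius binary-closing radius, in bins.
#' @param positivity_threshold minimum raw count to call a cell positive.
#' @param min_pos minimum positive Tfh for a gene to enter the PPV ranking.
#' @param pseudocount epsilon added to normalised group means in log2FC.
#' @param mt_method multiple-testing method, `"bonferroni"` or `"BH"`.
#' @param bandwidth_um Gaussian kernel bandwidth for decay curves.
#' @param grid_max_um,grid_step_um distance grid for decay curves.
#' @param seed master random seed.
#' @return a list classed `gc_analysis_config`.
#' @export
analysis_config <- function(k = 20L, n_cn = 10L, bin_um = 20, closing_radius = 2L,
                            positivity_threshold = 1L, min_pos = 20L,
                            pseudocount = 1e-9, mt_method = "bonferroni",
                            bandwidth_um = 25, grid_max_um = 300,
                            grid_step_um = 5, seed = 1L) {
  cfg <- list(k = as.integer(k), n_cn = as.integer(n_cn), bin_um = bin_um,
              closing_radius = as.integer(closing_radius),
              positivity_threshold = as.integer(positivity_threshold),
              min_pos = as.integer(min_pos), pseudocount = pseudocount,
              mt_method = match.arg(mt_method, c("bonferroni", "BH")),
              bandwidth_um = bandwidth_um, grid_max_um = grid_max_um,
              grid_step_um = grid_step_um, seed = as.integer(seed))
  numeric_fields <- setdiff(names(cfg), "mt_method")
  for (f in numeric_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stop("config validation error: '", f, "' must be a single positive number",
           call. = FALSE)
    }
  }
  class(cfg) <- "gc_analysis_config"
  cfg
}

# Short provenance fingerprint of a config, stamped on output tables.
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v) paste(format(v), collapse = ","),
                                   ""), sep = "=", collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483629
  sprintf("cfg%08x", as.integer(h))
}

stamp_provenance <- function(x, config) {
  attr(x, "config_hash") <- config_hash(config)
  attr(x, "seed") <- config$seed
  x
}
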