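#' Call per-gene positivity from raw counts
#'
#' A cell is positive for a gene iff its raw count reaches the threshold.
#' Probe-based spatial counts are near-binary at typical depths, so the
#' default threshold is a single transcript.
#'
#' @param counts gene-by-cell count matrix.
#' @param threshold minimum raw count (>= 1).
#' @return logical gene-by-cell matrix (sparse if the input is sparse).
#' @export
call_positivity <- function(counts, threshold = 1L) {
  stopifnot(threshold >= 1)
  counts >= threshold
}

#' Per-gene positional positive-predictive value for the GC niche
#'
#' For each gene: among Tfh positive for the gene, the fraction positioned
#' inside the merged GC mask. Genes with fewer than `min_pos` positive Tfh
#' are reported but excluded from ranking.
#'
#' @param positivity logical gene-by-cell matrix.
#' @param tfh_mask per-cell logical, TRUE for Tfh cells.
#' @param in_gc per-cell logical, TRUE inside the GC mask.
#' @param min_pos minimum positive Tfh for ranking inclusion.
#' @return data.frame with one row per gene: `gene`, `n_pos_tfh`,
#'   `n_pos_tfh_in_gc`, `ppv`, `included` (rank/percentile are added by
#'   [rank_percentile()]).
#' @export
gc_ppv <- function(positivity, tfh_mask, in_gc, min_pos = 20L) {
  stopifnot(length(tfh_mask) == ncol(positivity),
            length(in_gc) == ncol(positivity))
  if (!any(tfh_mask)) stop("specificity error: no Tfh cells in dataset",
                           call. = FALSE)
  pos_tfh <- positivity[, tfh_mask, drop = FALSE]
  n_pos <- Matrix::rowSums(pos_tfh)
  n_pos_gc <- Matrix::rowSums(positivity[, tfh_mask & in_gc, drop = FALSE])
  data.frame(gene = rownames(positivity),
             n_pos_tfh = as.integer(n_pos),
             n_pos_tfh_in_gc = as.integer(n_pos_gc),
             ppv = ifelse(n_pos > 0, n_pos_gc / n_pos, NA_real_),
             included = n_pos >= min_pos,
             stringsAsFactors = FALSE)
}

#' Rank included genes by PPV and assign percentiles
#'
#' Included genes are sorted by PPV descending, ties broken by the number of
#' positive Tfh descending then gene name ascending. Rank 1 is the highest
#' PPV; the percentile convention is `100 * (1 - (rank - 1) / n)`, reported
#' to one decimal, so rank 1 of any n is 100.0 and rank 25 of 5,101 is 99.5.
#'
#' @param rows output of [gc_ppv()].
#' @return the same data.frame with `rank` and `percentile` columns
#'   (NA for excluded genes), sorted with ranked genes first.
#' @export
rank_percentile <- function(rows) {
  if (!any(rows$included)) stop("specificity error: no included genes",
                                call. = FALSE)
  rows$rank <- NA_integer_
  rows$percentile <- NA_real_
  inc <- which(rows$included)
  ord <- inc[order(-rows$ppv[inc], -rows$n_pos_tfh[inc], rows$gene[inc])]
  n <- length(ord)
  rows$rank[ord] <- seq_len(n)
  rows$percentile[ord] <- round(100 * (1 - (seq_len(n) - 1) / n), 1)
  rows[order(is.na(rows$rank), rows$rank), , drop = FALSE]
}

# Vectorised two-sided Wilcoxon rank-sum p-values across the rows of a
# matrix: normal approximation with tie correction and continuity
# correction, the standard large-sample form.
rank_sum_p <- function(values, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  v <- values[, c(idx1, idx2), drop = FALSE]
  apply(v, 1, function(x) {
    r <- rank(x)
    U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- tabulate(match(x, unique(x)))
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (U1 - mu - sign(U1 - mu) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

#' Wilcoxon rank-sum contrast between two cell groups
#'
#' Per gene: two-sided rank-sum test (normal approximation with tie and
#' continuity corrections) between two disjoint cell groups, and a fold
#' change `log2((mean1 + eps) / (mean2 + eps))` of the supplied values
#' (pass library-size-normalised values; see [normalize_counts()]).
#' Adjusted p-values use Bonferroni by default across the tested genes.
#'
#' @param values gene-by-cell matrix of (normalised) expression values.
#' @param group1,group2 disjoint cell identifier vectors or column indices,
#'   each with at least 3 cells.
#' @param pseudocount epsilon in the fold-change ratio.
#' @param mt_method `"bonferroni"` (default) or `"BH"`.
#' @param name contrast label carried on the result.
#' @return data.frame classed `contrast_result`: `gene`, `log2fc`, `p`,
#'   `p_adj`, `n_group1`, `n_group2`, with the contrast name as attribute.
#' @export
wilcoxon_contrast <- function(values, group1, group2, pseudocount = 1e-9,
                              mt_method = c("bonferroni", "BH"),
                              name = "contrast") {
  mt_method <- match.arg(mt_method)
  to_idx <- function(g) {
    if (is.character(g)) match(g, colnames(values)) else as.integer(g)
  }
  idx1 <- to_idx(group1); idx2 <- to_idx(group2)
  if (anyNA(idx1) || anyNA(idx2)) {
    stop("contrast error: group cells not found in matrix", call. = FALSE)
  }
  if (length(idx1) < 3 || length(idx2) < 3) {
    stop("contrast error: each group needs at least 3 cells", call. = FALSE)
  }
  if (length(intersect(idx1, idx2))) {
    stop("contrast error: groups overlap", call. = FALSE)
  }
  dense <- as.matrix(values[, c(idx1, idx2), drop = FALSE])
  m1 <- rowMeans(dense[, seq_along(idx1), drop = FALSE])
  m2 <- rowMeans(dense[, length(idx1) + seq_along(idx2), drop = FALSE])
  p <- rank_sum_p(dense, seq_along(idx1), length(idx1) + seq_along(idx2))
  res <- data.frame(gene = rownames(values) %||% as.character(seq_len(nrow(values))),
                    log2fc = log2((m1 + pseudocount) / (m2 + pseudocount)),
                    p = p,
                    p_adj = stats::p.adjust(p, method = mt_method),
                    n_group1 = length(idx1), n_group2 = length(idx2),
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- name
  attr(res, "mt_method") <- mt_method
  class(res) <- c("contrast_result", class(res))
  res
}

#' Three-way contamination-aware GC specificity integration
#'
#' Combines, per gene with mutual panel coverage, the fold changes of three
#' Wilcoxon contrasts: (1) Tfh inside versus outside the GC mask, (2) Tfh
#' versus all other cells within the GC mask, and (3) dissociated-reference
#' Tfh versus all other reference lineages. Genes driven by contamination
#' from neighbouring GC populations appear positive in (1) but negative in
#' (3); truly Tfh-intrinsic GC programs are positive in all three.
#'
#' @param spatial_counts gene-by-cell spatial count matrix.
#' @param tfh_mask,in_gc per-cell logicals aligned to `spatial_counts`.
#' @param reference_counts gene-by-cell reference count matrix.
#' @param reference_tfh per-reference-cell logical, TRUE for Tfh.
#' @param alpha significance level applied to the adjusted p of each
#'   comparison.
#' @param pseudocount,mt_method passed to [wilcoxon_contrast()].
#' @return data.frame: `gene`, `lfc_gc_vs_out`, `lfc_tfh_vs_other_in_gc`,
#'   `lfc_reference`, the three adjusted p-values, and `passes_filter`.
#' @export
three_way_specificity <- function(spatial_counts, tfh_mask, in_gc,
                                  reference_counts, reference_tfh,
                                  alpha = 0.05, pseudocount = 1e-9,
                                  mt_method = "bonferroni") {
  shared <- intersect(rownames(spatial_counts), rownames(reference_counts))
  if (!length(shared)) {
    stop("three-way error: empty gene panel intersection", call. = FALSE)
  }
  sp <- normalize_counts(spatial_counts[shared, , drop = FALSE])
  rf <- normalize_counts(reference_counts[shared, , drop = FALSE])
  cells <- seq_len(ncol(sp))
  c1 <- wilcoxon_contrast(sp, cells[tfh_mask & in_gc], cells[tfh_mask & !in_gc],
                          pseudocount, mt_method, name = "tfh_gc_vs_out")
  c2 <- wilcoxon_contrast(sp, cells[tfh_mask & in_gc], cells[!tfh_mask & in_gc],
                          pseudocount, mt_method, name = "tfh_vs_other_in_gc")
  rcells <- seq_len(ncol(rf))
  c3 <- wilcoxon_contrast(rf, rcells[reference_tfh], rcells[!reference_tfh],
                          pseudocount, mt_method, name = "reference_tfh_vs_other")
  data.frame(gene = shared,
             lfc_gc_vs_out = c1$log2fc,
             lfc_tfh_vs_other_in_gc = c2$log2fc,
             lfc_reference = c3$log2fc,
             p_adj_gc_vs_out = c1$p_adj,
             p_adj_tfh_vs_other_in_gc = c2$p_adj,
             p_adj_reference = c3$p_adj,
             passes_filter = c1$p_adj < alpha & c2$p_adj < alpha &
               c3$p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Distance from every cell to its nearest target cell
#'
#' Euclidean centroid-to-centroid distance to the nearest cell of a target
#' set (e.g. LZ GC B cells), computed within sample. Target cells get 0.
#' Samples without any target cell get NA distances and are listed in the
#' `missing_target_samples` attribute.
#'
#' @param cells cell table.
#' @param target per-cell logical marking target cells.
#' @return named numeric vector of distances (micrometres).
#' @export
distance_to_nearest <- function(cells, target) {
  cells <- validate_cell_table(cells)
  stopifnot(length(target) == nrow(cells))
  d <- setNames(rep(NA_real_, nrow(cells)), cells$cell_id)
  flagged <- character(0)
  for (s in unique(cells$sample_id)) {
    idx <- which(cells$sample_id == s)
    tgt <- idx[target[idx]]
    if (!length(tgt)) {
      flagged <- c(flagged, s)
      next
    }
    nn <- RANN::nn2(cells[tgt, c("x", "y"), drop = FALSE],
                    cells[idx, c("x", "y"), drop = FALSE], k = 1)
    d[idx] <- nn$nn.dists[, 1]
    d[idx[target[idx]]] <- 0
  }
  attr(d, "missing_target_samples") <- flagged
  d
}

#' Kernel-smoothed expression-versus-distance decay curve
#'
#' Nadaraya-Watson estimate with a Gaussian kernel of the mean expression as
#' a function of distance (e.g. to the nearest LZ GC B cell), evaluated on a
#' regular grid. Grid points with no cell within three bandwidths are
#' reported as NA.
#'
#' @param expr per-cell expression values (library-size normalised).
#' @param distances per-cell distances, micrometres.
#' @param bandwidth Gaussian kernel bandwidth, micrometres.
#' @param grid distance grid (strictly increasing).
#' @return data.frame `distance`, `value`, with `bandwidth` attribute.
#' @export
smoothed_decay <- function(expr, distances, bandwidth = 25,
                           grid = seq(0, 300, by = 5)) {
  stopifnot(bandwidth > 0, length(expr) == length(distances),
            all(diff(grid) > 0))
  keep <- is.finite(expr) & is.finite(distances)
  if (!any(keep)) stop("decay error: no usable cells", call. = FALSE)
  expr <- expr[keep]; distances <- distances[keep]
  value <- vapply(grid, function(g) {
    u <- (distances - g) / bandwidth
    if (!any(abs(u) <= 3)) return(NA_real_)
    w <- exp(-u^2 / 2)
    sum(w * expr) / sum(w)
  }, numeric(1))
  out <- data.frame(distance = grid, value = value)
  attr(out, "bandwidth") <- bandwidth
  out
}
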