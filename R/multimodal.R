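#' Combine two modality contrasts into a meta-ranking
#'
#' For every gene tested in both modalities (e.g. a transcriptomic contrast
#' and a chromatin gene-activity contrast with the same group definitions),
#' combines the two p-values by Fisher's method — the statistic
#' `-2 (ln p1 + ln p2)` referred to a chi-square with 4 degrees of freedom —
#' and averages the two log2 fold changes. The top set is the genes below a
#' meta-p ceiling, ranked by meta log2FC descending; the default ceiling is
#' the smallest threshold retaining at least `min_top` genes. Stouffer's
#' Z combination is available as an alternative.
#'
#' @param contrast_rna,contrast_activity `contrast_result` data.frames from
#'   [wilcoxon_contrast()].
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @param min_top size of the retained top set used to set the default
#'   meta-p ceiling.
#' @param ceiling optional explicit meta-p ceiling.
#' @return data.frame: `gene`, `lfc_rna`, `p_rna`, `lfc_activity`,
#'   `p_activity`, `meta_p`, `meta_lfc`, `in_top`, `rank` (by meta_lfc
#'   descending within the top set), sorted top set first; combination
#'   method recorded in the `method` attribute.
#' @export
combine_meta <- function(contrast_rna, contrast_activity,
                         method = c("fisher", "stouffer"), min_top = 10L,
                         ceiling = NULL) {
  method <- match.arg(method)
  shared <- intersect(contrast_rna$gene, contrast_activity$gene)
  if (!length(shared)) stop("meta error: empty gene intersection",
                            call. = FALSE)
  a <- contrast_rna[match(shared, contrast_rna$gene), ]
  b <- contrast_activity[match(shared, contrast_activity$gene), ]
  p1 <- a$p; p2 <- b$p
  if (any(p1 == 0) || any(p2 == 0)) {
    warning("meta warning: p = 0 clamped to smallest positive double")
    p1 <- pmax(p1, .Machine$double.xmin)
    p2 <- pmax(p2, .Machine$double.xmin)
  }
  meta_p <- if (method == "fisher") {
    pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
  } else {
    z <- (stats::qnorm(p1, lower.tail = FALSE) +
            stats::qnorm(p2, lower.tail = FALSE)) / sqrt(2)
    stats::pnorm(z, lower.tail = FALSE)
  }
  res <- data.frame(gene = shared, lfc_rna = a$log2fc, p_rna = p1,
                    lfc_activity = b$log2fc, p_activity = p2,
                    meta_p = meta_p, meta_lfc = (a$log2fc + b$log2fc) / 2,
                    stringsAsFactors = FALSE)
  if (is.null(ceiling)) {
    ceiling <- sort(res$meta_p)[min(min_top, nrow(res))]
  }
  res$in_top <- res$meta_p <= ceiling
  res$rank <- NA_integer_
  top <- which(res$in_top)
  res$rank[top[order(-res$meta_lfc[top])]] <- seq_along(top)
  res <- res[order(!res$in_top, res$rank, res$meta_p), , drop = FALSE]
  attr(res, "method") <- method
  attr(res, "ceiling") <- ceiling
  res
}

# log of the hypergeometric probability of a contingency cell count
log_hyper <- function(nij, ai, bj, N) {
  lgamma(ai + 1) + lgamma(bj + 1) + lgamma(N - ai + 1) + lgamma(N - bj + 1) -
    lgamma(N + 1) - lgamma(nij + 1) - lgamma(ai - nij + 1) -
    lgamma(bj - nij + 1) - lgamma(N - ai - bj + nij + 1)
}

#' Adjusted mutual information between two cell labelings
#'
#' Chance-corrected similarity of two clusterings of the same cells,
#' invariant to label naming:
#' `AMI = (MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`,
#' with the expected mutual information under the permutation
#' (hypergeometric) model and arithmetic-mean entropy normalisation.
#' A degenerate denominator (both labelings single-cluster) yields 0 by
#' convention; identical labelings yield 1.
#'
#' @param a,b labelings: named vectors (cell id to label) or data.frames
#'   with `cell_id` and `label` columns. Unequal cell universes are
#'   intersected with a warning.
#' @return list classed `concordance_result`: `ami`, `mi`, `emi`,
#'   `h_a`, `h_b`, `table` (contingency), `n`.
#' @export
ami <- function(a, b) {
  as_map <- function(x) {
    if (is.data.frame(x)) setNames(as.character(x$label), x$cell_id)
    else setNames(as.character(x), names(x))
  }
  a <- as_map(a); b <- as_map(b)
  common <- intersect(names(a), names(b))
  if (length(common) < length(a) || length(common) < length(b)) {
    warning("ami warning: cell universes differ; intersecting to ",
            length(common), " cells")
  }
  if (length(common) < 2) stop("ami error: fewer than 2 shared cells",
                               call. = FALSE)
  tab <- table(a[common], b[common])
  N <- sum(tab)
  ai <- rowSums(tab); bj <- colSums(tab)
  pa <- ai / N; pb <- bj / N
  h_a <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  h_b <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  pij <- tab / N
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer(pa, pb)), 0))
  # expected MI under the permutation model
  emi <- 0
  for (i in seq_along(ai)) {
    for (j in seq_along(bj)) {
      lo <- max(1, ai[i] + bj[j] - N)
      hi <- min(ai[i], bj[j])
      if (hi < lo) next
      nij <- lo:hi
      term <- (nij / N) * log(N * nij / (ai[i] * bj[j])) *
        exp(log_hyper(nij, ai[i], bj[j], N))
      emi <- emi + sum(term)
    }
  }
  denom <- (h_a + h_b) / 2 - emi
  ami_val <- if (abs(denom) < .Machine$double.eps^0.5) 0 else (mi - emi) / denom
  structure(list(ami = ami_val, mi = mi, emi = emi, h_a = h_a, h_b = h_b,
                 table = tab, n = N),
            class = "concordance_result")
}

#' All pairwise AMIs over a set of labelings
#'
#' @param labelings named list of labelings (see [ami()]).
#' @return symmetric matrix of AMI values with unit diagonal.
#' @export
ami_matrix <- function(labelings) {
  k <- length(labelings)
  m <- matrix(1, k, k, dimnames = list(names(labelings), names(labelings)))
  if (k < 2) return(m)
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- ami(labelings[[i]], labelings[[j]])$ami
    }
  }
  m
}
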