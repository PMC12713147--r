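run_stage <- function(stage, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline error in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  message(sprintf("[gcniche] stage %-14s %6.2fs", stage, elapsed))
  log[[stage]] <- elapsed
  list(res = res, log = log)
}

#' Run the full GC positional-specificity pipeline
#'
#' Executes the stages in order — neighborhood composition and clustering,
#' GC mask construction, positional PPV ranking, the Tfh in-GC versus
#' out-of-GC contrast, the optional three-way reference integration, and
#' distance-decay curves — on a validated (cell table, count matrix) pair.
#' Every output table carries the configuration hash and seed; a per-stage
#' timing log is written to stderr and returned.
#'
#' @param config an [analysis_config()].
#' @param cells cell table.
#' @param counts paired gene-by-cell count matrix.
#' @param reference optional list with `counts` and `labels` (a dissociated
#'   reference, e.g. from [generate_dissociated_reference()]); enables the
#'   three-way specificity stage.
#' @param decay_genes genes for the distance-decay stage; defaults to the
#'   top 5 ranked genes.
#' @return list with `model`, `mask`, `specificity`, `contrast_gc`,
#'   `three_way` (or NULL), `decay`, `config`, `log`.
#' @export
run_pipeline <- function(config, cells, counts, reference = NULL,
                         decay_genes = NULL) {
  stopifnot(inherits(config, "gc_analysis_config"))
  cells <- validate_cell_table(cells)
  validate_pairing(cells, counts)
  counts <- counts[, cells$cell_id, drop = FALSE]
  log <- list()

  st <- run_stage("neighborhoods", log, {
    comp <- knn_composition(cells, config$k)
    model <- cluster_neighborhoods(comp, config$n_cn,
                                   seed = stage_seed(config$seed, "cn"))
    annotate_cn(model)
  })
  model <- st$res; log <- st$log
  message(sprintf("[gcniche]   %d cells, %d neighborhoods", nrow(cells),
                  model$n_cn))

  st <- run_stage("gc_mask", log, {
    merge_gc_mask(cells, model, bin_um = config$bin_um,
                  closing_radius = config$closing_radius)
  })
  mask <- st$res; log <- st$log
  message(sprintf("[gcniche]   %d / %d cells in GC mask", sum(mask$in_gc),
                  nrow(cells)))

  tfh <- cells$type_l1 == "Tfh"
  in_gc <- unname(mask$in_gc[cells$cell_id])

  st <- run_stage("specificity", log, {
    pos <- call_positivity(counts, config$positivity_threshold)
    rank_percentile(gc_ppv(pos, tfh, in_gc, config$min_pos))
  })
  spec <- stamp_provenance(st$res, config); log <- st$log
  message(sprintf("[gcniche]   %d genes ranked", sum(spec$included)))

  st <- run_stage("contrast_gc", log, {
    norm <- normalize_counts(counts)
    idx <- seq_len(ncol(norm))
    wilcoxon_contrast(norm, idx[tfh & in_gc], idx[tfh & !in_gc],
                      config$pseudocount, config$mt_method,
                      name = "tfh_gc_vs_out")
  })
  contrast_gc <- stamp_provenance(st$res, config); log <- st$log

  three_way <- NULL
  if (!is.null(reference)) {
    st <- run_stage("three_way", log, {
      ref_tfh <- reference$labels$label == "Tfh"
      three_way_specificity(counts, tfh, in_gc, reference$counts, ref_tfh,
                            pseudocount = config$pseudocount,
                            mt_method = config$mt_method)
    })
    three_way <- stamp_provenance(st$res, config); log <- st$log
  }

  st <- run_stage("decay", log, {
    if (is.null(decay_genes)) {
      decay_genes <- head(spec$gene[!is.na(spec$rank)], 5)
    }
    lzgcb <- cells$type_l1 == "LZ_GCB"
    d <- distance_to_nearest(cells, lzgcb)
    norm <- normalize_counts(counts)
    curves <- lapply(decay_genes, function(g) {
      smoothed_decay(as.numeric(norm[g, tfh]), unname(d[cells$cell_id[tfh]]),
                     bandwidth = config$bandwidth_um,
                     grid = seq(0, config$grid_max_um,
                                by = config$grid_step_um))
    })
    names(curves) <- decay_genes
    curves
  })
  decay <- st$res; log <- st$log

  list(model = model, mask = mask, specificity = spec,
       contrast_gc = contrast_gc, three_way = three_way, decay = decay,
       config = config, log = log)
}
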