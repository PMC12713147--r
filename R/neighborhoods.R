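#' k-nearest-neighbour cell-type composition vectors
#'
#' For each cell, the normalised histogram of level-1 types among its k
#' nearest neighbours by Euclidean centroid distance, with the cell itself
#' included in the window. Neighbours are found within the same sample only.
#'
#' @param cells cell table.
#' @param k window size (neighbours including self).
#' @param vocabulary type categories defining the vector components.
#' @return a cells-by-types matrix of fractions; every row sums to 1.
#' @export
knn_composition <- function(cells, k = 20L, vocabulary = GC_TYPE_L1) {
  cells <- validate_cell_table(cells, vocabulary)
  k <- as.integer(k)
  stopifnot(k >= 1)
  comp <- matrix(0, nrow(cells), length(vocabulary),
                 dimnames = list(cells$cell_id, vocabulary))
  type_idx <- match(cells$type_l1, vocabulary)
  for (s in unique(cells$sample_id)) {
    idx <- which(cells$sample_id == s)
    if (length(idx) <= k) {
      stop("neighborhood error: sample '", s, "' has ", length(idx),
           " cells but k = ", k, " requires more than k cells", call. = FALSE)
    }
    nn <- RANN::nn2(cells[idx, c("x", "y")], k = k)   # includes self
    nb_types <- matrix(type_idx[idx][nn$nn.idx], nrow(nn$nn.idx))
    for (tt in seq_along(vocabulary)) {
      comp[idx, tt] <- rowSums(nb_types == tt) / k
    }
  }
  comp
}

#' Cluster composition vectors into cellular neighborhoods
#'
#' k-means over all samples jointly (shared neighbourhood vocabulary), with
#' multiple random restarts under a fixed seed for reproducibility.
#'
#' @param comp composition matrix from [knn_composition()].
#' @param n_cn number of neighborhoods (>= 2).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return a list classed `cn_model`: `cn_id` (0-based per-cell assignment,
#'   named by cell id), `centroids`, `enrichment` (CN type fraction over
#'   global fraction), `annotation` (filled by [annotate_cn()]), `n_cn`.
#' @export
cluster_neighborhoods <- function(comp, n_cn = 10L, seed = 1L, nstart = 10L) {
  n_cn <- as.integer(n_cn)
  stopifnot(n_cn >= 2)
  n_distinct <- nrow(unique(comp))
  if (n_cn > n_distinct) {
    stop("neighborhood error: n_cn = ", n_cn, " exceeds the ", n_distinct,
         " distinct composition vectors", call. = FALSE)
  }
  km <- with_seed(seed,
                  kmeans(comp, centers = n_cn, nstart = nstart,
                         iter.max = 100L))
  cn_id <- setNames(km$cluster - 1L, rownames(comp))
  centroids <- km$centers
  rownames(centroids) <- paste0("CN", seq_len(n_cn) - 1L)
  global_frac <- colMeans(comp)
  enrichment <- sweep(centroids, 2, pmax(global_frac, 1e-12), "/")
  structure(list(cn_id = cn_id, centroids = centroids,
                 enrichment = enrichment, global_fraction = global_frac,
                 annotation = setNames(rep("Other", n_cn),
                                       rownames(centroids)),
                 n_cn = n_cn),
            class = "cn_model")
}

#' Default declarative neighborhood annotation rules
#'
#' Each rule is a label plus a predicate on a CN's centroid composition
#' (`frac`) and enrichment over global (`enr`). The GC rules require
#' dominance of the matching zone so a mixed LZ/DZ neighborhood cannot fire
#' both; unmatched CNs stay "Other".
#'
#' @return a named list of predicate functions.
#' @export
default_cn_rules <- function() {
  list(
    GC_LZ = function(frac, enr) {
      enr["LZ_GCB"] > 2 && frac["LZ_GCB"] > 0.2 &&
        frac["LZ_GCB"] >= frac["DZ_GCB"]
    },
    GC_DZ = function(frac, enr) {
      enr["DZ_GCB"] > 2 && frac["DZ_GCB"] > 0.2 &&
        frac["DZ_GCB"] > frac["LZ_GCB"]
    },
    Mantle = function(frac, enr) frac["NaiveB"] > 0.5,
    TZone = function(frac, enr) frac["nnCD4"] > 0.4 && frac["NaiveB"] <= 0.5,
    Epithelium = function(frac, enr) frac["Epithelium"] > 0.4
  )
}

#' Annotate cellular neighborhoods by declarative rules
#'
#' @param model a `cn_model`.
#' @param rules named list of predicates over (centroid fraction vector,
#'   enrichment vector); see [default_cn_rules()].
#' @return the model with its `annotation` field filled; a CN matched by two
#'   rules raises an ambiguity error naming both.
#' @export
annotate_cn <- function(model, rules = default_cn_rules()) {
  stopifnot(inherits(model, "cn_model"))
  ann <- setNames(rep("Other", model$n_cn), rownames(model$centroids))
  for (cn in seq_len(model$n_cn)) {
    hits <- names(rules)[vapply(rules, function(rule)
      isTRUE(rule(model$centroids[cn, ], model$enrichment[cn, ])), FALSE)]
    if (length(hits) > 1) {
      stop("annotation ambiguity error: CN", cn - 1L,
           " matched by rules: ", paste(hits, collapse = ", "),
           call. = FALSE)
    }
    if (length(hits) == 1) ann[cn] <- hits
  }
  model$annotation <- ann
  model
}

# Rasterize points to a logical bin grid covering the cells' bounding box.
rasterize_points <- function(x, y, origin, bin_um, dims) {
  ix <- pmin(pmax(floor((x - origin[1]) / bin_um) + 1L, 1L), dims[1])
  iy <- pmin(pmax(floor((y - origin[2]) / bin_um) + 1L, 1L), dims[2])
  grid <- matrix(FALSE, dims[1], dims[2])
  grid[cbind(ix, iy)] <- TRUE
  grid
}

#' Close and hole-fill a binary raster
#'
#' Binary closing with a disc structuring element bridges gaps between
#' rasterized cells; hole filling then sets every background component not
#' connected to the raster border. Iterated to a fixed point so the operator
#' is exactly idempotent and monotone (output is a superset of the input).
#'
#' @param grid logical matrix.
#' @param closing_radius disc radius in bins (0 skips closing).
#' @return logical matrix of the same dimensions.
#' @export
close_and_fill <- function(grid, closing_radius = 2L) {
  brush <- if (closing_radius > 0) {
    EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
  }
  cur <- grid
  for (iter in 1:10) {
    img <- matrix(as.numeric(cur), nrow(cur), ncol(cur))
    if (!is.null(brush)) img <- EBImage::closing(img, brush)
    nxt <- matrix(as.logical(EBImage::fillHull(img > 0.5)),
                  nrow(cur), ncol(cur)) | cur
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

#' Build the merged, hole-filled GC mask
#'
#' Merges the cells of the GC-annotated neighborhoods onto a raster grid,
#' applies binary closing to bridge inter-cell gaps, and fills every
#' enclosed hole (background regions not reachable from the raster border),
#' so that neighborhoods interspersed inside the merged GC compartment are
#' included. Each cell is then in-GC iff its containing bin is set.
#'
#' @param cells cell table.
#' @param model annotated `cn_model`.
#' @param gc_cn_ids 0-based ids of the CNs to merge; defaults to all CNs
#'   annotated GC_LZ or GC_DZ.
#' @param bin_um raster bin size, micrometres.
#' @param closing_radius closing radius in bins.
#' @return a list classed `region_mask`: `raster` (logical matrix, x bins by
#'   y bins), `origin`, `bin_um`, `in_gc` (named per-cell logical), and
#'   `provenance`.
#' @export
merge_gc_mask <- function(cells, model, gc_cn_ids = NULL, bin_um = 20,
                          closing_radius = 2L) {
  cells <- validate_cell_table(cells)
  if (is.null(gc_cn_ids)) {
    gc_cn_ids <- which(model$annotation %in% c("GC_LZ", "GC_DZ")) - 1L
  }
  if (length(gc_cn_ids) == 0) {
    stop("mask error: gc_cn_ids is empty (no GC-annotated neighborhoods)",
         call. = FALSE)
  }
  cn <- model$cn_id[cells$cell_id]
  is_gc_cell <- cn %in% gc_cn_ids
  origin <- c(min(cells$x), min(cells$y))
  dims <- c(max(1L, ceiling((max(cells$x) - origin[1]) / bin_um + 1e-9) + 1L),
            max(1L, ceiling((max(cells$y) - origin[2]) / bin_um + 1e-9) + 1L))
  if (!any(is_gc_cell)) {
    warning("mask warning: no cells assigned to any GC neighborhood; ",
            "mask is all-false")
    raster <- matrix(FALSE, dims[1], dims[2])
  } else {
    raster <- rasterize_points(cells$x[is_gc_cell], cells$y[is_gc_cell],
                               origin, bin_um, dims)
    raster <- close_and_fill(raster, closing_radius)
  }
  ix <- pmin(pmax(floor((cells$x - origin[1]) / bin_um) + 1L, 1L), dims[1])
  iy <- pmin(pmax(floor((cells$y - origin[2]) / bin_um) + 1L, 1L), dims[2])
  in_gc <- setNames(raster[cbind(ix, iy)], cells$cell_id)
  structure(list(raster = raster, origin = origin, bin_um = bin_um,
                 in_gc = in_gc,
                 provenance = list(gc_cn_ids = gc_cn_ids,
                                   closing_radius = closing_radius)),
            class = "region_mask")
}
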