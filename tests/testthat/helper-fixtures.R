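# Fixture builders and independent oracles shared across test files.

# Random scattered cells with uniform types.
make_cells <- function(n, seed = 1, sample_id = "S1", field = 1000,
                       types = GC_TYPE_L1) {
  set.seed(seed)
  data.frame(cell_id = sprintf("%s_c%04d", sample_id, seq_len(n)),
             x = runif(n, 0, field), y = runif(n, 0, field),
             sample_id = sample_id,
             type_l1 = sample(types, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Reduced-size tissue for multi-seed simulations.
small_tissue_config <- function(seed = 1, lambda = 0.1, swap_prob = 0.05,
                                overlap_prob = 0.03) {
  tissue_config(field_um = c(1500, 1500), n_follicles = 4L,
                follicle_radius_um = c(150, 180), mantle_um = 50,
                epithelium_um = 80,
                contamination = list(lambda = lambda, radius_um = 15,
                                     swap_prob = swap_prob,
                                     swap_fraction = 0.3,
                                     overlap_prob = overlap_prob,
                                     overlap_fraction = 0.5),
                seed = seed)
}

# Neighborhood -> mask -> PPV ranking, without the contrast stages.
ppv_from_tissue <- function(tis, cfg = analysis_config()) {
  comp <- knn_composition(tis$cells, cfg$k)
  model <- annotate_cn(cluster_neighborhoods(comp, cfg$n_cn,
                                             seed = stage_seed(cfg$seed, "cn")))
  mask <- merge_gc_mask(tis$cells, model, bin_um = cfg$bin_um,
                        closing_radius = cfg$closing_radius)
  pos <- call_positivity(tis$counts, cfg$positivity_threshold)
  tfh <- tis$cells$type_l1 == "Tfh"
  in_gc <- unname(mask$in_gc[tis$cells$cell_id])
  spec <- rank_percentile(gc_ppv(pos, tfh, in_gc, cfg$min_pos))
  list(spec = spec, mask = mask, model = model, tfh = tfh, in_gc = in_gc)
}

# Exact two-sided rank-sum p by exhaustive enumeration of group assignments
# (midranks, so ties are handled); feasible for combined sizes <= 16.
exact_wilcox_p <- function(x, y) {
  v <- c(x, y)
  n1 <- length(x); n <- length(v)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Fill background components not reachable from the raster border (BFS,
# 4-connectivity) — the hole-filling oracle.
flood_fill_oracle <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  reach <- matrix(FALSE, nr, nc)
  queue <- integer(0)
  push <- function(i, j) {
    if (i >= 1 && i <= nr && j >= 1 && j <= nc && !reach[i, j] && !grid[i, j]) {
      reach[i, j] <<- TRUE
      queue <<- c(queue, (j - 1L) * nr + i)
    }
  }
  for (i in 1:nr) { push(i, 1L); push(i, nc) }
  for (j in 1:nc) { push(1L, j); push(nr, j) }
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    i <- ((cur - 1L) %% nr) + 1L
    j <- ((cur - 1L) %/% nr) + 1L
    push(i - 1L, j); push(i + 1L, j); push(i, j - 1L); push(i, j + 1L)
  }
  grid | !reach
}

# Random blob raster: union of a few filled discs plus salt noise.
random_blob_raster <- function(seed, nr = 30, nc = 30) {
  set.seed(seed)
  g <- matrix(FALSE, nr, nc)
  for (b in seq_len(sample(2:4, 1))) {
    ci <- runif(1, 5, nr - 5); cj <- runif(1, 5, nc - 5)
    r <- runif(1, 2, 6)
    ij <- expand.grid(i = 1:nr, j = 1:nc)
    hit <- (ij$i - ci)^2 + (ij$j - cj)^2 <= r^2
    g[cbind(ij$i[hit], ij$j[hit])] <- TRUE
  }
  noise <- matrix(runif(nr * nc) < 0.02, nr, nc)
  g | noise
}

# Brute-force k nearest neighbours (self included) from the full distance
# matrix.
brute_knn_idx <- function(xy, k) {
  d <- as.matrix(dist(xy))
  t(apply(d, 1, function(row) order(row)[seq_len(k)]))
}
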