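test_that("positivity calls agree with elementwise comparison", {
  expect_false(call_positivity(matrix(0, 1, 1), 1)[1, 1])
  expect_true(call_positivity(matrix(1, 1, 1), 1)[1, 1])
  set.seed(3)
  m <- matrix(rpois(600, 1), 20, 30)
  expect_equal(unname(as.matrix(call_positivity(m, 2))), m >= 2)
})

test_that("gc_ppv equals the literal set-intersection computation", {
  # gene positive in 5 Tfh, 4 inside the GC -> ppv 0.8
  pos <- matrix(FALSE, 2, 10, dimnames = list(c("gA", "gB"), NULL))
  pos["gA", 1:5] <- TRUE
  tfh <- rep(TRUE, 10)
  in_gc <- c(rep(TRUE, 4), rep(FALSE, 6))
  rows <- gc_ppv(pos, tfh, in_gc, min_pos = 2)
  expect_equal(rows$ppv[rows$gene == "gA"], 0.8)
  expect_true(is.na(rows$ppv[rows$gene == "gB"]))   # 0 positive Tfh
  expect_false(rows$included[rows$gene == "gB"])

  # random fixture vs a literal intersection oracle
  set.seed(7)
  pos <- matrix(runif(50 * 40) < 0.3, 50, 40,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
  tfh <- runif(40) < 0.5
  in_gc <- runif(40) < 0.5
  rows <- gc_ppv(pos, tfh, in_gc, min_pos = 1)
  for (g in sample(rownames(pos), 10)) {
    p_cells <- which(pos[g, ] & tfh)
    expect_equal(rows$n_pos_tfh[rows$gene == g], length(p_cells))
    if (length(p_cells)) {
      expect_equal(rows$ppv[rows$gene == g],
                   length(intersect(p_cells, which(in_gc))) / length(p_cells))
    }
  }
  expect_error(gc_ppv(pos, rep(FALSE, 40), in_gc), "no Tfh")
})

test_that("percentile convention reproduces worked examples and monotonicity", {
  rows <- data.frame(gene = sprintf("g%04d", 1:5101),
                     n_pos_tfh = 100L, n_pos_tfh_in_gc = 50L,
                     ppv = seq(1, 0, length.out = 5101), included = TRUE)
  ranked <- rank_percentile(rows)
  expect_equal(ranked$percentile[ranked$rank == 25], 99.5)
  expect_equal(ranked$percentile[ranked$rank == 1], 100.0)
  expect_equal(ranked$percentile[ranked$rank == 5101],
               round(100 * (1 - 5100 / 5101), 1))
  # reported to one decimal, so monotone non-increasing; the underlying
  # convention is strictly decreasing in rank
  expect_true(all(diff(ranked$percentile[order(ranked$rank)]) <= 0))
  expect_true(all(diff(100 * (1 - (seq_len(5101) - 1) / 5101)) < 0))
})

test_that("ranking is invariant under positive monotone transforms of ppv", {
  set.seed(5)
  rows <- data.frame(gene = sprintf("g%02d", 1:30),
                     n_pos_tfh = sample(20:100, 30, TRUE),
                     n_pos_tfh_in_gc = 0L,
                     ppv = round(runif(30), 2), included = TRUE)
  r1 <- rank_percentile(rows)
  rows2 <- rows
  rows2$ppv <- rows$ppv^3 + 1          # strictly increasing transform
  r2 <- rank_percentile(rows2)
  expect_identical(r1$gene, r2$gene)
  expect_identical(r1$rank, r2$rank)
})

test_that("rank-sum p matches exact enumeration and handles degeneracy", {
  v123 <- matrix(c(1, 2, 3, 4, 5, 6), 1)
  expect_equal(exact_wilcox_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  res <- wilcoxon_contrast(v123, 1:3, 4:6)
  expect_lt(abs(res$p - 0.1), 0.02)

  # identical constants: p = 1, log2FC = 0
  const <- matrix(rep(2, 8), 1)
  res <- wilcoxon_contrast(const, 1:4, 5:8)
  expect_equal(res$p, 1)
  expect_equal(res$log2fc, 0)

  # untied small-sample sweep against the enumeration oracle: the
  # exhaustive worst case of the continuity-corrected approximation over
  # all untied configurations with groups of 3..8 is 0.0375 (at 3 vs 3,
  # mid-range p), so 0.04 is the frozen bound
  set.seed(31)
  for (i in 1:200) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    vals <- runif(n1 + n2)
    p_exact <- exact_wilcox_p(vals[seq_len(n1)], vals[n1 + seq_len(n2)])
    p_approx <- wilcoxon_contrast(matrix(vals, 1), seq_len(n1),
                                  n1 + seq_len(n2))$p
    expect_lt(abs(p_approx - p_exact), 0.04)
  }

  # cross-check the normal approximation against stats::wilcox.test
  set.seed(21)
  for (i in 1:20) {
    x <- rpois(30, 2); y <- rpois(25, 3)
    ours <- wilcoxon_contrast(matrix(c(x, y), 1), seq_along(x),
                              length(x) + seq_along(y))$p
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE)$p.value)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("contrasts are antisymmetric and validate their groups", {
  set.seed(4)
  vals <- matrix(rpois(200, 2), 4, 50,
                 dimnames = list(sprintf("g%d", 1:4), NULL))
  a <- wilcoxon_contrast(vals, 1:20, 21:50)
  b <- wilcoxon_contrast(vals, 21:50, 1:20)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  expect_true(all(a$p_adj >= a$p))
  expect_error(wilcoxon_contrast(vals, 1:10, 5:20), "overlap")
  expect_error(wilcoxon_contrast(vals, 1:2, 3:10), "at least 3")
})

test_that("nearest-target distances match brute force and flag missing samples", {
  q <- data.frame(cell_id = "q", x = 0, y = 0, sample_id = "S1",
                  type_l1 = "Tfh", stringsAsFactors = FALSE)
  t1 <- data.frame(cell_id = "t", x = 3, y = 4, sample_id = "S1",
                   type_l1 = "LZ_GCB", stringsAsFactors = FALSE)
  d <- distance_to_nearest(rbind(q, t1), c(FALSE, TRUE))
  expect_equal(unname(d["q"]), 5)
  expect_equal(unname(d["t"]), 0)

  cells <- make_cells(400, seed = 12)
  target <- cells$type_l1 == "LZ_GCB"
  d <- distance_to_nearest(cells, target)
  dm <- as.matrix(dist(cells[, c("x", "y")]))
  oracle <- apply(dm[, target, drop = FALSE], 1, min)
  expect_equal(unname(d), unname(oracle), tolerance = 1e-9,
               ignore_attr = TRUE)

  cells2 <- cells
  cells2$type_l1[cells2$sample_id == "S1"] <- "Tfh"
  d2 <- distance_to_nearest(cells2, cells2$type_l1 == "LZ_GCB")
  expect_true(all(is.na(d2)))
  expect_equal(attr(d2, "missing_target_samples"), "S1")
})

test_that("decay curves reproduce constants, limits, and planted decay lengths", {
  set.seed(10)
  d <- runif(500, 0, 300)
  curve <- smoothed_decay(rep(3, 500), d)
  expect_true(all(abs(curve$value - 3) < 1e-9))

  # infinite-bandwidth limit: global mean everywhere
  e <- rnorm(500, 5)
  curve <- smoothed_decay(e, d, bandwidth = 1e9)
  expect_true(all(abs(curve$value - mean(e)) < 1e-6))

  # exponential decay length recovery within 20%
  d0 <- 50
  expr <- exp(-d / d0) * exp(rnorm(500, 0, 0.1))
  curve <- smoothed_decay(expr, d, bandwidth = 25)
  mid <- curve$distance >= 50 & curve$distance <= 250 & curve$value > 0
  fit <- lm(log(curve$value[mid]) ~ curve$distance[mid])
  expect_lt(abs(-1 / coef(fit)[2] - d0) / d0, 0.2)

  # sparse far field: grid points with no cell within 3 bandwidths are NA
  curve <- smoothed_decay(c(1, 2), c(0, 10), bandwidth = 5,
                          grid = c(0, 10, 200))
  expect_true(is.na(curve$value[3]))
  expect_error(smoothed_decay(numeric(0), numeric(0)), "no usable")
})

test_that("three-way integration conserves gene sets and validates panels", {
  ref <- generate_dissociated_reference(n_cells = 400, seed = 5)
  tis <- generate_tissue(small_tissue_config(seed = 5))
  tfh <- tis$cells$type_l1 == "Tfh"
  in_gc <- tis$truth$cells$true_region %in% c("GC_LZ", "GC_DZ")
  tw <- three_way_specificity(tis$counts, tfh, in_gc, ref$counts,
                              ref$labels$label == "Tfh")
  expect_true(all(tw$gene %in% rownames(tis$counts)))
  expect_true(all(tw$gene %in% rownames(ref$counts)))
  sub <- ref$counts
  rownames(sub) <- paste0("ZZZ_", rownames(sub))
  expect_error(three_way_specificity(tis$counts, tfh, in_gc, sub,
                                     ref$labels$label == "Tfh"),
               "empty gene panel")
})
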