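test_that("generated cell count matches the point-process expectation", {
  cfg <- small_tissue_config(seed = 1)
  tis <- generate_tissue(cfg)
  expect_lt(abs(nrow(tis$cells) - expected_cell_count(cfg)) /
              expected_cell_count(cfg), 0.10)
})

test_that("generation is deterministic in config and seed", {
  a <- generate_tissue(small_tissue_config(seed = 5))
  b <- generate_tissue(small_tissue_config(seed = 5))
  expect_identical(a$cells, b$cells)
  expect_true(all(a$counts == b$counts))
  c <- generate_tissue(small_tissue_config(seed = 6))
  expect_false(nrow(c$cells) == nrow(a$cells) &&
                 all(c$cells$x == a$cells$x))
})

test_that("true regions are recomputable from geometry", {
  cfg <- small_tissue_config(seed = 3)
  tis <- generate_tissue(cfg)
  # independent restatement of the geometric rule
  f <- tis$follicles
  oracle <- vapply(seq_len(nrow(tis$cells)), function(i) {
    x <- tis$cells$x[i]; y <- tis$cells$y[i]
    if (x <= cfg$epithelium_um) reg <- "Epithelium" else reg <- "TZone"
    for (k in seq_len(nrow(f))) {
      d <- sqrt((x - f$cx[k])^2 + (y - f$cy[k])^2)
      if (d <= f$r[k]) {
        proj <- (x - f$cx[k]) * cos(f$theta[k]) +
          (y - f$cy[k]) * sin(f$theta[k])
        reg <- if (proj >= 0) "GC_LZ" else "GC_DZ"
      } else if (d <= f$r[k] + cfg$mantle_um) {
        reg <- "Mantle"
      }
    }
    reg
  }, character(1))
  expect_identical(tis$truth$cells$true_region, oracle)
})

test_that("zero contamination leaves counts untouched and restricted genes in place", {
  cfg <- small_tissue_config(seed = 2, lambda = 0, swap_prob = 0,
                             overlap_prob = 0)
  # make the flagship gene strictly GC-Tfh-only (zero modifier elsewhere)
  gt <- cfg$gene_table
  flag <- gt$gene == "GCTFH1"
  gt[flag, grep("^m_", names(gt))] <- 0
  gt$m_tfh_gc[flag] <- 60
  cfg$gene_table <- gt
  tis <- generate_tissue(cfg)
  expect_true(all(tis$counts == tis$clean_counts))
  # with modifier 0 elsewhere, every positive cell is a GC-positioned Tfh
  pos <- as.numeric(tis$counts["GCTFH1", ]) >= 1
  tfh <- tis$cells$type_l1 == "Tfh"
  in_gc <- tis$truth$cells$true_region %in% c("GC_LZ", "GC_DZ")
  expect_gt(sum(pos), 0)
  expect_true(all(tfh[pos] & in_gc[pos]))
})

test_that("diffusion and swap conserve per-gene totals; overlap additions are logged", {
  cfg <- small_tissue_config(seed = 4, overlap_prob = 0)
  tis <- generate_tissue(cfg)
  expect_equal(Matrix::rowSums(tis$counts), Matrix::rowSums(tis$clean_counts))
  expect_equal(attr(tis$counts, "overlap_added"), 0)

  cfg2 <- small_tissue_config(seed = 4)
  tis2 <- generate_tissue(cfg2)
  expect_equal(sum(tis2$counts) - attr(tis2$counts, "overlap_added"),
               sum(tis2$clean_counts))
})

test_that("an isolated cell with no neighbour in range keeps its counts", {
  cells <- data.frame(cell_id = c("a", "b"), x = c(0, 500), y = c(0, 0),
                      sample_id = "S1", type_l1 = "Tfh",
                      stringsAsFactors = FALSE)
  counts <- Matrix::Matrix(matrix(c(10, 7), 1, 2,
                                  dimnames = list("g1", c("a", "b"))),
                           sparse = TRUE)
  out <- apply_contamination(counts, cells,
                             list(lambda = 1, radius_um = 15,
                                  swap_prob = 0, overlap_prob = 0),
                             seed = 1)
  expect_equal(as.numeric(out), c(10, 7))
})

test_that("diffusion retains the expected donor fraction on a 3-cell line", {
  cells <- data.frame(cell_id = c("a", "b", "c"), x = c(0, 10, 20), y = 0,
                      sample_id = "S1", type_l1 = "Tfh",
                      stringsAsFactors = FALSE)
  n0 <- 100
  counts <- Matrix::Matrix(matrix(c(n0, 0, 0), 1, 3,
                                  dimnames = list("g1", cells$cell_id)),
                           sparse = TRUE)
  lam <- 0.2
  kept <- vapply(1:1000, function(s) {
    out <- apply_contamination(counts, cells,
                               list(lambda = lam, radius_um = 15,
                                    swap_prob = 0, overlap_prob = 0),
                               seed = s)
    expect_equal(sum(out), n0)   # column-sum conservation every draw
    out[1, "a"]
  }, numeric(1))
  # Monte-Carlo mean of retained counts vs the Binomial expectation
  expect_lt(abs(mean(kept) / n0 - (1 - lam)), 0.01)
})

test_that("contamination parameter validation fires", {
  cells <- make_cells(5)
  counts <- Matrix::Matrix(0, 2, 5, sparse = TRUE,
                           dimnames = list(c("g1", "g2"), cells$cell_id))
  expect_error(apply_contamination(counts, cells,
                                   list(lambda = 0.5, radius_um = 0)),
               "radius_um")
  expect_error(apply_contamination(counts, cells, list(lambda = 1.5)),
               "lambda")
})

test_that("dissociated reference recovers planted lineage contrasts", {
  ref <- generate_dissociated_reference(seed = 8)
  expect_identical(colnames(ref$counts), ref$labels$cell_id)
  tfh <- ref$labels$label == "Tfh"
  res <- wilcoxon_contrast(ref$counts, which(tfh), which(!tfh))
  expect_gt(res$log2fc[res$gene == "GCTFH1"], 1)
  expect_gt(res$log2fc[res$gene == "PANTFH01"], 1)
  expect_lt(res$log2fc[res$gene == "GCBLZ01"], -1)
  # housekeeping genes have identical planted means in every lineage, so
  # their fold changes are pure sampling error: standardised by the
  # delta-method standard error of log2(mean ratio) under the planted
  # negative binomial, they behave like half-normal draws
  hk <- grepl("^HK", res$gene)
  mu <- ref$type_means[res$gene[hk], "Tfh"]
  v <- mu + mu^2 / 2                      # NB variance at dispersion 2
  n1 <- sum(tfh); n2 <- sum(!tfh)
  sd_lfc <- sqrt(v * (1 / n1 + 1 / n2)) / (mu * log(2))
  z <- abs(res$log2fc[hk]) / sd_lfc
  expect_lt(max(z), 4.5)
  expect_lt(mean(z), 1.5)

  again <- generate_dissociated_reference(seed = 8)
  expect_true(all(ref$counts == again$counts))
  expect_error(generate_dissociated_reference(lineage_probs = c(Tfh = 1)),
               "at least 2 lineages")
})

test_that("gene activity is a monotone transform of planted means, degraded by noise", {
  ref <- generate_dissociated_reference(n_cells = 300, seed = 2)
  act0 <- generate_gene_activity(ref, noise_sd = 0, seed = 3)
  cell1 <- ref$labels$cell_id[1]
  mu <- ref$type_means[, ref$labels$label[1]]
  expect_equal(cor(act0[, cell1], log1p(mu), method = "spearman"), 1)
  # rank correlation decays toward 0 as noise dominates
  cors <- vapply(c(0.1, 1, 10, 100), function(s) {
    act <- generate_gene_activity(ref, noise_sd = s, seed = 3)
    cor(act[, cell1], log1p(mu), method = "spearman")
  }, numeric(1))
  expect_true(all(diff(abs(cors)) < 0.2))   # non-increasing up to jitter
  expect_lt(abs(cors[4]), 0.3)
  expect_error(generate_gene_activity(ref, noise_sd = -1), "noise_sd")
})

test_that("planted >=4-fold effects are Bonferroni-significant at n = 500 per group", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    g1 <- rnbinom(500, mu = 0.8, size = 2)
    g2 <- rnbinom(500, mu = 0.2, size = 2)
    vals <- matrix(c(g1, g2), 1, dimnames = list("g", NULL))
    res <- wilcoxon_contrast(vals, seq_len(500), 500 + seq_len(500))
    res$p * 200 < 0.05   # Bonferroni at a 200-gene panel
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
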