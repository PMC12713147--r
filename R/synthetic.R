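TISSUE_REGIONS <- c("GC_LZ", "GC_DZ", "Mantle", "TZone", "Epithelium")

#' Default region-conditioned cell-type composition
#'
#' Probability of each level-1 type given the microanatomic region, loosely
#' calibrated to tonsil histology: follicle cores dominated by zone-specific
#' GC B cells with interspersed Tfh and FDC, a naive-B mantle, a CD4-rich
#' interfollicular T zone, and a surface epithelial band. Rows sum to 1.
#'
#' @return a region-by-type probability matrix.
#' @export
default_region_composition <- function() {
  m <- rbind(
    GC_LZ      = c(Tfh = 0.15, nnCD4 = 0.04, LZ_GCB = 0.52, DZ_GCB = 0.04,
                   NaiveB = 0.05, FDC = 0.14, Epithelium = 0.00, Other = 0.06),
    GC_DZ      = c(Tfh = 0.07, nnCD4 = 0.04, LZ_GCB = 0.06, DZ_GCB = 0.63,
                   NaiveB = 0.07, FDC = 0.03, Epithelium = 0.00, Other = 0.10),
    Mantle     = c(Tfh = 0.05, nnCD4 = 0.10, LZ_GCB = 0.01, DZ_GCB = 0.01,
                   NaiveB = 0.70, FDC = 0.01, Epithelium = 0.00, Other = 0.12),
    TZone      = c(Tfh = 0.10, nnCD4 = 0.52, LZ_GCB = 0.01, DZ_GCB = 0.01,
                   NaiveB = 0.18, FDC = 0.01, Epithelium = 0.01, Other = 0.16),
    Epithelium = c(Tfh = 0.01, nnCD4 = 0.06, LZ_GCB = 0.00, DZ_GCB = 0.00,
                   NaiveB = 0.05, FDC = 0.00, Epithelium = 0.78, Other = 0.10))
  stopifnot(all(abs(rowSums(m) - 1) < 1e-12))
  m
}

#' Default synthetic gene panel
#'
#' A 200-gene program table covering seven expression classes with graded
#' restriction to the GC niche. Each row gives a baseline negative-binomial
#' mean plus fold multipliers applied by cell type, with Tfh split into
#' GC-positioned versus non-GC-positioned states (the only type whose program
#' is region-conditioned). Classes:
#' \describe{
#'   \item{gc_tfh_restricted}{one flagship gene expressed almost exclusively
#'     by GC-positioned Tfh (the GNG4-like planted signal).}
#'   \item{pan_tfh}{expressed by Tfh regardless of position.}
#'   \item{gc_unrestricted}{GC-associated but leaky outside the GC (the
#'     BCL6/TOX2-like class), with moderate GC B cell expression.}
#'   \item{gcb_restricted}{zone-specific GC B cell programs — the class whose
#'     transcripts contaminate neighbouring Tfh inside GCs.}
#'   \item{fdc_restricted}{follicular dendritic cell programs.}
#'   \item{nongc_tfh}{Tfh programs of the mantle/T-zone (RORC-like).}
#'   \item{housekeeping}{uniform across all cells, varied baselines.}
#' }
#' Restricted classes keep a small nonspecific floor (baseline x 0.4)
#' emulating probe background.
#'
#' @param seed seed for the housekeeping baseline draw.
#' @return data.frame with columns `gene`, `class`, `baseline`, and
#'   multiplier columns `m_tfh_gc`, `m_tfh_nongc`, `m_lzgcb`, `m_dzgcb`,
#'   `m_fdc`, `m_naiveb`, `m_nncd4`, `m_epithelium`, `m_other`.
#' @export
default_gene_panel <- function(seed = 99L) {
  row <- function(gene, class, baseline, tfh_gc = 0.4, tfh_nongc = 0.4,
                  lzgcb = 0.4, dzgcb = 0.4, fdc = 0.4, naiveb = 0.4,
                  nncd4 = 0.4, epithelium = 0.4, other = 0.4) {
    data.frame(gene = gene, class = class, baseline = baseline,
               m_tfh_gc = tfh_gc, m_tfh_nongc = tfh_nongc, m_lzgcb = lzgcb,
               m_dzgcb = dzgcb, m_fdc = fdc, m_naiveb = naiveb,
               m_nncd4 = nncd4, m_epithelium = epithelium, m_other = other,
               stringsAsFactors = FALSE)
  }
  pad <- function(p, i) sprintf("%s%02d", p, i)
  tab <- rbind(
    row("GCTFH1", "gc_tfh_restricted", 0.05, tfh_gc = 60),
    do.call(rbind, lapply(1:10, function(i)
      row(pad("PANTFH", i), "pan_tfh", 0.05, tfh_gc = 15, tfh_nongc = 15))),
    do.call(rbind, lapply(1:15, function(i)
      row(pad("GCUNR", i), "gc_unrestricted", 0.05, tfh_gc = 30,
          tfh_nongc = 8, lzgcb = 8, dzgcb = 8))),
    do.call(rbind, lapply(1:15, function(i)
      row(pad("GCBLZ", i), "gcb_restricted", 0.05, lzgcb = 80))),
    do.call(rbind, lapply(1:15, function(i)
      row(pad("GCBDZ", i), "gcb_restricted", 0.05, dzgcb = 80))),
    do.call(rbind, lapply(1:15, function(i)
      row(pad("FDCR", i), "fdc_restricted", 0.05, fdc = 80))),
    do.call(rbind, lapply(1:10, function(i)
      row(pad("NGTFH", i), "nongc_tfh", 0.05, tfh_nongc = 25))))
  n_hk <- 200L - nrow(tab)
  hk_base <- with_seed(seed, runif(n_hk, 0.05, 0.6))
  hk <- do.call(rbind, lapply(seq_len(n_hk), function(i)
    row(sprintf("HK%03d", i), "housekeeping", hk_base[i],
        tfh_gc = 1, tfh_nongc = 1, lzgcb = 1, dzgcb = 1, fdc = 1,
        naiveb = 1, nncd4 = 1, epithelium = 1, other = 1)))
  rbind(tab, hk)
}

#' Synthetic tonsil tissue configuration
#'
#' Defaults generate one ~30,000-cell tissue section of 3 x 3 mm with eight
#' follicles, a 200-gene panel, and moderate cell-to-cell contamination
#' (10\% transcript diffusion within 15 um, occasional segmentation swaps and
#' vertical overlaps).
#'
#' @param field_um field width and height, micrometres.
#' @param n_follicles number of non-overlapping follicles.
#' @param follicle_radius_um uniform range for follicle (GC core) radii.
#' @param mantle_um mantle annulus thickness.
#' @param lz_fraction fraction of the GC disk assigned to the light zone.
#' @param epithelium_um width of the epithelial band along the x = 0 edge.
#' @param densities per-region cell densities, cells per square micrometre.
#' @param composition region-by-type probability matrix (rows sum to 1).
#' @param gene_table gene program table (see [default_gene_panel()]).
#' @param dispersion negative-binomial size parameter (var = mu + mu^2/size).
#' @param contamination list with `lambda` (diffusion fraction in [0,1]),
#'   `radius_um`, `swap_prob`, `swap_fraction`, `overlap_prob`,
#'   `overlap_fraction`.
#' @param sample_id sample label stamped on generated cells.
#' @param seed master seed.
#' @return a list classed `tissue_config`.
#' @export
tissue_config <- function(field_um = c(3000, 3000), n_follicles = 8L,
                          follicle_radius_um = c(230, 270), mantle_um = 60,
                          lz_fraction = 0.5, epithelium_um = 120,
                          densities = c(GC_LZ = 0.0075, GC_DZ = 0.0075,
                                        Mantle = 0.007, TZone = 0.0018,
                                        Epithelium = 0.005),
                          composition = default_region_composition(),
                          gene_table = default_gene_panel(),
                          dispersion = 2.0,
                          contamination = list(lambda = 0.1, radius_um = 15,
                                               swap_prob = 0.05,
                                               swap_fraction = 0.3,
                                               overlap_prob = 0.03,
                                               overlap_fraction = 0.5),
                          sample_id = "S1", seed = 1L) {
  stopifnot(length(field_um) == 2, all(field_um > 0), n_follicles >= 1,
            length(follicle_radius_um) == 2, mantle_um > 0,
            lz_fraction > 0, lz_fraction < 1,
            all(TISSUE_REGIONS %in% names(densities)), all(densities > 0),
            all(abs(rowSums(composition) - 1) < 1e-9),
            dispersion > 0, all(gene_table$baseline >= 0))
  lam <- contamination$lambda
  if (lam < 0 || lam > 1) stop("contamination lambda must be in [0,1]")
  cfg <- list(field_um = field_um, n_follicles = as.integer(n_follicles),
              follicle_radius_um = follicle_radius_um, mantle_um = mantle_um,
              lz_fraction = lz_fraction, epithelium_um = epithelium_um,
              densities = densities[TISSUE_REGIONS], composition = composition,
              gene_table = gene_table, dispersion = dispersion,
              contamination = contamination, sample_id = sample_id,
              seed = as.integer(seed))
  class(cfg) <- "tissue_config"
  cfg
}

#' Closed-form expected cell count of a tissue configuration
#'
#' Expectation of the region-wise homogeneous Poisson point processes, using
#' the mean follicle disk area under the uniform radius distribution.
#'
#' @param config a [tissue_config()].
#' @return expected total number of cells (a double).
#' @export
expected_cell_count <- function(config) {
  a <- config$follicle_radius_um[1]; b <- config$follicle_radius_um[2]
  er2 <- (a^2 + a * b + b^2) / 3                 # E[r^2], r ~ U(a, b)
  emr2 <- ((a + config$mantle_um)^2 + (a + config$mantle_um) *
             (b + config$mantle_um) + (b + config$mantle_um)^2) / 3
  gc_area <- config$n_follicles * pi * er2
  mantle_area <- config$n_follicles * pi * (emr2 - er2)
  epi_area <- config$epithelium_um * config$field_um[2]
  total <- prod(config$field_um)
  tz_area <- total - gc_area - mantle_area - epi_area
  d <- config$densities
  unname(d["GC_LZ"] * gc_area * config$lz_fraction +
           d["GC_DZ"] * gc_area * (1 - config$lz_fraction) +
           d["Mantle"] * mantle_area + d["TZone"] * tz_area +
           d["Epithelium"] * epi_area)
}

# Place non-overlapping follicle centers by rejection sampling.
place_follicles <- function(config) {
  W <- config$field_um[1]; H <- config$field_um[2]
  margin <- 10
  out <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                    theta = numeric(0))
  for (i in seq_len(config$n_follicles)) {
    r <- runif(1, config$follicle_radius_um[1], config$follicle_radius_um[2])
    R <- r + config$mantle_um
    placed <- FALSE
    for (try in seq_len(1000L)) {
      cx <- runif(1, config$epithelium_um + R + margin, W - R - margin)
      cy <- runif(1, R + margin, H - R - margin)
      if (nrow(out) == 0 ||
          all(sqrt((out$cx - cx)^2 + (out$cy - cy)^2) >
              out$r + config$mantle_um + R + 2 * margin)) {
        out <- rbind(out, data.frame(cx = cx, cy = cy, r = r,
                                     theta = runif(1, 0, 2 * pi)))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("tissue generation error: could not place ", config$n_follicles,
           " non-overlapping follicles; try fewer or smaller follicles",
           call. = FALSE)
    }
  }
  out
}

#' Recompute true regions from coordinates and follicle geometry
#'
#' The geometric ground-truth rule: the epithelial band is `x <=
#' epithelium_um`; a point within a follicle radius is GC, split into LZ/DZ
#' by the follicle's random split axis; within radius + mantle it is Mantle;
#' everything else is T zone.
#'
#' @param x,y coordinates (micrometres).
#' @param follicles data.frame with `cx`, `cy`, `r`, `theta`.
#' @param config the [tissue_config()].
#' @return character vector of region labels.
#' @export
assign_region <- function(x, y, follicles, config) {
  region <- rep("TZone", length(x))
  region[x <= config$epithelium_um] <- "Epithelium"
  for (f in seq_len(nrow(follicles))) {
    dx <- x - follicles$cx[f]; dy <- y - follicles$cy[f]
    d <- sqrt(dx^2 + dy^2)
    in_mantle <- d <= follicles$r[f] + config$mantle_um
    in_gc <- d <= follicles$r[f]
    # split axis: LZ is the half-plane on the +u side of the center, where a
    # chord at quantile lz_fraction of the diameter would generalise; at the
    # default 0.5 the chord passes through the center.
    u <- c(cos(follicles$theta[f]), sin(follicles$theta[f]))
    proj <- dx * u[1] + dy * u[2]
    cut <- follicles$r[f] * (1 - 2 * config$lz_fraction)
    region[in_mantle] <- "Mantle"
    region[in_gc] <- ifelse(proj[in_gc] >= cut, "GC_LZ", "GC_DZ")
  }
  region
}

# Per-(type, gc-position) expected means for every gene in the table.
# Returns a genes x group matrix; group names like "Tfh.gc", "LZ_GCB.any".
gene_mean_matrix <- function(gene_table) {
  g <- gene_table
  m <- cbind(Tfh.gc = g$m_tfh_gc, Tfh.nongc = g$m_tfh_nongc,
             LZ_GCB.any = g$m_lzgcb, DZ_GCB.any = g$m_dzgcb,
             FDC.any = g$m_fdc, NaiveB.any = g$m_naiveb,
             nnCD4.any = g$m_nncd4, Epithelium.any = g$m_epithelium,
             Other.any = g$m_other)
  m <- m * g$baseline
  rownames(m) <- g$gene
  m
}

mean_group_of <- function(type, region) {
  in_gc <- region %in% c("GC_LZ", "GC_DZ")
  ifelse(type == "Tfh", ifelse(in_gc, "Tfh.gc", "Tfh.nongc"),
         paste0(type, ".any"))
}

#' Generate a synthetic tonsil tissue section with known ground truth
#'
#' Places non-overlapping follicles (LZ/DZ half-disks plus a mantle annulus)
#' in a field with an epithelial band and an interfollicular T zone; places
#' cells by region-wise homogeneous Poisson point processes; samples types
#' from the region composition and counts from per-(gene, cell)
#' negative-binomial distributions; then applies the configured cell-to-cell
#' contamination. Ground truth (regions, types, gene classes, planted in-GC
#' positivity fractions) is recorded before contamination.
#'
#' @param config a [tissue_config()].
#' @return list with `cells` (cell table), `counts` (contaminated sparse
#'   gene-by-cell matrix), `clean_counts` (pre-contamination), `truth`
#'   (list `cells` and `genes` data.frames), and `follicles`.
#' @export
generate_tissue <- function(config = tissue_config()) {
  stopifnot(inherits(config, "tissue_config"))
  with_seed(stage_seed(config$seed, "tissue"), {
    follicles <- place_follicles(config)
    W <- config$field_um[1]; H <- config$field_um[2]
    d <- config$densities
    pts <- list()
    # follicle cores and mantles
    for (f in seq_len(nrow(follicles))) {
      R <- follicles$r[f] + config$mantle_um
      core_rate <- max(d["GC_LZ"], d["GC_DZ"])
      n <- rpois(1, core_rate * pi * follicles$r[f]^2)
      rr <- follicles$r[f] * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
      pts[[length(pts) + 1]] <- cbind(follicles$cx[f] + rr * cos(th),
                                      follicles$cy[f] + rr * sin(th))
      n <- rpois(1, d["Mantle"] * pi * (R^2 - follicles$r[f]^2))
      rr <- sqrt(runif(n, follicles$r[f]^2, R^2)); th <- runif(n, 0, 2 * pi)
      pts[[length(pts) + 1]] <- cbind(follicles$cx[f] + rr * cos(th),
                                      follicles$cy[f] + rr * sin(th))
    }
    # epithelial band
    n <- rpois(1, d["Epithelium"] * config$epithelium_um * H)
    pts[[length(pts) + 1]] <- cbind(runif(n, 0, config$epithelium_um),
                                    runif(n, 0, H))
    # T zone by thinning a field-wide process
    n <- rpois(1, d["TZone"] * W * H)
    cand <- cbind(runif(n, 0, W), runif(n, 0, H))
    keep <- assign_region(cand[, 1], cand[, 2], follicles, config) == "TZone"
    pts[[length(pts) + 1]] <- cand[keep, , drop = FALSE]

    xy <- do.call(rbind, pts)
    region <- assign_region(xy[, 1], xy[, 2], follicles, config)
    # thin unequal LZ/DZ densities down from the common core rate
    core_rate <- max(d["GC_LZ"], d["GC_DZ"])
    acc <- rep(TRUE, nrow(xy))
    lz <- region == "GC_LZ"; dz <- region == "GC_DZ"
    acc[lz] <- runif(sum(lz)) < d["GC_LZ"] / core_rate
    acc[dz] <- runif(sum(dz)) < d["GC_DZ"] / core_rate
    xy <- xy[acc, , drop = FALSE]; region <- region[acc]
    n_cells <- nrow(xy)

    comp <- config$composition
    type <- character(n_cells)
    for (rg in TISSUE_REGIONS) {
      idx <- which(region == rg)
      if (length(idx)) {
        type[idx] <- sample(colnames(comp), length(idx), replace = TRUE,
                            prob = comp[rg, ])
      }
    }
    cell_id <- sprintf("%s_c%06d", config$sample_id, seq_len(n_cells))
    cells <- data.frame(cell_id = cell_id, x = xy[, 1], y = xy[, 2],
                        sample_id = config$sample_id, type_l1 = type,
                        stringsAsFactors = FALSE)
    cells <- validate_cell_table(cells)

    # clean counts: negative binomial per (gene, cell)
    mu_mat <- gene_mean_matrix(config$gene_table)
    grp <- mean_group_of(type, region)
    counts <- matrix(0, nrow(mu_mat), n_cells,
                     dimnames = list(rownames(mu_mat), cell_id))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      mu <- mu_mat[, g]
      counts[, idx] <- rnbinom(length(mu) * length(idx),
                               mu = rep(mu, length(idx)),
                               size = config$dispersion)
    }
    clean <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  })

  contaminated <- apply_contamination(
    clean, cells, config$contamination,
    seed = stage_seed(config$seed, "contamination"))

  thr <- 1L
  tfh <- cells$type_l1 == "Tfh"
  in_gc_true <- region %in% c("GC_LZ", "GC_DZ")
  pos <- clean[, tfh, drop = FALSE] >= thr
  n_pos <- Matrix::rowSums(pos)
  n_pos_gc <- Matrix::rowSums(pos[, in_gc_true[tfh], drop = FALSE])
  truth_genes <- data.frame(gene = config$gene_table$gene,
                            class = config$gene_table$class,
                            planted_gc_fraction =
                              ifelse(n_pos > 0, n_pos_gc / n_pos, NA_real_),
                            n_pos_tfh_clean = as.integer(n_pos),
                            stringsAsFactors = FALSE)
  truth_cells <- data.frame(cell_id = cells$cell_id, true_region = region,
                            true_type = cells$type_l1,
                            stringsAsFactors = FALSE)
  list(cells = cells, counts = contaminated, clean_counts = clean,
       truth = list(cells = truth_cells, genes = truth_genes,
                    positivity_threshold = thr),
       follicles = follicles)
}

#' Apply cell-to-cell contamination to a clean count matrix
#'
#' Models the three contamination channels of imaging-based spatial assays at
#' the assigned-count level:
#' \itemize{
#' \item \emph{transcript diffusion}: for each cell a Binomial(count, lambda)
#'   portion of each gene's transcripts is reassigned to neighbours within
#'   `radius_um`, with probability proportional to a Gaussian kernel of scale
#'   `radius_um / 2` truncated at the radius. Cells with no neighbour in
#'   range retain their counts. Per-gene totals are conserved exactly.
#' \item \emph{segmentation swap}: with probability `swap_prob` a cell
#'   exchanges a Binomial(`swap_fraction`) portion of each gene's counts with
#'   its nearest neighbour. Conservative.
#' \item \emph{vertical overlap}: with probability `overlap_prob` a cell
#'   additively receives a Binomial(`overlap_fraction`) copy of its nearest
#'   neighbour's profile, mimicking two stacked cells segmented as one. This
#'   channel adds counts; the additions are logged in the
#'   `overlap_added` attribute so conservation checks can exclude them.
#' }
#'
#' @param counts clean sparse gene-by-cell matrix.
#' @param cells matching cell table (positions used for neighbour search,
#'   within sample only).
#' @param params contamination parameter list (see [tissue_config()]).
#' @param seed RNG seed for this stage.
#' @return contaminated sparse matrix with an `overlap_added` attribute
#'   (total counts added by the overlap channel).
#' @export
apply_contamination <- function(counts, cells, params, seed = 1L) {
  lam <- params$lambda %||% 0
  swap_p <- params$swap_prob %||% 0
  over_p <- params$overlap_prob %||% 0
  if (lam < 0 || lam > 1) stop("contamination parameter error: lambda not in [0,1]")
  if (lam > 0 && (is.null(params$radius_um) || params$radius_um <= 0)) {
    stop("contamination parameter error: radius_um must be > 0 when lambda > 0")
  }
  if (lam == 0 && swap_p == 0 && over_p == 0) {
    attr(counts, "overlap_added") <- 0
    return(counts)
  }
  validate_pairing(cells, counts)
  counts <- methods::as(counts, "CsparseMatrix")
  n <- ncol(counts)
  xy <- as.matrix(cells[, c("x", "y")])

  apply_delta <- function(m, rem_i, rem_j, rem_x, add_i, add_j, add_x) {
    if (!length(rem_i) && !length(add_i)) return(m)
    delta <- Matrix::sparseMatrix(i = c(rem_i, add_i), j = c(rem_j, add_j),
                                  x = c(-rem_x, add_x), dims = dim(m))
    methods::as(m + delta, "CsparseMatrix")
  }

  out <- with_seed(seed, {
    ## --- diffusion ---
    if (lam > 0) {
      trip <- Matrix::summary(counts)   # i = gene, j = cell, x = count
      add_i <- integer(0); add_j <- integer(0); add_x <- numeric(0)
      rem_i <- integer(0); rem_j <- integer(0); rem_x <- numeric(0)
      r <- params$radius_um
      kmax <- min(n, 31L)
      nb <- RANN::nn2(xy, xy, k = kmax, searchtype = "radius", radius = r)
      same_sample <- matrix(cells$sample_id[pmax(nb$nn.idx, 1L)] ==
                              rep(cells$sample_id, kmax), n, kmax)
      valid <- nb$nn.idx > 0 & nb$nn.idx != seq_len(n) & same_sample
      w <- exp(-nb$nn.dists^2 / (2 * (r / 2)^2)) * valid
      has_nb <- rowSums(valid) > 0
      cw <- t(apply(w, 1, cumsum))
      tot <- cw[, kmax]
      cw <- cw / ifelse(tot > 0, tot, 1)

      src_ok <- has_nb[trip$j]
      moved <- integer(nrow(trip))
      moved[src_ok] <- rbinom(sum(src_ok), trip$x[src_ok], lam)
      mv <- moved > 0
      if (any(mv)) {
        # expand to unit transcripts and draw recipients by inverse CDF
        src <- rep(trip$j[mv], moved[mv])
        gene <- rep(trip$i[mv], moved[mv])
        u <- runif(length(src))
        pick <- rowSums(u > cw[src, , drop = FALSE]) + 1L
        pick <- pmin(pick, kmax)
        recip <- nb$nn.idx[cbind(src, pick)]
        # guard: if the pick landed on an invalid slot, route to the first
        # valid neighbour of that source cell
        badpick <- !valid[cbind(src, pick)]
        if (any(badpick)) {
          first_valid <- apply(valid, 1, function(v) which(v)[1])
          recip[badpick] <- nb$nn.idx[cbind(src[badpick],
                                            first_valid[src[badpick]])]
        }
        rem_i <- c(rem_i, trip$i[mv]); rem_j <- c(rem_j, trip$j[mv])
        rem_x <- c(rem_x, moved[mv])
        add_i <- c(add_i, gene); add_j <- c(add_j, recip)
        add_x <- c(add_x, rep(1, length(gene)))
      }
      counts <- apply_delta(counts, rem_i, rem_j, rem_x, add_i, add_j, add_x)
    }

    partner <- rep(NA_integer_, n)
    if ((swap_p > 0 || over_p > 0) && n >= 2) {
      nn1 <- RANN::nn2(xy, xy, k = min(n, 2L))
      partner <- nn1$nn.idx[, min(ncol(nn1$nn.idx), 2L)]
      partner[cells$sample_id[partner] != cells$sample_id] <- NA_integer_
    }

    ## --- segmentation swap (drawn on the post-diffusion matrix; each cell
    ## participates in at most one exchange so removals never exceed counts)
    if (swap_p > 0) {
      trip <- Matrix::summary(counts)
      col_rows <- split(seq_len(nrow(trip)),
                        factor(trip$j, levels = seq_len(n)))
      add_i <- integer(0); add_j <- integer(0); add_x <- numeric(0)
      rem_i <- integer(0); rem_j <- integer(0); rem_x <- numeric(0)
      sel <- which(runif(n) < swap_p & !is.na(partner))
      used <- logical(n)
      for (j in sel) {
        m <- partner[j]
        if (used[j] || used[m]) next
        used[j] <- used[m] <- TRUE
        for (pair in list(c(j, m), c(m, j))) {
          rows <- col_rows[[pair[1]]]
          if (length(rows)) {
            mv <- rbinom(length(rows), trip$x[rows], params$swap_fraction)
            nz <- mv > 0
            if (any(nz)) {
              rem_i <- c(rem_i, trip$i[rows][nz]); rem_j <- c(rem_j, rep(pair[1], sum(nz)))
              rem_x <- c(rem_x, mv[nz])
              add_i <- c(add_i, trip$i[rows][nz]); add_j <- c(add_j, rep(pair[2], sum(nz)))
              add_x <- c(add_x, mv[nz])
            }
          }
        }
      }
      counts <- apply_delta(counts, rem_i, rem_j, rem_x, add_i, add_j, add_x)
    }

    ## --- vertical overlap (additive; logged) ---
    overlap_added <- 0
    if (over_p > 0) {
      trip <- Matrix::summary(counts)
      col_rows <- split(seq_len(nrow(trip)),
                        factor(trip$j, levels = seq_len(n)))
      add_i <- integer(0); add_j <- integer(0); add_x <- numeric(0)
      sel <- which(runif(n) < over_p & !is.na(partner))
      for (j in sel) {
        m <- partner[j]
        rows <- col_rows[[m]]
        if (length(rows)) {
          cp <- rbinom(length(rows), trip$x[rows], params$overlap_fraction)
          nz <- cp > 0
          if (any(nz)) {
            add_i <- c(add_i, trip$i[rows][nz]); add_j <- c(add_j, rep(j, sum(nz)))
            add_x <- c(add_x, cp[nz])
            overlap_added <- overlap_added + sum(cp[nz])
          }
        }
      }
      counts <- apply_delta(counts, integer(0), integer(0), numeric(0),
                            add_i, add_j, add_x)
    }

    attr(counts, "overlap_added") <- overlap_added
    counts
  })
  stopifnot(all(out@x >= 0))
  dimnames(out) <- dimnames(counts)
  out
}

#' Generate a dissociated single-cell reference with lineage labels
#'
#' Contamination-free counts for labelled lineages sharing the tissue
#' generator's gene programs, standing in for a dissociated trimodal RNA
#' reference. Reference Tfh are a mixture of GC- and non-GC-positioned
#' programs with weight `gc_weight`, since dissociation erases position.
#'
#' @param gene_table gene program table.
#' @param n_cells total reference cells.
#' @param lineage_probs named sampling probabilities over lineages (>= 2).
#' @param gc_weight fraction of the GC-positioned program mixed into the
#'   reference Tfh mean.
#' @param dispersion negative-binomial size.
#' @param seed RNG seed.
#' @return list with `counts` (sparse gene-by-cell), `labels` (data.frame
#'   `cell_id`, `label`), and `type_means` (gene-by-lineage planted means).
#' @export
generate_dissociated_reference <- function(gene_table = default_gene_panel(),
                                           n_cells = 2000L,
                                           lineage_probs = c(Tfh = 0.15,
                                                             nnCD4 = 0.30,
                                                             LZ_GCB = 0.15,
                                                             DZ_GCB = 0.15,
                                                             NaiveB = 0.20,
                                                             FDC = 0.05),
                                           gc_weight = 0.5, dispersion = 2.0,
                                           seed = 1L) {
  if (length(lineage_probs) < 2) {
    stop("reference parameter error: at least 2 lineages required")
  }
  mu_mat <- gene_mean_matrix(gene_table)
  type_means <- sapply(names(lineage_probs), function(tp) {
    if (tp == "Tfh") {
      gc_weight * mu_mat[, "Tfh.gc"] + (1 - gc_weight) * mu_mat[, "Tfh.nongc"]
    } else mu_mat[, paste0(tp, ".any")]
  })
  with_seed(seed, {
    label <- sample(names(lineage_probs), n_cells, replace = TRUE,
                    prob = lineage_probs)
    cell_id <- sprintf("ref_c%05d", seq_len(n_cells))
    counts <- matrix(0, nrow(mu_mat), n_cells,
                     dimnames = list(rownames(mu_mat), cell_id))
    for (tp in unique(label)) {
      idx <- which(label == tp)
      counts[, idx] <- rnbinom(nrow(mu_mat) * length(idx),
                               mu = rep(type_means[, tp], length(idx)),
                               size = dispersion)
    }
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"),
         labels = data.frame(cell_id = cell_id, label = label,
                             stringsAsFactors = FALSE),
         type_means = type_means)
  })
}

#' Generate a correlated chromatin "gene activity" matrix
#'
#' Builds a continuous per-gene accessibility-activity matrix as a monotone
#' noisy transform of the planted expression means: `log1p(mean) +
#' Normal(0, noise_sd)` per (gene, cell). Serves as the second modality for
#' meta-ranking, with ground truth inherited from the reference.
#'
#' @param reference output of [generate_dissociated_reference()].
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return dense gene-by-cell activity matrix.
#' @export
generate_gene_activity <- function(reference, noise_sd = 0.3, seed = 1L) {
  if (noise_sd < 0) stop("activity parameter error: noise_sd must be >= 0")
  mu <- reference$type_means[, reference$labels$label, drop = FALSE]
  with_seed(seed, {
    act <- log1p(mu) + matrix(rnorm(length(mu), sd = noise_sd),
                              nrow(mu), ncol(mu))
    dimnames(act) <- list(rownames(reference$type_means),
                          reference$labels$cell_id)
    act
  })
}
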