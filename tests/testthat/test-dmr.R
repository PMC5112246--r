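test_that("probe clustering follows the gap rule with an inclusive boundary", {
  m <- manifest(data.frame(probe_id = c("a", "b", "c"), chrom = "chr1",
                           pos = c(100, 400, 2000)))
  expect_equal(cluster_probes(m, maxgap = 500), c(1, 1, 2))
  single <- manifest(data.frame(probe_id = "a", chrom = "chrX", pos = 5))
  expect_equal(cluster_probes(single), 1)
  even <- manifest(data.frame(probe_id = letters[1:4], chrom = "chr1",
                              pos = c(0, 500, 1000, 1500) + 1))
  expect_equal(cluster_probes(even, maxgap = 500), rep(1, 4))
  expect_equal(cluster_probes(even, maxgap = 499), 1:4)
  two_chrom <- manifest(data.frame(probe_id = letters[1:4],
                                   chrom = c("chr1", "chr1", "chr2", "chr2"),
                                   pos = c(100, 200, 100, 200)))
  expect_equal(cluster_probes(two_chrom), c(1, 1, 2, 2))
})

test_that("the smoother reproduces constants, linear trends and singletons", {
  m <- flat_manifest(10, gap = 100)
  cl <- cluster_probes(m)
  expect_equal(smooth_within_clusters(rep(0.3, 10), m, cl), rep(0.3, 10),
               tolerance = 1e-12)
  lin <- 0.001 * m$pos
  expect_equal(smooth_within_clusters(lin, m, cl), lin, tolerance = 1e-9)

  single <- flat_manifest(1)
  expect_equal(smooth_within_clusters(7, single, 1L), 7)

  # mid-size cluster: running mean of window 3, cross-checked naively
  m4 <- flat_manifest(4, gap = 100)
  y <- c(0, 1, 0, 2)
  expect_equal(smooth_within_clusters(y, m4, rep(1L, 4)),
               naive_smooth(m4$pos, y), tolerance = 1e-12)

  # irregular spacing: package operator equals the naive loess loop
  set.seed(41)
  m12 <- manifest(data.frame(probe_id = sprintf("cg%d", 1:12),
                             chrom = "chr1",
                             pos = sort(sample(1:3000, 12))))
  y <- rnorm(12)
  expect_equal(smooth_within_clusters(y, m12, rep(1L, 12)),
               naive_smooth(m12$pos, y), tolerance = 1e-8)
})

test_that("thresholds are the interpolated 99th percentile of absolute values", {
  vals <- c(-(1:100), 1:100)
  thr <- compute_thresholds(vals)
  expect_equal(thr$upper, 99.01)    # type-7 quantile on the 200-point sample
  expect_equal(thr$lower, -99.01)
  expect_equal(thr$upper, unname(quantile(abs(vals), 0.99)))

  spike <- c(rep(0, 999), 5)
  thr2 <- compute_thresholds(spike)
  expect_lt(thr2$upper, 5)
  expect_warning(compute_thresholds(rep(0.2, 200)), "degenerate")
})

test_that("bump detection finds runs, splits signs and ranks by area", {
  m <- flat_manifest(6, gap = 100)
  cl <- cluster_probes(m)
  sm <- c(0, 0, 0.2, 0.3, 0.2, 0)
  b <- detect_bumps(sm, m, cl, list(upper = 0.1, lower = -0.1))
  expect_equal(nrow(b), 1L)
  expect_equal(b$n_probes, 3L)
  expect_equal(b$area, 0.7)
  expect_equal(b$direction, "hyper")
  expect_equal(c(b$start, b$end), c(m$pos[3], m$pos[5]))

  m2 <- flat_manifest(2, gap = 100)
  b2 <- detect_bumps(c(-0.3, 0.3), m2, c(1L, 1L),
                     list(upper = 0.1, lower = -0.1))
  expect_equal(nrow(b2), 2L)
  expect_setequal(b2$direction, c("hypo", "hyper"))

  b3 <- detect_bumps(c(0, 0.05, 0), flat_manifest(3), rep(1L, 3),
                     list(upper = 0.1, lower = -0.1))
  expect_equal(nrow(b3), 0L)
})

test_that("bump areas are invariant to mirroring probe positions within a cluster", {
  set.seed(43)
  m <- flat_manifest(15, gap = 80)
  y <- rnorm(15, 0, 0.1)
  mirrored <- manifest(data.frame(probe_id = m$probe_id, chrom = m$chrom,
                                  pos = max(m$pos) + min(m$pos) - m$pos))
  cl <- cluster_probes(m)
  thr <- list(upper = 0.05, lower = -0.05)
  a1 <- detect_bumps(smooth_within_clusters(y, m, cl), m, cl, thr)$area
  a2 <- detect_bumps(smooth_within_clusters(rev(y), mirrored, cl),
                     mirrored, cl, thr)$area
  expect_equal(sort(a1), sort(a2), tolerance = 1e-10)
})

test_that("exhaustive sign assignments reproduce the brute-force FWER exactly", {
  set.seed(47)
  design <- tiny_design(3)
  m <- generate_manifest(n_clusters = 12, probes_per_cluster = c(8, 12),
                         seed = 48)
  m <- m[seq_len(min(nrow(m), 120)), ]
  m <- manifest(m)
  delta <- matrix(rnorm(nrow(m) * 3, 0, 0.05), nrow(m), 3,
                  dimnames = list(m$probe_id, design$pair_id))
  delta[10:18, ] <- delta[10:18, ] + 0.12   # a real bump in cluster 1/2

  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  res <- permutation_inference(delta, design, m,
                               covariates = character(0), min_pairs = 3,
                               perm_signs = signs)

  # independent brute force over all 8 assignments; smoothing and run
  # detection are done cluster by cluster so runs never span clusters
  cl <- cluster_probes(m)
  by_cluster <- split(seq_len(nrow(m)), factor(cl, levels = unique(cl)))
  smooth_all <- function(d) lapply(by_cluster, function(ix)
    naive_smooth(m$pos[ix], rowMeans(d[ix, , drop = FALSE])))
  areas_all <- function(sm_list, thr) unlist(lapply(sm_list, function(sm)
    naive_bump_areas(sm, thr, -thr)), use.names = FALSE)
  obs_sm <- smooth_all(delta)
  thr <- quantile(abs(unlist(obs_sm)), 0.99)
  obs_areas <- sort(areas_all(obs_sm, thr), decreasing = TRUE)
  max_areas <- apply(signs, 1, function(s) {
    a <- areas_all(smooth_all(sweep(delta, 2, s, "*")), thr)
    if (length(a)) max(a) else 0
  })
  expect_equal(res$area, obs_areas, tolerance = 1e-9)
  oracle_fwer <- vapply(obs_areas, function(a) mean(max_areas > a),
                        numeric(1))
  expect_identical(res$fwer_p, oracle_fwer)
  expect_true(all(res$fwer_p * 8 == round(res$fwer_p * 8)))
})

test_that("permutation p-values live on the 1/n_perm grid and suggestive follows the min-max rule", {
  design <- tiny_design(6)
  m <- generate_manifest(n_clusters = 10, seed = 53)
  set.seed(54)
  delta <- matrix(rnorm(nrow(m) * 6, 0, 0.05), nrow(m), 6,
                  dimnames = list(m$probe_id, design$pair_id))
  res <- permutation_inference(delta, design, m,
                               covariates = character(0), min_pairs = 6,
                               n_perm = 40, seed = 55)
  if (nrow(res)) {
    expect_true(all(res$fwer_p >= 0 & res$fwer_p <= 1))
    expect_equal(res$fwer_p * 40, round(res$fwer_p * 40))
    ma <- attr(res, "max_areas")
    expect_identical(res$suggestive, res$area > min(ma))
    expect_true(all(res$fdr >= 0 & res$fdr <= 1))
    # monotone: larger area never has larger fdr
    ord <- order(-res$area)
    expect_true(all(diff(res$fdr[ord]) >= -1e-12))
  }
  expect_error(permutation_inference(delta, design, m, n_perm = 0,
                                     covariates = character(0),
                                     min_pairs = 6),
               "n_perm")
})

test_that("covariate surfaces are scanned separately and constant ones skipped", {
  m <- generate_manifest(n_clusters = 30, seed = 57)
  design <- generate_pairs(n_pairs = 12, p_accp = 0, seed = 58)
  ds <- generate_dataset(m, design, seed = 59)
  expect_warning(
    tabs <- find_dmrs(ds$betas, design, m,
                      surfaces = c("alpha", "accp", "dmard"),
                      n_perm = 20, seed = 60, min_pairs = 5),
    "accp")
  expect_setequal(names(tabs), c("alpha", "dmard"))
  expect_true(all(c("fwer_p", "emp_p", "fdr", "fold_change") %in%
                    names(tabs$alpha)))
})
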