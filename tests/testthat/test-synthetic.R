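test_that("generated manifests are deterministic with recoverable cluster structure", {
  m1 <- generate_manifest(n_chrom = 1, n_clusters = 2,
                          probes_per_cluster = c(10, 10), seed = 5)
  m2 <- generate_manifest(n_chrom = 1, n_clusters = 2,
                          probes_per_cluster = c(10, 10), seed = 5)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 20L)
  expect_equal(unname(cluster_probes(m1, maxgap = 500)), m1$cluster)

  singles <- generate_manifest(n_clusters = 5,
                               probes_per_cluster = c(1, 1), seed = 6)
  expect_equal(nrow(singles), 5L)
  expect_equal(cluster_probes(singles), 1:5)
})

test_that("generated cohorts follow the configured prevalences", {
  d <- generate_pairs(n_pairs = 28, seed = 7)
  expect_s3_class(d, "pair_design")
  expect_equal(nrow(d), 28L)
  big <- generate_pairs(n_pairs = 4000, seed = 8)
  expect_lt(abs(mean(big$smoking, na.rm = TRUE) - 0.69), 0.03)
  expect_lt(abs(mean(is.na(big$smoking)) - 0.14), 0.02)
  expect_lt(abs(mean(big$accp) - 0.61), 0.03)
  expect_lt(abs(mean(big$dmard) - 0.68), 0.03)

  none <- generate_pairs(n_pairs = 20, p_accp = 0, seed = 9)
  expect_true(all(none$accp == 0))
  allmiss <- generate_pairs(n_pairs = 20, p_smoking_missing = 1, seed = 9)
  expect_true(all(is.na(allmiss$smoking)))
})

test_that("datasets are deterministic, in range, and null without noise or spikes", {
  m <- generate_manifest(n_clusters = 20, seed = 11)
  d <- generate_pairs(n_pairs = 10, seed = 12)
  ds1 <- generate_dataset(m, d, seed = 13)
  ds2 <- generate_dataset(m, d, seed = 13)
  expect_identical(ds1$betas, ds2$betas)
  expect_true(all(ds1$betas >= 0 & ds1$betas <= 1))

  silent <- generate_dataset(m, d, pair_sd = 0, noise_sd = 0, seed = 14)
  delta <- compute_pair_differences(silent$betas, d)$delta
  expect_true(all(delta == 0))
})

test_that("an alpha spike is realised exactly without noise and on average with noise", {
  m <- generate_manifest(n_clusters = 20, probes_per_cluster = c(10, 12),
                         seed = 15)
  d <- generate_pairs(n_pairs = 28, seed = 16)
  sp <- spike_regions(m, "alpha", effect = 0.15, n_probes = 10, seed = 17)
  exact <- generate_dataset(m, d, spikes = sp, pair_sd = 0, noise_sd = 0,
                            seed = 18)
  delta <- compute_pair_differences(exact$betas, d)$delta
  idx <- which(m$chrom == sp$chrom & m$pos >= sp$start & m$pos <= sp$end)
  in_region <- delta[idx, ]
  unclipped <- exact$betas[idx, d$case_sample] < 1
  expect_true(all(abs(in_region[unclipped] - 0.15) < 1e-12))
  expect_true(all(delta[-idx, ] == 0))

  noisy <- generate_dataset(m, d, spikes = sp, pair_sd = 0.05,
                            noise_sd = 0.05, seed = 19)
  nd <- compute_pair_differences(noisy$betas, d)$delta[idx, ]
  se <- 0.05 * sqrt(2) / sqrt(28)
  expect_lt(abs(mean(nd) - 0.15), 3 * se)
})

test_that("covariate spikes touch only exposed pairs' case twins", {
  m <- generate_manifest(n_clusters = 20, probes_per_cluster = c(10, 12),
                         seed = 21)
  d <- generate_pairs(n_pairs = 20, p_smoking_missing = 0, seed = 22)
  sp <- spike_regions(m, "smoking", effect = 0.2, n_probes = 10, seed = 23)
  ds <- generate_dataset(m, d, spikes = sp, pair_sd = 0, noise_sd = 0,
                         seed = 24)
  delta <- compute_pair_differences(ds$betas, d)$delta
  idx <- which(m$chrom == sp$chrom & m$pos >= sp$start & m$pos <= sp$end)
  unexposed <- d$pair_id[d$smoking == 0]
  expect_true(all(delta[idx, unexposed] == 0))
  exposed <- d$pair_id[d$smoking == 1]
  unclipped <- ds$betas[idx, d$case_sample[d$smoking == 1]] < 1
  expect_true(all(abs(delta[idx, exposed][unclipped] - 0.2) < 1e-12))
})

test_that("within-pair correlation exceeds between-pair correlation", {
  m <- generate_manifest(n_clusters = 100, seed = 25)
  d <- generate_pairs(n_pairs = 20, seed = 26)
  ds <- generate_dataset(m, d, pair_sd = 0.08, noise_sd = 0.03, seed = 27)
  b <- ds$betas
  centered <- b - rowMeans(b)
  within <- mean(vapply(seq_len(nrow(d)), function(j)
    cor(centered[, d$case_sample[j]], centered[, d$control_sample[j]]),
    numeric(1)))
  between <- mean(vapply(seq_len(nrow(d) - 1L), function(j)
    cor(centered[, d$case_sample[j]], centered[, d$control_sample[j + 1L]]),
    numeric(1)))
  expect_gt(within, between)
})

test_that("detection-p artifacts are injected at the requested rate", {
  m <- generate_manifest(n_clusters = 50, seed = 31)
  d <- generate_pairs(n_pairs = 14, seed = 32)
  ds <- generate_dataset(m, d, detp_frac = 0.02, seed = 33)
  expect_false(is.null(ds$detp))
  expect_equal(mean(ds$detp > 0.01), 0.02, tolerance = 0.005)
  masked <- mask_by_detection(ds$betas, ds$detp)
  expect_equal(sum(is.na(masked)), sum(ds$detp > 0.01))
})

test_that("a spike region outside any cluster is rejected", {
  m <- generate_manifest(n_clusters = 5, probes_per_cluster = c(4, 4),
                         seed = 35)
  d <- generate_pairs(n_pairs = 6, seed = 36)
  bad <- data.frame(surface = "alpha", effect = 0.1,
                    chrom = "chr1", start = min(m$pos),
                    end = max(m$pos), n_probes = 20, cluster = NA)
  expect_error(generate_dataset(m, d, spikes = bad, seed = 37),
               "more than one cluster")
})
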