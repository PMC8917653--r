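test_that("median rescaling sets every sample median to 1", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 1, 1))
  out <- median_rescale(m)
  expect_equal(out[, "a"], c(a1 = 0.5, a2 = 1, a3 = 1.5),
               ignore_attr = TRUE)
  expect_equal(out[, "b"], rep(1, 3), ignore_attr = TRUE)
  set.seed(1)
  r <- matrix(rexp(200) + 0.1, 20, 10)
  expect_equal(unname(apply(median_rescale(r), 2, median)), rep(1, 10))
  expect_error(median_rescale(matrix(c(-1, 0, 1), ncol = 1)), "median")
})

test_that("KNN imputation uses nearest features and honours drop thresholds", {
  set.seed(2)
  base <- rnorm(10)
  m <- rbind(f1 = base, f2 = base, f3 = rnorm(10))
  m["f1", 4] <- NA
  out <- knn_impute(m, k = 1)
  # the duplicate feature is at distance 0, so the twin's value is copied
  expect_equal(unname(out["f1", 4]), base[4])
  # a feature missing in >= 50% of samples is dropped first
  m2 <- rbind(f1 = c(NA, NA, NA, NA, NA, NA, 7, 8, 9, 10), f2 = base,
              f3 = base + 0.1)
  out2 <- knn_impute(m2, k = 1)
  expect_false("f1" %in% rownames(out2))
  # identity when complete
  m3 <- matrix(rnorm(20), 4, 5)
  expect_equal(knn_impute(m3), m3)
  expect_error(knn_impute(m3, k = 0), "k")
})

test_that("EB batch adjustment removes planted batch shifts, keeps group effects", {
  set.seed(3)
  n <- 200; p <- 40
  batch <- rep(c("b1", "b2"), each = n / 2)
  group <- rep(c("case", "ctrl"), times = n / 2)
  delta <- 2
  eff <- 1.5
  m <- matrix(rnorm(p * n), p, n)
  m[, batch == "b2"] <- m[, batch == "b2"] + delta
  m[1:5, group == "case"] <- m[1:5, group == "case"] + eff
  lay <- omics_layer(m, batch = batch, status = group)
  adj <- .layer_matrix(eb_batch_adjust(lay))
  batch_diff <- abs(rowMeans(adj[, batch == "b2"]) -
                    rowMeans(adj[, batch == "b1"]))
  expect_lt(mean(batch_diff), 0.05 * delta)
  grp_diff <- rowMeans(adj[1:5, group == "case"]) -
    rowMeans(adj[1:5, group == "ctrl"])
  expect_lt(abs(mean(grp_diff) - eff), 0.1 * eff)
  # planted batch F statistic reduced by >= 80%
  fstat <- function(mm) mean(apply(mm, 1, function(v)
    summary(lm(v ~ batch))$fstatistic[1]))
  expect_lt(fstat(adj), 0.2 * fstat(m))
  # single batch is an identity with warning
  expect_warning(same <- eb_batch_adjust(m, batch = rep("b1", n)),
                 "single")
  expect_equal(.layer_matrix(same), m, tolerance = 1e-8)
})

test_that("TMM factors are 1 for identical columns and depth-invariant", {
  set.seed(4)
  base <- rnbinom(500, mu = 100, size = 5)
  m <- cbind(s1 = base, s2 = base, s3 = base)
  f <- tmm_factors(m)
  expect_equal(unname(f$factors), rep(1, 3), tolerance = 1e-12)
  expect_equal(prod(f$factors), 1, tolerance = 1e-12)
  # a pure depth change: factors stay ~1, effective library doubles
  m2 <- cbind(s1 = base, s2 = 2 * base)
  f2 <- tmm_factors(m2)
  expect_equal(unname(f2$factors[2] / f2$factors[1]), 1,
               tolerance = 0.02)
  expect_equal(unname(f2$effective_lib_size[2] /
                      f2$effective_lib_size[1]), 2, tolerance = 0.05)
  expect_error(tmm_factors(cbind(base, 0 * base)), "all-zero")
})

test_that("log-CPM transform is finite, monotone, and equal-input-equal-output", {
  m <- cbind(s1 = c(0, 10, 100), s2 = c(0, 10, 100))
  out <- counts_to_logcpm(m, effective_lib_sizes = c(110, 110))
  expect_true(all(is.finite(out)))
  expect_equal(out[, 1], out[, 2])
  expect_true(all(diff(out[, 1]) > 0))
  expect_equal(unname(out[2, 1]),
               log2((10 + 0.5) / (110 + 1) * 1e6))
})

test_that("beta/M transforms are exact inverses with the documented values", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  g <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(g)), g, tolerance = 1e-9)
  expect_true(is.finite(beta_to_m(0)) && is.finite(beta_to_m(1)))
})

test_that("quantile normalisation equalises column distributions", {
  set.seed(5)
  v <- rnorm(50)
  m <- cbind(a = v, b = sample(v), c = sample(v))
  out <- quantile_normalize(m)
  expect_equal(sort(out[, 1]), sort(out[, 2]))
  expect_equal(sort(out[, 1]), sort(out[, 3]))
  expect_equal(mean(out[, 1]), mean(out[, 2]), tolerance = 1e-12)
  # random tie-free input: columns are equal as multisets
  m2 <- matrix(rnorm(120), 30, 4)
  o2 <- quantile_normalize(m2)
  for (j in 2:4) expect_equal(sort(o2[, 1]), sort(o2[, j]))
  expect_error(quantile_normalize(cbind(c(1, NA), c(2, 3))), "missing")
})

test_that("variance filter drops constants and honours the threshold", {
  m <- rbind(f1 = rep(3, 6), f2 = c(1, 2, 3, 4, 5, 6),
             f3 = c(0, 0, 0, 0, 0, 0.1))
  out <- variance_filter(m)
  expect_false("f1" %in% rownames(out))
  expect_equal(nrow(variance_filter(m, min_variance = -1)), 3)
  # explicit threshold: only f2 has variance > 0.01
  expect_equal(rownames(variance_filter(m, min_variance = 0.01)), "f2")
})

test_that("RRBS site filter drops SNP, low-coverage and missing-heavy sites", {
  cov <- rbind(s_snp = c(10, 10, 10, 10),
               s_low = c(4, 4, 4, 4),
               s_ok  = c(10, 12, 9, 11),
               s_half = c(10, 4, 10, 10))
  res <- rrbs_site_filter(cov, snp_sites = "s_snp", min_cov = 5,
                          high_cov_quantile = 1, max_missing = 0.05)
  expect_false("s_snp" %in% res$kept)
  expect_false("s_low" %in% res$kept)
  expect_true("s_ok" %in% res$kept)
  expect_false("s_half" %in% res$kept) # 25% missing > 5%
  expect_setequal(res$audit$reason[res$audit$site == "s_snp"],
                  "snp_overlap")
  # an extreme-coverage site is treated as missing and dropped
  set.seed(7)
  cov2 <- matrix(rpois(120, 20) + 5, 30, 4,
                 dimnames = list(paste0("x", 1:30), NULL))
  cov2["x1", 2] <- 1e5
  res2 <- rrbs_site_filter(cov2, min_cov = 1, high_cov_quantile = 0.9,
                           max_missing = 0.05)
  expect_false("x1" %in% res2$kept)
})

test_that("cross-technology filter drops discordant sites", {
  a <- matrix(50, 3, 5, dimnames = list(paste0("s", 1:3),
                                        paste0("i", 1:5)))
  b <- a
  expect_setequal(cross_technology_filter(a, b)$kept, rownames(a))
  b2 <- b; b2["s2", ] <- b2["s2", ] + 50
  res <- cross_technology_filter(a, b2)
  expect_false("s2" %in% res$kept)
  # discordant in only 3/5 individuals (60% <= 70%): kept
  b3 <- b; b3["s3", 1:3] <- b3["s3", 1:3] + 50
  expect_true("s3" %in% cross_technology_filter(a, b3)$kept)
  expect_error(cross_technology_filter(a, b[, c()]), "shared")
})

test_that("reproducible-peak merging equals the per-base counting oracle", {
  # 5 identical intervals -> same span back
  iv <- data.frame(chrom = "chr1", start = 100, end = 200,
                   sample_id = paste0("s", 1:5))
  out <- merge_reproducible_peaks(iv, min_support = 5)
  expect_equal(out$start, 100)
  expect_equal(out$end, 200)
  # 4 samples cannot reach support 5
  expect_equal(nrow(merge_reproducible_peaks(iv[1:4, ], 5)), 0)
  # staggered random intervals vs brute force on a 10 kb genome
  set.seed(6)
  rand <- do.call(rbind, lapply(1:8, function(s) {
    st <- sort(sample(0:9900, 12))
    data.frame(chrom = sample(c("chrA", "chrB"), 12, replace = TRUE),
               start = st, end = st + sample(20:400, 12, replace = TRUE),
               sample_id = paste0("s", s))
  }))
  rand$end <- pmin(rand$end, 10000)
  for (ms in c(2, 4, 5)) {
    got <- merge_reproducible_peaks(rand, min_support = ms)
    want <- oracle_merge_peaks(rand, ms)
    got <- got[order(got$chrom, got$start), ]
    want <- want[order(want$chrom, want$start), ]
    expect_equal(got$start, want$start, info = paste("support", ms))
    expect_equal(got$end, want$end, info = paste("support", ms))
  }
  bad <- data.frame(chrom = "c", start = 10, end = 10, sample_id = "s")
  expect_error(merge_reproducible_peaks(bad), "line")
})
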