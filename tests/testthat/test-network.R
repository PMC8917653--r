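test_that("bicor matches the direct-formula oracle and is bounded", {
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(30); y <- 0.5 * x + rnorm(30)
    expect_equal(bicor(x, y), oracle_bicor(x, y), tolerance = 1e-12)
  }
  x <- rnorm(25)
  expect_equal(bicor(x, x), 1)
  expect_equal(bicor(x, -x), -1)
  expect_warning(r <- bicor(rep(1, 10), rnorm(10)), "MAD")
  expect_error(bicor(1:5, 1:4), "length")
})

test_that("bicor and the correlation matrix are invariant to positive affine rescaling", {
  set.seed(2)
  x <- matrix(rnorm(40 * 6), 40, 6)
  colnames(x) <- paste0("m", 1:6)
  r1 <- cor_matrix(x, "bicor")
  x2 <- sweep(sweep(x, 2, runif(6, 0.5, 5), "*"), 2, rnorm(6), "+")
  r2 <- cor_matrix(x2, "bicor")
  expect_equal(r1, r2, tolerance = 1e-10)
  # matrix path agrees with the pairwise scalar path
  expect_equal(r1[2, 5], bicor(x[, 2], x[, 5]), tolerance = 1e-12)
})

test_that("signed adjacency follows ((1+r)/2)^beta", {
  r <- matrix(c(1, 0, -1, 0, 1, 0.5, -1, 0.5, 1), 3, 3)
  a <- signed_adjacency(r, 6)
  expect_equal(a[1, 3], 0)
  expect_equal(a[1, 2], 0.5^6)
  expect_equal(diag(a), rep(1, 3))
  expect_equal(a[2, 3], 0.75^6)
})

test_that("signed TOM matches a direct triple-sum oracle on a hand case", {
  set.seed(3)
  r <- cor_matrix(matrix(rnorm(30 * 4), 30, 4), "pearson")
  a <- signed_adjacency(r, 2)
  tom <- signed_tom(a)
  # independent elementwise oracle
  p <- ncol(a)
  for (i in 1:p) for (j in 1:p) {
    if (i == j) { expect_equal(tom[i, j], 1); next }
    shared <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    expect_equal(tom[i, j],
                 (shared + a[i, j]) / (min(ki, kj) + 1 - a[i, j]),
                 tolerance = 1e-12)
  }
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  # degenerate cases
  expect_equal(signed_tom(diag(4)), diag(4))
  ones <- matrix(1, 4, 4)
  expect_equal(signed_tom(ones), ones)
})

test_that("soft-threshold selection: monotone connectivity, noise takes the warning path", {
  bd <- block_data(n = 60, n_noise = 40, seed = 4)
  cc <- cor_matrix(bd$x, "pearson")
  fit <- suppressWarnings(pick_soft_threshold(cc))
  expect_true(all(diff(fit$fit_table$mean_k) <= 1e-12))
  expect_true(fit$power >= 1)
  noise <- cor_matrix(matrix(rnorm(50 * 40), 50, 40), "pearson")
  expect_warning(pick_soft_threshold(noise), "target|degenerate")
})

test_that("eigen-metabolite matches the SVD oracle and fixes its sign", {
  set.seed(5)
  # identical members: ME proportional to the z-scored metabolite
  v <- rnorm(30)
  mod <- cbind(v, v, v)
  em <- eigen_metabolite(mod)
  expect_equal(em$variance_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(em$me, v)), 1, tolerance = 1e-12)
  expect_gte(mean(cor(em$me, scale(mod))), 0)
  # variance explained equals sigma1^2 / sum sigma^2 from a full SVD
  x <- matrix(rnorm(50 * 8), 50, 8)
  em2 <- eigen_metabolite(x)
  d <- svd(scale(x))$d
  expect_equal(em2$variance_explained, d[1]^2 / sum(d^2),
               tolerance = 1e-8)
  expect_gte(mean(cor(em2$me, scale(x))), 0)
})

test_that("module detection recovers planted blocks and leaves noise unassigned", {
  aris <- numeric(3)
  for (s in 1:3) {
    bd <- block_data(n = 100, seed = s)
    cc <- cor_matrix(bd$x, "bicor")
    beta <- suppressWarnings(pick_soft_threshold(cc))$power
    tom <- signed_tom(signed_adjacency(cc, beta))
    mr <- detect_modules(tom, bd$x, network_config())
    aris[s] <- mclust::adjustedRandIndex(mr$assignment, bd$truth)
  }
  expect_gte(mean(aris), 0.7)
  # perfectly correlated data collapse into one module
  one <- matrix(rep(rnorm(50), 25), 50, 25)
  colnames(one) <- paste0("m", 1:25)
  cc1 <- cor_matrix(one, "pearson")
  mr1 <- detect_modules(signed_tom(signed_adjacency(cc1, 6)), one,
                        network_config(min_module_size = 5))
  expect_equal(unname(unique(mr1$assignment)), "M1")
  # independent noise: nearly everything unassigned
  set.seed(99)
  noise <- matrix(rnorm(80 * 60), 80, 60)
  colnames(noise) <- paste0("m", 1:60)
  ccn <- cor_matrix(noise, "pearson")
  mrn <- detect_modules(signed_tom(signed_adjacency(ccn, 6)), noise,
                        network_config())
  expect_gte(mean(mrn$assignment == "unassigned"), 0.9)
})

test_that("close modules merge on eigen-metabolite correlation", {
  set.seed(7)
  n <- 80
  f <- rnorm(n)
  # two nominal modules driven by the same factor -> diss < 0.25 -> merge
  x <- cbind(matrix(rep(f, 25), n, 25) + matrix(rnorm(n * 25, 0, 0.4), n),
             matrix(rep(f, 25), n, 25) + matrix(rnorm(n * 25, 0, 0.4), n),
             matrix(rep(rnorm(n), 25), n, 25) +
               matrix(rnorm(n * 25, 0, 0.4), n))
  colnames(x) <- paste0("m", 1:75)
  res <- structure(list(assignment = setNames(
    rep(c("M1", "M2", "M3"), each = 25), colnames(x))), class = "module_result")
  merged <- merge_close_modules(res, x, cut_height = 0.25)
  expect_equal(length(unique(merged$assignment)), 2)
  # orthogonal modules stay put
  y <- cbind(matrix(rep(rnorm(n), 25), n, 25),
             matrix(rep(rnorm(n), 25), n, 25)) +
    matrix(rnorm(n * 50, 0, 0.4), n)
  colnames(y) <- paste0("m", 1:50)
  res2 <- structure(list(assignment = setNames(
    rep(c("M1", "M2"), each = 25), colnames(y))), class = "module_result")
  merged2 <- merge_close_modules(res2, y, cut_height = 0.25)
  expect_equal(length(unique(merged2$assignment)), 2)
})

test_that("module-trait association: exact r, Student-t p, full-grid FDR", {
  set.seed(8)
  mes <- matrix(rnorm(40 * 3), 40, 3,
                dimnames = list(NULL, paste0("ME", 1:3)))
  traits <- data.frame(t1 = mes[, 1], t2 = rnorm(40), t3 = rnorm(40),
                       t4 = rnorm(40))
  out <- module_trait_association(mes, traits)
  expect_equal(nrow(out), 12) # m x t tests enter the FDR
  self <- out[out$module == "ME1" & out$trait == "t1", ]
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_lt(self$p, 1e-20)
  # r = 0.632, n = 10 -> p ~= 0.05 (Student-t oracle)
  expect_equal(cor_pvalue_student(0.632, 10), 0.0500, tolerance = 0.01)
  # constant trait -> NA cell
  traits$t2 <- 1
  out2 <- module_trait_association(mes, traits)
  expect_true(all(is.na(out2$r[out2$trait == "t2"])))
})

test_that("module-trait p-values agree with a permutation null", {
  set.seed(12)
  n <- 30
  me <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "ME1"))
  tr <- data.frame(t1 = rnorm(n))
  obs <- module_trait_association(me, tr)
  r_obs <- abs(obs$r)
  perm <- replicate(1000, abs(cor(me[, 1], sample(tr$t1))))
  p_perm <- mean(perm >= r_obs)
  expect_lt(abs(p_perm - obs$p), 0.05)
})

test_that("ME adjacency clustering separates anti-correlated ME sets", {
  set.seed(9)
  base <- rnorm(60)
  mes <- cbind(A1 = base + rnorm(60, 0, 0.2),
               A2 = base + rnorm(60, 0, 0.2),
               B1 = -base + rnorm(60, 0, 0.2),
               B2 = -base + rnorm(60, 0, 0.2))
  res <- me_adjacency_clusters(mes, n_clusters = 2)
  expect_true(all(res$adjacency >= 0 & res$adjacency <= 1))
  expect_equal(res$clusters[["A1"]], res$clusters[["A2"]])
  expect_equal(res$clusters[["B1"]], res$clusters[["B2"]])
  expect_false(res$clusters[["A1"]] == res$clusters[["B1"]])
  expect_equal(ncol(res$cluster_means), 2)
})

test_that("consensus TOM is the scaled elementwise minimum", {
  bd <- block_data(n = 50, n_modules = 2, module_size = 10,
                   n_noise = 10, seed = 10)
  cc <- cor_matrix(bd$x, "pearson")
  tom <- signed_tom(signed_adjacency(cc, 4))
  expect_equal(consensus_tom(tom, tom), tom, tolerance = 1e-12)
  tom_b <- signed_tom(signed_adjacency(cc * 0.9, 4))
  cons <- consensus_tom(tom, tom_b)
  q <- quantile(tom_b[upper.tri(tom_b)], 0.95) /
    quantile(tom[upper.tri(tom)], 0.95)
  scaled_b <- pmin(tom_b / q, 1)
  off <- upper.tri(cons)
  expect_true(all(cons[off] <= pmin(tom[off], scaled_b[off]) + 1e-12))
})
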