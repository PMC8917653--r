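test_that("cohort simulation is deterministic and sized by the config", {
  cfg <- small_config(seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$subjects), 6 + 6 + 10 + 40)
  expect_equal(as.numeric(table(a$subjects$group)[c("lean-BD", "obese")]),
               c(6, 6))
  cfg2 <- simulation_config(group_sizes = c(obese = 6, "lean-BD" = 6),
                            layer_specs = list(
                              layer_spec("m", "abundance",
                                         n_features = 10, n_planted = 2)),
                            n_modules = 0)
  expect_equal(nrow(simulate_cohort(cfg2)$subjects), 12)
  expect_error(simulation_config(group_sizes = c(alien = 5)), "unknown")
  # derived indices recomputed from the assays
  s <- a$subjects
  expect_equal(s$lar, s$leptin / s$adiponectin)
  expect_equal(s$homa, homa_ir_si(s$glucose, s$insulin))
})

test_that("clinical draws separate the extreme groups along adiposity markers", {
  coh <- simulate_cohort(small_config(seed = 3))
  s <- coh$subjects
  expect_gt(mean(s$bmi[s$group == "obese"]),
            mean(s$bmi[s$group == "lean-BD"]) + 10)
  expect_gt(mean(s$tg[s$group == "lipodystrophy"]),
            mean(s$tg[s$group == "lean-BD"]))
  expect_true(all(s$leptin > 0 & s$adiponectin > 0 & s$glucose > 0))
})

test_that("count layers are integer, non-negative, with batch offsets when configured", {
  groups <- setNames(rep(c("lean-BD", "obese"), each = 10),
                     paste0("s", 1:20))
  sp <- layer_spec("cnt", "counts", n_features = 50, n_planted = 5,
                   effect_size = 1, batch_count = 2, batch_offset = 2)
  lay <- simulate_layer(sp, groups, seed = 5)
  m <- lay$matrix
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  # per-batch feature means differ before adjustment
  b <- lay$batch
  lcpm <- counts_to_logcpm(m)
  bdiff <- abs(rowMeans(lcpm[, b == "b1"]) - rowMeans(lcpm[, b == "b2"]))
  expect_gt(mean(bdiff), 0.2)
  expect_error(layer_spec("x", "weird"), "arg")
})

test_that("degenerate layers (no noise, no effect) are identical up to library scaling", {
  groups <- setNames(rep("lean-BD", 6), paste0("s", 1:6))
  sp <- layer_spec("ab", "abundance", n_features = 20, n_planted = 0,
                   effect_size = 0, noise_sd = 0)
  m <- simulate_layer(sp, groups, seed = 1)$matrix
  expect_equal(m[, 1], m[, 2], ignore_attr = TRUE)
  spc <- layer_spec("cnt", "counts", n_features = 20, n_planted = 0,
                    effect_size = 0, noise_sd = 0)
  mc <- simulate_layer(spc, groups, seed = 1)$matrix
  ratios <- sweep(mc + 1, 1, mc[, 1] + 1, "/")
  # each column is a (rounded) scalar multiple of the first
  expect_lt(max(apply(ratios, 2, sd)), 0.05)
})

test_that("planted-feature power matches a Monte-Carlo nominal oracle", {
  n_seeds <- 20
  hits <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cfg <- simulation_config(
      group_sizes = c("lean-BD" = 6, obese = 6, lipodystrophy = 10),
      layer_specs = list(layer_spec("ab", "abundance", n_features = 40,
                                    n_planted = 10, effect_size = 2)),
      n_modules = 0, seed = 100 + s)
    coh <- simulate_cohort(cfg)
    m <- coh$layers$ab$matrix
    case <- coh$subjects$group %in% c("obese", "lipodystrophy")
    pvals <- apply(m[coh$truth$planted_features$ab, ], 1, function(v)
      t.test(v[case], v[!case])$p.value)
    hits[s] <- sum(pvals < 0.05)
  }
  # independent nominal-power oracle: plain normal two-sample simulation
  set.seed(1)
  nominal <- mean(replicate(3000,
    t.test(rnorm(16, 2), rnorm(6))$p.value < 0.05))
  expect_gte(mean(hits), 9)
  expect_lt(abs(mean(hits) / 10 - nominal), 0.1)
})

test_that("difference-in-means estimator of the planted effect is unbiased", {
  ests <- numeric(50)
  for (s in 1:50) {
    groups <- setNames(rep(c("lean-BD", "obese"), each = 25),
                       paste0("s", 1:50))
    sp <- layer_spec("ab", "abundance", n_features = 10, n_planted = 5,
                     effect_size = 1.5, noise_sd = 1)
    m <- simulate_layer(sp, groups, seed = 2000 + s)$matrix
    ests[s] <- mean(rowMeans(m[1:5, groups == "obese"]) -
                    rowMeans(m[1:5, groups == "lean-BD"]))
  }
  expect_equal(mean(ests), 1.5, tolerance = 0.1) # MC error over 50 seeds
})

test_that("module planting delivers the requested within-module correlation and coupling", {
  groups <- setNames(rep(c("lean-BD", "obese"), each = 50),
                     paste0("s", 1:100))
  sp <- layer_spec("met", "abundance", n_features = 140, n_planted = 0,
                   effect_size = 0, noise_sd = 1)
  lay <- simulate_layer(sp, groups, seed = 11)
  traits <- data.frame(bmi = rnorm(100), tg = rnorm(100),
                       row.names = names(groups))
  pm <- plant_module_structure(lay, traits, n_modules = 4,
                               module_size = 30,
                               within_module_corr = 0.6,
                               trait_coupling_strength = 0.9, seed = 12)
  m <- pm$layer$matrix
  mem1 <- names(pm$module_map)[pm$module_map == "true_M1"]
  cc <- cor(t(m[mem1, ]))
  mean_r <- mean(cc[upper.tri(cc)])
  expect_gte(mean_r, 0.5)
  expect_lte(mean_r, 0.7)
  # strong coupling propagates to the eigen-metabolite / trait correlation
  em <- eigen_metabolite(t(m[mem1, ]))
  expect_gte(abs(cor(em$me, traits[[pm$coupled_traits[["true_M1"]]]])),
             0.7)
  expect_error(plant_module_structure(lay, traits, n_modules = 10,
                                      module_size = 30), "enough")
})

test_that("zero within-module correlation yields no detectable modules", {
  groups <- setNames(rep("lean-BD", 80), paste0("s", 1:80))
  sp <- layer_spec("met", "abundance", n_features = 100, n_planted = 0,
                   effect_size = 0, noise_sd = 1)
  lay <- simulate_layer(sp, groups, seed = 21)
  traits <- data.frame(bmi = rnorm(80), row.names = names(groups))
  pm <- plant_module_structure(lay, traits, n_modules = 2,
                               module_size = 30,
                               within_module_corr = 0,
                               trait_coupling_strength = 0, seed = 22)
  x <- t(pm$layer$matrix)
  cc <- cor_matrix(x, "pearson")
  mr <- detect_modules(signed_tom(signed_adjacency(cc, 6)), x,
                       network_config())
  expect_gte(mean(mr$assignment == "unassigned"), 0.9)
})

test_that("missingness masks at the configured rate but never the training set", {
  cfg <- small_config(seed = 5, missing_layer_fraction = 0.3)
  coh <- simulate_cohort(cfg)
  av <- coh$availability
  training <- coh$truth$training_subjects
  expect_true(all(av[training, ]))
  bd <- setdiff(rownames(av), training)
  frac <- mean(!av[bd, ])
  n_cells <- length(bd) * ncol(av)
  ci <- 4 * sqrt(0.3 * 0.7 / n_cells)
  expect_lt(abs(frac - 0.3), ci + 0.02)
  # fraction 0: everyone complete
  coh0 <- simulate_cohort(small_config(seed = 5))
  expect_true(all(coh0$availability))
})

test_that("cohort export writes readable plain-text files", {
  coh <- simulate_cohort(small_config(seed = 2))
  dir <- file.path(tempdir(), "cohort_out")
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  sub <- read.delim(paths["subjects"])
  expect_equal(nrow(sub), nrow(coh$subjects))
  lay <- read.delim(file.path(dir, "layer_metabolites.tsv"))
  expect_equal(nrow(lay), 60)
  expect_equal(lay$feature_id[1], "metabolites_f001")
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$seed, 2L)
  unlink(dir, recursive = TRUE)
})
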