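#' Preprocess a simulated layer for model fitting
#'
#' Count layers are TMM-normalised and transformed to log2-CPM; other
#' kinds pass through unchanged. This is the minimal harmonisation the
#' selection stage expects.
#'
#' @param layer an `omics_layer`.
#' @return an `omics_layer` on a modelling-ready scale.
#' @export
prepare_layer <- function(layer) {
  if (inherits(layer, "omics_layer") && layer$kind == "counts") {
    tf <- tmm_factors(layer)
    counts_to_logcpm(layer, tf$effective_lib_size)
  } else layer
}

#' Signature-selection recovery benchmark on synthetic cohorts
#'
#' For each seed, simulates a three-layer cohort (200 features per
#' layer, 10 planted discriminative features at 1.5 within-group SD),
#' selects per-layer signatures on the 6 obese vs 6 lean-BD training
#' subjects, fits the ridge subset models, and scores every
#' obese/lean-BD/BD subject. Reports per-seed planted-feature
#' sensitivity and the log loss of the multi-layer model against the
#' best single-layer model. The benchmark runs without clinical
#' covariates throughout: the simulated ground truth places the signal
#' entirely in the omics features, unpenalised covariates at a 6 vs 6
#' training size destabilise the fold-level fits, and the simulated age
#' structure (BD subjects are the oldest group) would otherwise leak an
#' age confound into the ranking. The covariate paths are exercised by
#' the unit tests.
#'
#' @param seeds integer vector of simulation seeds.
#' @param bd_size number of general blood-donor subjects (default 40).
#' @param n_rounds CV rounds for the penalty choice (default 20).
#' @return data frame (seed, sensitivity, multi_logloss,
#'   best_single_logloss, multi_wins).
#' @export
benchmark_selection_recovery <- function(seeds = 1:20, bd_size = 40,
                                         n_rounds = 20) {
  rows <- lapply(seeds, function(s) {
    cfg <- simulation_config(
      group_sizes = c("lean-BD" = 6, obese = 6, lipodystrophy = 10,
                      BD = bd_size),
      n_modules = 0, seed = s)
    coh <- simulate_cohort(cfg)
    sub <- coh$subjects
    layers <- lapply(coh$layers, prepare_layer)
    train <- rownames(sub)[sub$group %in% c("obese", "lean-BD")]
    y <- as.integer(sub[train, "group"] == "obese")
    sigs <- lapply(names(layers), function(nm)
      select_signature_layer(layers[[nm]], train, y,
                             n_rounds = n_rounds, seed = s))
    names(sigs) <- names(layers)
    sens <- vapply(names(layers), function(nm)
      mean(coh$truth$planted_features[[nm]] %in%
           sigs[[nm]]$selected_features), numeric(1))
    ms <- fit_subset_models(sigs, layers, NULL, train, y, seed = s)
    eval_ids <- rownames(sub)[sub$group %in% c("obese", "lean-BD", "BD")]
    y_eval <- stats::setNames(as.integer(sub[eval_ids, "group"] == "obese"),
                              eval_ids)
    score_subset <- function(key, lns) {
      X <- assemble_design(sigs[lns], layers, NULL, eval_ids)$X
      log_loss(y_eval, predict(ms$models[[key]], X))
    }
    multi_key <- paste(sort(names(layers)), collapse = "+")
    multi_ll <- score_subset(multi_key, names(layers))
    single_ll <- vapply(names(layers), function(nm)
      score_subset(nm, nm), numeric(1))
    data.frame(seed = s, sensitivity = mean(sens),
               multi_logloss = multi_ll,
               best_single_logloss = min(single_ll),
               multi_wins = multi_ll <= min(single_ll))
  })
  do.call(rbind, rows)
}

#' Metabolite-network recovery benchmark
#'
#' For each seed, generates four correlated modules of 30 metabolites
#' (within-module correlation 0.6) over `n_samples` samples plus
#' `n_noise` independent metabolites, runs the full network pipeline
#' (bicor, soft threshold by scale-free fit, signed TOM, static-cut
#' module detection with ME merging) and reports the adjusted Rand
#' index against the planted assignment and the scale-free fit R^2 at
#' the selected power.
#'
#' @param seeds simulation seeds.
#' @param n_samples samples (default 100).
#' @param n_noise background metabolites (default 200).
#' @return data frame (seed, power, r2, ari).
#' @export
benchmark_network_recovery <- function(seeds = 1:10, n_samples = 100,
                                       n_noise = 200) {
  rows <- lapply(seeds, function(s) {
    groups <- stats::setNames(rep("lean-BD", n_samples),
                              paste0("s", seq_len(n_samples)))
    sp <- layer_spec("met", "abundance",
                     n_features = 4 * 30 + n_noise, n_planted = 0,
                     effect_size = 0, noise_sd = 1)
    lay <- simulate_layer(sp, groups, seed = s)
    traits <- data.frame(bmi = stats::rnorm(n_samples),
                         row.names = names(groups))
    pm <- plant_module_structure(lay, traits, n_modules = 4,
                                 module_size = 30,
                                 within_module_corr = 0.6,
                                 trait_coupling_strength = 0,
                                 seed = s + 10000L)
    x <- t(pm$layer$matrix)
    cc <- cor_matrix(x, "bicor")
    st <- suppressWarnings(pick_soft_threshold(cc))
    r2 <- st$fit_table$r2[st$fit_table$power == st$power]
    tom <- signed_tom(signed_adjacency(cc, st$power))
    mr <- detect_modules(tom, x, network_config())
    ari <- .adjusted_rand(mr$assignment[colnames(x)],
                          pm$module_map[colnames(x)])
    data.frame(seed = s, power = st$power, r2 = r2, ari = ari)
  })
  do.call(rbind, rows)
}

# adjusted Rand index (Hubert & Arabie) between two labelings
.adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(0)
  (sum_ij - expected) / (maxidx - expected)
}

#' Run the full default pipeline on a synthetic cohort
#'
#' Simulates the default cohort (6 lean-BD, 6 obese, 10 lipodystrophy,
#' 202 BD; three layers), prepares each layer, selects per-layer
#' signatures for patients (obese + lipodystrophy) vs lean-BD, fits
#' the ridge subset models, and ranks every subject by predicted
#' probability of patient-group membership. Clinical covariates are
#' left out for the reasons given at
#' [benchmark_selection_recovery()].
#'
#' @param seed integer master seed.
#' @param n_rounds CV rounds (default 10).
#' @param config optional [simulation_config()] overriding the default
#'   (its seed is replaced by `seed`).
#' @return list with `rankings` (data frame), `signatures`, `models`,
#'   `log_loss` (over subjects with known extreme-group status), and
#'   `cohort`.
#' @export
run_default_pipeline <- function(seed = 1L, n_rounds = 10,
                                 config = NULL) {
  if (is.null(config)) config <- simulation_config(seed = seed)
  else config$seed <- as.integer(seed)
  coh <- simulate_cohort(config)
  sub <- coh$subjects
  layers <- lapply(coh$layers, prepare_layer)
  train <- coh$truth$training_subjects
  y <- as.integer(sub[train, "group"] %in% c("obese", "lipodystrophy"))
  sigs <- lapply(names(layers), function(nm)
    select_signature_layer(layers[[nm]], train, y,
                           n_rounds = n_rounds, seed = seed))
  names(sigs) <- names(layers)
  ms <- fit_subset_models(sigs, layers, NULL, train, y, seed = seed)
  rk <- predict_and_rank(ms, layers, NULL,
                         availability = coh$availability,
                         subjects = rownames(sub))
  y_all <- stats::setNames(
    as.integer(sub$group %in% c("obese", "lipodystrophy")),
    rownames(sub))
  ll <- log_loss(y_all[rk$subject], rk$probability)
  list(rankings = rk, signatures = sigs, models = ms, log_loss = ll,
       cohort = coh)
}
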