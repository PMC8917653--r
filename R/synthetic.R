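#' Specification of one synthetic omics layer
#'
#' @param name layer name.
#' @param kind "abundance", "counts", "m-value" or "intensity".
#' @param n_features number of features.
#' @param n_planted number of discriminative (planted) features.
#' @param effect_size planted group shift in within-group SD units
#'   (log-scale for counts).
#' @param batch_count number of batches (1 = no batch structure).
#' @param batch_offset additive per-batch offset magnitude in SD units
#'   (default 1; used when `batch_count > 1`).
#' @param noise_sd within-group noise SD (for counts this scales the
#'   gamma-Poisson dispersion; 0 gives deterministic expected counts).
#' @param dispersion negative-binomial dispersion for counts
#'   (default 0.2).
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(name, kind = c("abundance", "counts", "m-value",
                                      "intensity"),
                       n_features = 200, n_planted = 10,
                       effect_size = 1.5, batch_count = 1,
                       batch_offset = 1, noise_sd = 1,
                       dispersion = 0.2) {
  kind <- match.arg(kind)
  stopifnot(n_features >= 0, n_planted >= 0, n_planted <= n_features,
            effect_size >= 0, batch_count >= 1, noise_sd >= 0,
            dispersion >= 0)
  structure(list(name = name, kind = kind, n_features = n_features,
                 n_planted = n_planted, effect_size = effect_size,
                 batch_count = batch_count, batch_offset = batch_offset,
                 noise_sd = noise_sd, dispersion = dispersion),
            class = "layer_spec")
}

#' Configuration of a synthetic multi-omic cohort
#'
#' The defaults mirror the study design this package models: training
#' groups of 6 lean blood donors (lean-BD), 6 obese and 10 lipodystrophy
#' subjects, plus 202 general blood donors (BD); three layers
#' (metabolite abundances, expression counts, methylation M-values) with
#' 200 features each and 10 planted discriminative features at 1.5 SD;
#' and a correlated-module block (4 modules of 30 metabolites at
#' within-module correlation 0.6, coupled to clinical traits at 0.7).
#'
#' @param group_sizes named integer vector of group sizes.
#' @param layer_specs list of [layer_spec()]s.
#' @param n_modules,module_size,within_module_corr,trait_coupling_strength
#'   correlated metabolite module structure planted into the first layer.
#' @param missing_layer_fraction probability that a non-training subject
#'   lacks a given layer (MCAR).
#' @param seed integer master seed; all randomness derives from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(group_sizes = c("lean-BD" = 6, obese = 6,
                                              lipodystrophy = 10,
                                              BD = 202),
                              layer_specs = list(
                                layer_spec("metabolites", "abundance"),
                                layer_spec("rna", "counts"),
                                layer_spec("methylation", "m-value")),
                              n_modules = 4, module_size = 30,
                              within_module_corr = 0.6,
                              trait_coupling_strength = 0.7,
                              missing_layer_fraction = 0,
                              seed = 1L) {
  known <- c("lean-BD", "lean-Control", "control", "obese",
             "post-surgery", "lipodystrophy", "BD")
  bad <- setdiff(names(group_sizes), known)
  if (length(bad) > 0)
    stop("simulation_config: unknown group label(s): ",
         paste(bad, collapse = ", "))
  if (any(group_sizes < 0) || is.null(names(group_sizes)))
    stop("simulation_config: group sizes must be named and >= 0")
  stopifnot(within_module_corr >= 0, within_module_corr < 1,
            trait_coupling_strength >= 0, trait_coupling_strength <= 1,
            missing_layer_fraction >= 0, missing_layer_fraction < 1)
  structure(list(group_sizes = group_sizes, layer_specs = layer_specs,
                 n_modules = n_modules, module_size = module_size,
                 within_module_corr = within_module_corr,
                 trait_coupling_strength = trait_coupling_strength,
                 missing_layer_fraction = missing_layer_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# group-level clinical distributions (mean, sd); BD/obese/lipodystrophy
# follow the descriptive statistics of the study groups, lean-BD the
# metabolically healthy control profile. direction: +1 biomarkers rise
# with the latent adiposity factor, -1 fall.
.clinical_params <- local({
  mk <- function(...) {
    v <- c(...); matrix(v, ncol = 2, byrow = TRUE,
                        dimnames = list(NULL, c("mean", "sd")))
  }
  vars <- c("age", "bw", "bmi", "leptin", "adiponectin", "insulin",
            "glucose", "ffa", "tg", "tc", "hdl", "ldl", "alt", "ast",
            "hscrp")
  tab <- list(
    "BD" = mk(57.3, 11.1, 76, 14.9, 26.4, 4.9, 14.2, 14.7, 10.1, 6.3,
              118.4, 117.1, 5.4, 1.8, 189.3, 132.8, 1.6, 0.9, 5.3, 1.1,
              1.6, 0.5, 2.9, 0.9, 34.6, 12, 25.5, 11.1, 1.9, 1.8),
    "lean-BD" = mk(40.7, 11, 68, 8, 23, 1.3, 10, 6, 10.7, 3.7,
                   70, 30, 4.8, 0.4, 156.5, 103.3, 1.1, 0.35, 4.9, 1,
                   1.7, 0.25, 2.3, 0.25, 27.1, 7.5, 21.8, 6.9, 2.2, 1.2),
    "obese" = mk(46.3, 12.3, 137.9, 35.2, 45, 5.1, 74.1, 30.4, 5.9, 1.9,
                 190.6, 120, 5.3, 0.6, 293.1, 164.6, 1.9, 0.7, 4.5, 0.8,
                 1.3, 0.2, 2.4, 0.8, 35.7, 9.4, 22.6, 3.8, 7.4, 6.9),
    "lipodystrophy" = mk(45.1, 9.6, 73.2, 9.7, 23, 1.5, 7.6, 7.8,
                         3.2, 2.3, 261.7, 180, 8.3, 3.4, 259.6, 174.9,
                         5.6, 3.5, 4.2, 1, 0.8, 0.3, 1.7, 0.5, 56, 12.7,
                         39, 16.8, 2.3, 3.3),
    "control" = mk(40.7, 11, 70, 10, 24, 2, 19.8, 17.1, 10.7, 3.7,
                   76.4, 55.6, 4.9, 1, 156.5, 103.3, 1.2, 0.9, 4.9, 1,
                   1.7, 0.4, 2.7, 0.8, 27.1, 7.5, 21.8, 6.9, 2.2, 1.2)
  )
  tab[["lean-Control"]] <- tab[["lean-BD"]]
  tab[["post-surgery"]] <- mk(43, 12.6, 90, 15, 30, 4, 29.9, 21,
                              6.4, 2.6, 178.7, 150, 5.3, 1.5,
                              232.2, 141.5, 1, 0.4, 4.1, 1.4, 1.3, 0.2,
                              2.6, 1, 36.1, 17, 18.9, 6.9, 2.9, 5.6)
  for (g in names(tab)) rownames(tab[[g]]) <- vars
  list(table = tab, vars = vars,
       direction = c(age = 0, bw = 1, bmi = 1, leptin = 1,
                     adiponectin = -1, insulin = 1, glucose = 1, ffa = 1,
                     tg = 1, tc = 0, hdl = -1, ldl = 0, alt = 1, ast = 1,
                     hscrp = 1))
})

# lower-truncated correlated normal draws: one latent adiposity factor
# per subject induces biomarker correlations (loading rho)
.draw_clinical <- function(groups, rho = 0.5) {
  pars <- .clinical_params
  n <- length(groups)
  adip <- stats::rnorm(n)
  out <- data.frame(row.names = seq_len(n))
  for (v in pars$vars) {
    d <- pars$direction[[v]]
    load <- rho * d
    eps <- stats::rnorm(n)
    z <- load * adip + sqrt(1 - load^2) * eps
    mu <- vapply(groups, function(g) pars$table[[g]][v, "mean"],
                 numeric(1))
    sd <- vapply(groups, function(g) pars$table[[g]][v, "sd"],
                 numeric(1))
    x <- mu + sd * z
    # truncate at a small positive floor (concentrations cannot be < 0)
    bad <- which(x <= 0)
    for (i in bad) {
      for (try in 1:50) {
        xx <- mu[i] + sd[i] * stats::rnorm(1)
        if (xx > 0) { x[i] <- xx; break }
      }
      if (x[i] <= 0) x[i] <- mu[i] * 0.05
    }
    out[[v]] <- x
  }
  out
}

#' Simulate one omics layer
#'
#' Planted features get a mean shift of `effect_size` within-group SD
#' units (log scale for counts) in the case groups (obese and
#' lipodystrophy). Counts follow a gamma-Poisson (negative binomial)
#' model with per-sample library sizes and log-link group effects;
#' M-values arise from a logit-type transform of latent methylation
#' proportions; batches add recorded additive offsets.
#'
#' @param spec a [layer_spec()].
#' @param groups named character vector, subject id -> group.
#' @param seed integer seed.
#' @return an `omics_layer` with attributes `planted` (feature ids) and
#'   `effect_sizes`.
#' @export
simulate_layer <- function(spec, groups, seed = 1L) {
  stopifnot(inherits(spec, "layer_spec"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- length(groups)
  ids <- names(groups)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  p <- spec$n_features
  feat <- sprintf("%s_f%03d", spec$name, seq_len(p))
  planted <- feat[seq_len(spec$n_planted)]
  is_case <- groups %in% c("obese", "lipodystrophy")
  batch <- rep_len(paste0("b", seq_len(spec$batch_count)), n)

  if (spec$kind == "counts") {
    base_log <- stats::runif(p, 3, 8) # log mean expression
    eff <- matrix(rep(base_log, n), nrow = p)
    eff[seq_len(spec$n_planted), is_case] <-
      eff[seq_len(spec$n_planted), is_case] +
      spec$effect_size * sqrt(spec$dispersion + 0.05)
    if (spec$batch_count > 1) {
      boff <- stats::setNames(
        spec$batch_offset * sqrt(spec$dispersion + 0.05) *
          (seq_len(spec$batch_count) - 1),
        paste0("b", seq_len(spec$batch_count)))
      eff <- eff + matrix(rep(boff[batch], each = p), nrow = p)
    }
    libfac <- exp(stats::rnorm(n, 0, 0.2))
    mu <- sweep(exp(eff), 2, libfac, "*")
    if (spec$noise_sd == 0) {
      m <- round(mu)
    } else {
      size <- 1 / spec$dispersion
      m <- matrix(stats::rnbinom(p * n, mu = mu, size = size), nrow = p)
    }
  } else {
    sdn <- if (spec$noise_sd > 0) spec$noise_sd else 0
    base <- if (spec$kind == "m-value") stats::rnorm(p, 0, 1.5)
            else stats::runif(p, 5, 10)
    m <- matrix(rep(base, n), nrow = p) +
      matrix(stats::rnorm(p * n, 0, sdn), nrow = p)
    shift <- spec$effect_size * max(sdn, 1e-12)
    if (spec$noise_sd == 0) shift <- spec$effect_size
    m[seq_len(spec$n_planted), is_case] <-
      m[seq_len(spec$n_planted), is_case] + shift
    if (spec$batch_count > 1) {
      boff <- stats::setNames(
        spec$batch_offset * max(sdn, 1) *
          (seq_len(spec$batch_count) - 1),
        paste0("b", seq_len(spec$batch_count)))
      m <- m + matrix(rep(boff[batch], each = p), nrow = p)
    }
    if (spec$kind == "m-value") {
      # interpret as latent logit-scale values: map through the
      # proportion scale and back so values are genuine M-values
      m <- beta_to_m(stats::plogis(m * log(2)))
    }
  }
  dimnames(m) <- list(feat, ids)
  lay <- omics_layer(m, name = spec$name,
                     kind = if (spec$kind == "intensity") "intensity"
                            else if (spec$kind == "counts") "counts"
                            else if (spec$kind == "m-value") "m-value"
                            else "abundance",
                     batch = batch)
  attr(lay, "planted") <- planted
  attr(lay, "effect_sizes") <-
    stats::setNames(rep(spec$effect_size, length(planted)), planted)
  lay
}

#' Plant correlated module structure into a layer
#'
#' The first `n_modules * module_size` non-planted features are grouped
#' into modules sharing a latent factor, so their pairwise correlation is
#' approximately `within_module_corr`. Each module's latent factor is
#' coupled to one clinical trait at `trait_coupling_strength` (cycling
#' over the supplied traits). Remaining features keep their independent
#' noise.
#'
#' @param layer an `omics_layer` (abundance-like).
#' @param traits subjects x traits numeric data frame (aligned with the
#'   layer's columns); used for coupling.
#' @param n_modules,module_size,within_module_corr,trait_coupling_strength
#'   module structure parameters.
#' @param skip_features feature ids to leave untouched (e.g. planted
#'   discriminative features).
#' @param seed integer seed.
#' @return list with `layer` (modified) and `module_map` (feature ->
#'   module id, "none" elsewhere) and `coupled_traits` (module -> trait).
#' @export
plant_module_structure <- function(layer, traits, n_modules = 4,
                                   module_size = 30,
                                   within_module_corr = 0.6,
                                   trait_coupling_strength = 0.7,
                                   skip_features = character(0),
                                   seed = 1L) {
  m <- .layer_matrix(layer)
  avail <- setdiff(rownames(m), skip_features)
  if (n_modules * module_size > length(avail))
    stop("plant_module_structure: not enough features for ",
         n_modules, " x ", module_size, " modules")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- ncol(m)
  traits <- as.data.frame(traits)
  trait_names <- names(traits)[vapply(traits, is.numeric, logical(1))]
  module_map <- stats::setNames(rep("none", nrow(m)), rownames(m))
  coupled <- character(0)
  w <- within_module_corr
  for (k in seq_len(n_modules)) {
    members <- avail[((k - 1) * module_size + 1):(k * module_size)]
    tr <- trait_names[(k - 1) %% length(trait_names) + 1]
    zt <- as.numeric(scale(traits[[tr]]))
    cc <- trait_coupling_strength
    f <- cc * zt + sqrt(1 - cc^2) * stats::rnorm(n)
    noise <- matrix(stats::rnorm(length(members) * n), ncol = n)
    vals <- sqrt(w) * matrix(rep(f, each = length(members)), ncol = n) +
      sqrt(1 - w) * noise
    scale_ref <- stats::sd(m[members[1], ])
    if (!is.finite(scale_ref) || scale_ref == 0) scale_ref <- 1
    m[members, ] <- sweep(vals * scale_ref, 1,
                          rowMeans(m[members, , drop = FALSE]), "+")
    module_map[members] <- paste0("true_M", k)
    coupled[paste0("true_M", k)] <- tr
  }
  list(layer = .layer_rewrap(layer, m), module_map = module_map,
       coupled_traits = coupled)
}

#' Mask layers per subject (missing-at-random availability)
#'
#' Each (subject, layer) cell is masked independently with probability
#' `fraction`, except that training subjects are always complete.
#'
#' @param layers named list of layers.
#' @param subjects subject ids.
#' @param fraction masking probability in \[0, 1).
#' @param training_subjects ids never masked.
#' @param seed integer seed.
#' @return subjects x layers logical availability matrix (TRUE =
#'   measured).
#' @export
apply_missingness <- function(layers, subjects, fraction = 0,
                              training_subjects = character(0),
                              seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  L <- names(layers)
  avail <- matrix(stats::runif(length(subjects) * length(L)) >= fraction,
                  nrow = length(subjects),
                  dimnames = list(subjects, L))
  avail[subjects %in% training_subjects, ] <- TRUE
  avail
}

#' Simulate a full multi-omic cohort with known ground truth
#'
#' Draws the subject table (group-specific clinical distributions with a
#' shared latent adiposity factor, derived LAR/HOMA-IR/AT-IR indices),
#' simulates every configured layer with planted discriminative
#' features, plants correlated metabolite modules coupled to clinical
#' traits into the first abundance-kind layer, and draws the per-subject
#' layer availability mask. Identical config and seed give bit-identical
#' output.
#'
#' @param config a [simulation_config()].
#' @return list with `subjects` (data frame), `layers` (named list of
#'   `omics_layer`s), `availability` (subjects x layers logical), and
#'   `truth` (planted features, module map, coupled traits, group
#'   assignment, effect sizes, seed).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  gs <- config$group_sizes
  groups <- rep(names(gs), times = gs)
  n <- length(groups)
  ids <- sprintf("S%04d", seq_len(n))
  names(groups) <- ids

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  clin <- .draw_clinical(groups)
  subjects <- data.frame(id = ids, group = groups, sex = sex, clin,
                         row.names = ids)
  # derived indices are always recomputed from the assay values
  subjects$lar <- lar(subjects$leptin, subjects$adiponectin)
  subjects$homa <- homa_ir_si(subjects$glucose, subjects$insulin)
  subjects$at_ir <- at_ir_si(subjects$insulin, subjects$ffa)

  layers <- list(); truth_planted <- list(); effect_sizes <- list()
  for (i in seq_along(config$layer_specs)) {
    sp <- config$layer_specs[[i]]
    lay <- simulate_layer(sp, groups, seed = config$seed + 1000L * i)
    layers[[sp$name]] <- lay
    truth_planted[[sp$name]] <- attr(lay, "planted")
    effect_sizes[[sp$name]] <- attr(lay, "effect_sizes")
  }

  module_map <- NULL; coupled <- NULL
  first_ab <- which(vapply(config$layer_specs, function(s)
    s$kind %in% c("abundance", "intensity"), logical(1)))[1]
  if (!is.na(first_ab) && config$n_modules > 0) {
    nm <- config$layer_specs[[first_ab]]$name
    pm <- plant_module_structure(
      layers[[nm]], traits = subjects[, c("bmi", "tg", "hdl", "lar")],
      n_modules = config$n_modules, module_size = config$module_size,
      within_module_corr = config$within_module_corr,
      trait_coupling_strength = config$trait_coupling_strength,
      skip_features = truth_planted[[nm]],
      seed = config$seed + 500000L)
    layers[[nm]] <- pm$layer
    module_map <- pm$module_map
    coupled <- pm$coupled_traits
  }

  training <- ids[groups %in% c("lean-BD", "obese", "lipodystrophy")]
  availability <- apply_missingness(layers, ids,
                                    fraction = config$missing_layer_fraction,
                                    training_subjects = training,
                                    seed = config$seed + 900000L)
  truth <- list(planted_features = truth_planted,
                module_assignment_true = module_map,
                coupled_traits = coupled,
                group_assignment = groups,
                effect_sizes = effect_sizes,
                training_subjects = training,
                seed = config$seed)
  list(subjects = subjects, layers = layers,
       availability = availability, truth = truth)
}

#' Write a simulated cohort to plain-text files
#'
#' Subject table and availability mask as TSV, each layer as TSV
#' (features in rows, first column the feature id), truth as JSON.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(subjects = file.path(dir, "subjects.tsv"),
             availability = file.path(dir, "availability.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(cohort$subjects, paths["subjects"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(id = rownames(cohort$availability),
                                cohort$availability),
                     paths["availability"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  for (nm in names(cohort$layers)) {
    p <- file.path(dir, paste0("layer_", nm, ".tsv"))
    m <- .layer_matrix(cohort$layers[[nm]])
    utils::write.table(data.frame(feature_id = rownames(m), m),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("layer_", nm)] <- p
  }
  invisible(paths)
}
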