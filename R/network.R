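#' Configuration for the signed weighted metabolite network
#'
#' @param correlation "bicor" (biweight midcorrelation, default) or
#'   "pearson".
#' @param power soft-threshold exponent, an integer >= 1 or "auto" to
#'   select by scale-free fit.
#' @param min_module_size smallest allowed proper module (default 20).
#' @param merge_cut_height eigen-metabolite dissimilarity below which
#'   modules are merged (default 0.25).
#' @param reassign_threshold kept for interface compatibility (default 0).
#' @param scale_free_target_r2 target signed scale-free fit R^2 for
#'   automatic power selection (default 0.80).
#' @param powers_grid candidate powers for "auto" (default 1:30).
#' @param cut_height_frac static tree-cut height as a fraction of the
#'   dendrogram merge-height range (default 0.99).
#' @param kme_min minimum absolute correlation of a member with its
#'   module eigen-metabolite (kME); weaker members are moved to the
#'   "unassigned" background module (default 0.3). This is what sends
#'   uncorrelated metabolites to the ad hoc extra module.
#' @return a `network_config` list.
#' @export
network_config <- function(correlation = c("bicor", "pearson"),
                           power = "auto", min_module_size = 20,
                           merge_cut_height = 0.25,
                           reassign_threshold = 0,
                           scale_free_target_r2 = 0.80,
                           powers_grid = 1:30,
                           cut_height_frac = 0.99,
                           kme_min = 0.3) {
  correlation <- match.arg(correlation)
  stopifnot(min_module_size >= 2,
            merge_cut_height > 0, merge_cut_height < 1)
  structure(list(correlation = correlation, power = power,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height,
                 reassign_threshold = reassign_threshold,
                 scale_free_target_r2 = scale_free_target_r2,
                 powers_grid = powers_grid,
                 cut_height_frac = cut_height_frac,
                 kme_min = kme_min),
            class = "network_config")
}

#' Biweight midcorrelation
#'
#' Robust correlation: with u = (x - median(x)) / (9 * MAD(x)) (MAD
#' unscaled) and weights w = (1 - u^2)^2 on |u| < 1, the biweight
#' midcorrelation is the correlation of the weighted, median-centred
#' observations. Falls back to Pearson with a warning when either MAD is
#' zero.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\].
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("bicor: length mismatch")
  if (length(x) < 3) stop("bicor: need length >= 3")
  wx <- .bicor_weights(x); wy <- .bicor_weights(y)
  if (is.null(wx) || is.null(wy)) {
    warning("bicor: zero MAD; falling back to Pearson")
    return(stats::cor(x, y))
  }
  a <- wx$w * (x - wx$med)
  b <- wy$w * (y - wy$med)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

.bicor_weights <- function(x) {
  med <- stats::median(x)
  m <- stats::mad(x, constant = 1)
  if (m == 0) return(NULL)
  u <- (x - med) / (9 * m)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  list(w = w, med = med)
}

#' Pairwise correlation matrix of metabolites
#'
#' @param data samples x metabolites numeric matrix.
#' @param method "bicor" or "pearson".
#' @return metabolites x metabolites correlation matrix.
#' @export
cor_matrix <- function(data, method = c("bicor", "pearson")) {
  method <- match.arg(method)
  data <- as.matrix(data)
  if (method == "pearson") return(stats::cor(data))
  p <- ncol(data)
  # precompute weighted residuals; Pearson fallback for zero-MAD columns
  pre <- vector("list", p)
  fallback <- logical(p)
  for (j in seq_len(p)) {
    wj <- .bicor_weights(data[, j])
    if (is.null(wj)) {
      fallback[j] <- TRUE
      v <- data[, j] - mean(data[, j])
    } else {
      v <- wj$w * (data[, j] - wj$med)
    }
    pre[[j]] <- v / sqrt(sum(v^2))
  }
  if (any(fallback))
    warning("cor_matrix: zero MAD for ", sum(fallback),
            " column(s); Pearson fallback used there")
  v <- do.call(cbind, pre)
  r <- crossprod(v)
  r <- pmin(pmax(r, -1), 1)
  dimnames(r) <- list(colnames(data), colnames(data))
  diag(r) <- 1
  r
}

#' Signed adjacency from a correlation matrix
#'
#' a_ij = ((1 + cor_ij) / 2)^beta, with unit diagonal.
#'
#' @param corr correlation matrix in \[-1, 1\].
#' @param beta soft-threshold power (>= 1).
#' @return adjacency matrix in \[0, 1\].
#' @export
signed_adjacency <- function(corr, beta) {
  stopifnot(beta >= 1)
  a <- ((1 + corr) / 2)^beta
  diag(a) <- 1
  a
}

#' Soft-threshold selection by scale-free topology fit
#'
#' For each candidate power the signed adjacency is formed, the
#' connectivities k_i are computed, and log10 p(k) is regressed on
#' log10 k over equal-width connectivity bins. The signed fit index is
#' R^2 times the sign of the negative slope (a scale-free network has a
#' decreasing degree distribution). The selected power is the smallest
#' one reaching `scale_free_target_r2`; if none does, the power with the
#' best fit is returned with a warning.
#'
#' @param corr correlation matrix.
#' @param config a [network_config()].
#' @param n_bins connectivity bins for the fit (default 10).
#' @param k_min minimum mean connectivity for a power to be considered;
#'   below this the network is degenerate (nodes essentially isolated)
#'   and an apparently good log-log fit is meaningless (default 0.1).
#' @return list with `power` and `fit_table` (power, signed R^2, mean k).
#' @export
pick_soft_threshold <- function(corr, config = network_config(),
                                n_bins = 10, k_min = 0.1) {
  powers <- config$powers_grid
  rows <- lapply(powers, function(b) {
    a <- signed_adjacency(corr, b)
    k <- colSums(a) - 1
    data.frame(power = b, r2 = .scale_free_r2(k, n_bins), mean_k = mean(k))
  })
  fit <- do.call(rbind, rows)
  rownames(fit) <- NULL
  usable <- fit$mean_k >= k_min
  ok <- which(fit$r2 >= config$scale_free_target_r2 & usable)
  if (length(ok) > 0) {
    power <- fit$power[ok[1]]
  } else {
    warning("pick_soft_threshold: no usable power reached target R^2 ",
            config$scale_free_target_r2, "; using best fit")
    cand <- if (any(usable)) which(usable) else seq_len(nrow(fit))
    power <- fit$power[cand[which.max(fit$r2[cand])]]
  }
  list(power = power, fit_table = fit)
}

.scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  keep <- !is.na(dk) & dk > 0 & !is.na(pk) & pk > 0
  if (sum(keep) < 3) return(0)
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[2]
  -sign(slope) * r2
}

#' Signed topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij), with
#' the sum over u distinct from i and j, k_i the connectivity of node i,
#' and unit diagonal.
#'
#' @param adjacency symmetric adjacency in \[0, 1\] with unit diagonal.
#' @return TOM matrix in \[0, 1\].
#' @export
signed_tom <- function(adjacency) {
  a <- as.matrix(adjacency)
  stopifnot(nrow(a) == ncol(a))
  k <- colSums(a) - 1
  num_shared <- a %*% a
  # remove the u = i and u = j terms from the shared-neighbour sum
  num_shared <- num_shared - sweep(a, 1, diag(a), "*") -
    sweep(a, 2, diag(a), "*")
  num <- num_shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Eigen-metabolite of a module
#'
#' The module's summary profile: member columns are z-scored and the
#' first singular direction over samples is extracted (equivalently the
#' first principal-component score vector, scaled to unit norm). The
#' sign is fixed so the mean correlation with the members is
#' non-negative. Variance explained is sigma_1^2 / sum sigma^2.
#'
#' @param module_data samples x members numeric matrix (>= 2 members,
#'   >= 3 samples).
#' @return list with `me` (unit-norm vector over samples) and
#'   `variance_explained`.
#' @export
eigen_metabolite <- function(module_data) {
  x <- as.matrix(module_data)
  if (ncol(x) < 2) stop("eigen_metabolite: need >= 2 members")
  if (nrow(x) < 3) stop("eigen_metabolite: need >= 3 samples")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) < 1) stop("eigen_metabolite: all members constant")
  z <- scale(x)
  sv <- svd(z)
  me <- sv$u[, 1]
  if (mean(stats::cor(me, z)) < 0) me <- -me
  list(me = stats::setNames(me, rownames(x)),
       variance_explained = sv$d[1]^2 / sum(sv$d^2))
}

#' Detect metabolite modules from a TOM
#'
#' Average-linkage hierarchical clustering on 1 - TOM with a static tree
#' cut at `cut_height_frac` of the merge-height range; clusters smaller
#' than `min_module_size` are pooled into the reserved "unassigned"
#' label. Close modules (by eigen-metabolite correlation) are then
#' merged via [merge_close_modules()].
#'
#' @param tom topological overlap matrix.
#' @param data samples x metabolites matrix (needed for eigen-metabolite
#'   merging); column order must match `tom`.
#' @param config a [network_config()].
#' @return a `module_result` list: `assignment` (named character vector,
#'   "unassigned" for the background module), `eigen_metabolites`
#'   (samples x modules), `variance_explained`.
#' @export
detect_modules <- function(tom, data, config = network_config()) {
  tom <- as.matrix(tom)
  p <- ncol(tom)
  ids <- colnames(tom)
  if (is.null(ids)) ids <- paste0("m", seq_len(p))
  if (p < config$min_module_size) {
    return(.module_result(stats::setNames(rep("unassigned", p), ids), data))
  }
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  hr <- range(h$height)
  cut_h <- hr[1] + config$cut_height_frac * (hr[2] - hr[1])
  cl <- stats::cutree(h, h = cut_h)
  tab <- table(cl)
  lab <- ifelse(tab[as.character(cl)] >= config$min_module_size,
                paste0("M", cl), "unassigned")
  # renumber proper modules by decreasing size
  proper <- setdiff(unique(lab), "unassigned")
  sizes <- sort(table(lab[lab != "unassigned"]), decreasing = TRUE)
  remap <- stats::setNames(paste0("M", seq_along(sizes)), names(sizes))
  lab[lab != "unassigned"] <- remap[lab[lab != "unassigned"]]
  assignment <- stats::setNames(lab, ids)
  assignment <- .prune_weak_members(assignment, data, config)
  res <- .module_result(assignment, data)
  merge_close_modules(res, data, cut_height = config$merge_cut_height)
}

# membership quality control: members whose correlation with their
# module eigen-metabolite (kME) is below kme_min go to "unassigned",
# then modules falling under min_module_size are dissolved. A single
# pass against the original module ME keeps the rule non-adaptive (no
# re-estimation that could let a noise cluster concentrate itself).
.prune_weak_members <- function(assignment, data, config) {
  data <- as.matrix(data)
  for (m in setdiff(unique(assignment), "unassigned")) {
    members <- names(assignment)[assignment == m]
    if (length(members) >= 2) {
      em <- eigen_metabolite(data[, members, drop = FALSE])
      kme <- as.numeric(stats::cor(em$me, data[, members, drop = FALSE]))
      assignment[members[abs(kme) < config$kme_min]] <- "unassigned"
    }
    members <- names(assignment)[assignment == m]
    if (length(members) < config$min_module_size)
      assignment[members] <- "unassigned"
  }
  assignment
}

.module_result <- function(assignment, data) {
  data <- as.matrix(data)
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  mes <- NULL; ve <- numeric(0)
  if (length(mods) > 0) {
    out <- lapply(mods, function(m) {
      eigen_metabolite(data[, names(assignment)[assignment == m],
                            drop = FALSE])
    })
    mes <- do.call(cbind, lapply(out, `[[`, "me"))
    colnames(mes) <- mods
    rownames(mes) <- rownames(data)
    ve <- stats::setNames(vapply(out, `[[`, numeric(1),
                                 "variance_explained"), mods)
  }
  structure(list(assignment = assignment, eigen_metabolites = mes,
                 variance_explained = ve),
            class = "module_result")
}

#' Merge modules with correlated eigen-metabolites
#'
#' Iteratively merges the closest module pair while their
#' eigen-metabolite dissimilarity 1 - cor(ME_a, ME_b) is below
#' `cut_height`, recomputing eigen-metabolites after every merge.
#'
#' @param result a `module_result`.
#' @param data samples x metabolites matrix.
#' @param cut_height merge threshold on ME dissimilarity (default 0.25).
#' @return updated `module_result`.
#' @export
merge_close_modules <- function(result, data, cut_height = 0.25) {
  assignment <- result$assignment
  repeat {
    mods <- setdiff(sort(unique(assignment)), "unassigned")
    if (length(mods) < 2) break
    res <- .module_result(assignment, data)
    cc <- stats::cor(res$eigen_metabolites)
    diss <- 1 - cc
    diag(diss) <- Inf
    min_d <- min(diss)
    if (min_d >= cut_height) break
    idx <- which(diss == min_d, arr.ind = TRUE)[1, ]
    a <- mods[idx[1]]; b <- mods[idx[2]]
    assignment[assignment == b] <- a
  }
  # relabel by decreasing size for stable naming
  mods <- setdiff(unique(assignment), "unassigned")
  if (length(mods) > 0) {
    sizes <- sort(table(assignment[assignment != "unassigned"]),
                  decreasing = TRUE)
    remap <- stats::setNames(paste0("M", seq_along(sizes)), names(sizes))
    assignment[assignment != "unassigned"] <-
      remap[assignment[assignment != "unassigned"]]
  }
  .module_result(assignment, data)
}

#' Module-trait association table
#'
#' Pearson correlation of each eigen-metabolite with each trait; the
#' p-value uses the Student-t transform t = r sqrt(n - 2) / sqrt(1 - r^2)
#' with n - 2 degrees of freedom; FDR (Benjamini-Hochberg) is applied
#' across the full module x trait grid.
#'
#' @param mes samples x modules eigen-metabolite matrix.
#' @param traits samples x traits numeric data frame/matrix (aligned on
#'   rows).
#' @return data frame (module, trait, n, r, p, fdr); constant traits give
#'   NA cells.
#' @export
module_trait_association <- function(mes, traits) {
  mes <- as.matrix(mes)
  traits <- as.matrix(traits)
  stopifnot(nrow(mes) == nrow(traits))
  grid <- expand.grid(module = colnames(mes), trait = colnames(traits),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- mes[, grid$module[i]]; y <- traits[, grid$trait[i]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 4 || stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0)
      return(data.frame(grid[i, ], n = n, r = NA_real_, p = NA_real_))
    r <- stats::cor(x[ok], y[ok])
    p <- cor_pvalue_student(r, n)
    data.frame(grid[i, ], n = n, r = r, p = p)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Student-t p-value of a Pearson correlation
#'
#' @param r correlation.
#' @param n number of paired observations.
#' @return two-sided p-value.
#' @export
cor_pvalue_student <- function(r, n) {
  t <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Cluster eigen-metabolites by adjacency
#'
#' ME adjacency (1 + cor) / 2; average-linkage clustering on
#' 1 - adjacency cut into `n_clusters` groups; per-cluster average ME per
#' subject is returned for group-separation plots.
#'
#' @param mes samples x modules eigen-metabolite matrix.
#' @param n_clusters number of ME clusters.
#' @return list with `clusters` (module -> cluster label), `adjacency`,
#'   and `cluster_means` (samples x clusters).
#' @export
me_adjacency_clusters <- function(mes, n_clusters) {
  mes <- as.matrix(mes)
  adj <- (1 + stats::cor(mes)) / 2
  h <- stats::hclust(stats::as.dist(1 - adj), method = "average")
  cl <- stats::cutree(h, k = n_clusters)
  means <- sapply(sort(unique(cl)), function(k)
    rowMeans(mes[, names(cl)[cl == k], drop = FALSE]))
  colnames(means) <- paste0("C", sort(unique(cl)))
  list(clusters = stats::setNames(paste0("C", cl), names(cl)),
       adjacency = adj, cluster_means = means)
}

#' Consensus topological overlap of two cohorts
#'
#' TOM_B is rescaled so that its upper `scale_quantile` quantile matches
#' TOM_A's, then the consensus is the element-wise minimum.
#'
#' @param tom_a,tom_b TOM matrices over the same metabolites.
#' @param scale_quantile quantile used for scale matching (default 0.95).
#' @return consensus TOM matrix.
#' @export
consensus_tom <- function(tom_a, tom_b, scale_quantile = 0.95) {
  a <- as.matrix(tom_a); b <- as.matrix(tom_b)
  if (!all(dim(a) == dim(b)))
    stop("consensus_tom: dimension mismatch")
  off <- upper.tri(a)
  qa <- stats::quantile(a[off], scale_quantile)
  qb <- stats::quantile(b[off], scale_quantile)
  if (qb > 0) b <- b * (qa / qb)
  cons <- pmin(a, pmin(b, 1))
  diag(cons) <- 1
  cons
}
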