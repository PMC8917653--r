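#' Construct an omics layer container
#'
#' A light container for a features x samples matrix plus layer metadata.
#' Used throughout the pipeline; all preprocessing operations accept and
#' return either a bare matrix or an `omics_layer`.
#'
#' @param matrix numeric matrix, features in rows, samples in columns.
#' @param name layer name.
#' @param kind one of "counts", "m-value", "beta-value", "abundance",
#'   "intensity".
#' @param batch optional per-sample batch labels.
#' @param status optional per-sample status covariate (e.g. patient/donor).
#' @return An `omics_layer` object.
#' @export
omics_layer <- function(matrix, name = "layer",
                        kind = c("abundance", "counts", "m-value",
                                 "beta-value", "intensity"),
                        batch = NULL, status = NULL) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  if (is.null(rownames(matrix)))
    rownames(matrix) <- paste0("f", seq_len(nrow(matrix)))
  if (is.null(colnames(matrix)))
    colnames(matrix) <- paste0("s", seq_len(ncol(matrix)))
  if (anyDuplicated(rownames(matrix)) || anyDuplicated(colnames(matrix)))
    stop("omics_layer: duplicate feature or sample ids")
  if (kind == "counts" &&
      any(matrix < 0 | abs(matrix - round(matrix)) > 1e-8, na.rm = TRUE))
    stop("omics_layer: counts must be non-negative integers")
  if (!is.null(batch)) {
    batch <- stats::setNames(as.character(batch), colnames(matrix))
  }
  if (!is.null(status)) {
    status <- stats::setNames(as.character(status), colnames(matrix))
  }
  structure(list(name = name, kind = kind, matrix = matrix,
                 batch = batch, status = status),
            class = "omics_layer")
}

.layer_matrix <- function(x) if (inherits(x, "omics_layer")) x$matrix else as.matrix(x)

.layer_rewrap <- function(x, m) {
  if (inherits(x, "omics_layer")) { x$matrix <- m; x } else m
}

#' Rescale each sample to unit median
#'
#' Divides every sample column by its median over observed values, so the
#' per-sample median becomes 1 (the standard metabolomics rescaling).
#'
#' @param layer matrix or `omics_layer` (features x samples).
#' @return same shape, rescaled.
#' @export
median_rescale <- function(layer) {
  m <- .layer_matrix(layer)
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med)) || any(med <= 0))
    stop("median_rescale: each sample needs a positive median")
  .layer_rewrap(layer, sweep(m, 2, med, "/"))
}

#' K-nearest-neighbour imputation in feature space
#'
#' Features missing in at least `max_missing_feature` of samples and
#' samples missing at least `max_missing_sample` of features are dropped
#' first (strict thresholds). Each remaining missing cell (feature f,
#' sample s) is replaced by the mean over the k features nearest to f
#' (Euclidean distance over co-observed samples) of their values in
#' sample s.
#'
#' @param layer matrix or `omics_layer`.
#' @param k number of neighbours (default 10); clamped with a warning when
#'   fewer neighbours are available.
#' @param max_missing_feature drop features with missing fraction >= this
#'   (default 0.5).
#' @param max_missing_sample drop samples with missing fraction >= this
#'   (default 0.8).
#' @return completed matrix/layer (possibly with dropped rows/columns).
#' @export
knn_impute <- function(layer, k = 10, max_missing_feature = 0.5,
                       max_missing_sample = 0.8) {
  if (k < 1) stop("knn_impute: k must be >= 1")
  stopifnot(max_missing_feature > 0, max_missing_feature <= 1,
            max_missing_sample > 0, max_missing_sample <= 1)
  m <- .layer_matrix(layer)
  keep_f <- rowMeans(is.na(m)) < max_missing_feature
  m <- m[keep_f, , drop = FALSE]
  keep_s <- colMeans(is.na(m)) < max_missing_sample
  m <- m[, keep_s, drop = FALSE]
  if (!anyNA(m)) return(.layer_rewrap(layer, m))
  if (k > nrow(m) - 1) {
    warning("knn_impute: k clamped to ", nrow(m) - 1)
    k <- nrow(m) - 1
  }
  need <- which(rowSums(is.na(m)) > 0)
  out <- m
  for (f in need) {
    # Euclidean distance to every other feature over co-observed samples,
    # scaled up to the full sample count (standard KNN-imputation metric)
    diffs <- sweep(m, 2, m[f, ], "-")
    d2 <- rowMeans(diffs^2, na.rm = TRUE)
    d2[f] <- Inf
    d2[!is.finite(d2)] <- Inf
    ord <- order(d2)
    miss_cols <- which(is.na(m[f, ]))
    for (s in miss_cols) {
      cand <- ord[!is.na(m[ord, s]) & is.finite(d2[ord])]
      nb <- utils::head(cand, k)
      if (length(nb) == 0) {
        out[f, s] <- mean(m[f, ], na.rm = TRUE)
      } else {
        if (length(nb) < k)
          warning("knn_impute: only ", length(nb),
                  " neighbours available for a cell; using those")
        out[f, s] <- mean(m[nb, s])
      }
    }
  }
  .layer_rewrap(layer, out)
}

#' Empirical-Bayes batch adjustment
#'
#' Location/scale batch adjustment with parametric empirical-Bayes
#' shrinkage (ComBat), preserving the effects of the supplied biological
#' covariates (e.g. patient/donor status). With a single batch the input
#' is returned unchanged with a warning.
#'
#' @param layer matrix or `omics_layer` with batch labels.
#' @param batch per-sample batch labels; defaults to the layer's.
#' @param covariates optional data frame (or vector) of per-sample
#'   biological covariates to protect; defaults to the layer's status.
#' @return adjusted matrix/layer.
#' @export
eb_batch_adjust <- function(layer, batch = NULL, covariates = NULL) {
  m <- .layer_matrix(layer)
  if (is.null(batch) && inherits(layer, "omics_layer")) batch <- layer$batch
  if (is.null(batch)) stop("eb_batch_adjust: batch labels required")
  batch <- as.character(batch)
  if (length(unique(batch)) < 2) {
    warning("eb_batch_adjust: single batch; returning input unchanged")
    return(layer)
  }
  if (min(table(batch)) < 2)
    stop("eb_batch_adjust: every batch needs >= 2 samples")
  if (is.null(covariates) && inherits(layer, "omics_layer"))
    covariates <- layer$status
  mod <- NULL
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    mod <- stats::model.matrix(~ ., data = cv)
    if (qr(cbind(mod, stats::model.matrix(~ batch)))$rank <
        ncol(mod) + length(unique(batch)) - 1)
      stop("eb_batch_adjust: covariates confounded with batch")
  }
  adj <- suppressMessages(
    sva::ComBat(dat = m, batch = batch, mod = mod,
                par.prior = TRUE, prior.plots = FALSE))
  .layer_rewrap(layer, adj)
}

#' Trimmed mean of M-values (TMM) scale factors
#'
#' Computes per-sample TMM normalisation factors; the effective library
#' size of a sample is its raw library size multiplied by its factor.
#' The reference sample is the column whose library size is closest to
#' the median library size. Factors are normalised to geometric mean 1.
#'
#' @param counts matrix or `omics_layer` of non-negative counts.
#' @param trim_m two-sided trim fraction on log-ratios (default 0.3).
#' @param trim_a two-sided trim fraction on average abundance
#'   (default 0.05).
#' @return list with `factors`, `lib_size`, `effective_lib_size`.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  m <- .layer_matrix(counts)
  if (ncol(m) < 2) stop("tmm_factors: need >= 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0)) stop("tmm_factors: all-zero sample")
  ref <- which.min(abs(lib - stats::median(lib)))
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref,
                              logratioTrim = trim_m, sumTrim = trim_a)
  f <- stats::setNames(as.numeric(f), colnames(m))
  list(factors = f, lib_size = lib, effective_lib_size = lib * f)
}

#' Counts to log2 counts-per-million
#'
#' log2-CPM with a pseudocount: log2((count + prior) /
#' (effective_lib_size + 2 * prior) * 1e6). This is the standard
#' log-scale CPM transform used downstream of TMM normalisation.
#'
#' @param counts matrix or `omics_layer` of counts.
#' @param effective_lib_sizes per-sample effective library sizes
#'   (default: raw column sums).
#' @param prior pseudocount (default 0.5).
#' @return real-valued matrix/layer.
#' @export
counts_to_logcpm <- function(counts, effective_lib_sizes = NULL,
                             prior = 0.5) {
  m <- .layer_matrix(counts)
  if (is.null(effective_lib_sizes)) effective_lib_sizes <- colSums(m)
  if (any(effective_lib_sizes <= 0))
    stop("counts_to_logcpm: effective library sizes must be > 0")
  out <- log2(sweep(m + prior, 2, effective_lib_sizes + 2 * prior, "/") * 1e6)
  res <- .layer_rewrap(counts, out)
  if (inherits(res, "omics_layer")) res$kind <- "abundance"
  res
}

#' Methylation beta-value / M-value transforms
#'
#' M = log2(beta / (1 - beta)); beta values are clipped to
#' \[eps, 1 - eps\] first so the transform is finite. `m_to_beta` is the
#' exact inverse.
#'
#' @param beta beta values in (0, 1) (clipped).
#' @param eps clipping bound (default 1e-6).
#' @return M values.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m M values.
#' @export
m_to_beta <- function(m) {
  x <- 2^m
  x / (1 + x)
}

#' Quantile normalisation across samples
#'
#' Forces every sample column to share the same distribution (the
#' row-rank means); ties are resolved by averaging the tied quantiles.
#'
#' @param layer matrix or `omics_layer` with no missing values.
#' @return normalised matrix/layer.
#' @export
quantile_normalize <- function(layer) {
  m <- .layer_matrix(layer)
  if (anyNA(m))
    stop("quantile_normalize: missing values present; impute first")
  if (ncol(m) == 1) return(layer)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  .layer_rewrap(layer, out)
}

#' Drop zero/low-variance features
#'
#' @param layer matrix or `omics_layer`.
#' @param min_variance features with variance <= this are dropped
#'   (default 0, i.e. drop constants).
#' @return filtered matrix/layer with attribute `n_retained`.
#' @export
variance_filter <- function(layer, min_variance = 0) {
  m <- .layer_matrix(layer)
  v <- apply(m, 1, stats::var, na.rm = TRUE)
  keep <- !is.na(v) & v > min_variance
  out <- .layer_rewrap(layer, m[keep, , drop = FALSE])
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Filter RRBS methylation sites on coverage and SNP overlap
#'
#' Sites overlapping a SNP are dropped. Per sample, coverage below
#' `min_cov` or above the per-sample `high_cov_quantile` quantile is
#' marked missing; sites missing in more than `max_missing` of
#' individuals are then dropped.
#'
#' @param coverage sites x samples integer coverage matrix with site
#'   rownames.
#' @param snp_sites character vector of site ids overlapping SNPs.
#' @param min_cov minimum per-sample coverage (default 5).
#' @param high_cov_quantile per-sample upper coverage quantile beyond
#'   which a site is treated as missing (default 0.999).
#' @param max_missing maximum tolerated missing fraction per site
#'   (default 0.05).
#' @return list with `kept` site ids and an `audit` data frame
#'   (site, reason) for dropped sites.
#' @export
rrbs_site_filter <- function(coverage, snp_sites = character(0),
                             min_cov = 5, high_cov_quantile = 0.999,
                             max_missing = 0.05) {
  m <- as.matrix(coverage)
  if (any(m < 0, na.rm = TRUE)) stop("rrbs_site_filter: negative coverage")
  sites <- rownames(m)
  if (is.null(sites)) sites <- as.character(seq_len(nrow(m)))
  audit <- data.frame(site = character(0), reason = character(0))
  snp_hit <- sites %in% snp_sites
  if (any(snp_hit))
    audit <- rbind(audit, data.frame(site = sites[snp_hit],
                                     reason = "snp_overlap"))
  hi <- apply(m, 2, stats::quantile, probs = high_cov_quantile,
              na.rm = TRUE)
  missing_mask <- is.na(m) | m < min_cov |
    sweep(m, 2, hi, ">")
  frac_missing <- rowMeans(missing_mask)
  too_missing <- !snp_hit & frac_missing > max_missing
  if (any(too_missing))
    audit <- rbind(audit, data.frame(site = sites[too_missing],
                                     reason = "coverage_missingness"))
  list(kept = sites[!snp_hit & !too_missing], audit = audit)
}

#' Cross-technology reproducibility filter for methylation sites
#'
#' Compares methylation percentages measured on the same individuals by
#' two technologies and drops sites whose absolute difference exceeds
#' `max_abs_diff` percentage points in more than `max_frac` of
#' individuals.
#'
#' @param meth_pct_a,meth_pct_b sites x individuals matrices of
#'   methylation percentages, aligned on sites and shared individuals.
#' @param max_abs_diff tolerated absolute difference in percentage points
#'   (default 10).
#' @param max_frac tolerated fraction of discordant individuals
#'   (default 0.7).
#' @return list with `kept` site ids and `audit` of dropped sites.
#' @export
cross_technology_filter <- function(meth_pct_a, meth_pct_b,
                                    max_abs_diff = 10, max_frac = 0.7) {
  a <- as.matrix(meth_pct_a); b <- as.matrix(meth_pct_b)
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) == 0)
    stop("cross_technology_filter: no shared individuals")
  a <- a[, shared, drop = FALSE]; b <- b[rownames(a), shared, drop = FALSE]
  frac_bad <- rowMeans(abs(a - b) > max_abs_diff, na.rm = TRUE)
  drop <- frac_bad > max_frac
  sites <- rownames(a)
  if (is.null(sites)) sites <- as.character(seq_len(nrow(a)))
  list(kept = sites[!drop],
       audit = data.frame(site = sites[drop],
                          reason = rep("cross_technology_variation",
                                       sum(drop))))
}

#' Merge peaks reproducible across individuals
#'
#' Builds a master peak set: positions covered by peaks from at least
#' `min_support` distinct samples are kept, and overlapping qualifying
#' stretches are merged into single intervals. Coordinates are 0-based
#' half-open (BED convention).
#'
#' @param intervals data frame with columns `chrom`, `start`, `end`,
#'   `sample_id` (0-based half-open).
#' @param min_support minimum number of distinct supporting samples
#'   (default 5).
#' @return data frame of merged intervals (`chrom`, `start`, `end`) with
#'   attribute `width_summary` (min/median/max merged widths).
#' @export
merge_reproducible_peaks <- function(intervals, min_support = 5) {
  need <- c("chrom", "start", "end", "sample_id")
  if (!all(need %in% names(intervals)))
    stop("merge_reproducible_peaks: need columns ",
         paste(need, collapse = ", "))
  bad <- which(intervals$start >= intervals$end)
  if (length(bad) > 0)
    stop("merge_reproducible_peaks: start >= end at line ", bad[1])
  if (nrow(intervals) == 0 ||
      length(unique(intervals$sample_id)) < min_support) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0))
    attr(out, "width_summary") <- c(min = NA_real_, median = NA_real_,
                                    max = NA_real_)
    return(out)
  }
  # common seqinfo so per-sample coverage vectors are conformable
  chroms <- sort(unique(as.character(intervals$chrom)))
  seqlen <- vapply(chroms, function(cc)
    max(intervals$end[intervals$chrom == cc]) + 1L, numeric(1))
  # per-sample reduce so one sample contributes at most 1 to any base
  gr_list <- lapply(split(intervals, intervals$sample_id), function(d) {
    gr <- GenomicRanges::GRanges(
      factor(d$chrom, levels = chroms),
      IRanges::IRanges(start = d$start + 1, end = d$end),
      seqlengths = seqlen)
    GenomicRanges::reduce(gr)
  })
  cov <- Reduce(`+`, lapply(gr_list, GenomicRanges::coverage))
  keep <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(keep))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr))
  w <- out$end - out$start
  attr(out, "width_summary") <- c(min = min(w), median = stats::median(w),
                                  max = max(w))
  out
}
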