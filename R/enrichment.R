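#' Hypergeometric set-overlap test (upper tail)
#'
#' P\[X >= k\] for the overlap of two sets of sizes nA and nB drawn from a
#' universe of size N: the standard enrichment test for gene-set
#' overlaps.
#'
#' @param n_universe universe size N.
#' @param n_a,n_b set sizes.
#' @param k observed overlap.
#' @return exact upper-tail p-value.
#' @export
hypergeometric_overlap <- function(n_universe, n_a, n_b, k) {
  if (n_a > n_universe || n_b > n_universe || k > min(n_a, n_b) ||
      k < 0 || k < n_a + n_b - n_universe)
    stop("hypergeometric_overlap: impossible configuration")
  stats::phyper(k - 1, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
}

#' Tissue-specificity classification of expression profiles
#'
#' Classifies each gene from a TPM matrix using, in precedence order:
#' tissue enriched (expression > `min_tpm` and at least `fold` times
#' higher in one tissue than in every other tissue), group enriched
#' (a group of 2..`group_max` tissues whose minimum is > `min_tpm` and
#' at least `fold` times the maximum of all remaining tissues), and
#' tissue enhanced (expression > `min_tpm` and at least `fold` times the
#' average of all other tissues).
#'
#' @param tpm genes x tissues non-negative matrix.
#' @param fold fold-change threshold (default 5).
#' @param min_tpm expression floor in TPM (default 1).
#' @param group_max largest allowed enriched group (default 7).
#' @return data frame (gene, class, tissues), class in
#'   tissue-enriched / group-enriched / tissue-enhanced / none.
#' @export
tissue_specificity_classify <- function(tpm, fold = 5, min_tpm = 1,
                                        group_max = 7) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) stop("tissue_specificity_classify: negative TPM")
  tissues <- colnames(tpm)
  if (is.null(tissues)) tissues <- paste0("t", seq_len(ncol(tpm)))
  genes <- rownames(tpm)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tpm)))
  if (ncol(tpm) < 2)
    return(data.frame(gene = genes, class = "none", tissues = ""))
  out <- lapply(seq_len(nrow(tpm)), function(i) {
    v <- tpm[i, ]
    ord <- order(v, decreasing = TRUE)
    top <- ord[1]
    # tissue enriched
    if (v[top] > min_tpm && v[top] >= fold * max(v[-top]))
      return(c("tissue-enriched", tissues[top]))
    # group enriched: greedy over the expression-sorted prefix is exact
    # for this rule since any qualifying group must be a top-g prefix
    for (g in 2:min(group_max, ncol(tpm) - 1)) {
      grp <- ord[seq_len(g)]
      rest <- v[-grp]
      if (min(v[grp]) > min_tpm && min(v[grp]) >= fold * max(rest))
        return(c("group-enriched",
                 paste(tissues[sort(grp)], collapse = ",")))
    }
    # tissue enhanced
    if (v[top] > min_tpm && v[top] >= fold * mean(v[-top]))
      return(c("tissue-enhanced", tissues[top]))
    c("none", "")
  })
  res <- do.call(rbind, out)
  data.frame(gene = genes, class = res[, 1], tissues = res[, 2])
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the two methods
#' used in this pipeline: Bonferroni (min(1, m p)) and Benjamini-Hochberg
#' step-up.
#'
#' @param p p-values.
#' @param method "bonferroni" or "BH".
#' @return adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "BH")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}
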