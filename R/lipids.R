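#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. When both groups have at most 8 observations
#' and there are no ties the p-value is computed by exact enumeration of
#' the permutation distribution of U; otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @return list with `U` (statistic for `x`) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("mann_whitney_u: both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_x <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(r)
  all_tied <- length(ties) == 1
  if (all_tied) return(list(U = u_x, p_value = 1))
  exact <- nx <= 8 && ny <= 8 && all(ties == 1)
  if (exact) {
    # enumerate U over all C(nx+ny, nx) assignments of ranks to x
    # with no ties the ranks are a permutation of 1..n, so each
    # assignment of x's ranks is a size-nx subset of {1..n}
    combos <- utils::combn(nx + ny, nx)
    u_all <- colSums(combos) - nx * (nx + 1) / 2
    m_u <- nx * ny / 2
    p <- mean(abs(u_all - m_u) >= abs(u_x - m_u) - 1e-9)
  } else {
    n <- nx + ny
    m_u <- nx * ny / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    s2 <- nx * ny / 12 * ((n + 1) - tie_term)
    z <- (u_x - m_u - sign(u_x - m_u) * 0.5) / sqrt(s2)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    p <- min(p, 1)
  }
  list(U = u_x, p_value = p)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 = #\{p > lambda\} / (m (1 - lambda))
#' (capped at 1) with a single tuning constant lambda, then computes
#' step-down q-values q(i) = min over j >= i of pi0 m p(j) / j on the
#' sorted p-values, capped at 1. With pi0 = 1 these coincide with
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param p p-values in \[0, 1\].
#' @param lambda_tuning pi0 tuning constant (default 0.5).
#' @return q-values in the input order; `pi0` is attached as an
#'   attribute.
#' @export
storey_qvalues <- function(p, lambda_tuning = 0.5) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("storey_qvalues: p-values must lie in [0, 1]")
  m <- length(p)
  pi0 <- min(1, sum(p > lambda_tuning) / (m * (1 - lambda_tuning)))
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

.three_contrasts <- function(groups) {
  list(obese_vs_lean = list(a = "obese", b = "lean-BD"),
       lipo_vs_lean = list(a = "lipodystrophy", b = "lean-BD"),
       patients_vs_lean = list(a = c("obese", "lipodystrophy"),
                               b = "lean-BD"))
}

.contrast_qvalues <- function(panel, groups, lambda_tuning = 0.5) {
  contrasts <- .three_contrasts(groups)
  need <- c("obese", "lipodystrophy", "lean-BD")
  absent <- setdiff(need, unique(groups))
  if (length(absent) > 0)
    stop("missing group(s): ", paste(absent, collapse = ", "))
  sapply(contrasts, function(ct) {
    ia <- groups %in% ct$a; ib <- groups %in% ct$b
    p <- apply(panel, 1, function(v)
      mann_whitney_u(v[ia], v[ib])$p_value)
    storey_qvalues(p, lambda_tuning)
  })
}

#' Prioritise signature lipid species
#'
#' A species is prioritised when (1) it belongs to the selected lipidomic
#' signature and (2) the null hypothesis of equal distributions is
#' rejected (Storey q < `q_threshold`, Mann-Whitney test, q-values
#' computed per comparison across the panel) in all three contrasts:
#' obese vs lean-BD, lipodystrophy vs lean-BD, and
#' obese+lipodystrophy vs lean-BD.
#'
#' @param panel lipids x samples intensity matrix with rownames.
#' @param groups per-sample group labels ("obese", "lipodystrophy",
#'   "lean-BD", ...).
#' @param signature character vector of signature lipid ids.
#' @param q_threshold rejection threshold (default 0.05).
#' @return character vector of prioritised lipid ids.
#' @export
prioritize_species <- function(panel, groups, signature,
                               q_threshold = 0.05) {
  panel <- as.matrix(panel)
  if (length(signature) == 0) return(character(0))
  qs <- .contrast_qvalues(panel, groups)
  reject_all <- rowSums(qs < q_threshold) == ncol(qs)
  rownames(panel)[reject_all & rownames(panel) %in% signature]
}

#' Select negative-control lipid species
#'
#' Controls must (1) not be in the signature, (2) be matchable in the
#' replication panel, and (3) fail to reject (q >= `q_threshold`) in all
#' three group contrasts. Eligible species are ranked by their mean
#' absolute Pearson correlation with the prioritised species and the
#' `n_controls` least-correlated are returned.
#'
#' @param panel lipids x samples matrix.
#' @param prioritized ids of prioritised species (non-empty).
#' @param groups per-sample group labels.
#' @param signature signature lipid ids.
#' @param matchable ids matchable in the replication cohort (default:
#'   all).
#' @param n_controls number of controls (default 5).
#' @param q_threshold threshold defining "fail to reject" (default 0.05).
#' @return character vector of control ids.
#' @export
select_negative_controls <- function(panel, prioritized, groups,
                                     signature,
                                     matchable = rownames(panel),
                                     n_controls = 5,
                                     q_threshold = 0.05) {
  panel <- as.matrix(panel)
  if (length(prioritized) == 0)
    stop("select_negative_controls: no prioritised species")
  qs <- .contrast_qvalues(panel, groups)
  fail_all <- rowSums(qs >= q_threshold) == ncol(qs)
  eligible <- rownames(panel)[fail_all &
                              !(rownames(panel) %in% signature) &
                              rownames(panel) %in% matchable]
  if (length(eligible) == 0) {
    warning("select_negative_controls: no eligible species")
    return(character(0))
  }
  if (length(eligible) < n_controls)
    warning("select_negative_controls: only ", length(eligible),
            " eligible species; returning all")
  pr <- t(panel[prioritized, , drop = FALSE])
  score <- vapply(eligible, function(id)
    mean(abs(stats::cor(panel[id, ], pr))), numeric(1))
  names(sort(score))[seq_len(min(n_controls, length(eligible)))]
}

#' Age/sex-adjusted linear associations of lipids with risk factors
#'
#' For each (lipid, factor) pair an ordinary least-squares model
#' factor ~ lipid + age + sex is fitted on complete cases; the p-value of
#' the lipid coefficient is tested against the Bonferroni-corrected
#' threshold alpha / family_size.
#'
#' @param lipids lipids x samples matrix.
#' @param risk_factors factors x samples matrix (or samples x factors
#'   data frame, auto-oriented by sample names).
#' @param age,sex per-sample covariates (sex coded 0/1 or two-level).
#' @param family_size Bonferroni family size (default: number of tests
#'   performed).
#' @param alpha nominal level (default 0.05).
#' @return data frame (lipid, factor, beta, se, p, significant); rank
#'   deficient cells are NA with reason.
#' @export
adjusted_linear_associations <- function(lipids, risk_factors, age, sex,
                                         family_size = NULL,
                                         alpha = 0.05) {
  lipids <- as.matrix(lipids)
  risk_factors <- as.matrix(risk_factors)
  if (is.character(sex) || is.factor(sex))
    sex <- as.integer(factor(sex)) - 1L
  n <- ncol(lipids)
  stopifnot(ncol(risk_factors) == n, length(age) == n, length(sex) == n)
  grid <- expand.grid(lipid = rownames(lipids),
                      factor = rownames(risk_factors),
                      stringsAsFactors = FALSE)
  if (is.null(family_size)) family_size <- nrow(grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    lv <- lipids[grid$lipid[i], ]
    fv <- risk_factors[grid$factor[i], ]
    ok <- stats::complete.cases(lv, fv, age, sex)
    if (sum(ok) < 10)
      return(data.frame(grid[i, ], beta = NA_real_, se = NA_real_,
                        p = NA_real_, reason = "n<10"))
    fit <- stats::lm(fv[ok] ~ lv[ok] + age[ok] + sex[ok])
    sm <- summary(fit)$coefficients
    if (!"lv[ok]" %in% rownames(sm))
      return(data.frame(grid[i, ], beta = NA_real_, se = NA_real_,
                        p = NA_real_, reason = "rank_deficient"))
    data.frame(grid[i, ], beta = sm["lv[ok]", 1], se = sm["lv[ok]", 2],
               p = sm["lv[ok]", 4], reason = NA_character_)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < alpha / family_size
  rownames(out) <- NULL
  out
}
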