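#' Unit conversion constants for clinical assays
#'
#' The insulin-resistance formulas are stated in conventional units
#' (glucose in mg/dL, insulin in mIU/L a.k.a. uIU/mL) while plasma assays
#' are typically reported in SI units (mmol/L, pmol/L). This helper
#' centralises the conversion constants so they are applied consistently
#' and can be overridden if a laboratory uses different factors.
#'
#' @param glucose_mgdl_per_mmol mg/dL per mmol/L of glucose (default 18.016,
#'   the molar mass based factor).
#' @param insulin_pmol_per_miu pmol/L per mIU/L of insulin (default 6.945).
#' @param ffa_umol_per_mmol umol/L per mmol/L (default 1000).
#' @return A list of class `unit_conventions`.
#' @export
unit_conventions <- function(glucose_mgdl_per_mmol = 18.016,
                             insulin_pmol_per_miu = 6.945,
                             ffa_umol_per_mmol = 1000) {
  stopifnot(glucose_mgdl_per_mmol > 0, insulin_pmol_per_miu > 0,
            ffa_umol_per_mmol > 0)
  structure(list(glucose_mgdl_per_mmol = glucose_mgdl_per_mmol,
                 insulin_pmol_per_miu = insulin_pmol_per_miu,
                 ffa_umol_per_mmol = ffa_umol_per_mmol),
            class = "unit_conventions")
}

#' Homeostatic Model Assessment of insulin resistance (HOMA-IR)
#'
#' HOMA-IR = glucose (mg/dL) x insulin (mIU/L) / 405.
#'
#' @param glucose_mg_dl fasting glucose in mg/dL (non-negative).
#' @param insulin_miu_l fasting insulin in mIU/L (non-negative).
#' @return HOMA-IR index (dimensionless), vectorised.
#' @export
homa_ir <- function(glucose_mg_dl, insulin_miu_l) {
  if (any(glucose_mg_dl < 0, na.rm = TRUE) ||
      any(insulin_miu_l < 0, na.rm = TRUE))
    stop("homa_ir: glucose and insulin must be non-negative")
  glucose_mg_dl * insulin_miu_l / 405
}

#' Adipose-tissue insulin resistance index (AT-IR)
#'
#' AT-IR = insulin (uIU/mL) x free fatty acids (mmol/L).
#'
#' @param insulin_uiu_ml fasting insulin in uIU/mL (= mIU/L).
#' @param ffa_mmol_l fasting free fatty acids in mmol/L.
#' @return AT-IR index, vectorised.
#' @export
at_ir <- function(insulin_uiu_ml, ffa_mmol_l) {
  if (any(insulin_uiu_ml < 0, na.rm = TRUE) || any(ffa_mmol_l < 0, na.rm = TRUE))
    stop("at_ir: inputs must be non-negative")
  insulin_uiu_ml * ffa_mmol_l
}

#' Leptin-adiponectin ratio (LAR)
#'
#' @param leptin ng/ml.
#' @param adiponectin ug/ml; must be strictly positive.
#' @return leptin / adiponectin, vectorised.
#' @export
lar <- function(leptin, adiponectin) {
  if (any(adiponectin <= 0, na.rm = TRUE))
    stop("lar: adiponectin must be > 0 (ratio undefined)")
  leptin / adiponectin
}

#' SI-unit convenience wrappers for the insulin-resistance indices
#'
#' Convert SI-unit assay values and apply [homa_ir()] / [at_ir()].
#'
#' @param glucose_mmol_l glucose in mmol/L.
#' @param insulin_pmol_l insulin in pmol/L.
#' @param ffa_umol_l free fatty acids in umol/L.
#' @param units a [unit_conventions()] object.
#' @return the index value.
#' @export
homa_ir_si <- function(glucose_mmol_l, insulin_pmol_l,
                       units = unit_conventions()) {
  homa_ir(glucose_mmol_l * units$glucose_mgdl_per_mmol,
          insulin_pmol_l / units$insulin_pmol_per_miu)
}

#' @rdname homa_ir_si
#' @export
at_ir_si <- function(insulin_pmol_l, ffa_umol_l, units = unit_conventions()) {
  at_ir(insulin_pmol_l / units$insulin_pmol_per_miu,
        ffa_umol_l / units$ffa_umol_per_mmol)
}

#' Metabolically-lean gating of subjects
#'
#' A subject is gated as lean when all six criteria hold (strict
#' inequalities): BMI < 25, glucose < 5.4 mmol/L, TG < 1.7 mmol/L,
#' LDL-C < 2.59 mmol/L, HDL-C > 1 mmol/L for men and > 1.3 mmol/L for
#' women, and HOMA-IR < 2.2. Missing values fail the gate with reason
#' "missing".
#'
#' @param bmi kg/m^2.
#' @param glucose_mmol_l fasting glucose, mmol/L.
#' @param tg_mmol_l triglycerides, mmol/L.
#' @param ldl_mmol_l LDL cholesterol, mmol/L.
#' @param hdl_mmol_l HDL cholesterol, mmol/L.
#' @param homa HOMA-IR index.
#' @param sex "M" or "F" (required for the HDL threshold).
#' @return A list with `pass` (logical) and `reasons` (character vector of
#'   failed criteria, empty when passing).
#' @export
lean_gate <- function(bmi, glucose_mmol_l, tg_mmol_l, ldl_mmol_l,
                      hdl_mmol_l, homa, sex) {
  vals <- list(bmi = bmi, glucose = glucose_mmol_l, tg = tg_mmol_l,
               ldl = ldl_mmol_l, hdl = hdl_mmol_l, homa = homa, sex = sex)
  missing_fields <- names(vals)[vapply(vals, function(v)
    is.null(v) || length(v) == 0 || is.na(v), logical(1))]
  if (length(missing_fields) > 0)
    return(list(pass = FALSE,
                reasons = paste0("missing:", missing_fields)))
  if (!sex %in% c("M", "F")) stop("lean_gate: sex must be 'M' or 'F'")
  hdl_threshold <- if (sex == "M") 1.0 else 1.3
  checks <- c(bmi = bmi < 25,
              glucose = glucose_mmol_l < 5.4,
              tg = tg_mmol_l < 1.7,
              ldl = ldl_mmol_l < 2.59,
              hdl = hdl_mmol_l > hdl_threshold,
              homa = homa < 2.2)
  list(pass = all(checks), reasons = names(checks)[!checks])
}

#' Gate a subject table
#'
#' Applies [lean_gate()] rowwise to a subject data frame with columns
#' `bmi`, `glucose`, `tg`, `ldl`, `hdl`, `homa`, `sex`.
#'
#' @param subjects data frame of subjects.
#' @return the input with logical column `lean` and character `gate_reasons`.
#' @export
lean_gate_table <- function(subjects) {
  need <- c("bmi", "glucose", "tg", "ldl", "hdl", "homa", "sex")
  missing_cols <- setdiff(need, names(subjects))
  if (length(missing_cols) > 0)
    stop("lean_gate_table: missing columns: ",
         paste(missing_cols, collapse = ", "))
  res <- lapply(seq_len(nrow(subjects)), function(i)
    lean_gate(subjects$bmi[i], subjects$glucose[i], subjects$tg[i],
              subjects$ldl[i], subjects$hdl[i], subjects$homa[i],
              subjects$sex[i]))
  subjects$lean <- vapply(res, `[[`, logical(1), "pass")
  subjects$gate_reasons <- vapply(res, function(r)
    paste(r$reasons, collapse = ";"), character(1))
  subjects
}

#' Chained-equations imputation of clinical variables
#'
#' Iterative per-variable regression imputation in the spirit of multiple
#' imputation by chained equations: each incomplete variable is regressed
#' on all others (linear model for continuous variables, logistic for
#' two-level factors) and its missing entries are replaced by the model's
#' predictive means, cycling over variables for `n_iterations` rounds.
#' A single completed data set is returned; predictions are deterministic
#' (no posterior draws), so repeated calls agree exactly.
#'
#' @param table data frame; continuous columns numeric, binary columns
#'   factor/character with two levels.
#' @param n_iterations number of full cycles (default 10).
#' @param seed integer recorded in the result attributes.
#' @return completed data frame with attribute `imputation_seed`.
#' @export
chained_imputation <- function(table, n_iterations = 10, seed = 1L) {
  stopifnot(is.data.frame(table), n_iterations >= 1)
  miss <- vapply(table, function(x) mean(is.na(x)), numeric(1))
  if (any(miss == 1))
    stop("chained_imputation: all-missing column(s): ",
         paste(names(table)[miss == 1], collapse = ", "))
  if (all(miss == 0)) {
    attr(table, "imputation_seed") <- as.integer(seed)
    return(table)
  }
  if (!any(miss == 0))
    stop("chained_imputation: need at least one complete variable")
  if (any(miss >= 0.5))
    warning("chained_imputation: column(s) with >=50% missing: ",
            paste(names(table)[miss >= 0.5], collapse = ", "))

  is_bin <- vapply(table, function(x)
    !is.numeric(x) && length(unique(stats::na.omit(x))) == 2, logical(1))
  na_mask <- lapply(table, is.na)
  work <- table
  # initial fill: mean for continuous, modal level for binary
  for (j in names(work)) {
    if (!any(na_mask[[j]])) next
    if (is_bin[[j]]) {
      lv <- names(sort(table(work[[j]]), decreasing = TRUE))[1]
      work[[j]][na_mask[[j]]] <- lv
    } else {
      work[[j]][na_mask[[j]]] <- mean(work[[j]], na.rm = TRUE)
    }
  }
  visit <- names(work)[miss > 0]
  for (it in seq_len(n_iterations)) {
    for (j in visit) {
      idx <- na_mask[[j]]
      preds <- setdiff(names(work), j)
      df <- work[, preds, drop = FALSE]
      df$.y <- work[[j]]
      if (is_bin[[j]]) {
        df$.y <- factor(df$.y)
        fit <- suppressWarnings(
          stats::glm(.y ~ ., data = df[!idx, , drop = FALSE],
                     family = stats::binomial()))
        p <- stats::predict(fit, newdata = df[idx, , drop = FALSE],
                            type = "response")
        work[[j]][idx] <- levels(df$.y)[1 + as.integer(p >= 0.5)]
      } else {
        fit <- stats::lm(.y ~ ., data = df[!idx, , drop = FALSE])
        work[[j]][idx] <- stats::predict(fit,
                                         newdata = df[idx, , drop = FALSE])
      }
    }
  }
  attr(work, "imputation_seed") <- as.integer(seed)
  work
}

#' Two-sample Hotelling T-squared test
#'
#' Multivariate two-sample location test. With mean difference d and
#' pooled covariance S,
#' T2 = (n1 n2 / (n1 + n2)) d' S^-1 d, and
#' F = T2 (n1 + n2 - p - 1) / ((n1 + n2 - 2) p) is referred to the
#' F(p, n1 + n2 - p - 1) distribution.
#'
#' @param x1,x2 numeric matrices (rows = observations, columns = the same
#'   p variables).
#' @return list with `statistic` (T2), `F`, `df1`, `df2`, `p_value`.
#' @export
hotelling_two_sample <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  if (ncol(x1) != ncol(x2)) stop("hotelling_two_sample: column mismatch")
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x1)
  if (n1 + n2 <= p + 1)
    stop("hotelling_two_sample: need n1 + n2 > p + 1")
  d <- colMeans(x1) - colMeans(x2)
  S <- ((n1 - 1) * stats::cov(x1) + (n2 - 1) * stats::cov(x2)) / (n1 + n2 - 2)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("hotelling_two_sample: pooled covariance is singular; ",
         "reduce dimensions before testing"))
  t2 <- as.numeric((n1 * n2 / (n1 + n2)) * t(d) %*% Sinv %*% d)
  f <- t2 * (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p)
  df2 <- n1 + n2 - p - 1
  list(statistic = t2, F = f, df1 = p, df2 = df2,
       p_value = stats::pf(f, p, df2, lower.tail = FALSE))
}

#' PCA of standardised clinical variables with contribution analysis
#'
#' Variables are z-scored before the decomposition; constant variables are
#' dropped with a warning. The contribution of variable j to component k
#' is 100 * loading(j,k)^2 / sum_j loading(j,k)^2, so contributions on
#' each component sum to 100.
#'
#' @param table data frame or matrix of subjects x variables.
#' @param variables character vector of columns to use (default: all
#'   numeric columns).
#' @return list with `scores`, `loadings`, `contributions` (percent),
#'   `sdev`, and `variables` retained.
#' @export
pca_group_separation <- function(table, variables = NULL) {
  m <- as.data.frame(table)
  if (is.null(variables))
    variables <- names(m)[vapply(m, is.numeric, logical(1))]
  x <- as.matrix(m[, variables, drop = FALSE])
  if (nrow(x) < 3) stop("pca_group_separation: need >= 3 subjects")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant variable(s): ",
            paste(variables[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    variables <- variables[sds > 0]
  }
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  list(scores = pc$x, loadings = pc$rotation, contributions = contrib,
       sdev = pc$sdev, variables = variables)
}

#' Percent adhesion from fluorescence readings
#'
#' Percent adhesion = 100 * (RFU_stimulus - RFU_buffer) / RFU_total.
#' Negative values (stimulus below buffer control) are passed through and
#' flagged.
#'
#' @param rfu_stim relative fluorescence with stimulus.
#' @param rfu_hepes buffer-only (HEPES) control reading.
#' @param rfu_total 100% adhesion control reading; must be > 0.
#' @return list with `percent` and logical `flagged_negative`.
#' @export
adhesion_percent <- function(rfu_stim, rfu_hepes, rfu_total) {
  if (any(rfu_total <= 0)) stop("adhesion_percent: rfu_total must be > 0")
  pct <- 100 * (rfu_stim - rfu_hepes) / rfu_total
  list(percent = pct, flagged_negative = pct < 0)
}
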