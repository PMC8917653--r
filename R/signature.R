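#' Standardise features using training-set statistics
#'
#' Per-feature z-scoring with mean/SD computed from the training subjects
#' only, so test subjects never leak into the scaling. Constant features
#' get an SD floor so they standardise to zero rather than NaN.
#'
#' @param x subjects x features matrix.
#' @param fit_subjects row indices or names of the training subjects
#'   (default: all rows).
#' @param params optional previously computed parameters to reuse.
#' @param sd_floor minimum SD (default 1e-8).
#' @return list with `x` (standardised matrix) and `params`
#'   (`center`, `scale`).
#' @export
standardize_features <- function(x, fit_subjects = NULL, params = NULL,
                                 sd_floor = 1e-8) {
  x <- as.matrix(x)
  if (is.null(params)) {
    xt <- if (is.null(fit_subjects)) x else x[fit_subjects, , drop = FALSE]
    center <- colMeans(xt)
    scale <- pmax(apply(xt, 2, stats::sd), sd_floor)
    params <- list(center = center, scale = scale)
  }
  z <- sweep(sweep(x, 2, params$center, "-"), 2, params$scale, "/")
  list(x = z, params = params)
}

#' Undo feature standardisation
#'
#' @param z standardised matrix.
#' @param params the `params` element from [standardize_features()].
#' @return matrix on the original scale.
#' @export
destandardize_features <- function(z, params) {
  sweep(sweep(as.matrix(z), 2, params$scale, "*"), 2, params$center, "+")
}

.design_with_covariates <- function(x, covariates) {
  x <- as.matrix(x)
  if (is.null(covariates) || NCOL(covariates) == 0)
    return(list(X = x, n_cov = 0L))
  cv <- as.matrix(as.data.frame(covariates))
  storage.mode(cv) <- "double"
  if (is.null(colnames(cv)))
    colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
  list(X = cbind(x, cv), n_cov = ncol(cv))
}

#' Elastic-net penalised logistic regression with unpenalised covariates
#'
#' Minimises the negative Bernoulli log-likelihood plus
#' lambda * sum over penalised columns of alpha |beta_j| +
#' (1 - alpha) beta_j^2 / 2. Clinical covariates (age, sex) are appended
#' unpenalised. Fitting is done with glmnet; features are expected to be
#' standardised already (no internal standardisation).
#'
#' @param x subjects x features matrix (penalised block).
#' @param y binary response (0/1 or two-level factor).
#' @param covariates optional subjects x covariates matrix/data frame,
#'   unpenalised.
#' @param alpha elastic-net mixing (default 0.1).
#' @param lambda penalty value (scalar).
#' @param thresh convergence threshold passed to glmnet (default 1e-12).
#' @return list with `intercept`, `beta` (penalised coefficients, named),
#'   `gamma` (covariate coefficients), `lambda`, `alpha`.
#' @export
fit_penalized_logistic <- function(x, y, covariates = NULL, alpha = 0.1,
                                   lambda, thresh = 1e-12) {
  y <- .as_binary(y)
  d <- .design_with_covariates(x, covariates)
  pf <- c(rep(1, ncol(as.matrix(x))), rep(0, d$n_cov))
  # glmnet is fitted along a short decreasing path ending at the target
  # lambda: warm starts make the final solution accurate even at 0
  lam_path <- sort(unique(c(lambda * c(32, 16, 8, 4, 2), lambda)),
                   decreasing = TRUE)
  if (lambda == 0)
    lam_path <- c(0.256, 0.128, 0.064, 0.032, 0.016, 0.008, 0.004,
                  0.002, 0.001, 0)
  fit <- .quiet_smalln(
    glmnet::glmnet(d$X, y, family = "binomial", alpha = alpha,
                   lambda = lam_path, penalty.factor = pf,
                   standardize = FALSE, thresh = thresh,
                   maxit = 1e6))
  co <- as.numeric(stats::coef(fit, s = lambda))
  names(co) <- c("(Intercept)", colnames(d$X))
  p <- ncol(as.matrix(x))
  beta <- co[2:(p + 1)]
  gamma <- if (d$n_cov > 0) co[(p + 2):(p + 1 + d$n_cov)] else numeric(0)
  list(intercept = co[1], beta = beta, gamma = gamma,
       lambda = lambda, alpha = alpha)
}

# glmnet emits small-sample advisories on every fold with training sets
# of 6-16 subjects; those sizes are this design's normal operating point
.quiet_smalln <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8|grouped=FALSE", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

.as_binary <- function(y) {
  if (is.factor(y) || is.character(y)) {
    lv <- sort(unique(as.character(y)))
    if (length(lv) != 2) stop("response must be binary")
    y <- as.integer(as.character(y) == lv[2])
  }
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  as.numeric(y)
}

#' Stratified cross-validation fold assignment
#'
#' @param y binary response.
#' @param n_folds number of folds.
#' @return integer fold ids, balanced within each class.
#' @keywords internal
stratified_folds <- function(y, n_folds) {
  y <- .as_binary(y)
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Repeated cross-validation choice of the elastic-net penalty
#'
#' Each round draws stratified folds and records the
#' deviance-minimising lambda along a common grid; the final lambda is
#' the modal choice across rounds, with ties broken toward the larger
#' (sparser) lambda. A round only moves off the top of the grid (the
#' all-null model) when the deviance improvement at the minimum exceeds
#' `tolerance_se` cross-validation standard errors — the argmin of a
#' flat noisy curve is ill-defined, and without this gate no-signal
#' data yields arbitrary mid-grid penalties and inflated signatures.
#' Fold counts larger than the smaller class are clamped so
#' stratification can always place both classes in every fold.
#'
#' @param x subjects x features matrix (standardised).
#' @param y binary response.
#' @param covariates optional unpenalised covariates.
#' @param alpha elastic-net mixing (default 0.1).
#' @param n_rounds number of CV rounds (default 50).
#' @param n_folds folds per round (default 10; clamped to the smaller
#'   class count).
#' @param lambda_grid decreasing penalty grid; default 100-point log grid
#'   scaled from the data's lambda_max.
#' @param tolerance_se size of the improvement gate in CV standard
#'   errors of the deviance minimum (default 1).
#' @param seed integer seed driving all fold draws.
#' @return list with `lambda` (modal choice), `per_round` lambdas, and
#'   `lambda_grid`.
#' @export
repeated_cv_lambda <- function(x, y, covariates = NULL, alpha = 0.1,
                               n_rounds = 50, n_folds = 10,
                               lambda_grid = NULL, tolerance_se = 1,
                               seed = 1L) {
  y <- .as_binary(y)
  if (n_folds < 3) stop("repeated_cv_lambda: n_folds must be >= 3")
  n_min <- min(sum(y == 0), sum(y == 1))
  if (n_folds > n_min) n_folds <- max(3L, n_min)
  d <- .design_with_covariates(x, covariates)
  pf <- c(rep(1, ncol(as.matrix(x))), rep(0, d$n_cov))
  if (is.null(lambda_grid)) {
    base <- .quiet_smalln(
      glmnet::glmnet(d$X, y, family = "binomial", alpha = alpha,
                     penalty.factor = pf, standardize = FALSE,
                     nlambda = 100))
    lambda_grid <- base$lambda
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  per_round <- vapply(seq_len(n_rounds), function(r) {
    foldid <- stratified_folds(y, n_folds)
    cvfit <- .quiet_smalln(
      glmnet::cv.glmnet(d$X, y, family = "binomial", alpha = alpha,
                        lambda = lambda_grid, penalty.factor = pf,
                        standardize = FALSE, foldid = foldid,
                        type.measure = "deviance"))
    keep <- match(cvfit$lambda, lambda_grid)
    i_min <- which.min(cvfit$cvm)
    improvement <- cvfit$cvm[1] - cvfit$cvm[i_min]
    if (improvement > tolerance_se * cvfit$cvsd[i_min])
      keep[i_min] else keep[1]
  }, numeric(1))
  per_round <- as.integer(per_round)
  # modal lambda by grid index (grid is decreasing, so the tie-break
  # toward the larger/sparser lambda is the smallest winning index)
  counts <- tabulate(per_round, nbins = length(lambda_grid))
  winners <- which(counts == max(counts))
  list(lambda = lambda_grid[min(winners)],
       per_round = lambda_grid[per_round],
       lambda_grid = lambda_grid)
}

#' Select a per-layer signature by penalised logistic regression
#'
#' The layer's features are standardised on the training subjects,
#' the penalty is chosen by [repeated_cv_lambda()], a final elastic-net
#' fit at the chosen lambda is performed on the full training set, and
#' the features with nonzero penalised coefficients form the signature.
#' Covariates are never counted as selected features.
#'
#' @param layer features x samples matrix or `omics_layer`.
#' @param subjects character vector of training subject ids (columns of
#'   the layer).
#' @param labels binary response for the training subjects (0/1 or
#'   two-level).
#' @param covariates optional training-subject covariate matrix
#'   (e.g. age, sex), unpenalised.
#' @param alpha elastic-net mixing (default 0.1).
#' @param n_rounds,n_folds CV settings (see [repeated_cv_lambda()]).
#' @param seed integer seed.
#' @return a `signature_model`: selected features, all coefficients,
#'   alpha, lambda, standardisation parameters, training ids, per-round
#'   lambda record.
#' @export
select_signature_layer <- function(layer, subjects, labels,
                                   covariates = NULL, alpha = 0.1,
                                   n_rounds = 50, n_folds = 10,
                                   seed = 1L) {
  m <- .layer_matrix(layer)
  missing_sub <- setdiff(subjects, colnames(m))
  if (length(missing_sub) > 0)
    stop("select_signature_layer: subjects not in layer: ",
         paste(missing_sub, collapse = ", "))
  xt <- t(m[, subjects, drop = FALSE])
  std <- standardize_features(xt)
  cv <- repeated_cv_lambda(std$x, labels, covariates = covariates,
                           alpha = alpha, n_rounds = n_rounds,
                           n_folds = n_folds, seed = seed)
  fit <- fit_penalized_logistic(std$x, labels, covariates = covariates,
                                alpha = alpha, lambda = cv$lambda)
  sel <- names(fit$beta)[abs(fit$beta) > 0]
  name <- if (inherits(layer, "omics_layer")) layer$name else "layer"
  structure(list(layer = name, selected_features = sel,
                 intercept = fit$intercept, beta = fit$beta,
                 gamma = fit$gamma, alpha = alpha, lambda = cv$lambda,
                 standardization = std$params,
                 training_subjects = subjects,
                 cv_record = cv$per_round),
            class = "signature_model")
}

#' Per-group mean z-scores of selected features
#'
#' Features are z-scored over all supplied subjects; the mean z-score is
#' reported per group (the heatmap summary of a signature).
#'
#' @param features feature ids to summarise.
#' @param data features x samples matrix or `omics_layer`.
#' @param groups named group label per sample (aligned with columns).
#' @return groups x features matrix of mean z-scores.
#' @export
group_mean_zscores <- function(features, data, groups) {
  m <- .layer_matrix(data)
  stopifnot(length(groups) == ncol(m))
  z <- t(scale(t(m[features, , drop = FALSE])))
  g <- sort(unique(as.character(groups)))
  out <- t(vapply(g, function(gr)
    rowMeans(z[, groups == gr, drop = FALSE]), numeric(length(features))))
  dimnames(out) <- list(g, features)
  out
}
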