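#' Assemble a cross-layer design matrix from selected signatures
#'
#' Column-binds the standardised selected features of each signature
#' (standardisation parameters from the signature's training set are
#' reused) with the clinical covariates. Column provenance (layer,
#' feature id) is recorded so subset models can be audited.
#'
#' @param signatures list of `signature_model` objects.
#' @param layers named list of features x samples matrices or
#'   `omics_layer`s matching the signatures' `layer` names.
#' @param covariates subjects x covariates matrix/data frame (e.g. age,
#'   sex); may be NULL.
#' @param subjects subject ids (columns) to include.
#' @return list with `X` (subjects x columns), `provenance` (data frame
#'   column, layer, feature).
#' @export
assemble_design <- function(signatures, layers, covariates = NULL,
                            subjects) {
  blocks <- list(); prov <- list()
  for (sig in signatures) {
    if (length(sig$selected_features) == 0) next
    lay <- layers[[sig$layer]]
    if (is.null(lay))
      stop("assemble_design: no layer named '", sig$layer, "'")
    m <- .layer_matrix(lay)
    absent <- setdiff(sig$selected_features, rownames(m))
    if (length(absent) > 0)
      stop("assemble_design: layer '", sig$layer,
           "' is missing feature(s): ", paste(absent, collapse = ", "))
    xt <- t(m[sig$selected_features, subjects, drop = FALSE])
    keep <- sig$selected_features
    pars <- list(center = sig$standardization$center[keep],
                 scale = sig$standardization$scale[keep])
    z <- standardize_features(xt, params = pars)$x
    colnames(z) <- paste(sig$layer, keep, sep = ":")
    blocks[[length(blocks) + 1]] <- z
    prov[[length(prov) + 1]] <- data.frame(column = colnames(z),
                                           layer = sig$layer,
                                           feature = keep)
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates)[subjects, , drop = FALSE])
    storage.mode(cv) <- "double"
    blocks[[length(blocks) + 1]] <- cv
    prov[[length(prov) + 1]] <- data.frame(column = colnames(cv),
                                           layer = "clinical",
                                           feature = colnames(cv))
  }
  if (length(blocks) == 0) {
    # all signatures empty and no covariates: an intercept-only design
    warning("assemble_design: no selected features or covariates; ",
            "returning an empty design (intercept-only model)")
    X <- matrix(numeric(0), nrow = length(subjects), ncol = 0,
                dimnames = list(subjects, NULL))
    return(list(X = X,
                provenance = data.frame(column = character(0),
                                        layer = character(0),
                                        feature = character(0))))
  }
  X <- do.call(cbind, blocks)
  rownames(X) <- subjects
  list(X = X, provenance = do.call(rbind, prov))
}

#' Ridge-penalised logistic regression
#'
#' L2-penalised logistic fit; the penalty is chosen by 10-fold
#' cross-validated deviance unless a fixed value is given.
#'
#' @param x subjects x columns design matrix.
#' @param y binary response.
#' @param lambda_ridge "cv" (default) or a fixed non-negative value.
#' @param n_folds CV folds when `lambda_ridge = "cv"` (clamped to the
#'   smaller class count).
#' @param seed integer seed for the CV fold draw.
#' @return a `ridge_model`: `intercept`, `beta`, `lambda`.
#' @export
fit_ridge_logistic <- function(x, y, lambda_ridge = "cv", n_folds = 10,
                               seed = 1L) {
  y <- .as_binary(y)
  x <- as.matrix(x)
  # degenerate design (no informative columns): closed-form
  # intercept-only model, the ridge limit of total shrinkage
  if (ncol(x) == 0 || all(apply(x, 2, stats::sd) == 0)) {
    return(structure(list(intercept = stats::qlogis(mean(y)),
                          beta = stats::setNames(rep(0, ncol(x)),
                                                 colnames(x)),
                          lambda = Inf),
                     class = "ridge_model"))
  }
  while (ncol(x) < 2) { # glmnet needs >= 2 columns; pad with zeros
    x <- cbind(x, 0)
    colnames(x)[ncol(x)] <- paste0(".pad", ncol(x))
  }
  if (identical(lambda_ridge, "cv")) {
    n_min <- min(sum(y == 0), sum(y == 1))
    n_folds <- max(3L, min(n_folds, n_min))
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    foldid <- stratified_folds(y, n_folds)
    cvfit <- .quiet_smalln(
      glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0,
                        standardize = FALSE, foldid = foldid,
                        type.measure = "deviance"))
    lambda <- cvfit$lambda.min
  } else {
    lambda <- as.numeric(lambda_ridge)
  }
  lam_path <- sort(unique(c(lambda * c(32, 8, 2), lambda)),
                   decreasing = TRUE)
  if (lambda == 0)
    lam_path <- c(0.128, 0.032, 0.008, 0.002, 0.0005, 0)
  fit <- .quiet_smalln(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = lam_path, standardize = FALSE,
                   thresh = 1e-12, maxit = 1e6))
  co <- as.numeric(stats::coef(fit, s = lambda))
  beta <- stats::setNames(co[-1], colnames(x))
  beta <- beta[!grepl("^\\.pad", names(beta))]
  structure(list(intercept = co[1], beta = beta, lambda = lambda),
            class = "ridge_model")
}

#' Predict class probabilities from a ridge model
#'
#' @param object a `ridge_model`.
#' @param newdata subjects x columns matrix containing the model's
#'   columns.
#' @param ... unused.
#' @return probabilities in (0, 1).
#' @export
predict.ridge_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, names(object$beta), drop = FALSE]
  eta <- object$intercept + drop(x %*% object$beta)
  stats::plogis(eta)
}

#' Fit ridge models for every non-empty layer subset
#'
#' One ridge model per non-empty subset of layers (2^L - 1 models), each
#' on the union of the subset's selected features plus the clinical
#' covariates, trained on the complete-layer training subjects; plus a
#' clinical-only model. This lets every subject be scored by the model
#' matching exactly its available layers.
#'
#' @param signatures list of `signature_model`s (one per layer).
#' @param layers named list of layer matrices/`omics_layer`s.
#' @param covariates subjects x covariates matrix (rownames = subject
#'   ids) or NULL.
#' @param subjects training subject ids.
#' @param y binary response for the training subjects.
#' @param seed integer seed (CV fold draws).
#' @return an `integrated_model_set`: named list `models` (keys are
#'   sorted layer names joined by "+", plus "clinical"), `provenance`,
#'   `layer_names`, `training_subjects`.
#' @export
fit_subset_models <- function(signatures, layers, covariates, subjects,
                              y, seed = 1L) {
  layer_names <- vapply(signatures, `[[`, character(1), "layer")
  names(signatures) <- layer_names
  subsets <- unlist(lapply(seq_along(layer_names), function(k)
    utils::combn(layer_names, k, simplify = FALSE)), recursive = FALSE)
  models <- list(); prov <- list()
  for (s in subsets) {
    key <- paste(sort(s), collapse = "+")
    des <- assemble_design(signatures[s], layers, covariates, subjects)
    models[[key]] <- fit_ridge_logistic(des$X, y, seed = seed)
    prov[[key]] <- des$provenance
  }
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates)[subjects, , drop = FALSE])
    storage.mode(cv) <- "double"
    models[["clinical"]] <- fit_ridge_logistic(cv, y, seed = seed)
    prov[["clinical"]] <- data.frame(column = colnames(cv),
                                     layer = "clinical",
                                     feature = colnames(cv))
  }
  structure(list(models = models, provenance = prov,
                 signatures = signatures, layer_names = layer_names,
                 training_subjects = subjects),
            class = "integrated_model_set")
}

#' Predict probabilities and rank subjects
#'
#' Every subject is scored by the model of exactly its available-layer
#' subset (clinical-only when no layer is available); subjects are then
#' ranked by decreasing predicted probability of extreme-group
#' membership, ties broken by subject id.
#'
#' @param model_set an `integrated_model_set`.
#' @param layers named list of layer matrices/`omics_layer`s.
#' @param covariates subjects x covariates matrix (rownames = ids) or
#'   NULL.
#' @param availability subjects x layers logical matrix (TRUE = layer
#'   measured); default: all available.
#' @param subjects subject ids to score.
#' @return a `ranking_result` data frame (subject, model, probability,
#'   rank), ordered by rank.
#' @export
predict_and_rank <- function(model_set, layers, covariates = NULL,
                             availability = NULL, subjects) {
  stopifnot(inherits(model_set, "integrated_model_set"))
  ln <- model_set$layer_names
  if (is.null(availability)) {
    availability <- matrix(TRUE, length(subjects), length(ln),
                           dimnames = list(subjects, ln))
  }
  probs <- model_keys <- rep(NA_real_, length(subjects))
  model_keys <- character(length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    avail <- ln[availability[s, ln]]
    key <- if (length(avail) == 0) "clinical"
           else paste(sort(avail), collapse = "+")
    mod <- model_set$models[[key]]
    if (is.null(mod)) {
      warning("no model for subject ", s, " (", key, "); skipped")
      next
    }
    if (key == "clinical") {
      X <- as.matrix(as.data.frame(covariates)[s, , drop = FALSE])
      storage.mode(X) <- "double"
    } else {
      sigs <- model_set$signatures[avail]
      X <- assemble_design(sigs, layers, covariates, s)$X
    }
    probs[i] <- predict(mod, X)
    model_keys[i] <- key
  }
  ord <- order(-probs, subjects)
  out <- data.frame(subject = subjects, model = model_keys,
                    probability = probs)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranking_result", class(out))
  out
}

#' Log loss (cross-entropy) of predicted probabilities
#'
#' -(1/n) sum y log p + (1 - y) log(1 - p), probabilities clipped at
#' `eps`.
#'
#' @param y_true binary labels.
#' @param p predicted probabilities.
#' @param eps clipping bound (default 1e-15).
#' @return non-negative log loss.
#' @export
log_loss <- function(y_true, p, eps = 1e-15) {
  y <- .as_binary(y_true)
  if (length(y) != length(p)) stop("log_loss: length mismatch")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Order models by log loss
#'
#' @param rankings named list of `ranking_result`s (or data frames with
#'   `subject` and `probability`).
#' @param y_true named binary labels (names = subject ids); subjects
#'   absent from the labels are ignored.
#' @return data frame (model, log_loss, n) ordered by increasing loss
#'   (best first), with the per-model probability vectors attached as
#'   attribute `probabilities`.
#' @export
compare_models <- function(rankings, y_true) {
  stopifnot(!is.null(names(rankings)))
  rows <- lapply(names(rankings), function(nm) {
    r <- rankings[[nm]]
    keep <- r$subject %in% names(y_true) & !is.na(r$probability)
    r <- r[keep, ]
    data.frame(model = nm,
               log_loss = log_loss(y_true[r$subject], r$probability),
               n = nrow(r))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$log_loss, out$model), ]
  rownames(out) <- NULL
  attr(out, "probabilities") <- lapply(rankings, function(r)
    stats::setNames(r$probability, r$subject))
  out
}
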