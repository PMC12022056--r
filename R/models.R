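#' Classifier specification
#'
#' Hyperparameter defaults follow the values selected by grid search in the
#' underlying study: random forest with 150 trees, Gini criterion and a
#' minimum of five samples per leaf; RBF-kernel SVM with gamma 1e-4 and C = 1;
#' gradient boosting with 50 rounds. Logistic regression uses unpenalized
#' maximum likelihood. All defaults can be overridden through `params`.
#'
#' @param kind one of `"random_forest"`, `"svm_rbf"`, `"gradient_boosting"`,
#'   `"logistic_regression"`.
#' @param params named list of overrides for the kind's defaults.
#' @param seed integer seed used at fit time.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(kind = c("random_forest", "svm_rbf",
                                "gradient_boosting", "logistic_regression"),
                       params = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    random_forest = list(ntree = 150, nodesize = 5),
    svm_rbf = list(gamma = 1e-4, cost = 1),
    gradient_boosting = list(nrounds = 50, max_depth = 3, eta = 0.1),
    logistic_regression = list())
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) {
    stop("unknown hyperparameters for ", kind, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  defaults[names(params)] <- params
  structure(list(kind = kind, params = defaults, seed = as.integer(seed)),
            class = "model_spec")
}

#' Train a probabilistic RRMS/SPMS classifier
#'
#' Fits the classifier named by `spec` on a numeric feature matrix. The
#' fitted object stores the feature-schema fingerprint and the training
#' patient ids so downstream stages can refuse mismatched data and guard
#' against calibration leakage.
#'
#' @param spec a [model_spec()].
#' @param X numeric matrix (rows = visits, columns = schema features).
#' @param y factor or character of labels in `c("RRMS", "SPMS")`.
#' @param patient_ids optional patient id per row, retained for leakage
#'   checks.
#' @param fingerprint optional schema fingerprint (taken from `X`'s
#'   originating feature frame via [feature_matrix()] in normal use).
#' @return object of class `ms_classifier`.
#' @export
train_model <- function(spec, X, y, patient_ids = NULL, fingerprint = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- factor(y, levels = CLASS_LEVELS)
  if (nrow(X) != length(y)) stop("X rows must match length(y)", call. = FALSE)
  if (anyNA(y)) stop("labels must be RRMS or SPMS", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training labels contain a single class; ",
         "class-conditional calibration would be impossible", call. = FALSE)
  }
  set.seed(spec$seed)
  p <- spec$params
  fit <- switch(spec$kind,
    random_forest = randomForest::randomForest(
      x = X, y = y, ntree = p$ntree, nodesize = p$nodesize),
    svm_rbf = e1071::svm(
      x = X, y = y, kernel = "radial", gamma = p$gamma, cost = p$cost,
      probability = TRUE),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = p$max_depth,
                    eta = p$eta, nthread = 1, seed = spec$seed),
      data = xgboost::xgb.DMatrix(X, label = as.integer(y == "SPMS")),
      nrounds = p$nrounds, verbose = 0),
    logistic_regression = suppressWarnings(stats::glm.fit(
      x = cbind(1, X), y = as.integer(y == "SPMS"),
      family = stats::binomial())))
  structure(list(kind = spec$kind, spec = spec, fit = fit,
                 features = colnames(X), fingerprint = fingerprint,
                 train_patient_ids = unique(patient_ids),
                 X_train = X, y_train = y,
                 cache = new.env(parent = emptyenv())),
            class = "ms_classifier")
}

#' @export
print.ms_classifier <- function(x, ...) {
  cat("mscourse classifier:", x$kind, "\n")
  cat("  features:", length(x$features),
      " training visits:", nrow(x$X_train), "\n")
  invisible(x)
}

#' Class-probability predictions
#'
#' Returns a matrix of per-visit probabilities with columns `RRMS` and
#' `SPMS` (rows sum to 1). Refuses feature matrices whose schema fingerprint
#' does not match the one the model was trained on.
#'
#' @param model an `ms_classifier`.
#' @param X numeric matrix with the model's feature columns.
#' @param fingerprint optional schema fingerprint of `X` to check.
#' @return numeric matrix `n x 2`.
#' @export
predict_proba <- function(model, X, fingerprint = NULL) {
  stopifnot(inherits(model, "ms_classifier"))
  if (!is.null(fingerprint) && !is.null(model$fingerprint) &&
      !identical(fingerprint, model$fingerprint)) {
    stop("feature schema fingerprint does not match the model's", call. = FALSE)
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- model$features
  X <- X[, model$features, drop = FALSE]
  p_spms <- switch(model$kind,
    random_forest = {
      pr <- stats::predict(model$fit, X, type = "prob")
      pr[, "SPMS"]
    },
    svm_rbf = {
      pr <- attr(stats::predict(model$fit, X, probability = TRUE),
                 "probabilities")
      pr[, "SPMS"]
    },
    gradient_boosting = stats::predict(model$fit, xgboost::xgb.DMatrix(X)),
    logistic_regression = {
      coefs <- model$fit$coefficients
      coefs[is.na(coefs)] <- 0  # aliased (constant/collinear) columns
      eta <- drop(cbind(1, X) %*% coefs)
      stats::plogis(eta)
    })
  out <- cbind(RRMS = 1 - p_spms, SPMS = p_spms)
  rownames(out) <- NULL
  out
}

# Macro-averaged F1 over the two course labels; a class with no predicted
# or true members contributes an F1 of 0.
#' @keywords internal
macro_f1 <- function(truth, pred) {
  f1 <- vapply(CLASS_LEVELS, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0) return(0)
    prec <- tp / (tp + fp)
    rec <- tp / (tp + fn)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

#' Grouped k-fold cross-validated macro-F1
#'
#' Folds are formed over patients, never visits, so all visits of a patient
#' fall in the same fold (no within-patient leakage). Patients are shuffled
#' with `seed` and dealt round-robin to the `k` folds.
#'
#' @param spec a [model_spec()].
#' @param X,y feature matrix and labels as in [train_model()].
#' @param groups patient id per row.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return list with `mean`, `sd` and per-fold `scores` of macro-F1.
#' @export
cross_validate_f1 <- function(spec, X, y, groups, k = 10, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y, levels = CLASS_LEVELS)
  ids <- unique(groups)
  if (k > length(ids)) stop("k exceeds the number of patient groups", call. = FALSE)
  set.seed(seed)
  ids <- sample(ids)
  fold_of <- stats::setNames(rep_len(seq_len(k), length(ids)), ids)
  fold <- unname(fold_of[as.character(groups)])
  scores <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- train_model(spec, X[tr, , drop = FALSE], y[tr])
    pr <- predict_proba(model, X[!tr, , drop = FALSE])
    pred <- CLASS_LEVELS[1 + (pr[, "SPMS"] >= 0.5)]
    macro_f1(y[!tr], pred)
  }, numeric(1))
  list(mean = mean(scores), sd = stats::sd(scores), scores = scores,
       folds = fold)
}
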