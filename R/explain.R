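# Additive per-visit feature attributions. Sign convention follows the
# disease-course semantics: positive contributions push the prediction toward
# SPMS, negative toward RRMS. For random forests the attribution target is
# the SPMS vote fraction (the model's predicted probability); for gradient
# boosting it is the margin (log-odds) as returned by exact TreeSHAP; for
# LR/SVM a seeded permutation-Shapley estimator targets the SPMS probability.

# -- random forest: exact tree-path decomposition ------------------------------

# Extract per-tree structures with node values (training-coverage-weighted
# SPMS vote expectation below each node). Cached on the model object.
#' @keywords internal
rf_structures <- function(model) {
  if (!is.null(model$cache$rf_struct)) return(model$cache$rf_struct)
  fit <- model$fit
  X <- model$X_train
  ntree <- fit$ntree
  structs <- vector("list", ntree)
  for (k in seq_len(ntree)) {
    tr <- randomForest::getTree(fit, k, labelVar = FALSE)
    nnode <- nrow(tr)
    left <- tr[, "left daughter"]
    right <- tr[, "right daughter"]
    svar <- tr[, "split var"]
    spoint <- tr[, "split point"]
    terminal <- tr[, "status"] == -1
    # drop every training row through the tree to get node coverage
    counts <- integer(nnode)
    node_rows <- vector("list", nnode)
    node_rows[[1]] <- seq_len(nrow(X))
    for (i in seq_len(nnode)) {
      rows <- node_rows[[i]]
      counts[i] <- length(rows)
      if (terminal[i] || !length(rows)) next
      go_left <- X[rows, svar[i]] <= spoint[i]
      node_rows[[left[i]]] <- rows[go_left]
      node_rows[[right[i]]] <- rows[!go_left]
    }
    # bottom-up node values: terminal value is the SPMS vote indicator,
    # internal value the coverage-weighted mean of the daughters
    value <- numeric(nnode)
    for (i in rev(seq_len(nnode))) {
      if (terminal[i]) {
        value[i] <- as.numeric(tr[i, "prediction"] == 2)  # level 2 = SPMS
      } else {
        wl <- counts[left[i]]
        wr <- counts[right[i]]
        if (wl + wr == 0) {
          value[i] <- mean(c(value[left[i]], value[right[i]]))
        } else {
          value[i] <- (wl * value[left[i]] + wr * value[right[i]]) / (wl + wr)
        }
      }
    }
    structs[[k]] <- list(left = left, right = right, svar = svar,
                         spoint = spoint, terminal = terminal, value = value)
  }
  model$cache$rf_struct <- structs
  structs
}

# Batch tree-path attributions for a random forest: every parent-to-daughter
# move along a visit's decision path credits the split feature with the
# change in node value; summed over trees this reproduces the SPMS vote
# fraction exactly.
#' @keywords internal
rf_path_attributions <- function(model, X) {
  structs <- rf_structures(model)
  n <- nrow(X)
  p <- ncol(X)
  contrib <- matrix(0, n, p, dimnames = list(NULL, model$features))
  base <- 0
  for (st in structs) {
    base <- base + st$value[1]
    node_rows <- list(seq_len(n))
    nodes <- 1L
    while (length(nodes)) {
      nxt_rows <- list()
      nxt_nodes <- integer(0)
      for (q in seq_along(nodes)) {
        i <- nodes[q]
        rows <- node_rows[[q]]
        if (st$terminal[i] || !length(rows)) next
        go_left <- X[rows, st$svar[i]] <= st$spoint[i]
        for (d in c(st$left[i], st$right[i])) {
          rws <- if (d == st$left[i]) rows[go_left] else rows[!go_left]
          if (!length(rws)) next
          contrib[rws, st$svar[i]] <- contrib[rws, st$svar[i]] +
            (st$value[d] - st$value[i])
          nxt_rows[[length(nxt_rows) + 1]] <- rws
          nxt_nodes <- c(nxt_nodes, d)
        }
      }
      node_rows <- nxt_rows
      nodes <- nxt_nodes
    }
  }
  ntree <- length(structs)
  list(contrib = contrib / ntree, base = base / ntree)
}

# -- sampling fallback (LR / SVM) ----------------------------------------------

# Permutation-Shapley on the SPMS probability with a fixed background sample.
# Each permutation's marginal contributions telescope to
# f(x) - f(background row), so local accuracy is exact after averaging.
#' @keywords internal
sampling_attribution <- function(model, x, background, n_perm = 10, seed = 1L) {
  set.seed(seed)
  p <- length(x)
  nb <- nrow(background)
  contrib <- numeric(p)
  grid <- vector("list", n_perm * nb)
  perms <- replicate(n_perm, sample.int(p), simplify = FALSE)
  # build one matrix of all intermediate points, predict once
  idx <- 1L
  for (perm in perms) {
    for (b in seq_len(nb)) {
      z <- matrix(rep(background[b, ], p + 1), nrow = p + 1, byrow = TRUE)
      for (step in seq_len(p)) {
        z[(step + 1):(p + 1), perm[step]] <- x[perm[step]]
      }
      grid[[idx]] <- z
      idx <- idx + 1L
    }
  }
  big <- do.call(rbind, grid)
  colnames(big) <- model$features
  f <- predict_proba(model, big)[, "SPMS"]
  pos <- 0L
  base_acc <- 0
  for (perm in perms) {
    for (b in seq_len(nb)) {
      fv <- f[(pos + 1):(pos + p + 1)]
      contrib[perm] <- contrib[perm] + diff(fv)
      base_acc <- base_acc + fv[1]
      pos <- pos + p + 1L
    }
  }
  m <- n_perm * nb
  list(contrib = stats::setNames(contrib / m, model$features),
       base = base_acc / m)
}

# -- public surface ------------------------------------------------------------

#' Additive attribution of one visit's prediction
#'
#' Decomposes the model output for a single visit into a base value plus one
#' signed contribution per feature (positive toward SPMS, negative toward
#' RRMS), satisfying local accuracy: base + sum(contributions) equals the
#' model output to numerical precision. Random forests use an exact tree-path
#' decomposition of the SPMS vote fraction; gradient boosting uses exact
#' TreeSHAP on the margin; logistic regression and SVM use a seeded
#' permutation-Shapley estimator of the SPMS probability (enable with
#' `method = "sampling"`).
#'
#' @param model an `ms_classifier`.
#' @param x a single visit: named numeric vector or one-row matrix with the
#'   model's features.
#' @param method `"auto"` picks the exact method for tree ensembles and
#'   errors otherwise; `"sampling"` forces the permutation estimator.
#' @param background background matrix for the sampling estimator (default: a
#'   seeded sample of up to 25 training rows).
#' @param n_perm permutations for the sampling estimator.
#' @param seed seed for the sampling estimator.
#' @return object of class `ms_attribution`: named `values`, `base`,
#'   `output`, `method`, `output_scale`.
#' @export
local_attribution <- function(model, x, method = c("auto", "tree_path", "sampling"),
                              background = NULL, n_perm = 10, seed = 1L) {
  method <- match.arg(method)
  stopifnot(inherits(model, "ms_classifier"))
  xm <- rbind(x)
  if (!is.null(colnames(xm))) xm <- xm[, model$features, drop = FALSE]
  colnames(xm) <- model$features
  if (method == "auto") {
    method <- if (model$kind %in% c("random_forest", "gradient_boosting"))
      "tree_path" else "sampling"
  }
  if (method == "tree_path" &&
      !model$kind %in% c("random_forest", "gradient_boosting")) {
    stop("tree-path attribution supports random_forest and gradient_boosting; ",
         "use method = 'sampling' for ", model$kind, call. = FALSE)
  }
  if (method == "tree_path") {
    if (model$kind == "random_forest") {
      at <- rf_path_attributions(model, xm)
      values <- stats::setNames(at$contrib[1, ], model$features)
      base <- at$base
      scale <- "probability"
    } else {
      pc <- stats::predict(model$fit, xgboost::xgb.DMatrix(xm),
                           predcontrib = TRUE)
      # last column is the bias term (named BIAS or (Intercept) by version)
      values <- stats::setNames(pc[1, seq_along(model$features)],
                                model$features)
      base <- unname(pc[1, ncol(pc)])
      scale <- "margin"
    }
  } else {
    if (is.null(background)) {
      set.seed(seed)
      take <- sample.int(nrow(model$X_train), min(25, nrow(model$X_train)))
      background <- model$X_train[take, , drop = FALSE]
    }
    at <- sampling_attribution(model, xm[1, ], background, n_perm, seed)
    values <- at$contrib
    base <- at$base
    scale <- "probability"
  }
  structure(list(values = values, base = base,
                 output = base + sum(values), method = method,
                 output_scale = scale),
            class = "ms_attribution")
}

#' @export
print.ms_attribution <- function(x, top = 8, ...) {
  cat(sprintf("Additive attribution (%s, %s scale)\n", x$method, x$output_scale))
  cat(sprintf("  base %.4f + contributions %.4f = output %.4f\n",
              x$base, sum(x$values), x$output))
  v <- sort(x$values, decreasing = TRUE)
  v <- v[order(-abs(v))][seq_len(min(top, length(v)))]
  for (nm in names(v)) cat(sprintf("  %+0.4f  %s\n", v[nm], nm))
  invisible(x)
}

#' Plot an attribution as a force-style bar chart
#'
#' @param x an `ms_attribution`.
#' @param top number of largest-magnitude features to show.
#' @param ... unused.
#' @export
plot.ms_attribution <- function(x, top = 10, ...) {
  v <- x$values[order(-abs(x$values))][seq_len(min(top, length(x$values)))]
  v <- rev(v)
  graphics::barplot(v, horiz = TRUE, las = 1,
                    col = ifelse(v > 0, "firebrick", "steelblue"),
                    xlab = sprintf("contribution (%s; red -> SPMS)",
                                   x$output_scale),
                    cex.names = 0.7)
  invisible(x)
}

#' Global feature importance over a dataset
#'
#' Mean absolute per-visit contribution of every feature, ranked in
#' descending order with alphabetical tie-breaking (the summary-plot
#' ordering).
#'
#' @param model an `ms_classifier`.
#' @param X matrix of visits to attribute.
#' @param method,background,n_perm,seed as in [local_attribution()].
#' @return data frame with columns `feature`, `mean_abs_contribution`, ranked.
#' @export
global_importance <- function(model, X, method = c("auto", "tree_path", "sampling"),
                              background = NULL, n_perm = 10, seed = 1L) {
  method <- match.arg(method)
  stopifnot(nrow(X) >= 1)
  X <- as.matrix(X)
  if (!is.null(colnames(X))) X <- X[, model$features, drop = FALSE]
  if (method == "auto") {
    method <- if (model$kind %in% c("random_forest", "gradient_boosting"))
      "tree_path" else "sampling"
  }
  if (method == "tree_path" && model$kind == "random_forest") {
    contrib <- rf_path_attributions(model, X)$contrib
  } else if (method == "tree_path" && model$kind == "gradient_boosting") {
    pc <- stats::predict(model$fit, xgboost::xgb.DMatrix(X), predcontrib = TRUE)
    contrib <- pc[, seq_along(model$features), drop = FALSE]
    colnames(contrib) <- model$features
  } else {
    rows <- lapply(seq_len(nrow(X)), function(i) {
      local_attribution(model, X[i, ], method = "sampling",
                        background = background, n_perm = n_perm,
                        seed = seed)$values
    })
    contrib <- do.call(rbind, rows)
  }
  imp <- colMeans(abs(contrib))
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord],
             mean_abs_contribution = unname(imp[ord]),
             stringsAsFactors = FALSE)
}
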