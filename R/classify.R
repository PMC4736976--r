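#' Train an SWLDA classifier
#'
#' Stepwise linear discriminant analysis: features are chosen by
#' p-value-driven stepwise regression ([stepwise_select()]) of +1/-1 class
#' codes on the feature columns, and the decision threshold is placed at
#' the midpoint of the projected class-mean scores (training sets here are
#' balanced by construction).
#'
#' @param X numeric feature matrix.
#' @param y labels (`"P300"`/`"NONP300"`, or +1/-1).
#' @param p_enter,p_remove stepwise entry/removal p-values.
#' @return An object of class `swlda_model` with `mask`, `weights`,
#'   `intercept` (the decision threshold is score > 0 after subtracting
#'   it) fields and a [predict()] method returning labels.
#' @export
swlda_train <- function(X, y, p_enter = 0.1, p_remove = 0.15) {
  X <- as.matrix(X)
  yn <- if (is.character(y) || is.factor(y)) ifelse(as.character(y) == "P300", 1, -1) else as.numeric(y)
  if (length(unique(yn)) < 2) abort("training needs both classes present.")
  sw <- suppressMessages(stepwise_select(X, yn, p_enter, p_remove))
  score <- if (sum(sw$mask) == 0) rep(0, nrow(X))
           else as.vector(X[, sw$mask, drop = FALSE] %*% sw$weights)
  thr <- (mean(score[yn > 0]) + mean(score[yn < 0])) / 2
  flip <- mean(score[yn > 0]) < mean(score[yn < 0])
  structure(list(mask = sw$mask, weights = sw$weights, intercept = thr,
                 flip = flip), class = "swlda_model")
}

#' @export
predict.swlda_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  score <- if (sum(object$mask) == 0) rep(0, nrow(X))
           else as.vector(X[, object$mask, drop = FALSE] %*% object$weights)
  s <- score - object$intercept
  if (object$flip) s <- -s
  ifelse(s > 0, "P300", "NONP300")
}

#' Train a linear maximum-margin classifier
#'
#' Soft-margin linear SVM (via \pkg{e1071}) on the shape-feature vectors.
#' `margin_train_loo()` runs the leave-one-out protocol: it fits one model
#' per held-out example (2U models on a balanced 2U-example set) and
#' selects one of them at random under a fixed seed.
#'
#' @param X numeric feature matrix.
#' @param y labels (`"P300"`/`"NONP300"`, or +1/-1).
#' @param cost soft-margin regularization constant (default 1).
#' @return `margin_train()` returns an object of class `margin_model` with
#'   the fitted SVM, the separating `weights` and `intercept`;
#'   `margin_train_loo()` returns a list with `models` (all leave-one-out
#'   fits), `selected` (the chosen index) and `model` (the chosen fit).
#' @export
margin_train <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  lab <- if (is.character(y) || is.factor(y)) as.character(y)
         else ifelse(as.numeric(y) > 0, "P300", "NONP300")
  if (length(unique(lab)) < 2) abort("training needs both classes present.")
  fit <- e1071::svm(X, factor(lab, levels = c("NONP300", "P300")),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  structure(list(fit = fit, weights = w, intercept = -fit$rho,
                 mask = rep(TRUE, ncol(X))), class = "margin_model")
}

#' @export
predict.margin_model <- function(object, newdata, ...) {
  as.character(predict(object$fit, as.matrix(newdata)))
}

#' @rdname margin_train
#' @param seed integer seed for the random model selection.
#' @export
margin_train_loo <- function(X, y, cost = 1, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  models <- lapply(seq_len(n), function(i) {
    margin_train(X[-i, , drop = FALSE], y[-i], cost)
  })
  pick <- withr::with_seed(as.integer(seed), sample.int(n, 1))
  list(models = models, selected = pick, model = models[[pick]])
}

#' Confusion counts and classification accuracy
#'
#' `confusion_counts()` tallies true/false positives and negatives of
#' predicted against true labels (positive class `"P300"`);
#' `accuracy()` is their proportion correct, `(TP + TN) / total`.
#'
#' @param truth,pred label vectors.
#' @param counts a list or one-row data frame with `TP`, `TN`, `FP`, `FN`.
#' @return `confusion_counts()` returns a one-row tibble; `accuracy()` a
#'   real in `[0, 1]`.
#' @examples
#' accuracy(list(TP = 9, TN = 8, FP = 2, FN = 1))
#' @export
confusion_counts <- function(truth, pred) {
  tibble(TP = sum(truth == "P300" & pred == "P300"),
         TN = sum(truth == "NONP300" & pred == "NONP300"),
         FP = sum(truth == "NONP300" & pred == "P300"),
         FN = sum(truth == "P300" & pred == "NONP300"))
}

#' @rdname confusion_counts
#' @export
accuracy <- function(counts) {
  tot <- counts$TP + counts$TN + counts$FP + counts$FN
  if (any(c(counts$TP, counts$TN, counts$FP, counts$FN) < 0)) {
    abort("confusion counts must be nonnegative.")
  }
  if (tot == 0) abort("total confusion count must be positive.")
  (counts$TP + counts$TN) / tot
}

#' Validate a calibration profile on held-out epochs
#'
#' Implements the balanced validation protocol: from the validation set it
#' draws `D = floor(P'/K)` disjoint groups of K P300 trials and D disjoint
#' groups of K non-P300 trials, coherently averages each group, extracts
#' its shape-feature vector against the profile's template for each
#' selected electrode, classifies it with a model trained on the profile's
#' stored balanced training block, and reports per-electrode confusion
#' counts and accuracy, ranked best to worst. A `"concatenated"` mode
#' instead joins the feature blocks of all selected electrodes into one
#' vector per candidate and reports a single row.
#'
#' @param profile a `p300_calibration` with at least one selected electrode.
#' @param validation an `epoch_set` of held-out labeled trials.
#' @param K stimulations per averaged candidate; defaults to the profile's
#'   optimum `K'`.
#' @param seed integer seed for the balanced subset draws.
#' @param classifier `"swlda"` (default) or `"svm"`.
#' @param electrode_mode `"per_electrode"` (default) or `"concatenated"`.
#' @return A tibble of class `p300_validation`: `electrode`, `rank`, `TP`,
#'   `TN`, `FP`, `FN`, `accuracy`.
#' @export
validate_profile <- function(profile, validation, K = NULL, seed = 1,
                             classifier = c("swlda", "svm"),
                             electrode_mode = c("per_electrode", "concatenated")) {
  classifier <- match.arg(classifier)
  electrode_mode <- match.arg(electrode_mode)
  stopifnot(inherits(profile, "p300_calibration"), inherits(validation, "epoch_set"))
  if (length(profile$electrodes) == 0) {
    abort("profile has no selected electrodes (status unsuitable).")
  }
  K <- as.integer(K %||% profile$K_opt)
  Pp <- sum(validation$labels == "P300")
  Np <- sum(validation$labels == "NONP300")
  D <- Pp %/% K
  if (D < 1) abort(sprintf("validation set has %d P300 trials, fewer than K = %d.", Pp, K))
  if (Np < D * K) {
    abort(sprintf("validation set needs %d non-P300 trials, has %d.", D * K, Np))
  }
  S <- profile$params$S
  mode <- profile$params$mode
  pool_P <- which(validation$labels == "P300")
  pool_N <- which(validation$labels == "NONP300")
  xs <- seq_len(n_samples(validation))

  # disjoint balanced groups, shared across electrodes
  groups <- list(P = vector("list", D), N = vector("list", D))
  used_P <- integer(0); used_N <- integer(0)
  for (g in seq_len(D)) {
    pidx <- sample_from_pool(setdiff(pool_P, used_P), K, derive_seed(seed, 301, g))
    used_P <- c(used_P, pidx)
    nidx <- sample_from_pool(setdiff(pool_N, used_N), K, derive_seed(seed, 307, g))
    used_N <- c(used_N, nidx)
    groups$P[[g]] <- pidx
    groups$N[[g]] <- nidx
  }
  truth <- c(rep("P300", D), rep("NONP300", D))

  feat_block <- function(e) {
    mat <- electrode_series(validation, e)
    tpl <- profile$templates[[e]]
    rows <- lapply(c(groups$P, groups$N), function(idx) {
      cand <- erp_curve(xs, colMeans(mat[idx, , drop = FALSE]))
      as.numeric(shape_vector_from_curves(tpl$curve, tpl$chain, cand, S, mode))
    })
    X <- do.call(rbind, rows)
    colnames(X) <- feature_names(S)
    X
  }
  train_model <- function(X, y) {
    if (classifier == "swlda") {
      swlda_train(X, y, profile$params$p_enter, profile$params$p_remove)
    } else {
      loo <- margin_train_loo(X, y, seed = derive_seed(seed, 311))
      loo$model
    }
  }

  if (electrode_mode == "concatenated") {
    Xv <- do.call(cbind, lapply(profile$electrodes, feat_block))
    Xt <- do.call(cbind, lapply(profile$electrodes,
                                function(e) profile$train_blocks[[e]]$X))
    colnames(Xv) <- colnames(Xt) <- paste0("c", seq_len(ncol(Xt)))
    y <- profile$train_blocks[[profile$electrodes[1]]]$y
    mdl <- train_model(Xt, y)
    cc <- confusion_counts(truth, predict(mdl, Xv))
    out <- dplyr::bind_cols(tibble(electrode = "all", rank = 1L), cc,
                            tibble(accuracy = accuracy(cc)))
  } else {
    rows <- lapply(profile$electrodes, function(e) {
      blk <- profile$train_blocks[[e]]
      mdl <- train_model(blk$X, blk$y)
      cc <- confusion_counts(truth, predict(mdl, feat_block(e)))
      dplyr::bind_cols(tibble(electrode = e), cc,
                       tibble(accuracy = accuracy(cc)))
    })
    out <- dplyr::bind_rows(rows) |>
      dplyr::arrange(dplyr::desc(.data$accuracy)) |>
      dplyr::mutate(rank = dplyr::row_number(), .after = "electrode")
  }
  class(out) <- c("p300_validation", class(out))
  attr(out, "D") <- D
  attr(out, "K") <- K
  attr(out, "classifier") <- classifier
  out
}

#' @exportS3Method ggplot2::autoplot
autoplot.p300_validation <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$electrode, .data$rank),
                                   y = .data$accuracy)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(x = "electrode (ranked)", y = expression(psi~"(accuracy)")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
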