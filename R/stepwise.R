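#' P-value-driven stepwise feature selection
#'
#' Forward-entry / backward-removal stepwise least-squares regression of
#' numeric class labels on the columns of `X`, the feature-reduction engine
#' behind SWLDA. At each forward step the candidate with the smallest
#' partial-F p-value enters if that p-value is below `p_enter`; at each
#' backward step the retained column with the largest p-value leaves if it
#' exceeds `p_remove`. Iteration stops when neither step changes the model.
#' Constant (zero-variance) columns are skipped with a note. The procedure
#' is fully deterministic given `X` and `y`; ties break toward the lowest
#' column index.
#'
#' @param X numeric feature matrix (rows = examples).
#' @param y class labels: numeric (+1/-1) or anything coercible via
#'   `"P300"` -> +1, otherwise -1.
#' @param p_enter entry threshold on the partial-F p-value (default 0.1).
#' @param p_remove removal threshold (default 0.15); must exceed `p_enter`.
#' @return A list with `mask` (logical, length `ncol(X)`), `weights` (named
#'   coefficients of the retained columns), `intercept`, and `features`
#'   (the retained column values of `X`).
#' @export
stepwise_select <- function(X, y, p_enter = 0.1, p_remove = 0.15) {
  X <- as.matrix(X)
  if (is.character(y) || is.factor(y)) y <- ifelse(as.character(y) == "P300", 1, -1)
  y <- as.numeric(y)
  n <- nrow(X); V <- ncol(X)
  if (length(y) != n) abort("length(y) must equal nrow(X).")
  if (!(p_enter > 0 && p_enter < p_remove && p_remove < 1)) {
    abort("need 0 < p_enter < p_remove < 1.")
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(V))

  usable <- apply(X, 2, function(col) sd(col) > 0)
  if (any(!usable)) {
    rlang::inform(sprintf("stepwise: skipping %d constant column(s).", sum(!usable)))
  }

  selected <- logical(V)
  max_terms <- n - 2                      # keep every fit overdetermined
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 10L * V + 10L) break       # cycle guard
    changed <- FALSE
    # forward entry: partial F of each candidate given the current model,
    # computed by residualizing y and the candidates against the design
    cand <- which(usable & !selected)
    if (length(cand) > 0 && sum(selected) < max_terms) {
      Q <- qr.Q(qr(cbind(1, X[, selected, drop = FALSE])))
      ry <- y - Q %*% crossprod(Q, y)
      RC <- X[, cand, drop = FALSE]
      RC <- RC - Q %*% crossprod(Q, RC)
      ssy <- sum(ry^2)
      cc <- as.vector(crossprod(RC, ry))
      ss <- colSums(RC^2)
      ok <- ss > 1e-10 * n & ssy > 0
      df2 <- n - sum(selected) - 2
      if (df2 > 0 && any(ok)) {
        r2 <- numeric(length(cand))
        r2[ok] <- (cc[ok]^2 / ss[ok]) / ssy
        r2 <- pmin(r2, 1)
        pvals <- rep(Inf, length(cand))
        f <- df2 * r2[ok] / pmax(1 - r2[ok], 1e-300)
        pvals[ok] <- pf(f, 1, df2, lower.tail = FALSE)
        j <- which.min(pvals)
        if (pvals[j] < p_enter) {
          selected[cand[j]] <- TRUE
          changed <- TRUE
        }
      }
    }
    # backward removal: coefficient p-values in the current fit
    if (sum(selected) > 0) {
      Xs <- cbind(`(Intercept)` = 1, X[, selected, drop = FALSE])
      fit <- lm.fit(Xs, y)
      df <- n - fit$rank
      if (df > 0) {
        s2 <- sum(fit$residuals^2) / df
        R <- qr.R(fit$qr)
        covm <- chol2inv(R) * s2
        se <- sqrt(diag(covm))
        tvals <- fit$coefficients / se
        pv <- pf(tvals[-1]^2, 1, df, lower.tail = FALSE)  # two-sided t == F(1, df)
        worst <- which.max(pv)
        if (length(pv) > 0 && is.finite(pv[worst]) && pv[worst] > p_remove) {
          selected[which(selected)[worst]] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  if (sum(selected) == 0) {
    return(list(mask = selected, weights = numeric(0), intercept = mean(y),
                features = X[, selected, drop = FALSE]))
  }
  fit <- lm.fit(cbind(1, X[, selected, drop = FALSE]), y)
  w <- fit$coefficients[-1]
  names(w) <- colnames(X)[selected]
  list(mask = selected, weights = w, intercept = unname(fit$coefficients[1]),
       features = X[, selected, drop = FALSE])
}
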