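# Shared fixtures and independent oracles for the test suite.

# Small epoch set of pure noise with optional per-electrode signal added to
# the P300 class. `signal` is a function(t_index) -> amplitude vector, or a
# numeric vector of per-electrode scales applied to a fixed bump.
make_epochs <- function(nP = 6, nN = 12, C = 2, T = 40, fs = 50,
                        amp = rep(0, C), noise_sd = 1, seed = 1,
                        electrodes = paste0("E", seq_len(C))) {
  withr::with_seed(seed, {
    n <- nP + nN
    arr <- array(rnorm(n * C * T, sd = noise_sd), c(n, C, T))
    bump <- exp(-((seq_len(T) - 0.6 * T)^2) / (2 * (T / 10)^2))
    if (nP > 0) {
      for (c in seq_len(C)) {
        arr[seq_len(nP), c, ] <-
          arr[seq_len(nP), c, ] + rep(amp[c] * bump, each = nP)
      }
    }
    epoch_set(arr, c(rep("P300", nP), rep("NONP300", nN)), electrodes,
              fs, T / fs * 1000)
  })
}

# Exhaustive pairwise AUROC oracle: (wins + half ties) / (n * m), counting
# a win when the P300 distance is strictly smaller.
auroc_oracle <- function(dP, dN) {
  wins <- 0
  for (p in dP) for (q in dN) {
    if (p < q) wins <- wins + 1 else if (p == q) wins <- wins + 0.5
  }
  wins / (length(dP) * length(dN))
}

# Independent stepwise path oracle built on lm()/anova(): forward-enters
# the candidate with the smallest partial-F p-value below p_enter, then
# backward-removes the worst retained term above p_remove, until stable.
stepwise_oracle <- function(X, y, p_enter = 0.1, p_remove = 0.15) {
  X <- as.matrix(X)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(y = y, X)
  usable <- which(apply(X, 2, stats::sd) > 0)
  sel <- integer(0)
  repeat {
    changed <- FALSE
    cand <- setdiff(usable, sel)
    if (length(cand) > 0) {
      base_terms <- if (length(sel) == 0) "1" else paste(colnames(X)[sel], collapse = "+")
      f0 <- stats::lm(stats::as.formula(paste("y ~", base_terms)), data = df)
      pv <- vapply(cand, function(j) {
        f1 <- stats::update(f0, stats::as.formula(paste(". ~ . +", colnames(X)[j])))
        if (f1$rank <= f0$rank) return(Inf)
        a <- stats::anova(f0, f1)
        a$`Pr(>F)`[2]
      }, numeric(1))
      if (any(is.finite(pv)) && min(pv) < p_enter) {
        sel <- c(sel, cand[which.min(pv)])
        changed <- TRUE
      }
    }
    if (length(sel) > 0) {
      ft <- stats::lm(stats::as.formula(
        paste("y ~", paste(colnames(X)[sel], collapse = "+"))), data = df)
      sm <- summary(ft)$coefficients
      pv <- sm[-1, 4]
      if (max(pv) > p_remove) {
        worst <- names(pv)[which.max(pv)]
        sel <- sel[colnames(X)[sel] != worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(sel)
}

# Random valid chain of length S (two-decimal symbols in (-1, 1)).
random_chain <- function(S) {
  shcc_chain(sample(seq(-99, 99)) [seq_len(S)] / 100)
}
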