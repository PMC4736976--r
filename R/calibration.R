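#' Calibration parameters
#'
#' Bundles the tunables of the per-subject calibration wrapper: the chain
#' segment count `S`, the number of P300 trials averaged into each template
#' `A`, the maximum stimulation count `K`, the number of candidate
#' templates per electrode `O`, the AUROC acceptance and fallback
#' thresholds of the electrode selector, the stepwise entry/removal
#' p-values, a cap on cross-validation folds, and the master seed from
#' which every randomized operator derives its own seed.
#'
#' @param S segments per chain (default 16: a 20 Hz shape-preserving
#'   resampling of an 800 ms epoch).
#' @param A P300 trials averaged per template (default 180).
#' @param K maximum number of stimulations (default 15).
#' @param O candidate templates per electrode (default 10).
#' @param auroc_accept electrode acceptance threshold on the mean AUROC
#'   (default 0.8).
#' @param auroc_fallback fallback threshold used when no electrode reaches
#'   acceptance (default 0.6).
#' @param p_enter,p_remove stepwise regression entry/removal p-values
#'   (defaults 0.1 / 0.15).
#' @param max_folds cap on the number of cross-validation folds `U`
#'   (default 20, the value of `floor((480-180)/15)` in the reference
#'   regime); `U = min(floor((P - A)/k), max_folds)` is recomputed at every
#'   stimulation count `k`.
#' @param master_seed integer master seed.
#' @param mode chain symbol convention passed to [encode_chain()].
#' @return A list of class `calibration_params`.
#' @export
calibration_params <- function(S = 16, A = 180, K = 15, O = 10,
                               auroc_accept = 0.8, auroc_fallback = 0.6,
                               p_enter = 0.1, p_remove = 0.15,
                               max_folds = 20, master_seed = 1,
                               mode = c("angle", "rise")) {
  mode <- match.arg(mode)
  if (!(auroc_fallback > 0 && auroc_fallback < auroc_accept && auroc_accept <= 1)) {
    abort("need 0 < auroc_fallback < auroc_accept <= 1.")
  }
  if (!(p_enter > 0 && p_enter < p_remove && p_remove < 1)) {
    abort("need 0 < p_enter < p_remove < 1.")
  }
  stopifnot(S >= 1, A >= 1, K >= 1, O >= 1, max_folds >= 1)
  structure(list(S = as.integer(S), A = as.integer(A), K = as.integer(K),
                 O = as.integer(O), auroc_accept = auroc_accept,
                 auroc_fallback = auroc_fallback, p_enter = p_enter,
                 p_remove = p_remove, max_folds = as.integer(max_folds),
                 master_seed = as.integer(master_seed), mode = mode),
            class = "calibration_params")
}

#' Area under the ROC curve from class-wise distances
#'
#' Rank-based (Mann-Whitney) AUROC for discriminating P300 from non-P300
#' by their template distances, oriented so that *smaller* P300 distances
#' score toward 1. Ties contribute one half.
#'
#' @param dP distances of P300-class averages to the template.
#' @param dN distances of non-P300-class averages to the template.
#' @return The AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.1, 0.2), c(0.9, 1.0))  # perfect separation -> 1
#' @export
auroc <- function(dP, dN) {
  nP <- length(dP); nN <- length(dN)
  if (nP == 0 || nN == 0) abort("both distance samples must be nonempty.")
  r <- rank(c(dP, dN))
  # P(dN > dP) + 0.5 P(ties), via the rank-sum of the non-P300 sample
  (sum(r[nP + seq_len(nN)]) - nN * (nN + 1) / 2) / (nP * nN)
}

#' Build one P300 template
#'
#' Randomly selects `A` P300-labeled trials at one electrode, coherently
#' averages them, and encodes the average as a length-`S` chain. The used
#' trial indices are reported so downstream cross-validation folds can
#' exclude them.
#'
#' @param epochs an `epoch_set`.
#' @param electrode electrode name or index.
#' @param A number of P300 trials to average.
#' @param S chain segment count.
#' @param seed integer seed for the random selection.
#' @param mode chain symbol convention.
#' @return A list with `curve` (the averaged `erp_curve`), `chain` (the
#'   template `shcc_chain`), and `indices` (the A trial indices used).
#' @export
build_template <- function(epochs, electrode, A, S, seed,
                           mode = c("angle", "rise")) {
  mode <- match.arg(mode)
  sel <- random_subset(epochs, "P300", A, seed)
  curve <- coherent_average(sel$epochs, electrode)
  list(curve = curve, chain = encode_chain(curve, S, mode), indices = sel$indices)
}

#' Extract one shape-feature vector against a template
#'
#' Randomly selects `k` trials of the requested class (outside `exclude`),
#' coherently averages them, encodes the average, and assembles the
#' (2S+2)-dimensional shape-feature vector relative to the template: signed
#' per-segment area differences and their absolute sum, the l1 chain
#' distance, the candidate chain's tortuosity, and the candidate chain
#' symbols.
#'
#' @param template result of [build_template()] (needs `curve` and `chain`).
#' @param epochs an `epoch_set`.
#' @param electrode electrode name or index.
#' @param label class to draw the candidate trials from.
#' @param k number of trials averaged into the candidate.
#' @param S chain segment count (must match the template chain).
#' @param seed integer seed.
#' @param exclude trial indices ineligible for selection (e.g. the
#'   template's own trials).
#' @param mode chain symbol convention.
#' @return A list with `v` (a `shape_features` vector) and `indices`.
#' @export
feature_pair <- function(template, epochs, electrode, label, k, S, seed,
                         exclude = integer(0), mode = c("angle", "rise")) {
  mode <- match.arg(mode)
  sel <- random_subset(epochs, label, k, seed, exclude)
  cand <- coherent_average(sel$epochs, electrode)
  v <- shape_vector_from_curves(template$curve, template$chain, cand, S, mode)
  list(v = v, indices = sel$indices)
}

# Shared assembly: template curve/chain vs a candidate curve.
shape_vector_from_curves <- function(template_curve, template_chain,
                                     candidate_curve, S, mode) {
  tnc <- normalize_curve(resample_curve(template_curve, S))
  cnc <- normalize_curve(resample_curve(candidate_curve, S))
  cchain <- shcc_chain(chain_symbols(cnc, mode))
  ad <- area_difference_features(tnc, cnc)
  assemble_vector(ad$area_diffs, ad$area_diff_sum,
                  chain_distance(template_chain, cchain),
                  tortuosity(cchain), cchain)
}

#' Mean AUROC per electrode
#'
#' Column-wise mean of the template-score matrix `Z` (templates in rows,
#' electrodes in columns): the per-electrode performance summary the
#' electrode selector thresholds.
#'
#' @param Z an O x C matrix of per-template AUROCs.
#' @return A numeric vector of length C (named if `Z` has column names).
#' @export
average_auroc <- function(Z) {
  Z <- as.matrix(Z)
  colMeans(Z)
}

#' Threshold electrodes on their mean AUROC
#'
#' Electrodes whose mean AUROC reaches `accept` are selected and the
#' calibration loop continues; if none do, electrodes strictly above
#' `fallback` are selected and the loop stops; if none reach the fallback
#' either, the subject is flagged unsuitable for shape-domain P300
#' detection.
#'
#' @param phi per-electrode mean AUROCs (named or positional).
#' @param accept acceptance threshold (default 0.8).
#' @param fallback fallback threshold (default 0.6).
#' @return A list with `electrodes` (indices into `phi`), `continue`
#'   (logical), and `status` (`"accept"`, `"fallback"` or `"unsuitable"`).
#' @export
select_electrodes <- function(phi, accept = 0.8, fallback = 0.6) {
  sel <- which(phi >= accept)
  if (length(sel) > 0) {
    return(list(electrodes = sel, continue = TRUE, status = "accept"))
  }
  sel <- which(phi > fallback)
  if (length(sel) > 0) {
    return(list(electrodes = sel, continue = FALSE, status = "fallback"))
  }
  list(electrodes = integer(0), continue = FALSE, status = "unsuitable")
}

#' Calibrate the shape-domain P300 detector for one subject
#'
#' Runs the wrapper calibration over decreasing stimulation counts k. At
#' each k it recomputes `U = min(floor((P - A)/k), max_folds)`, and for
#' every electrode builds `O` candidate templates (each the coherent
#' average of `A` random P300 trials, encoded as a chain); every template
#' is scored by extracting `U` P300 and `U` non-P300 averaged candidates
#' (k trials each, disjoint from the template and from one another),
#' assembling their shape-feature vectors, and computing the AUROC of the
#' chain-distance component (position S+1). Stepwise regression reduces
#' each template's 2U x V feature block. Per-electrode mean AUROCs are
#' thresholded by [select_electrodes()]: while some electrode reaches the
#' acceptance threshold, k is decremented and the passing state recorded;
#' when none does, the profile from the smallest passing k is returned
#' (or, if no k ever passed, the fallback/unsuitable branch at the first
#' k). For each selected electrode the template with the highest AUROC
#' (ties toward the lowest template index) supplies the returned chain,
#' feature mask, regression weights and retained features.
#'
#' @param train an `epoch_set` with P300/NONP300-labeled training trials.
#' @param params a [calibration_params()] object.
#' @return An object of class `p300_calibration`; see [tidy.p300_calibration()]
#'   and [glance.p300_calibration()] for tabular summaries.
#' @export
calibrate <- function(train, params = calibration_params()) {
  stopifnot(inherits(train, "epoch_set"), inherits(params, "calibration_params"))
  P <- sum(train$labels == "P300")
  N <- sum(train$labels == "NONP300")
  C <- n_electrodes(train)
  S <- params$S
  V <- 2 * S + 2
  if (P < params$A + params$K) {
    abort(sprintf("need at least A + K = %d P300 trials, have %d.",
                  params$A + params$K, P))
  }
  pool_P <- which(train$labels == "P300")
  pool_N <- which(train$labels == "NONP300")
  series <- lapply(seq_len(C), function(c) electrode_series(train, c))
  Tn <- n_samples(train)
  xs <- seq_len(Tn)

  phi_history <- list()
  z_history <- list()
  last_pass <- NULL
  final <- NULL

  for (k in seq(params$K, 1)) {
    U <- min((P - params$A) %/% k, params$max_folds)
    if (U < 1) break
    if (N < U * k) {
      abort(sprintf("need at least U*k = %d non-P300 trials at k = %d, have %d.",
                    U * k, k, N))
    }
    Z <- matrix(NA_real_, params$O, C)
    iter <- vector("list", C)               # per-electrode per-template records
    for (c in seq_len(C)) {
      mat <- series[[c]]
      recs <- vector("list", params$O)
      for (o in seq_len(params$O)) {
        seed_t <- derive_seed(params$master_seed, 101, k, c, o)
        tidx <- sample_from_pool(pool_P, params$A, seed_t)
        tcurve <- erp_curve(xs, colMeans(mat[tidx, , drop = FALSE]))
        tchain <- encode_chain(tcurve, S, params$mode)
        template <- list(curve = tcurve, chain = tchain, indices = tidx)

        used_P <- tidx
        used_N <- integer(0)
        XP <- matrix(NA_real_, U, V)
        XN <- matrix(NA_real_, U, V)
        for (u in seq_len(U)) {
          pidx <- sample_from_pool(setdiff(pool_P, used_P), k,
                                   derive_seed(params$master_seed, 211, k, c, o, u))
          used_P <- c(used_P, pidx)
          pcurve <- erp_curve(xs, colMeans(mat[pidx, , drop = FALSE]))
          XP[u, ] <- shape_vector_from_curves(tcurve, tchain, pcurve, S, params$mode)

          nidx <- sample_from_pool(setdiff(pool_N, used_N), k,
                                   derive_seed(params$master_seed, 223, k, c, o, u))
          used_N <- c(used_N, nidx)
          ncurve <- erp_curve(xs, colMeans(mat[nidx, , drop = FALSE]))
          XN[u, ] <- shape_vector_from_curves(tcurve, tchain, ncurve, S, params$mode)
        }
        X <- rbind(XP, XN)
        colnames(X) <- feature_names(S)
        y <- c(rep(1, U), rep(-1, U))
        Z[o, c] <- auroc(XP[, S + 1], XN[, S + 1])
        sw <- suppressMessages(
          stepwise_select(X, y, params$p_enter, params$p_remove))
        recs[[o]] <- list(template = template, X = X, y = y, step = sw,
                          fold_P = used_P[-seq_len(params$A)], fold_N = used_N)
      }
      iter[[c]] <- recs
    }
    phi <- average_auroc(Z)
    names(phi) <- train$electrodes
    phi_history[[length(phi_history) + 1]] <-
      tibble(k = k, U = U, electrode = train$electrodes, phi = unname(phi))
    z_history[[length(z_history) + 1]] <-
      tibble(k = k,
             electrode = rep(train$electrodes, each = params$O),
             template = rep(seq_len(params$O), times = C),
             z = as.vector(Z))

    sel <- select_electrodes(phi, params$auroc_accept, params$auroc_fallback)
    snap <- snapshot_profile(sel, k, U, phi, Z, iter, train$electrodes)
    if (sel$status == "accept") {
      last_pass <- snap
    } else {
      final <- if (!is.null(last_pass)) last_pass else snap
      break
    }
  }
  if (is.null(final)) {
    final <- last_pass                       # passed all the way down to k = 1
  }
  if (is.null(final)) {
    abort("calibration could not run a single iteration (check A, K and trial counts).")
  }
  status <- if (length(final$electrodes) == 0) "unsuitable"
            else if (final$sel_status == "accept") "calibrated" else "fallback"
  structure(
    c(final,
      list(status = status,
           phi_history = dplyr::bind_rows(phi_history),
           z_history = dplyr::bind_rows(z_history),
           params = params,
           all_electrodes = train$electrodes)),
    class = "p300_calibration")
}

# Uniform draw without replacement from an integer pool, reproducible and
# shared with random_subset() so both sample identically.
sample_from_pool <- function(pool, count, seed) {
  if (count > length(pool)) {
    abort(sprintf("requested %d trials but only %d are eligible.",
                  count, length(pool)))
  }
  withr::with_seed(as.integer(seed), {
    if (count == 0) integer(0) else pool[sample.int(length(pool), count)]
  })
}

feature_names <- function(S) {
  c(paste0("a", seq_len(S - 1)), "Tsum", "d", "tort", paste0("b", seq_len(S)))
}

# Freeze the per-electrode argmax-template state of one iteration.
snapshot_profile <- function(sel, k, U, phi, Z, iter, electrodes) {
  chosen <- electrodes[sel$electrodes]
  templates <- list(); masks <- list(); weights <- list()
  features <- list(); train_blocks <- list(); o_star <- integer(0)
  for (ci in sel$electrodes) {
    o <- which.max(Z[, ci])                  # ties: lowest template index
    rec <- iter[[ci]][[o]]
    nm <- electrodes[ci]
    templates[[nm]] <- rec$template
    masks[[nm]] <- rec$step$mask
    weights[[nm]] <- rec$step$weights
    features[[nm]] <- rec$step$features
    train_blocks[[nm]] <- list(X = rec$X, y = rec$y)
    o_star[nm] <- o
  }
  list(electrodes = chosen, K_opt = k, U = U, phi = phi, Z = Z,
       sel_status = sel$status, o_star = o_star, templates = templates,
       masks = masks, weights = weights, features = features,
       train_blocks = train_blocks)
}

#' @export
print.p300_calibration <- function(x, ...) {
  cat(sprintf("<p300_calibration> status: %s\n", x$status))
  if (length(x$electrodes) > 0) {
    cat(sprintf("  electrodes: %s\n", paste(x$electrodes, collapse = ", ")))
    cat(sprintf("  optimum stimulations K' = %d (U = %d folds)\n", x$K_opt, x$U))
  }
  cat("  mean AUROC by electrode:\n")
  print(round(x$phi, 3))
  invisible(x)
}

#' Tidy a calibration profile
#'
#' @param x a `p300_calibration`.
#' @param ... unused.
#' @return A tibble with one row per electrode: mean AUROC `phi` at the
#'   returned stimulation count, whether the electrode was selected, the
#'   winning template index and its retained feature count.
#' @exportS3Method generics::tidy
tidy.p300_calibration <- function(x, ...) {
  tibble(
    electrode = x$all_electrodes,
    phi = unname(x$phi[x$all_electrodes]),
    selected = x$all_electrodes %in% x$electrodes,
    template = unname(x$o_star[x$all_electrodes]),
    n_features = vapply(x$all_electrodes, function(e) {
      if (is.null(x$masks[[e]])) NA_integer_ else sum(x$masks[[e]])
    }, integer(1))
  ) |>
    dplyr::arrange(dplyr::desc(.data$phi))
}

#' One-row summary of a calibration profile
#'
#' @param x a `p300_calibration`.
#' @param ... unused.
#' @return A one-row tibble: status, K', number of selected electrodes,
#'   best mean AUROC and the fold count U.
#' @exportS3Method generics::glance
glance.p300_calibration <- function(x, ...) {
  tibble(status = x$status,
         K_opt = if (length(x$electrodes) > 0) x$K_opt else NA_integer_,
         n_electrodes = length(x$electrodes),
         best_phi = max(x$phi),
         U = x$U)
}

#' @exportS3Method ggplot2::autoplot
autoplot.p300_calibration <- function(object, ...) {
  h <- object$phi_history
  ggplot2::ggplot(h, ggplot2::aes(x = .data$electrode, y = .data$phi,
                                  group = factor(.data$k),
                                  color = factor(.data$k))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$params$auroc_accept,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$params$auroc_fallback,
                        linetype = "dotted") +
    ggplot2::labs(x = "electrode", y = expression(phi~"(mean AUROC)"),
                  color = "stimulations k") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
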