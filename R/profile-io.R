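#' Write and read calibration profiles
#'
#' `write_profile()` stores a calibration result twice: a human-readable
#' text report at `path` (electrode names, K', template chains in the
#' space-separated chain dialect, feature masks as 0/1 strings, weights as
#' decimals, the AUROC trace) and a machine-readable JSON copy at
#' `paste0(path, ".json")` from which `read_profile()` reconstructs a
#' profile usable by [validate_profile()].
#'
#' @param profile a `p300_calibration`.
#' @param path output path for the text report.
#' @return `write_profile()` returns `path` invisibly; `read_profile()`
#'   returns a `p300_calibration`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "p300_calibration"))
  ln <- c("# P300 shape-domain calibration profile",
          sprintf("status: %s", profile$status),
          sprintf("optimum_stimulations: %s",
                  if (length(profile$electrodes) > 0) profile$K_opt else "NA"),
          sprintf("folds_U: %d", profile$U),
          sprintf("electrodes: %s", paste(profile$electrodes, collapse = " ")),
          "")
  for (e in profile$electrodes) {
    w <- profile$weights[[e]]
    ln <- c(ln,
            sprintf("[electrode %s]", e),
            sprintf("phi: %.6f", profile$phi[[e]]),
            sprintf("template_chain: %s", format(profile$templates[[e]]$chain)),
            sprintf("feature_mask: %s",
                    paste(as.integer(profile$masks[[e]]), collapse = "")),
            sprintf("weights: %s",
                    paste(sprintf("%s=%.8g", names(w), w), collapse = " ")),
            "")
  }
  ln <- c(ln, "[phi trace]",
          sprintf("k=%d U=%d %s", profile$phi_history$k, profile$phi_history$U,
                  sprintf("%s=%.4f", profile$phi_history$electrode,
                          profile$phi_history$phi)))
  writeLines(ln, path)

  js <- list(
    status = profile$status,
    K_opt = if (length(profile$electrodes) > 0) profile$K_opt else NA,
    U = profile$U,
    electrodes = profile$electrodes,
    all_electrodes = profile$all_electrodes,
    phi = as.list(profile$phi),
    o_star = as.list(profile$o_star),
    params = unclass(profile$params),
    templates = lapply(profile$templates, function(t) {
      list(chain = as.numeric(t$chain), curve_x = t$curve$x,
           curve_y = t$curve$y, indices = t$indices)
    }),
    masks = lapply(profile$masks, as.integer),
    weights = lapply(profile$weights, function(w) {
      list(names = names(w), values = as.numeric(w))
    }),
    train_blocks = lapply(profile$train_blocks, function(b) {
      list(X = b$X, y = b$y, colnames = colnames(b$X))
    }),
    phi_history = profile$phi_history,
    z_history = profile$z_history
  )
  jsonlite::write_json(js, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  jpath <- if (grepl("\\.json$", path)) path else paste0(path, ".json")
  if (!file.exists(jpath)) abort(sprintf("file not found: %s", jpath))
  js <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  pr <- js$params
  params <- calibration_params(pr$S, pr$A, pr$K, pr$O, pr$auroc_accept,
                               pr$auroc_fallback, pr$p_enter, pr$p_remove,
                               pr$max_folds, pr$master_seed, pr$mode)
  electrodes <- as.character(js$electrodes %||% character(0))
  templates <- lapply(js$templates, function(t) {
    list(curve = erp_curve(t$curve_x, t$curve_y),
         chain = shcc_chain(t$chain), indices = t$indices)
  })
  weights <- lapply(js$weights, function(w) {
    v <- as.numeric(w$values)
    names(v) <- as.character(w$names)
    v
  })
  train_blocks <- lapply(js$train_blocks, function(b) {
    X <- as.matrix(b$X)
    colnames(X) <- as.character(b$colnames)
    list(X = X, y = as.numeric(b$y))
  })
  phi <- unlist(js$phi)
  structure(
    list(electrodes = electrodes,
         K_opt = if (is.null(js$K_opt) || is.na(js$K_opt)) NA_integer_ else as.integer(js$K_opt),
         U = as.integer(js$U), phi = phi, Z = NULL,
         sel_status = js$status, o_star = unlist(js$o_star),
         templates = templates,
         masks = lapply(js$masks, function(m) as.logical(as.integer(m))),
         weights = weights, features = NULL, train_blocks = train_blocks,
         status = js$status,
         phi_history = as_tibble(js$phi_history),
         z_history = as_tibble(js$z_history),
         params = params,
         all_electrodes = as.character(js$all_electrodes)),
    class = "p300_calibration")
}
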