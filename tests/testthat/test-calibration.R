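test_that("auroc handles separation, identity and the exhaustive-count case", {
  expect_equal(auroc(c(0.1, 0.2), c(0.9, 1.0)), 1.0)
  expect_equal(auroc(c(0.3, 0.7, 0.5), c(0.3, 0.7, 0.5)), 0.5)
  # frozen from the exhaustive pairwise oracle: 6 wins, 0 ties out of 9
  expect_equal(auroc(c(0.1, 0.4, 0.6), c(0.3, 0.5, 0.7)), 6 / 9)
  expect_equal(auroc_oracle(c(0.1, 0.4, 0.6), c(0.3, 0.5, 0.7)), 6 / 9)
  expect_error(auroc(numeric(0), 1), "nonempty")
})

test_that("auroc equals the pairwise oracle and is monotone-invariant", {
  withr::with_seed(55, {
    for (i in 1:200) {
      nP <- sample(1:8, 1); nN <- sample(1:8, 1)
      # draw from a coarse grid to provoke ties
      dP <- sample(seq(0, 1, by = 0.1), nP, replace = TRUE)
      dN <- sample(seq(0, 1, by = 0.1), nN, replace = TRUE)
      a <- auroc(dP, dN)
      expect_equal(a, auroc_oracle(dP, dN))
      # invariance under a strictly monotone transform of pooled distances
      expect_equal(auroc(exp(3 * dP), exp(3 * dN)), a)
    }
  })
})

test_that("templates average the selected trials and report their indices", {
  x <- make_epochs(nP = 20, nN = 10, C = 1, T = 30, amp = 3, seed = 2)
  tpl <- build_template(x, 1, A = 8, S = 5, seed = 99)
  expect_length(tpl$indices, 8)
  expect_true(all(x$labels[tpl$indices] == "P300"))
  expect_equal(tpl$curve$y,
               coherent_average(x, 1, tpl$indices)$y)
  expect_length(tpl$chain, 5)

  # A = 1: the template is that single trial's chain
  tpl1 <- build_template(x, 1, A = 1, S = 5, seed = 4)
  expect_equal(as.numeric(tpl1$chain),
               as.numeric(encode_chain(erp_curve(1:30, x$data[tpl1$indices, 1, ]), 5)))

  # identical trials: template chain equals the waveform's chain
  arr <- array(rep(sin(seq_len(30) / 3), each = 6), c(6, 1, 30))
  same <- epoch_set(arr, rep("P300", 6), "Cz", 50, 600)
  tpl2 <- build_template(same, 1, A = 4, S = 6, seed = 1)
  expect_equal(as.numeric(tpl2$chain),
               as.numeric(encode_chain(erp_curve(1:30, arr[1, 1, ]), 6)))

  expect_error(build_template(x, 1, A = 21, S = 5, seed = 1), "eligible")
})

test_that("feature extraction is deterministic and respects exclusions", {
  x <- make_epochs(nP = 20, nN = 30, C = 1, T = 30, amp = 2, seed = 6)
  tpl <- build_template(x, 1, A = 8, S = 5, seed = 10)
  f1 <- feature_pair(tpl, x, 1, "P300", k = 3, S = 5, seed = 20,
                     exclude = tpl$indices)
  f2 <- feature_pair(tpl, x, 1, "P300", k = 3, S = 5, seed = 20,
                     exclude = tpl$indices)
  expect_identical(f1$v, f2$v)
  expect_length(f1$v, 12)                       # 2S+2 at S=5
  expect_length(intersect(f1$indices, tpl$indices), 0)

  # candidate identical to the template's own average: zero dissimilarity
  v0 <- erpshape:::shape_vector_from_curves(tpl$curve, tpl$chain, tpl$curve, 5,
                                            "angle")
  u <- unpack_vector(v0)
  expect_equal(u$area_diffs, rep(0, 4))
  expect_equal(u$area_diff_sum, 0)
  expect_equal(u$distance, 0)
})

test_that("feature vectors are 34-dimensional in the S=16 regime", {
  x <- make_epochs(nP = 12, nN = 12, C = 1, T = 204, amp = 2, seed = 8)
  tpl <- build_template(x, 1, A = 4, S = 16, seed = 1)
  fp <- feature_pair(tpl, x, 1, "NONP300", k = 2, S = 16, seed = 2)
  expect_length(fp$v, 34)
})

test_that("average_auroc is the template-wise column mean", {
  Z <- rbind(c(0.6, 1), c(0.8, 1), c(1.0, 1))
  expect_equal(average_auroc(Z), c(0.8, 1))
  withr::with_seed(2, {
    Zr <- matrix(runif(12), 3)
    expect_equal(average_auroc(Zr), apply(Zr, 2, mean))
  })
})

test_that("electrode selection applies accept, fallback and unsuitable branches", {
  s1 <- select_electrodes(c(0.9, 0.85, 0.4))
  expect_equal(s1$electrodes, c(1, 2))
  expect_true(s1$continue)

  s2 <- select_electrodes(c(0.7, 0.65, 0.5))
  expect_equal(s2$electrodes, c(1, 2))
  expect_false(s2$continue)
  expect_equal(s2$status, "fallback")

  s3 <- select_electrodes(c(0.5, 0.4))
  expect_length(s3$electrodes, 0)
  expect_equal(s3$status, "unsuitable")

  # boundary semantics: >= accept, strictly > fallback
  expect_equal(select_electrodes(c(0.8))$status, "accept")
  expect_equal(select_electrodes(c(0.6))$status, "unsuitable")
})

test_that("calibration recovers the signal electrode on a small subject", {
  x <- make_epochs(nP = 60, nN = 120, C = 3, T = 60, fs = 75,
                   amp = c(6, 0, 0), noise_sd = 1, seed = 42,
                   electrodes = c("Cz", "P3", "P4"))
  params <- calibration_params(S = 8, A = 20, K = 4, O = 3, max_folds = 8,
                               master_seed = 9)
  pr <- calibrate(x, params)
  expect_s3_class(pr, "p300_calibration")
  expect_true("Cz" %in% pr$electrodes)
  expect_gte(pr$phi[["Cz"]], 0.8)
  expect_true(all(pr$phi[c("P3", "P4")] < 0.8))
  expect_true(pr$K_opt >= 1 && pr$K_opt <= 4)

  td <- tidy(pr)
  expect_setequal(td$electrode, c("Cz", "P3", "P4"))
  expect_equal(td$electrode[1], "Cz")          # ranked by phi
  gl <- glance(pr)
  expect_equal(gl$status, "calibrated")

  # bit-reproducibility under the master seed
  pr2 <- calibrate(x, params)
  expect_identical(pr$phi_history, pr2$phi_history)
  expect_identical(lapply(pr$templates, function(t) as.numeric(t$chain)),
                   lapply(pr2$templates, function(t) as.numeric(t$chain)))
})

test_that("calibration declares a null subject unsuitable", {
  x <- make_epochs(nP = 100, nN = 200, C = 2, T = 40, amp = c(0, 0), seed = 17)
  pr <- calibrate(x, calibration_params(S = 6, A = 20, K = 4, O = 5,
                                        max_folds = 20, master_seed = 3))
  expect_equal(pr$status, "unsuitable")
  expect_length(pr$electrodes, 0)
  expect_true(all(abs(pr$phi - 0.5) < 0.25))
})

test_that("profiles round-trip through the text + JSON serialization", {
  x <- make_epochs(nP = 40, nN = 80, C = 2, T = 40, amp = c(5, 0),
                   noise_sd = 1, seed = 12, electrodes = c("Cz", "P3"))
  pr <- calibrate(x, calibration_params(S = 6, A = 12, K = 3, O = 2,
                                        max_folds = 6, master_seed = 5))
  f <- withr::local_tempfile(fileext = ".txt")
  write_profile(pr, f)
  expect_true(file.exists(f))
  expect_true(file.exists(paste0(f, ".json")))
  txt <- readLines(f)
  expect_true(any(grepl("^template_chain:", txt)))

  back <- read_profile(f)
  expect_equal(back$electrodes, pr$electrodes)
  expect_equal(back$K_opt, pr$K_opt)
  expect_equal(back$phi, pr$phi, tolerance = 1e-12)
  for (e in pr$electrodes) {
    expect_equal(as.numeric(back$templates[[e]]$chain),
                 as.numeric(pr$templates[[e]]$chain))
    expect_equal(back$masks[[e]], pr$masks[[e]])
    expect_equal(back$weights[[e]], pr$weights[[e]], tolerance = 1e-10)
    expect_equal(back$train_blocks[[e]]$X, pr$train_blocks[[e]]$X,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})
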